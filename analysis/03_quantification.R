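#!/usr/bin/env Rscript
# Step 3: peptaibiome composition and microheterogeneity. The packaged
# tables carry per-compound EIC area percentages; this step checks the
# bookkeeping (per-strain shares), builds area-weighted consensus sequences
# for the full-length families, and lists where the consensus differs from
# each strain's most produced compound.

library(peptaibr)

dir.create("results", showWarnings = FALSE)

sf1 <- read_compound_table(peptaibr_example("sf1_peptaibols_viride.tsv"))

# per-strain peptaibol share recovered by summing the printed per-compound
# peptaibiome percentages
shares <- stats::aggregate(pct_peptaibiome ~ strain, sf1, sum)
names(shares)[2] <- "peptaibol_share_recovered"
utils::write.table(shares, "results/03_peptaibol_shares.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("Recovered per-strain peptaibol shares (% of peptaibiome):\n")
print(shares)

# consensus vs most-produced per family (full-length members only)
families <- list(
  `Strigaibol-like` = "^Strigaibol-like",
  `Trikoningin KA-like` = "^Trikoningin KA-like",
  `Trichorzianin TA-like` = "^Trichorzianin TA-like",
  `Tricholongin LB-like` = "^Tricholongin LB-like",
  `Dorothopsin B` = "^Dorothopsin B"
)
rows <- list()
for (fam in names(families)) {
  sel <- sf1[grepl(families[[fam]], sf1$name), ]
  full <- vapply(sel$model, function(m) !is.null(m$terminus) &&
                   seq_length(m) == 19L, logical(1))
  sel <- sel[full, ]
  cs <- consensus_sequence(sel$model, mode = "unweighted")
  dv <- consensus_vs_top(sel$model, sel$pct_class)
  top <- sel$name[which.max(sel$pct_class)]
  rows[[fam]] <- data.frame(
    family = fam, n = nrow(sel), most_produced = top,
    consensus = sequence_string(cs$consensus),
    differs_at = if (nrow(dv)) paste(
      sprintf("%d (%s vs %s)", dv$position, dv$consensus_token, dv$top_token),
      collapse = "; ") else "",
    stringsAsFactors = FALSE)
}
cons <- do.call(rbind, rows)
utils::write.table(cons, "results/03_consensus.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("\nConsensus vs most-produced compound:\n")
for (i in seq_len(nrow(cons))) {
  cat(sprintf("  %-22s n=%2d top=%s%s\n", cons$family[i], cons$n[i],
              cons$most_produced[i],
              if (nzchar(cons$differs_at[i]))
                paste0("  consensus differs at ", cons$differs_at[i]) else ""))
}
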