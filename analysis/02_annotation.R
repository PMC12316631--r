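#!/usr/bin/env Rscript
# Step 2: novelty annotation. Every full-length 19-residue Strigaibol-family
# compound is compared against the curated reference database
# (minimal-substitution matching with Lxx/Vxx ambiguity), and the shortened
# Dorothopsin A variants are aligned to their 19-residue template to place
# the skipped NRPS modules.

library(peptaibr)

dir.create("results", showWarnings = FALSE)

db <- read_reference_db(peptaibr_example("reference_peptaibiotics.tsv"))
sf1 <- read_compound_table(peptaibr_example("sf1_peptaibols_viride.tsv"))

strig <- sf1[grepl("^Strigaibol-like", sf1$name), ]
rows <- lapply(seq_len(nrow(strig)), function(i) {
  nr <- nearest_reference(strig$model[[i]], db)
  nms <- vapply(nr$matches, `[[`, character(1), "name")
  subs <- vapply(nr$matches,
                 function(m) substitution_notation(m$substitutions),
                 character(1))
  data.frame(name = strig$name[i], status = nr$status,
             distance = nr$distance,
             nearest = paste(nms, collapse = " / "),
             substitutions = paste(unique(subs), collapse = " / "),
             stringsAsFactors = FALSE)
})
ann <- do.call(rbind, rows)
utils::write.table(ann, "results/02_strigaibol_annotation.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat(sprintf("Strigaibol family: %d known, %d new (of %d)\n",
            sum(ann$status == "known"), sum(ann$status == "new"), nrow(ann)))

# module-skip alignment of the 16-18-residue Dorothopsin A variants against
# the most produced 19-residue family member
template <- sf1$model[[match("Dorothopsin A-a VII", sf1$name)]]
shorts <- sf1[grepl("^Dorothopsin A-[b-f]", sf1$name), ]
strip_gaps <- function(x) peptaibol(x$cap, x$residues[!is.na(x$residues)],
                                    terminus = x$terminus, label = x$label)
skips <- lapply(seq_len(nrow(shorts)), function(i) {
  m <- shorts$model[[i]]
  if (is.null(m$terminus)) return(NULL)
  al <- skip_alignment(strip_gaps(m), template)
  data.frame(name = shorts$name[i], deficit = al$deficit,
             gaps = paste(al$solutions[[1]]$gaps, collapse = ","),
             n_substitutions = al$solutions[[1]]$n_substitutions,
             aligned = sequence_string(al$aligned),
             stringsAsFactors = FALSE)
})
skips <- do.call(rbind, skips)
utils::write.table(skips, "results/02_module_skips.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("Module-skip placements (gap positions in the 19-residue frame):\n")
print(stats::aggregate(name ~ gaps, skips, length))
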