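test_that("compounds classify by cap and length", {
  short <- parse_peptaibol("Oc-Aib-Gly-Lxx-Aib-Gly-Lxx-Lxxol")
  expect_identical(classify_compound(short),
                   list(class = "lipopeptaibol", length_class = "short"))
  long <- parse_peptaibol(
    "Oc-Aib-Gly-Lxx-Aib-Gly-Gly-Lxx-Aib-Gly-Gly-Lxx-Aib-Gly-Lxx-Lxxol")
  expect_identical(classify_compound(long)$length_class, "long")
  pep <- parse_peptaibol(paste0(
    "Ac-Vxx-Ser-Aib-Aib-Lxx-Gln-Aib-Aib-Aib-Ser-Lxx-Aib-Pro-Vxx-Aib-Aib-",
    "Gln-Gln-Lxxol"))
  expect_identical(classify_compound(pep),
                   list(class = "peptaibol", length_class = NA_character_))
  odd <- peptaibol("Oc", rep("Gly", 8), terminus = "Lxxol")
  expect_warning(cl <- classify_compound(odd), "outside")
  expect_identical(cl$length_class, "other")
})

test_that("a single compound gets 100% everywhere", {
  rec <- data.frame(compound = "only", strain = "s1", class = "peptaibol",
                    area = 5)
  out <- peptaibiome_percentages(rec)
  expect_equal(out$compounds$pct_class, 100)
  expect_equal(out$compounds$pct_peptaibiome, 100)
  expect_equal(out$strains$pct_peptaibol, 100)
})

test_that("percentages conserve mass exactly before rounding", {
  set.seed(5)
  n <- 50
  rec <- data.frame(
    compound = paste0("c", 1:n),
    strain = rep(c("s1", "s2"), length.out = n),
    class = sample(c("peptaibol", "lipopeptaibol"), n, replace = TRUE),
    length_class = sample(c("short", "medium", "long"), n, replace = TRUE),
    area = rlnorm(n, 0, 1.5)
  )
  rec$length_class[rec$class == "peptaibol"] <- NA
  out <- peptaibiome_percentages(rec)
  for (s in unique(rec$strain)) {
    st <- out$strains[out$strains$strain == s, ]
    expect_equal(st$pct_peptaibol + st$pct_short_lipo + st$pct_medium_lipo +
                   st$pct_long_lipo + st$pct_other_lipo, 100,
                 tolerance = 1e-9)
    comp <- out$compounds[out$compounds$strain == s, ]
    expect_equal(sum(comp$pct_peptaibiome), 100, tolerance = 1e-9)
    for (cl in unique(comp$class)) {
      expect_equal(sum(comp$pct_class[comp$class == cl]), 100,
                   tolerance = 1e-9)
    }
  }
  # scale invariance
  rec2 <- rec
  rec2$area <- rec2$area * 1e4
  out2 <- peptaibiome_percentages(rec2)
  expect_equal(out2$compounds$pct_peptaibiome, out$compounds$pct_peptaibiome)
  expect_error(peptaibiome_percentages(
    data.frame(compound = "a", strain = "s", class = "peptaibol", area = 0)),
    "undefined")
})

test_that("printed peptaibiome and class percentages cross-check via the class share", {
  # for every compound of one strain, peptaibiome% / class% must equal the
  # strain's peptaibol share of the whole peptaibiome
  tab <- utils::read.delim(fixture_path("sf1_peptaibols_viride.tsv"))
  ham <- tab[tab$strain == "SZMC 28747", ]
  expect_equal(nrow(ham), 21L)
  ratio <- ham$pct_peptaibiome / ham$pct_class
  expect_equal(mean(ratio), 0.2362, tolerance = 0.01)
})

test_that("family consensus can differ from the most-produced compound", {
  # family where the top producer carries a minority residue at one position
  base <- "Ac-Aib-Gly-Ala-Aib-Lxx-Gln-Aib-Aib-Aib-Ser-Lxx-Aib-Pro-Vxx-Aib-Lxx-%s-Gln-Lxxol"
  seqs <- parse_peptaibol(c(sprintf(base, "Glu"),    # top producer has Glu17
                            sprintf(base, "Gln"),
                            sprintf(base, "Gln"),
                            sprintf(base, "Gln")))
  w <- c(10, 4, 4, 3)
  cs <- consensus_sequence(seqs, mode = "unweighted")
  expect_identical(cs$consensus$residues[17], "Gln")
  dv <- consensus_vs_top(seqs, w)
  expect_true(17 %in% dv$position)
  expect_identical(dv$consensus_token[dv$position == 17], "Gln")
  expect_identical(dv$top_token[dv$position == 17], "Glu")
})

test_that("consensus handles identity, weighting, ties and idempotence", {
  s <- "Oc-Aib-Gly-Lxx-Aib-Gly-Lxx-Lxxol"
  same <- parse_peptaibol(rep(s, 3))
  cs <- consensus_sequence(same, c(1, 2, 3))
  expect_identical(sequence_string(cs$consensus), s)
  expect_length(cs$ties, 0L)

  # heavier token wins two-to-one
  a <- parse_peptaibol("Oc-Aib-Gly-Lxx-Aib-Gly-Lxx-Lxxol")
  b <- parse_peptaibol("Oc-Vxx-Gly-Lxx-Aib-Gly-Lxx-Lxxol")
  cs2 <- consensus_sequence(list(a, a, b), c(2, 2, 1) / 5)
  expect_identical(cs2$consensus$residues[1], "Aib")
  cs3 <- consensus_sequence(list(a, b), c(1, 1))
  expect_true(1L %in% (cs3$ties - 1L) || length(cs3$ties) > 0)  # tie flagged
  expect_identical(cs3$consensus$residues[1], "Aib")  # alphabetical break

  # equal weights equal the unweighted mode
  cs_w <- consensus_sequence(list(a, a, b), rep(2, 3))
  cs_u <- consensus_sequence(list(a, a, b), mode = "unweighted")
  expect_identical(sequence_string(cs_w$consensus),
                   sequence_string(cs_u$consensus))

  # idempotence
  cs4 <- consensus_sequence(list(cs2$consensus), 1)
  expect_identical(sequence_string(cs4$consensus),
                   sequence_string(cs2$consensus))

  expect_error(consensus_sequence(list(), NULL), "length")
  expect_error(consensus_sequence(list(a, parse_peptaibol("Oc-Aib-Gly-Lxx-Lxxol"))),
               "equal-length")
})

test_that("consensus positions differing from the top producer match brute force", {
  set.seed(13)
  toks <- c("Aib", "Gly", "Lxx", "Vxx")
  mk <- function() peptaibol("Oc", sample(toks, 6, replace = TRUE),
                             terminus = "Lxxol")
  seqs <- list(mk(), mk(), mk())
  w <- c(5, 3, 3)
  dv <- consensus_vs_top(seqs, w)
  cons <- consensus_sequence(seqs, mode = "unweighted")$consensus
  top <- seqs[[1]]
  pos_all <- seq_len(7)
  brute <- pos_all[c(cons$residues, cons$terminus) != c(top$residues, top$terminus)]
  expect_identical(dv$position, brute)
})

test_that("display rounding is half-up at 2 decimals", {
  expect_equal(round_pct(0.005), 0.01)
  expect_equal(round_pct(23.624999), 23.62)
  expect_equal(round_pct(29.085), 29.09)
})
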