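test_that("residue masses follow from elemental composition", {
  expect_equal(residue_mass("Gly"), 57.02146, tolerance = 1e-5)
  expect_equal(residue_mass("Aib"), 85.05276, tolerance = 1e-5)
  expect_equal(residue_mass("Lxxol"), 117.11536, tolerance = 1e-5)
  expect_error(residue_mass("Xyz"), "Xyz")
})

test_that("isobaric ambiguity members share a mass and a canonical code", {
  lib <- residue_library()
  expect_equal(residue_mass("Leu"), residue_mass("Ile"))
  expect_equal(residue_mass("Leu"), residue_mass("Lxx"))
  expect_equal(residue_mass("Val"), residue_mass("Iva"))
  expect_identical(canonical_token(c("Leu", "Ile", "Val", "Iva", "Leuol")),
                   c("Lxx", "Lxx", "Vxx", "Vxx", "Lxxol"))
  expect_true(all(lib$mono_mass > 0))
  expect_false(anyDuplicated(lib$token) > 0)
})

test_that("near-isobaric residues are documented as resolvable", {
  # Gln/Glu and Gln/Lys gaps drive the disambiguation rules; Lys itself is
  # excluded from the library (not observed in peptaibols)
  lys_residue <- 128.09496
  expect_lt(abs(abs(residue_mass("Gln") - residue_mass("Glu")) - 0.98402), 1e-4)
  expect_lt(abs(abs(residue_mass("Gln") - lys_residue) - 0.03639), 1e-4)
  expect_false("Lys" %in% residue_library()$token)
})

test_that("neutral mass matches the token-sum oracle", {
  toks <- c("Oc", "Aib", "Gly", "Lxx", "Aib", "Gly", "Lxx", "Lxxol")
  p <- parse_peptaibol(paste(toks, collapse = "-"))
  expect_equal(neutral_mass(p), oracle_neutral(toks), tolerance = 1e-3)
  expect_equal(neutral_mass(p), 753.536, tolerance = 1e-3)

  # degenerate chain: cap + amino alcohol only
  p0 <- peptaibol("Ac", character(0), terminus = "Lxxol")
  expect_equal(neutral_mass(p0), 42.01057 + 117.11536, tolerance = 1e-5)

  # 19-residue SF1 model
  xii <- parse_peptaibol(paste0(
    "Ac-Vxx-Ser-Aib-Aib-Lxx-Gln-Aib-Aib-Aib-Ser-Lxx-Aib-Pro-Vxx-Aib-Aib-",
    "Gln-Gln-Lxxol"))
  expect_equal(neutral_mass(xii),
               oracle_neutral(strsplit(sequence_string(xii), "-")[[1]]),
               tolerance = 2e-3)
  expect_equal(neutral_mass(xii), 1919.146, tolerance = 2e-3)
})

test_that("neutral mass is undefined for residual-mass termini", {
  p <- parse_peptaibol("Ac-Aib-Gln-146")
  expect_null(p$terminus)
  expect_equal(p$residual_mass, 146)
  expect_error(neutral_mass(p), "unresolved")
})

test_that("adduct m/z arithmetic is exact", {
  p <- parse_peptaibol("Oc-Aib-Gly-Lxx-Aib-Gly-Lxx-Lxxol")
  expect_equal(mh_plus(p), adduct_mz(p, "M+H", 1))
  expect_equal(adduct_mz(p, "M+2H", 2), (mh_plus(p) + 1.007276) / 2,
               tolerance = 1e-9)
  expect_equal(adduct_mz(p, "M+Na", 1), 776.526, tolerance = 2e-3)
  xii <- parse_peptaibol(paste0(
    "Ac-Vxx-Ser-Aib-Aib-Lxx-Gln-Aib-Aib-Aib-Ser-Lxx-Aib-Pro-Vxx-Aib-Aib-",
    "Gln-Gln-Lxxol"))
  expect_equal(adduct_mz(xii, "M+2H", 2), 960.580, tolerance = 2e-3)
  expect_error(adduct_mz(p, "M+2H", 1), "charge")
  expect_error(adduct_mz(p, "M+Na", 2), "charge")
})

test_that("gap markers contribute no mass anywhere", {
  base <- c("Aib", "Gly", "Lxx", "Aib", "Gly", "Lxx")
  p <- peptaibol("Oc", base, terminus = "Lxxol")
  for (at in 0:length(base)) {
    with_gap <- append(base, NA_character_, after = at)
    expect_equal(neutral_mass(peptaibol("Oc", with_gap, terminus = "Lxxol")),
                 neutral_mass(p))
  }
})

test_that("neutral mass is permutation invariant in the residue multiset", {
  set.seed(42)
  toks <- c("Aib", "Ser", "Lxx", "Gln", "Pro", "Vxx", "Gly", "Phe")
  p1 <- peptaibol("Ac", toks, terminus = "Lxxol")
  for (i in 1:5) {
    p2 <- peptaibol("Ac", sample(toks), terminus = "Lxxol")
    expect_equal(neutral_mass(p2), neutral_mass(p1))
  }
})

test_that("sequence strings round-trip through the parser", {
  strs <- c(
    "Oc-Aib-Gly-Lxx-Aib-Gly-Lxx-Lxxol",
    "Ac-Aib-Ala-Aib-Aib-Lxx-Gln-Aib-Aib-(skip)-Ser-Lxx-Aib-Pro-Vxx-Aib-Lxx-Glu-Ala-Alaol",
    "Ac-Aib-Gln-146"
  )
  for (s in strs) expect_identical(sequence_string(parse_peptaibol(s)), s)
})

test_that("residue library is extensible without code changes", {
  extra <- data.frame(token = "Hyp", class = "internal", mono_mass = 113.04768)
  lib <- residue_library(extra = extra)
  expect_equal(residue_mass("Hyp", lib), 113.04768)
  expect_error(residue_library(extra = data.frame(
    token = "Aib", class = "internal", mono_mass = 1)), "already defined")
})

test_that("sequence model validates its parts", {
  expect_error(peptaibol("Aib", "Gly", terminus = "Lxxol"), "acyl cap")
  expect_error(peptaibol("Ac", "Lxxol", terminus = "Lxxol"), "internal")
  expect_error(peptaibol("Ac", "Gly", terminus = "Gln"), "amino alcohol")
  expect_error(peptaibol("Ac", "Gly"), "exactly one")
  expect_error(peptaibol("Ac", "Gly", terminus = "Lxxol", residual_mass = 1),
               "exactly one")
})

test_that("residue counting includes the terminus and skips gaps", {
  p <- parse_peptaibol("Ac-Aib-Ala-Aib-Aib-Lxx-Gln-Aib-Aib-(skip)-Ser-Lxx-Aib-Pro-Vxx-Aib-Lxx-Glu-Ala-Alaol")
  expect_equal(seq_length(p), 18L)  # 17 internal + alcohol
  full <- parse_peptaibol("Oc-Aib-Gly-Lxx-Aib-Gly-Lxx-Lxxol")
  expect_equal(seq_length(full), 7L)
})
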