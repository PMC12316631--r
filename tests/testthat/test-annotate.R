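ref_db <- read_reference_db(fixture_path("reference_peptaibiotics.tsv"))

seq_xii <- paste0(
  "Ac-Vxx-Ser-Aib-Aib-Lxx-Gln-Aib-Aib-Aib-Ser-Lxx-Aib-Pro-Vxx-Aib-Aib-",
  "Gln-Gln-Lxxol")
seq_v <- sub("^Ac-Vxx", "Ac-Aib", seq_xii)

test_that("nearest reference finds minimal-substitution matches", {
  nr <- nearest_reference(parse_peptaibol(seq_xii), ref_db)
  expect_equal(nr$distance, 1L)
  expect_identical(nr$status, "new")
  nms <- vapply(nr$matches, `[[`, character(1), "name")
  expect_true("Strigaibol C" %in% nms)
  expect_identical(nms, sort(nms))  # alphabetical display order
  hit <- nr$matches[[which(nms == "Strigaibol C")]]
  expect_identical(substitution_notation(hit$substitutions),
                   "[Aib]^1 → [Vxx]^1")
})

test_that("identity gives distance zero and status known", {
  nr <- nearest_reference(parse_peptaibol(seq_v), ref_db)
  expect_equal(nr$distance, 0L)
  expect_identical(nr$status, "known")
  expect_true("Strigaibol B" %in% vapply(nr$matches, `[[`, character(1), "name"))
  expect_equal(nrow(nr$matches[[1]]$substitutions), 0L)

  # any sequence vs a db containing itself
  self_db <- ref_db[ref_db$name == "Trikoningin KA V", ]
  nr2 <- nearest_reference(self_db$model[[1]], self_db)
  expect_equal(nr2$distance, 0L)
})

test_that("max_dist filters matches", {
  far <- parse_peptaibol(
    "Ac-Phe-Gly-Gly-Phe-Gly-Gly-Phe-Gly-Gly-Phe-Gly-Gly-Pro-Phe-Gly-Gly-Phe-Gly-Pheol")
  nr <- nearest_reference(far, ref_db, max_dist = 3)
  expect_length(nr$matches, 0L)
  expect_identical(nr$status, "new")
})

test_that("substitution notation lists ascending positions joined by semicolons", {
  b <- parse_peptaibol(seq_v)  # Strigaibol B sequence
  obs <- parse_peptaibol(paste0(
    "Ac-Vxx-Ser-Aib-Aib-Lxx-Gln-Aib-Ala-Aib-Ser-Lxx-Aib-Pro-Vxx-Aib-Aib-",
    "Gln-Gln-Lxxol"))
  expect_identical(substitution_notation(b, obs),
                   "[Aib]^1 → [Vxx]^1; [Aib]^8 → [Ala]^8")
  expect_identical(substitution_notation(b, b), "")

  # three differences, positions ascending whatever the input order
  obs3 <- parse_peptaibol(paste0(
    "Ac-Vxx-Ser-Aib-Aib-Lxx-Gln-Aib-Ala-Aib-Ser-Lxx-Aib-Pro-Vxx-Aib-Aib-",
    "Gln-Gln-Vxxol"))
  out <- substitution_notation(b, obs3)
  expect_length(strsplit(out, "; ")[[1]], 3L)
  pos <- as.integer(gsub("\\D+", " ", out) |> trimws() |>
                      strsplit(" +") |> unlist())
  expect_identical(pos, sort(pos))
  expect_error(substitution_notation(b, parse_peptaibol("Oc-Aib-Gly-Lxx-Lxxol")),
               "skip_alignment")
})

test_that("compositional (swap) isomers are flagged from the token multiset", {
  a <- peptaibol("Ac", c("Aib", "Phe", "Gly"), terminus = "Lxxol")
  b <- peptaibol("Ac", c("Phe", "Aib", "Gly"), terminus = "Lxxol")
  c_ <- peptaibol("Ac", c("Aib", "Aib", "Gly"), terminus = "Lxxol")
  expect_true(is_compositional_isomer(a, b))
  expect_false(is_compositional_isomer(a, a))
  expect_false(is_compositional_isomer(a, c_))
})

test_that("module-skip alignment reproduces published gap placements", {
  template <- parse_peptaibol(paste0(
    "Ac-Aib-Ala-Aib-Aib-Lxx-Gln-Aib-Aib-Aib-Ser-Lxx-Aib-Pro-Vxx-Aib-Lxx-",
    "Gln-Gln-Vxxol"))
  # 18-residue variant: one skipped module inside the Aib run, annotated at
  # the last position of the run
  ab1 <- parse_peptaibol(paste0(
    "Ac-Aib-Ala-Aib-Aib-Lxx-Gln-Aib-Aib-Ser-Lxx-Aib-Pro-Vxx-Aib-Lxx-Glu-",
    "Ala-Alaol"))
  al <- skip_alignment(ab1, template)
  expect_equal(al$deficit, 1L)
  expect_equal(al$solutions[[1]]$gaps, 9L)
  expect_match(sequence_string(al$aligned), "Aib-Aib-\\(skip\\)-Ser")

  # 16-residue variant: three skipped modules at 9, 16, 17
  ae1 <- parse_peptaibol(paste0(
    "Ac-Aib-Ala-Aib-Aib-Lxx-Gln-Aib-Aib-Ser-Lxx-Aib-Pro-Vxx-Aib-Gly-Alaol"))
  al3 <- skip_alignment(ae1, template)
  expect_equal(al3$deficit, 3L)
  expect_equal(al3$solutions[[1]]$gaps, c(9L, 16L, 17L))
})

test_that("template minus its last residue aligns with a final-position gap", {
  template <- parse_peptaibol(paste0(
    "Ac-Aib-Ala-Aib-Aib-Lxx-Gln-Aib-Aib-Aib-Ser-Lxx-Aib-Pro-Vxx-Aib-Lxx-",
    "Gln-Gln-Vxxol"))
  short <- peptaibol("Ac", template$residues[-18], terminus = "Vxxol")
  al <- skip_alignment(short, template)
  gaps <- lapply(al$solutions, `[[`, "gaps")
  expect_true(18L %in% unlist(gaps))
  expect_equal(al$solutions[[1]]$gaps, 18L)  # canonical = rightmost in run
})

test_that("skip alignment equals exhaustive enumeration for deficits 1-3", {
  set.seed(7)
  toks <- c("Aib", "Gly", "Ala", "Ser", "Lxx", "Vxx", "Gln", "Pro")
  for (deficit in 1:3) {
    for (rep in 1:5) {
      t_res <- sample(toks, 18, replace = TRUE)
      template <- peptaibol("Ac", t_res, terminus = "Lxxol")
      drop <- sort(sample(18, deficit))
      s_res <- t_res[-drop]
      # sprinkle a substitution
      s_res[1] <- if (s_res[1] == "Aib") "Gly" else "Aib"
      short <- peptaibol("Ac", s_res, terminus = "Lxxol")
      al <- skip_alignment(short, template)
      got <- lapply(al$solutions, `[[`, "gaps")
      want <- oracle_min_gap_solutions(
        c(canonical_token(s_res), "Lxxol"),
        c(canonical_token(t_res), "Lxxol"))
      norm <- function(l) sort(vapply(l, paste, character(1), collapse = ","))
      expect_identical(norm(got), norm(want))
    }
  }
})

test_that("oversized deficits are refused", {
  template <- peptaibol("Ac", rep("Aib", 18), terminus = "Lxxol")
  short <- peptaibol("Ac", rep("Aib", 10), terminus = "Lxxol")
  expect_error(skip_alignment(short, template), "max_skips")
})

test_that("substitution distance behaves like a metric on equal lengths", {
  set.seed(21)
  toks <- c("Aib", "Gly", "Ala", "Lxx", "Vxx", "Gln")
  mk <- function() peptaibol("Ac", sample(toks, 10, replace = TRUE),
                             terminus = "Lxxol")
  for (i in 1:10) {
    a <- mk(); b <- mk()
    db_a <- data.frame(name = "a", stringsAsFactors = FALSE)
    db_a$model <- list(a)
    db_b <- data.frame(name = "b", stringsAsFactors = FALSE)
    db_b$model <- list(b)
    d_ab <- nearest_reference(a, db_b)$distance
    d_ba <- nearest_reference(b, db_a)$distance
    expect_identical(d_ab, d_ba)                       # symmetry
    expect_identical(nearest_reference(a, db_a)$distance, 0L)  # identity
    if (d_ab == 0L) {
      expect_identical(sequence_string(a), sequence_string(b))
    }
  }
})

test_that("roman-numeral names follow elution order", {
  expect_identical(assign_names(c(6.57, 7.23, 9.3, 10.54), "Lipostrigosellin"),
                   paste("Lipostrigosellin", c("I", "II", "III", "IV")))
  expect_identical(assign_names(5, "Dorothopsin"), "Dorothopsin I")
  # scrambled input maps back to rt order
  expect_identical(assign_names(c(9.3, 6.57, 10.54, 7.23), "X"),
                   paste("X", c("III", "I", "IV", "II")))
  # numeral correctness at 40 against R's own roman converter
  nm <- assign_names(seq_len(40) + 0.5, "S")
  expect_identical(nm[40], "S XL")
  expect_identical(sub("^S ", "", nm), as.character(utils::as.roman(1:40)))
  expect_warning(assign_names(c(1, 1), "S"), "duplicate")
})
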