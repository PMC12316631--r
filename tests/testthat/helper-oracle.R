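# Independent mass oracle for the tests: residue masses restated from atomic
# composition (H 1.00782503, C 12, N 14.00307401, O 15.99491462) and summed
# by hand-check arithmetic, independent of the package's library/summation
# code paths.

oracle_masses <- c(
  Gly = 57.02146, Ala = 71.03711, Ser = 87.03203, Pro = 97.05276,
  Aib = 85.05276, Vxx = 99.06841, Lxx = 113.08406, Gln = 128.05858,
  Glu = 129.04259, Phe = 147.06841, Trp = 186.07931, Tyr = 163.06333,
  Lxxol = 117.11536, Vxxol = 103.09971, Pheol = 151.09971,
  Trpol = 190.11061, Alaol = 75.06841, Glyol = 61.05276,
  Ac = 42.01057, Oc = 126.10446
)
ORACLE_PROTON <- 1.007276

# neutral mass by direct token-sum (gaps and the oracle's own bookkeeping)
oracle_neutral <- function(tokens) {
  tokens <- tokens[tokens != "(skip)"]
  sum(oracle_masses[tokens])
}

# cumulative b/y ladders by direct cumsum over a token vector
oracle_b_ladder <- function(cap, residues) {
  unname(oracle_masses[cap] + cumsum(oracle_masses[residues]) + ORACLE_PROTON)
}
oracle_y_ladder <- function(residues, alcohol) {
  unname(oracle_masses[alcohol] +
           rev(cumsum(rev(c(oracle_masses[residues][-1], 0)))) + ORACLE_PROTON)
}

# exhaustive gap-placement enumeration (recursive, structured differently
# from the package's combn-based search)
oracle_min_gap_solutions <- function(short, template) {
  n_t <- length(template)
  deficit <- n_t - length(short)
  place <- function(remaining, start) {
    if (remaining == 0L) return(list(integer()))
    if (start > n_t - 1L) return(list())
    out <- list()
    for (g in start:(n_t - 1L)) {
      for (rest in place(remaining - 1L, g + 1L)) {
        out[[length(out) + 1L]] <- c(g, rest)
      }
    }
    out
  }
  placements <- place(deficit, 1L)
  subs <- vapply(placements, function(g) {
    keep <- setdiff(seq_len(n_t), g)
    sum(template[keep] != short)
  }, numeric(1))
  placements[subs == min(subs)]
}

fixture_path <- function(file) {
  system.file("extdata", file, package = "peptaibr", mustWork = TRUE)
}
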