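# Seeded generator of ground-truthed peptaibiomes: sequences with
# position-specific microheterogeneity, log-normal abundances, and synthetic
# MS2 spectra with ppm-scale mass error and decoy peaks.

# run expr under a deterministic substream derived from (seed, counter), so
# per-compound outputs do not depend on the order of generation
.with_substream <- function(seed, counter, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed((as.numeric(seed) * 1000003 + counter) %% 2147483647)
  expr
}

#' Family template for the long SF1 peptaibols
#'
#' Position-specific token alphabets with probabilities, emulating the
#' microheterogeneity of the 19-residue subfamily-1 peptaibols: the conserved
#' Gln6-Aib7-Aib8-Aib9-Ser10-Lxx11-Aib12-Pro13-Vxx14 core is fixed
#' (probability 1), the flanking positions vary the way co-produced variants
#' of one family do, and module skipping is allowed at the positions where
#' shortened variants have been observed (9, 16, 17).
#'
#' @param skip_probability Per-compound probability of one module-skip event.
#' @return A template list (`name`, `cap`, `positions`, `terminus`,
#'   `skip_probability`, `skip_positions`).
#' @export
sf1_template <- function(skip_probability = 0.05) {
  list(
    name = "SF1",
    cap = "Ac",
    positions = list(
      c(Aib = 0.7, Vxx = 0.3),                 # R1
      c(Ser = 0.4, Ala = 0.4, Gly = 0.2),      # R2
      c(Aib = 0.6, Ala = 0.2, Phe = 0.2),      # R3
      c(Aib = 1),                              # R4
      c(Lxx = 0.6, Vxx = 0.3, Aib = 0.1),      # R5
      c(Gln = 1), c(Aib = 1), c(Aib = 1), c(Aib = 1),  # R6-R9 core
      c(Ser = 1), c(Lxx = 1), c(Aib = 1), c(Pro = 1), c(Vxx = 1),  # R10-R14
      c(Aib = 1),                              # R15
      c(Aib = 0.5, Lxx = 0.25, Vxx = 0.25),    # R16
      c(Gln = 0.8, Glu = 0.2),                 # R17
      c(Gln = 0.9, Ala = 0.1)                  # R18
    ),
    terminus = c(Lxxol = 0.6, Vxxol = 0.3, Pheol = 0.1),
    skip_probability = skip_probability,
    skip_positions = c(9L, 16L, 17L)
  )
}

#' Family template for octanoyl-capped lipopeptaibols
#'
#' Short (7), medium (11) and long (15 residue) lipopeptaibol families built
#' on the repetitive Lxx/Vxx-Aib-Gly motif with Gly spacers, octanoyl cap
#' and leucinol/valinol terminus - the composition pattern of trichogin- and
#' lipostrigocin-type compounds.
#'
#' @param length_class `"short"`, `"medium"` or `"long"` (7, 11, 15
#'   residues including the amino alcohol).
#' @return A template list as in [sf1_template()].
#' @export
lipopeptaibol_template <- function(length_class = c("short", "medium", "long")) {
  length_class <- match.arg(length_class)
  vl <- c(Lxx = 0.5, Vxx = 0.5)
  pos <- switch(length_class,
    short = list(c(Aib = 0.8, Ala = 0.2), c(Gly = 1), vl,
                 c(Aib = 0.8, Vxx = 0.2), c(Gly = 0.8, Ala = 0.2), vl),
    medium = list(c(Aib = 0.6, Ala = 0.2, Vxx = 0.2), c(Gly = 1), vl,
                  c(Aib = 0.8, Ala = 0.2), c(Gly = 1), c(Gly = 1), vl,
                  c(Aib = 1), c(Gly = 1), vl),
    long = list(c(Aib = 0.7, Vxx = 0.3), c(Gly = 1), vl, c(Aib = 1),
                c(Gly = 0.9, Ala = 0.1), c(Gly = 1), vl, c(Aib = 1),
                c(Gly = 1), c(Gly = 1), vl, c(Aib = 1), c(Gly = 1), vl)
  )
  list(
    name = paste0("lipopeptaibol_", length_class),
    cap = "Oc",
    positions = pos,
    terminus = c(Lxxol = 0.8, Vxxol = 0.2),
    skip_probability = 0,
    skip_positions = integer()
  )
}

.draw_token <- function(alphabet, substitution_rate = NULL) {
  toks <- names(alphabet)
  if (length(toks) == 1L) return(toks)
  p <- alphabet / sum(alphabet)
  if (!is.null(substitution_rate)) {
    modal <- toks[which.max(p)]
    if (stats::runif(1) >= substitution_rate) return(modal)
    alt <- p[names(p) != modal]
    return(sample(names(alt), 1L, prob = alt))
  }
  sample(toks, 1L, prob = p)
}

#' Simulate a family of co-produced compounds
#'
#' Draws `n` sequences from a family template, each with a log-normal
#' abundance and a distinct retention time. Deterministic under `seed` and
#' independent of generation order (each compound uses a counter-derived
#' substream).
#'
#' @param template Template from [sf1_template()] or
#'   [lipopeptaibol_template()].
#' @param n Number of compounds.
#' @param seed Integer seed (mandatory for reproducibility).
#' @param substitution_rate If given, overrides the template probabilities:
#'   at every position that has alternatives, the modal token is replaced
#'   with probability `substitution_rate` (0 gives the modal sequence
#'   everywhere).
#' @param abundance_meanlog,abundance_sdlog Log-normal abundance model.
#' @param rt_range Retention-time window in minutes.
#' @return List of records, each with `model` (a `peptaibol`), `abundance`
#'   and `rt`.
#' @export
simulate_compounds <- function(template, n, seed,
                               substitution_rate = NULL,
                               abundance_meanlog = 0, abundance_sdlog = 1.5,
                               rt_range = c(20, 45)) {
  stopifnot(n >= 1L, !missing(seed))
  if (!length(template$positions) ||
      any(!lengths(template$positions))) stop("degenerate template")
  lapply(seq_len(n), function(i) {
    .with_substream(seed, i, {
      res <- vapply(template$positions, .draw_token, character(1),
                    substitution_rate = substitution_rate)
      if (length(template$skip_positions) &&
          stats::runif(1) < template$skip_probability) {
        res[sample(template$skip_positions, 1L)] <- NA_character_
      }
      term <- .draw_token(template$terminus, substitution_rate)
      abundance <- stats::rlnorm(1, abundance_meanlog, abundance_sdlog)
      rt <- stats::runif(1, rt_range[1], rt_range[2])
      list(model = peptaibol(template$cap, res, terminus = term,
                             label = sprintf("%s_%03d", template$name, i),
                             rt = rt),
           abundance = abundance, rt = rt)
    })
  })
}

#' Simulate an MS2 spectrum with ground truth
#'
#' Emits the theoretical fragment peaks of a compound (b and/or y ladders,
#' for y including the acyl-bond cleavage ion - the full chain without the
#' cap - plus optional water-loss companions of the y series and optional
#' precursor adducts), perturbs every m/z with Gaussian error of `mz_sd_ppm` ppm,
#' assigns rank-decay intensities, and adds decoy peaks uniformly over the
#' observed m/z range - either Poisson per 100 Da (`decoy_per_100da`) or as
#' a fraction of the signal peak count (`decoy_fraction`). The returned
#' ground truth records which peaks are signal.
#'
#' @param x A resolved `peptaibol`.
#' @param seed Integer seed.
#' @param ladders Which fragment series to emit (`"y"`, `"b"` or both).
#' @param adducts Precursor adducts to include (default none - pure MS2).
#' @param water_loss_y Add `[y - H2O]+` companions.
#' @param mz_sd_ppm Gaussian m/z error, standard deviation in ppm.
#' @param decoy_per_100da Poisson decoy density per 100 Da.
#' @param decoy_fraction Decoy count as a fraction of signal peaks.
#' @param intensity_exponent Rank-decay exponent e (intensity = rank^-e).
#' @param library Residue library.
#' @return List with `peaks` (a [peaklist()] whose `precursor_mz` is the
#'   theoretical `[M+H]+`) and `truth` (data frame: `mz_theoretical`,
#'   `mz_observed`, `kind`, `signal`).
#' @export
simulate_spectrum <- function(x, seed, ladders = c("b", "y"),
                              adducts = character(0), water_loss_y = FALSE,
                              mz_sd_ppm = 0, decoy_per_100da = 0,
                              decoy_fraction = 0, intensity_exponent = 0.5,
                              library = residue_library()) {
  stopifnot(inherits(x, "peptaibol"), !missing(seed))
  ladders <- match.arg(ladders, c("b", "y"), several.ok = TRUE)
  frag <- fragment_ladder(x, ladders, library = library)
  kind <- paste0(frag$series, frag$index)
  mz_theo <- frag$mz
  if ("y" %in% ladders) {
    # cleavage of the acyl-amide bond: the full chain without the cap
    n_total <- seq_length(x)
    mz_theo <- c(mz_theo, neutral_mass(x, library) -
                   residue_mass(x$cap, library) + mass_constants()$proton)
    kind <- c(kind, paste0("y", n_total))
  }
  if (water_loss_y && "y" %in% ladders) {
    ys <- frag[frag$series == "y", , drop = FALSE]
    wl <- water_loss(ys)
    mz_theo <- c(mz_theo, wl$mz)
    kind <- c(kind, paste0("y", wl$index, "-H2O"))
  }
  for (ad in adducts) {
    z <- if (ad %in% c("M+H", "M+Na")) 1L else 2L
    mz_theo <- c(mz_theo, adduct_mz(x, ad, z, library))
    kind <- c(kind, ad)
  }
  .with_substream(seed, 0L, {
    n_sig <- length(mz_theo)
    mz_obs <- mz_theo * (1 + stats::rnorm(n_sig, 0, mz_sd_ppm * 1e-6))
    inten <- sample(n_sig)^(-intensity_exponent)
    span <- diff(range(mz_obs))
    n_decoy <- stats::rpois(1, decoy_per_100da * span / 100) +
      round(decoy_fraction * n_sig)
    if (n_decoy > 0) {
      dmz <- stats::runif(n_decoy, min(mz_obs), max(mz_obs))
      dint <- stats::runif(n_decoy, 0, stats::median(inten))
      mz_all <- c(mz_obs, dmz)
      int_all <- c(inten, dint)
      kind_all <- c(kind, rep("decoy", n_decoy))
      theo_all <- c(mz_theo, rep(NA_real_, n_decoy))
    } else {
      mz_all <- mz_obs; int_all <- inten; kind_all <- kind; theo_all <- mz_theo
    }
    o <- order(mz_all)
    truth <- data.frame(mz_theoretical = theo_all[o], mz_observed = mz_all[o],
                        kind = kind_all[o], signal = kind_all[o] != "decoy",
                        stringsAsFactors = FALSE)
    peaks <- peaklist(mz_all[o], int_all[o],
                      precursor_mz = mh_plus(x, library),
                      precursor_charge = 1L, title = x$label, rt = x$rt)
    list(peaks = peaks, truth = truth)
  })
}

#' Fraction of residues recovered by a ladder solution
#'
#' Compares an [infer_from_ladder()] solution with the true sequence at the
#' canonical-token level, aligning from the C terminus (the anchored end of
#' a y ladder). The denominator is the number of true internal residues.
#'
#' @param solution One solution from [infer_from_ladder()].
#' @param x The true `peptaibol`.
#' @param library Residue library.
#' @return A fraction in `[0, 1]`.
#' @export
residue_recovery <- function(solution, x, library = residue_library()) {
  truth <- canonical_token(x$residues[!is.na(x$residues)], library)
  got <- solution$tokens
  n <- length(truth)
  if (!length(got)) return(0)
  m <- min(length(got), n)
  # align at the C-terminal end (tokens are reported N to C)
  hits <- sum(utils::tail(got, m) == utils::tail(truth, m))
  hits / n
}

#' Monte-Carlo benchmark of ladder inference
#'
#' Simulates `n_spectra` compounds from a template, builds a y-ladder
#' spectrum for each under the given noise model, runs
#' [infer_from_ladder()], and returns the per-spectrum residue recovery.
#'
#' @param template Family template.
#' @param n_spectra Number of simulated spectra.
#' @param seed Integer seed.
#' @param mz_sd_ppm,decoy_fraction Noise model passed to
#'   [simulate_spectrum()].
#' @param tol_ppm Matching tolerance for the inference; differencing two
#'   peaks that each carry `mz_sd_ppm` error inflates the step error by
#'   sqrt(2), so the default scales the tolerance to 3 * sqrt(2) * sigma
#'   (minimum 5 ppm).
#' @param library Residue library.
#' @return Numeric vector of recoveries, one per spectrum.
#' @export
benchmark_recovery <- function(template, n_spectra, seed, mz_sd_ppm = 0,
                               decoy_fraction = 0,
                               tol_ppm = max(5, 3 * sqrt(2) * mz_sd_ppm),
                               library = residue_library()) {
  comps <- simulate_compounds(template, n_spectra, seed = seed)
  vapply(seq_along(comps), function(i) {
    sim <- simulate_spectrum(comps[[i]]$model, seed = seed + i, ladders = "y",
                             mz_sd_ppm = mz_sd_ppm,
                             decoy_fraction = decoy_fraction,
                             library = library)
    sols <- infer_from_ladder(sim$peaks, series = "y", tol_ppm = tol_ppm,
                              library = library)
    if (!length(sols)) return(0)
    residue_recovery(sols[[1L]], comps[[i]]$model, library)
  }, numeric(1))
}
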