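# De novo sequence inference from observed fragment ladders: residue-mass
# differencing with ppm tolerance, terminal assignment, residual reporting.

.match_tol <- function(mz, tol_ppm, abs_tol_da) {
  pmax(tol_ppm * 1e-6 * mz, abs_tol_da)
}

# nearest-residue lookup for one mass difference; returns token + error or NULL
.match_residue <- function(delta, at_mz, tol_ppm, abs_tol_da, tokens, masses) {
  tol <- .match_tol(at_mz, tol_ppm, abs_tol_da)
  err <- abs(masses - delta)
  i <- which.min(err)
  if (err[i] <= tol) {
    list(token = tokens[i], err_da = masses[i] - delta,
         err_ppm = (masses[i] - delta) / at_mz * 1e6)
  } else NULL
}

#' Infer a sequence from an observed fragment ladder
#'
#' Consecutive mass differences between selected peaks are matched to
#' internal-residue masses within a tolerance (Leu/Ile and Val/Iva are
#' reported as their ambiguity codes `Lxx`/`Vxx`); the low-mass end is matched
#' to an amino alcohol (`y` ladder) or to an acyl cap plus first residue
#' (`b` ladder), and the gap between the largest matched peak and the
#' precursor to the complementary terminus. Mass that no residue or terminus
#' combination explains is reported as an unexplained residual, displayed at
#' integer Da but stored at full precision.
#'
#' The chain is found by exact longest-path search over the peak graph; ties
#' are broken by smaller cumulative ppm error, then by lower starting m/z.
#'
#' @param peaks A [peaklist()] whose `precursor_mz` is the singly protonated
#'   mass of the sequenced species (the molecule, or the diagnostic fragment
#'   when sequencing an in-source cleavage product).
#' @param series `"y"` or `"b"` - which ladder the peaks represent.
#' @param tol_ppm,abs_tol_da Matching tolerance; a difference matches when it
#'   is within `max(tol_ppm * 1e-6 * mz, abs_tol_da)` of a residue mass.
#' @param caps Candidate acyl-cap tokens.
#' @param alcohols Candidate amino-alcohol tokens (defaults to the canonical
#'   codes in the residue library).
#' @param max_solutions Number of ranked alternatives to return.
#' @param library Residue library.
#' @return A list of solutions, ranked by score (fraction of bonds explained)
#'   then mean absolute ppm error. Each solution is a list with elements
#'   `tokens` (N-to-C internal residues), `cap`, `terminus`,
#'   `residual` (Da, `NA` if fully explained), `residual_display` (integer
#'   Da), `score`, `per_step_ppm`, `matched_peaks` (indices into `peaks`),
#'   `direction`. An empty list means no chainable path was found.
#' @export
infer_from_ladder <- function(peaks, series = c("y", "b"), tol_ppm = 5,
                              abs_tol_da = 0.005,
                              caps = c("Ac", "Oc"), alcohols = NULL,
                              max_solutions = 5L,
                              library = residue_library()) {
  stopifnot(inherits(peaks, "peaklist"))
  series <- match.arg(series)
  if (tol_ppm <= 0 || abs_tol_da < 0) stop("tolerances must be positive")
  mz <- peaks$mz
  if (length(mz) < 2L) stop("need at least 2 peaks to difference a ladder")
  prec <- peaks$precursor_mz
  if (!is.na(prec) && prec < max(mz) - .match_tol(max(mz), tol_ppm, abs_tol_da)) {
    stop("precursor m/z below the largest fragment peak: inconsistent input")
  }
  intern <- library[library$class == "internal" &
                      library$token == library$canonical, ]
  if (is.null(alcohols)) {
    alc_tab <- library[library$class == "amino_alcohol" &
                         library$token == library$canonical, ]
  } else {
    alc_tab <- library[match(alcohols, library$token), ]
  }
  cap_tab <- library[match(caps, library$token), ]
  k <- mass_constants()

  # edges: j reachable from i when mz[j]-mz[i] matches a residue mass
  n <- length(mz)
  edge_from <- vector("list", n)
  for (j in 2:n) {
    for (i in seq_len(j - 1L)) {
      m <- .match_residue(mz[j] - mz[i], mz[j], tol_ppm, abs_tol_da,
                          intern$token, intern$mono_mass)
      if (!is.null(m)) {
        edge_from[[j]] <- c(edge_from[[j]],
                            list(list(i = i, token = m$token,
                                      ppm = m$err_ppm)))
      }
    }
  }
  # exact longest chain by DP; ties -> smaller cumulative |ppm|, lower start mz
  best_len <- rep(1L, n)
  best_ppm <- rep(0, n)
  best_prev <- rep(NA_integer_, n)
  best_tok <- rep(NA_character_, n)
  for (j in seq_len(n)) {
    for (e in edge_from[[j]]) {
      cand_len <- best_len[e$i] + 1L
      cand_ppm <- best_ppm[e$i] + abs(e$ppm)
      upd <- cand_len > best_len[j] ||
        (cand_len == best_len[j] && !is.na(best_prev[j]) && cand_ppm < best_ppm[j])
      if (upd) {
        best_len[j] <- cand_len
        best_ppm[j] <- cand_ppm
        best_prev[j] <- e$i
        best_tok[j] <- e$token
      }
    }
  }
  ends <- order(-best_len, best_ppm, mz)
  ends <- ends[best_len[ends] >= 2L]
  if (!length(ends)) return(list())
  ends <- utils::head(ends, max_solutions)

  sols <- lapply(ends, function(j) {
    idx <- j
    toks <- character()
    ppms <- numeric()
    while (!is.na(best_prev[idx[1L]])) {
      toks <- c(best_tok[idx[1L]], toks)
      # recompute step ppm for reporting
      idx <- c(best_prev[idx[1L]], idx)
    }
    # step errors low->high
    steps <- length(idx) - 1L
    ppms <- vapply(seq_len(steps), function(s) {
      d <- mz[idx[s + 1L]] - mz[idx[s]]
      m <- .match_residue(d, mz[idx[s + 1L]], tol_ppm, abs_tol_da,
                          intern$token, intern$mono_mass)
      m$err_ppm
    }, numeric(1))
    low <- mz[idx[1L]]
    high <- mz[idx[length(idx)]]

    cap <- NA_character_
    terminus <- NA_character_
    residual <- 0
    explained <- steps
    low_toks <- character()
    if (series == "y") {
      # low end: alcohol + proton (y1)
      m <- .match_residue(low - k$proton, low, tol_ppm, abs_tol_da,
                          alc_tab$token, alc_tab$mono_mass)
      if (!is.null(m)) {
        terminus <- m$token
        explained <- explained + 1L
      } else {
        residual <- residual + (low - k$proton)
      }
      # high end: precursor - y_last = cap delta (whole molecule) or 0 (fragment)
      if (!is.na(prec)) {
        gap <- prec - high
        tolh <- .match_tol(prec, tol_ppm, abs_tol_da)
        if (abs(gap) > tolh) {
          m <- .match_residue(gap, prec, tol_ppm, abs_tol_da,
                              cap_tab$token, cap_tab$mono_mass)
          if (!is.null(m)) {
            cap <- m$token
            explained <- explained + 1L
          } else {
            # one unread residue plus a cap?
            done <- FALSE
            for (ci in seq_len(nrow(cap_tab))) {
              m2 <- .match_residue(gap - cap_tab$mono_mass[ci], prec, tol_ppm,
                                   abs_tol_da, intern$token, intern$mono_mass)
              if (!is.null(m2)) {
                cap <- cap_tab$token[ci]
                low_toks <- m2$token  # N-terminal residue read from the gap
                explained <- explained + 2L
                done <- TRUE
                break
              }
            }
            if (!done) residual <- residual + gap
          }
        }
      }
      tokens <- c(low_toks, rev(toks))
    } else {
      # b ladder: low end is cap + first residue + proton
      matched_low <- FALSE
      for (ci in seq_len(nrow(cap_tab))) {
        m <- .match_residue(low - k$proton - cap_tab$mono_mass[ci], low,
                            tol_ppm, abs_tol_da, intern$token, intern$mono_mass)
        if (!is.null(m)) {
          cap <- cap_tab$token[ci]
          toks <- c(m$token, toks)
          explained <- explained + 2L
          matched_low <- TRUE
          break
        }
      }
      if (!matched_low) residual <- residual + (low - k$proton)
      if (!is.na(prec)) {
        gap <- prec - high
        tolh <- .match_tol(prec, tol_ppm, abs_tol_da)
        if (abs(gap) > tolh) {
          m <- .match_residue(gap, prec, tol_ppm, abs_tol_da,
                              alc_tab$token, alc_tab$mono_mass)
          if (!is.null(m)) {
            terminus <- m$token
            explained <- explained + 1L
          } else {
            done <- FALSE
            for (ai in seq_len(nrow(alc_tab))) {
              m2 <- .match_residue(gap - alc_tab$mono_mass[ai], prec, tol_ppm,
                                   abs_tol_da, intern$token, intern$mono_mass)
              if (!is.null(m2)) {
                terminus <- alc_tab$token[ai]
                toks <- c(toks, m2$token)
                explained <- explained + 2L
                done <- TRUE
                break
              }
            }
            if (!done) residual <- residual + gap
          }
        }
      }
      tokens <- toks
    }
    unexplained <- if (residual > max(abs_tol_da, 1e-9)) residual else NA_real_
    est_missing <- if (is.na(unexplained)) 0L else max(1L, round(unexplained / 110))
    score <- explained / (explained + est_missing)
    list(tokens = tokens, cap = cap, terminus = terminus,
         residual = unexplained,
         residual_display = if (is.na(unexplained)) NA_integer_
                            else as.integer(round(unexplained)),
         score = score, per_step_ppm = ppms,
         matched_peaks = idx, direction = paste0(series, "-ladder"))
  })
  ord <- order(-vapply(sols, `[[`, numeric(1), "score"),
               -lengths(lapply(sols, `[[`, "matched_peaks")),
               vapply(sols, function(s) mean(abs(s$per_step_ppm)), numeric(1)))
  sols[ord]
}

#' Detect a repeating mass-difference unit in a peak list
#'
#' Bins the consecutive mass differences of the sorted peaks and reports
#' recurring values - the signature of oligomeric/polymeric series whose
#' composition cannot be read as residues (e.g. an unidentified compound
#' whose MS2 differences repeat 72 and 127 Da).
#'
#' @param peaks A [peaklist()] (at least 3 peaks).
#' @param abs_tol_da Bin width for grouping differences.
#' @return A data frame with columns `delta` (mean difference of the bin) and
#'   `count`, restricted to multiplicities >= 2 and sorted by decreasing
#'   count. May have zero rows.
#' @export
detect_repeat_unit <- function(peaks, abs_tol_da = 0.02) {
  stopifnot(inherits(peaks, "peaklist"))
  if (length(peaks$mz) < 3L) stop("need at least 3 peaks")
  d <- sort(diff(peaks$mz))
  groups <- cumsum(c(TRUE, diff(d) > abs_tol_da))
  agg <- vapply(split(d, groups), mean, numeric(1))
  cnt <- vapply(split(d, groups), length, integer(1))
  keep <- cnt >= 2L
  out <- data.frame(delta = unname(agg[keep]), count = unname(cnt[keep]))
  out[order(-out$count, out$delta), , drop = FALSE]
}

#' Group positional isomers
#'
#' Compounds with identical token strings (cap, residues including gaps, and
#' terminus) that elute at different retention times are positional isomers:
#' the token string cannot resolve Leu/Ile/Val/Iva isomerism, so one string
#' may correspond to several distinct molecules. Members whose retention
#' times agree within `rt_tol` are treated as duplicate observations and
#' merged.
#'
#' @param compounds List of `peptaibol` objects, each carrying `rt`.
#' @param rt_tol Retention-time tolerance in minutes for merging duplicates.
#' @return A list of groups, each a data frame with columns `label`, `rt`,
#'   `sequence`, sorted by retention time; groups of more than one row are
#'   positional-isomer families.
#' @export
group_positional_isomers <- function(compounds, rt_tol = 0.1) {
  stopifnot(all(vapply(compounds, inherits, logical(1), "peptaibol")))
  rt <- vapply(compounds, function(x) x$rt, numeric(1))
  if (anyNA(rt)) stop("every compound needs a retention time")
  seqs <- vapply(compounds, sequence_string, character(1))
  labs <- vapply(compounds, function(x) x$label, character(1))
  out <- lapply(split(seq_along(compounds), seqs), function(ix) {
    ix <- ix[order(rt[ix])]
    keep <- ix[c(TRUE, diff(rt[ix]) > rt_tol)]
    data.frame(label = labs[keep], rt = rt[keep], sequence = seqs[keep][1L],
               stringsAsFactors = FALSE, row.names = NULL)
  })
  unname(out[order(vapply(out, function(g) g$rt[1L], numeric(1)))])
}
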