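# Novelty annotation against a reference sequence set: minimal-substitution
# matching, substitution notation, module-skip gap alignment, naming.

#' Read a reference peptaibiotics database
#'
#' A TSV with columns `name`, `sequence` (hyphen-joined tokens), and
#' optionally `organism` and `citation`. Every sequence is validated against
#' the residue library. The package ships a small curated reference set
#' (`reference_peptaibiotics.tsv`) assembled from published peptaibiotic
#' sequences for testing; real novelty assessment should use a comprehensive
#' user-supplied database in the same schema.
#'
#' @param path TSV path.
#' @param library Residue library.
#' @return Data frame with a parsed `model` list column.
#' @export
read_reference_db <- function(path, library = residue_library()) {
  read_compound_table(path, library = library)
}

# position-wise token vector over the full coordinate system:
# cap, residues (NA = gap), terminus. Ambiguity codes are canonicalised so
# Lxx matches Leu and Ile etc.
.position_tokens <- function(x, library = residue_library()) {
  stopifnot(inherits(x, "peptaibol"))
  if (is.null(x$terminus)) stop("sequence must be fully resolved: ", x$label)
  canon <- function(t) ifelse(is.na(t), NA_character_, canonical_token(t, library))
  list(cap = canonical_token(x$cap, library),
       pos = c(canon(x$residues), canon(x$terminus)))
}

#' Nearest reference sequences
#'
#' Compares a resolved compound position-by-position against every
#' equal-length reference (the amino-alcohol terminus counts as a position;
#' ambiguity codes match their members, so `Lxx` equals `Leu` or `Ile`).
#' All references at the minimal substitution distance are returned, in
#' alphabetical name order. Length differences are not scored here; align
#' shorter compounds with [skip_alignment()] first.
#'
#' @param x A resolved `peptaibol`.
#' @param db Reference database from [read_reference_db()].
#' @param max_dist Maximum substitution distance to report (default
#'   unlimited); an empty result means nothing within range.
#' @param library Residue library.
#' @return A list with elements `distance` (minimal substitution count, or
#'   `NA` when no equal-length reference exists), `status` (`"known"` at
#'   distance 0, otherwise `"new"`), and `matches` - a list of entries, each
#'   with `name`, `entry` (the db row), and `substitutions`, a data frame
#'   of `position`, `ref_token`, `obs_token`.
#' @export
nearest_reference <- function(x, db, max_dist = Inf,
                              library = residue_library()) {
  stopifnot(is.data.frame(db), !is.null(db$model), nrow(db) > 0)
  obs <- .position_tokens(x, library)
  cand <- list()
  for (i in seq_len(nrow(db))) {
    ref <- .position_tokens(db$model[[i]], library)
    if (length(ref$pos) != length(obs$pos)) next
    # NA-safe position comparison (NA = gap marker)
    eq <- (is.na(ref$pos) & is.na(obs$pos)) |
      (!is.na(ref$pos) & !is.na(obs$pos) & ref$pos == obs$pos)
    diff_pos <- which(!eq)
    d <- length(diff_pos) + as.integer(ref$cap != obs$cap)
    cand[[length(cand) + 1L]] <- list(i = i, d = d, diff = diff_pos)
  }
  if (!length(cand)) {
    return(list(distance = NA_integer_, status = "new", matches = list()))
  }
  dmin <- min(vapply(cand, `[[`, numeric(1), "d"))
  if (dmin > max_dist) {
    return(list(distance = as.integer(dmin), status = "new", matches = list()))
  }
  hits <- Filter(function(c) c$d == dmin, cand)
  obs_raw <- c(x$residues, x$terminus)
  matches <- lapply(hits, function(h) {
    ref_model <- db$model[[h$i]]
    ref_raw <- c(ref_model$residues, ref_model$terminus)
    subs <- data.frame(position = h$diff,
                       ref_token = ref_raw[h$diff],
                       obs_token = obs_raw[h$diff],
                       stringsAsFactors = FALSE)
    list(name = db$name[h$i], entry = db[h$i, , drop = FALSE],
         substitutions = subs)
  })
  matches <- matches[order(vapply(matches, `[[`, character(1), "name"))]
  list(distance = as.integer(dmin),
       status = if (dmin == 0L) "known" else "new",
       matches = matches)
}

#' Substitution notation
#'
#' Renders position-wise differences between a reference and an observed
#' sequence in the conventional bracket notation, e.g.
#' `"[Aib]^1 -> [Vxx]^1; [Aib]^8 -> [Ala]^8"` (with a Unicode arrow).
#' Identical sequences give an empty string. When the two sequences
#' additionally share the same token multiset, they are compositional (swap)
#' isomers; check that separately with [is_compositional_isomer()].
#'
#' @param ref,obs Resolved `peptaibol` objects of equal length (after gap
#'   reconciliation), or a substitution data frame as produced by
#'   [nearest_reference()].
#' @param library Residue library.
#' @return A single display string.
#' @export
substitution_notation <- function(ref, obs = NULL, library = residue_library()) {
  if (is.data.frame(ref) && is.null(obs)) {
    subs <- ref
  } else {
    a <- .position_tokens(ref, library)
    b <- .position_tokens(obs, library)
    if (length(a$pos) != length(b$pos)) {
      stop("sequences differ in length; run skip_alignment() first")
    }
    eq <- (is.na(a$pos) & is.na(b$pos)) |
      (!is.na(a$pos) & !is.na(b$pos) & a$pos == b$pos)
    d <- which(!eq)
    ref_raw <- c(ref$residues, ref$terminus)
    obs_raw <- c(obs$residues, obs$terminus)
    subs <- data.frame(position = d, ref_token = ref_raw[d],
                       obs_token = obs_raw[d], stringsAsFactors = FALSE)
  }
  if (!nrow(subs)) return("")
  subs <- subs[order(subs$position), , drop = FALSE]
  paste(sprintf("[%s]^%d → [%s]^%d", subs$ref_token, subs$position,
                subs$obs_token, subs$position), collapse = "; ")
}

#' Compositional (swap) isomer check
#'
#' TRUE when two equal-length sequences differ only in the order of their
#' residues (identical token multisets): a two-position exchange rather than
#' independent substitutions.
#'
#' @inheritParams substitution_notation
#' @return Logical.
#' @export
is_compositional_isomer <- function(ref, obs, library = residue_library()) {
  a <- .position_tokens(ref, library)
  b <- .position_tokens(obs, library)
  length(a$pos) == length(b$pos) && a$cap == b$cap &&
    identical(sort(a$pos[!is.na(a$pos)]), sort(b$pos[!is.na(b$pos)])) &&
    !identical(a$pos, b$pos)
}

# enumerate all gap-position subsets (internal helper, also the test oracle's
# counterpart lives in the test suite)
.gap_placements <- function(n_template, deficit) {
  utils::combn(n_template, deficit, simplify = FALSE)
}

#' Align a shorter sequence to a template by module-skip gaps
#'
#' A compound one to three residues shorter than a template family member is
#' modelled as the template with skipped NRPS modules. All placements of the
#' length deficit as gaps in the template coordinate system are enumerated
#' and scored by the number of residue substitutions the alignment then
#' requires; all substitution-minimal placements are returned.
#'
#' Among co-minimal placements the canonical (first) solution is the one a
#' left-to-right scan produces: the template is matched as far as possible
#' and a gap is placed at the first mismatching position. Formally, ties are
#' broken by preferring substitutions as C-terminal as possible, then the
#' rightmost gap vector; in a run of identical template residues this places
#' the gap at the last position of the run, which is where the skipped
#' module is conventionally annotated.
#'
#' @param short_seq Resolved `peptaibol`, shorter than the template; any gap
#'   markers it already carries are ignored (the alignment re-derives them).
#' @param template_seq Resolved `peptaibol` template.
#' @param max_skips Refuse larger deficits (default 3, the most observed).
#' @param library Residue library.
#' @return A list with `deficit`, `solutions` (each with `gaps` - template
#'   positions skipped - plus `substitutions` data frame and `n_substitutions`),
#'   and `aligned`: `short_seq` rewritten with gap markers at the canonical
#'   solution's template positions.
#' @export
skip_alignment <- function(short_seq, template_seq, max_skips = 3L,
                           library = residue_library()) {
  stopifnot(inherits(short_seq, "peptaibol"), inherits(template_seq, "peptaibol"))
  if (is.null(short_seq$terminus) || is.null(template_seq$terminus)) {
    stop("both sequences must have resolved termini")
  }
  s_res <- short_seq$residues[!is.na(short_seq$residues)]
  t_res <- template_seq$residues[!is.na(template_seq$residues)]
  s_pos <- c(canonical_token(s_res, library),
             canonical_token(short_seq$terminus, library))
  t_pos <- c(canonical_token(t_res, library),
             canonical_token(template_seq$terminus, library))
  deficit <- length(t_pos) - length(s_pos)
  if (deficit <= 0L) stop("short_seq must be shorter than template_seq")
  if (deficit > max_skips) {
    stop("length deficit ", deficit, " exceeds max_skips = ", max_skips,
         "; refusing to enumerate implausibly many skipped modules")
  }
  s_raw <- c(s_res, short_seq$terminus)
  t_raw <- c(t_res, template_seq$terminus)
  n_t <- length(t_pos)
  # terminus cannot be skipped: gaps go into internal template positions
  placements <- .gap_placements(n_t - 1L, deficit)
  scored <- lapply(placements, function(g) {
    keep <- setdiff(seq_len(n_t), g)
    eq <- t_pos[keep] == s_pos
    d <- which(!eq)
    list(gaps = g,
         substitutions = data.frame(position = keep[d],
                                    ref_token = t_raw[keep[d]],
                                    obs_token = s_raw[d],
                                    stringsAsFactors = FALSE),
         n_substitutions = length(d))
  })
  nmin <- min(vapply(scored, `[[`, numeric(1), "n_substitutions"))
  sols <- Filter(function(s) s$n_substitutions == nmin, scored)
  # canonical order: substitutions as late as possible, then rightmost gaps
  key <- vapply(sols, function(s) {
    subs <- sort(s$substitutions$position)
    paste(sprintf("%03d", c(1000 - subs, 1000 - rev(s$gaps))), collapse = "")
  }, character(1))
  sols <- sols[order(key)]
  chosen <- sols[[1L]]
  new_res <- rep(NA_character_, n_t - 1L)
  new_res[setdiff(seq_len(n_t - 1L), chosen$gaps)] <- s_res
  aligned <- peptaibol(short_seq$cap, new_res, terminus = short_seq$terminus,
                       label = short_seq$label, rt = short_seq$rt,
                       library = library)
  list(deficit = deficit, solutions = sols, aligned = aligned)
}

#' Roman-numeral names in elution order
#'
#' Compounds in a family are named by a stem plus a Roman numeral assigned in
#' ascending retention-time order (the stem is the closest known compound for
#' variants, or the producer species for wholly new families; the caller
#' supplies it). Duplicate retention times keep their input order, with a
#' warning.
#'
#' @param rt Numeric retention times.
#' @param stem Name stem, e.g. `"Lipostrigosellin"`.
#' @return Character vector of names aligned with the input order.
#' @export
#' @examples
#' assign_names(c(6.57, 7.23, 9.3, 10.54), "Lipostrigosellin")
assign_names <- function(rt, stem) {
  stopifnot(is.numeric(rt), length(rt) >= 1L, nzchar(stem))
  if (anyDuplicated(rt)) {
    warning("duplicate retention times; keeping input order for ties")
  }
  rank <- order(order(rt))  # stable: ties keep input order
  paste(stem, as.character(utils::as.roman(rank)))
}
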