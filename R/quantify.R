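# Relative quantification from EIC peak areas and peptaibiome composition /
# microheterogeneity analytics.

#' Classify a compound into peptaibiome classes
#'
#' A compound with a fatty-acyl cap (octanoyl) is a lipopeptaibol; acetylated
#' compounds are peptaibols. Lipopeptaibols are binned by residue count into
#' the short (6-7), medium (10-11) and long (15) length classes; counts
#' outside those bins get `"other"` with a warning. Peptaibols carry no
#' length class.
#'
#' @param x A resolved `peptaibol`.
#' @param library Residue library.
#' @return List with `class` (`"peptaibol"` or `"lipopeptaibol"`) and
#'   `length_class` (`"short"`, `"medium"`, `"long"`, `"other"` or `NA`).
#' @export
#' @examples
#' classify_compound(parse_peptaibol("Oc-Aib-Gly-Lxx-Aib-Gly-Lxx-Lxxol"))
classify_compound <- function(x, library = residue_library()) {
  stopifnot(inherits(x, "peptaibol"))
  lipo <- identical(canonical_token(x$cap, library), "Oc")
  n <- seq_length(x)
  if (!lipo) {
    return(list(class = "peptaibol", length_class = NA_character_))
  }
  lc <- if (n %in% 6:7) "short" else if (n %in% 10:11) "medium"
        else if (n == 15) "long" else {
          warning("lipopeptaibol of ", n,
                  " residues falls outside the short/medium/long classes")
          "other"
        }
  list(class = "lipopeptaibol", length_class = lc)
}

#' Peptaibiome percentage structure from EIC areas
#'
#' Per strain, each compound's share of its class (peptaibol vs
#' lipopeptaibol, the latter optionally split by length class) and of the
#' whole peptaibiome is the ratio of its extracted-ion-chromatogram peak
#' area to the class or grand total, times 100. Peptaibols are quantified
#' under their major y ion and lipopeptaibols under `[M+H]+`; both are plain
#' areas here - peak integration is upstream of this package.
#'
#' @param records Data frame with columns `compound`, `strain`, `class`
#'   (`"peptaibol"`/`"lipopeptaibol"`), `area` (>= 0), and optionally
#'   `length_class` for lipopeptaibols.
#' @return List with `compounds` (the input plus `pct_class` and
#'   `pct_peptaibiome`) and `strains` (per-strain class shares in percent;
#'   lipopeptaibol shares split by length class when available). Shares per
#'   strain sum to 100 exactly (before any display rounding).
#' @export
peptaibiome_percentages <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("compound", "strain", "class", "area") %in% names(records)))
  if (any(records$area < 0)) stop("areas must be non-negative")
  out <- records
  out$pct_class <- NA_real_
  out$pct_peptaibiome <- NA_real_
  strain_rows <- list()
  for (s in unique(records$strain)) {
    ix <- which(records$strain == s)
    tot <- sum(records$area[ix])
    if (tot == 0) stop("all areas are zero for strain ", s,
                       ": percentages undefined")
    out$pct_peptaibiome[ix] <- records$area[ix] / tot * 100
    for (cl in unique(records$class[ix])) {
      jx <- ix[records$class[ix] == cl]
      out$pct_class[jx] <- records$area[jx] / sum(records$area[jx]) * 100
    }
    share <- function(sel) sum(records$area[ix][sel]) / tot * 100
    cls <- records$class[ix]
    lc <- if ("length_class" %in% names(records)) records$length_class[ix]
          else rep(NA_character_, length(ix))
    strain_rows[[s]] <- data.frame(
      strain = s,
      pct_peptaibol = share(cls == "peptaibol"),
      pct_short_lipo = share(cls == "lipopeptaibol" & !is.na(lc) & lc == "short"),
      pct_medium_lipo = share(cls == "lipopeptaibol" & !is.na(lc) & lc == "medium"),
      pct_long_lipo = share(cls == "lipopeptaibol" & !is.na(lc) & lc == "long"),
      pct_other_lipo = share(cls == "lipopeptaibol" & (is.na(lc) | lc == "other")),
      stringsAsFactors = FALSE
    )
  }
  list(compounds = out,
       strains = do.call(rbind, c(strain_rows, list(make.row.names = FALSE))))
}

# shared validation for the consensus operations
.consensus_matrix <- function(seqs, weights, library) {
  stopifnot(length(seqs) >= 1L)
  if (is.null(weights)) weights <- rep(1, length(seqs))
  stopifnot(length(weights) == length(seqs), all(weights >= 0))
  toks <- lapply(seqs, function(x) {
    p <- .position_tokens(x, library)
    c(p$cap, p$pos)
  })
  lens <- lengths(toks)
  if (length(unique(lens)) != 1L) {
    stop("consensus requires equal-length sequences; reconcile gaps first")
  }
  list(mat = do.call(rbind, toks), w = weights)
}

#' Consensus sequence and per-position variant table
#'
#' Per position (cap, each residue slot including gap markers, terminus) the
#' token with the greatest total weight wins. In unweighted mode (the
#' default when no weights are given) each sequence counts once - the
#' construction behind published family consensus tables, which take the
#' most abundant residue present at each position among the sequences; in
#' weighted mode the weight is the compound's EIC area, so the consensus
#' reflects production rather than variant counts. Gap markers are treated
#' as a token of their own so
#' module-skip variants do not distort the full-length coordinate system.
#' Ties are broken alphabetically and flagged.
#'
#' @param seqs List of equal-length resolved `peptaibol` objects.
#' @param weights Non-negative weights (e.g. EIC areas); `NULL` for
#'   unweighted.
#' @param mode `"weighted"` or `"unweighted"`; defaults to weighted when
#'   `weights` are supplied, unweighted otherwise.
#' @param library Residue library.
#' @return List with `consensus` (a `peptaibol`), `variants` (data frame of
#'   `position`, `token`, `weight`, `share`), and `ties` (positions whose
#'   maximum was not unique).
#' @export
consensus_sequence <- function(seqs, weights = NULL, mode = NULL,
                               library = residue_library()) {
  if (is.null(mode)) mode <- if (is.null(weights)) "unweighted" else "weighted"
  mode <- match.arg(mode, c("weighted", "unweighted"))
  if (mode == "unweighted") weights <- NULL
  cm <- .consensus_matrix(seqs, weights, library)
  mat <- cm$mat
  w <- cm$w
  npos <- ncol(mat)
  cons <- character(npos)
  ties <- integer()
  var_rows <- list()
  for (p in seq_len(npos)) {
    tok <- mat[, p]
    tok[is.na(tok)] <- "(skip)"
    tw <- vapply(split(w, tok), sum, numeric(1))
    tw <- sort(tw, decreasing = TRUE)
    top <- names(tw)[tw == tw[1L]]
    if (length(top) > 1L) ties <- c(ties, p)
    cons[p] <- sort(top)[1L]
    var_rows[[p]] <- data.frame(position = p - 1L,  # 0 = cap
                                token = names(tw), weight = unname(tw),
                                share = unname(tw) / sum(tw) * 100,
                                stringsAsFactors = FALSE)
  }
  res <- cons[-c(1L, npos)]
  res[res == "(skip)"] <- NA_character_
  consensus <- peptaibol(cons[1L], res, terminus = cons[npos],
                         label = "consensus", library = library)
  list(consensus = consensus,
       variants = do.call(rbind, var_rows),
       ties = ties)
}

#' Positions where the consensus differs from the most-produced compound
#'
#' The most-produced sequence is the one with the largest weight (EIC
#' area); the consensus is the count-based (unweighted) family consensus,
#' the construction used in published comparison tables. The two differ
#' wherever the majority of co-produced variants carry a different residue
#' than the single dominant compound.
#'
#' @inheritParams consensus_sequence
#' @return Data frame with `position` (1-based over residues, terminus
#'   last), `consensus_token`, `top_token`. Zero rows when they agree.
#' @export
consensus_vs_top <- function(seqs, weights, library = residue_library()) {
  stopifnot(!is.null(weights))
  cs <- consensus_sequence(seqs, mode = "unweighted", library = library)
  top <- seqs[[which.max(weights)]]
  a <- .position_tokens(cs$consensus, library)
  b <- .position_tokens(top, library)
  eq <- (is.na(a$pos) & is.na(b$pos)) |
    (!is.na(a$pos) & !is.na(b$pos) & a$pos == b$pos)
  d <- which(!eq)
  cons_raw <- c(cs$consensus$residues, cs$consensus$terminus)
  top_raw <- c(top$residues, top$terminus)
  data.frame(position = d, consensus_token = cons_raw[d],
             top_token = top_raw[d], stringsAsFactors = FALSE)
}

#' Round percentages for display
#'
#' Half-up rounding to 2 decimal places, mirroring how compound tables print
#' area percentages. Computation elsewhere keeps full precision.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 2).
#' @return Rounded numeric vector.
#' @export
round_pct <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}
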