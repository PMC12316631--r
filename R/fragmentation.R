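# Theoretical fragment-ion prediction: b/y ladders, the diagnostic in-source
# Aib-Pro pair, and water-loss ions. All fragments are singly protonated.

#' Theoretical b/y fragment ladder
#'
#' One singly charged ion per peptide bond: b ions accumulate from the acyl
#' cap (cap delta + residue masses + proton), y ions from the C terminus
#' (amino-alcohol free mass + residue masses + proton). Fragment indices count
#' residues in the fragment; for y ions the amino alcohol counts as one. Gap
#' markers contribute no mass and no bond.
#'
#' @param x A `peptaibol` with a resolved terminus.
#' @param series `"b"`, `"y"`, or both.
#' @param bonds Optional integer vector restricting the ladder to a range of
#'   cleavage sites (1-based bond index; bond k joins non-gap residue k to
#'   k+1, the last bond joining the final internal residue to the amino
#'   alcohol). Default: every bond. An empty selection gives an empty table.
#' @param library Residue library.
#' @return A data frame with columns `series`, `index` (residues in the
#'   fragment), `bond` (cleavage site), `mz`, `loss` (`"none"`).
#' @export
#' @examples
#' fragment_ladder(parse_peptaibol("Oc-Aib-Gly-Lxx-Lxxol"), "b")
fragment_ladder <- function(x, series = c("b", "y"), bonds = NULL,
                            library = residue_library()) {
  stopifnot(inherits(x, "peptaibol"))
  if (is.null(x$terminus)) {
    stop("fragment ladders require a resolved amino-alcohol terminus")
  }
  series <- match.arg(series, several.ok = TRUE)
  res <- x$residues[!is.na(x$residues)]
  n_res <- length(res)
  n_total <- n_res + 1L  # internal residues + amino alcohol
  if (n_res == 0L) {
    return(data.frame(series = character(), index = integer(),
                      bond = integer(), mz = numeric(), loss = character(),
                      stringsAsFactors = FALSE))
  }
  all_bonds <- seq_len(n_res)
  if (is.null(bonds)) bonds <- all_bonds
  if (length(bonds) && !all(bonds %in% all_bonds)) {
    stop("bond index out of range (1..", n_res, ")")
  }
  k <- mass_constants()
  masses <- residue_mass(res, library)
  cap_delta <- residue_mass(x$cap, library)
  alc <- residue_mass(x$terminus, library)
  out <- list()
  if ("b" %in% series) {
    bmz <- cap_delta + cumsum(masses) + k$proton
    out$b <- data.frame(series = "b", index = all_bonds, bond = all_bonds,
                        mz = bmz, stringsAsFactors = FALSE)
  }
  if ("y" %in% series) {
    # y at bond k contains residues k+1..n plus the alcohol
    ymz <- alc + (sum(masses) - cumsum(masses)) + k$proton
    out$y <- data.frame(series = "y", index = n_total - all_bonds,
                        bond = all_bonds, mz = ymz, stringsAsFactors = FALSE)
  }
  res_df <- do.call(rbind, out)
  res_df <- res_df[res_df$bond %in% bonds, , drop = FALSE]
  res_df$loss <- rep("none", nrow(res_df))
  rownames(res_df) <- NULL
  res_df
}

#' Diagnostic in-source Aib-Pro fragment pair
#'
#' Long peptaibols cleave between the central Aib and Pro residues already in
#' the ion source, giving a characteristic b/y pair whose masses identify the
#' compound. The cleavage site is the bond N-terminal of the unique Pro.
#'
#' @inheritParams fragment_ladder
#' @return A data frame of two rows (the b and y ion) with the columns of
#'   [fragment_ladder()].
#' @export
#' @examples
#' p <- parse_peptaibol(
#'   "Ac-Vxx-Ser-Aib-Aib-Lxx-Gln-Aib-Aib-Aib-Ser-Lxx-Aib-Pro-Vxx-Aib-Aib-Gln-Gln-Lxxol")
#' diagnostic_pair(p)
diagnostic_pair <- function(x, library = residue_library()) {
  stopifnot(inherits(x, "peptaibol"))
  res <- x$residues[!is.na(x$residues)]
  pro <- which(res == "Pro")
  if (length(pro) == 0L) {
    stop("no Pro residue: no diagnostic in-source cleavage site ",
         "(sequence the whole molecule by MS2 instead)",
         call. = FALSE)
  }
  if (length(pro) > 1L) {
    stop("multiple Pro residues (positions ", paste(pro, collapse = ", "),
         "): diagnostic site ambiguous", call. = FALSE)
  }
  bond <- pro - 1L
  if (bond == 0L) stop("Pro at position 1: no N-terminal bond to cleave")
  lad <- fragment_ladder(x, c("b", "y"), bonds = bond, library = library)
  rownames(lad) <- NULL
  lad
}

#' Precursor mass in the diagnostic-pair reporting convention
#'
#' Compound tables for in-source-fragmenting peptaibols conventionally list,
#' as the precursor, the sum of the diagnostic b- and y-ion m/z values. That
#' sum carries two protons, so it sits exactly one proton above the true
#' protonated molecular ion; use [mh_plus()] for the chemically true value.
#'
#' @inheritParams diagnostic_pair
#' @return b + y in Da.
#' @export
reported_precursor <- function(x, library = residue_library()) {
  sum(diagnostic_pair(x, library)$mz)
}

#' Water-loss ion
#'
#' Shifts a fragment ion down by one water; MS2 spectra of amino-alcohol
#' terminated peptides typically show `[y - H2O]+` companions.
#'
#' @param ion A row subset of a [fragment_ladder()] table with `loss ==
#'   "none"`.
#' @return The same table with `loss = "H2O"` and `mz` reduced by the
#'   monoisotopic water mass.
#' @export
water_loss <- function(ion) {
  stopifnot(is.data.frame(ion), all(c("mz", "loss") %in% names(ion)))
  if (any(ion$loss != "none")) stop("ion already carries a neutral loss")
  ion$mz <- ion$mz - mass_constants()$water
  ion$loss <- "H2O"
  ion
}

#' Write a fragment table to TSV
#'
#' @param fragments A [fragment_ladder()] table.
#' @param path Output file.
#' @export
write_fragments_tsv <- function(fragments, path) {
  utils::write.table(fragments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
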