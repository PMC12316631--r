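#' @keywords internal
"_PACKAGE"

# package-local cache for the residue library
.peptaibr_env <- new.env(parent = emptyenv())

#' Physical mass constants
#'
#' Monoisotopic masses (Da) used throughout the package: the proton (charge
#' carrier), the hydrogen atom, water, and the sodium cation (atomic Na minus
#' one electron).
#'
#' @return Named list with elements `proton`, `hydrogen`, `water`,
#'   `sodium_cation`.
#' @export
#' @examples
#' mass_constants()$proton
mass_constants <- function() {
  list(
    proton        = 1.00727646,
    hydrogen      = 1.00782503,
    water         = 18.01056468,
    sodium_cation = 22.98922190
  )
}

#' Residue library for peptaibol-type molecules
#'
#' Loads the packaged table of chemical building blocks: internal residues
#' (stored as residue masses, i.e. amino acid minus water), C-terminal amino
#' alcohols (free-molecule masses) and N-terminal acyl caps (neutral
#' substitution deltas replacing one amine hydrogen). Isobaric pairs that
#' MS cannot resolve carry ambiguity codes: Leu/Ile collapse to `Lxx`,
#' Val/Iva to `Vxx`, and likewise for the corresponding amino alcohols.
#'
#' @param extra Optional extension: a data frame with columns `token`,
#'   `class`, `mono_mass` (and optionally `formula`, `ambiguity`,
#'   `canonical`), or the path to a TSV/YAML file with those fields. Rows are
#'   appended to the packaged table; duplicate tokens are rejected.
#' @param reload Force re-reading the packaged table (the library is cached).
#' @return A data frame with columns `token`, `class`, `formula`,
#'   `mono_mass`, `ambiguity`, `canonical`.
#' @export
#' @examples
#' lib <- residue_library()
#' lib[lib$token == "Aib", "mono_mass"]
residue_library <- function(extra = NULL, reload = FALSE) {
  if (is.null(.peptaibr_env$library) || reload) {
    path <- system.file("extdata", "residue_masses.tsv", package = "peptaibr",
                        mustWork = TRUE)
    lib <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = c(mono_mass = "numeric"))
    .peptaibr_env$library <- lib
  }
  lib <- .peptaibr_env$library
  if (!is.null(extra)) {
    if (is.character(extra) && length(extra) == 1L) {
      extra <- .read_residue_config(extra)
    }
    stopifnot(is.data.frame(extra),
              all(c("token", "class", "mono_mass") %in% names(extra)))
    for (col in c("formula", "ambiguity")) {
      if (is.null(extra[[col]])) extra[[col]] <- ""
    }
    if (is.null(extra$canonical)) extra$canonical <- extra$token
    dup <- intersect(extra$token, lib$token)
    if (length(dup)) {
      stop("residue token(s) already defined: ", paste(dup, collapse = ", "))
    }
    lib <- rbind(lib, extra[, names(lib)])
  }
  bad <- !lib$class %in% c("internal", "amino_alcohol", "acyl_cap")
  if (any(bad)) stop("unknown residue class: ", unique(lib$class[bad]))
  if (any(lib$mono_mass <= 0)) stop("residue masses must be positive")
  lib
}

# a residue config file may append tokens without code changes (TSV, or YAML
# with a top-level `residues:` list of records)
.read_residue_config <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML residue configs requires the 'yaml' package")
    }
    cfg <- yaml::read_yaml(path)
    rows <- if (!is.null(cfg$residues)) cfg$residues else cfg
    do.call(rbind, lapply(rows, function(r) {
      data.frame(token = r$token, class = r$class,
                 formula = r$formula %||% "",
                 mono_mass = as.numeric(r$mono_mass),
                 ambiguity = r$ambiguity %||% "",
                 canonical = r$canonical %||% r$token,
                 stringsAsFactors = FALSE)
    }))
  } else {
    utils::read.delim(path, stringsAsFactors = FALSE)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Monoisotopic mass of a single residue token
#'
#' @param token Character vector of residue tokens (internal residue, amino
#'   alcohol or acyl cap).
#' @param library Residue library (see [residue_library()]).
#' @return Numeric vector of monoisotopic masses in Da. For internal residues
#'   this is the residue mass (amino acid minus water); for amino alcohols
#'   the free-molecule mass; for acyl caps the neutral substitution delta.
#' @export
#' @examples
#' residue_mass(c("Gly", "Aib", "Lxxol"))
residue_mass <- function(token, library = residue_library()) {
  idx <- match(token, library$token)
  if (anyNA(idx)) {
    stop("unknown residue token(s): ",
         paste(unique(token[is.na(idx)]), collapse = ", "))
  }
  library$mono_mass[idx]
}

#' Collapse concrete isomers to their MS-ambiguity codes
#'
#' Leu/Ile map to `Lxx`, Val/Iva to `Vxx`, Leuol/Ileol to `Lxxol`, Valol to
#' `Vxxol`; all other tokens map to themselves. Gap markers (`NA`) pass
#' through.
#'
#' @inheritParams residue_mass
#' @return Character vector of canonical tokens.
#' @export
canonical_token <- function(token, library = residue_library()) {
  idx <- match(token, library$token)
  out <- ifelse(is.na(idx), NA_character_, library$canonical[idx])
  bad <- !is.na(token) & is.na(idx)
  if (any(bad)) {
    stop("unknown residue token(s): ", paste(unique(token[bad]), collapse = ", "))
  }
  out
}

#' Construct a peptaibol sequence model
#'
#' A compound is an N-terminal acyl cap, an ordered list of internal residues
#' (with optional gap markers for skipped NRPS modules, given as `NA`), and
#' either a C-terminal amino alcohol or an unresolved residual mass.
#'
#' @param cap Acyl cap token (e.g. `"Ac"`, `"Oc"`).
#' @param residues Character vector of internal residue tokens; `NA` marks a
#'   skipped module (gap), which contributes no mass but keeps its position.
#' @param terminus Amino-alcohol token, or `NULL` if the C terminus is
#'   unresolved.
#' @param residual_mass Unresolved C-terminal mass in Da (mutually exclusive
#'   with `terminus`).
#' @param label Free-text compound label.
#' @param rt Retention time in minutes (optional).
#' @param library Residue library used for validation.
#' @return An object of class `peptaibol`.
#' @export
#' @examples
#' p <- peptaibol("Oc", c("Aib", "Gly", "Lxx", "Aib", "Gly", "Lxx"), "Lxxol")
#' neutral_mass(p)
peptaibol <- function(cap, residues, terminus = NULL, residual_mass = NULL,
                      label = "", rt = NA_real_, library = residue_library()) {
  stopifnot(length(cap) == 1L)
  if (is.null(terminus) == is.null(residual_mass)) {
    stop("exactly one of `terminus` and `residual_mass` must be given")
  }
  cls <- library$class[match(cap, library$token)]
  if (is.na(cls) || cls != "acyl_cap") stop("not an acyl cap token: ", cap)
  res_cls <- library$class[match(residues[!is.na(residues)], library$token)]
  if (anyNA(res_cls) || any(res_cls != "internal")) {
    bad <- residues[!is.na(residues)][is.na(res_cls) | res_cls != "internal"]
    stop("not internal residue token(s): ", paste(unique(bad), collapse = ", "))
  }
  if (!is.null(terminus)) {
    tcls <- library$class[match(terminus, library$token)]
    if (is.na(tcls) || tcls != "amino_alcohol") {
      stop("not an amino alcohol token: ", terminus)
    }
  } else {
    stopifnot(is.numeric(residual_mass), residual_mass > 0)
  }
  structure(
    list(cap = cap, residues = as.character(residues), terminus = terminus,
         residual_mass = residual_mass, label = label, rt = rt),
    class = "peptaibol"
  )
}

#' Parse a sequence string into a peptaibol model
#'
#' The grammar is hyphen-joined tokens: the acyl cap first, then internal
#' residues, then either an amino-alcohol token or a numeric residual mass.
#' A skipped module is written `(skip)`.
#'
#' @param x Character vector of sequence strings, e.g.
#'   `"Ac-Aib-Ser-...-Lxxol"`.
#' @param label,rt Optional labels / retention times recycled along `x`.
#' @param library Residue library.
#' @return A `peptaibol` for a single string, otherwise a list of them.
#' @export
#' @examples
#' parse_peptaibol("Oc-Aib-Gly-Lxx-Aib-Gly-Lxx-Lxxol")
parse_peptaibol <- function(x, label = x, rt = NA_real_,
                            library = residue_library()) {
  label <- rep_len(label, length(x))
  rt <- rep_len(rt, length(x))
  out <- lapply(seq_along(x), function(i) {
    toks <- strsplit(x[[i]], "-", fixed = TRUE)[[1]]
    if (length(toks) < 2L) stop("sequence needs at least a cap and a terminus: ", x[[i]])
    toks[toks == "(skip)"] <- NA_character_
    cap <- toks[1L]
    last <- toks[length(toks)]
    mid <- toks[-c(1L, length(toks))]
    if (!is.na(last) && grepl("^[0-9.]+$", last)) {
      peptaibol(cap, mid, residual_mass = as.numeric(last),
                label = label[[i]], rt = rt[[i]], library = library)
    } else {
      peptaibol(cap, mid, terminus = last,
                label = label[[i]], rt = rt[[i]], library = library)
    }
  })
  if (length(out) == 1L) out[[1L]] else out
}

#' Sequence string of a peptaibol model
#'
#' Inverse of [parse_peptaibol()]: hyphen-joined tokens with gaps rendered
#' `(skip)` and an unresolved terminus rendered as its residual mass rounded
#' to integer Da (full precision is kept in the object).
#'
#' @param x A `peptaibol`.
#' @return A single string.
#' @export
sequence_string <- function(x) {
  stopifnot(inherits(x, "peptaibol"))
  res <- ifelse(is.na(x$residues), "(skip)", x$residues)
  term <- if (!is.null(x$terminus)) x$terminus else as.character(round(x$residual_mass))
  paste(c(x$cap, res, term), collapse = "-")
}

#' @export
print.peptaibol <- function(x, ...) {
  n <- seq_length(x)
  cat(sprintf("<peptaibol> %s (%d residues%s)\n", sequence_string(x), n,
              if (!is.null(x$residual_mass)) " + residual" else ""))
  if (nzchar(x$label) && !identical(x$label, sequence_string(x))) {
    cat("  label:", x$label, "\n")
  }
  if (!is.na(x$rt)) cat("  rt:", x$rt, "min\n")
  invisible(x)
}

#' @export
format.peptaibol <- function(x, ...) sequence_string(x)

#' Residue count of a compound
#'
#' Counts non-gap internal residues plus the amino-alcohol terminus (when
#' resolved), matching the field convention in which a "19-residue" peptaibol
#' has 18 internal residues and one C-terminal amino alcohol.
#'
#' @param x A `peptaibol`.
#' @return Integer residue count.
#' @export
seq_length <- function(x) {
  stopifnot(inherits(x, "peptaibol"))
  sum(!is.na(x$residues)) + as.integer(!is.null(x$terminus))
}

#' Monoisotopic neutral mass
#'
#' The neutral molecule mass: acyl-cap delta plus the sum of non-gap internal
#' residue masses plus the free amino-alcohol mass. The two terminal
#' hydrogens of the bookkeeping cancel, so no further correction applies.
#'
#' @param x A `peptaibol` with a resolved terminus.
#' @param library Residue library.
#' @return Neutral monoisotopic mass in Da.
#' @export
#' @examples
#' neutral_mass(parse_peptaibol("Oc-Aib-Gly-Lxx-Aib-Gly-Lxx-Lxxol"))
neutral_mass <- function(x, library = residue_library()) {
  stopifnot(inherits(x, "peptaibol"))
  if (is.null(x$terminus)) {
    stop("neutral mass is undefined for an unresolved (residual-mass) terminus")
  }
  res <- x$residues[!is.na(x$residues)]
  residue_mass(x$cap, library) + sum(residue_mass(res, library)) +
    residue_mass(x$terminus, library)
}

#' Protonated molecular ion m/z
#'
#' @inheritParams neutral_mass
#' @return The `[M+H]+` m/z in Da.
#' @export
mh_plus <- function(x, library = residue_library()) {
  neutral_mass(x, library) + mass_constants()$proton
}

#' Adduct ion m/z
#'
#' Supported adducts are the ones routinely observed in positive-mode full
#' scans of peptaibols: `M+H`, `M+Na` (singly charged), `M+2H`, `M+2Na`,
#' `M+H+Na` (doubly charged).
#'
#' @inheritParams neutral_mass
#' @param adduct One of `"M+H"`, `"M+Na"`, `"M+2H"`, `"M+2Na"`, `"M+H+Na"`.
#' @param z Charge; must match the adduct (1 for the singly, 2 for the doubly
#'   charged forms).
#' @return m/z in Da.
#' @export
#' @examples
#' p <- parse_peptaibol("Oc-Aib-Gly-Lxx-Aib-Gly-Lxx-Lxxol")
#' adduct_mz(p, "M+Na", z = 1)
adduct_mz <- function(x, adduct = c("M+H", "M+Na", "M+2H", "M+2Na", "M+H+Na"),
                      z = NULL, library = residue_library()) {
  adduct <- match.arg(adduct)
  k <- mass_constants()
  cations <- switch(adduct,
    "M+H"    = k$proton,
    "M+Na"   = k$sodium_cation,
    "M+2H"   = 2 * k$proton,
    "M+2Na"  = 2 * k$sodium_cation,
    "M+H+Na" = k$proton + k$sodium_cation
  )
  need_z <- if (adduct %in% c("M+H", "M+Na")) 1L else 2L
  if (is.null(z)) z <- need_z
  if (z != need_z) {
    stop(sprintf("adduct %s requires charge %d (got %d)", adduct, need_z, z))
  }
  (neutral_mass(x, library) + cations) / z
}
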