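# Peak-list container and file-format adapters (MGF, TSV compound tables).

#' Construct a centroided peak list
#'
#' @param mz Numeric vector of m/z values (positive, finite).
#' @param intensity Non-negative intensities (defaults to 1).
#' @param precursor_mz Precursor m/z.
#' @param precursor_charge Precursor charge (default 1).
#' @param title Spectrum title / free metadata.
#' @param rt Retention time in minutes (optional).
#' @return An object of class `peaklist`, sorted ascending by m/z.
#' @export
peaklist <- function(mz, intensity = rep(1, length(mz)), precursor_mz = NA_real_,
                     precursor_charge = 1L, title = "", rt = NA_real_) {
  stopifnot(is.numeric(mz), is.numeric(intensity),
            length(mz) == length(intensity))
  if (anyNA(mz) || anyNA(intensity)) stop("peak lists must not contain NA")
  if (any(mz <= 0)) stop("m/z values must be positive")
  if (any(intensity < 0)) stop("intensities must be non-negative")
  o <- order(mz)
  structure(
    list(mz = mz[o], intensity = intensity[o], precursor_mz = precursor_mz,
         precursor_charge = as.integer(precursor_charge), title = title,
         rt = rt),
    class = "peaklist"
  )
}

#' @export
print.peaklist <- function(x, ...) {
  cat(sprintf("<peaklist> %d peaks, precursor %.4f (z=%d)%s\n",
              length(x$mz), x$precursor_mz, x$precursor_charge,
              if (nzchar(x$title)) paste0(" - ", x$title) else ""))
  invisible(x)
}

#' @export
length.peaklist <- function(x) length(x$mz)

#' Read a Mascot generic format (MGF) file
#'
#' Parses the standard dialect: `BEGIN IONS`/`END IONS` blocks with `TITLE`,
#' `PEPMASS`, `CHARGE`, `RTINSECONDS` headers and whitespace-separated
#' m/z-intensity lines. CRLF and LF files parse identically; empty blocks are
#' preserved as empty peak lists.
#'
#' @param path MGF file path.
#' @return A list of [peaklist()] objects.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  starts <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(starts) != length(ends) || any(ends < starts)) {
    stop("malformed MGF: unbalanced BEGIN IONS/END IONS")
  }
  lapply(seq_along(starts), function(i) {
    block <- lines[(starts[i] + 1L):(ends[i] - 1L)]
    block <- block[nzchar(block)]
    is_hdr <- grepl("^[A-Z]+=", block)
    hdr <- block[is_hdr]
    keys <- sub("=.*$", "", hdr)
    vals <- sub("^[A-Z]+=", "", hdr)
    names(vals) <- keys
    if (!"PEPMASS" %in% keys) stop("MGF block ", i, " lacks PEPMASS")
    pep <- as.numeric(strsplit(vals[["PEPMASS"]], "[ \t]+")[[1]][1])
    charge <- if ("CHARGE" %in% keys) {
      as.integer(sub("\\+$", "", vals[["CHARGE"]]))
    } else 1L
    rt <- if ("RTINSECONDS" %in% keys) as.numeric(vals[["RTINSECONDS"]]) / 60 else NA_real_
    peaks <- block[!is_hdr]
    if (length(peaks)) {
      mat <- do.call(rbind, lapply(strsplit(peaks, "[ \t]+"), as.numeric))
      peaklist(mat[, 1], mat[, 2], precursor_mz = pep, precursor_charge = charge,
               title = if ("TITLE" %in% keys) vals[["TITLE"]] else "", rt = rt)
    } else {
      peaklist(numeric(), numeric(), precursor_mz = pep,
               precursor_charge = charge,
               title = if ("TITLE" %in% keys) vals[["TITLE"]] else "", rt = rt)
    }
  })
}

#' Write peak lists to MGF
#'
#' @param spectra A [peaklist()] or list of them.
#' @param path Output file.
#' @param digits Decimal places for m/z (default 6).
#' @export
write_mgf <- function(spectra, path, digits = 6) {
  if (inherits(spectra, "peaklist")) spectra <- list(spectra)
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines("BEGIN IONS", con)
    if (nzchar(sp$title)) writeLines(paste0("TITLE=", sp$title), con)
    writeLines(sprintf("PEPMASS=%.*f", digits, sp$precursor_mz), con)
    writeLines(sprintf("CHARGE=%d+", sp$precursor_charge), con)
    if (!is.na(sp$rt)) writeLines(sprintf("RTINSECONDS=%.3f", sp$rt * 60), con)
    if (length(sp$mz)) {
      writeLines(sprintf("%.*f %.6g", digits, sp$mz, sp$intensity), con)
    }
    writeLines("END IONS", con)
  }
  invisible(path)
}

#' Read a compound table
#'
#' A TSV with at least `name` and `sequence` columns (hyphen-joined token
#' strings, gaps written `(skip)`, an unresolved terminus as an integer
#' residual mass); typical extra columns are `strain`, `rt`, printed ion
#' masses and area percentages. Every sequence is validated against the
#' residue library; a malformed row is reported with its file row number and
#' the offending token.
#'
#' @param path TSV path.
#' @param library Residue library.
#' @return A data frame; the parsed models are attached as the list column
#'   `model`.
#' @export
read_compound_table <- function(path, library = residue_library()) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("name", "sequence") %in% names(df))) {
    stop("compound table needs `name` and `sequence` columns")
  }
  rt <- if ("rt" %in% names(df)) df$rt else rep(NA_real_, nrow(df))
  models <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    models[[i]] <- tryCatch(
      parse_peptaibol(df$sequence[i], label = df$name[i], rt = rt[i],
                      library = library),
      error = function(e) {
        stop(sprintf("row %d (%s): %s", i + 1L, df$name[i], conditionMessage(e)),
             call. = FALSE)
      }
    )
  }
  df$model <- models
  df
}

#' Write a compound table
#'
#' @param df Data frame as returned by [read_compound_table()]; a `model`
#'   list column, if present, is serialised back to `sequence` strings and
#'   dropped.
#' @param path Output TSV path.
#' @export
write_compound_table <- function(df, path) {
  if (!is.null(df$model)) {
    df$sequence <- vapply(df$model, sequence_string, character(1))
    df$model <- NULL
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Path to a packaged data file
#'
#' Convenience accessor for the tables shipped with the package: the residue
#' library, the curated reference peptaibiotics database, and the compound
#' tables of SF1 peptaibols and lipopeptaibols of Trichoderma clade Viride
#' strains.
#'
#' @param file File name under `extdata/`; with no argument, lists them.
#' @return A file path (or a vector of available names).
#' @export
peptaibr_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "peptaibr")))
  }
  system.file("extdata", file, package = "peptaibr", mustWork = TRUE)
}
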