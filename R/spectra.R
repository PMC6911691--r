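#' Construct a SpectraSet
#'
#' A `SpectraSet` holds a sample-by-band reflectance matrix on a strictly
#' increasing, uniformly spaced wavelength grid (nm), together with unique
#' sample identifiers and a processing-stage tag.
#'
#' @param reflectance numeric matrix, samples in rows, bands in columns.
#' @param wavelengths numeric vector of band centres in nm; strictly
#'   increasing with a constant step.
#' @param sample_ids character vector of unique sample labels; defaults to
#'   the matrix rownames or `"S1"..."Sn"`.
#' @param stage processing stage, one of `"raw"`, `"trimmed"`, `"smoothed"`,
#'   `"snv"`.
#' @return an object of class `SpectraSet`.
#' @export
spectra_set <- function(reflectance, wavelengths,
                        sample_ids = NULL,
                        stage = c("raw", "trimmed", "smoothed", "snv")) {
  stage <- match.arg(stage)
  reflectance <- as.matrix(reflectance)
  storage.mode(reflectance) <- "double"
  wavelengths <- as.numeric(wavelengths)
  if (ncol(reflectance) != length(wavelengths))
    stop("number of reflectance columns (", ncol(reflectance),
         ") must equal length of wavelength grid (", length(wavelengths), ")")
  if (length(wavelengths) > 1) {
    dw <- diff(wavelengths)
    if (any(dw <= 0))
      stop("wavelengths must be strictly increasing")
    if (max(dw) - min(dw) > 1e-9)
      stop("wavelength step must be constant (tolerance 1e-9 nm)")
  }
  if (is.null(sample_ids))
    sample_ids <- rownames(reflectance)
  if (is.null(sample_ids))
    sample_ids <- paste0("S", seq_len(nrow(reflectance)))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(reflectance))
    stop("sample_ids length must match number of spectra")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyNA(reflectance) || any(!is.finite(reflectance))) {
    bad <- which(!is.finite(reflectance), arr.ind = TRUE)[1, ]
    stop("missing/non-finite reflectance for sample '", sample_ids[bad[1]],
         "' at ", wavelengths[bad[2]], " nm")
  }
  dimnames(reflectance) <- list(sample_ids, format(wavelengths, trim = TRUE))
  structure(list(wavelengths = wavelengths,
                 reflectance = reflectance,
                 sample_ids = sample_ids,
                 stage = stage),
            class = "SpectraSet")
}

#' @export
print.SpectraSet <- function(x, ...) {
  cat("SpectraSet:", nrow(x$reflectance), "samples x",
      length(x$wavelengths), "bands\n")
  cat("  wavelengths:", min(x$wavelengths), "-", max(x$wavelengths),
      "nm (step", if (length(x$wavelengths) > 1) diff(x$wavelengths)[1] else NA,
      "nm)\n")
  cat("  stage:", x$stage, "\n")
  invisible(x)
}

#' @export
dim.SpectraSet <- function(x) dim(x$reflectance)

#' Subset a SpectraSet by sample and/or band
#' @param x a `SpectraSet`.
#' @param i sample index (logical, integer or id character).
#' @param j band index (logical or integer over the wavelength grid).
#' @param ... ignored.
#' @export
`[.SpectraSet` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$reflectance))
  if (is.character(i)) i <- match(i, x$sample_ids)
  wl <- x$wavelengths
  if (!missing(j)) wl <- wl[j] else j <- seq_along(wl)
  # a band subset may break the uniform-step invariant; rebuild without the
  # constructor checks only when the subset is contiguous
  r <- x$reflectance[i, j, drop = FALSE]
  out <- x
  out$reflectance <- r
  out$wavelengths <- wl
  out$sample_ids <- x$sample_ids[i]
  out
}

#' Read a wide spectral table
#'
#' Expects the deposited supplementary-table layout: first column sample id,
#' remaining column headers numeric wavelengths in nm, one row per sample.
#' Comma- and tab-separated files are both accepted (auto-sniffed from the
#' header line).
#'
#' @param path file path.
#' @param stage stage tag to attach (default `"raw"`; use `"snv"` when
#'   loading an already-transformed sheet).
#' @param sep field separator; `NULL` (default) sniffs `\t` vs `,` from the
#'   header line.
#' @return a [spectra_set()].
#' @export
read_spectra <- function(path, stage = "raw", sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- sniff_sep(path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, colClasses = "character",
                           comment.char = "", quote = "\"",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("format error: need an id column plus band columns")
  wl <- suppressWarnings(as.numeric(colnames(tab)[-1]))
  if (anyNA(wl))
    stop("format error: non-numeric wavelength header(s): ",
         paste(colnames(tab)[-1][is.na(wl)][1:min(3, sum(is.na(wl)))],
               collapse = ", "))
  ids <- tab[[1]]
  vals <- suppressWarnings(vapply(tab[-1], as.numeric, numeric(nrow(tab))))
  vals <- matrix(vals, nrow = nrow(tab))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop("missing value for sample '", ids[bad[1]], "' at ",
         wl[bad[2]], " nm")
  }
  spectra_set(vals, wl, sample_ids = ids, stage = stage)
}

sniff_sep <- function(path) {
  header <- readLines(path, n = 1L)
  n_tab <- lengths(regmatches(header, gregexpr("\t", header)))
  n_com <- lengths(regmatches(header, gregexpr(",", header)))
  if (n_tab >= n_com) "\t" else ","
}

#' Write a SpectraSet to a wide text table
#'
#' Values are written with 17 significant digits so that a
#' write-then-read round trip reproduces the matrix bit-exactly.
#'
#' @param s a `SpectraSet`.
#' @param path output path.
#' @param sep field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_spectra <- function(s, path, sep = "\t") {
  stopifnot(inherits(s, "SpectraSet"))
  header <- paste(c("sample_id", format(s$wavelengths, trim = TRUE)),
                  collapse = sep)
  body <- vapply(seq_len(nrow(s$reflectance)), function(i) {
    paste(c(s$sample_ids[i],
            sprintf("%.17g", s$reflectance[i, ])), collapse = sep)
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Construct a ChemTable
#'
#' Per-sample laboratory concentrations of the water-quality parameters
#' (COD, BOD, NH3-N, TDS, TA in mg/L; TH in mmol/L). These are the
#' signature sequences that band screening correlates against.
#'
#' @param values numeric matrix or data.frame, samples in rows, parameters in
#'   named columns.
#' @param sample_ids unique sample labels matching a `SpectraSet`.
#' @param units optional named character vector of units per parameter.
#' @return an object of class `ChemTable`.
#' @export
chem_table <- function(values, sample_ids = NULL, units = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(colnames(values)))
    stop("parameter columns must be named")
  if (is.null(sample_ids)) sample_ids <- rownames(values)
  if (is.null(sample_ids))
    sample_ids <- paste0("S", seq_len(nrow(values)))
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids in ChemTable")
  if (length(sample_ids) != nrow(values))
    stop("sample_ids length must match rows of values")
  if (anyNA(values) || any(!is.finite(values)))
    stop("all concentrations must be finite")
  if (any(values < 0)) stop("concentrations must be >= 0")
  rownames(values) <- sample_ids
  if (is.null(units)) {
    units <- rep("mg/L", ncol(values))
    names(units) <- colnames(values)
    units[names(units) == "TH"] <- "mmol/L"
  }
  structure(list(values = values, sample_ids = sample_ids,
                 parameters = colnames(values), units = units),
            class = "ChemTable")
}

#' @export
print.ChemTable <- function(x, ...) {
  cat("ChemTable:", nrow(x$values), "samples x",
      ncol(x$values), "parameters (",
      paste(x$parameters, collapse = ", "), ")\n")
  invisible(x)
}

#' Read a chemistry table
#'
#' First column sample id, remaining named columns parameter concentrations.
#'
#' @inheritParams read_spectra
#' @return a [chem_table()].
#' @export
read_chem <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- sniff_sep(path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  chem_table(as.matrix(tab[-1]), sample_ids = tab[[1]])
}

#' Write a ChemTable
#' @param chem a `ChemTable`.
#' @param path output path.
#' @param sep field separator (default comma).
#' @export
write_chem <- function(chem, path, sep = ",") {
  stopifnot(inherits(chem, "ChemTable"))
  header <- paste(c("sample_id", chem$parameters), collapse = sep)
  body <- vapply(seq_len(nrow(chem$values)), function(i) {
    paste(c(chem$sample_ids[i], sprintf("%.17g", chem$values[i, ])),
          collapse = sep)
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Align spectra with chemistry by sample id
#'
#' Restricts both tables to their common sample ids, in the original
#' spectral row order, and reports the ids dropped from either side.
#'
#' @param spectra a `SpectraSet`.
#' @param chem a `ChemTable`.
#' @return a list with elements `spectra`, `chem` (aligned, common ids only)
#'   and `dropped` (list of ids present on one side only).
#' @export
join_chem <- function(spectra, chem) {
  stopifnot(inherits(spectra, "SpectraSet"), inherits(chem, "ChemTable"))
  common <- spectra$sample_ids[spectra$sample_ids %in% chem$sample_ids]
  if (length(common) == 0)
    stop("no common sample ids between spectra and chemistry tables")
  dropped <- list(
    spectra_only = setdiff(spectra$sample_ids, chem$sample_ids),
    chem_only = setdiff(chem$sample_ids, spectra$sample_ids))
  s <- spectra[common, ]
  cvals <- chem$values[match(common, chem$sample_ids), , drop = FALSE]
  list(spectra = s,
       chem = chem_table(cvals, sample_ids = common, units = chem$units),
       dropped = dropped)
}

#' Extract one parameter's concentration vector
#' @param chem a `ChemTable`.
#' @param parameter parameter name, e.g. `"COD"`.
#' @return named numeric vector.
#' @export
chem_values <- function(chem, parameter) {
  stopifnot(inherits(chem, "ChemTable"))
  if (!parameter %in% chem$parameters)
    stop("unknown parameter '", parameter, "'; available: ",
         paste(chem$parameters, collapse = ", "))
  stats::setNames(chem$values[, parameter], chem$sample_ids)
}
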