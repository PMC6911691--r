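#' Pretreatment configuration
#'
#' Controls the two-step spectral pretreatment: (1) marginal-band removal
#' and Savitzky-Golay least-squares smoothing, then (2) the standard normal
#' variate (SNV) transform that removes baseline shift and multiplicative
#' surface scatter.
#'
#' @param trim_low lower wavelength bound kept, nm (default 400).
#' @param trim_high upper wavelength bound kept, nm (default 2400).
#' @param sg_order Savitzky-Golay polynomial order (default 2).
#' @param sg_window Savitzky-Golay window size, odd, `> sg_order`
#'   (default 5).
#' @param snv_ddof degrees-of-freedom convention for the per-spectrum
#'   standard deviation in SNV: 1 (sample sd, default) or 0.
#' @return a list of class `preprocess_config`.
#' @export
preprocess_config <- function(trim_low = 400, trim_high = 2400,
                              sg_order = 2, sg_window = 5, snv_ddof = 1) {
  if (sg_window %% 2 != 1) stop("sg_window must be odd")
  if (sg_window <= sg_order) stop("sg_window must exceed sg_order")
  if (trim_low >= trim_high) stop("trim_low must be below trim_high")
  if (!snv_ddof %in% c(0, 1)) stop("snv_ddof must be 0 or 1")
  structure(list(trim_low = trim_low, trim_high = trim_high,
                 sg_order = sg_order, sg_window = sg_window,
                 snv_ddof = snv_ddof),
            class = "preprocess_config")
}

#' Remove noisy marginal wavelengths
#'
#' Drops bands outside `[trim_low, trim_high]`; with the defaults a
#' 350-2,500 nm grid becomes 400-2,400 nm (2,001 bands at 1-nm step).
#'
#' @param s a `SpectraSet` (stage `"raw"`).
#' @param cfg a [preprocess_config()].
#' @return trimmed `SpectraSet` with stage `"trimmed"`.
#' @export
trim_margins <- function(s, cfg = preprocess_config()) {
  stopifnot(inherits(s, "SpectraSet"))
  keep <- s$wavelengths >= cfg$trim_low & s$wavelengths <= cfg$trim_high
  if (sum(keep) < cfg$sg_window)
    stop("trimming leaves ", sum(keep), " bands, fewer than sg_window (",
         cfg$sg_window, ")")
  out <- s[, keep]
  out$stage <- "trimmed"
  out
}

# Symmetric least-squares smoothing kernel: the row of the polynomial
# projection matrix that evaluates the fit at the window centre.
savgol_kernel <- function(window, order) {
  h <- (window - 1L) / 2L
  A <- outer(seq(-h, h), 0:order, `^`)
  (A %*% solve(crossprod(A), t(A)))[h + 1L, ]
}

#' Savitzky-Golay smoothing
#'
#' Convolves each spectrum with the least-squares polynomial filter
#' (default order 2, window 5, interior weights (-3, 12, 17, 12, -3)/35).
#' Edges are handled by mirror padding so the band grid is not shortened.
#'
#' @param s a `SpectraSet` (stage `"trimmed"` or `"raw"`).
#' @param cfg a [preprocess_config()].
#' @return smoothed `SpectraSet`, stage `"smoothed"`.
#' @export
savgol_smooth <- function(s, cfg = preprocess_config()) {
  stopifnot(inherits(s, "SpectraSet"))
  n <- length(s$wavelengths)
  if (cfg$sg_window > n)
    stop("sg_window (", cfg$sg_window, ") exceeds band count (", n, ")")
  k <- savgol_kernel(cfg$sg_window, cfg$sg_order)
  h <- (cfg$sg_window - 1L) / 2L
  # mirror padding without repeating the edge sample
  idx <- c(seq(h + 1L, 2L), seq_len(n), seq(n - 1L, n - h))
  sm <- t(apply(s$reflectance, 1L, function(row) {
    padded <- row[idx]
    as.numeric(stats::filter(padded, k, sides = 2))[(h + 1L):(h + n)]
  }))
  out <- s
  out$reflectance <- sm
  dimnames(out$reflectance) <- dimnames(s$reflectance)
  out$stage <- "smoothed"
  out
}

#' Standard normal variate transform
#'
#' Centres and scales each spectrum to mean 0 and unit standard deviation,
#' removing per-sample baseline shift and multiplicative scatter.
#'
#' @param s a `SpectraSet`.
#' @param cfg a [preprocess_config()] (only `snv_ddof` is used).
#' @return transformed `SpectraSet`, stage `"snv"`.
#' @export
snv_transform <- function(s, cfg = preprocess_config()) {
  stopifnot(inherits(s, "SpectraSet"))
  n <- ncol(s$reflectance)
  mu <- rowMeans(s$reflectance)
  centred <- s$reflectance - mu
  denom <- if (cfg$snv_ddof == 1) n - 1L else n
  sds <- sqrt(rowSums(centred^2) / denom)
  if (any(sds == 0))
    stop("constant spectrum (zero spread) for sample(s): ",
         paste(s$sample_ids[sds == 0], collapse = ", "))
  out <- s
  out$reflectance <- centred / sds
  dimnames(out$reflectance) <- dimnames(s$reflectance)
  out$stage <- "snv"
  out
}

#' Full pretreatment pipeline
#'
#' `trim_margins()` then `savgol_smooth()` then `snv_transform()`, in the
#' order the pretreatment is defined.
#'
#' @inheritParams trim_margins
#' @return `SpectraSet` with stage `"snv"`.
#' @export
preprocess_spectra <- function(s, cfg = preprocess_config()) {
  snv_transform(savgol_smooth(trim_margins(s, cfg), cfg), cfg)
}
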