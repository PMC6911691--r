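#' Default synthetic analyte templates
#'
#' Six wastewater parameters with Gaussian absorption features placed in
#' the spectral regions where screening on real sewage spectra responds
#' (near 460, 760, 820 and 990 nm, plus two NIR features), so screening
#' tests have known answers. Strengths are per mg/L (per mmol/L for TH)
#' and concentration ranges follow typical inlet-to-outlet sewage spans.
#'
#' @return a list of analyte descriptors (`name`, `centers`, `widths`,
#'   `strengths`, `range`, `unit`).
#' @export
default_analytes <- function() {
  list(
    list(name = "COD", centers = 820, widths = 30, strengths = 5e-4,
         range = c(20, 425), unit = "mg/L"),
    list(name = "BOD", centers = 760, widths = 25, strengths = 2e-3,
         range = c(3.1, 86), unit = "mg/L"),
    list(name = "NH3-N", centers = 990, widths = 20, strengths = 5e-3,
         range = c(0, 34.853), unit = "mg/L"),
    list(name = "TDS", centers = 460, widths = 25, strengths = 4e-4,
         range = c(317, 351), unit = "mg/L"),
    list(name = "TH", centers = 1200, widths = 40, strengths = 0.09,
         range = c(1.09, 1.17), unit = "mmol/L"),
    list(name = "TA", centers = 1650, widths = 45, strengths = 8e-4,
         range = c(101.15, 251.70), unit = "mg/L"))
}

#' Synthetic-spectra configuration
#'
#' Describes wastewater-like reflectance spectra with known structure:
#' a smooth polynomial baseline, concentration-linear Gaussian absorption
#' features per analyte, per-sample multiplicative scatter (which SNV
#' removes), and additive Gaussian noise. The primary (first) analyte's
#' concentrations are snapped to a dilution-grid granularity, emulating a
#' pure-water dilution series.
#'
#' @param n_samples number of samples (default 87).
#' @param wavelengths band grid in nm (default 400-2,400 at 1 nm).
#' @param analytes list of analyte descriptors as in [default_analytes()].
#' @param baseline_coef polynomial coefficients over the normalised
#'   wavelength `u = (lambda - min) / (max - min)`; kept gentle so the
#'   baseline does not swamp the absorption features.
#' @param scatter_range per-sample multiplicative factor range.
#' @param noise_sd additive noise standard deviation (default 0.002,
#'   about 1% of the absorption signal range).
#' @param dilution_step concentration granularity of the primary analyte,
#'   mg/L (default 5).
#' @param seed integer seed (default 1).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 87,
                       wavelengths = seq(400, 2400, by = 1),
                       analytes = default_analytes(),
                       baseline_coef = c(0.50, 0.03, -0.02),
                       scatter_range = c(0.95, 1.05),
                       noise_sd = 0.002,
                       dilution_step = 5,
                       seed = 1) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (dilution_step <= 0) stop("dilution_step must be > 0")
  for (a in analytes) {
    if (any(a$widths <= 0)) stop("analyte widths must be > 0")
    if (any(a$range < 0)) stop("concentration ranges must be nonnegative")
  }
  structure(list(n_samples = n_samples, wavelengths = wavelengths,
                 analytes = analytes, baseline_coef = baseline_coef,
                 scatter_range = scatter_range, noise_sd = noise_sd,
                 dilution_step = dilution_step, seed = seed),
            class = "sim_config")
}

#' Generate synthetic wastewater spectra
#'
#' Reflectance is `baseline(lambda) - sum_a conc_a * shape_a(lambda)`
#' (Gaussian absorption features), then a per-sample multiplicative
#' scatter factor and additive Gaussian noise; negative values are clipped
#' at zero with a reported count. Deterministic for a given config seed;
#' the caller's RNG state is left untouched.
#'
#' @param cfg a [sim_config()].
#' @return list with `spectra` (a `SpectraSet`, stage `"raw"`), `chem`
#'   (a `ChemTable`), and `truth` (planted centers, concentrations,
#'   baseline, scatter factors, clip count).
#' @export
generate_spectra <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  wl <- cfg$wavelengths
  n <- cfg$n_samples
  u <- (wl - min(wl)) / diff(range(wl))
  baseline <- drop(outer(u, seq_along(cfg$baseline_coef) - 1, `^`) %*%
                     cfg$baseline_coef)
  shapes <- lapply(cfg$analytes, function(a) {
    rowSums(mapply(function(ctr, w, s) s * exp(-(wl - ctr)^2 / (2 * w^2)),
                   a$centers, a$widths, a$strengths))
  })
  out <- with_seed(cfg$seed, {
    conc <- do.call(cbind, lapply(seq_along(cfg$analytes), function(i) {
      a <- cfg$analytes[[i]]
      ci <- stats::runif(n, a$range[1], a$range[2])
      if (i == 1)  # primary analyte: dilution-grid granularity
        ci <- pmin(pmax(round(ci / cfg$dilution_step) * cfg$dilution_step,
                        a$range[1]), a$range[2])
      ci
    }))
    colnames(conc) <- vapply(cfg$analytes, `[[`, "", "name")
    R <- matrix(rep(baseline, each = n), nrow = n)
    for (i in seq_along(shapes))
      R <- R - tcrossprod(conc[, i], shapes[[i]])
    scatter <- stats::runif(n, cfg$scatter_range[1], cfg$scatter_range[2])
    R <- R * scatter
    if (cfg$noise_sd > 0)
      R <- R + matrix(stats::rnorm(n * length(wl), 0, cfg$noise_sd),
                      nrow = n)
    list(conc = conc, R = R, scatter = scatter)
  })
  n_clip <- sum(out$R < 0)
  if (n_clip > 0) {
    warning(n_clip, " negative reflectance value(s) clipped to 0")
    out$R[out$R < 0] <- 0
  }
  ids <- sprintf("WW%03d", seq_len(n))
  units <- stats::setNames(vapply(cfg$analytes, `[[`, "", "unit"),
                           colnames(out$conc))
  list(spectra = spectra_set(out$R, wl, sample_ids = ids, stage = "raw"),
       chem = chem_table(out$conc, sample_ids = ids, units = units),
       truth = list(centers = lapply(cfg$analytes, `[[`, "centers"),
                    names = colnames(out$conc),
                    concentrations = out$conc,
                    baseline = baseline, scatter = out$scatter,
                    clipped = n_clip, config = cfg))
}

#' Pure-water dilution series
#'
#' Arithmetic descending concentration grid from a stock solution,
#' clipped at zero.
#'
#' @param stock starting concentration (mg/L).
#' @param step dilution step (mg/L, default 5).
#' @param n number of dilutions.
#' @return numeric vector of length `n`.
#' @export
dilution_series <- function(stock, step = 5, n) {
  if (step <= 0) stop("step must be > 0")
  if (n <= 0) stop("n must be >= 1")
  pmax(stock - step * (seq_len(n) - 1), 0)
}

# Evaluate expr under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}
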