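#' Fit a water-quality inversion model from spectra
#'
#' One call runs the full workflow for one parameter: pretreatment
#' (trim + Savitzky-Golay + SNV, skipped when the input is already at
#' stage `"snv"`), band screening, a Kennard-Stone calibration/validation
#' split on the full-band SNV spectra, model fitting on the screened
#' calibration bands, and validation-set evaluation.
#'
#' @param spectra a `SpectraSet` (stage `"raw"` or `"snv"`).
#' @param chem a `ChemTable` sharing sample ids with `spectra`.
#' @param parameter which parameter to invert (e.g. `"COD"`).
#' @param screen band-screening method: `"gc"` (gray correlation degree),
#'   `"vip"`, `"spa"` (set-pair fusion of gc and vip), `"pearson"`, or
#'   `"all"` (no screening, full band).
#' @param model regressor: `"plsr"` (NIPALS) or `"elm"`.
#' @param preprocess_cfg a [preprocess_config()].
#' @param gc_cfg a [gc_config()].
#' @param vip_cfg a [vip_config()].
#' @param ncomp PLSR component count, or `"cv"` (default) for 10-fold
#'   cross-validated choice on the calibration set.
#' @param hidden ELM hidden-layer size, or `"cv"` for a 5-fold
#'   cross-validated choice over `c(5, 10, 20, 40, 80)`.
#' @param fraction calibration share of the Kennard-Stone split
#'   (default 2/3).
#' @param screen_on `"all"` (default; screening uses every sample, the
#'   convention behind published score tables) or `"calibration"` (avoids
#'   validation leakage into band selection).
#' @param seed integer seed for the ELM hidden layer (ignored for PLSR).
#' @return an object of class `wqi` with the screening result (`screen`),
#'   split (`split`), fitted model (`model_fit`), evaluation (`report`),
#'   and bookkeeping needed by `predict()`.
#' @seealso [predict.wqi()], [summary.wqi()]
#' @examples
#' sim <- generate_spectra(sim_config(seed = 7))
#' fit <- wqi(sim$spectra, sim$chem, "COD", screen = "gc", model = "plsr")
#' summary(fit)
#' @export
wqi <- function(spectra, chem, parameter,
                screen = c("gc", "vip", "spa", "pearson", "all"),
                model = c("plsr", "elm"),
                preprocess_cfg = preprocess_config(),
                gc_cfg = gc_config(), vip_cfg = vip_config(),
                ncomp = "cv", hidden = "cv",
                fraction = 2 / 3,
                screen_on = c("all", "calibration"),
                seed = 1) {
  screen <- match.arg(screen)
  model <- match.arg(model)
  screen_on <- match.arg(screen_on)
  cl <- match.call()
  joined <- join_chem(spectra, chem)
  snv <- if (joined$spectra$stage == "snv") joined$spectra
         else preprocess_spectra(joined$spectra, preprocess_cfg)
  y <- chem_values(joined$chem, parameter)
  split <- split_two_thirds(snv, fraction = fraction)
  cal <- split$calibration
  scr_idx <- if (screen_on == "all") seq_along(y) else cal
  scr <- screen_bands(snv[scr_idx, ], y[scr_idx], parameter, screen,
                      gc_cfg, vip_cfg)
  sel <- select_bands(scr, snv)
  fit <- fit_inversion(sel$x[cal, , drop = FALSE], y[cal], model,
                       ncomp, hidden, seed)
  val <- split$validation
  pred_val <- predict(fit$fit, sel$x[val, , drop = FALSE])
  report <- model_report(y[cal], fit$fit$fitted, y[val], pred_val,
                         parameter = parameter, method = screen,
                         model = model, hyper = fit$hyper,
                         n_bands = ncol(sel$x))
  structure(list(call = cl, parameter = parameter,
                 screen_method = screen, model_type = model,
                 screen = scr, split = split, model_fit = fit$fit,
                 hyper = fit$hyper, report = report,
                 wavelengths = sel$wavelengths,
                 preprocess_cfg = preprocess_cfg,
                 y = y, predicted_validation = pred_val,
                 seed = seed),
            class = "wqi")
}

# one screening dispatch shared by wqi() and run_pipeline()
screen_bands <- function(snv, y, parameter, method, gc_cfg, vip_cfg) {
  switch(method,
         gc = gcd_screen(y, snv, gc_cfg, parameter = parameter),
         vip = vip_screen(snv, y, vip_cfg, parameter = parameter),
         spa = spa_screen(gcd_screen(y, snv, gc_cfg, parameter = parameter),
                          vip_screen(snv, y, vip_cfg,
                                     parameter = parameter)),
         pearson = pearson_screen(snv, y, parameter = parameter),
         all = new_screen_result("all", parameter, snv$wavelengths,
                                 rep(1, length(snv$wavelengths)),
                                 rep(TRUE, length(snv$wavelengths)),
                                 threshold = 0))
}

fit_inversion <- function(x, y, model, ncomp, hidden, seed) {
  if (model == "plsr") {
    m <- if (identical(ncomp, "cv")) select_ncomp(x, y)
         else as.integer(ncomp)
    m <- min(m, nrow(x) - 1L, ncol(x))
    list(fit = fit_plsr(x, y, m), hyper = m)
  } else {
    L <- if (identical(hidden, "cv")) select_hidden(x, y, seed = seed)
         else as.integer(hidden)
    list(fit = fit_elm(x, y, L, seed = seed), hyper = L)
  }
}

#' Choose an ELM hidden size by cross-validation
#'
#' 5-fold cross-validated RMSE over a candidate grid, with folds assigned
#' deterministically by cycling sample indices and the same hidden-layer
#' seed used throughout.
#'
#' @inheritParams fit_elm
#' @param candidates hidden sizes tried (default `c(5, 10, 20, 40, 80)`).
#' @param folds number of folds (default 5).
#' @return the candidate minimising cross-validated RMSE.
#' @export
select_hidden <- function(x, y, candidates = c(5, 10, 20, 40, 80),
                          folds = 5, seed = 1) {
  x <- as.matrix(x)
  n <- nrow(x)
  folds <- min(folds, n)
  fold_id <- rep_len(seq_len(folds), n)
  press <- numeric(length(candidates))
  for (kf in seq_len(folds)) {
    tr <- fold_id != kf
    for (i in seq_along(candidates)) {
      L <- min(candidates[i], sum(tr))
      fit <- fit_elm(x[tr, , drop = FALSE], y[tr], L, seed = seed)
      pred <- predict(fit, x[!tr, , drop = FALSE])
      press[i] <- press[i] + sum((y[!tr] - pred)^2)
    }
  }
  candidates[which.min(press)]
}

#' @export
print.wqi <- function(x, ...) {
  cat("Water-quality inversion:", x$parameter,
      "|", x$screen_method, "bands |", toupper(x$model_type), "\n")
  cat("  bands used:", x$report$n_bands,
      "| hyperparameter:", x$hyper, "\n")
  cat(sprintf("  R2c %.3f  R2p %.3f  RMSEP %.4g  RPD %.3f (%s)\n",
              x$report$r2c, x$report$r2p, x$report$rmsep,
              x$report$rpd, x$report$rpd_category))
  invisible(x)
}

#' @export
summary.wqi <- function(object, ...) {
  cat("Call: "); print(object$call)
  print(object$screen)
  print(object$split)
  print(object$model_fit)
  print(object$report)
  invisible(object)
}

#' @export
coef.wqi <- function(object, ...) {
  if (!inherits(object$model_fit, "wq_plsr"))
    stop("coefficients are defined for PLSR fits only")
  stats::setNames(
    c(coef(object$model_fit)[1], object$model_fit$coef),
    c("(Intercept)", format(object$wavelengths, trim = TRUE)))
}

#' Predict concentrations for new spectra
#'
#' Applies the stored pretreatment (unless the input is already at stage
#' `"snv"`) and band selection, then the fitted regressor.
#'
#' @param object a fitted [wqi()] model.
#' @param newdata a `SpectraSet` (or band matrix already on the model's
#'   selected-band grid).
#' @param ... ignored.
#' @return numeric vector of predicted concentrations.
#' @export
predict.wqi <- function(object, newdata, ...) {
  if (inherits(newdata, "SpectraSet")) {
    snv <- if (newdata$stage == "snv") newdata
           else preprocess_spectra(newdata, object$preprocess_cfg)
    if (length(snv$wavelengths) != length(object$screen$wavelengths))
      stop("newdata band grid does not match the training grid")
    x <- snv$reflectance[, object$screen$mask, drop = FALSE]
  } else {
    x <- band_matrix(newdata)
  }
  predict(object$model_fit, x)
}

#' @export
fitted.wqi <- function(object, ...) object$model_fit$fitted

#' @export
residuals.wqi <- function(object, ...) {
  resid <- residuals(object$model_fit)
  names(resid) <- object$split$calibration_ids
  resid
}

#' Observed-vs-predicted plot for a fitted inversion
#'
#' Calibration and validation samples against the 1:1 line.
#'
#' @param x a fitted [wqi()] model.
#' @param ... passed to [graphics::plot()].
#' @export
plot.wqi <- function(x, ...) {
  cal <- x$split$calibration
  val <- x$split$validation
  obs <- c(x$y[cal], x$y[val])
  pred <- c(x$model_fit$fitted, x$predicted_validation)
  graphics::plot(obs, pred,
                 col = c(rep("grey40", length(cal)),
                         rep("firebrick", length(val))),
                 pch = c(rep(1, length(cal)), rep(16, length(val))),
                 xlab = paste("observed", x$parameter),
                 ylab = paste("predicted", x$parameter),
                 main = sprintf("%s (%s bands, %s)", x$parameter,
                                x$screen_method, toupper(x$model_type)),
                 ...)
  graphics::abline(0, 1, lty = 2)
  graphics::legend("topleft", c("calibration", "validation"),
                   col = c("grey40", "firebrick"), pch = c(1, 16),
                   bty = "n")
  invisible(x)
}
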