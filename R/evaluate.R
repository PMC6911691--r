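#' Calibration/prediction regression metrics
#'
#' R-squared as the squared Pearson correlation between observed and
#' predicted values (the usual convention in chemometric calibration
#' reporting; set `method = "ss"` for 1 - SSE/SST) and the root mean
#' squared residual.
#'
#' @param observed,predicted numeric vectors of equal length (>= 2).
#' @param method `"cor"` (default, squared correlation) or `"ss"`
#'   (sum-of-squares definition).
#' @return list with `r2` and `rmse`.
#' @export
regression_metrics <- function(observed, predicted,
                               method = c("cor", "ss")) {
  method <- match.arg(method)
  if (length(observed) != length(predicted) || length(observed) < 2)
    stop("observed and predicted must share length >= 2")
  if (stats::var(observed) == 0)
    stop("observed values are constant; R2 undefined")
  r2 <- if (method == "cor") {
    if (stats::sd(predicted) == 0) 0 else
      stats::cor(observed, predicted)^2
  } else {
    1 - sum((observed - predicted)^2) / sum((observed - mean(observed))^2)
  }
  list(r2 = r2, rmse = sqrt(mean((observed - predicted)^2)))
}

#' Relative prediction deviation and its category
#'
#' RPD = sd(validation observations) / RMSEP, with the conventional
#' five-band interpretation: poor (<= 1.5), satisfactory (1.5, 2\],
#' good (2, 2.5\], very good (2.5, 3\], excellent (> 3).
#'
#' @param observed_validation reference values of the validation set.
#' @param rmsep root mean square error of prediction.
#' @param ddof 1 (default, sample sd) or 0.
#' @return list with `rpd` and `category`; a zero `rmsep` yields infinite
#'   RPD and category `"excellent"`.
#' @export
rpd <- function(observed_validation, rmsep, ddof = 1) {
  n <- length(observed_validation)
  s2 <- sum((observed_validation - mean(observed_validation))^2) /
    (if (ddof == 1) n - 1 else n)
  s <- sqrt(s2)
  if (rmsep < 0) stop("rmsep must be >= 0")
  if (rmsep == 0) return(list(rpd = Inf, category = "excellent"))
  val <- s / rmsep
  list(rpd = val, category = rpd_category(val))
}

#' RPD category label
#' @param x positive RPD value (vectorised).
#' @return character vector of category labels.
#' @export
rpd_category <- function(x) {
  as.character(cut(x, breaks = c(0, 1.5, 2, 2.5, 3, Inf),
                   labels = c("poor", "satisfactory", "good",
                              "very good", "excellent"),
                   right = TRUE))
}

#' Model robustness ratio
#'
#' Ratio of prediction to calibration determination coefficients,
#' `R2p / R2c`; values near 1 indicate a model that generalises as well
#' as it fits, and the ratio may exceed 1.
#'
#' @param r2c calibration R-squared (> 0).
#' @param r2p prediction R-squared.
#' @return the ratio.
#' @export
robustness <- function(r2c, r2p) {
  if (any(r2c <= 0)) stop("r2c must be > 0")
  r2p / r2c
}

#' Assemble a model report
#'
#' @param observed_cal,predicted_cal calibration-set observed/predicted.
#' @param observed_val,predicted_val validation-set observed/predicted.
#' @param parameter,method,model labels (parameter name, band-selection
#'   method, regressor type).
#' @param hyper hyperparameter value (PLSR components or ELM neurons).
#' @param rpd_ddof sd convention for RPD (default 1).
#' @return a list of class `ModelReport` with `r2c`, `r2p`, `rmsec`,
#'   `rmsep`, `rpd`, `rpd_category`, `robustness`, `n_bands`, labels.
#' @export
model_report <- function(observed_cal, predicted_cal,
                         observed_val, predicted_val,
                         parameter = "", method = "", model = "",
                         hyper = NA, n_bands = NA, rpd_ddof = 1) {
  mc <- regression_metrics(observed_cal, predicted_cal)
  mp <- regression_metrics(observed_val, predicted_val)
  rp <- rpd(observed_val, mp$rmse, ddof = rpd_ddof)
  structure(list(parameter = parameter, method = method, model = model,
                 hyper = hyper, n_bands = n_bands,
                 r2c = mc$r2, r2p = mp$r2,
                 rmsec = mc$rmse, rmsep = mp$rmse,
                 rpd = rp$rpd, rpd_category = rp$category,
                 robustness = robustness(mc$r2, mp$r2)),
            class = "ModelReport")
}

#' @export
print.ModelReport <- function(x, ...) {
  cat(sprintf("ModelReport %s/%s/%s: R2c %.3f R2p %.3f RMSEC %.4g RMSEP %.4g RPD %.3f (%s) robustness %.3f\n",
              x$parameter, x$method, x$model, x$r2c, x$r2p,
              x$rmsec, x$rmsep, x$rpd, x$rpd_category, x$robustness))
  invisible(x)
}

#' @export
as.data.frame.ModelReport <- function(x, ...) {
  data.frame(parameter = x$parameter, method = x$method, model = x$model,
             hyper = x$hyper, n_bands = x$n_bands,
             r2c = x$r2c, r2p = x$r2p, rmsec = x$rmsec, rmsep = x$rmsep,
             rpd = x$rpd, rpd_category = x$rpd_category,
             robustness = x$robustness, stringsAsFactors = FALSE)
}

#' Rank a set of model reports
#'
#' Sorted by RPD descending, ties broken by prediction R-squared; the top
#' report per parameter is flagged as best.
#'
#' @param reports list of `ModelReport` objects (or a data.frame from
#'   previous calls).
#' @return data.frame, one row per report, with a logical `best` column.
#' @export
compare_models <- function(reports) {
  if (inherits(reports, "ModelReport")) reports <- list(reports)
  if (length(reports) < 1) stop("need at least one report")
  tab <- do.call(rbind, lapply(reports, as.data.frame))
  ord <- order(-tab$rpd, -tab$r2p)
  tab <- tab[ord, , drop = FALSE]
  tab$best <- !duplicated(tab$parameter)
  rownames(tab) <- NULL
  tab
}
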