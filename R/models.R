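#' Fit a partial least squares regression (NIPALS)
#'
#' Single-response PLS1 by the NIPALS algorithm with X-deflation. Predictors
#' and response are centred internally. The fitted object stores the
#' unit-norm weight matrix W and the per-component fraction of response
#' variance explained, Rd(Y; t_h) — both of which the VIP statistic reuses.
#'
#' @param x numeric matrix, samples in rows, bands in columns.
#' @param y numeric response vector (concentrations).
#' @param ncomp number of latent components, `<= min(n - 1, n_bands)`.
#' @return an object of class `wq_plsr` with elements `weights` (W,
#'   band x component, unit columns), `loadings` (P), `q` (response
#'   loadings), `coef` (regression vector on centred data), `rd`
#'   (per-component explained response-variance fraction), `scores`,
#'   `x_mean`, `y_mean`, `fitted`.
#' @export
fit_plsr <- function(x, y, ncomp) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  n <- nrow(x); p <- ncol(x)
  if (length(y) != n) stop("length(y) must equal nrow(x)")
  if (stats::var(y) == 0) stop("response has zero variance")
  if (ncomp < 1 || ncomp > min(n - 1, p))
    stop("ncomp must be in [1, min(n - 1, n_bands)] = [1, ",
         min(n - 1, p), "]")
  x_mean <- colMeans(x)
  y_mean <- mean(y)
  E <- sweep(x, 2, x_mean)
  f <- y - y_mean
  ssy <- sum(f^2)
  W <- matrix(0, p, ncomp)
  P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp)
  q <- numeric(ncomp)
  rd <- numeric(ncomp)
  for (h in seq_len(ncomp)) {
    w <- crossprod(E, f)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-300) {           # residual X carries no covariance with y
      W <- W[, seq_len(h - 1), drop = FALSE]
      P <- P[, seq_len(h - 1), drop = FALSE]
      Tm <- Tm[, seq_len(h - 1), drop = FALSE]
      q <- q[seq_len(h - 1)]
      rd <- rd[seq_len(h - 1)]
      ncomp <- h - 1L
      break
    }
    w <- w / nw
    t_h <- drop(E %*% w)
    tt <- sum(t_h^2)
    p_h <- crossprod(E, t_h) / tt
    q_h <- sum(f * t_h) / tt
    E <- E - tcrossprod(t_h, p_h)
    f <- f - t_h * q_h
    W[, h] <- w; P[, h] <- p_h; Tm[, h] <- t_h
    q[h] <- q_h
    rd[h] <- q_h^2 * tt / ssy
  }
  if (ncomp == 0) stop("no usable PLS component (X uncorrelated with y)")
  # B = W (P'W)^-1 q maps centred X to centred fitted y
  B <- drop(W %*% solve(crossprod(P, W), q))
  fitted <- drop(sweep(x, 2, x_mean) %*% B) + y_mean
  structure(list(ncomp = ncomp, weights = W, loadings = P, q = q,
                 coef = B, rd = rd, scores = Tm,
                 x_mean = x_mean, y_mean = y_mean,
                 fitted = fitted, y = y),
            class = "wq_plsr")
}

#' @export
print.wq_plsr <- function(x, ...) {
  cat("PLSR (NIPALS):", length(x$x_mean), "bands,", x$ncomp,
      "components; cumulative Rd(Y) =", round(sum(x$rd), 4), "\n")
  invisible(x)
}

#' @export
coef.wq_plsr <- function(object, ...) {
  c("(Intercept)" = object$y_mean - sum(object$x_mean * object$coef),
    stats::setNames(object$coef, names(object$x_mean)))
}

#' @export
predict.wq_plsr <- function(object, newdata, ...) {
  newdata <- band_matrix(newdata)
  if (ncol(newdata) != length(object$x_mean))
    stop("newdata has ", ncol(newdata), " bands; model expects ",
         length(object$x_mean))
  drop(sweep(newdata, 2, object$x_mean) %*% object$coef) + object$y_mean
}

#' @export
residuals.wq_plsr <- function(object, ...) object$y - object$fitted

#' Choose a PLSR component count by cross-validation
#'
#' k-fold cross-validated RMSE over component counts `1..max_ncomp`;
#' folds are assigned deterministically by cycling sample indices.
#'
#' @inheritParams fit_plsr
#' @param max_ncomp largest component count tried (default
#'   `min(n - ceiling(n / folds) - 1, n_bands, 15)`).
#' @param folds number of folds (default 10).
#' @return the component count minimising cross-validated RMSE.
#' @export
select_ncomp <- function(x, y, max_ncomp = NULL, folds = 10) {
  x <- as.matrix(x)
  n <- nrow(x)
  folds <- min(folds, n)
  fold_id <- rep_len(seq_len(folds), n)
  max_train <- n - max(tabulate(fold_id))
  if (is.null(max_ncomp)) max_ncomp <- 15L
  max_ncomp <- min(max_ncomp, max_train - 1L, ncol(x))
  if (max_ncomp < 1) stop("too few samples for cross-validation")
  press <- numeric(max_ncomp)
  for (kf in seq_len(folds)) {
    tr <- fold_id != kf
    fit <- fit_plsr(x[tr, , drop = FALSE], y[tr], max_ncomp)
    # nested predictions for every component count from one fit
    Ete <- sweep(x[!tr, , drop = FALSE], 2, fit$x_mean)
    for (m in seq_len(fit$ncomp)) {
      Bm <- drop(fit$weights[, 1:m, drop = FALSE] %*%
                   solve(crossprod(fit$loadings[, 1:m, drop = FALSE],
                                   fit$weights[, 1:m, drop = FALSE]),
                         fit$q[1:m]))
      pred <- drop(Ete %*% Bm) + fit$y_mean
      press[m] <- press[m] + sum((y[!tr] - pred)^2)
    }
    if (fit$ncomp < max_ncomp)   # deflation exhausted early: reuse last
      press[(fit$ncomp + 1):max_ncomp] <-
        press[(fit$ncomp + 1):max_ncomp] + sum((y[!tr] - pred)^2)
  }
  which.min(press)
}

#' Fit an extreme learning machine regressor
#'
#' Single-hidden-layer feed-forward network with fixed random hidden
#' weights and least-squares output weights. Inputs are standardised to
#' zero mean and unit variance (training statistics); hidden weights and
#' biases are drawn uniformly on \[-1, 1\], neuron by neuron, so nested
#' hidden sizes under the same seed share their leading neurons;
#' pre-activations carry a `1/sqrt(p)` fan-in scaling so the logistic
#' sigmoid stays responsive at hyperspectral band counts; output weights
#' are the minimum-norm least-squares (SVD pseudoinverse) solution.
#'
#' @param x numeric matrix, samples in rows, bands in columns.
#' @param y numeric response vector.
#' @param hidden number of hidden neurons L (>= 1).
#' @param seed integer seed fixing the hidden layer (mandatory; recorded in
#'   the fit).
#' @return an object of class `wq_elm`.
#' @export
fit_elm <- function(x, y, hidden, seed) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  n <- nrow(x); p <- ncol(x)
  if (length(y) != n) stop("length(y) must equal nrow(x)")
  if (hidden < 1) stop("hidden must be >= 1")
  if (missing(seed)) stop("seed is mandatory for a reproducible ELM fit")
  x_mean <- colMeans(x)
  x_sd <- apply(x, 2, stats::sd)
  x_sd[x_sd == 0] <- 1
  xs <- sweep(sweep(x, 2, x_mean), 2, x_sd, "/")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  # draw per neuron (p weights then 1 bias) so seed prefixes nest over L
  Wh <- matrix(0, p, hidden)
  b <- numeric(hidden)
  for (j in seq_len(hidden)) {
    draw <- stats::runif(p + 1, -1, 1)
    Wh[, j] <- draw[seq_len(p)]
    b[j] <- draw[p + 1]
  }
  # fan-in scaling keeps pre-activations O(1) regardless of band count,
  # so the sigmoid stays in its responsive range
  H <- stats::plogis(xs %*% Wh / sqrt(p) + rep(b, each = n))
  if (any(!is.finite(H))) stop("non-finite hidden activations")
  beta <- drop(MASS::ginv(H) %*% y)
  fitted <- drop(H %*% beta)
  structure(list(hidden = hidden, seed = seed,
                 w_hidden = Wh, b_hidden = b, beta = beta,
                 x_mean = x_mean, x_sd = x_sd,
                 fitted = fitted, y = y),
            class = "wq_elm")
}

#' @export
print.wq_elm <- function(x, ...) {
  cat("ELM:", length(x$x_mean), "bands,", x$hidden,
      "hidden neurons (logistic), seed", x$seed, "\n")
  invisible(x)
}

#' @export
predict.wq_elm <- function(object, newdata, ...) {
  newdata <- band_matrix(newdata)
  if (ncol(newdata) != length(object$x_mean))
    stop("newdata has ", ncol(newdata), " bands; model expects ",
         length(object$x_mean))
  xs <- sweep(sweep(newdata, 2, object$x_mean), 2, object$x_sd, "/")
  H <- stats::plogis(xs %*% object$w_hidden / sqrt(ncol(xs)) +
                       rep(object$b_hidden, each = nrow(xs)))
  drop(H %*% object$beta)
}

#' @export
residuals.wq_elm <- function(object, ...) object$y - object$fitted

# Accept a SpectraSet, matrix or single spectrum vector as predictor input.
band_matrix <- function(x) {
  if (inherits(x, "SpectraSet")) return(x$reflectance)
  if (is.null(dim(x))) return(matrix(x, nrow = 1))
  as.matrix(x)
}
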