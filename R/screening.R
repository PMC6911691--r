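#' Gray-correlation configuration
#'
#' @param rho discrimination coefficient in (0, 1]; 0.5 is the conventional
#'   choice.
#' @param gcd_threshold sensitive-band cut-off on the gray correlation
#'   degree (default 0.5).
#' @param extrema_scope where the extreme differences are taken:
#'   `"global"` (over all bands and samples for a parameter — classical
#'   Deng gray relational analysis, the default, giving comparable scores
#'   across bands) or `"per-band"`.
#' @return a list of class `gc_config`.
#' @export
gc_config <- function(rho = 0.5, gcd_threshold = 0.5,
                      extrema_scope = c("global", "per-band")) {
  if (rho <= 0 || rho > 1) stop("rho must be in (0, 1]")
  structure(list(rho = rho, gcd_threshold = gcd_threshold,
                 extrema_scope = match.arg(extrema_scope)),
            class = "gc_config")
}

#' VIP configuration
#'
#' @param n_components PLSR component count for the screening-stage fit, or
#'   `"cv"` (default) to choose by cross-validated RMSE.
#' @param vip_threshold sensitive-band cut-off (default 1: a variable of
#'   average explanatory power scores exactly 1).
#' @param cv_folds folds for the component-count selection (default 10).
#' @return a list of class `vip_config`.
#' @export
vip_config <- function(n_components = "cv", vip_threshold = 1, cv_folds = 10) {
  if (!identical(n_components, "cv") &&
      (!is.numeric(n_components) || n_components < 1))
    stop("n_components must be a positive integer or \"cv\"")
  structure(list(n_components = n_components,
                 vip_threshold = vip_threshold, cv_folds = cv_folds),
            class = "vip_config")
}

new_screen_result <- function(method, parameter, wavelengths, scores,
                              mask, threshold, details = list()) {
  stopifnot(length(scores) == length(wavelengths),
            length(mask) == length(wavelengths))
  if (any(!is.finite(scores))) stop("non-finite screening scores")
  imax <- which.max(scores)
  structure(list(method = method, parameter = parameter,
                 wavelengths = wavelengths, scores = scores, mask = mask,
                 threshold = threshold,
                 argmax_band = wavelengths[imax],
                 max_score = scores[imax],
                 n_selected = sum(mask),
                 details = details),
            class = "ScreenResult")
}

#' @export
print.ScreenResult <- function(x, ...) {
  cat("ScreenResult [", x$method, "] for ", x$parameter, "\n", sep = "")
  cat("  bands: ", length(x$wavelengths), ", selected: ", x$n_selected,
      " (threshold ", format(x$threshold, digits = 4), ")\n", sep = "")
  cat("  max score ", format(x$max_score, digits = 4), " at ",
      x$argmax_band, " nm\n", sep = "")
  invisible(x)
}

#' @export
plot.ScreenResult <- function(x, ...) {
  graphics::plot(x$wavelengths, x$scores, type = "l",
                 xlab = "wavelength (nm)",
                 ylab = paste(x$method, "score"),
                 main = paste(x$method, "screening:", x$parameter), ...)
  graphics::abline(h = x$threshold, lty = 2, col = "grey40")
  if (any(x$mask))
    graphics::points(x$wavelengths[x$mask], x$scores[x$mask],
                     pch = 16, cex = 0.3, col = "firebrick")
  invisible(x)
}

#' Pearson correlation screening
#'
#' Per-band Pearson correlation between reflectance and a parameter, with
#' the two-tailed critical |r| derived from the t distribution at
#' `df = n - 2` rather than a tabulated constant.
#'
#' @param x band reflectance matrix (samples x bands) or `SpectraSet`.
#' @param y concentration vector.
#' @param alpha two-tailed significance level (default 0.001).
#' @param wavelengths band centres in nm (taken from `x` if a `SpectraSet`).
#' @param parameter parameter label for reporting.
#' @return a `ScreenResult` with `scores` = r (signed), `mask` =
#'   `|r| >= critical r`; constant bands get r = 0 and are flagged in
#'   `details$constant_bands`.
#' @export
pearson_screen <- function(x, y, alpha = 0.001, wavelengths = NULL,
                           parameter = "parameter") {
  wl <- screen_wavelengths(x, wavelengths)
  x <- band_matrix(x)
  n <- nrow(x)
  if (n < 3) stop("need at least 3 samples")
  if (stats::var(y) == 0) stop("parameter vector has zero variance")
  sds <- apply(x, 2, stats::sd)
  const <- sds == 0
  r <- numeric(ncol(x))
  if (any(!const))
    r[!const] <- drop(stats::cor(x[, !const, drop = FALSE], y))
  if (any(const))
    warning(sum(const), " constant band(s); their r set to 0")
  tcrit <- stats::qt(1 - alpha / 2, df = n - 2)
  rcrit <- tcrit / sqrt(n - 2 + tcrit^2)
  new_screen_result("pearson", parameter, wl, r, abs(r) >= rcrit, rcrit,
                    details = list(alpha = alpha, critical_r = rcrit,
                                   constant_bands = which(const)))
}

#' Dimensionless averaging operator
#'
#' Divides a sequence by its mean so the output has mean 1; the first step
#' of gray relational analysis.
#'
#' @param seq numeric vector with nonzero mean.
#' @return `seq / mean(seq)`.
#' @export
averaging_operator <- function(seq) {
  m <- mean(seq)
  if (m == 0) stop("sequence mean is zero; averaging operator undefined")
  seq / m
}

#' Gray correlation degree screening
#'
#' Deng-style gray relational analysis between a signature sequence (the
#' parameter concentrations across samples) and each band's factor sequence
#' (its reflectance across samples). Both are made dimensionless by the
#' averaging operator; relational coefficients use the discrimination
#' coefficient `rho`, and the gray correlation degree is their mean across
#' samples. When a factor's differences vanish entirely the coefficient is
#' taken as 1 (a proportional factor is maximally related).
#'
#' @param signature concentration vector x0 (length = n samples).
#' @param factors band matrix (samples x bands) or `SpectraSet`.
#' @param cfg a [gc_config()].
#' @param wavelengths band centres in nm.
#' @param parameter parameter label.
#' @return a `ScreenResult` with `scores` = gamma per band, `mask` =
#'   `gamma > gcd_threshold`.
#' @export
gcd_screen <- function(signature, factors, cfg = gc_config(),
                       wavelengths = NULL, parameter = "parameter") {
  wl <- screen_wavelengths(factors, wavelengths)
  X <- band_matrix(factors)
  m <- nrow(X)
  if (length(signature) != m) stop("signature length must equal sample count")
  if (m < 2) stop("need at least 2 samples")
  x0 <- averaging_operator(signature)
  means <- colMeans(X)
  if (any(means == 0))
    stop("zero-mean factor sequence(s) at band(s): ",
         paste(utils::head(wl[means == 0], 3), collapse = ", "))
  Xn <- sweep(X, 2, means, "/")
  D <- abs(Xn - x0)                     # |x0(t) - xi(t)|, samples x bands
  if (cfg$extrema_scope == "global") {
    dmin <- min(D); dmax <- max(D)
    gamma <- gc_gamma(D, dmin, dmax, cfg$rho)
  } else {
    gamma <- vapply(seq_len(ncol(D)), function(j) {
      gc_gamma(D[, j, drop = FALSE], min(D[, j]), max(D[, j]), cfg$rho)
    }, numeric(1))
  }
  new_screen_result("gc", parameter, wl, gamma,
                    gamma > cfg$gcd_threshold, cfg$gcd_threshold,
                    details = list(rho = cfg$rho,
                                   extrema_scope = cfg$extrema_scope))
}

gc_gamma <- function(D, dmin, dmax, rho) {
  if (dmax == 0) return(rep(1, ncol(D)))  # identical sequences
  xi <- (dmin + rho * dmax) / (D + rho * dmax)
  colMeans(xi)
}

#' Variable importance in projection screening
#'
#' Fits a PLSR on all bands (component count from `cfg`) and scores each
#' band j as
#' `VIP_j = sqrt( p * sum_h Rd(Y; t_h) W_hj^2 / sum_h Rd(Y; t_h) )`,
#' where W are the unit-norm PLS weights and Rd(Y; t_h) the response
#' variance explained by component h. Mean squared VIP is 1 by
#' construction, so 1 marks average explanatory power.
#'
#' @param x band matrix (samples x bands) or `SpectraSet`.
#' @param y concentration vector.
#' @param cfg a [vip_config()].
#' @param wavelengths band centres in nm.
#' @param parameter parameter label.
#' @return a `ScreenResult` with `scores` = VIP, `mask` =
#'   `VIP > vip_threshold`; the PLSR fit is kept in `details$fit`.
#' @export
vip_screen <- function(x, y, cfg = vip_config(), wavelengths = NULL,
                       parameter = "parameter") {
  wl <- screen_wavelengths(x, wavelengths)
  X <- band_matrix(x)
  m <- if (identical(cfg$n_components, "cv"))
    select_ncomp(X, y, folds = cfg$cv_folds) else as.integer(cfg$n_components)
  fit <- fit_plsr(X, y, m)
  v <- vip_from_fit(fit)
  new_screen_result("vip", parameter, wl, v, v > cfg$vip_threshold,
                    cfg$vip_threshold,
                    details = list(n_components = fit$ncomp, fit = fit))
}

#' VIP scores of a fitted PLSR
#' @param fit a `wq_plsr` object.
#' @return numeric VIP vector (one per band; mean square 1).
#' @export
vip_from_fit <- function(fit) {
  stopifnot(inherits(fit, "wq_plsr"))
  rd_total <- sum(fit$rd)
  if (rd_total <= 0) stop("PLSR explains no response variance")
  p <- nrow(fit$weights)
  sqrt(p * drop(fit$weights^2 %*% fit$rd) / rd_total)
}

#' Set-pair connection of two band masks
#'
#' Counts identity / discrepancy / opposite bands between two selection
#' masks and forms the connection (contact) number
#' `mu = S + F*I + P*J` with `J = -1` and the discrepancy coefficient
#' `I = (S - P) / (S + P)` (0 when S + P = 0).
#'
#' Conventions for the counts:
#' * `"symmetric"` — identity `s = #(a & b)`, opposite `p = #(!a & !b)`,
#'   discrepancy `f = n - s - p`.
#' * `"asymmetric"` — from the viewpoint of the first mask against the
#'   second: `s = #(a & b)`, opposite `p = #(!a & b)` (bands the other
#'   method asserts but this one rejects), `f = n - s - p`.
#'
#' @param mask_a,mask_b logical vectors of equal length.
#' @param convention `"symmetric"` (default) or `"asymmetric"`.
#' @return a list of class `SetPairState` with counts `s, f, p`, degrees
#'   `S, F, P` (summing to 1), `I`, `J`, and `mu`.
#' @export
set_pair_connection <- function(mask_a, mask_b,
                                convention = c("symmetric", "asymmetric")) {
  convention <- match.arg(convention)
  if (length(mask_a) != length(mask_b))
    stop("masks must have equal length")
  a <- as.logical(mask_a); b <- as.logical(mask_b)
  n <- length(a)
  if (n == 0) stop("empty masks")
  s <- sum(a & b)
  p <- if (convention == "symmetric") sum(!a & !b) else sum(!a & b)
  f <- n - s - p
  S <- s / n; F_ <- f / n; P <- p / n
  I <- if (S + P == 0) 0 else (S - P) / (S + P)
  mu <- S + F_ * I - P
  structure(list(n = n, s = s, f = f, p = p,
                 S = S, F = F_, P = P, I = I, J = -1, mu = mu,
                 convention = convention),
            class = "SetPairState")
}

#' @export
print.SetPairState <- function(x, ...) {
  cat("SetPairState (", x$convention, "): n = ", x$n,
      "; s/f/p = ", x$s, "/", x$f, "/", x$p,
      "; mu = ", format(x$mu, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Set-pair relative memberships and weights
#'
#' For N methods with contact numbers `mu_i`, the relative membership is
#' `v_i = 1/N + mu_i/N` and the weight `W_i = v_i / sum(v)`.
#'
#' @param mu numeric vector of contact numbers in \[-1, 1\], one per method.
#' @return normalized weight vector (nonnegative, sums to 1).
#' @export
spa_weights <- function(mu) {
  N <- length(mu)
  if (N < 2) stop("need at least two methods")
  if (any(mu < -1 - 1e-12 | mu > 1 + 1e-12))
    stop("contact numbers must lie in [-1, 1]")
  v <- 1 / N + mu / N
  if (sum(v) == 0)
    stop("degenerate opposition: all relative memberships are zero")
  v / sum(v)
}

#' Set-pair-analysis fusion of gray and VIP screening
#'
#' Treats the gray-correlation score vector and the VIP score vector as the
#' two sets of a set pair. Each method's contact number is computed from
#' the selection masks (GCD > 0.5, VIP > 1) with the asymmetric counting
#' convention of [set_pair_connection()], converted to relative memberships
#' and weights, and the fused score is the weight-blended
#' `W_gc * gamma + W_vip * VIP` with selection threshold
#' `W_gc * 0.5 + W_vip * 1`.
#'
#' @param gc a `ScreenResult` from [gcd_screen()].
#' @param vip a `ScreenResult` from [vip_screen()].
#' @return a `ScreenResult` with method `"spa"`; weights and per-method
#'   connection states are kept in `details`.
#' @export
spa_screen <- function(gc, vip) {
  stopifnot(inherits(gc, "ScreenResult"), inherits(vip, "ScreenResult"))
  if (length(gc$wavelengths) != length(vip$wavelengths) ||
      any(gc$wavelengths != vip$wavelengths))
    stop("gray and VIP results are on different band grids")
  if (!identical(gc$parameter, vip$parameter))
    stop("gray and VIP results are for different parameters")
  st_gc <- set_pair_connection(gc$mask, vip$mask, "asymmetric")
  st_vip <- set_pair_connection(vip$mask, gc$mask, "asymmetric")
  w <- spa_weights(c(st_gc$mu, st_vip$mu))
  scores <- w[1] * gc$scores + w[2] * vip$scores
  thr <- w[1] * gc$threshold + w[2] * vip$threshold
  new_screen_result("spa", gc$parameter, gc$wavelengths, scores,
                    scores > thr, thr,
                    details = list(weights = stats::setNames(w, c("gc", "vip")),
                                   state_gc = st_gc, state_vip = st_vip))
}

#' Restrict a band matrix to the screened bands
#'
#' @param result a `ScreenResult` with a nonempty selection mask.
#' @param x band matrix (samples x bands) or `SpectraSet` on the same grid.
#' @return list with `x` (selected columns, ascending wavelength) and
#'   `wavelengths`.
#' @export
select_bands <- function(result, x) {
  stopifnot(inherits(result, "ScreenResult"))
  X <- band_matrix(x)
  if (ncol(X) != length(result$wavelengths))
    stop("band matrix and screening result are on different grids")
  if (!any(result$mask))
    stop("empty band selection for ", result$parameter, " (", result$method,
         "); relax the threshold")
  list(x = X[, result$mask, drop = FALSE],
       wavelengths = result$wavelengths[result$mask])
}

#' Tabulate a screening result
#' @param result a `ScreenResult`.
#' @return data.frame with columns `wavelength`, `score`, `selected`.
#' @export
screen_table <- function(result) {
  data.frame(wavelength = result$wavelengths,
             score = result$scores,
             selected = result$mask)
}

screen_wavelengths <- function(x, wavelengths) {
  if (inherits(x, "SpectraSet")) return(x$wavelengths)
  if (!is.null(wavelengths)) return(as.numeric(wavelengths))
  nb <- if (is.null(dim(x))) length(x) else ncol(x)
  seq_len(nb)
}
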