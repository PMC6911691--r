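#' Kennard-Stone sample partition
#'
#' Deterministic max-min selection of a representative calibration set:
#' the first two picks are the most distant sample pair (Euclidean), and
#' each subsequent pick maximises its minimum distance to the samples
#' already selected. Ties are broken toward the lowest original row index.
#'
#' @param x band matrix (samples x bands) or `SpectraSet`; distances are
#'   Euclidean over its columns.
#' @param k calibration set size, `2 <= k <= n`.
#' @param sample_ids labels (taken from `x` if a `SpectraSet`).
#' @return an object of class `SplitIndex` with `calibration` and
#'   `validation` index vectors (and ids), `fraction`, and `metric`.
#' @export
kennard_stone_split <- function(x, k, sample_ids = NULL) {
  if (inherits(x, "SpectraSet") && is.null(sample_ids))
    sample_ids <- x$sample_ids
  X <- band_matrix(x)
  n <- nrow(X)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n))
  if (k < 2) stop("k must be >= 2")
  if (k > n) stop("k must be <= n")
  D <- as.matrix(stats::dist(X))
  # seed pair: maximum pairwise distance, lexicographically lowest on ties
  Du <- D
  Du[lower.tri(Du, diag = TRUE)] <- -Inf
  best <- which(Du == max(Du), arr.ind = TRUE)
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
  sel <- as.integer(best)
  mind <- unname(pmin(D[, sel[1]], D[, sel[2]]))
  while (length(sel) < k) {
    mind[sel] <- -Inf
    nxt <- which.max(mind)            # which.max takes the first (lowest index)
    sel <- c(sel, nxt)
    mind <- pmin(mind, D[, nxt])
  }
  sel <- as.integer(unname(sel))
  structure(list(calibration = sel,
                 validation = setdiff(seq_len(n), sel),
                 calibration_ids = sample_ids[sel],
                 validation_ids = sample_ids[setdiff(seq_len(n), sel)],
                 fraction = k / n,
                 metric = "euclidean"),
            class = "SplitIndex")
}

#' @export
print.SplitIndex <- function(x, ...) {
  cat("SplitIndex (Kennard-Stone,", x$metric, "):",
      length(x$calibration), "calibration /",
      length(x$validation), "validation\n")
  invisible(x)
}

#' Two-thirds Kennard-Stone split
#'
#' Calibration size `k = round(fraction * n)` with half-up rounding
#' (87 samples give the 58/29 partition), delegated to
#' [kennard_stone_split()].
#'
#' @inheritParams kennard_stone_split
#' @param fraction calibration share (default 2/3).
#' @return a `SplitIndex`.
#' @export
split_two_thirds <- function(x, fraction = 2 / 3, sample_ids = NULL) {
  X <- band_matrix(x)
  n <- nrow(X)
  if (n < 3) stop("need at least 3 samples")
  k <- floor(fraction * n + 0.5)
  kennard_stone_split(x, k, sample_ids = sample_ids)
}
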