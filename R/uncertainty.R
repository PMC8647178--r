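#' Out-of-bag calibration residuals
#'
#' For each training row, the residual between the observed outcome and the
#' out-of-bag prediction: the mean over only those trees whose bootstrap
#' resample excluded the row. Rows that are in-bag for every tree are
#' skipped. When the forest was trained without bagging no row is ever
#' out-of-bag, so residuals fall back to 10-fold cross-validation (each fold
#' refits the forest on the other folds), with a notice.
#'
#' @param forest A [train_forest()] `perf_forest`.
#' @param train The table it was trained on (same row order).
#' @param k Number of folds for the no-bagging fallback.
#' @return Numeric vector of residuals (observed minus held-out prediction).
#' @export
calibration_residuals <- function(forest, train, k = 10L) {
  stopifnot(inherits(forest, "perf_forest"))
  check_training_table(train, forest$features)
  if (!forest$config$bagging) {
    message("bagging disabled; using ", k, "-fold cross-validated residuals")
    return(cv_residuals(train, forest$config, forest$features, k))
  }
  pred_all <- predict(forest$engine,
                      data = train[, forest$features, drop = FALSE],
                      predict.all = TRUE, num.threads = 1)$predictions
  inbag <- do.call(cbind, forest$engine$inbag.counts)  # n x n_trees
  oob <- inbag == 0
  n_oob <- rowSums(oob)
  keep <- which(n_oob > 0)
  oob_pred <- rowSums(pred_all * oob)[keep] / n_oob[keep]
  train$outcome[keep] - oob_pred
}

cv_residuals <- function(train, config, features, k) {
  n <- nrow(train)
  k <- min(k, n)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  fold <- sample(rep_len(seq_len(k), n))
  resid <- numeric(n)
  for (f in seq_len(k)) {
    hold <- fold == f
    fit <- train_forest(train[!hold, , drop = FALSE], config, features)
    resid[hold] <- train$outcome[hold] - predict(fit, train[hold, , drop = FALSE])
  }
  resid
}

# Quantile of the Gaussian-kernel mixture density over `residuals` with
# bandwidth bw: solves mean(pnorm((q - r_i)/bw)) = p.
kde_quantile <- function(residuals, p, bw) {
  lo <- min(residuals) - 10 * bw
  hi <- max(residuals) + 10 * bw
  f <- function(q) mean(stats::pnorm((q - residuals) / bw)) - p
  stats::uniroot(f, c(lo, hi), tol = bw * 1e-6)$root
}

#' Kernel-estimator prediction interval
#'
#' Fits a Gaussian-kernel density to the calibration residual distribution
#' (bandwidth by Silverman's rule) and places the central `confidence`
#' quantile range of that density around the point prediction. The interval
#' may be asymmetric about the point when the residuals are skewed; its width
#' expresses the prediction uncertainty.
#'
#' @param point Point prediction.
#' @param residuals Calibration residuals (>= 10 values).
#' @param confidence Confidence level in (0, 1); default 0.95.
#' @param bw_floor Minimum bandwidth, guarding degenerate (zero-spread)
#'   residual sets; the interval width is never below `2 * bw_floor`.
#' @return Numeric vector `c(lower, upper)`.
#' @export
kernel_interval <- function(point, residuals, confidence = 0.95,
                            bw_floor = 1e-6) {
  if (length(residuals) < 10L)
    stop("need at least 10 calibration residuals for a kernel interval")
  if (confidence <= 0 || confidence >= 1)
    stop("confidence must be in (0, 1)")
  bw <- if (stats::sd(residuals) > 0) stats::bw.nrd0(residuals) else 0
  bw <- max(bw, bw_floor)
  lo <- point + kde_quantile(residuals, (1 - confidence) / 2, bw)
  hi <- point + kde_quantile(residuals, (1 + confidence) / 2, bw)
  if (hi - lo < 2 * bw_floor) {
    mid <- (lo + hi) / 2
    lo <- mid - bw_floor; hi <- mid + bw_floor
  }
  c(lower = lo, upper = hi)
}
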