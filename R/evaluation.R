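#' Error metrics
#'
#' Mean absolute error and root-mean-square error between predicted and
#' actual values.
#'
#' @param predicted,actual Equal-length non-empty numeric vectors.
#' @return A single number.
#' @export
mae <- function(predicted, actual) {
  check_metric_args(predicted, actual)
  mean(abs(predicted - actual))
}

#' @rdname mae
#' @export
rmse <- function(predicted, actual) {
  check_metric_args(predicted, actual)
  sqrt(mean((predicted - actual)^2))
}

check_metric_args <- function(predicted, actual) {
  if (length(predicted) != length(actual)) stop("length mismatch")
  if (length(predicted) == 0L) stop("empty vectors")
  invisible(NULL)
}

#' Compare the suite against the Zero-R baseline
#'
#' Fills the evaluation report for every (variant, measure) cell: MAE and
#' RMSE of the forest and of the Zero-R median baseline, side by side, on the
#' supplied rows. Rows with missing outcomes are excluded with a logged
#' count.
#'
#' @param suite A fitted `suite_matrix`.
#' @param data Long-format table (`dataset_id`, features, `variant_id`,
#'   `measure`, `outcome`) — typically the held-out test rows.
#' @return Data frame with one row per cell: `variant_id`, `measure`,
#'   `n_test`, `mae_model`, `rmse_model`, `mae_baseline`, `rmse_baseline`.
#' @export
compare_to_baseline <- function(suite, data) {
  stopifnot(inherits(suite, "suite_matrix"))
  n_missing <- sum(is.na(data$outcome))
  if (n_missing > 0) {
    message("excluding ", n_missing, " rows with missing outcomes")
    data <- data[!is.na(data$outcome), , drop = FALSE]
  }
  rows <- lapply(suite$cells, function(cl) {
    sub <- data[data$variant_id == cl$variant_id & data$measure == cl$measure, ,
                drop = FALSE]
    if (nrow(sub) == 0L) return(NULL)
    p_model <- predict(cl$forest, sub)
    if (cl$measure == "completeness") p_model <- pmin(pmax(p_model, 0), 1)
    p_base <- predict(cl$baseline, sub)
    data.frame(variant_id = cl$variant_id, measure = cl$measure,
               n_test = nrow(sub),
               mae_model = mae(p_model, sub$outcome),
               rmse_model = rmse(p_model, sub$outcome),
               mae_baseline = mae(p_base, sub$outcome),
               rmse_baseline = rmse(p_base, sub$outcome),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Leave-one-feature-out ablation
#'
#' Retrains the suite with one feature removed at a time (same configuration
#' and seeds) and reports the change in held-out MAE and RMSE relative to the
#' all-features suite, averaged over cells. A positive delta means the
#' removed feature was informative.
#'
#' @param train,test Long-format train and test tables.
#' @param registry Variant registry.
#' @param config [forest_config()].
#' @param features Feature columns to ablate (>= 2; all by default).
#' @param phasing_mode Phasing mode for [fit_suite()].
#' @return Data frame: `feature`, `mae_full`, `mae_ablated`, `delta_mae`,
#'   `rmse_full`, `rmse_ablated`, `delta_rmse`.
#' @export
ablation <- function(train, test, registry = NULL,
                     config = forest_config(),
                     features = NULL,
                     phasing_mode = c("experimental", "MR")) {
  phasing_mode <- match.arg(phasing_mode)
  if (is.null(features)) features <- feature_columns(train, phasing_mode)
  if (length(features) < 2L) stop("need at least 2 features to ablate")
  full <- fit_suite(train, registry, phasing_mode, config, features)
  full_eval <- compare_to_baseline(full, test)
  mae_full <- mean(full_eval$mae_model)
  rmse_full <- mean(full_eval$rmse_model)
  rows <- lapply(features, function(f) {
    sub_feats <- setdiff(features, f)
    fit <- fit_suite(train, registry, phasing_mode, config, sub_feats)
    ev <- compare_to_baseline(fit, test)
    data.frame(feature = f,
               mae_full = mae_full, mae_ablated = mean(ev$mae_model),
               delta_mae = mean(ev$mae_model) - mae_full,
               rmse_full = rmse_full, rmse_ablated = mean(ev$rmse_model),
               delta_rmse = mean(ev$rmse_model) - rmse_full,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Resolution-binned prediction statistics
#'
#' Groups test datasets into fixed-width resolution bins and reports, per
#' bin, the mean and standard deviation (sample convention, n - 1) of the
#' predicted and of the actual outcome values. Empty bins are reported with
#' `n = 0` and `NA` statistics.
#'
#' @param predicted,actual Equal-length outcome vectors.
#' @param resolution Resolution (Angstrom) of each entry.
#' @param bin_width Bin width in Angstrom (default 0.1).
#' @return Data frame: `bin_low`, `bin_high`, `n`, `mean_predicted`,
#'   `sd_predicted`, `mean_actual`, `sd_actual`.
#' @export
resolution_binned_stats <- function(predicted, actual, resolution,
                                    bin_width = 0.1) {
  check_metric_args(predicted, actual)
  if (length(resolution) != length(predicted)) stop("length mismatch")
  lo <- floor(min(resolution) / bin_width) * bin_width
  hi <- ceiling(max(resolution) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  edges <- seq(lo, hi, by = bin_width)
  idx <- findInterval(resolution, edges, rightmost.closed = TRUE)
  rows <- lapply(seq_len(length(edges) - 1L), function(b) {
    inb <- idx == b
    n <- sum(inb)
    data.frame(bin_low = edges[b], bin_high = edges[b + 1L], n = n,
               mean_predicted = if (n) mean(predicted[inb]) else NA_real_,
               sd_predicted = if (n > 1) stats::sd(predicted[inb]) else NA_real_,
               mean_actual = if (n) mean(actual[inb]) else NA_real_,
               sd_actual = if (n > 1) stats::sd(actual[inb]) else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Group hit rate of the uncertainty ranking
#'
#' For each test dataset, checks whether the variant with the lowest
#' prediction error (|predicted - actual|, the default) is a member of the
#' first (most certain) group of the ranked report. Alternatively
#' (`best = "actual"`), whether the variant with the best actual outcome is.
#' Datasets with missing actual outcomes are excluded with a logged count.
#'
#' @param records Grouped prediction records over multiple datasets
#'   (`dataset_id`, `variant_id`, `measure`, `point`, `width`, `group`), e.g.
#'   rows of [ranked_report()]s.
#' @param actuals Long table of actual outcomes (`dataset_id`, `variant_id`,
#'   `measure`, `outcome`).
#' @param best `"error"` (lowest |predicted - actual|) or `"actual"` (best
#'   actual outcome).
#' @return Named numeric vector: hit-rate fraction per measure.
#' @export
group_hit_rate <- function(records, actuals, best = c("error", "actual")) {
  best <- match.arg(best)
  m <- merge(records, actuals[, c("dataset_id", "variant_id", "measure", "outcome")],
             by = c("dataset_id", "variant_id", "measure"))
  n_lost <- sum(is.na(m$outcome))
  if (n_lost > 0) {
    message("excluding ", n_lost, " records with missing actual outcomes")
    m <- m[!is.na(m$outcome), , drop = FALSE]
  }
  out <- c()
  for (msr in unique(m$measure)) {
    sub <- m[m$measure == msr, , drop = FALSE]
    hits <- vapply(split(sub, sub$dataset_id), function(d) {
      score <- switch(best,
                      error = abs(d$point - d$outcome),
                      actual = if (higher_is_better(msr)) -d$outcome else d$outcome)
      d$group[which.min(score)] == 1L
    }, logical(1))
    out[msr] <- mean(hits)
  }
  out
}

#' Recommendation quality: within-k-of-best fractions
#'
#' For each measure and threshold k, the fraction of datasets for which the
#' outcome actually achieved by the recommended variant is within k of the
#' best outcome achievable by any variant (completeness: best = maximum;
#' R factors: best = minimum). Fractions are cumulative, hence non-decreasing
#' in k.
#'
#' @param recommendations Data frame `dataset_id`, `measure`, `variant_id`
#'   (the recommended variant per dataset and measure).
#' @param actuals Long table of actual outcomes per (dataset, variant,
#'   measure).
#' @param thresholds Numeric thresholds (default 0.01 and 0.05).
#' @return Data frame: `measure`, `k`, `fraction`.
#' @export
within_k_analysis <- function(recommendations, actuals,
                              thresholds = c(0.01, 0.05)) {
  rows <- list()
  for (msr in unique(recommendations$measure)) {
    rec <- recommendations[recommendations$measure == msr, , drop = FALSE]
    act <- actuals[actuals$measure == msr & !is.na(actuals$outcome), , drop = FALSE]
    gaps <- vapply(seq_len(nrow(rec)), function(i) {
      d <- act[act$dataset_id == rec$dataset_id[i], , drop = FALSE]
      got <- d$outcome[d$variant_id == rec$variant_id[i]]
      if (length(got) == 0L) return(NA_real_)
      bst <- if (higher_is_better(msr)) max(d$outcome) else min(d$outcome)
      abs(got - bst)
    }, numeric(1))
    gaps <- gaps[!is.na(gaps)]
    for (k in sort(thresholds))
      rows[[length(rows) + 1L]] <- data.frame(
        measure = msr, k = k, fraction = mean(gaps <= k),
        stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
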