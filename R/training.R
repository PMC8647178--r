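#' Forest configuration
#'
#' Hyper-parameters of the per-cell regression forests. The defaults follow
#' the reference configuration: 1024 trees, unlimited depth, bagging on.
#'
#' @param n_trees Number of trees (>= 1).
#' @param max_depth Maximum tree depth; `0` means unlimited.
#' @param bagging Fit each tree on a bootstrap resample of the training rows
#'   (variance reduction). When off, every tree sees all rows.
#' @param seed Integer seed making training reproducible.
#' @return A list of class `forest_config`.
#' @export
forest_config <- function(n_trees = 1024L, max_depth = 0L, bagging = TRUE,
                          seed = 1L) {
  if (n_trees < 1L) stop("n_trees must be >= 1")
  structure(list(n_trees = as.integer(n_trees), max_depth = as.integer(max_depth),
                 bagging = isTRUE(bagging), seed = as.integer(seed)),
            class = "forest_config")
}

feature_columns <- function(data, phasing_mode = NULL) {
  base <- c("resolution", "rmsd", "skew", "max_density", "min_density")
  if (is.null(phasing_mode))
    phasing_mode <- if ("sequence_identity" %in% names(data) &&
                        !all(is.na(data$sequence_identity))) "MR" else "experimental"
  if (phasing_mode == "MR") c(base, "sequence_identity") else base
}

check_training_table <- function(table, features) {
  if (!all(features %in% names(table)))
    stop("training table lacks feature columns: ",
         paste(setdiff(features, names(table)), collapse = ", "))
  if (!"outcome" %in% names(table)) stop("training table lacks `outcome`")
  if (anyNA(table[, c(features, "outcome")]))
    stop("missing values in features or outcome")
  invisible(table)
}

#' Split a training table into train and test partitions by dataset
#'
#' A simple random partition of the dataset ids, reproducible for a fixed
#' seed. The train size is `round(train_fraction * n)`.
#'
#' @param table Data frame with a `dataset_id` column (one row per dataset,
#'   or a long table whose rows are assigned by their dataset id).
#' @param train_fraction Fraction of datasets assigned to training.
#' @param seed Integer seed.
#' @return List with elements `train` and `test` (disjoint, union = input).
#' @export
split_dataset <- function(table, train_fraction = 0.8, seed = 1L) {
  if (!"dataset_id" %in% names(table)) stop("table lacks `dataset_id`")
  ids <- unique(table$dataset_id)
  if (length(ids) < 2L) stop("need at least 2 datasets to split")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  n_train <- round(train_fraction * length(ids))
  n_train <- max(1L, min(length(ids) - 1L, n_train))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  train_ids <- sample(ids, n_train)
  list(train = table[table$dataset_id %in% train_ids, , drop = FALSE],
       test = table[!table$dataset_id %in% train_ids, , drop = FALSE])
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Train one regression forest
#'
#' Fits an ensemble of regression trees on the training rows; with bagging on
#' each tree is fitted on a bootstrap resample. The prediction is the mean of
#' the tree predictions and is therefore bounded by the training outcome
#' range.
#'
#' @param train Training table: feature columns plus an `outcome` column.
#' @param config A [forest_config].
#' @param features Feature column names; inferred from the table by default.
#' @return An object of class `perf_forest`.
#' @export
train_forest <- function(train, config = forest_config(), features = NULL) {
  if (is.null(features)) features <- feature_columns(train)
  check_training_table(train, features)
  if (nrow(train) < 2L) stop("need at least 2 training rows")
  fit <- ranger::ranger(
    dependent.variable.name = "outcome",
    data = train[, c(features, "outcome")],
    num.trees = config$n_trees,
    max.depth = config$max_depth,
    replace = config$bagging,
    sample.fraction = 1,
    keep.inbag = TRUE,
    seed = config$seed,
    num.threads = 1)
  structure(list(engine = fit, features = features, config = config,
                 outcome_range = range(train$outcome), n_train = nrow(train)),
            class = "perf_forest")
}

#' @export
predict.perf_forest <- function(object, newdata, ...) {
  p <- predict(object$engine, data = newdata[, object$features, drop = FALSE],
               num.threads = 1)
  as.numeric(p$predictions)
}

#' @export
print.perf_forest <- function(x, ...) {
  cat(sprintf("perf_forest: %d trees on %d rows, features: %s\n",
              x$config$n_trees, x$n_train, paste(x$features, collapse = ", ")))
  invisible(x)
}

#' Zero-R baseline regressor
#'
#' Predicts the median of the training outcomes for every input, regardless
#' of the features (even-count median = mean of the two middle values).
#'
#' @param train Training table with an `outcome` column (>= 1 row).
#' @return An object of class `zero_r`.
#' @export
zero_r <- function(train) {
  if (!"outcome" %in% names(train)) stop("training table lacks `outcome`")
  if (nrow(train) < 1L) stop("need at least 1 training row")
  structure(list(median = stats::median(train$outcome), n_train = nrow(train)),
            class = "zero_r")
}

#' @export
predict.zero_r <- function(object, newdata, ...) {
  rep(object$median, if (is.data.frame(newdata)) nrow(newdata) else length(newdata))
}

#' @export
print.zero_r <- function(x, ...) {
  cat(sprintf("zero_r baseline: predicts median %.4f (n = %d)\n",
              x$median, x$n_train))
  invisible(x)
}

#' Fit the full suite of per-(variant, measure) regressors
#'
#' The central fitting function. For every applicable (variant, measure) cell
#' of the registry it trains a regression forest and a Zero-R baseline on the
#' rows of `data` for that cell, and stores out-of-bag calibration residuals
#' for prediction intervals.
#'
#' @param data Long-format table: `dataset_id`, the feature columns, and
#'   `variant_id`, `measure`, `outcome`.
#' @param registry Named list of [pipeline_variant]s (default registry of the
#'   phasing mode).
#' @param config A [forest_config]; each cell is trained with a cell-specific
#'   seed derived deterministically from `config$seed`.
#' @param phasing_mode `"experimental"` or `"MR"`; controls the feature set
#'   (MR adds sequence identity).
#' @param features Feature column names (inferred by default).
#' @param split_seed Optional seed of the train/test split that produced
#'   `data`, recorded as metadata.
#' @return An object of class `suite_matrix`: a list of trained cells plus
#'   metadata.
#' @export
fit_suite <- function(data, registry = NULL,
                      phasing_mode = c("experimental", "MR"),
                      config = forest_config(), features = NULL,
                      split_seed = NULL) {
  phasing_mode <- match.arg(phasing_mode)
  if (is.null(registry)) registry <- default_registry(phasing_mode)
  if (is.null(features)) features <- feature_columns(data, phasing_mode)
  cells_df <- suite_cells(registry)
  cells <- vector("list", nrow(cells_df))
  for (i in seq_len(nrow(cells_df))) {
    vid <- cells_df$variant_id[i]; msr <- cells_df$measure[i]
    rows <- data[data$variant_id == vid & data$measure == msr, , drop = FALSE]
    if (nrow(rows) == 0L)
      stop("no training rows for registered cell (", vid, ", ", msr, ")")
    check_training_table(rows, features)
    cell_cfg <- config
    cell_cfg$seed <- cell_seed(config$seed, vid, msr)
    forest <- train_forest(rows, cell_cfg, features)
    baseline <- zero_r(rows)
    resid <- calibration_residuals(forest, rows)
    cells[[i]] <- list(variant_id = vid, measure = msr, forest = forest,
                       baseline = baseline, residuals = resid,
                       n_train = nrow(rows))
  }
  names(cells) <- paste(cells_df$variant_id, cells_df$measure, sep = "::")
  structure(list(cells = cells, registry = registry, config = config,
                 features = features, phasing_mode = phasing_mode,
                 split_seed = split_seed),
            class = "suite_matrix")
}

# deterministic 31-bit seed per (variant, measure) cell
cell_seed <- function(base, variant_id, measure) {
  h <- sum(utf8ToInt(paste(variant_id, measure)) *
             seq_along(utf8ToInt(paste(variant_id, measure)))) %% 99991L
  as.integer((as.numeric(base) * 100003 + h) %% .Machine$integer.max)
}

#' @export
print.suite_matrix <- function(x, ...) {
  cat(sprintf("suite_matrix (%s phasing): %d regressors over %d variants\n",
              x$phasing_mode, length(x$cells), length(x$registry)))
  cat(sprintf("  forest: %d trees, bagging %s; features: %s\n",
              x$config$n_trees, if (x$config$bagging) "on" else "off",
              paste(x$features, collapse = ", ")))
  invisible(x)
}

#' @export
summary.suite_matrix <- function(object, ...) {
  df <- do.call(rbind, lapply(object$cells, function(cl) data.frame(
    variant_id = cl$variant_id, measure = cl$measure, n_train = cl$n_train,
    train_median = cl$baseline$median, n_oob_residuals = length(cl$residuals),
    stringsAsFactors = FALSE)))
  rownames(df) <- NULL
  df
}

#' Predict outcomes (with prediction intervals) for new datasets
#'
#' @param object A fitted [fit_suite()] `suite_matrix`.
#' @param newdata Data frame of feature rows (one per dataset), with a
#'   `dataset_id` column.
#' @param interval Attach kernel-estimator prediction intervals.
#' @param confidence Interval confidence level in (0, 1).
#' @param ... Unused.
#' @return Data frame of prediction records: `dataset_id`, `variant_id`,
#'   `measure`, `point`, and (with intervals) `lower`, `upper`, `confidence`,
#'   `width`. Completeness points are clamped to \[0, 1\].
#' @export
predict.suite_matrix <- function(object, newdata, interval = TRUE,
                                 confidence = 0.95, ...) {
  if (!"dataset_id" %in% names(newdata))
    newdata$dataset_id <- seq_len(nrow(newdata))
  out <- lapply(object$cells, function(cl) {
    point <- predict(cl$forest, newdata)
    if (cl$measure == "completeness") point <- pmin(pmax(point, 0), 1)
    rec <- data.frame(dataset_id = newdata$dataset_id,
                      variant_id = cl$variant_id, measure = cl$measure,
                      point = point, stringsAsFactors = FALSE)
    if (interval) {
      iv <- t(vapply(point, kernel_interval, numeric(2),
                     residuals = cl$residuals, confidence = confidence))
      rec$lower <- iv[, 1]; rec$upper <- iv[, 2]
      rec$confidence <- confidence
      rec$width <- rec$upper - rec$lower
    }
    rec
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Persist / restore a fitted suite
#'
#' Writes the suite to a directory with a JSON manifest (configuration, seed,
#' cell list, feature schema) plus one serialized regressor per cell.
#'
#' @param suite A `suite_matrix`.
#' @param dir Output directory (created if needed).
#' @return `save_suite` returns `dir` invisibly; `load_suite` returns the
#'   restored `suite_matrix`.
#' @export
save_suite <- function(suite, dir) {
  stopifnot(inherits(suite, "suite_matrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package = "mbperf",
    phasing_mode = suite$phasing_mode,
    features = suite$features,
    config = unclass(suite$config),
    split_seed = suite$split_seed,
    cells = lapply(unname(suite$cells), function(cl)
      list(variant_id = cl$variant_id, measure = cl$measure,
           n_train = cl$n_train)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  saveRDS(suite, file.path(dir, "suite.rds"))
  invisible(dir)
}

#' @rdname save_suite
#' @export
load_suite <- function(dir) {
  manifest <- file.path(dir, "manifest.json")
  if (!file.exists(manifest))
    stop("no trained suite at ", dir, " (missing manifest.json)")
  readRDS(file.path(dir, "suite.rds"))
}
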