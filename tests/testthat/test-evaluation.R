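one_variant_suite <- function(n = 200, seed = 1, noise = 0.05,
                              trees = 128) {
  reg <- list(buccaneer = pipeline_variant("Buccaneer"))
  gen <- make_outcome_table(outcome_generator_spec(noise_sigma = noise),
                            n_datasets = n, registry = reg, seed = seed)
  sp <- split_dataset(gen$data, 0.8, seed = seed)
  suite <- fit_suite(sp$train, registry = reg,
                     config = forest_config(n_trees = trees, seed = seed))
  list(suite = suite, train = sp$train, test = sp$test, reg = reg, gen = gen)
}

test_that("mae and rmse match hand computations and each other's bound", {
  expect_identical(mae(c(1, 2), c(1, 2)), 0)
  expect_identical(rmse(c(1, 2), c(1, 2)), 0)
  expect_equal(mae(c(0.1, 0.2), c(0.2, 0.4)), 0.15)
  expect_equal(rmse(c(0.1, 0.2), c(0.2, 0.4)), sqrt(0.025))
  for (i in 1:20) {
    set.seed(i)
    p <- rnorm(10); a <- rnorm(10)
    expect_gte(rmse(p, a), mae(p, a))
  }
  expect_error(mae(1:3, 1:2), "mismatch")
  expect_error(rmse(numeric(0), numeric(0)), "empty")
})

test_that("compare_to_baseline reports every cell with the metric invariants", {
  ctx <- one_variant_suite()
  ev <- compare_to_baseline(ctx$suite, ctx$test)
  expect_equal(nrow(ev), 3)
  expect_true(all(ev$rmse_model >= ev$mae_model))
  expect_true(all(ev$rmse_baseline >= ev$mae_baseline))
  expect_true(all(ev$mae_model < ev$mae_baseline))  # planted signal

  with_na <- ctx$test
  with_na$outcome[1:4] <- NA
  expect_message(ev2 <- compare_to_baseline(ctx$suite, with_na), "excluding 4")
  expect_equal(sum(ev2$n_test), nrow(ctx$test) - 4)
})

test_that("training error does not exceed test error on most replicates", {
  gaps <- vapply(1:6, function(seed) {
    ctx <- one_variant_suite(n = 150, seed = 300 + seed, trees = 64)
    tr <- compare_to_baseline(ctx$suite, ctx$train)
    te <- compare_to_baseline(ctx$suite, ctx$test)
    mean(te$mae_model) - mean(tr$mae_model)
  }, numeric(1))
  expect_gte(sum(gaps > 0), 5)
})

test_that("ablation recovers a planted single-feature signal", {
  reg <- list(buccaneer = pipeline_variant("Buccaneer"))
  spec <- outcome_generator_spec(
    noise_sigma = 0.03,
    response = function(f, v, m) plogis((2.5 - f$resolution) / 0.4),
    feature_sampler = function(n) data.frame(
      resolution = runif(n, 1, 4), rmsd = runif(n), skew = runif(n),
      max_density = runif(n), min_density = -runif(n)))
  gen <- make_outcome_table(spec, n_datasets = 300, registry = reg, seed = 17)
  sp <- split_dataset(gen$data, 0.8, seed = 17)
  ab <- ablation(sp$train, sp$test, registry = reg,
                 config = forest_config(n_trees = 64, seed = 17))
  expect_equal(nrow(ab), 5)
  best <- ab$feature[which.max(ab$delta_mae)]
  expect_identical(best, "resolution")
  # removing the only informative feature degrades the model to ~baseline
  base_mae <- mean(compare_to_baseline(
    fit_suite(sp$train, reg, config = forest_config(n_trees = 64, seed = 17)),
    sp$test)$mae_baseline)
  expect_gt(ab$mae_ablated[ab$feature == "resolution"], 0.8 * base_mae)
  expect_error(ablation(sp$train, sp$test, reg, features = "resolution"),
               "at least 2")
})

test_that("resolution-binned statistics partition the test sets", {
  ctx <- one_variant_suite(n = 150, seed = 33)
  cell <- ctx$suite$cells[["buccaneer::completeness"]]
  sub <- ctx$test[ctx$test$measure == "completeness", ]
  pred <- predict(cell$forest, sub)
  rep <- resolution_binned_stats(pred, sub$outcome, sub$resolution,
                                 bin_width = 0.5)
  expect_equal(sum(rep$n), nrow(sub))
  expect_true(all(diff(rep$bin_low) > 0))
  expect_true(all(is.na(rep$mean_actual[rep$n == 0])))

  # predictions identical to actuals give identical bin statistics
  rep2 <- resolution_binned_stats(sub$outcome, sub$outcome, sub$resolution,
                                  bin_width = 0.5)
  expect_equal(rep2$mean_predicted, rep2$mean_actual)
  expect_equal(rep2$sd_predicted, rep2$sd_actual)

  # single resolution -> a single populated bin
  rep3 <- resolution_binned_stats(pred, sub$outcome,
                                  rep(2.0, nrow(sub)), bin_width = 0.1)
  expect_equal(sum(rep3$n > 0), 1)

  # completeness decays with resolution in the generator
  rep4 <- resolution_binned_stats(sub$outcome, sub$outcome, sub$resolution,
                                  bin_width = 1.0)
  mm <- rep4$mean_actual[rep4$n > 3]
  expect_true(all(diff(mm) < 0))
})

test_that("group hit rate handles the degenerate ranking layouts", {
  actuals <- expand.grid(dataset_id = c("d1", "d2"),
                         variant_id = c("A", "B", "C"),
                         stringsAsFactors = FALSE)
  actuals$measure <- "completeness"
  actuals$outcome <- c(0.9, 0.2, 0.5, 0.4, 0.7, 0.6)

  base <- expand.grid(dataset_id = c("d1", "d2"),
                      variant_id = c("A", "B", "C"),
                      stringsAsFactors = FALSE)
  base$measure <- "completeness"
  base$point <- c(0.9, 0.2, 0.5, 0.4, 0.7, 0.6)  # perfect predictions
  base$width <- 0.1

  all_one <- base; all_one$group <- 1L
  expect_equal(unname(group_hit_rate(all_one, actuals)), 1)

  # singleton groups with the lowest-error variant always ranked last:
  # C predicts perfectly but sits in group 3; A and B are far off in groups 1-2
  worst <- base
  worst$point[worst$variant_id %in% c("A", "B")] <- -5
  worst$group <- c(A = 1L, B = 2L, C = 3L)[worst$variant_id]
  expect_equal(unname(group_hit_rate(worst, actuals)), 0)

  # the alternative criterion: best actual outcome in the first group
  expect_equal(unname(group_hit_rate(all_one, actuals, best = "actual")), 1)
})

test_that("equally predictable variants put the lowest-error variant in the first group", {
  # all four MR variants share one response and one noise level, so their
  # calibrated interval widths coincide up to sampling error and the first
  # group captures the per-dataset best predictions most of the time
  reg <- default_registry("MR")
  spec <- outcome_generator_spec(
    "MR", noise_sigma = 0.05,
    response = function(f, v, m) plogis((2.5 - f$resolution) / 0.5))
  gen <- make_outcome_table(spec, n_datasets = 500, registry = reg, seed = 55)
  sp <- split_dataset(gen$data, 0.8, seed = 55)
  suite <- fit_suite(sp$train, reg, "MR", forest_config(n_trees = 256, seed = 55))
  test_ids <- unique(sp$test$dataset_id)
  feats <- gen$features[gen$features$dataset_id %in% test_ids, ]
  preds <- predict(suite, feats, interval = TRUE)
  comp <- preds[preds$measure == "completeness", ]
  grouped <- do.call(rbind, lapply(split(comp, comp$dataset_id),
                                   function(d) ranked_report(d)$records))
  hr <- group_hit_rate(grouped, sp$test)
  expect_gte(unname(hr["completeness"]), 0.5)
})

test_that("within-k fractions are cumulative and exact for a perfect recommender", {
  actuals <- expand.grid(dataset_id = sprintf("d%d", 1:20),
                         variant_id = c("A", "B"), stringsAsFactors = FALSE)
  actuals$measure <- "completeness"
  set.seed(44)
  actuals$outcome <- runif(nrow(actuals))
  best <- vapply(split(actuals, actuals$dataset_id),
                 function(d) d$variant_id[which.max(d$outcome)], "")
  perfect <- data.frame(dataset_id = names(best), measure = "completeness",
                        variant_id = unname(best), stringsAsFactors = FALSE)
  wk <- within_k_analysis(perfect, actuals, thresholds = c(0, 0.01, 0.05))
  expect_true(all(wk$fraction == 1))

  always_a <- perfect; always_a$variant_id <- "A"
  wk2 <- within_k_analysis(always_a, actuals, thresholds = c(0, 0.05, 0.2, 1))
  expect_true(all(diff(wk2$fraction) >= 0))
  expect_equal(wk2$fraction[wk2$k == 1], 1)
  # k = 0 is the exact-best fraction
  frac_exact <- mean(best == "A")
  expect_equal(wk2$fraction[wk2$k == 0], frac_exact)
})
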