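# single-cell (Buccaneer, completeness) table: one outcome per dataset
small_table <- function(n = 60, seed = 1, noise = 0.05,
                        phasing_mode = "experimental") {
  reg <- list(buccaneer = pipeline_variant("Buccaneer",
                                           phasing_mode = phasing_mode))
  gen <- make_outcome_table(outcome_generator_spec(phasing_mode,
                                                   noise_sigma = noise),
                            n_datasets = n, registry = reg, seed = seed)
  gen$data <- gen$data[gen$data$measure == "completeness", , drop = FALSE]
  gen$truth <- gen$truth[gen$truth$measure == "completeness", , drop = FALSE]
  gen
}

test_that("split_dataset partitions reproducibly with the documented sizes", {
  tab <- data.frame(dataset_id = sprintf("d%04d", 1:10), outcome = runif(10))
  sp <- split_dataset(tab, 0.8, seed = 3)
  expect_equal(nrow(sp$train), 8)
  expect_equal(nrow(sp$test), 2)
  expect_length(intersect(sp$train$dataset_id, sp$test$dataset_id), 0)
  expect_setequal(c(sp$train$dataset_id, sp$test$dataset_id), tab$dataset_id)

  sp2 <- split_dataset(tab, 0.8, seed = 3)
  expect_identical(sp$train$dataset_id, sp2$train$dataset_id)

  big <- data.frame(dataset_id = sprintf("d%04d", 1:1203))
  expect_equal(nrow(split_dataset(big, 0.8, seed = 1)$train), 962)

  expect_error(split_dataset(tab[1, , drop = FALSE]), "at least 2")
  expect_error(split_dataset(tab, 1.2), "train_fraction")
})

test_that("a forest on a constant target predicts the constant exactly", {
  tab <- small_table(n = 40, seed = 2)$data
  tab$outcome <- 0.7
  fit <- train_forest(tab, forest_config(n_trees = 32, seed = 1))
  expect_equal(unique(predict(fit, tab)), 0.7)
})

test_that("forest predictions stay within the training outcome range", {
  gen <- small_table(n = 150, seed = 5)
  sp <- split_dataset(gen$data, 0.8, seed = 5)
  fit <- train_forest(sp$train, forest_config(n_trees = 128, seed = 2))
  p <- predict(fit, sp$test)
  expect_true(all(p >= min(sp$train$outcome) - 1e-12))
  expect_true(all(p <= max(sp$train$outcome) + 1e-12))
})

test_that("forest training is reproducible for a fixed seed", {
  tab <- small_table(n = 80, seed = 6)$data
  f1 <- train_forest(tab, forest_config(n_trees = 64, seed = 9))
  f2 <- train_forest(tab, forest_config(n_trees = 64, seed = 9))
  expect_identical(predict(f1, tab), predict(f2, tab))
})

test_that("the forest beats Zero-R on planted signal", {
  gen <- small_table(n = 500, seed = 7, noise = 0.02)
  sp <- split_dataset(gen$data, 0.8, seed = 7)
  fit <- train_forest(sp$train, forest_config(n_trees = 256, seed = 3))
  base <- zero_r(sp$train)
  expect_lt(mae(predict(fit, sp$test), sp$test$outcome),
            mae(predict(base, sp$test), sp$test$outcome))
})

test_that("many trees do not do worse than a single tree on noisy data", {
  wins <- 0L
  for (seed in 1:10) {
    gen <- small_table(n = 200, seed = 20 + seed, noise = 0.08)
    sp <- split_dataset(gen$data, 0.8, seed = seed)
    f1 <- train_forest(sp$train, forest_config(n_trees = 1, seed = seed))
    fN <- train_forest(sp$train, forest_config(n_trees = 256, seed = seed))
    r1 <- rmse(predict(f1, sp$test), sp$test$outcome)
    rN <- rmse(predict(fN, sp$test), sp$test$outcome)
    if (rN <= r1) wins <- wins + 1L
  }
  expect_gte(wins, 9)
})

test_that("Zero-R predicts the training median with the even-count convention", {
  b1 <- zero_r(data.frame(outcome = c(0.2, 0.9, 0.3)))
  expect_identical(predict(b1, data.frame(x = 1:5)), rep(0.3, 5))
  b2 <- zero_r(data.frame(outcome = c(0.2, 0.4)))
  expect_equal(unique(predict(b2, data.frame(x = 1:3))), 0.3)
  expect_error(zero_r(data.frame(outcome = numeric(0))), "at least 1")
})

test_that("Zero-R held-out MAE equals the mean deviation from the training median", {
  gen <- small_table(n = 300, seed = 8)
  sp <- split_dataset(gen$data, 0.8, seed = 8)
  base <- zero_r(sp$train)
  got <- mae(predict(base, sp$test), sp$test$outcome)
  expect_equal(got, mean(abs(sp$test$outcome - median(sp$train$outcome))))
})

test_that("fit_suite trains exactly the applicable cells and predicts all of them", {
  reg <- default_registry("MR")
  gen <- make_outcome_table(outcome_generator_spec("MR"), n_datasets = 50,
                            registry = reg, seed = 10)
  suite <- fit_suite(gen$data, registry = reg, phasing_mode = "MR",
                     config = forest_config(n_trees = 32, seed = 4))
  expect_s3_class(suite, "suite_matrix")
  expect_length(suite$cells, 10)
  expect_setequal(names(suite$cells),
                  paste(suite_cells(reg)$variant_id, suite_cells(reg)$measure,
                        sep = "::"))
  preds <- predict(suite, gen$features[1:3, ], interval = TRUE)
  expect_equal(nrow(preds), 30)
  expect_true(all(preds$width > 0))
  expect_true(all(preds$point[preds$measure == "completeness"] >= 0 &
                    preds$point[preds$measure == "completeness"] <= 1))

  smry <- summary(suite)
  expect_equal(nrow(smry), 10)

  # missing cell data is an error
  drop <- gen$data[gen$data$variant_id != "shelxe", ]
  expect_error(fit_suite(drop, registry = reg, phasing_mode = "MR",
                         config = forest_config(n_trees = 8)),
               "no training rows")
})

test_that("suites persist to a manifest directory and restore", {
  reg <- default_registry("MR")[1:2]
  gen <- make_outcome_table(outcome_generator_spec("MR"), n_datasets = 40,
                            registry = reg, seed = 11)
  suite <- fit_suite(gen$data, registry = reg, phasing_mode = "MR",
                     config = forest_config(n_trees = 16, seed = 5))
  dir <- withr::local_tempdir()
  save_suite(suite, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_length(manifest$cells, 5)
  back <- load_suite(dir)
  expect_identical(predict(back, gen$features[1:2, ], interval = FALSE),
                   predict(suite, gen$features[1:2, ], interval = FALSE))
  expect_error(load_suite(withr::local_tempdir()), "manifest")
})
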