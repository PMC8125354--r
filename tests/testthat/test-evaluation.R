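# Small separable state-mode dataset: class effect 10 with unit noise.
separable_ds <- function(seed, P = 4, n_per = 15, d = 5) {
  generate_feature_dataset(synthetic_config(P = P, n_per = n_per, d = d,
                                            delta = 10, sigma_participant = 0,
                                            sigma_noise = 1, seed = seed))
}

test_that("Wald intervals match closed-form arithmetic and clamp to [0, 1]", {
  expect_equal(wald_ci(0.5, 100), c(0.402, 0.598), tolerance = 1e-3)
  expect_equal(wald_ci(1, 500), c(1, 1))
  expect_equal(wald_ci(0, 500), c(0, 0))
  # width is monotone decreasing in n at fixed accuracy
  widths <- vapply(c(50, 200, 1000, 5000),
                   function(n) diff(wald_ci(0.8, n)), numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("a linear model is perfect on a wide-margin separable fold", {
  ds <- separable_ds(1)
  plan <- lopo_partition(ds)
  res <- train_eval_fold(ds, plan$folds[[1]], model_spec("linear", seed = 1))
  expect_equal(res$accuracy, 1.0)
})

test_that("accuracy on independently randomised labels is at chance", {
  set.seed(20)
  n <- 2400
  feat <- matrix(rnorm(n * 4), ncol = 4)
  lab <- rep(c(0L, 1L), n / 2)
  ds <- participant_dataset(feat, rep("A", n), lab)
  fold <- list(train = 1:1200, eval = 1201:2400)
  res <- train_eval_fold(ds, fold, model_spec("linear", seed = 3))
  expect_lte(abs(res$accuracy - 0.5), 3 * sqrt(0.25 / 1200))
})

test_that("fold training is deterministic and rejects single-class folds", {
  ds <- separable_ds(2)
  fold <- lopo_partition(ds)$folds[[2]]
  spec <- model_spec("feedforward", hidden = 3, maxit = 30, seed = 9)
  r1 <- train_eval_fold(ds, fold, spec)
  r2 <- train_eval_fold(ds, fold, spec)
  expect_identical(r1$correct, r2$correct)
  bad_fold <- list(train = which(ds$label == 0L), eval = which(ds$label == 1L))
  expect_error(train_eval_fold(ds, bad_fold, spec), "single class")
})

test_that("pooled accuracy is the eval-size-weighted mean of fold accuracies", {
  ds <- generate_feature_dataset(synthetic_config(P = 5, n_per = 12, d = 6,
                                                  delta = 1, sigma_participant = 1,
                                                  sigma_noise = 1, seed = 4))
  plan <- lnpo_partition(ds, 3, seed = 2)
  res <- run_cv(ds, plan, model_spec("linear", seed = 1))
  expect_equal(res$accuracy,
               sum(res$fold_accuracy * res$fold_n) / sum(res$fold_n),
               tolerance = 1e-12)
  expect_equal(res$n_eval, ds$n)
  expect_true(res$ci[1] <= res$accuracy && res$accuracy <= res$ci[2])
})

test_that("the sweep selects the planted winner deterministically", {
  ds <- separable_ds(5)
  plan <- lopo_partition(ds)
  # constant-prediction decoys against a real learner
  decoy <- function(const, id) model_spec("custom",
    fit = function(x, y) const,
    predict_fun = function(model, x) rep(model, nrow(x)),
    id = id)
  grid <- list(decoy(0L, "always0"), model_spec("linear", seed = 1),
               decoy(1L, "always1"))
  sw1 <- hyperparameter_sweep(ds, plan, grid)
  expect_equal(sw1$best$id, "linear_lambda0.01")
  expect_equal(sw1$best_result$accuracy, 1.0)
  sw2 <- hyperparameter_sweep(ds, plan, grid)
  expect_identical(sw1$table, sw2$table)
  # single-spec grid returns that spec
  one <- hyperparameter_sweep(ds, plan, list(model_spec("linear", seed = 1)))
  expect_equal(one$best$id, "linear_lambda0.01")
  expect_error(hyperparameter_sweep(ds, plan, list()), "empty")
})

test_that("comparison arithmetic handles identity and degenerate cases", {
  ds <- separable_ds(6)
  res <- run_cv(ds, lopo_partition(ds), model_spec("linear", seed = 1))
  same <- comparison_report(res, res)
  if (res$error_rate > 0) {
    expect_equal(same$error_ratio, 1.0)
    expect_equal(same$percent_error_increase, 0)
  } else {
    expect_true(is.na(same$error_ratio))
  }
  expect_false(same$ci_dominance)
  expect_error(compare_error_rates(0, 0.3), "must be positive")
})

test_that("compare_partitioning builds matched plans and a full report", {
  ds <- generate_feature_dataset(synthetic_config(P = 6, n_per = 20, d = 20,
                                                  delta = 1, sigma_participant = 2,
                                                  sigma_noise = 0.5, seed = 7))
  cmp <- compare_partitioning(ds, model_spec("linear", seed = 7), seed = 7)
  expect_s3_class(cmp, "comparison_report")
  expect_equal(cmp$improper$n_eval, ds$n)
  expect_equal(cmp$proper$n_eval, ds$n)
  expect_equal(length(cmp$improper$fold_accuracy), 6L)
  expect_equal(length(cmp$proper$fold_accuracy), 6L)
})

test_that("the demo pipeline emits the 2 x 3 design with purity and grids", {
  cfg <- synthetic_config(P = 6, n_per = 15, d = 12, delta = 1,
                          sigma_participant = 3, sigma_noise = 0.5, seed = 11)
  demo <- run_demo_pipeline(cfg, model_spec("linear", seed = 11))
  expect_equal(nrow(demo$table), 6L)
  expect_setequal(unique(demo$table$policy), c("improper", "proper"))
  expect_setequal(unique(demo$table$transform),
                  c("untransformed", "shifted_heaviside", "shift_to_median"))
  expect_length(demo$purity, 3L)
  expect_s3_class(demo$grids$proper, "weight_grid")
  expect_s3_class(demo$grids$improper, "weight_grid")
  # file outputs
  out <- tempfile("demo")
  run_demo_pipeline(cfg, model_spec("linear", seed = 11), out_dir = out)
  expect_true(file.exists(file.path(out, "results_table.csv")))
  expect_true(file.exists(file.path(out, "grid_proper.json")))
})
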