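#' Classifier specification for the CV harness
#'
#' The harness is deliberately model-agnostic: any object with a
#' \code{fit(x, y)} function returning a predictor usable via
#' \code{predict_fun(model, x)} can be plugged in. Two built-in kinds cover
#' the experiments here:
#' \itemize{
#'   \item \code{"linear"}: ridge-regularised logistic regression
#'     (\code{glmnet}, alpha = 0) at a fixed penalty \code{lambda}.
#'   \item \code{"feedforward"}: a single-hidden-layer network
#'     (\code{nnet}) with \code{hidden} units, weight decay \code{decay} and
#'     \code{maxit} training iterations.
#' }
#'
#' @param kind \code{"linear"}, \code{"feedforward"}, or \code{"custom"}.
#' @param lambda ridge penalty for the linear model.
#' @param hidden hidden units for the feedforward model.
#' @param decay weight decay for the feedforward model.
#' @param maxit training iterations for the feedforward model.
#' @param seed RNG seed used before every fit (mandatory: fits are
#'   deterministic given the seed).
#' @param fit,predict_fun custom fit/predict pair for \code{kind = "custom"}:
#'   \code{fit(x, y)} receives a numeric matrix and a 0/1 vector and returns a
#'   model; \code{predict_fun(model, x)} returns 0/1 predictions.
#' @param id optional identifier used in sweep tables; derived from the
#'   parameters when omitted.
#' @return an object of class \code{model_spec}.
#' @export
model_spec <- function(kind = c("linear", "feedforward", "custom"),
                       lambda = 0.01, hidden = 10L, decay = 1e-3,
                       maxit = 100L, seed = 1L,
                       fit = NULL, predict_fun = NULL, id = NULL) {
  kind <- match.arg(kind)
  if (kind == "custom" && (is.null(fit) || is.null(predict_fun)))
    stop("custom models need both fit and predict_fun")
  if (is.null(id)) {
    id <- switch(kind,
                 linear = sprintf("linear_lambda%g", lambda),
                 feedforward = sprintf("ff_h%d_d%g_it%d", hidden, decay, maxit),
                 custom = "custom")
  }
  n_par <- switch(kind, linear = 1L, feedforward = 3L, custom = 0L)
  structure(list(kind = kind, lambda = lambda, hidden = as.integer(hidden),
                 decay = decay, maxit = as.integer(maxit),
                 seed = as.integer(seed), fit = fit,
                 predict_fun = predict_fun, id = id, n_par = n_par),
            class = "model_spec")
}

fit_model <- function(spec, x, y) {
  set.seed(spec$seed)
  switch(spec$kind,
         linear = glmnet::glmnet(x, factor(y, levels = c(0, 1)),
                                 family = "binomial", alpha = 0,
                                 lambda = spec$lambda, standardize = TRUE),
         feedforward = nnet::nnet(x, y, size = spec$hidden, decay = spec$decay,
                                  maxit = spec$maxit, entropy = TRUE,
                                  trace = FALSE,
                                  MaxNWts = 10000L),
         custom = spec$fit(x, y))
}

predict_model <- function(spec, model, x) {
  switch(spec$kind,
         linear = as.integer(stats::predict(model, newx = x, type = "class")),
         feedforward = as.integer(stats::predict(model, x) > 0.5),
         custom = as.integer(spec$predict_fun(model, x)))
}

#' Train on one fold and evaluate its held-out set
#'
#' Fits the model on the fold's train indices and predicts its evaluation
#' indices. Deterministic for a fixed model seed.
#'
#' @param ds a \code{participant_dataset}.
#' @param fold a list with integer \code{train} and \code{eval} index vectors.
#' @param spec a \code{model_spec}.
#' @param fold_id optional label used in error messages.
#' @return list with \code{accuracy} and \code{correct} (0/1 vector aligned
#'   with \code{fold$eval}).
#' @export
train_eval_fold <- function(ds, fold, spec, fold_id = NULL) {
  stopifnot(inherits(ds, "participant_dataset"), inherits(spec, "model_spec"))
  if (!length(fold$train) || !length(fold$eval))
    stop("fold train and eval sets must be non-empty")
  ytr <- ds$label[fold$train]
  if (length(unique(ytr)) < 2L)
    stop("training fold ", if (is.null(fold_id)) "" else fold_id,
         " contains a single class; cannot fit a classifier")
  model <- fit_model(spec, ds$features[fold$train, , drop = FALSE], ytr)
  pred <- predict_model(spec, model,
                        ds$features[fold$eval, , drop = FALSE])
  correct <- as.integer(pred == ds$label[fold$eval])
  list(accuracy = mean(correct), correct = correct)
}

#' Wald binomial confidence interval for a pooled accuracy
#'
#' acc +/- z * sqrt(acc (1 - acc) / n), clamped to [0, 1].
#'
#' @param acc pooled accuracy in [0, 1].
#' @param n number of evaluated observations.
#' @param conf confidence level, default 0.95.
#' @return numeric \code{c(low, high)}.
#' @export
wald_ci <- function(acc, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  half <- z * sqrt(acc * (1 - acc) / n)
  c(max(0, acc - half), min(1, acc + half))
}

#' Run cross-validation under a partition plan
#'
#' Each fold is trained and evaluated with \code{\link{train_eval_fold}};
#' accuracy is pooled over all evaluated observations (each observation is
#' evaluated exactly once under the plans built here) and a 95% Wald binomial
#' interval is attached.
#'
#' @param ds a \code{participant_dataset}.
#' @param plan a \code{partition_plan} for \code{ds}.
#' @param spec a \code{model_spec}.
#' @param conf confidence level for the interval.
#' @return an object of class \code{cv_result}: per-fold accuracies and sizes,
#'   pooled accuracy, error rate, CI, \code{n_eval}, plan policy and model id.
#' @export
run_cv <- function(ds, plan, spec, conf = 0.95) {
  stopifnot(inherits(plan, "partition_plan"))
  all_eval <- unlist(lapply(plan$folds, `[[`, "eval"))
  if (any(all_eval < 1L | all_eval > ds$n))
    stop("plan indexes outside the dataset")
  fold_acc <- numeric(length(plan$folds))
  fold_n <- integer(length(plan$folds))
  total_correct <- 0L
  for (f in seq_along(plan$folds)) {
    res <- train_eval_fold(ds, plan$folds[[f]], spec, fold_id = f)
    fold_acc[f] <- res$accuracy
    fold_n[f] <- length(res$correct)
    total_correct <- total_correct + sum(res$correct)
  }
  n_eval <- sum(fold_n)
  acc <- total_correct / n_eval
  ci <- wald_ci(acc, n_eval, conf)
  structure(list(fold_accuracy = fold_acc, fold_n = fold_n,
                 accuracy = acc, error_rate = 1 - acc,
                 ci = ci, conf = conf, n_eval = n_eval,
                 policy = plan$policy, model_id = spec$id),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, digits = 3, ...) {
  cat("cv_result (", x$policy, ", model ", x$model_id, ")\n", sep = "")
  cat("  pooled accuracy: ", round(x$accuracy, digits),
      " (", round(100 * x$conf), "% CI: ", round(x$ci[1], digits), ", ",
      round(x$ci[2], digits), ")\n", sep = "")
  cat("  error rate: ", round(x$error_rate, digits),
      "  over n_eval = ", x$n_eval, " in ", length(x$fold_accuracy),
      " folds\n", sep = "")
  invisible(x)
}

#' Sweep a grid of model specifications under one plan
#'
#' Runs \code{\link{run_cv}} for every specification and selects the one with
#' the highest pooled accuracy; ties are broken toward fewer hyperparameters,
#' then lexicographically by spec id, so selection is deterministic.
#'
#' @param ds a \code{participant_dataset}.
#' @param plan a \code{partition_plan}.
#' @param grid list of \code{model_spec}s.
#' @return list with \code{best} (a \code{model_spec}), \code{best_result}
#'   (its \code{cv_result}) and \code{table} (data.frame of id, accuracy, CI).
#' @export
hyperparameter_sweep <- function(ds, plan, grid) {
  if (!length(grid)) stop("sweep grid is empty")
  results <- lapply(grid, function(s) run_cv(ds, plan, s))
  tab <- data.frame(id = vapply(grid, `[[`, character(1), "id"),
                    n_par = vapply(grid, `[[`, integer(1), "n_par"),
                    accuracy = vapply(results, `[[`, numeric(1), "accuracy"),
                    ci_low = vapply(results, function(r) r$ci[1], numeric(1)),
                    ci_high = vapply(results, function(r) r$ci[2], numeric(1)),
                    stringsAsFactors = FALSE)
  ord <- order(-tab$accuracy, tab$n_par, tab$id)
  best_i <- ord[1]
  list(best = grid[[best_i]], best_result = results[[best_i]],
       table = tab[ord, ])
}

#' Arithmetic comparison of two error rates
#'
#' @param err_improper,err_proper error rates of the improper and proper
#'   evaluations (the improper one must be positive).
#' @return list with \code{error_ratio} = err_proper / err_improper and
#'   \code{percent_error_increase} = 100 (err_proper - err_improper) /
#'   err_improper.
#' @export
compare_error_rates <- function(err_improper, err_proper) {
  if (err_improper <= 0)
    stop("error ratio undefined: improper error rate must be positive")
  list(error_ratio = err_proper / err_improper,
       percent_error_increase = 100 * (err_proper - err_improper) / err_improper)
}

#' Build a comparison report from two CV results
#'
#' @param improper,proper \code{cv_result}s from the improper and proper plans.
#' @return an object of class \code{comparison_report}: both results, the
#'   error ratio, the percent error increase, and \code{ci_dominance}
#'   (\code{TRUE} iff the proper accuracy CI lies entirely below the improper
#'   accuracy CI).
#' @export
comparison_report <- function(improper, proper) {
  stopifnot(inherits(improper, "cv_result"), inherits(proper, "cv_result"))
  cmp <- if (improper$error_rate > 0)
    compare_error_rates(improper$error_rate, proper$error_rate)
  else list(error_ratio = NA_real_, percent_error_increase = NA_real_)
  structure(list(improper = improper, proper = proper,
                 error_ratio = cmp$error_ratio,
                 percent_error_increase = cmp$percent_error_increase,
                 ci_dominance = proper$ci[2] < improper$ci[1]),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, digits = 3, ...) {
  cat("comparison_report: improper vs proper partitioning\n")
  cat("  improper: acc ", round(x$improper$accuracy, digits), " (",
      round(x$improper$ci[1], digits), ", ", round(x$improper$ci[2], digits),
      "), err ", round(x$improper$error_rate, digits), "\n", sep = "")
  cat("  proper:   acc ", round(x$proper$accuracy, digits), " (",
      round(x$proper$ci[1], digits), ", ", round(x$proper$ci[2], digits),
      "), err ", round(x$proper$error_rate, digits), "\n", sep = "")
  if (!is.na(x$error_ratio))
    cat("  proper error is ", round(x$error_ratio, 2), "x the improper error (",
        round(x$percent_error_increase, 1), "% increase)\n", sep = "")
  cat("  proper CI entirely below improper CI: ", x$ci_dominance, "\n", sep = "")
  invisible(x)
}

#' Compare improper and proper partitioning on one dataset
#'
#' Builds matched plans -- improper shuffled k-fold with k equal to the proper
#' fold count, so train and evaluation quantities per fold agree -- runs CV
#' under both (optionally sweeping a grid per method, mirroring
#' sweep-and-select protocols), and reports the error ratio, percent error
#' increase and CI dominance.
#'
#' @param ds a \code{participant_dataset}.
#' @param spec a \code{model_spec}, or a list of them to sweep per method.
#' @param proper \code{"lopo"} or \code{"lnpo"}.
#' @param n_folds fold count for the \code{"lnpo"} proper plan (defaults to
#'   the participant count, i.e. LOPO-equivalent grouping).
#' @param seed seed for the improper shuffle (and LNPO grouping).
#' @return a \code{comparison_report}.
#' @export
compare_partitioning <- function(ds, spec, proper = c("lopo", "lnpo"),
                                 n_folds = NULL, seed = 1L) {
  proper <- match.arg(proper)
  P <- n_participants(ds)
  if (P < 2L) stop("need at least 2 participants")
  proper_plan <- if (proper == "lopo") lopo_partition(ds) else
    lnpo_partition(ds, if (is.null(n_folds)) P else n_folds, seed = seed)
  k <- proper_plan$k
  improper_plan <- improper_shuffled_kfold(ds, k, seed = seed)
  if (length(improper_plan$folds) != length(proper_plan$folds))
    stop("fold counts of the two plans do not match")
  run1 <- function(plan) {
    if (inherits(spec, "model_spec")) run_cv(ds, plan, spec)
    else hyperparameter_sweep(ds, plan, spec)$best_result
  }
  comparison_report(run1(improper_plan), run1(proper_plan))
}

#' End-to-end demonstration pipeline on synthetic data
#'
#' Generates a synthetic multi-participant dataset, applies the
#' 2 x 3 experimental design {improper, proper} x {untransformed, shifted
#' Heaviside, shift to median}, and collects pooled accuracies with 95%
#' intervals, participant purity before/after transformation, and
#' density-ratio weight grids for the proper and improper splits of the
#' untransformed data. Fully seeded.
#'
#' @param config a \code{synthetic_config}.
#' @param spec a \code{model_spec} or list of them (swept per cell).
#' @param n_bins weight-grid resolution, default 7.
#' @param purity_k neighbourhood size for the purity statistic.
#' @param out_dir optional directory; when given, the results table (CSV),
#'   weight grids (JSON) and heat maps (PNG) are written there.
#' @return an object of class \code{demo_result}: \code{table} (6-row
#'   data.frame: policy x transform with accuracy, CI, error rate),
#'   \code{comparisons} (per-transform \code{comparison_report}s),
#'   \code{purity} (named vector), \code{grids} (proper/improper
#'   \code{weight_grid}s) and \code{config}.
#' @export
run_demo_pipeline <- function(config, spec, n_bins = 7L, purity_k = 10L,
                              out_dir = NULL) {
  ds <- generate_feature_dataset(config)
  versions <- list(untransformed = ds,
                   shifted_heaviside = shifted_heaviside(ds, leakage_acknowledged = TRUE),
                   shift_to_median = shift_to_median(ds, leakage_acknowledged = TRUE))
  comparisons <- lapply(versions, function(v)
    compare_partitioning(v, spec, proper = "lopo", seed = config$seed))
  rows <- list()
  for (tn in names(versions)) {
    cmp <- comparisons[[tn]]
    for (pol in c("improper", "proper")) {
      r <- cmp[[pol]]
      rows[[length(rows) + 1L]] <-
        data.frame(policy = pol, transform = tn, accuracy = r$accuracy,
                   ci_low = r$ci[1], ci_high = r$ci[2],
                   error_rate = r$error_rate, n_eval = r$n_eval,
                   stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  purity <- vapply(versions, function(v)
    participant_purity(v$features, v$participant, k = purity_k), numeric(1))
  # weight grids on the shared PCA plane of the untransformed data
  proj <- pca2_project(ds$features)$scores
  lopo_eval <- lopo_partition(ds)$folds[[1]]
  imp_eval <- improper_shuffled_kfold(ds, n_participants(ds),
                                      seed = config$seed)$folds[[1]]
  grids <- list(
    proper = weight_ratio_grid(proj[lopo_eval$train, , drop = FALSE],
                               proj[lopo_eval$eval, , drop = FALSE],
                               n_bins = n_bins),
    improper = weight_ratio_grid(proj[imp_eval$train, , drop = FALSE],
                                 proj[imp_eval$eval, , drop = FALSE],
                                 n_bins = n_bins))
  res <- structure(list(table = tab, comparisons = comparisons,
                        purity = purity, grids = grids, config = config),
                   class = "demo_result")
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.csv(tab, file.path(out_dir, "results_table.csv"),
                     row.names = FALSE)
    write_weight_grid_json(grids$proper, file.path(out_dir, "grid_proper.json"))
    write_weight_grid_json(grids$improper, file.path(out_dir, "grid_improper.json"))
    for (g in c("proper", "improper")) {
      grDevices::png(file.path(out_dir, paste0("grid_", g, ".png")),
                     width = 600, height = 600)
      plot(grids[[g]], main = paste("log10 weights,", g, "split"))
      grDevices::dev.off()
    }
  }
  res
}

#' @export
print.demo_result <- function(x, digits = 3, ...) {
  cat("demo_result: {improper, proper} x {untransformed, shifted Heaviside, shift to median}\n")
  tab <- x$table
  tab$accuracy <- round(tab$accuracy, digits)
  tab$ci_low <- round(tab$ci_low, digits)
  tab$ci_high <- round(tab$ci_high, digits)
  tab$error_rate <- round(tab$error_rate, digits)
  print(tab, row.names = FALSE)
  cat("participant purity: ",
      paste(names(x$purity), round(x$purity, 3), sep = " = ", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
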