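#' Train and evaluate one matched run
#'
#' Fits the age forest on the reference training rows restricted to the
#' panel CpGs (plus sex), predicts both matched test arms, and returns the
#' per-arm mean absolute error and mean age gap (predicted minus
#' chronological age, signed; positive = overestimation).
#'
#' @param ref,target [methylation_cohort()]s sharing the panel CpGs.
#' @param split a `matched_split` from [draw_matched_split()] /
#'   [generate_splits()].
#' @param cpgs ordered CpG names forming the model panel (non-empty).
#' @param n_trees,min_leaf,predictor_selection,surrogate forest parameters,
#'   see [age_forest()].
#' @param seed forest seed for this run.
#' @param model_tag label stored on the result (e.g. `"clock"`, `"robust"`).
#' @param fit_fun optional override for the learner, called as
#'   `fit_fun(train_cohort, cpgs)` and returning either an object with a
#'   `predict(object, cohort)` method or a plain prediction function
#'   `function(cohort)`; used for stub models in validation.
#' @return One-row `data.frame`: `run_id`, `model_tag`, `mae_ref`,
#'   `mae_target`, `gap_ref`, `gap_target`.
#' @export
run_once <- function(ref, target, split, cpgs, n_trees = 1000, min_leaf = 1,
                     predictor_selection = "curvature", surrogate = TRUE,
                     seed = NULL, model_tag = "clock", fit_fun = NULL) {
  if (length(cpgs) == 0) stop("empty CpG panel")
  train <- subset_cohort(ref, split$ref_train_indices)
  ref_test <- subset_cohort(ref, split$ref_test_indices)
  target_test <- subset_cohort(target, split$target_test_indices)
  fit <- if (is.null(fit_fun)) {
    age_forest(train, cpgs = cpgs, n_trees = n_trees, min_leaf = min_leaf,
               predictor_selection = predictor_selection,
               surrogate = surrogate, oob = FALSE, seed = seed)
  } else fit_fun(train, cpgs)
  pr <- if (is.function(fit)) fit(ref_test) else predict(fit, ref_test)
  pt <- if (is.function(fit)) fit(target_test) else predict(fit, target_test)
  data.frame(run_id = split$run_id, model_tag = model_tag,
             mae_ref = mean(abs(pr - ref_test$age)),
             mae_target = mean(abs(pt - target_test$age)),
             gap_ref = mean(pr - ref_test$age),
             gap_target = mean(pt - target_test$age),
             stringsAsFactors = FALSE)
}

#' Aggregate per-run results into a bias summary
#'
#' Arithmetic mean and median (midpoint convention for even counts) of the
#' per-run MAEs and mean age gaps for each arm.
#'
#' @param runs `data.frame` of [run_once()] rows sharing one `model_tag`.
#' @param target_group label of the target cohort, carried into the summary.
#' @return A one-row `data.frame` of class `bias_summary` with columns
#'   `model_tag`, `target_group`, `n_runs` and
#'   `{mean,median}_{mae,gap}_{ref,target}`.
#' @export
aggregate_runs <- function(runs, target_group = NA_character_) {
  if (is.null(runs) || nrow(runs) == 0) stop("no runs to aggregate")
  if (length(unique(runs$model_tag)) != 1)
    stop("runs must share a single model_tag")
  out <- data.frame(
    model_tag = runs$model_tag[1], target_group = target_group,
    n_runs = nrow(runs),
    mean_mae_ref = mean(runs$mae_ref), median_mae_ref = median(runs$mae_ref),
    mean_mae_target = mean(runs$mae_target),
    median_mae_target = median(runs$mae_target),
    mean_gap_ref = mean(runs$gap_ref), median_gap_ref = median(runs$gap_ref),
    mean_gap_target = mean(runs$gap_target),
    median_gap_target = median(runs$gap_target),
    stringsAsFactors = FALSE)
  class(out) <- c("bias_summary", "data.frame")
  out
}

#' Run the full matched-subsampling bias comparison
#'
#' The core procedure: a stream of unique age- and sex-matched paired test
#' subsamples is drawn; for every split a forest is trained on the
#' remaining reference samples once per model panel (the clock panel and,
#' when non-empty, the robust panel share the same splits and training
#' rows, differing only in features); both matched test arms are predicted;
#' per-run MAEs and mean age gaps are aggregated into means and medians
#' across runs.
#'
#' @param ref reference (healthy) [methylation_cohort()].
#' @param target target (clinical) [methylation_cohort()].
#' @param panels a `panel_assignment` from [assign_panels()], or a list with
#'   elements `clock` and optionally `robust` (character CpG vectors).
#' @param n_runs number of matched splits (the full-scale protocol uses
#'   25000; desk-scale analyses use 50--200).
#' @param n_trees trees per forest (full scale 1000; desk scale 100).
#' @param test_fraction,p_threshold matching parameters, see
#'   [generate_splits()].
#' @param min_leaf,predictor_selection,surrogate forest parameters.
#' @param seed integer master seed; split stream and per-run forest seeds
#'   are derived from it deterministically.
#' @return An object of class `bias_comparison`: list with `runs` (long
#'   per-run table), `summaries` (one `bias_summary` row per model), and
#'   `params`.
#' @export
run_comparison <- function(ref, target, panels, n_runs = 25000,
                           n_trees = 1000, test_fraction = 0.10,
                           p_threshold = 0.3, min_leaf = 1,
                           predictor_selection = "curvature",
                           surrogate = TRUE, seed = NULL) {
  if (length(panels$clock) == 0) stop("empty clock panel")
  models <- list(clock = panels$clock)
  if (!is.null(panels$robust) && length(panels$robust) > 0) {
    models$robust <- panels$robust
  } else if (!is.null(panels$robust)) {
    warning("robust panel empty; robust model skipped")
  }
  seeds <- derive_seeds(seed, 1 + n_runs * length(models))
  splits <- generate_splits(ref, target, n_runs = n_runs,
                            test_fraction = test_fraction,
                            p_threshold = p_threshold, seed = seeds[1])
  rows <- vector("list", n_runs * length(models))
  k <- 0L
  for (r in seq_len(n_runs)) {
    for (mi in seq_along(models)) {
      k <- k + 1L
      rows[[k]] <- run_once(ref, target, splits[[r]], models[[mi]],
                            n_trees = n_trees, min_leaf = min_leaf,
                            predictor_selection = predictor_selection,
                            surrogate = surrogate, seed = seeds[1 + k],
                            model_tag = names(models)[mi])
    }
  }
  runs <- do.call(rbind, rows)
  target_group <- target$group[1]
  summaries <- do.call(rbind, lapply(names(models), function(tag)
    aggregate_runs(runs[runs$model_tag == tag, , drop = FALSE],
                   target_group = target_group)))
  class(summaries) <- c("bias_summary", "data.frame")
  structure(list(runs = runs, summaries = summaries, splits = splits,
                 params = list(n_runs = n_runs, n_trees = n_trees,
                               test_fraction = test_fraction,
                               p_threshold = p_threshold,
                               min_leaf = min_leaf,
                               predictor_selection = predictor_selection,
                               seed = seed,
                               m = attr(splits, "m"))),
            class = "bias_comparison")
}

#' @export
print.bias_comparison <- function(x, ...) {
  cat(sprintf("bias_comparison: %d runs x %d model(s), m = %d, %d trees\n",
              x$params$n_runs, nrow(x$summaries), x$params$m,
              x$params$n_trees))
  print_summary_block(x$summaries)
  invisible(x)
}

#' @export
summary.bias_comparison <- function(object, ...) object$summaries

print_summary_block <- function(s) {
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  [%s] target group '%s' (%d runs)\n", s$model_tag[i],
                s$target_group[i], s$n_runs[i]))
    cat(sprintf("    test samples:      MAE mean %.2f median %.2f | age gap mean %+.2f median %+.2f\n",
                s$mean_mae_target[i], s$median_mae_target[i],
                s$mean_gap_target[i], s$median_gap_target[i]))
    cat(sprintf("    reference samples: MAE mean %.2f median %.2f | age gap mean %+.2f median %+.2f\n",
                s$mean_mae_ref[i], s$median_mae_ref[i],
                s$mean_gap_ref[i], s$median_gap_ref[i]))
  }
  invisible(s)
}

#' Write per-run and summary tables
#'
#' Writes the long per-run table (`runs.csv`) and a block-structured summary
#' (`summary.csv`): one block per target group, two rows per block (target
#' test arm, reference test arm), with mean and median MAE and age gap per
#' model.
#'
#' @param comparisons a `bias_comparison` or list of them (one per target
#'   group).
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
report_bias <- function(comparisons, dir) {
  if (inherits(comparisons, "bias_comparison"))
    comparisons <- list(comparisons)
  stopifnot(length(comparisons) >= 1)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  runs <- do.call(rbind, lapply(seq_along(comparisons), function(i) {
    r <- comparisons[[i]]$runs
    r$target_group <- comparisons[[i]]$summaries$target_group[1]
    r
  }))
  runs_path <- file.path(dir, "runs.csv")
  write.csv(runs, runs_path, row.names = FALSE)
  blocks <- lapply(comparisons, function(cmp) {
    s <- cmp$summaries
    wide <- function(col, tag) {
      i <- match(tag, s$model_tag)
      if (is.na(i)) NA_real_ else s[[col]][i]
    }
    data.frame(
      target_group = s$target_group[1],
      arm = c("test_samples", "reference_samples"),
      mean_mae_clock = c(wide("mean_mae_target", "clock"),
                         wide("mean_mae_ref", "clock")),
      median_mae_clock = c(wide("median_mae_target", "clock"),
                           wide("median_mae_ref", "clock")),
      mean_mae_robust = c(wide("mean_mae_target", "robust"),
                          wide("mean_mae_ref", "robust")),
      median_mae_robust = c(wide("median_mae_target", "robust"),
                            wide("median_mae_ref", "robust")),
      mean_gap_clock = c(wide("mean_gap_target", "clock"),
                         wide("mean_gap_ref", "clock")),
      median_gap_clock = c(wide("median_gap_target", "clock"),
                           wide("median_gap_ref", "clock")),
      mean_gap_robust = c(wide("mean_gap_target", "robust"),
                          wide("mean_gap_ref", "robust")),
      median_gap_robust = c(wide("median_gap_target", "robust"),
                            wide("median_gap_ref", "robust")),
      stringsAsFactors = FALSE)
  })
  summary_path <- file.path(dir, "summary.csv")
  write.csv(do.call(rbind, blocks), summary_path, row.names = FALSE)
  invisible(c(runs_path, summary_path))
}
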