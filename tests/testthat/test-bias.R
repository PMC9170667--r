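test_that("run_once is symmetric under identical arms and exact for a
           perfect stub model", {
  pair <- default_pair(41, n_target = 104)
  m <- subsample_size(95, 104)
  set.seed(2)
  sp <- draw_matched_split(pair$ref, pair$ref, m, run_id = 1L)
  r <- run_once(pair$ref, pair$ref, sp, clock_names(pair$panel),
                n_trees = 20, seed = 3)
  # same test arm on both sides -> identical metrics
  sp2 <- sp; sp2$target_test_indices <- sp$ref_test_indices
  r2 <- run_once(pair$ref, pair$ref, sp2, clock_names(pair$panel),
                 n_trees = 20, seed = 3)
  expect_equal(r2$mae_ref, r2$mae_target)
  expect_equal(r2$gap_ref, r2$gap_target)

  # stub model returning true ages -> zero error everywhere
  oracle_fit <- function(train, cpgs) function(cohort) cohort$age
  sp3 <- draw_matched_split(pair$ref, pair$target, m, run_id = 2L)
  r3 <- run_once(pair$ref, pair$target, sp3, clock_names(pair$panel),
                 fit_fun = oracle_fit)
  expect_equal(r3$mae_ref, 0)
  expect_equal(r3$mae_target, 0)
  expect_equal(r3$gap_ref, 0)
  expect_equal(r3$gap_target, 0)

  expect_error(run_once(pair$ref, pair$target, sp3, character(0)),
               "empty CpG panel")
})

test_that("|mean age gap| never exceeds MAE (triangle inequality)", {
  pair <- default_pair(43)
  cmp <- run_comparison(pair$ref, pair$target,
                        list(clock = clock_names(pair$panel),
                             robust = robust_names(pair$panel)),
                        n_runs = 10, n_trees = 30, seed = 5)
  expect_true(all(abs(cmp$runs$gap_ref) <= cmp$runs$mae_ref + 1e-12))
  expect_true(all(abs(cmp$runs$gap_target) <= cmp$runs$mae_target + 1e-12))
})

test_that("aggregation matches a two-pass streaming oracle and the even-count
           median convention", {
  mk <- function(mt) data.frame(run_id = seq_along(mt), model_tag = "clock",
                                mae_ref = mt / 2, mae_target = mt,
                                gap_ref = mt / 4, gap_target = mt / 3)
  s <- aggregate_runs(mk(c(1, 2, 3)))
  expect_equal(s$mean_mae_target, 2)
  expect_equal(s$median_mae_target, 2)
  s4 <- aggregate_runs(mk(c(1, 2, 3, 10)))
  expect_equal(s4$mean_mae_target, 4)
  expect_equal(s4$median_mae_target, 2.5)

  # two-pass streaming oracle on a large synthetic run table
  set.seed(6)
  runs <- data.frame(run_id = 1:1000, model_tag = "clock",
                     mae_ref = rexp(1000), mae_target = rexp(1000),
                     gap_ref = rnorm(1000), gap_target = rnorm(1000))
  stream_mean <- function(v) { acc <- 0; for (x in v) acc <- acc + x
                               acc / length(v) }
  stream_median <- function(v) { s <- sort(v); n <- length(s)
    if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2 }
  agg <- aggregate_runs(runs)
  expect_equal(agg$mean_gap_target, stream_mean(runs$gap_target),
               tolerance = 1e-12)
  expect_equal(agg$median_gap_target, stream_median(runs$gap_target),
               tolerance = 1e-12)
  expect_equal(agg$mean_mae_ref, stream_mean(runs$mae_ref),
               tolerance = 1e-12)
  expect_equal(agg$median_mae_ref, stream_median(runs$mae_ref),
               tolerance = 1e-12)

  expect_error(aggregate_runs(runs[0, ]), "no runs")
  runs$model_tag[1] <- "robust"
  expect_error(aggregate_runs(runs), "single model_tag")
})

test_that("single-run summaries collapse to the run's own values", {
  pair <- default_pair(47)
  cmp <- run_comparison(pair$ref, pair$target,
                        list(clock = clock_names(pair$panel)),
                        n_runs = 1, n_trees = 20, seed = 8)
  s <- cmp$summaries
  r <- cmp$runs
  expect_equal(s$mean_mae_target, r$mae_target)
  expect_equal(s$median_mae_target, r$mae_target)
  expect_equal(s$mean_gap_ref, r$gap_ref)
})

test_that("report_bias writes re-aggregable per-run and summary tables", {
  pair <- default_pair(53)
  cmp <- run_comparison(pair$ref, pair$target,
                        list(clock = clock_names(pair$panel),
                             robust = robust_names(pair$panel)),
                        n_runs = 6, n_trees = 20, seed = 9)
  dir <- withr::local_tempdir()
  paths <- report_bias(cmp, dir)
  expect_true(all(file.exists(paths)))

  summ <- read.csv(file.path(dir, "summary.csv"))
  expect_identical(nrow(summ), 2L)  # one block: test + reference rows
  expect_identical(summ$arm, c("test_samples", "reference_samples"))
  expect_identical(sum(vapply(summ, is.numeric, logical(1))), 8L)

  # re-reading the per-run table and re-aggregating reproduces the summary
  runs <- read.csv(file.path(dir, "runs.csv"))
  for (tag in c("clock", "robust")) {
    re <- aggregate_runs(runs[runs$model_tag == tag, ])
    i <- match(tag, cmp$summaries$model_tag)
    expect_equal(re$mean_gap_target, cmp$summaries$mean_gap_target[i],
                 tolerance = 1e-8)
    expect_equal(re$median_mae_ref, cmp$summaries$median_mae_ref[i],
                 tolerance = 1e-8)
  }

  # two target groups -> two blocks in input order
  cmp2 <- cmp
  cmp2$summaries$target_group <- "short_stature"
  paths2 <- report_bias(list(cmp, cmp2), dir)
  summ2 <- read.csv(file.path(dir, "summary.csv"))
  expect_identical(summ2$target_group,
                   rep(c("growth_disorder", "short_stature"), each = 2))
})

test_that("recovered clock-model bias is positive and increases with the
           injected shift", {
  diffs <- vapply(c(1, 2, 3), function(sh) {
    p <- default_panel(shift_years = sh)
    ref <- generate_cohort(p, cohort_spec(95), seed = 71)
    tgt <- generate_cohort(p, cohort_spec(104, group = "gd"),
                           apply_disease_shift = TRUE, seed = 72)
    cmp <- run_comparison(ref, tgt, list(clock = clock_names(p)),
                          n_runs = 20, n_trees = 50, seed = 73)
    cmp$summaries$mean_gap_target - cmp$summaries$mean_gap_ref
  }, numeric(1))
  expect_true(all(diffs > 0))
  expect_true(all(diff(diffs) > 0))
})

test_that("the full pipeline is deterministic in the master seed", {
  pair <- default_pair(59, n_ref = 40, n_target = 44)
  pa <- list(clock = clock_names(pair$panel))
  c1 <- run_comparison(pair$ref, pair$target, pa, n_runs = 3, n_trees = 10,
                       seed = 77)
  c2 <- run_comparison(pair$ref, pair$target, pa, n_runs = 3, n_trees = 10,
                       seed = 77)
  expect_identical(c1$runs, c2$runs)
  expect_identical(c1$summaries, c2$summaries)
})
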