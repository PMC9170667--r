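#' Matched test-subsample size
#'
#' The paired test subsamples each contain 10 percent (rounded upwards) of
#' the smaller of the two cohorts, so at least 90 percent of the reference
#' cohort always remains for training.
#'
#' @param n_ref,n_target cohort sizes (>= 2).
#' @param test_fraction fraction of the smaller cohort (default 0.10).
#' @return Integer subsample size `m = ceiling(test_fraction *
#'   min(n_ref, n_target))`.
#' @export
subsample_size <- function(n_ref, n_target, test_fraction = 0.10) {
  stopifnot(n_ref >= 2, n_target >= 2, test_fraction > 0, test_fraction < 1)
  m <- as.integer(ceiling(test_fraction * min(n_ref, n_target)))
  if (m >= min(n_ref, n_target))
    stop("test subsample as large as the smaller cohort; nothing to train on")
  max(m, 1L)
}

#' Age-matching p-value (Welch two-sample t-test)
#'
#' Two-sided Welch t-test between the two age vectors; used to accept a
#' candidate paired subsample as age-matched. Degenerate zero-variance
#' inputs return 1 when the means agree and 0 otherwise.
#'
#' @param ages_a,ages_b non-empty numeric vectors.
#' @param method `"welch"` (default) or `"wilcoxon"` (Mann-Whitney).
#' @return p-value in `[0, 1]`.
#' @export
age_match_p <- function(ages_a, ages_b, method = c("welch", "wilcoxon")) {
  method <- match.arg(method)
  stopifnot(length(ages_a) >= 1, length(ages_b) >= 1)
  if (method == "wilcoxon")
    return(suppressWarnings(
      stats::wilcox.test(ages_a, ages_b, exact = FALSE)$p.value))
  if (sd(ages_a) == 0 && sd(ages_b) == 0)
    return(if (isTRUE(all.equal(mean(ages_a), mean(ages_b)))) 1 else 0)
  t.test(ages_a, ages_b)$p.value
}

#' Sex-matching p-value (Fisher's exact test)
#'
#' Exact conditional test on the 2x2 table of cohort by sex. A table with a
#' zero margin (all samples the same sex) gives p = 1.
#'
#' @param sexes_a,sexes_b vectors of `"F"`/`"M"` labels.
#' @param method `"fisher"` (default) or `"chisq"`.
#' @return p-value in `(0, 1]`.
#' @export
sex_match_p <- function(sexes_a, sexes_b, method = c("fisher", "chisq")) {
  method <- match.arg(method)
  stopifnot(length(sexes_a) >= 1, length(sexes_b) >= 1)
  tab <- rbind(table(factor(as.character(sexes_a), levels = c("F", "M"))),
               table(factor(as.character(sexes_b), levels = c("F", "M"))))
  if (any(colSums(tab) == 0)) return(1)
  if (method == "chisq")
    return(suppressWarnings(stats::chisq.test(tab)$p.value))
  fisher.test(tab)$p.value
}

split_fingerprint <- function(ref_idx, target_idx) {
  paste(paste(sort(ref_idx), collapse = ","),
        paste(sort(target_idx), collapse = ","), sep = "|")
}

new_matched_split <- function(ref_test, target_test, n_ref, age_p, sex_p,
                              run_id) {
  structure(list(ref_test_indices = sort(ref_test),
                 target_test_indices = sort(target_test),
                 ref_train_indices = setdiff(seq_len(n_ref), ref_test),
                 age_match_p = age_p, sex_match_p = sex_p, run_id = run_id),
            class = "matched_split")
}

#' Draw one age- and sex-matched paired test subsample
#'
#' Rejection sampling: a uniform random `m`-subset is drawn from each
#' cohort and accepted iff both matching p-values exceed `p_threshold` and
#' the ordered pair of index sets has not been accepted before. The
#' complementary reference indices form the training set.
#'
#' @param ref,target [methylation_cohort()]s.
#' @param m subsample size per cohort (from [subsample_size()]).
#' @param p_threshold acceptance threshold on both p-values (default 0.3,
#'   strict inequality).
#' @param used environment used as a fingerprint registry across calls
#'   (created internally if `NULL`).
#' @param max_attempts attempts before declaring matching infeasible.
#' @param run_id identifier stored on the returned split.
#' @param age_method,sex_method test choices passed to [age_match_p()] /
#'   [sex_match_p()].
#' @return A `matched_split`: list with `ref_test_indices`,
#'   `target_test_indices`, `ref_train_indices`, `age_match_p`,
#'   `sex_match_p`, `run_id`.
#' @export
draw_matched_split <- function(ref, target, m, p_threshold = 0.3,
                               used = NULL, max_attempts = 10000,
                               run_id = 1L, age_method = "welch",
                               sex_method = "fisher") {
  n_ref <- length(ref$sample_id)
  n_target <- length(target$sample_id)
  stopifnot(m >= 1, m < n_ref, m <= n_target, p_threshold > 0,
            p_threshold < 1)
  if (is.null(used)) used <- new.env(parent = emptyenv())
  accepted <- 0L
  for (att in seq_len(max_attempts)) {
    ri <- sample.int(n_ref, m)
    ti <- sample.int(n_target, m)
    ap <- age_match_p(ref$age[ri], target$age[ti], method = age_method)
    if (ap <= p_threshold) next
    sp <- sex_match_p(ref$sex[ri], target$sex[ti], method = sex_method)
    if (sp <= p_threshold) next
    fp <- split_fingerprint(ri, ti)
    if (exists(fp, envir = used, inherits = FALSE)) next
    assign(fp, TRUE, envir = used)
    return(new_matched_split(ri, ti, n_ref, ap, sp, run_id))
  }
  stop(sprintf(paste0("matching infeasible: no accepted split in %d ",
                      "attempts (acceptance rate so far 0)"), max_attempts))
}

#' Generate a stream of unique matched paired splits
#'
#' Draws `n_runs` unique accepted splits by rejection sampling, after a
#' 100-attempt pilot probing feasibility. The full stream is a pure
#' function of `(ref, target, parameters, seed)`.
#'
#' @inheritParams draw_matched_split
#' @param n_runs number of splits (default 25000, the full-scale protocol).
#' @param test_fraction test fraction passed to [subsample_size()].
#' @param attempts_per_run attempt budget, pooled over the whole stream
#'   (default 10000 per run).
#' @param seed integer seed.
#' @return List of `n_runs` `matched_split` objects with attributes
#'   `attempts` (total draws) and `acceptance_rate`.
#' @export
generate_splits <- function(ref, target, n_runs = 25000,
                            test_fraction = 0.10, p_threshold = 0.3,
                            attempts_per_run = 10000, seed = NULL,
                            age_method = "welch", sex_method = "fisher") {
  stopifnot(n_runs >= 1)
  n_ref <- length(ref$sample_id)
  n_target <- length(target$sample_id)
  m <- subsample_size(n_ref, n_target, test_fraction)
  with_seed(seed, {
    # feasibility pilot: any acceptable (not necessarily unique) split?
    pilot_ok <- FALSE
    for (i in seq_len(100)) {
      ri <- sample.int(n_ref, m)
      ti <- sample.int(n_target, m)
      if (age_match_p(ref$age[ri], target$age[ti],
                      method = age_method) > p_threshold &&
          sex_match_p(ref$sex[ri], target$sex[ti],
                      method = sex_method) > p_threshold) {
        pilot_ok <- TRUE
        break
      }
    }
    if (!pilot_ok)
      stop("matching infeasible: pilot of 100 attempts found no ",
           "acceptable split (cohorts differ too much in age/sex)")
    used <- new.env(parent = emptyenv())
    budget <- attempts_per_run * n_runs
    splits <- vector("list", n_runs)
    for (r in seq_len(n_runs)) {
      splits[[r]] <- draw_matched_split(
        ref, target, m, p_threshold = p_threshold, used = used,
        max_attempts = budget, run_id = r,
        age_method = age_method, sex_method = sex_method)
    }
    attr(splits, "m") <- m
    attr(splits, "n_accepted") <- length(ls(used))
    splits
  })
}
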