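#' Spearman rank correlation with midrank tie handling
#'
#' Pairs with a missing value in either vector are removed first. Ties get
#' average (mid) ranks. A constant vector after pair removal has no defined
#' rank correlation and raises an error rather than returning 0.
#'
#' @param x,y numeric vectors of equal length (>= 3 complete pairs).
#' @return Correlation in `[-1, 1]`.
#' @export
spearman_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0)
    stop("undefined rank correlation: constant input")
  cor(x, y, method = "spearman")
}

#' Screen CpGs for age association (clock panel selection)
#'
#' Computes the Spearman correlation between percent methylation and
#' chronological age for every CpG and selects those with signed
#' `R > threshold` (strict). A negatively age-correlated CpG is therefore
#' not selected under the default rule; set `absolute = TRUE` to select on
#' `|R|` instead. CpGs with undefined correlation (constant methylation) are
#' retained with `selected = FALSE` and a warning.
#'
#' @param cohort a [methylation_cohort()] with >= 3 samples.
#' @param threshold selection threshold on the correlation (default 0.75).
#' @param absolute select on `|R|` rather than signed `R`.
#' @return A `data.frame` of class `selection_result` with columns `cpg`,
#'   `spearman_r`, `selected`, and attributes `threshold`, `absolute`.
#' @export
select_clock_cpgs <- function(cohort, threshold = 0.75, absolute = FALSE) {
  stopifnot(inherits(cohort, "methylation_cohort"),
            length(cohort$sample_id) >= 3)
  cpgs <- cpg_names(cohort)
  r <- vapply(cpgs, function(cg) {
    tryCatch(spearman_r(cohort$age, cohort$betas[, cg]),
             error = function(e) {
               warning(sprintf("CpG '%s': %s", cg, conditionMessage(e)),
                       call. = FALSE)
               NA_real_
             })
  }, numeric(1))
  crit <- if (absolute) abs(r) else r
  out <- data.frame(cpg = cpgs, spearman_r = as.numeric(r),
                    selected = !is.na(crit) & crit > threshold,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "threshold") <- threshold
  attr(out, "absolute") <- absolute
  class(out) <- c("selection_result", "data.frame")
  out
}

#' ANCOVA test for a group effect on methylation, adjusting for age
#'
#' Fits the linear model `beta = b0 + b1 * age + b2 * group` (optionally
#' `+ b3 * sex`) and returns the F test of `b2 = 0`, i.e. the nested-model
#' comparison against the age-only model, with 1 numerator degree of
#' freedom. Samples with missing `beta` are dropped first.
#'
#' @param beta percent methylation at one CpG across both cohorts.
#' @param age chronological ages.
#' @param group two-level factor (or coercible) separating the cohorts.
#' @param alpha significance level (default 0.05).
#' @param sex optional F/M factor added as a covariate when
#'   `include_sex = TRUE`.
#' @param include_sex add sex to the covariate set (default `FALSE`).
#' @return A list with `f_statistic`, `p_value`, `significant`, `alpha`,
#'   `n_used`, `df` (numerator, denominator).
#' @export
ancova_group_effect <- function(beta, age, group, alpha = 0.05,
                                sex = NULL, include_sex = FALSE) {
  keep <- !is.na(beta) & !is.na(age)
  beta <- beta[keep]; age <- age[keep]
  group <- factor(group)[keep]
  if (include_sex) sex <- factor(sex)[keep]
  if (nlevels(droplevels(group)) != 2)
    stop("need exactly two non-empty groups")
  n <- length(beta)
  if (n < 4) stop("need at least 4 usable samples")
  if (sd(age) == 0) stop("singular design: constant age")
  f0 <- if (include_sex) lm(beta ~ age + sex) else lm(beta ~ age)
  f1 <- if (include_sex) lm(beta ~ age + sex + group) else
    lm(beta ~ age + group)
  rss0 <- sum(residuals(f0)^2)
  rss1 <- sum(residuals(f1)^2)
  # exact fits leave O(eps^2)-scale residual sums; treat those as zero
  eps <- 1e-22 * sum(beta^2) * n
  if (rss0 < eps) rss0 <- 0
  if (rss1 < eps) rss1 <- 0
  df2 <- f1$df.residual
  if (df2 < 1) stop("singular design: no residual degrees of freedom")
  fstat <- if (rss1 <= 0) {
    if (rss0 - rss1 <= 0) 0 else Inf
  } else (rss0 - rss1) / (rss1 / df2)
  p <- if (fstat == 0) 1 else stats::pf(fstat, 1, df2, lower.tail = FALSE)
  list(f_statistic = fstat, p_value = p, significant = p < alpha,
       alpha = alpha, n_used = n, df = c(1L, df2))
}

#' ANCOVA robustness screen across all CpGs of two cohorts
#'
#' Runs [ancova_group_effect()] per CpG on the pooled reference + target
#' samples, testing for a methylation difference between the cohorts while
#' adjusting for age.
#'
#' @param ref,target [methylation_cohort()]s sharing the same CpG columns.
#' @param alpha per-CpG significance level (no multiple-testing correction,
#'   matching per-CpG reporting at alpha = 0.05).
#' @param include_sex adjust for sex as well (default `FALSE`).
#' @return A `data.frame` of class `ancova_result` with columns `cpg`,
#'   `f_statistic`, `p_value`, `significant`, `n_used`.
#' @export
ancova_screen <- function(ref, target, alpha = 0.05, include_sex = FALSE) {
  stopifnot(inherits(ref, "methylation_cohort"),
            inherits(target, "methylation_cohort"))
  if (!identical(cpg_names(ref), cpg_names(target)))
    stop("reference and target cohorts must share the same CpG columns")
  age <- c(ref$age, target$age)
  grp <- factor(rep(c("ref", "target"),
                    c(length(ref$sample_id), length(target$sample_id))))
  sex <- factor(c(as.character(ref$sex), as.character(target$sex)),
                levels = c("F", "M"))
  rows <- lapply(cpg_names(ref), function(cg) {
    b <- c(ref$betas[, cg], target$betas[, cg])
    a <- ancova_group_effect(b, age, grp, alpha = alpha, sex = sex,
                             include_sex = include_sex)
    data.frame(cpg = cg, f_statistic = a$f_statistic, p_value = a$p_value,
               significant = a$significant, n_used = a$n_used,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  class(out) <- c("ancova_result", "data.frame")
  out
}

#' Partition the clock panel into robust and sensitive CpGs
#'
#' The clock panel is the set of selected age-associated CpGs; robust CpGs
#' are clock CpGs with no significant cohort difference in the ANCOVA
#' screen; sensitive CpGs are the significant remainder. Robust and
#' sensitive always partition the clock panel.
#'
#' @param selection a `selection_result` from [select_clock_cpgs()].
#' @param ancova an `ancova_result` from [ancova_screen()] covering the same
#'   CpGs.
#' @return A list of class `panel_assignment` with character vectors
#'   `clock`, `robust`, `sensitive`.
#' @export
assign_panels <- function(selection, ancova) {
  stopifnot(inherits(selection, "selection_result"),
            inherits(ancova, "ancova_result"))
  if (!setequal(selection$cpg, ancova$cpg))
    stop("selection and ancova must cover the same CpG set")
  sig <- ancova$significant[match(selection$cpg, ancova$cpg)]
  clock <- selection$cpg[selection$selected]
  robust <- selection$cpg[selection$selected & !sig]
  sensitive <- selection$cpg[selection$selected & sig]
  stopifnot(setequal(union(robust, sensitive), clock),
            length(intersect(robust, sensitive)) == 0)
  structure(list(clock = clock, robust = robust, sensitive = sensitive),
            class = "panel_assignment")
}

#' @export
print.panel_assignment <- function(x, ...) {
  cat(sprintf("clock panel (%d): %s\n", length(x$clock),
              paste(x$clock, collapse = ", ")))
  cat(sprintf("robust (%d): %s\n", length(x$robust),
              paste(x$robust, collapse = ", ")))
  cat(sprintf("sensitive (%d): %s\n", length(x$sensitive),
              paste(x$sensitive, collapse = ", ")))
  invisible(x)
}
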