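#' Per-CpG simulation panel
#'
#' A `cpg_panel` is a data frame with one row per simulated CpG carrying its
#' ground-truth age trajectory and disease behaviour: percent methylation is
#' generated as `clip(intercept + slope * age + shift + noise, 0, 100)` where
#' the additive `disease_shift` applies only in a disease cohort and only at
#' CpGs flagged `sensitive`.
#'
#' @param name CpG names, `"GENE_CpGk"` convention, unique.
#' @param intercept percent methylation at age 0.
#' @param slope trajectory slope in percent per year (signed).
#' @param noise_sd measurement/biological noise SD in percent, `>= 0`.
#' @param sensitive logical; does the CpG shift in the disease cohort?
#' @param disease_shift additive percent shift in the disease cohort; must be
#'   0 wherever `sensitive` is `FALSE`.
#' @return A `data.frame` of class `cpg_panel`.
#' @export
cpg_panel <- function(name, intercept, slope, noise_sd = 1.0,
                      sensitive = FALSE, disease_shift = 0) {
  df <- data.frame(name = as.character(name), intercept = as.numeric(intercept),
                   slope = as.numeric(slope), noise_sd = as.numeric(noise_sd),
                   sensitive = as.logical(sensitive),
                   disease_shift = as.numeric(disease_shift),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$name)) stop("CpG names must be unique")
  if (any(df$noise_sd < 0)) stop("noise_sd must be >= 0")
  if (any(!df$sensitive & df$disease_shift != 0))
    stop("disease_shift must be 0 for non-sensitive CpGs")
  class(df) <- c("cpg_panel", "data.frame")
  df
}

#' Default 22-CpG simulation panel
#'
#' Emulates a pyrosequencing panel of 22 CpGs in the genes PDE4C, ELOVL2,
#' RPA2, EDARADD and DDO measured in buccal samples of children and
#' adolescents. Eleven "clock" CpGs (the nine ELOVL2 sites plus one PDE4C and
#' one RPA2 site) have steep enough trajectories that their population
#' Spearman correlation with age over 0.42--18 y exceeds 0.8; the other
#' eleven are weak (|R| <= 0.5), including negative-trend DDO/EDARADD sites.
#' Six clock CpGs are flagged `sensitive` and shift additively in a disease
#' cohort by `slope * shift_years` (the methylation displacement a healthy
#' child accrues in `shift_years` years); the five ELOVL2 sites CpG1, CpG2,
#' CpG5, CpG8 and CpG9 are robust (no shift).
#'
#' @param noise_sd per-CpG noise SD in percent (default 1.0, which keeps
#'   simulated replicate differences within the 3 percent QC bound with
#'   probability about 0.966; see [replicate_noise_check()]).
#' @param shift_years disease shift expressed in years of trajectory
#'   (default 2.0).
#' @return A [cpg_panel()] with 22 rows.
#' @examples
#' p <- default_panel()
#' sum(p$sensitive)                      # 6
#' p$name[p$clock & !p$sensitive]        # the 5 robust ELOVL2 sites
#' @export
default_panel <- function(noise_sd = 1.0, shift_years = 2.0) {
  clock <- data.frame(
    name = c(paste0("ELOVL2_CpG", 1:9), "PDE4C_CpG1", "RPA2_CpG3"),
    intercept = c(8, 10, 12, 9, 11, 14, 7, 13, 10, 20, 25),
    slope = c(0.45, 0.50, 0.55, 0.42, 0.48, 0.55, 0.40, 0.46, 0.44,
              0.38, 0.36),
    sensitive = c(FALSE, FALSE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, FALSE,
                  TRUE, TRUE),
    stringsAsFactors = FALSE)
  weak <- data.frame(
    name = c("PDE4C_CpG2", "PDE4C_CpG3", "RPA2_CpG1", "RPA2_CpG2",
             paste0("EDARADD_CpG", 1:4), paste0("DDO_CpG", 1:3)),
    intercept = c(30, 35, 28, 22, 60, 55, 48, 52, 65, 60, 58),
    slope = c(0.08, 0.06, 0.09, 0.07, -0.05, -0.04, 0.03, 0.05,
              -0.10, -0.06, 0.02),
    sensitive = FALSE,
    stringsAsFactors = FALSE)
  df <- rbind(clock, weak)
  shift <- ifelse(df$sensitive, df$slope * shift_years, 0)
  p <- cpg_panel(df$name, df$intercept, df$slope, noise_sd = noise_sd,
                 sensitive = df$sensitive, disease_shift = shift)
  p$clock <- c(rep(TRUE, nrow(clock)), rep(FALSE, nrow(weak)))
  p
}

#' Cohort sampling specification
#'
#' @param n_samples number of samples to draw.
#' @param age_range ages are drawn uniformly over `[age_range[1],
#'   age_range[2]]` (decimal years, within (0, 25)); alternatively supply
#'   `ages` to use a fixed empirical set.
#' @param sex_ratio probability that a sample is female.
#' @param group cohort label.
#' @param subgroup optional subgroup label.
#' @param ages optional fixed age vector (overrides `age_range`); recycled or
#'   truncated to `n_samples`.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples, age_range = c(0.42, 18), sex_ratio = 0.5,
                        group = "healthy", subgroup = NA_character_,
                        ages = NULL) {
  stopifnot(n_samples >= 0, sex_ratio >= 0, sex_ratio <= 1,
            length(age_range) == 2, age_range[1] > 0, age_range[2] < 25,
            age_range[1] <= age_range[2])
  structure(list(n_samples = as.integer(n_samples), age_range = age_range,
                 sex_ratio = sex_ratio, group = group, subgroup = subgroup,
                 ages = ages),
            class = "cohort_spec")
}

#' Generate a synthetic methylation cohort
#'
#' Draws ages and sexes per `spec`, then generates percent methylation as
#' `clip(intercept + slope * age + disease_shift * [apply_disease_shift and
#' sensitive] + noise, 0, 100)` with independent Gaussian noise per sample
#' and CpG. Sex has no effect on methylation. Fully reproducible from `seed`.
#'
#' @param panel a [cpg_panel()].
#' @param spec a [cohort_spec()].
#' @param apply_disease_shift if `TRUE`, sensitive CpGs are shifted by their
#'   `disease_shift` (a disease cohort); if `FALSE` the cohort follows the
#'   healthy trajectories.
#' @param seed integer seed; the cohort is a pure function of
#'   `(panel, spec, apply_disease_shift, seed)`.
#' @param id_prefix prefix for generated sample ids.
#' @return A [methylation_cohort()].
#' @export
generate_cohort <- function(panel, spec, apply_disease_shift = FALSE,
                            seed = NULL, id_prefix = NULL) {
  stopifnot(inherits(panel, "cpg_panel"), inherits(spec, "cohort_spec"))
  n <- spec$n_samples
  k <- nrow(panel)
  if (is.null(id_prefix))
    id_prefix <- if (apply_disease_shift) "T" else "R"
  with_seed(seed, {
    ages <- if (!is.null(spec$ages)) rep_len(as.numeric(spec$ages), n)
            else runif(n, spec$age_range[1], spec$age_range[2])
    sexes <- ifelse(runif(n) < spec$sex_ratio, "F", "M")
    mu <- outer(ages, panel$slope) +
      matrix(panel$intercept, n, k, byrow = TRUE)
    if (apply_disease_shift)
      mu <- mu + matrix(ifelse(panel$sensitive, panel$disease_shift, 0),
                        n, k, byrow = TRUE)
    eps <- matrix(rnorm(n * k), n, k) *
      matrix(panel$noise_sd, n, k, byrow = TRUE)
    betas <- pmin(pmax(mu + eps, 0), 100)
    colnames(betas) <- panel$name
    methylation_cohort(sprintf("%s%04d", id_prefix, seq_len(n)), ages, sexes,
                       spec$group, betas, subgroup = spec$subgroup)
  })
}

#' Fraction of simulated replicate pairs within the 3-percent QC bound
#'
#' Pyrosequencing QC re-measures samples and requires the two percent
#' methylation readings to differ by at most 3 points. This simulates
#' `n_pairs` paired re-measurements per CpG (two independent noise draws on
#' the same true value) and returns the fraction of pairs with
#' `|delta| <= 3`. For a single CpG with noise SD `s` the closed-form value
#' is `P(|N(0, 2 s^2)| <= 3)`.
#'
#' @param panel a [cpg_panel()].
#' @param n_pairs replicate pairs per CpG (`>= 1`).
#' @param seed integer seed.
#' @return Fraction in `[0, 1]` pooled over all CpGs.
#' @export
replicate_noise_check <- function(panel, n_pairs, seed = NULL) {
  stopifnot(inherits(panel, "cpg_panel"), n_pairs >= 1)
  with_seed(seed, {
    k <- nrow(panel)
    sds <- matrix(panel$noise_sd, n_pairs, k, byrow = TRUE)
    d <- matrix(rnorm(n_pairs * k), n_pairs, k) * sds -
         matrix(rnorm(n_pairs * k), n_pairs, k) * sds
    mean(abs(d) <= 3)
  })
}
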