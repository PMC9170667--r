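# shared fixtures, all generated in code

tiny_cohort <- function(n = 6, seed = 1, cpgs = c("ELOVL2_CpG1", "DDO_CpG1")) {
  set.seed(seed)
  b <- matrix(runif(n * length(cpgs), 5, 95), n, length(cpgs),
              dimnames = list(NULL, cpgs))
  methylation_cohort(sprintf("s%02d", seq_len(n)),
                     seq(1, 17, length.out = n),
                     rep(c("F", "M"), length.out = n),
                     "healthy", b)
}

default_pair <- function(seed, n_ref = 95, n_target = 104, shift = TRUE,
                         panel = default_panel()) {
  s <- clockbias:::derive_seeds(seed, 2)
  list(panel = panel,
       ref = generate_cohort(panel, cohort_spec(n_ref), seed = s[1]),
       target = generate_cohort(panel,
                                cohort_spec(n_target,
                                            group = "growth_disorder"),
                                apply_disease_shift = shift, seed = s[2]))
}

clock_names <- function(panel) panel$name[panel$clock]
robust_names <- function(panel) panel$name[panel$clock & !panel$sensitive]
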