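# Shared fixtures and independent oracles, built in code at test time.

# Independent just-identified IV solve: (W'X) b = W'y with W the
# instrument-side design and X the regressor-side design. Written against
# the moment conditions directly, not via two-stage fitting.
iv_oracle <- function(y, x, z, covariates = NULL) {
  C <- if (is.null(covariates)) NULL else as.matrix(covariates)
  X <- cbind(1, x, C)
  W <- cbind(1, z, C)
  drop(solve(crossprod(W, X), crossprod(W, y)))
}

# 100-probe fixture: 10 sex-chromosome + 5 cross-reactive (disjoint) +
# 3 probes carrying a missing beta-value among the retained ones.
small_panel <- function(n_subjects = 12, seed = 5) {
  pp <- gen_probe_panel(100, frac_sex = 0.10, frac_cross_reactive = 0.05,
                        frac_missing = 0, seed = seed)
  ch <- gen_cohort(cohort_spec(n = n_subjects, seed = seed))
  prof <- effect_profile(100, sigma_y = 0.03)
  panel <- gen_methylation(ch$cohort, ch$confounder, prof,
                           pp$annotations, seed = seed)
  # mark exactly 3 retained probes with one missing value each
  retained <- with(pp$annotations,
                   probe_id[!(chromosome %in% c("X", "Y")) & !cross_reactive])
  miss <- retained[1:3]
  panel$betas[match(miss, pp$annotations$probe_id), 1] <- NA_real_
  list(panel = panel, cohort = ch$cohort, missing = miss)
}

# Strong-instrument cohort used by calibration and power checks.
strong_cohort <- function(n = 50, seed = 1) {
  gen_cohort(cohort_spec(n = n, alpha1 = 0.4, sigma_x = 0.25, seed = seed))
}
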