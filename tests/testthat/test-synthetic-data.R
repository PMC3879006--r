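test_that("haplotype-level genotype generation enforces the trans constraint", {
  g <- gen_genotypes(1000, 0, 0, seed = 1)
  expect_true(all(g$g677 == 0) && all(g$g1298 == 0))

  g <- gen_genotypes(10000, 0.33, 0.23, seed = 1)
  expect_true(all(g$g677 + g$g1298 <= 2))
  # observed allele frequency within 3 binomial SDs of the target
  for (case in list(c(0.33, mean(g$g677) / 2), c(0.23, mean(g$g1298) / 2))) {
    sd3 <- 3 * sqrt(case[1] * (1 - case[1]) / (2 * 10000))
    expect_lt(abs(case[2] - case[1]), sd3)
  }

  expect_error(gen_genotypes(0, 0.3, 0.2), "positive")
  expect_error(gen_genotypes(10, 1.2, 0.2), "frequencies")
  expect_warning(gen_genotypes(10, 0.7, 0.6, seed = 1), "renormalizing")
})

test_that("cohort generation follows the first-stage linear model", {
  # degenerate model: folate pinned at the intercept
  sp <- cohort_spec(n = 30, alpha1 = 0, alpha2 = 0, alpha_c = 0,
                    alpha0 = 6.6, sigma_x = 1e-8, seed = 2)
  ch <- gen_cohort(sp)
  expect_equal(ch$cohort$log_rbc_folate, rep(6.6, 30), tolerance = 1e-6)

  # OLS consistency: the generating slope is recovered at large n
  sp <- cohort_spec(n = 50000, alpha0 = 6.0, alpha1 = 0.1, alpha2 = 0,
                    seed = 3)
  ch <- gen_cohort(sp)
  fit <- ols_fit(ch$cohort$log_rbc_folate,
                 cbind(1, ch$cohort$variant_count))
  expect_lt(abs(fit$coefficients[2] - 0.1), 3 * fit$se[2])

  # default parameters put folate in the observed 6.13-7.54 log(ng/mL) range
  ch <- gen_cohort(cohort_spec(n = 2000, seed = 4))
  fol <- ch$cohort$log_rbc_folate
  expect_gt(mean(fol >= 6.13 & fol <= 7.54), 0.9)
  expect_lt(abs(median(fol) - 6.66), 0.1)
  expect_true(all(is.finite(fol)))
})

test_that("generation is seed-deterministic and seed-sensitive", {
  a <- gen_cohort(cohort_spec(n = 40, seed = 7))
  b <- gen_cohort(cohort_spec(n = 40, seed = 7))
  d <- gen_cohort(cohort_spec(n = 40, seed = 8))
  expect_identical(a, b)
  expect_false(identical(a$cohort$log_rbc_folate, d$cohort$log_rbc_folate))
})

test_that("methylation generation follows the outcome model on the transformed scale", {
  ch <- gen_cohort(cohort_spec(n = 20, seed = 1))
  ann <- gen_probe_panel(1, seed = 1)$annotations

  # all coefficients zero: every beta collapses to sin^2(beta0)
  prof <- effect_profile(1, beta0 = pi / 8, beta1 = 0, sigma_y = 1e-9)
  pan <- gen_methylation(ch$cohort, ch$confounder, prof, ann, seed = 1)
  expect_equal(unname(pan$betas[1, ]), rep(sin(pi / 8)^2, 20),
               tolerance = 1e-6)

  # regression oracle: beta1 recovered from a single large-n probe
  ch <- gen_cohort(cohort_spec(n = 50000, seed = 2))
  prof <- effect_profile(1, beta0 = -0.6, beta1 = 0.2, beta2 = 0.01,
                         beta_c = 0, sigma_y = 0.05)
  pan <- gen_methylation(ch$cohort, ch$confounder, prof, ann, seed = 2)
  y <- transform_beta(pan$betas[1, ])
  fit <- ols_fit(y, cbind(1, ch$cohort$log_rbc_folate,
                          ch$cohort$conception_planned))
  expect_lt(abs(fit$coefficients[2] - 0.2), 3 * fit$se[2])

  # shared confounder induces positive cross-residual covariance
  ch <- gen_cohort(cohort_spec(n = 5000, alpha_c = 0.2, seed = 3))
  prof <- effect_profile(1, beta0 = -0.6, beta1 = 0.1, beta_c = 0.2,
                         sigma_y = 0.05)
  pan <- gen_methylation(ch$cohort, ch$confounder, prof, ann, seed = 3)
  y <- transform_beta(pan$betas[1, ])
  D <- cbind(1, ch$cohort$variant_count, ch$cohort$conception_planned)
  rx <- ols_fit(ch$cohort$log_rbc_folate, D)$residuals
  ry <- ols_fit(y, D)$residuals
  expect_gt(cov(rx, ry), 0)

  # dimension mismatches are hard errors
  expect_error(gen_methylation(ch$cohort, ch$confounder[-1], prof, ann),
               "confounders")
})

test_that("generated beta-values live in [0,1] and transformed values in [0, pi/2]", {
  ch <- gen_cohort(cohort_spec(n = 30, seed = 5))
  ann <- gen_probe_panel(50, seed = 5)$annotations
  prof <- effect_profile(50, beta1 = rep(c(0, 0.5, -0.5), length.out = 50),
                         sigma_y = 0.6)
  pan <- gen_methylation(ch$cohort, ch$confounder, prof, ann, seed = 5)
  expect_true(all(pan$betas >= 0 & pan$betas <= 1))
  y <- transform_beta(pan$betas)
  expect_true(all(y >= 0 & y <= pi / 2 + 1e-12))
})

test_that("with no confounder loading, u is asymptotically uncorrelated with folate and y", {
  n <- 50000
  ch <- gen_cohort(cohort_spec(n = n, alpha_c = 0, seed = 6))
  expect_lt(abs(cor(ch$confounder, ch$cohort$log_rbc_folate)), 3 / sqrt(n))
  ann <- gen_probe_panel(1, seed = 6)$annotations
  prof <- effect_profile(1, beta0 = -0.6, beta1 = 0.2, beta_c = 0,
                         sigma_y = 0.05)
  pan <- gen_methylation(ch$cohort, ch$confounder, prof, ann, seed = 6)
  expect_lt(abs(cor(ch$confounder, pan$betas[1, ])), 3 / sqrt(n))
})

test_that("probe panel generation flags deterministic counts", {
  pp <- gen_probe_panel(100, 0.1, 0.05, 0, seed = 1)
  expect_equal(sum(pp$annotations$chromosome %in% c("X", "Y")), 10)
  expect_equal(sum(pp$annotations$cross_reactive), 5)
  expect_equal(length(unique(pp$annotations$probe_id)), 100)

  empty <- gen_probe_panel(0)
  expect_equal(nrow(empty$annotations), 0)
  expect_error(gen_probe_panel(10, frac_sex = 1.5), "fractions")
})

test_that("intensity pairs are exactly consistent with their beta-values", {
  ch <- gen_cohort(cohort_spec(n = 10, seed = 9))
  ann <- gen_probe_panel(20, seed = 9)$annotations
  prof <- effect_profile(20, sigma_y = 0.3)
  pan <- gen_methylation(ch$cohort, ch$confounder, prof, ann, seed = 9,
                         intensities = TRUE)
  expect_true(all(pan$M >= 0) && all(pan$U >= 0))
  expect_equal(beta_from_intensities(pan$M, pan$U), pan$betas,
               tolerance = 1e-10)
})
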