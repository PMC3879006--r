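make_spec <- function(n = 50, beta1 = 0.2, level = 0, n_reps = 10,
                      seed = 1, ...) {
  ch <- strong_cohort(n = n, seed = seed)$cohort
  s1 <- ols_fit(ch$log_rbc_folate,
                cbind(1, ch$variant_count, ch$conception_planned))
  simulation_spec(ch$variant_count, ch$conception_planned, ch$log_rbc_folate,
                  alpha = s1$coefficients, beta = c(0, beta1, 0),
                  conf_level = level, n_reps = n_reps, seed = seed, ...)
}

test_that("simulate_dataset follows the two linear equations", {
  sp <- make_spec()
  # zero-noise hook: x and y exactly linear in the anchors
  d <- simulate_dataset(sp, 1, zero_noise = TRUE)
  a <- sp$alpha
  b <- sp$beta
  expect_equal(d$x, a[1] + a[2] * sp$genotype + a[3] * sp$conception,
               tolerance = 1e-12)
  expect_equal(d$y, b[1] + b[2] * sp$log_folate + b[3] * sp$conception,
               tolerance = 1e-12)

  # determinism: fixed seed and rep index give a bit-identical replicate
  expect_identical(simulate_dataset(sp, 3), simulate_dataset(sp, 3))
  expect_false(identical(simulate_dataset(sp, 3)$x,
                         simulate_dataset(sp, 4)$x))
})

test_that("the confounder correlates with the simulated exposure when loaded", {
  sp <- make_spec(level = 0.2, n_reps = 200)
  xs <- us <- numeric(0)
  for (r in 1:200) {
    d <- simulate_dataset(sp, r)
    xs <- c(xs, d$x)
    us <- c(us, d$u)
  }
  expect_gt(cor(us, xs), 0.1)
})

test_that("outcome equation uses observed folate by default, simulated x on request", {
  sp <- make_spec()
  sp_sim <- make_spec(y_from_simulated_x = TRUE)
  d1 <- simulate_dataset(sp, 5, zero_noise = TRUE)
  d2 <- simulate_dataset(sp_sim, 5, zero_noise = TRUE)
  b <- sp$beta
  expect_equal(d1$y, b[1] + b[2] * sp$log_folate, tolerance = 1e-12)
  expect_equal(d2$y, b[1] + b[2] * d2$x, tolerance = 1e-12)
})

test_that("run_confounding_sim summarizes both estimators", {
  s <- run_confounding_sim(make_spec(n_reps = 1, seed = 2))
  # a single replicate: median and quartiles all equal that estimate
  expect_equal(s$q25, s$median)
  expect_equal(s$q75, s$median)
  expect_equal(s$estimator, c("MR", "OLS"))

  s <- run_confounding_sim(make_spec(n_reps = 400, seed = 3))
  expect_true(all(s$q25 <= s$median & s$median <= s$q75))
  expect_equal(s$median_bias, s$median - s$truth)
})

test_that("with no confounding both estimators centre on the truth, MR less precisely", {
  # conventional mode: the outcome responds to the simulated exposure, so
  # OLS is unbiased at confounding level zero
  sp <- make_spec(beta1 = 0.2, level = 0, n_reps = 3000, seed = 4,
                  y_from_simulated_x = TRUE)
  s <- run_confounding_sim(sp)
  mr <- s[s$estimator == "MR", ]
  ols <- s[s$estimator == "OLS", ]
  # medians agree within Monte-Carlo error of the wider estimator
  mc <- 2 * 1.253 * (mr$q75 - mr$q25) / 1.349 / sqrt(3000)
  expect_lt(abs(mr$median - ols$median), 3 * mc + 0.02)
  expect_gt(mr$q75 - mr$q25, ols$q75 - ols$q25)
})

test_that("confounding_sweep produces the full grid with monotone OLS bias", {
  ch <- strong_cohort(n = 50, seed = 6)$cohort
  s1 <- ols_fit(ch$log_rbc_folate,
                cbind(1, ch$variant_count, ch$conception_planned))
  truth <- data.frame(locus = c("L1", "L2"),
                      alpha0 = s1$coefficients[1], alpha1 = s1$coefficients[2],
                      alpha2 = s1$coefficients[3],
                      beta0 = 0, beta1 = c(0.3, 0.2), beta2 = 0)
  tab <- confounding_sweep(ch, truth, levels = c(0.1, 0.2), n_reps = 1500,
                           seed = 6, y_from_simulated_x = TRUE)
  expect_equal(nrow(tab), 2 * 2 * 2)  # loci x levels x estimators
  expect_equal(sort(unique(tab$level)), c(0.1, 0.2))
  # OLS |median bias| does not decrease with the confounding level
  for (lc in unique(tab$locus)) {
    o <- tab[tab$locus == lc & tab$estimator == "OLS", ]
    o <- o[order(o$level), ]
    expect_gte(abs(o$median_bias[2]) + 0.02, abs(o$median_bias[1]))
  }
  expect_equal(nrow(confounding_sweep(ch, truth[0, ], n_reps = 10)), 0)
})

test_that("anchor_cohort returns a cohort with a significant first stage", {
  a <- anchor_cohort(seed = 5)
  expect_lt(a$qc$first_stage$p_value, 0.05)
  expect_equal(nrow(a$cohort), 50)
  expect_identical(anchor_cohort(seed = 5)$cohort, a$cohort)
})

test_that("spec validation rejects malformed inputs", {
  ch <- strong_cohort(n = 20, seed = 7)$cohort
  expect_error(simulation_spec(ch$variant_count, ch$conception_planned[-1],
                               ch$log_rbc_folate, alpha = c(6, 0.1, 0),
                               beta = c(0, 0.2, 0)), "equal length")
  expect_error(simulation_spec(ch$variant_count, ch$conception_planned,
                               ch$log_rbc_folate, alpha = c(6, 0.1),
                               beta = c(0, 0.2, 0)), "3 elements")
  expect_error(make_spec(n_reps = 0), "n_reps")
})
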