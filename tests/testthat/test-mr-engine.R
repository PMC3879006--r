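test_that("ols_fit matches a brute-force normal-equations oracle", {
  set.seed(31)
  for (i in 1:10) {
    n <- 20
    X <- cbind(1, rnorm(n), rnorm(n))
    y <- rnorm(n)
    fit <- ols_fit(y, X)
    b_oracle <- solve(t(X) %*% X) %*% t(X) %*% y
    expect_equal(unname(fit$coefficients), drop(b_oracle), tolerance = 1e-10)
    s2 <- sum((y - X %*% b_oracle)^2) / (n - 3)
    expect_equal(unname(fit$se), sqrt(diag(s2 * solve(t(X) %*% X))),
                 tolerance = 1e-10)
  }
  # exact fit and orthogonality corner cases
  x <- 1:10
  expect_equal(unname(ols_fit(2 * x, cbind(1, x))$coefficients), c(0, 2),
               tolerance = 1e-12)
  xo <- rep(c(-1, 1), 5)
  yo <- rep(c(1, 1), 5)
  expect_equal(unname(ols_fit(yo, cbind(1, xo))$coefficients[2]), 0,
               tolerance = 1e-12)
  expect_error(ols_fit(rnorm(3), cbind(1, 1:3, 2 * (1:3))), "rank deficient")
})

test_that("2SLS with a single binary instrument equals the Wald ratio", {
  fit <- tsls_fit(c(2, 3, 7, 10), c(1, 2, 3, 6), c(0, 0, 1, 1))
  expect_equal(unname(coef(fit)["exposure"]), 2, tolerance = 1e-10)

  set.seed(32)
  for (i in 1:50) {
    n <- sample(10:30, 1)
    z <- rbinom(n, 1, 0.5)
    if (var(z) == 0) next
    x <- rnorm(n, 1 + z)
    y <- rnorm(n, 2 + 0.5 * x)
    wald <- (mean(y[z == 1]) - mean(y[z == 0])) /
      (mean(x[z == 1]) - mean(x[z == 0]))
    expect_equal(unname(coef(tsls_fit(y, x, z))["exposure"]), wald,
                 tolerance = 1e-10)
  }
})

test_that("2SLS equals the closed-form IV solve on random just-identified instances", {
  set.seed(33)
  for (i in 1:100) {
    n <- sample(10:30, 1)
    z <- sample(0:2, n, replace = TRUE)
    if (var(z) == 0) next
    C <- if (i %% 2) cbind(rbinom(n, 1, 0.5)) else NULL
    if (!is.null(C) && var(C[, 1]) == 0) C <- NULL
    x <- rnorm(n, 0.3 * z)
    y <- rnorm(n, 0.5 * x)
    fit <- tsls_fit(y, x, z, covariates = C)
    oracle <- iv_oracle(y, x, z, covariates = C)
    expect_equal(unname(coef(fit)), unname(oracle), tolerance = 1e-10)
  }
})

test_that("when the exposure equals the instrument, 2SLS collapses to OLS", {
  set.seed(34)
  n <- 60
  z <- sample(0:2, n, replace = TRUE)
  cc <- rbinom(n, 1, 0.5)
  y <- rnorm(n, 1 + 0.4 * z + 0.2 * cc)
  tf <- tsls_fit(y, z, z, covariates = cbind(cc))
  of <- ols_fit(y, cbind(1, z, cc))
  expect_equal(unname(coef(tf)), unname(of$coefficients), tolerance = 1e-10)
  expect_equal(unname(tf$se), unname(of$se), tolerance = 1e-10)
})

test_that("the corrected 2SLS SE uses observed-exposure residuals", {
  set.seed(35)
  n <- 200
  z <- sample(0:2, n, replace = TRUE)
  x <- 0.5 * z + rnorm(n)
  y <- 0.3 * x + rnorm(n)
  fit <- tsls_fit(y, x, z)
  # residuals must come from the observed exposure, not the fitted one
  expect_equal(fit$residuals, y - coef(fit)[1] - coef(fit)[2] * x,
               tolerance = 1e-12)
  # and the naive OLS-on-fitted SE differs
  xhat <- fitted(ols_fit(x, cbind(1, z)))
  naive <- ols_fit(y, cbind(1, xhat))
  expect_false(isTRUE(all.equal(fit$se[["exposure"]], naive$se[2])))
})

test_that("tsls formula interface reproduces tsls_fit and supports methods", {
  set.seed(36)
  d <- data.frame(z = sample(0:2, 80, replace = TRUE),
                  cc = rbinom(80, 1, 0.5))
  d$a <- 6.5 + 0.3 * d$z + rnorm(80, sd = 0.3)
  d$y <- 1 + 0.2 * d$a + 0.1 * d$cc + rnorm(80, sd = 0.1)
  f1 <- tsls(y ~ a + cc | z + cc, data = d)
  f2 <- tsls_fit(d$y, d$a, d$z, covariates = cbind(cc = d$cc))
  expect_equal(unname(coef(f1)), unname(coef(f2)), tolerance = 1e-12)
  expect_equal(names(coef(f1))[2], "a")
  expect_s3_class(summary(f1), "summary.tsls")
  expect_output(print(summary(f1)), "First-stage")
  ci <- confint(f1, "a")
  expect_lt(ci[1], coef(f1)[["a"]])
  expect_gt(ci[2], coef(f1)[["a"]])
  expect_equal(length(residuals(f1)), nobs(f1))
  expect_equal(unname(predict(f1, d[1:3, ])),
               unname(coef(f1)[1] + coef(f1)[2] * d$a[1:3] + coef(f1)[3] * d$cc[1:3]),
               tolerance = 1e-12)
  expect_error(tsls_fit(d$y, d$a, rep(1, 80)), "constant")
})

test_that("2SLS is consistent under confounding where OLS is biased", {
  n <- 50000
  ch <- gen_cohort(cohort_spec(n = n, alpha1 = 0.4, sigma_x = 0.25,
                               alpha_c = 0.3, seed = 37))
  co <- ch$cohort
  # outcome straight from the linear structural model on the transformed
  # scale (no beta-scale round trip, which would clip the tails)
  set.seed(37)
  y <- -0.6 + 0.2 * co$log_rbc_folate + 0.3 * ch$confounder +
    rnorm(n, sd = 0.1)
  tf <- tsls_fit(y, co$log_rbc_folate, co$variant_count,
                 covariates = cbind(co$conception_planned))
  of <- ols_fit(y, cbind(1, co$log_rbc_folate, co$conception_planned))
  expect_lt(abs(coef(tf)[["exposure"]] - 0.2), 3 * tf$se[["exposure"]])
  expect_gt(abs(of$coefficients[2] - 0.2), 5 * of$se[2])  # detectably biased
})

test_that("genomewide_scan aligns subjects, ranks deterministically and flags significance", {
  ch <- strong_cohort(n = 50, seed = 5)
  pp <- gen_probe_panel(60, seed = 5)
  b1 <- rep(0, 60); b1[1:3] <- 0.6
  prof <- effect_profile(60, beta1 = b1, sigma_y = 0.05,
                         mean_exposure = mean(ch$cohort$log_rbc_folate))
  pan <- gen_methylation(ch$cohort, ch$confounder, prof, pp$annotations,
                         seed = 5)
  y <- transform_beta(pan$betas)
  sc <- genomewide_scan(y, ch$cohort, alpha = 0.05)
  expect_equal(nrow(sc$results), 60)
  expect_true(all(sc$results$tsls_p >= 0 & sc$results$tsls_p <= 1))

  # invariance to probe order and consistent subject permutation
  perm <- sample(ncol(y))
  ch2 <- ch$cohort[perm, ]
  sc2 <- genomewide_scan(y[rev(seq_len(60)), perm], ch2)
  expect_equal(sc2$results[match(sc$results$probe_id, sc2$results$probe_id),
                           "tsls_estimate"],
               sc$results$tsls_estimate, tolerance = 1e-10,
               ignore_attr = TRUE)

  # constant instrument is a hard, named error
  chc <- ch$cohort
  chc$variant_count <- 1L
  expect_error(genomewide_scan(y, chc), "instrument")

  # mismatched subjects are rejected
  expect_error(genomewide_scan(y[, 1:49], ch$cohort), "subject")
})

test_that("a strong planted effect ranks at the top of the scan", {
  hits <- 0L
  for (r in 1:20) {
    ch <- strong_cohort(n = 50, seed = 100 + r)
    pp <- gen_probe_panel(100, seed = 100 + r)
    b1 <- rep(0, 100); b1[57] <- 0.4
    prof <- effect_profile(100, beta1 = b1, sigma_y = 0.04,
                           mean_exposure = mean(ch$cohort$log_rbc_folate))
    pan <- gen_methylation(ch$cohort, ch$confounder, prof,
                           pp$annotations, seed = 100 + r)
    sc <- genomewide_scan(transform_beta(pan$betas), ch$cohort)
    top <- rank_loci(sc$results)$probe_id[1:5]
    hits <- hits + (pp$annotations$probe_id[57] %in% top)
  }
  expect_gte(hits, 15)  # most replicates
})

test_that("compare_scans reports correlation, ranges and top-k overlap", {
  expect_equal(compare_scans(1:10, 1:10)$r, 1)
  expect_equal(compare_scans(1:10, -(1:10))$r, -1)
  set.seed(38)
  n <- 16989
  x <- rnorm(n)
  y <- 0.44 * x + sqrt(1 - 0.44^2) * rnorm(n)
  cmp <- compare_scans(x, y)
  expect_equal(cmp$r, 0.44, tolerance = 0.03)
  expect_equal(cmp$r_squared, 0.19, tolerance = 0.03)
  expect_lt(cmp$p_value, 1e-10)
  expect_equal(cmp$overlap, length(intersect(cmp$top_tsls, cmp$top_ols)))
  expect_error(compare_scans(rep(1, 5), 1:5), "zero-variance")
  expect_error(compare_scans(1:5, 1:4), "equal length")
})

test_that("bootstrap CI collapses under zero noise and is seed-deterministic", {
  z <- rep(0:2, each = 20)
  x <- 6 + 0.5 * z                    # exposure exactly linear in instrument
  y <- 0.2 + 0.3 * x                  # outcome exactly linear in exposure
  b <- bootstrap_delta_beta(y, x, z, n_reps = 300, seed = 1)
  expect_equal(b$point, 0.3, tolerance = 1e-10)
  expect_equal(b$ci_low, 0.3, tolerance = 1e-8)
  expect_equal(b$ci_high, 0.3, tolerance = 1e-8)

  set.seed(39)
  xn <- x + rnorm(60, sd = 0.2)
  yn <- y + rnorm(60, sd = 0.05)
  b1 <- bootstrap_delta_beta(yn, xn, z, n_reps = 400, seed = 7)
  b2 <- bootstrap_delta_beta(yn, xn, z, n_reps = 400, seed = 7)
  expect_identical(b1[c("ci_low", "ci_high")], b2[c("ci_low", "ci_high")])
  b3 <- bootstrap_delta_beta(yn, xn, z, n_reps = 400, seed = 8)
  expect_false(identical(b1$ci_low, b3$ci_low))
  zs <- rep(0:1, 4)
  expect_warning(bootstrap_delta_beta(yn[1:8], xn[1:8], zs, n_reps = 300),
                 "fewer than 10")
})
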