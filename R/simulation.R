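#' Specification of the unmeasured-confounding simulation
#'
#' Anchors the data-generating process on an observed cohort (genotype,
#' conception and log RBC folate vectors are held fixed at their observed
#' values) and simulates, per replicate,
#'
#' \deqn{x_i = \hat\alpha_0 + \hat\alpha_1 Z_i + \hat\alpha_2 C_i + \alpha_c u_i + e_{x,i}}
#' \deqn{y_i = \hat\beta_0 + \hat\beta_1 A_i + \hat\beta_2 C_i + \beta_c u_i + e_{y,i}}
#'
#' with `u, e_x, e_y ~ N(0, 1)` drawn fresh each replicate. By default the
#' outcome equation uses the *observed* log RBC folate `A_i` (the literal
#' construction, where `x_i` is a separately simulated noisy exposure);
#' set `y_from_simulated_x = TRUE` for the conventional variant in which
#' `y` is generated from the simulated `x`.
#'
#' @param genotype,conception,log_folate Observed anchor vectors, equal
#'   length (typically n = 50).
#' @param alpha Numeric `c(alpha0, alpha1, alpha2)`: exposure-model
#'   intercept, per-variant effect, conception effect.
#' @param beta Numeric `c(beta0, beta1, beta2)`: outcome-model intercept,
#'   causal effect of log folate (the truth the estimators chase),
#'   conception effect.
#' @param conf_level Confounding level `alpha_c = beta_c` (>= 0).
#' @param n_reps Number of simulated datasets (default 10000).
#' @param seed Integer seed.
#' @param y_from_simulated_x Use the simulated exposure in the outcome
#'   equation instead of the observed anchor (default `FALSE`).
#' @return A list of class `"simulation_spec"`.
#' @export
simulation_spec <- function(genotype, conception, log_folate,
                            alpha, beta, conf_level = 0.1,
                            n_reps = 10000, seed = 1,
                            y_from_simulated_x = FALSE) {
  n <- length(genotype)
  if (length(conception) != n || length(log_folate) != n)
    stop("anchor vectors must have equal length")
  if (length(alpha) != 3 || length(beta) != 3)
    stop("alpha and beta must each have 3 elements (intercept, slope, conception)")
  if (conf_level < 0) stop("conf_level must be non-negative")
  if (n_reps < 1) stop("n_reps must be at least 1")
  structure(list(genotype = as.numeric(genotype),
                 conception = as.numeric(conception),
                 log_folate = as.numeric(log_folate),
                 alpha = as.numeric(alpha), beta = as.numeric(beta),
                 conf_level = conf_level, n_reps = as.integer(n_reps),
                 seed = as.integer(seed),
                 y_from_simulated_x = isTRUE(y_from_simulated_x)),
            class = "simulation_spec")
}

#' Draw an anchor cohort with a significant first stage
#'
#' The confounding simulation presumes an observed cohort whose
#' instrument demonstrably predicts the exposure (the study design this
#' emulates reported a significant first-stage F at n = 50). Because the
#' simulated exposure carries unit-variance noise, an anchor whose
#' realized first-stage slope is near zero would make the simulated
#' instrument vacuous; this helper draws synthetic cohorts from
#' successive seed substreams and returns the first whose first-stage
#' instrument-strength test has `p < alpha`.
#'
#' @param seed Integer seed.
#' @param n Cohort size (default 50).
#' @param alpha First-stage significance threshold (default 0.05).
#' @param max_tries Maximum substreams to try.
#' @param ... Further arguments passed to [cohort_spec()].
#' @return A list: `cohort` (data frame), `confounder`, `qc`
#'   (the [qc_report()]), `tries` (substreams consumed).
#' @export
anchor_cohort <- function(seed = 1, n = 50, alpha = 0.05, max_tries = 50,
                          ...) {
  for (k in seq_len(max_tries) - 1L) {
    ch <- gen_cohort(cohort_spec(n = n, seed = substream_seed(seed, 20L, k),
                                 ...))
    qc <- qc_report(ch$cohort)
    if (qc$first_stage$p_value < alpha)
      return(list(cohort = ch$cohort, confounder = ch$confounder,
                  qc = qc, tries = k + 1L))
  }
  stop("no cohort with first-stage p < ", alpha, " in ", max_tries, " draws")
}

#' Simulate one replicate dataset
#'
#' Draws `u`, `e_x`, `e_y` i.i.d. standard normal from a substream
#' determined by `(seed, rep_index)` — so a fixed seed and replicate
#' index give a bit-identical dataset regardless of execution order —
#' and evaluates the two linear equations of [simulation_spec()].
#'
#' @param spec A [simulation_spec()].
#' @param rep_index Replicate index (>= 1).
#' @param zero_noise Test hook: replace all three noise vectors by 0.
#' @return A list `x` (simulated exposure), `y` (simulated outcome),
#'   `u` (confounder draws).
#' @export
simulate_dataset <- function(spec, rep_index, zero_noise = FALSE) {
  stopifnot(inherits(spec, "simulation_spec"))
  n <- length(spec$genotype)
  if (zero_noise) {
    u <- e_x <- e_y <- numeric(n)
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(substream_seed(spec$seed, 9L, rep_index))
    u <- stats::rnorm(n)
    e_x <- stats::rnorm(n)
    e_y <- stats::rnorm(n)
  }
  a <- spec$alpha
  b <- spec$beta
  lvl <- spec$conf_level
  x <- a[1] + a[2] * spec$genotype + a[3] * spec$conception + lvl * u + e_x
  A_for_y <- if (spec$y_from_simulated_x) x else spec$log_folate
  y <- b[1] + b[2] * A_for_y + b[3] * spec$conception + lvl * u + e_y
  list(x = x, y = y, u = u)
}

#' Run the unmeasured-confounding simulation for one spec
#'
#' For each of `n_reps` replicates, fits the Mendelian-randomization
#' estimator (2SLS of `y` on the simulated exposure `x`, instrumented by
#' genotype, adjusting for conception) and ordinary least squares of `y`
#' on `x` and conception, and summarizes each estimator's distribution of
#' exposure-effect estimates by median and quartiles.
#'
#' @param spec A [simulation_spec()].
#' @return A data frame of class `"simulation_summary"`: one row per
#'   estimator (`MR`, `OLS`) with `median`, `q25`, `q75`, `truth`,
#'   `median_bias` (median - truth), `n_reps`, `n_failed`.
#' @export
run_confounding_sim <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  D1 <- cbind(1, spec$genotype, spec$conception)
  if (stats::var(spec$genotype) == 0)
    stop("anchor genotype vector is constant: instrument has no variance")
  est_mr <- numeric(spec$n_reps)
  est_ols <- numeric(spec$n_reps)
  failed <- 0L
  for (r in seq_len(spec$n_reps)) {
    d <- simulate_dataset(spec, r)
    fit <- tryCatch({
      D2o <- D1
      D2o[, 2L] <- d$x
      c(.tsls_coef(d$y, d$x, D1)[2L], .ols_coef(d$y, D2o)[2L])
    }, error = function(e) NULL)
    if (is.null(fit)) {
      failed <- failed + 1L
      est_mr[r] <- est_ols[r] <- NA_real_
    } else {
      est_mr[r] <- fit[1L]
      est_ols[r] <- fit[2L]
    }
  }
  truth <- spec$beta[2]
  summ <- function(est, name) {
    q <- stats::quantile(est, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
    data.frame(estimator = name, median = q[2], q25 = q[1], q75 = q[3],
               truth = truth, median_bias = q[2] - truth,
               n_reps = spec$n_reps, n_failed = failed,
               stringsAsFactors = FALSE)
  }
  out <- rbind(summ(est_mr, "MR"), summ(est_ols, "OLS"))
  attr(out, "estimates") <- list(MR = est_mr, OLS = est_ols)
  class(out) <- c("simulation_summary", "data.frame")
  out
}

#' Sweep the confounding simulation over loci and levels
#'
#' Drives [run_confounding_sim()] over a grid of per-locus truth vectors
#' and confounding levels, returning a long plot-ready table (the
#' structure behind an estimates-vs-truth sensitivity figure).
#'
#' @param cohort Anchor cohort data frame (`variant_count`,
#'   `conception_planned`, `log_rbc_folate`).
#' @param truth Data frame with one row per locus: columns `locus`,
#'   `alpha0`, `alpha1`, `alpha2`, `beta0`, `beta1`, `beta2`.
#' @param levels Confounding levels, e.g. `c(0.1, 0.2)`.
#' @param n_reps Replicates per cell (default 10000).
#' @param seed Integer seed.
#' @param y_from_simulated_x Passed through to [simulation_spec()].
#' @return Long data frame: `locus`, `level`, `estimator`, `median`,
#'   `q25`, `q75`, `truth`, `median_bias`, `n_reps`, `n_failed`.
#' @export
confounding_sweep <- function(cohort, truth, levels = c(0.1, 0.2),
                              n_reps = 10000, seed = 1,
                              y_from_simulated_x = FALSE) {
  if (nrow(truth) == 0)
    return(data.frame(locus = character(0), level = numeric(0),
                      estimator = character(0), median = numeric(0),
                      q25 = numeric(0), q75 = numeric(0), truth = numeric(0),
                      median_bias = numeric(0), n_reps = integer(0),
                      n_failed = integer(0), stringsAsFactors = FALSE))
  rows <- vector("list", nrow(truth) * length(levels))
  k <- 0L
  for (i in seq_len(nrow(truth))) {
    for (j in seq_along(levels)) {
      spec <- simulation_spec(
        genotype = cohort$variant_count,
        conception = cohort$conception_planned,
        log_folate = cohort$log_rbc_folate,
        alpha = c(truth$alpha0[i], truth$alpha1[i], truth$alpha2[i]),
        beta = c(truth$beta0[i], truth$beta1[i], truth$beta2[i]),
        conf_level = levels[j], n_reps = n_reps,
        seed = substream_seed(seed, 10L, i, j),
        y_from_simulated_x = y_from_simulated_x)
      s <- run_confounding_sim(spec)
      s$locus <- as.character(truth$locus[i])
      s$level <- levels[j]
      k <- k + 1L
      rows[[k]] <- as.data.frame(s)[, c("locus", "level", "estimator",
                                        "median", "q25", "q75", "truth",
                                        "median_bias", "n_reps", "n_failed")]
    }
  }
  do.call(rbind, rows)
}
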