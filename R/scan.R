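# Fast coefficient-only 2SLS and OLS used in the genome-wide scan,
# bootstrap and simulation loops. D1 = first-stage design, D2 built from
# its fitted exposure. Agrees with tsls_fit()/ols_fit() exactly (same
# normal equations); returns only what hot loops need.
.tsls_coef <- function(y, x, D1) {
  xhat <- D1 %*% solve(crossprod(D1), crossprod(D1, x))
  D2 <- D1
  D2[, 2L] <- xhat
  drop(solve(crossprod(D2), crossprod(D2, y)))
}

.ols_coef <- function(y, D) {
  drop(solve(crossprod(D), crossprod(D, y)))
}

#' Genome-wide per-locus 2SLS and OLS scan
#'
#' Fits, for every probe of a preprocessed (transformed, complete-case)
#' methylation matrix, the two-stage least squares model with the additive
#' variant count as instrument and, for comparison, the ordinary least
#' squares regression of methylation on log RBC folate — both adjusting
#' for conception intention only. Significance is declared at an
#' unadjusted `alpha`; Bonferroni and Benjamini-Hochberg columns can be
#' added as clearly-labelled extensions. For significant loci the effect
#' on the *untransformed* beta-value scale (`delta_beta`, change per unit
#' log RBC folate) is estimated by 2SLS with a pairs-bootstrap percentile
#' confidence interval.
#'
#' @param y Probes x subjects matrix of transformed methylation; column
#'   names must match `cohort$subject_id` (order is aligned by name when
#'   names are present).
#' @param cohort Cohort data frame (`variant_count`, `conception_planned`,
#'   `log_rbc_folate`, `subject_id`).
#' @param alpha Unadjusted significance level (default 0.05).
#' @param betas Optional matrix of untransformed beta-values (same probes
#'   and subjects) used for `delta_beta` and its bootstrap CI.
#' @param bootstrap_reps Bootstrap replicates for the CI (0 disables).
#' @param seed Integer seed for the bootstrap.
#' @param multiplicity Add `p_bonferroni` / `p_bh` columns (extensions;
#'   off by default).
#' @return An object of class `"mr_scan"`: `results` (one row per probe:
#'   `probe_id`, `tsls_estimate`, `tsls_se`, `tsls_p`, `ols_estimate`,
#'   `ols_se`, `ols_p`, `significant`, and where computed `delta_beta`,
#'   `bootstrap_ci_low`, `bootstrap_ci_high`), `comparison`
#'   (see [compare_scans()]), `first_stage_F`, `alpha`, `n`.
#' @export
genomewide_scan <- function(y, cohort, alpha = 0.05, betas = NULL,
                            bootstrap_reps = 0, seed = 1,
                            multiplicity = FALSE) {
  y <- as.matrix(y)
  n <- nrow(cohort)
  if (ncol(y) != n)
    stop("matrix has ", ncol(y), " subject columns but cohort has ", n, " rows")
  if (!is.null(colnames(y)) && !is.null(cohort$subject_id)) {
    if (!setequal(colnames(y), cohort$subject_id))
      stop("subject columns of the matrix do not match the cohort")
    y <- y[, cohort$subject_id, drop = FALSE]
    if (!is.null(betas)) betas <- betas[, cohort$subject_id, drop = FALSE]
  }
  z <- cohort$variant_count
  if (stats::var(z) == 0)
    stop("instrument (variant_count) is constant across the cohort")
  A <- cohort$log_rbc_folate
  C <- cohort$conception_planned

  p <- nrow(y)
  res <- data.frame(probe_id = rownames(y) %||% as.character(seq_len(p)),
                    tsls_estimate = NA_real_, tsls_se = NA_real_,
                    tsls_p = NA_real_, ols_estimate = NA_real_,
                    ols_se = NA_real_, ols_p = NA_real_,
                    stringsAsFactors = FALSE)
  fsF <- NA_real_
  X_ols <- cbind(1, A, C)
  for (i in seq_len(p)) {
    tf <- tsls_fit(y[i, ], A, z, covariates = cbind(conception = C))
    of <- ols_fit(y[i, ], X_ols)
    res$tsls_estimate[i] <- tf$coefficients[["exposure"]]
    res$tsls_se[i] <- tf$se[["exposure"]]
    res$tsls_p[i] <- tf$p[["exposure"]]
    res$ols_estimate[i] <- of$coefficients[2L]
    res$ols_se[i] <- of$se[2L]
    res$ols_p[i] <- of$p[2L]
    if (i == 1L) fsF <- tf$first_stage$F
  }
  res$significant <- res$tsls_p < alpha
  if (multiplicity) {
    res$p_bonferroni <- stats::p.adjust(res$tsls_p, "bonferroni")
    res$p_bh <- stats::p.adjust(res$tsls_p, "BH")
  }

  if (!is.null(betas) && bootstrap_reps > 0 && any(res$significant)) {
    res$delta_beta <- NA_real_
    res$bootstrap_ci_low <- NA_real_
    res$bootstrap_ci_high <- NA_real_
    sig <- which(res$significant)
    for (k in seq_along(sig)) {
      i <- sig[k]
      bb <- bootstrap_delta_beta(betas[i, ], A, z,
                                 covariates = cbind(conception = C),
                                 n_reps = bootstrap_reps,
                                 seed = substream_seed(seed, 7L, i))
      res$delta_beta[i] <- bb$point
      res$bootstrap_ci_low[i] <- bb$ci_low
      res$bootstrap_ci_high[i] <- bb$ci_high
    }
  }

  cmp <- if (p >= 3 && stats::var(res$tsls_estimate) > 0 &&
             stats::var(res$ols_estimate) > 0)
    compare_scans(res$tsls_estimate, res$ols_estimate,
                  probe_ids = res$probe_id,
                  tsls_p = res$tsls_p, ols_p = res$ols_p)
  else NULL
  structure(list(results = res, comparison = cmp, first_stage_F = fsF,
                 alpha = alpha, n = n),
            class = "mr_scan")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rank scan results
#'
#' Orders loci by 2SLS p-value ascending, breaking ties by absolute
#' estimate descending, then by probe id, for a deterministic ranking.
#'
#' @param results The `results` data frame of an `mr_scan` (or any data
#'   frame with `tsls_p`, `tsls_estimate`, `probe_id`).
#' @param p_col,est_col Column names to rank by (defaults: the 2SLS
#'   columns).
#' @return The data frame reordered.
#' @export
rank_loci <- function(results, p_col = "tsls_p", est_col = "tsls_estimate") {
  ord <- order(results[[p_col]], -abs(results[[est_col]]), results$probe_id)
  results[ord, , drop = FALSE]
}

#' Compare 2SLS and OLS estimate vectors across the scan
#'
#' Pearson correlation (with two-sided p) between the aligned per-locus
#' estimate vectors, the range of each, and the overlap of the two
#' methods' top-`k` loci (ranked by p when p-value vectors are supplied,
#' else by absolute estimate).
#'
#' @param tsls_estimates,ols_estimates Aligned numeric vectors, length >= 3.
#' @param probe_ids Optional probe ids for the top-k lists.
#' @param tsls_p,ols_p Optional aligned p-value vectors used for ranking.
#' @param k Size of the top lists (default 10).
#' @return A list of class `"scan_comparison"`: `r`, `r_squared`,
#'   `p_value`, `range_tsls`, `range_ols`, `top_tsls`, `top_ols`,
#'   `overlap`.
#' @export
compare_scans <- function(tsls_estimates, ols_estimates, probe_ids = NULL,
                          tsls_p = NULL, ols_p = NULL, k = 10) {
  m <- length(tsls_estimates)
  if (length(ols_estimates) != m)
    stop("estimate vectors must have equal length")
  if (m < 3) stop("need at least 3 loci to compare scans")
  if (stats::var(tsls_estimates) == 0 || stats::var(ols_estimates) == 0)
    stop("cannot correlate a zero-variance estimate vector")
  ct <- stats::cor.test(tsls_estimates, ols_estimates)
  if (is.null(probe_ids)) probe_ids <- as.character(seq_len(m))
  rank_by <- function(est, p) {
    ord <- if (is.null(p)) order(-abs(est), probe_ids)
           else order(p, -abs(est), probe_ids)
    probe_ids[ord][seq_len(min(k, m))]
  }
  top_t <- rank_by(tsls_estimates, tsls_p)
  top_o <- rank_by(ols_estimates, ols_p)
  structure(list(r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
                 p_value = ct$p.value,
                 range_tsls = range(tsls_estimates),
                 range_ols = range(ols_estimates),
                 top_tsls = top_t, top_ols = top_o,
                 overlap = length(intersect(top_t, top_o))),
            class = "scan_comparison")
}

#' @export
print.scan_comparison <- function(x, ...) {
  cat(sprintf("2SLS vs OLS estimates: r = %.3f (R^2 = %.3f), p = %.3g\n",
              x$r, x$r_squared, x$p_value))
  cat(sprintf("  2SLS range: [%.3f, %.3f]; OLS range: [%.3f, %.3f]\n",
              x$range_tsls[1], x$range_tsls[2],
              x$range_ols[1], x$range_ols[2]))
  cat(sprintf("  top-%d overlap: %d loci\n", length(x$top_tsls), x$overlap))
  invisible(x)
}

#' @export
print.mr_scan <- function(x, ...) {
  r <- x$results
  cat(sprintf("MR scan of %d loci, n = %d subjects\n", nrow(r), x$n))
  cat(sprintf("  significant at alpha = %g (unadjusted): %d\n",
              x$alpha, sum(r$significant)))
  cat(sprintf("  first-stage F = %.3f\n", x$first_stage_F))
  if (!is.null(x$comparison)) print(x$comparison)
  invisible(x)
}

#' @export
plot.mr_scan <- function(x, ...) {
  r <- x$results
  plot(r$ols_estimate, r$tsls_estimate,
       xlab = "OLS estimate", ylab = "2SLS estimate",
       pch = 16, cex = 0.4, col = "#00000055", ...)
  graphics::abline(stats::lm(r$tsls_estimate ~ r$ols_estimate), col = "blue")
  graphics::abline(0, 1, lty = 2, col = "grey")
  invisible(x)
}

#' Pairs-bootstrap percentile CI for the beta-scale 2SLS effect
#'
#' Point estimate: 2SLS of the untransformed beta-values on log RBC
#' folate (variant-count instrument, covariates in both stages).
#' Subjects (rows) are resampled with replacement `n_reps` times, the
#' model refit, and the empirical 2.5/97.5 percentiles taken. Resamples
#' with a constant instrument are redrawn and counted.
#'
#' @param beta_untransformed Per-subject untransformed beta-values.
#' @param exposure,instrument,covariates As in [tsls_fit()].
#' @param n_reps Bootstrap replicates (>= 200 for percentile CIs).
#' @param seed Integer seed.
#' @param level Confidence level (default 0.95).
#' @return A list `point`, `ci_low`, `ci_high`, `n_reps`, `n_redrawn`,
#'   `estimates` (the bootstrap distribution).
#' @export
bootstrap_delta_beta <- function(beta_untransformed, exposure, instrument,
                                 covariates = NULL, n_reps = 1000, seed = 1,
                                 level = 0.95) {
  if (n_reps < 200)
    warning("fewer than 200 bootstrap replicates: percentile CI is unstable")
  y <- as.numeric(beta_untransformed)
  n <- length(y)
  if (n < 10) warning("fewer than 10 subjects: bootstrap resampling is fragile")
  C <- if (is.null(covariates)) NULL else as.matrix(covariates)
  point <- tsls_fit(y, exposure, instrument, covariates = C)$coefficients[["exposure"]]
  D1 <- cbind(1, instrument, C)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(substream_seed(seed, 8L))
  est <- numeric(n_reps)
  n_redrawn <- 0L
  for (r in seq_len(n_reps)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (stats::var(instrument[idx]) > 0) break
      n_redrawn <- n_redrawn + 1L
    }
    est[r] <- .tsls_coef(y[idx], exposure[idx], D1[idx, , drop = FALSE])[2L]
  }
  a <- (1 - level) / 2
  ci <- unname(stats::quantile(est, c(a, 1 - a), type = 7))
  list(point = point, ci_low = ci[1], ci_high = ci[2],
       n_reps = n_reps, n_redrawn = n_redrawn, estimates = est)
}
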