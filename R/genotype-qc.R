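#' Hardy-Weinberg equilibrium chi-square test
#'
#' Pearson chi-square (1 df, no continuity correction) comparing observed
#' genotype counts with the `(p^2, 2pq, q^2) n` expectation at the sample
#' allele frequency. A monomorphic sample is reported with p-value 1 and
#' a warning.
#'
#' @param n_AA,n_Aa,n_aa Non-negative genotype counts; total >= 1.
#' @return A list of class `"hwe_test"`: `observed`, `expected`,
#'   `allele_freq` (of A), `chi2`, `df`, `p_value`.
#' @examples
#' hwe_test(49, 42, 9)  # exact HWE at p = 0.7: chi2 = 0
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa) {
  obs <- c(AA = n_AA, Aa = n_Aa, aa = n_aa)
  if (any(obs < 0)) stop("genotype counts must be non-negative")
  n <- sum(obs)
  if (n < 1) stop("total genotype count must be at least 1")
  p <- (2 * n_AA + n_Aa) / (2 * n)
  q <- 1 - p
  if (p == 0 || p == 1) {
    warning("monomorphic sample: HWE p-value defined as 1")
    exp_cnt <- c(AA = p^2, Aa = 2 * p * q, aa = q^2) * n
    return(structure(list(observed = obs, expected = exp_cnt,
                          allele_freq = p, chi2 = 0, df = 1L, p_value = 1),
                     class = "hwe_test"))
  }
  exp_cnt <- c(AA = p^2, Aa = 2 * p * q, aa = q^2) * n
  chi2 <- sum((obs - exp_cnt)^2 / exp_cnt)
  structure(list(observed = obs, expected = exp_cnt, allele_freq = p,
                 chi2 = chi2, df = 1L,
                 p_value = stats::pchisq(chi2, 1L, lower.tail = FALSE)),
            class = "hwe_test")
}

#' @export
print.hwe_test <- function(x, ...) {
  cat("Hardy-Weinberg chi-square test\n")
  cat("  observed:", paste(sprintf("%s=%g", names(x$observed), x$observed),
                           collapse = ", "), "\n")
  cat("  expected:", paste(sprintf("%s=%.2f", names(x$expected), x$expected),
                           collapse = ", "), "\n")
  cat(sprintf("  allele freq = %.4f, chi2 = %.4f (1 df), p = %.4g\n",
              x$allele_freq, x$chi2, x$p_value))
  invisible(x)
}

#' Additive instrument coding of two trans MTHFR variants
#'
#' Codes the instrument as the total number of variant alleles,
#' `g677 + g1298`, valid because the two variants lie on opposite
#' (trans) haplotypes, so a subject carries at most two variant alleles
#' in total. A sum above 2 implies a cis haplotype and, by default,
#' raises an error rather than silently recoding; `on_violation = "drop"`
#' instead returns `NA` for the offending subjects with a warning.
#'
#' @param g677,g1298 Allele counts in `{0, 1, 2}` (vectorized).
#' @param on_violation `"error"` (default) or `"drop"`.
#' @return Integer variant counts in `{0, 1, 2}` (or `NA` for dropped
#'   subjects).
#' @export
additive_code <- function(g677, g1298, on_violation = c("error", "drop")) {
  on_violation <- match.arg(on_violation)
  if (any(!(g677 %in% 0:2)) || any(!(g1298 %in% 0:2)))
    stop("allele counts must lie in {0, 1, 2}")
  z <- as.integer(g677 + g1298)
  bad <- z > 2L
  if (any(bad)) {
    msg <- sprintf("%d subject(s) violate the trans constraint (g677 + g1298 > 2, implied cis haplotype)",
                   sum(bad))
    if (on_violation == "error") stop(msg)
    warning(msg, "; coded NA")
    z[bad] <- NA_integer_
  }
  z
}

#' Extra-sum-of-squares F test for nested linear models
#'
#' Compares the residual sums of squares of a full and a reduced design,
#' `F = ((RSS_r - RSS_f) / df1) / (RSS_f / df2)`. Used both for the
#' additive-vs-codominant genotype comparison and for the first-stage
#' instrument-strength test.
#'
#' @param y Response vector.
#' @param X_full Full design matrix (include the intercept).
#' @param X_reduced Reduced design, nested in the full one.
#' @return A list `F`, `df1`, `df2`, `p_value`, `rss_full`, `rss_reduced`.
#' @export
nested_f_test <- function(y, X_full, X_reduced) {
  X_full <- as.matrix(X_full)
  X_reduced <- as.matrix(X_reduced)
  if (ncol(X_reduced) == ncol(X_full) &&
      isTRUE(all.equal(unname(X_full), unname(X_reduced)))) {
    # identical designs: no extra variation explained
    df2 <- length(y) - ncol(X_full)
    rss <- ols_fit(y, X_full)$rss
    return(list(F = 0, df1 = 0L, df2 = df2, p_value = 1,
                rss_full = rss, rss_reduced = rss))
  }
  if (ncol(X_reduced) >= ncol(X_full)) stop("designs are not nested")
  # nesting check: reduced columns must lie in the full column space
  qf <- qr(X_full)
  proj <- qr.fitted(qf, X_reduced)
  if (max(abs(proj - X_reduced)) > 1e-8 * max(1, max(abs(X_reduced))))
    stop("designs are not nested")
  ff <- ols_fit(y, X_full)
  fr <- ols_fit(y, X_reduced)
  df1 <- ncol(X_full) - ncol(X_reduced)
  df2 <- ff$df.residual
  Fstat <- ((fr$rss - ff$rss) / df1) / (ff$rss / df2)
  list(F = Fstat, df1 = df1, df2 = df2,
       p_value = stats::pf(Fstat, df1, df2, lower.tail = FALSE),
       rss_full = ff$rss, rss_reduced = fr$rss)
}

#' Instrument quality-control report for a cohort
#'
#' Computes, from a cohort table: Hardy-Weinberg chi-square tests per
#' SNP, the additive-vs-codominant nested F test for the first-stage
#' model of log RBC folate (conception intention in both designs), and
#' the first-stage instrument-strength F (additive variant count vs
#' intercept + conception).
#'
#' @param cohort Data frame with columns `g677`, `g1298`, `variant_count`,
#'   `conception_planned`, `log_rbc_folate`.
#' @return A list of class `"qc_report"`: `hwe_677`, `hwe_1298`,
#'   `codominant_vs_additive`, `first_stage`.
#' @export
qc_report <- function(cohort) {
  counts <- function(g) c(sum(g == 0), sum(g == 1), sum(g == 2))
  # "A" = wild-type allele, "a" = variant
  c677 <- counts(cohort$g677)
  c1298 <- counts(cohort$g1298)
  z <- cohort$variant_count
  cc <- cohort$conception_planned
  y <- cohort$log_rbc_folate
  X_add <- cbind(1, z, cc)
  X_codom <- cbind(1, as.integer(z == 1), as.integer(z == 2), cc)
  X_null <- cbind(1, cc)
  structure(list(
    hwe_677 = hwe_test(c677[1], c677[2], c677[3]),
    hwe_1298 = hwe_test(c1298[1], c1298[2], c1298[3]),
    codominant_vs_additive = nested_f_test(y, X_codom, X_add),
    first_stage = nested_f_test(y, X_add, X_null)
  ), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Instrument QC report\n\n== HWE, C677T ==\n")
  print(x$hwe_677)
  cat("\n== HWE, A1298C ==\n")
  print(x$hwe_1298)
  cat(sprintf("\nCodominant vs additive: F = %.3f (%d, %d df), p = %.4g\n",
              x$codominant_vs_additive$F, x$codominant_vs_additive$df1,
              x$codominant_vs_additive$df2, x$codominant_vs_additive$p_value))
  cat(sprintf("First-stage instrument strength: F = %.3f (%d, %d df), p = %.4g\n",
              x$first_stage$F, x$first_stage$df1, x$first_stage$df2,
              x$first_stage$p_value))
  invisible(x)
}
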