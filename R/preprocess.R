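#' Convert Infinium intensities to beta-values
#'
#' `beta = M / (M + U + 100)`, the standard Infinium methylation fraction
#' with the 100-unit regularizer in the denominator. Vectorized over
#' matrices; entries whose detection flag says the signal is not above
#' background are set missing.
#'
#' @param M,U Methylated / unmethylated intensities (non-negative, same
#'   shape).
#' @param detected Optional logical array of the same shape; `FALSE`
#'   entries are recorded `NA`.
#' @return Beta-values in `[0, 1)` with the shape of `M`.
#' @examples
#' beta_from_intensities(100, 0)  # 0.5
#' @export
beta_from_intensities <- function(M, U, detected = NULL) {
  if (any(M < 0, na.rm = TRUE) || any(U < 0, na.rm = TRUE))
    stop("intensities must be non-negative")
  beta <- M / (M + U + 100)
  if (!is.null(detected)) beta[!detected] <- NA_real_
  beta
}

#' Arcsine square-root transform of beta-values
#'
#' `y = asin(sqrt(beta))`, the variance-stabilizing transform for
#' proportion-like methylation beta-values; strictly monotone from
#' `[0, 1]` onto `[0, pi/2]`.
#'
#' @param beta Beta-values in `[0, 1]` (NA passed through).
#' @return Transformed values.
#' @export
transform_beta <- function(beta) {
  if (any(beta < 0 | beta > 1, na.rm = TRUE))
    stop("beta-values must lie in [0, 1]")
  asin(sqrt(beta))
}

#' Inverse of the arcsine square-root transform
#'
#' Maps transformed values back to the beta scale via `sin(y)^2`, after
#' clipping `y` to `[0, pi/2]` so the result stays in `[0, 1]`.
#'
#' @param y Transformed values.
#' @return Beta-values in `[0, 1]`.
#' @export
inv_transform_beta <- function(y) {
  sin(pmin(pmax(y, 0), pi / 2))^2
}

.filter_report <- function(stages, removed) {
  structure(list(counts = stages, removed = removed), class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Probe filter report\n")
  for (nm in names(x$counts))
    cat(sprintf("  %-28s %6d\n", nm, x$counts[[nm]]))
  invisible(x)
}

#' Probe-restriction cascade
#'
#' Applies, in fixed order: (1) restriction to autosomal probes
#' (chromosomes "1".."22"); (2) removal of cross-reactive probes (the
#' precomputed alignment flag); (3) restriction to probes with no missing
#' beta-value across subjects (complete case). The cascade is idempotent.
#'
#' @param panel A `methylation_panel` (annotations + `betas`, optionally
#'   `M`/`U`).
#' @return A list with the filtered `panel` and a `report`
#'   (`filter_report`: counts `input`, `after_autosome_restriction`,
#'   `after_cross_reactive_removal`, `after_complete_case`, plus the
#'   per-stage removed probe ids).
#' @export
restrict_probes <- function(panel) {
  ann <- panel$annotations
  valid_chr <- c(as.character(1:22), "X", "Y")
  bad <- setdiff(unique(ann$chromosome), valid_chr)
  if (length(bad))
    stop("unknown chromosome label(s): ", paste(bad, collapse = ", "))
  n0 <- nrow(ann)
  sex <- ann$chromosome %in% c("X", "Y")
  keep1 <- !sex
  cr <- ann$cross_reactive & keep1
  keep2 <- keep1 & !ann$cross_reactive
  miss <- rowSums(is.na(panel$betas)) > 0 & keep2
  keep3 <- keep2 & !miss
  if (!any(keep3))
    warning("no probes retained after the restriction cascade")
  report <- .filter_report(
    c(input = n0,
      after_autosome_restriction = sum(keep1),
      after_cross_reactive_removal = sum(keep2),
      after_complete_case = sum(keep3)),
    list(sex_chromosome = ann$probe_id[sex],
         cross_reactive = ann$probe_id[cr],
         incomplete = ann$probe_id[miss]))
  out <- panel
  out$annotations <- ann[keep3, , drop = FALSE]
  out$betas <- panel$betas[keep3, , drop = FALSE]
  if (!is.null(panel$M)) {
    out$M <- panel$M[keep3, , drop = FALSE]
    out$U <- panel$U[keep3, , drop = FALSE]
  }
  list(panel = out, report = report)
}

#' Shapiro-Wilk normality filter
#'
#' Computes a Shapiro-Wilk p-value per probe (row) of a transformed
#' methylation matrix and removes probes with `p < alpha`, with no
#' multiple-testing adjustment. Constant probes, for which the W statistic
#' is undefined, are removed with a warning.
#'
#' @param y Probes x subjects matrix of transformed methylation, no
#'   missing values; 3 <= subjects <= 5000 (test validity range).
#' @param alpha Removal threshold in (0, 1); default 0.05.
#' @return A list with the retained `matrix`, the per-probe `p_values`
#'   (all probes, input order), and a `report` (`filter_report` with
#'   counts `input`, `after_normality_filter`).
#' @export
normality_filter <- function(y, alpha = 0.05) {
  y <- as.matrix(y)
  n <- ncol(y)
  if (n < 3 || n > 5000)
    stop("Shapiro-Wilk requires between 3 and 5000 subjects; got ", n)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (anyNA(y)) stop("normality filter expects a complete-case matrix")
  const <- apply(y, 1L, function(v) max(v) == min(v))
  if (any(const))
    warning(sum(const), " constant probe(s) removed (W undefined)")
  pvals <- rep(NA_real_, nrow(y))
  if (any(!const))
    pvals[!const] <- apply(y[!const, , drop = FALSE], 1L,
                           function(v) stats::shapiro.test(v)$p.value)
  keep <- !const & pvals >= alpha
  keep[is.na(keep)] <- FALSE
  ids <- rownames(y)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(y)))
  report <- .filter_report(
    c(input = nrow(y), after_normality_filter = sum(keep)),
    list(non_normal = ids[!keep]))
  list(matrix = y[keep, , drop = FALSE], p_values = pvals, report = report)
}

#' Full preprocessing pipeline for a methylation panel
#'
#' Runs the probe-restriction cascade, transforms the retained
#' beta-values to the arcsine square-root scale, and applies the
#' Shapiro-Wilk normality filter, returning the analysis-ready matrix on
#' both scales and a combined filter report.
#'
#' @param panel A `methylation_panel`.
#' @param alpha Normality-filter threshold.
#' @return A list with `y` (transformed matrix), `betas` (untransformed,
#'   same probes), `annotations`, and `report` (counts `input`,
#'   `after_autosome_restriction`, `after_cross_reactive_removal`,
#'   `after_complete_case`, `after_normality_filter`; removed ids per
#'   stage).
#' @export
preprocess_panel <- function(panel, alpha = 0.05) {
  r1 <- restrict_probes(panel)
  y <- transform_beta(r1$panel$betas)
  r2 <- normality_filter(y, alpha = alpha)
  keep <- rownames(r2$matrix)
  report <- .filter_report(
    c(r1$report$counts,
      after_normality_filter = unname(r2$report$counts["after_normality_filter"])),
    c(r1$report$removed, r2$report$removed["non_normal"]))
  list(y = r2$matrix,
       betas = r1$panel$betas[keep, , drop = FALSE],
       annotations = r1$panel$annotations[
         match(keep, r1$panel$annotations$probe_id), , drop = FALSE],
       report = report)
}
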