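#' Cohort-generator specification
#'
#' Collects the parameters of the synthetic birth-cohort generator: two
#' biallelic MTHFR SNPs combined additively under the trans-haplotype
#' constraint, and a first-stage linear model for log RBC folate
#'
#' \deqn{A_i = \alpha_0 + \alpha_1 Z_i + \alpha_2 C_i + \alpha_c u_i + e_i}
#'
#' where `Z` is the variant count, `C` the conception-planned indicator,
#' `u` a standard-normal unmeasured confounder and `e ~ N(0, sigma_x^2)`.
#' Defaults emulate a cohort of 50 cord-blood samples with minor-allele
#' frequencies of 33% (C677T) and 23% (A1298C) and log RBC folate
#' concentrated in the 6.1--7.5 log(ng/mL) range.
#'
#' @param n Number of subjects (>= 2).
#' @param maf677,maf1298 Minor-allele frequencies, each in (0, 0.5] (0 allowed
#'   to switch a variant off).
#' @param alpha0,alpha1,alpha2 First-stage intercept, per-variant effect and
#'   conception effect on log RBC folate (log ng/mL).
#' @param alpha_c Confounder loading on the exposure.
#' @param sigma_x Exposure noise standard deviation (> 0).
#' @param p_planned Probability that conception was planned.
#' @param seed Integer seed.
#' @return A list of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n = 50, maf677 = 0.33, maf1298 = 0.23,
                        alpha0 = 6.5, alpha1 = 0.12, alpha2 = 0.05,
                        alpha_c = 0, sigma_x = 0.28,
                        p_planned = 0.5, seed = 1) {
  if (n < 2) stop("n must be at least 2")
  for (f in c(maf677, maf1298))
    if (f < 0 || f > 0.5) stop("allele frequencies must lie in [0, 0.5]")
  if (sigma_x <= 0) stop("sigma_x must be positive")
  if (p_planned < 0 || p_planned > 1) stop("p_planned must lie in [0, 1]")
  structure(list(n = as.integer(n), maf677 = maf677, maf1298 = maf1298,
                 alpha0 = alpha0, alpha1 = alpha1, alpha2 = alpha2,
                 alpha_c = alpha_c, sigma_x = sigma_x,
                 p_planned = p_planned, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Draw MTHFR genotypes under the trans-haplotype constraint
#'
#' Each subject receives two haplotypes drawn independently; a haplotype
#' carries the 677T variant with probability `maf677`, the 1298C variant
#' with probability `maf1298`, and is wild-type otherwise, so no haplotype
#' ever carries both variants. Genotypes are haplotype sums, which makes
#' `g677 + g1298 <= 2` hold by construction (the cis 677T/1298C haplotype
#' is rare in real populations and excluded here).
#'
#' @param n Number of subjects (>= 1).
#' @param maf677,maf1298 Per-haplotype variant frequencies in [0, 1); if
#'   their sum exceeds 1 they are renormalized with a warning.
#' @param seed Integer seed.
#' @return A data frame with integer columns `g677` and `g1298`.
#' @export
gen_genotypes <- function(n, maf677, maf1298, seed = 1) {
  if (n < 1) stop("n must be positive")
  for (f in c(maf677, maf1298))
    if (f < 0 || f >= 1) stop("allele frequencies must lie in [0, 1)")
  if (maf677 + maf1298 > 1) {
    warning("maf677 + maf1298 > 1; renormalizing haplotype frequencies")
    tot <- maf677 + maf1298
    maf677 <- maf677 / tot
    maf1298 <- maf1298 / tot
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(substream_seed(seed, 1L))
  # haplotype state: 0 = wild-type, 1 = 677T, 2 = 1298C
  hap <- matrix(sample.int(3L, 2L * n, replace = TRUE,
                           prob = c(max(0, 1 - maf677 - maf1298),
                                    maf677, maf1298)) - 1L,
                nrow = n)
  data.frame(g677 = rowSums(hap == 1L), g1298 = rowSums(hap == 2L))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Generate a synthetic cohort
#'
#' Draws genotypes via [gen_genotypes()], a conception-planned indicator,
#' a standard-normal confounder `u`, and log RBC folate from the linear
#' first-stage model in [cohort_spec()]. The confounder is returned
#' explicitly so that [gen_methylation()] can share it; analyses must not
#' use it.
#'
#' @param spec A [cohort_spec()].
#' @return A list with `cohort` (data frame with columns `subject_id`,
#'   `g677`, `g1298`, `variant_count`, `conception_planned`,
#'   `log_rbc_folate`) and `confounder` (numeric vector `u`).
#' @export
gen_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  g <- gen_genotypes(spec$n, spec$maf677, spec$maf1298, seed = spec$seed)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(substream_seed(spec$seed, 2L))
  n <- spec$n
  planned <- stats::rbinom(n, 1L, spec$p_planned)
  u <- stats::rnorm(n)
  e_x <- stats::rnorm(n, sd = spec$sigma_x)
  z <- g$g677 + g$g1298
  folate <- spec$alpha0 + spec$alpha1 * z + spec$alpha2 * planned +
    spec$alpha_c * u + e_x
  cohort <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    g677 = g$g677, g1298 = g$g1298,
    variant_count = as.integer(z),
    conception_planned = as.integer(planned),
    log_rbc_folate = folate,
    stringsAsFactors = FALSE)
  list(cohort = cohort, confounder = u)
}

#' Per-probe effect profile for the methylation generator
#'
#' One row per probe of the outcome model
#' \deqn{y_i = \beta_0 + \beta_1 A_i + \beta_2 C_i + \beta_c u_i + e_i}
#' on the arcsine square-root transformed scale. A null probe has
#' `beta1 = 0`.
#'
#' @param n_probes Number of probes.
#' @param beta0 Intercept on the transformed scale; recycled. The default
#'   centres a null probe near beta-value 0.5 for a cohort with mean log
#'   folate `mean_exposure` (the intercept absorbs `-beta1 * mean_exposure`).
#' @param beta1 Causal effect of log RBC folate on transformed methylation.
#' @param beta2 Conception effect.
#' @param beta_c Confounder loading.
#' @param sigma_y Noise standard deviation (> 0).
#' @param mean_exposure Mean exposure used to centre the default intercept.
#' @return A data frame of class `"effect_profile"` with columns `beta0`,
#'   `beta1`, `beta2`, `beta_c`, `sigma_y`.
#' @export
effect_profile <- function(n_probes, beta0 = NULL, beta1 = 0, beta2 = 0,
                           beta_c = 0, sigma_y = 0.05,
                           mean_exposure = 6.66) {
  if (n_probes < 0) stop("n_probes must be non-negative")
  if (any(sigma_y <= 0)) stop("sigma_y must be positive")
  b1 <- rep_len(beta1, n_probes)
  if (is.null(beta0)) beta0 <- pi / 4 - b1 * mean_exposure
  out <- data.frame(beta0 = rep_len(beta0, n_probes), beta1 = b1,
                    beta2 = rep_len(beta2, n_probes),
                    beta_c = rep_len(beta_c, n_probes),
                    sigma_y = rep_len(sigma_y, n_probes))
  class(out) <- c("effect_profile", "data.frame")
  out
}

#' Generate a synthetic probe annotation panel
#'
#' Produces `n_probes` annotations with deterministic counts of
#' sex-chromosome and cross-reactive probes (`round(n_probes * frac)`
#' each, disjoint by default), plus the identities of probes that will
#' carry at least one missing beta-value.
#'
#' @param n_probes Number of probes (>= 0).
#' @param frac_sex Fraction placed on chromosomes X/Y.
#' @param frac_cross_reactive Fraction flagged cross-reactive (a
#'   precomputed alignment-based flag: >= 40 matching bases, >= 90%
#'   identity, end-nucleotide match, gapless).
#' @param frac_missing Fraction of retained-category probes marked to
#'   receive missing beta-values.
#' @param seed Integer seed (placement of positions and gene symbols).
#' @param overlap Allow the sex / cross-reactive categories to overlap.
#' @return A list with `annotations` (data frame: `probe_id`, `chromosome`,
#'   `position`, `gene_symbols` — semicolon-separated, closest gene first —,
#'   `island_relation`, `cross_reactive`) and `missing_probes` (character
#'   vector of probe ids to receive missing values).
#' @export
gen_probe_panel <- function(n_probes, frac_sex = 0, frac_cross_reactive = 0,
                            frac_missing = 0, seed = 1, overlap = FALSE) {
  for (f in c(frac_sex, frac_cross_reactive, frac_missing))
    if (f < 0 || f > 1) stop("fractions must lie in [0, 1]")
  if (n_probes == 0) {
    return(list(annotations = data.frame(probe_id = character(0),
                                         chromosome = character(0),
                                         position = integer(0),
                                         gene_symbols = character(0),
                                         island_relation = character(0),
                                         cross_reactive = logical(0),
                                         stringsAsFactors = FALSE),
                missing_probes = character(0)))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(substream_seed(seed, 3L))
  n_sex <- round(n_probes * frac_sex)
  n_cr <- round(n_probes * frac_cross_reactive)
  idx <- seq_len(n_probes)
  sex_idx <- utils::head(idx, n_sex)
  cr_pool <- if (overlap) idx else setdiff(idx, sex_idx)
  cr_idx <- utils::head(cr_pool, n_cr)
  chrom <- sample(as.character(1:22), n_probes, replace = TRUE)
  chrom[sex_idx] <- sample(c("X", "Y"), length(sex_idx), replace = TRUE)
  ann <- data.frame(
    probe_id = sprintf("cg%08d", idx),
    chromosome = chrom,
    position = sort(sample.int(2.4e8, n_probes)),
    gene_symbols = sprintf("GENE%04d", idx),
    island_relation = sample(c("island", "shore", "none"), n_probes,
                             replace = TRUE, prob = c(0.6, 0.2, 0.2)),
    cross_reactive = idx %in% cr_idx,
    stringsAsFactors = FALSE)
  retained <- setdiff(idx, union(sex_idx, cr_idx))
  n_miss <- round(n_probes * frac_missing)
  miss_idx <- utils::head(retained, n_miss)
  list(annotations = ann, missing_probes = ann$probe_id[miss_idx])
}

#' Generate a synthetic methylation panel
#'
#' Generates per-probe transformed methylation from the outcome model in
#' [effect_profile()], maps it back to the beta-value scale via
#' `sin^2(y)` (after clipping `y` to `[0, pi/2]`), and optionally injects
#' missing values, matching (M, U) intensity pairs, and non-normal
#' "distractor" probes (bimodal mixtures) for the normality filter to
#' remove.
#'
#' @param cohort Cohort data frame from [gen_cohort()].
#' @param confounders The confounder vector `u` returned by [gen_cohort()]
#'   (the same draws; the outcome and exposure share it).
#' @param profile An [effect_profile()] with one row per probe.
#' @param annotations Probe annotation data frame (one row per probe),
#'   e.g. from [gen_probe_panel()].
#' @param seed Integer seed.
#' @param missing_probes Probe ids to receive missing beta-values.
#' @param missing_rate Fraction of subjects set missing within each probe
#'   in `missing_probes` (at least one subject).
#' @param intensities If `TRUE`, also generate (M, U) pairs consistent
#'   with each beta-value (`beta = M / (M + U + 100)` exactly).
#' @param nonnormal_probes Probe ids whose values are replaced by an
#'   extreme bimodal mixture on the transformed scale.
#' @return A list of class `"methylation_panel"` with `annotations`,
#'   `betas` (probes x subjects matrix, `NA` for missing), and optionally
#'   `M` and `U` intensity matrices.
#' @export
gen_methylation <- function(cohort, confounders, profile, annotations,
                            seed = 1, missing_probes = character(0),
                            missing_rate = 0.05, intensities = FALSE,
                            nonnormal_probes = character(0)) {
  n <- nrow(cohort)
  p <- nrow(profile)
  if (length(confounders) != n)
    stop("confounders length (", length(confounders),
         ") does not match cohort size (", n, ")")
  if (nrow(annotations) != p)
    stop("profile has ", p, " rows but annotations has ", nrow(annotations))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(substream_seed(seed, 4L))
  A <- cohort$log_rbc_folate
  C <- cohort$conception_planned
  mu <- outer(profile$beta0, rep(1, n)) +
    outer(profile$beta1, A) + outer(profile$beta2, C) +
    outer(profile$beta_c, confounders)
  y <- mu + matrix(stats::rnorm(p * n), p, n) * profile$sigma_y
  pid <- annotations$probe_id
  if (length(nonnormal_probes)) {
    ni <- match(nonnormal_probes, pid)
    if (anyNA(ni)) stop("unknown non-normal probe id")
    for (i in ni) {
      side <- stats::rbinom(n, 1L, 0.5)
      y[i, ] <- ifelse(side == 1L,
                       stats::rnorm(n, pi / 2 - 0.08, 0.02),
                       stats::rnorm(n, 0.08, 0.02))
    }
  }
  y <- pmin(pmax(y, 0), pi / 2)
  betas <- sin(y)^2
  dimnames(betas) <- list(pid, cohort$subject_id)

  out <- list(annotations = annotations, betas = betas)
  if (intensities) {
    # cap near-saturated betas so U = total - M stays positive
    betas <- pmin(betas, 0.995)
    out$betas <- betas
    set.seed(substream_seed(seed, 5L))
    # total signal M + U per (probe, subject); beta = M/(M+U+100) exactly
    total <- matrix(stats::runif(p * n, 2000, 10000), p, n)
    M <- betas * (total + 100)
    U <- total - M
    neg <- U < 0  # very high beta with low total: bump the total signal
    if (any(neg)) {
      total[neg] <- total[neg] + 200 * betas[neg] / pmax(1 - betas[neg], 1e-3)
      M[neg] <- betas[neg] * (total[neg] + 100)
      U[neg] <- total[neg] - M[neg]
    }
    dimnames(M) <- dimnames(U) <- dimnames(betas)
    out$M <- M
    out$U <- U
  }
  if (length(missing_probes)) {
    set.seed(substream_seed(seed, 6L))
    mi <- match(missing_probes, pid)
    if (anyNA(mi)) stop("unknown missing probe id")
    for (i in mi) {
      k <- max(1L, stats::rbinom(1L, n, missing_rate))
      out$betas[i, sample.int(n, k)] <- NA_real_
    }
  }
  class(out) <- "methylation_panel"
  out
}

#' @export
print.methylation_panel <- function(x, ...) {
  cat(sprintf("Methylation panel: %d probes x %d subjects\n",
              nrow(x$betas), ncol(x$betas)))
  cat(sprintf("  missing beta-values: %d; intensities: %s\n",
              sum(is.na(x$betas)), if (is.null(x$M)) "no" else "yes"))
  invisible(x)
}
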