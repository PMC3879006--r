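#' Read and validate a pipeline configuration (YAML)
#'
#' The configuration is a plain-text YAML file with sections `simulate`
#' (cohort and panel generator parameters), `preprocess` (`alpha`),
#' `scan` (`alpha`, `bootstrap_reps`, `multiplicity`), `confound_sim`
#' (`levels`, `n_reps`, `y_from_simulated_x`), `enrich` (optional
#' `gene2term` path), plus a global `seed` and `out_dir`. Validation is
#' fail-fast: every error is reported before any stage runs.
#'
#' @param path Path to the YAML file.
#' @return A validated config list of class `"run_config"`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg A configuration list (as parsed from YAML).
#' @export
validate_run_config <- function(cfg) {
  defaults <- list(
    seed = 1L, out_dir = ".",
    simulate = list(n = 50, n_probes = 200, n_signal = 5,
                    signal_beta1 = 0.3, frac_sex = 0.1,
                    frac_cross_reactive = 0.05, frac_missing = 0.03,
                    n_nonnormal = 5,
                    maf677 = 0.33, maf1298 = 0.23, alpha0 = 6.5,
                    alpha1 = 0.12, alpha2 = 0.05, alpha_c = 0,
                    sigma_x = 0.28, p_planned = 0.5, sigma_y = 0.05),
    preprocess = list(alpha = 0.05),
    scan = list(alpha = 0.05, bootstrap_reps = 1000, multiplicity = FALSE),
    confound_sim = list(levels = c(0.1, 0.2), n_reps = 10000,
                        y_from_simulated_x = FALSE),
    enrich = list(gene2term = NULL, n_terms = 20))
  cfg <- utils::modifyList(defaults, cfg %||% list())
  errs <- character(0)
  chk <- function(ok, msg) if (!isTRUE(ok)) errs <<- c(errs, msg)
  chk(is.numeric(cfg$seed) && cfg$seed == round(cfg$seed), "seed must be an integer")
  chk(cfg$preprocess$alpha > 0 && cfg$preprocess$alpha < 1,
      "preprocess$alpha must lie in (0, 1)")
  chk(cfg$scan$alpha > 0 && cfg$scan$alpha < 1, "scan$alpha must lie in (0, 1)")
  chk(cfg$scan$bootstrap_reps >= 1, "scan$bootstrap_reps must be >= 1")
  chk(cfg$confound_sim$n_reps >= 1, "confound_sim$n_reps must be >= 1")
  chk(all(cfg$confound_sim$levels >= 0), "confound_sim$levels must be >= 0")
  chk(cfg$simulate$n >= 2, "simulate$n must be >= 2")
  chk(cfg$simulate$n_probes >= 1, "simulate$n_probes must be >= 1")
  if (length(errs)) stop("invalid configuration:\n  - ",
                         paste(errs, collapse = "\n  - "))
  class(cfg) <- "run_config"
  cfg
}

.log_stage <- function(con, msg) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), msg)
  message(line)
  if (!is.null(con)) writeLines(line, con)
}

#' Run the full pipeline from one configuration
#'
#' Executes, in fixed order: synthetic-cohort + panel generation,
#' preprocessing (probe restriction, transform, normality filter),
#' instrument QC, the genome-wide 2SLS/OLS scan with bootstrap CIs for
#' significant loci, the unmeasured-confounding simulation sweep (truth
#' taken from the significant loci, or from the strongest loci when none
#' are significant), and gene-set enrichment. Each stage writes its
#' outputs under `out_dir` before the next reads them; failures abort
#' with the failing stage named.
#'
#' @param config A `run_config` (or path to one).
#' @return A run manifest (list): config echo, package version, per-stage
#'   row counts, seed provenance.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(out, "run.log")
  con <- file(logfile, open = "wt")
  on.exit(close(con))
  manifest <- list(config = unclass(config),
                   package_version = as.character(utils::packageVersion("mrewas")),
                   seed = config$seed, stages = list())
  stage <- function(name, expr) {
    .log_stage(con, paste("stage:", name))
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  sim <- config$simulate
  seed <- config$seed

  gen <- stage("simulate", {
    spec <- cohort_spec(n = sim$n, maf677 = sim$maf677, maf1298 = sim$maf1298,
                        alpha0 = sim$alpha0, alpha1 = sim$alpha1,
                        alpha2 = sim$alpha2, alpha_c = sim$alpha_c,
                        sigma_x = sim$sigma_x, p_planned = sim$p_planned,
                        seed = seed)
    ch <- gen_cohort(spec)
    panel_spec <- gen_probe_panel(sim$n_probes, sim$frac_sex,
                                  sim$frac_cross_reactive, sim$frac_missing,
                                  seed = seed)
    b1 <- rep(0, sim$n_probes)
    # signal probes placed among the retained (autosomal, unique) probes
    ann <- panel_spec$annotations
    eligible <- which(!(ann$chromosome %in% c("X", "Y")) &
                        !ann$cross_reactive &
                        !(ann$probe_id %in% panel_spec$missing_probes))
    sig_idx <- utils::head(eligible, sim$n_signal)
    b1[sig_idx] <- sim$signal_beta1
    nn <- utils::tail(eligible, sim$n_nonnormal)
    profile <- effect_profile(sim$n_probes, beta1 = b1, sigma_y = sim$sigma_y,
                              mean_exposure = mean(ch$cohort$log_rbc_folate))
    panel <- gen_methylation(ch$cohort, ch$confounder, profile, ann,
                             seed = seed,
                             missing_probes = panel_spec$missing_probes,
                             nonnormal_probes = ann$probe_id[nn])
    write_cohort(ch$cohort, file.path(out, "cohort.csv"))
    write_betas(panel$betas, file.path(out, "betas.tsv"))
    write_annotations(ann, file.path(out, "annotations.csv"))
    list(cohort = ch$cohort, panel = panel,
         signal_probes = ann$probe_id[sig_idx])
  })
  manifest$stages$simulate <- list(n_subjects = nrow(gen$cohort),
                                   n_probes = nrow(gen$panel$betas))

  prep <- stage("preprocess", {
    pp <- preprocess_panel(gen$panel, alpha = config$preprocess$alpha)
    write_betas(pp$y, file.path(out, "transformed.tsv"))
    write_filter_report(pp$report, file.path(out, "filter_report.tsv"))
    pp
  })
  manifest$stages$preprocess <- as.list(prep$report$counts)

  qc <- stage("qc", {
    q <- qc_report(gen$cohort)
    utils::capture.output(print(q), file = file.path(out, "qc_report.txt"))
    q
  })
  manifest$stages$qc <- list(first_stage_F = qc$first_stage$F)

  scan <- stage("scan", {
    sc <- genomewide_scan(prep$y, gen$cohort, alpha = config$scan$alpha,
                          betas = prep$betas,
                          bootstrap_reps = config$scan$bootstrap_reps,
                          seed = seed,
                          multiplicity = isTRUE(config$scan$multiplicity))
    ranked <- rank_loci(sc$results)
    utils::write.table(ranked, file.path(out, "locus_results.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    write_scan_bed(ranked, prep$annotations, file.path(out, "scan.bed"))
    if (!is.null(sc$comparison))
      utils::capture.output(print(sc$comparison),
                            file = file.path(out, "comparison.txt"))
    sc
  })
  manifest$stages$scan <- list(n_loci = nrow(scan$results),
                               n_significant = sum(scan$results$significant))

  sweep_tab <- stage("confound_sim", {
    r <- scan$results
    picked <- rank_loci(r)
    picked <- utils::head(picked[if (any(r$significant)) picked$significant
                                 else TRUE, , drop = FALSE], 7L)
    s1 <- ols_fit(gen$cohort$log_rbc_folate,
                  cbind(1, gen$cohort$variant_count,
                        gen$cohort$conception_planned))
    truth <- data.frame(locus = picked$probe_id,
                        alpha0 = s1$coefficients[1],
                        alpha1 = s1$coefficients[2],
                        alpha2 = s1$coefficients[3],
                        beta0 = 0, beta1 = picked$tsls_estimate, beta2 = 0)
    tab <- confounding_sweep(gen$cohort, truth,
                             levels = config$confound_sim$levels,
                             n_reps = config$confound_sim$n_reps,
                             seed = seed,
                             y_from_simulated_x =
                               isTRUE(config$confound_sim$y_from_simulated_x))
    utils::write.table(tab, file.path(out, "confounding_sweep.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    tab
  })
  manifest$stages$confound_sim <- list(n_rows = nrow(sweep_tab))

  enr <- stage("enrich", {
    sig_probes <- scan$results$probe_id[scan$results$significant]
    universe <- nearest_gene_assignment(prep$annotations$probe_id,
                                        prep$annotations)
    genes <- if (length(sig_probes))
      nearest_gene_assignment(sig_probes, prep$annotations) else character(0)
    map <- if (!is.null(config$enrich$gene2term))
      utils::read.csv(config$enrich$gene2term, stringsAsFactors = FALSE)
    else synthetic_gene2term(universe, n_terms = config$enrich$n_terms,
                             seed = seed)
    tab <- if (length(genes)) enrich(genes, map, universe)
    else data.frame(term = character(0), a = integer(0), K = integer(0),
                    m = integer(0), N = integer(0), odds_ratio = numeric(0),
                    p_value = numeric(0))
    utils::write.table(tab, file.path(out, "enrichment.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    tab
  })
  manifest$stages$enrich <- list(n_terms = nrow(enr))

  manifest_path <- file.path(out, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_path)
  .log_stage(con, "done")
  invisible(manifest)
}

#' Synthetic gene-to-term map
#'
#' Random flat annotation map for exercising the enrichment stage when no
#' real gene-to-term file is supplied; term sizes are drawn log-uniformly
#' between 3 and a quarter of the universe.
#'
#' @param universe_genes Character vector of genes.
#' @param n_terms Number of terms.
#' @param seed Integer seed.
#' @return Data frame with columns `term`, `gene`.
#' @export
synthetic_gene2term <- function(universe_genes, n_terms = 20, seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(substream_seed(seed, 11L))
  ng <- length(universe_genes)
  sizes <- pmax(3L, pmin(ng, round(exp(stats::runif(n_terms, log(3),
                                                    log(max(4, ng / 4)))))))
  do.call(rbind, lapply(seq_len(n_terms), function(i) {
    data.frame(term = sprintf("TERM%03d", i),
               gene = sample(universe_genes, sizes[i]),
               stringsAsFactors = FALSE)
  }))
}
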