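# Delimited-text readers/writers for the pipeline's tables. Cohorts and
# annotations travel as CSV, methylation matrices as TSV with probe_id in
# the first column and "NA" for missing beta-values, intensities as TSV
# with paired M_<id>/U_<id> columns.

#' Write / read a cohort table (CSV)
#'
#' @param cohort Cohort data frame.
#' @param path File path.
#' @return `read_cohort` returns the cohort data frame.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read a methylation beta-value matrix (TSV)
#'
#' First column `probe_id`, one column per subject, missing values as
#' `NA`.
#'
#' @param betas Probes x subjects matrix with dimnames.
#' @param path File path.
#' @return `read_betas` returns the matrix with dimnames restored.
#' @export
write_betas <- function(betas, path) {
  df <- data.frame(probe_id = rownames(betas), betas,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_betas
#' @export
read_betas <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$probe_id
  m
}

#' Write / read a probe annotation table (CSV)
#'
#' @param annotations Annotation data frame.
#' @param path File path.
#' @return `read_annotations` returns the data frame.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.csv(annotations, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  ann <- utils::read.csv(path, stringsAsFactors = FALSE)
  ann$chromosome <- as.character(ann$chromosome)
  ann
}

#' Write intensity matrices as paired-column TSV
#'
#' One row per probe; columns `M_<subject>` and `U_<subject>` for each
#' subject.
#'
#' @param M,U Intensity matrices with dimnames.
#' @param path File path.
#' @export
write_intensities <- function(M, U, path) {
  ids <- colnames(M)
  df <- data.frame(probe_id = rownames(M), stringsAsFactors = FALSE)
  for (s in ids) {
    df[[paste0("M_", s)]] <- M[, s]
    df[[paste0("U_", s)]] <- U[, s]
  }
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_intensities
#' @export
read_intensities <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mcols <- grep("^M_", names(df), value = TRUE)
  ids <- sub("^M_", "", mcols)
  M <- as.matrix(df[, paste0("M_", ids), drop = FALSE])
  U <- as.matrix(df[, paste0("U_", ids), drop = FALSE])
  dimnames(M) <- dimnames(U) <- list(df$probe_id, ids)
  list(M = M, U = U)
}

#' Write a filter report as structured text
#'
#' Tab-separated `stage`, `count`, `n_removed` rows.
#'
#' @param report A `filter_report`.
#' @param path File path.
#' @export
write_filter_report <- function(report, path) {
  cnt <- report$counts
  removed <- c(0, -diff(cnt))
  df <- data.frame(stage = names(cnt), count = unname(cnt),
                   n_removed = removed)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write scan results as a BED-style browser track
#'
#' 0-based half-open intervals: `chrom`, `start`, `start + 2` (the CpG
#' dinucleotide), `probe_id`, `tsls_p`.
#'
#' @param results Scan results data frame (`probe_id`, `tsls_p`).
#' @param annotations Annotation data frame (`probe_id`, `chromosome`,
#'   `position`).
#' @param path File path.
#' @export
write_scan_bed <- function(results, annotations, path) {
  idx <- match(results$probe_id, annotations$probe_id)
  bed <- data.frame(chrom = annotations$chromosome[idx],
                    start = annotations$position[idx],
                    end = annotations$position[idx] + 2L,
                    name = results$probe_id,
                    score = signif(results$tsls_p, 6))
  utils::write.table(bed, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}
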