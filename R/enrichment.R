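#' Hypergeometric gene-set enrichment with sample odds ratios
#'
#' For each annotation term with at least one hit in the significant
#' subset, builds the 2x2 table (`a` hits in subset, `b = K - a` term
#' genes outside the subset, `c = m - a` subset genes outside the term,
#' `d = N - K - m + a`), reports the uncorrected cross-product odds ratio
#' `(a d)/(b c)` (`Inf` when `b c = 0` and `a d > 0`) and the upper-tail
#' hypergeometric p-value `P[X >= a]`. The universe is the set of genes
#' with at least one annotation present on the panel.
#'
#' @param subset_genes Character vector of significant genes (must be a
#'   subset of the universe).
#' @param gene2term Data frame with columns `term` and `gene`.
#' @param universe_genes Character vector; the analyzed-gene universe.
#' @return Data frame sorted by p ascending (ties: odds ratio descending,
#'   then term): `term`, `a`, `K`, `m`, `N`, `odds_ratio`, `p_value`.
#' @examples
#' map <- data.frame(term = rep("t1", 10), gene = paste0("g", 1:10))
#' enrich(c("g1", "g2"), map, paste0("g", 1:50))
#' @export
enrich <- function(subset_genes, gene2term, universe_genes) {
  subset_genes <- unique(as.character(subset_genes))
  universe_genes <- unique(as.character(universe_genes))
  if (length(universe_genes) == 0) stop("empty gene universe")
  missing <- setdiff(subset_genes, universe_genes)
  if (length(missing))
    stop("subset gene(s) absent from the universe: ",
         paste(missing, collapse = ", "))
  g2t <- gene2term[gene2term$gene %in% universe_genes, , drop = FALSE]
  # universe restricted to genes carrying at least one annotation
  annotated <- unique(g2t$gene)
  N <- length(annotated)
  sub_ann <- intersect(subset_genes, annotated)
  m <- length(sub_ann)
  if (N == 0) stop("no universe gene carries an annotation")
  pairs <- unique(data.frame(term = as.character(g2t$term),
                             gene = as.character(g2t$gene),
                             stringsAsFactors = FALSE))
  term_genes <- split(pairs$gene, pairs$term)
  rows <- lapply(names(term_genes), function(tm) {
    genes <- term_genes[[tm]]
    K <- length(genes)
    a <- sum(genes %in% sub_ann)
    if (a == 0) return(NULL)
    b <- K - a
    cc <- m - a
    d <- N - K - m + a
    or <- if (b * cc == 0) {
      if (a * d > 0) Inf else NaN
    } else (a * d) / (b * cc)
    p <- stats::phyper(a - 1, K, N - K, m, lower.tail = FALSE)
    data.frame(term = tm, a = a, K = K, m = m, N = N,
               odds_ratio = or, p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    return(data.frame(term = character(0), a = integer(0), K = integer(0),
                      m = integer(0), N = integer(0), odds_ratio = numeric(0),
                      p_value = numeric(0), stringsAsFactors = FALSE))
  out <- out[order(out$p_value, -out$odds_ratio, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Nearest-gene assignment for significant probes
#'
#' Takes, for each significant probe, the first listed gene symbol in its
#' annotation (the closest gene by convention), collapsing duplicates.
#' Probes with no annotated gene are skipped with a warning.
#'
#' @param significant_probes Character vector of probe ids.
#' @param annotations Annotation data frame with `probe_id` and
#'   `gene_symbols` (semicolon-separated, closest first).
#' @return Character vector of unique gene symbols.
#' @export
nearest_gene_assignment <- function(significant_probes, annotations) {
  if (length(significant_probes) == 0) return(character(0))
  idx <- match(significant_probes, annotations$probe_id)
  if (anyNA(idx))
    stop("probe(s) absent from annotations: ",
         paste(significant_probes[is.na(idx)], collapse = ", "))
  syms <- annotations$gene_symbols[idx]
  first <- vapply(strsplit(syms, ";[[:space:]]*"),
                  function(v) if (length(v) && nzchar(v[1])) v[1] else NA_character_,
                  character(1))
  if (anyNA(first)) {
    warning(sum(is.na(first)), " probe(s) with no annotated gene skipped")
    first <- first[!is.na(first)]
  }
  unique(first)
}
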