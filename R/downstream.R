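# Hypergeometric gene-set enrichment with BH FDR, and the group-wise
# circRNA-mRNA correlation-pattern comparison.

#' Hypergeometric gene-set over-representation test
#'
#' For each term, tests whether the query gene set is enriched relative to
#' the universe using the upper-tail hypergeometric probability
#' `P(X >= k)` with `k` query genes in the term, `K` universe genes in the
#' term, query size `n` and universe size `N`. P-values are BH-adjusted
#' across all tested terms; a term is flagged significant when both
#' `fdr < fdr_threshold` and `p < p_threshold` hold.
#'
#' @param query Character vector of query gene IDs (must be a subset of
#'   `universe`).
#' @param annotation Term-to-gene table with columns `term_id`, `term_name`,
#'   `gene_id` (see [read_gene_sets()]).
#' @param universe Character vector of background gene IDs; defaults to all
#'   annotated genes.
#' @param p_threshold Raw p-value threshold (default 0.01).
#' @param fdr_threshold BH FDR threshold (default 0.05).
#' @return `data.frame` sorted by p-value with columns `term_id`,
#'   `term_name`, `k`, `K`, `n`, `N`, `p_value`, `fdr`, `significant`.
#' @export
hypergeom_enrich <- function(query, annotation,
                             universe = unique(annotation$gene_id),
                             p_threshold = 0.01, fdr_threshold = 0.05) {
  query <- unique(query)
  universe <- unique(universe)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    stop("query gene(s) not in the universe: ", paste(outside, collapse = ", "))
  }
  terms <- split(annotation, annotation$term_id)
  if (!length(terms)) stop("annotation table contains no terms")
  N <- length(universe)
  n <- length(query)
  rows <- lapply(terms, function(tt) {
    genes <- intersect(unique(tt$gene_id), universe)
    K <- length(genes)
    k <- length(intersect(query, genes))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = tt$term_id[1], term_name = tt$term_name[1],
               k = k, K = K, n = n, N = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$fdr < fdr_threshold & out$p_value < p_threshold
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pairwise circRNA-mRNA correlation pattern within one group
#'
#' Computes the correlation between every (circRNA, mRNA) pair over the
#' samples of one group. Pairs where either vector is constant are flagged
#' undefined (`NA`) and excluded from the summary statistics. `coherence` is
#' the mean of the defined correlations and `frac_positive` the fraction of
#' defined entries that are positive; together they operationalise the
#' "parallel vs chaotic" contrast seen in such heatmaps.
#'
#' @param circ_expr [expression_matrix()] of circRNA expression (TPM).
#' @param mrna_expr [expression_matrix()] of mRNA expression over the same
#'   samples.
#' @param group `"case"` or `"control"`.
#' @param pairs Optional `data.frame` with columns `circ_id`, `mrna_id`
#'   restricting the grid; default all combinations.
#' @param method Correlation method, `"pearson"` (default) or `"spearman"`.
#' @return A list of class `correlation_pattern` with `group`, `matrix`
#'   (circRNAs x mRNAs), `coherence`, `frac_positive`.
#' @export
correlation_pattern <- function(circ_expr, mrna_expr, group,
                                pairs = NULL,
                                method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(inherits(circ_expr, "expression_matrix"),
            inherits(mrna_expr, "expression_matrix"),
            group %in% c("case", "control"))
  cols <- names(circ_expr$groups)[circ_expr$groups == group]
  if (length(cols) < 3) stop("need at least 3 samples in group '", group, "'")
  if (!all(cols %in% colnames(mrna_expr$values))) {
    stop("mRNA matrix is missing sample(s) of group '", group, "'")
  }
  cv <- circ_expr$values[, cols, drop = FALSE]
  mv <- mrna_expr$values[, cols, drop = FALSE]
  if (!is.null(pairs)) {
    cv <- cv[unique(pairs$circ_id), , drop = FALSE]
    mv <- mv[unique(pairs$mrna_id), , drop = FALSE]
  }
  suppressWarnings(
    cm <- stats::cor(t(cv), t(mv), method = method)
  )
  if (!is.null(pairs)) {
    mask <- matrix(FALSE, nrow(cm), ncol(cm), dimnames = dimnames(cm))
    mask[cbind(match(pairs$circ_id, rownames(cm)),
               match(pairs$mrna_id, colnames(cm)))] <- TRUE
    cm[!mask] <- NA_real_
  }
  defined <- cm[is.finite(cm)]
  structure(list(group = group, matrix = cm,
                 coherence = if (length(defined)) mean(defined) else NA_real_,
                 frac_positive = if (length(defined)) mean(defined > 0) else NA_real_),
            class = "correlation_pattern")
}

#' Compare two correlation patterns
#'
#' Reports the difference in coherence (mean correlation) and in the
#' fraction of positive correlations between two groups' patterns, plus the
#' correlation between the two vectorised matrices over their mutually
#' defined entries.
#'
#' @param a,b `correlation_pattern` objects over the same pair grid.
#' @return List with `coherence_diff` (a - b), `frac_positive_diff`,
#'   `matrix_correlation`, `n_pairs_compared`.
#' @export
pattern_divergence <- function(a, b) {
  stopifnot(inherits(a, "correlation_pattern"),
            inherits(b, "correlation_pattern"))
  if (!identical(dim(a$matrix), dim(b$matrix))) {
    stop("patterns are defined on different pair grids")
  }
  va <- as.vector(a$matrix); vb <- as.vector(b$matrix)
  ok <- is.finite(va) & is.finite(vb)
  if (!any(ok)) stop("no mutually defined correlation entries")
  mc <- if (stats::sd(va[ok]) == 0 || stats::sd(vb[ok]) == 0) {
    NA_real_
  } else {
    stats::cor(va[ok], vb[ok])
  }
  list(coherence_diff = a$coherence - b$coherence,
       frac_positive_diff = a$frac_positive - b$frac_positive,
       matrix_correlation = mc,
       n_pairs_compared = sum(ok))
}
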