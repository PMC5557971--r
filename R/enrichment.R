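#' Transfer GO terms to genes via Pfam domains
#'
#' A gene's GO set is the union, over its Pfam accessions, of the mapped GO
#' ids. Genes with no mapped domain get the empty set but remain in the
#' background. Pfam accessions absent from the mapping contribute nothing
#' and are summarized in the `unmapped_pfams` attribute.
#'
#' @param domain_table data.frame with columns `gene_id`, `pfam`.
#' @param pfam2go named list from [read_pfam2go()].
#' @param genes character vector of all background gene ids (defaults to the
#'   genes of `domain_table`).
#' @return named list gene id -> character vector of GO ids, with attribute
#'   `unmapped_pfams`.
#' @export
annotate_genes_go <- function(domain_table, pfam2go, genes = NULL) {
  genes <- genes %||% unique(domain_table$gene_id)
  out <- setNames(vector("list", length(genes)), genes)
  for (g in genes) out[[g]] <- character(0)
  unmapped <- setdiff(unique(domain_table$pfam), names(pfam2go))
  known <- domain_table[domain_table$pfam %in% names(pfam2go) &
                          domain_table$gene_id %in% genes, , drop = FALSE]
  if (nrow(known)) {
    gos <- pfam2go[known$pfam]
    per_gene <- split(gos, known$gene_id)
    for (g in names(per_gene))
      out[[g]] <- sort(unique(unlist(per_gene[[g]], use.names = FALSE)))
  }
  attr(out, "unmapped_pfams") <- unmapped
  out
}

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` genes from a
#' background of `N` of which `K` carry the term. Exact (log-space tail from
#' the stats library).
#'
#' @param k observed carriers in the drawn set.
#' @param K carriers in the background.
#' @param n drawn set size.
#' @param N background size.
#' @return probability (vectorized over the arguments).
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  bad <- k < 0 | K < 0 | n < 0 | N < 0 | K > N | n > N | k > n | k > K
  if (any(bad))
    stop_input("inconsistent hypergeometric counts (need 0 <= k <= min(n, K), n <= N, K <= N)")
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' GO term over-representation in a gene set
#'
#' One hypergeometric test per GO term observed at least once in the study
#' set (`k >= 1`); fold enrichment is `(k/n) / (K/N)`; the Bonferroni
#' multiplier is the number of terms tested for this set, and `p_adj` is
#' capped at 1. Rows are ordered by `p_adj`, then term id.
#'
#' @param de_genes study gene ids (must be a subset of the background).
#' @param background_genes background gene ids.
#' @param gene2go mapping from [annotate_genes_go()].
#' @return data.frame with columns `term_id`, `k`, `n`, `K`, `N`,
#'   `fold_enrichment`, `p_raw`, `p_adj`.
#' @export
enrich_gene_set <- function(de_genes, background_genes, gene2go) {
  if (!all(de_genes %in% background_genes))
    stop_input("study genes must be a subset of the background")
  empty <- data.frame(term_id = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0),
                      fold_enrichment = numeric(0), p_raw = numeric(0),
                      p_adj = numeric(0), stringsAsFactors = FALSE)
  if (length(de_genes) == 0) {
    warning("empty study gene set: no terms tested")
    return(empty)
  }
  N <- length(background_genes)
  n <- length(de_genes)
  bg_terms <- unlist(gene2go[background_genes], use.names = FALSE)
  de_terms <- unlist(gene2go[de_genes], use.names = FALSE)
  if (length(de_terms) == 0) return(empty)
  Ktab <- table(bg_terms)
  ktab <- table(de_terms)
  terms <- sort(names(ktab))
  k <- as.integer(ktab[terms])
  K <- as.integer(Ktab[terms])
  p_raw <- hypergeom_upper_tail(k, K, n, N)
  m <- length(terms)
  out <- data.frame(term_id = terms, k = k, n = n, K = K, N = N,
                    fold_enrichment = (k / n) / (K / N),
                    p_raw = p_raw,
                    p_adj = p.adjust(p_raw, method = "bonferroni", n = m),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_adj, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select significantly up-/down-regulated genes
#'
#' Strict threshold: `q < alpha`. Significant rows with a fold change of
#' exactly zero are assigned to neither set and reported in the
#' `zero_lfc_genes` attribute.
#'
#' @param de_table data.frame from [read_de_table()] or
#'   [simulate_de_table()] (needs `gene_id`, `log2_fold_change`, `q_value`;
#'   the Cuffdiff-dialect column name is also recognized).
#' @param alpha significance threshold on the adjusted p (q) value.
#' @return list with character vectors `up` and `down`.
#' @export
select_de_genes <- function(de_table, alpha = 0.05) {
  lfc <- de_table$log2_fold_change %||% de_table[["log2(fold_change)"]]
  if (is.null(lfc)) stop_input("DE table missing log2 fold-change column")
  q <- de_table$q_value
  sig <- q < alpha
  up <- de_table$gene_id[sig & lfc > 0]
  down <- de_table$gene_id[sig & lfc < 0]
  zero <- de_table$gene_id[sig & lfc == 0]
  if (length(zero))
    warning(length(zero), " significant gene(s) with zero fold change assigned to neither set")
  structure(list(up = up, down = down), zero_lfc_genes = zero)
}

#' Chi-squared test for positional enrichment of DE genes on a contig
#'
#' Builds the 2x2 table `[[de_A, genes_A - de_A], [de_B, genes_B - de_B]]`
#' and applies Pearson's chi-squared test with one degree of freedom,
#' optionally with Yates continuity correction.
#'
#' @param de_a,genes_a DE and total gene counts on the first contig.
#' @param de_b,genes_b same for the comparison contig.
#' @param yates apply continuity correction.
#' @return list with `table`, `statistic`, `df`, `p_value`, `yates`.
#' @export
contig_chi_squared <- function(de_a, genes_a, de_b, genes_b, yates = FALSE) {
  if (de_a > genes_a || de_b > genes_b)
    stop_input("DE counts cannot exceed total gene counts")
  m <- rbind(c(de_a, genes_a - de_a), c(de_b, genes_b - de_b))
  dimnames(m) <- list(contig = c("A", "B"), status = c("DE", "non-DE"))
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected == 0))
    stop_input("expected cell count of zero: use an exact test instead")
  ht <- suppressWarnings(chisq.test(m, correct = yates))
  list(table = m, statistic = unname(ht$statistic), df = 1L,
       p_value = ht$p.value, yates = yates)
}
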