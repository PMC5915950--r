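# Term enrichment: one-sided Fisher exact tests of a study gene set
# against an annotated population, with exclusion of very large terms
# before testing and BH correction across the tested terms.

#' Exclude terms annotated to more than `max_genes` genes
#'
#' Very broad terms dominate enrichment output without being informative;
#' terms with strictly more than `max_genes` annotated genes are removed
#' (3000 by default), and the removal is logged via `message()`.
#'
#' @param annotations data frame with columns `term` and `gene`.
#' @param max_genes inclusive retention bound.
#' @return the filtered annotation data frame.
#' @export
filter_large_terms <- function(annotations, max_genes = 3000) {
  sizes <- tapply(annotations$gene, annotations$term,
                  function(g) length(unique(g)))
  drop <- names(sizes)[sizes > max_genes]
  if (length(drop))
    message("excluding ", length(drop), " term(s) with > ", max_genes,
            " genes: ", paste(utils::head(drop, 5), collapse = ", "),
            if (length(drop) > 5) ", ..." else "")
  annotations[!annotations$term %in% drop, , drop = FALSE]
}

#' One-sided Fisher exact p-value for a 2x2 enrichment table
#'
#' Upper hypergeometric tail `P(X >= k)` for `k` study genes observed in
#' a term of size `K`, with study size `n` and population size `N`.
#' Vectorized over `k`.
#'
#' @param k study genes in the term.
#' @param K term size.
#' @param n study size.
#' @param N population size.
#' @return p-value(s) in `(0, 1]`.
#' @export
fisher_test_p <- function(k, K, n, N) {
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Fisher exact term enrichment
#'
#' For each term, tests over-representation of the study set with the
#' one-sided (greater) Fisher exact test on the 2x2 table: `k` study
#' genes in the term, term size `K`, study size `n`, population size `N`.
#' The p-value is the hypergeometric upper tail
#' `P(X >= k)`; BH adjustment is applied across the tested terms.
#'
#' @param study character vector of study genes (must be a subset of the
#'   population).
#' @param annotations data frame with columns `term`, `gene`; genes
#'   outside the population are ignored.
#' @param population character vector: the gene universe.
#' @return data frame ranked by p: `term`, `k`, `K`, `n`, `N`, `p`, `fdr`.
#' @export
fisher_enrichment <- function(study, annotations, population) {
  study <- unique(study); population <- unique(population)
  bad <- setdiff(study, population)
  if (length(bad))
    stop("study genes absent from population: ",
         paste(utils::head(bad, 10), collapse = ", "))
  ann <- annotations[annotations$gene %in% population, , drop = FALSE]
  terms <- unique(ann$term)
  n <- length(study); N <- length(population)
  rows <- lapply(terms, function(tm) {
    genes <- unique(ann$gene[ann$term == tm])
    K <- length(genes)
    k <- length(intersect(genes, study))
    p <- fisher_test_p(k, K, n, N)
    data.frame(term = tm, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(term = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      fdr = numeric()))
  out$fdr <- bh_adjust(out$p)
  out[order(out$p, out$term), , drop = FALSE]
}
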