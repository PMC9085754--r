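#' Annotation set (gene-set collection)
#'
#' A named collection of gene sets with a background universe, as read from a
#' GMT file or built by [simulate_annotations()]. Term genes are harmonized
#' to the universe; empty terms are rejected.
#'
#' @param terms named list of character vectors (term id -> genes).
#' @param universe background gene universe; defaults to the union of all
#'   term genes.
#' @param descriptions optional named character vector of term descriptions.
#' @return an `annotation_set` list with `terms`, `descriptions`, `universe`.
#' @export
annotation_set <- function(terms, universe = NULL, descriptions = NULL) {
  if (length(terms) && (is.null(names(terms)) || anyDuplicated(names(terms))))
    stop("terms must be uniquely named", call. = FALSE)
  if (is.null(universe))
    universe <- sort(unique(unlist(terms, use.names = FALSE)))
  terms <- lapply(terms, function(g) sort(unique(intersect(g, universe))))
  if (any(lengths(terms) == 0L) && length(terms))
    stop("empty terms after harmonization to the universe", call. = FALSE)
  if (is.null(descriptions))
    descriptions <- setNames(rep("", length(terms)), names(terms))
  structure(list(terms = terms, descriptions = descriptions,
                 universe = universe),
            class = "annotation_set")
}

#' Upper-tail hypergeometric p-value
#'
#' `P[X >= k]` for the overlap `X` between a query of size `n` and a term of
#' size `K` drawn from a universe of size `N`:
#' `sum_{i = k}^{min(K, n)} C(K, i) C(N - K, n - i) / C(N, n)`. Equal to the
#' one-sided Fisher's exact test p-value for the 2x2 overlap table.
#'
#' @param N universe size.
#' @param K term (annotation) size.
#' @param n query size.
#' @param k observed overlap.
#' @return the upper-tail p-value in (0, 1].
#' @export
hypergeometric_pvalue <- function(N, K, n, k) {
  if (any(c(N, K, n, k) < 0) || k > min(K, n) || K > N || n > N)
    stop("inconsistent counts: need 0 <= k <= min(K, n) <= N", call. = FALSE)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Hypergeometric over-representation analysis
#'
#' Tests each annotation term for over-representation of the query gene set
#' by the upper-tail hypergeometric p-value, with Benjamini-Hochberg
#' correction across the tested terms. Query genes absent from the universe
#' are dropped (their count is reported in the `n_dropped` attribute).
#'
#' @param query character vector of gene ids.
#' @param annotations an [annotation_set()].
#' @param fdr_cut significance threshold on the BH-adjusted p-value.
#' @return data.frame sorted by p-value: `term`, `k` (overlap), `K` (term
#'   size), `n` (query size), `N` (universe size), `p`, `fdr`, `significant`,
#'   `genes` (comma-separated overlap).
#' @export
enrich <- function(query, annotations, fdr_cut = 0.05) {
  stopifnot(inherits(annotations, "annotation_set"))
  universe <- annotations$universe
  q0 <- unique(query)
  q <- intersect(q0, universe)
  if (length(q) == 0L)
    stop("query has no overlap with the annotation universe", call. = FALSE)
  N <- length(universe)
  n <- length(q)
  rows <- lapply(names(annotations$terms), function(tm) {
    gs <- annotations$terms[[tm]]
    hit <- intersect(q, gs)
    data.frame(term = tm, k = length(hit), K = length(gs), n = n, N = N,
               p = hypergeometric_pvalue(N, length(gs), n, length(hit)),
               genes = paste(sort(hit), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- p.adjust(out$p, method = "BH")
  out$significant <- out$fdr < fdr_cut
  out <- out[order(out$p, out$term),
             c("term", "k", "K", "n", "N", "p", "fdr", "significant",
               "genes")]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- length(q0) - length(q)
  out
}
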