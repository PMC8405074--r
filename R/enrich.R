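# Local Fisher-exact (hypergeometric upper-tail) gene-set enrichment
# against a GMT library, with BH adjustment across terms and the dual
# ranking criterion: adjusted P ascending, then overlap size descending.

#' One-sided Fisher exact enrichment for a single gene set
#'
#' P(X >= k) for X hypergeometric with population `universe_N`, `K`
#' successes (term size) and `n` draws (query size), where k is the
#' observed query/term overlap.
#'
#' @param query Character vector of query gene symbols (non-empty).
#' @param term_set Character vector of term member symbols.
#' @param universe_N Background universe size (>= query and term sizes).
#' @return List with `overlap_k`, `overlap_genes`, and `p`.
#' @export
fisher_enrich <- function(query, term_set, universe_N) {
  query <- unique(normalize_symbols(query))
  term_set <- unique(normalize_symbols(term_set))
  if (!length(query)) nm_stop("fisher_enrich requires a non-empty query")
  universe_N <- check_count(universe_N, "universe_N")
  if (universe_N < length(query) || universe_N < length(term_set)) {
    nm_stop("universe_N smaller than query or term set")
  }
  overlap <- intersect(query, term_set)
  k <- length(overlap)
  K <- length(term_set)
  n <- length(query)
  p <- if (k == 0) 1 else stats::phyper(k - 1, K, universe_N - K, n, lower.tail = FALSE)
  list(overlap_k = k, overlap_genes = sort(overlap), p = min(p, 1))
}

#' Enrich a query against every term of a gene-set library
#'
#' BH adjustment is applied across the whole library; rows are filtered to
#' adjusted P below `alpha` and sorted by adjusted P ascending, then by
#' overlap size descending (largest overlaps first among ties).
#'
#' @param query Character vector of gene symbols.
#' @param library A `gene_set_library` from [read_gmt()] (or named list).
#' @param universe Background symbols; defaults to the union of all library
#'   genes. The query is intersected with the universe before testing.
#' @param alpha Adjusted-P filter (set to 1 to keep all rows).
#' @return data.frame: term, overlap_k, set_size_K, query_size_n,
#'   universe_N, overlap (the "k/K" display string), p, p_adj, genes
#'   (comma-joined overlap symbols).
#' @export
enrich_library <- function(query, library, universe = NULL, alpha = 0.05) {
  if (!length(library)) nm_stop("enrich_library requires a non-empty library")
  sets <- lapply(library, function(s) unique(normalize_symbols(s)))
  if (is.null(universe)) universe <- Reduce(union, sets)
  universe <- unique(normalize_symbols(universe))
  query <- intersect(unique(normalize_symbols(query)), universe)
  if (!length(query)) nm_stop("query has no genes in the universe")
  N <- length(universe)
  rows <- lapply(names(sets), function(term) {
    ts <- intersect(sets[[term]], universe)
    fe <- fisher_enrich(query, ts, N)
    data.frame(term = term, overlap_k = fe$overlap_k, set_size_K = length(ts),
               query_size_n = length(query), universe_N = N,
               overlap = sprintf("%d/%d", fe$overlap_k, length(ts)),
               p = fe$p, genes = paste(fe$overlap_genes, collapse = ","),
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out <- out[out$p_adj < alpha, , drop = FALSE]
  out <- out[order(out$p_adj, -out$overlap_k, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out[c("term", "overlap_k", "set_size_K", "query_size_n", "universe_N",
        "overlap", "p", "p_adj", "genes")]
}
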