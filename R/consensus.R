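# Consensus biomarker logic: intersect compartment DEG calls (with
# direction agreement) and then intersect the shared set with the
# topologically central genes, keeping a per-gene provenance trail.

sig_set <- function(deg_table) {
  if (!is.data.frame(deg_table) || !nrow(deg_table)) {
    nm_stop("shared_degs requires non-empty DEG tables")
  }
  needed <- c("gene", "significant", "direction")
  if (!all(needed %in% names(deg_table))) {
    nm_stop("DEG table missing column(s): ",
            paste(setdiff(needed, names(deg_table)), collapse = ", "))
  }
  sig <- deg_table[deg_table$significant, c("gene", "direction")]
  stats::setNames(sig$direction, normalize_symbols(sig$gene))
}

# Combine several DEG tables from one compartment into a single signed
# significant-gene set. combine = "all" keeps genes significant in every
# table (directions must agree); "any" keeps genes significant in at least
# one table (conflicting directions are dropped).
combine_degs <- function(tables, combine = c("all", "any")) {
  combine <- match.arg(combine)
  if (is.data.frame(tables)) tables <- list(tables)
  sets <- lapply(tables, sig_set)
  genes <- switch(combine,
                  all = Reduce(intersect, lapply(sets, names)),
                  any = Reduce(union, lapply(sets, names)))
  keep <- character(0)
  dirs <- character(0)
  for (g in genes) {
    d <- unique(unlist(lapply(sets, function(s) unname(s[g]))))
    d <- d[!is.na(d)]
    if (length(d) == 1) {
      keep <- c(keep, g)
      dirs <- c(dirs, d)
    }
  }
  stats::setNames(dirs, keep)
}

#' Genes significant in both compartments
#'
#' @param tumor,pbmc DEG tables from [call_degs()] (or lists of tables per
#'   compartment, combined per `combine` before intersecting).
#' @param require_same_direction Keep only genes whose direction of change
#'   agrees across compartments (default TRUE).
#' @param combine How multiple tables within one compartment are merged:
#'   "all" (significant in every table) or "any".
#' @return Named character vector: directions keyed by shared gene symbol.
#' @export
shared_degs <- function(tumor, pbmc, require_same_direction = TRUE,
                        combine = "all") {
  t_set <- combine_degs(tumor, combine)
  p_set <- combine_degs(pbmc, combine)
  genes <- intersect(names(t_set), names(p_set))
  if (require_same_direction) {
    genes <- genes[t_set[genes] == p_set[genes]]
  }
  sort_genes <- sort(genes)
  stats::setNames(t_set[sort_genes], sort_genes)
}

#' Intersect shared DEGs with the central gene set
#'
#' @param shared Named direction vector from [shared_degs()] (or a plain
#'   character vector of symbols).
#' @param central A `central_gene_set` from [select_central()].
#' @return A `consensus_result`: list with `shared_degs`, `consensus`, and
#'   a per-gene `provenance` data.frame recording which criteria each
#'   shared gene satisfied.
#' @export
consensus_with_central <- function(shared, central) {
  stopifnot(inherits(central, "central_gene_set"))
  if (!length(central$central)) nm_stop("central gene set is empty")
  genes <- normalize_symbols(if (is.null(names(shared))) shared else names(shared))
  dirs <- if (is.null(names(shared))) rep(NA_character_, length(shared)) else unname(shared)
  prov <- data.frame(gene = genes,
                     direction = dirs,
                     shared_deg = rep(TRUE, length(genes)),
                     is_hub = genes %in% central$hubs,
                     is_high_betweenness = genes %in% central$high_betweenness,
                     row.names = NULL)
  prov$in_central <- prov$is_hub | prov$is_high_betweenness
  prov$consensus <- prov$shared_deg & prov$in_central
  prov <- prov[order(prov$gene), , drop = FALSE]
  rownames(prov) <- NULL
  structure(list(shared_degs = sort(genes),
                 consensus = prov$gene[prov$consensus],
                 provenance = prov),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("<consensus_result> shared DEGs: %s | consensus: %s\n",
              paste(x$shared_degs, collapse = ", "),
              if (length(x$consensus)) paste(x$consensus, collapse = ", ") else "(none)"))
  invisible(x)
}
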