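# Network topology scoring and central-gene selection: node degree,
# Brandes betweenness (unnormalized, endpoints excluded, unordered pairs),
# power-law goodness of fit on the log-log degree histogram, and the
# selection rule combining hubs with the top betweenness quantile.

as_igraph <- function(net) {
  stopifnot(inherits(net, "interaction_network"))
  igraph::graph_from_data_frame(as.data.frame(net$edges), directed = FALSE,
                                vertices = data.frame(name = net$nodes))
}

#' Node degrees of a simple undirected network
#' @param net An [interaction_network()].
#' @return Named integer vector over all nodes (isolated nodes get 0).
#' @export
degree_map <- function(net) {
  stopifnot(inherits(net, "interaction_network"))
  if (!length(net$nodes)) nm_stop("degree_map requires a non-empty network")
  counts <- table(factor(c(net$edges), levels = net$nodes))
  stats::setNames(as.integer(counts), net$nodes)
}

#' Shortest-path betweenness centrality
#'
#' Brandes betweenness with the classic convention: unnormalized counts
#' over unordered source-target pairs, endpoints excluded. Disconnected
#' networks are handled per component (unreachable pairs contribute
#' nothing).
#'
#' @param net An [interaction_network()].
#' @return Named numeric vector over all nodes.
#' @export
betweenness_map <- function(net) {
  stopifnot(inherits(net, "interaction_network"))
  if (!length(net$nodes)) nm_stop("betweenness_map requires a non-empty network")
  g <- as_igraph(net)
  b <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  b[net$nodes]
}

#' Goodness of fit of the degree distribution to a power law
#'
#' Least-squares fit of log(frequency) on log(degree) over the observed
#' positive degrees; returns the coefficient of determination. A high value
#' indicates a fat-tailed (hub-bearing) degree distribution. A
#' zero-variance response (all frequencies equal) is defined as 0.
#'
#' @param degrees Integer degree vector (zeros are dropped; at least three
#'   distinct positive values required).
#' @return R-squared in [0, 1].
#' @export
powerlaw_r2 <- function(degrees) {
  degrees <- degrees[degrees > 0]
  tab <- table(degrees)
  if (length(tab) < 3) {
    nm_stop("powerlaw_r2 undefined: need >= 3 distinct positive degrees")
  }
  x <- log(as.numeric(names(tab)))
  y <- log(as.numeric(tab))
  if (stats::sd(y) < .Machine$double.eps^0.5) return(0)
  suppressWarnings(summary(stats::lm(y ~ x))$r.squared)
}

#' Inclusive top-quantile cutoff
#'
#' Returns the cutoff value such that at least `ceiling(q * n)` items are
#' at or above it; items tied with the cutoff are all selected, so the
#' selected set never depends on sort stability.
#'
#' @param values Numeric vector.
#' @param q Fraction in (0, 1].
#' @return The cutoff value; select with `values >= cutoff`.
#' @export
tail_inclusive_quantile <- function(values, q) {
  if (!length(values)) nm_stop("tail_inclusive_quantile requires non-empty values")
  if (!is.numeric(q) || length(q) != 1 || q <= 0 || q > 1) {
    nm_stop("q must lie in (0, 1]")
  }
  k <- ceiling(q * length(values))
  sort(values, decreasing = TRUE)[k]
}

#' Select central genes: hubs plus the top betweenness quantile
#'
#' The central set is the union of (i) hub genes, chosen either as the
#' top-k nodes by degree (ties broken by degree then symbol) or as all
#' nodes meeting a fixed degree threshold, and (ii) nodes at or above the
#' inclusive top `betweenness_quantile` of betweenness. The quantile is
#' taken over the mediating nodes only (betweenness > 0): nodes lying on no
#' shortest path never qualify as high-betweenness, which keeps the
#' tie-inclusive cutoff meaningful in hub-dominated networks where most
#' nodes have betweenness exactly zero.
#'
#' @param net An [interaction_network()].
#' @param betweenness_quantile Top fraction of betweenness to keep (default
#'   0.20, the top 20 percent).
#' @param degree_rule Either `list(type = "top_k", k = <count>)` or
#'   `list(type = "threshold", value = <degree>)`.
#' @return A `central_gene_set`: list with `hubs`, `high_betweenness`,
#'   `central` (their union) and a per-node `table` (gene, degree,
#'   betweenness, is_hub, is_high_betweenness, is_central).
#' @export
select_central <- function(net, betweenness_quantile = 0.20,
                           degree_rule = list(type = "top_k", k = 6)) {
  deg <- degree_map(net)
  btw <- betweenness_map(net)
  pos <- btw[btw > 0]
  high_b <- if (length(pos)) {
    cutoff <- tail_inclusive_quantile(pos, betweenness_quantile)
    names(btw)[btw >= cutoff]
  } else {
    character(0)
  }
  hubs <- switch(
    degree_rule$type,
    top_k = {
      k <- check_count(degree_rule$k, "degree_rule$k")
      if (k > length(deg)) nm_stop("degree_rule$k exceeds node count")
      names(deg)[order(-deg, names(deg))][seq_len(k)]
    },
    threshold = names(deg)[deg >= degree_rule$value],
    nm_stop("degree_rule$type must be 'top_k' or 'threshold'")
  )
  if (!length(hubs)) {
    warning("degree rule selected no hubs", call. = FALSE)
  }
  central <- sort(union(hubs, high_b))
  tab <- data.frame(gene = names(deg),
                    degree = unname(deg),
                    betweenness = unname(btw),
                    is_hub = names(deg) %in% hubs,
                    is_high_betweenness = names(deg) %in% high_b,
                    row.names = NULL)
  tab$is_central <- tab$is_hub | tab$is_high_betweenness
  structure(list(hubs = sort(hubs), high_betweenness = sort(high_b),
                 central = central, table = tab),
            class = "central_gene_set")
}

#' @export
print.central_gene_set <- function(x, ...) {
  cat(sprintf("<central_gene_set> %d central (%d hubs, %d high-betweenness)\n",
              length(x$central), length(x$hubs), length(x$high_betweenness)))
  invisible(x)
}
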