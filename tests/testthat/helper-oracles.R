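# Independent brute-force oracles used by the unit and acceptance tests.
# Each one recomputes a quantity from its definition by direct enumeration,
# sharing no code with the implementation it checks.

# --- betweenness: enumerate every shortest path between every unordered
# pair and count the paths passing through each intermediate node.
oracle_betweenness <- function(net) {
  nodes <- net$nodes
  adj <- lapply(stats::setNames(nodes, nodes), function(v) {
    unique(c(net$edges[net$edges[, 1] == v, 2], net$edges[net$edges[, 2] == v, 1]))
  })
  all_simple_paths <- function(from, to) {
    out <- list()
    walk <- function(path) {
      last <- path[length(path)]
      if (last == to) {
        out[[length(out) + 1]] <<- path
        return(invisible())
      }
      for (nb in setdiff(adj[[last]], path)) walk(c(path, nb))
    }
    walk(from)
    out
  }
  btw <- stats::setNames(numeric(length(nodes)), nodes)
  n <- length(nodes)
  if (n < 3) return(btw)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    paths <- all_simple_paths(nodes[i], nodes[j])
    if (!length(paths)) next
    lens <- lengths(paths)
    shortest <- paths[lens == min(lens)]
    for (p in shortest) {
      inner <- p[-c(1, length(p))]
      btw[inner] <- btw[inner] + 1 / length(shortest)
    }
  }
  btw
}

# --- hypergeometric upper tail by direct PMF summation
oracle_hyper_tail <- function(k, K, n, N) {
  if (k == 0) return(1)
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# --- BH step-up from its definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# --- DPI by exhaustive triangle scan on an edge data.frame (from, to, mi)
oracle_dpi <- function(edges, eps) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  mi <- stats::setNames(edges$mi, key(edges$from, edges$to))
  removed <- logical(nrow(edges))
  nodes <- unique(c(edges$from, edges$to))
  for (e in seq_len(nrow(edges))) {
    i <- edges$from[e]; j <- edges$to[e]
    for (k in setdiff(nodes, c(i, j))) {
      ik <- key(i, k); jk <- key(j, k)
      if (!is.na(mi[ik]) && !is.na(mi[jk]) &&
          edges$mi[e] < min(mi[ik], mi[jk]) * (1 - eps)) {
        removed[e] <- TRUE
        break
      }
    }
  }
  removed
}

# --- tie-corrected Kruskal-Wallis H from the rank-sum formula
oracle_kw_h <- function(groups) {
  pooled <- unlist(groups)
  N <- length(pooled)
  r <- rank(pooled)
  sizes <- lengths(groups)
  idx <- rep(seq_along(groups), sizes)
  rbar <- tapply(r, idx, mean)
  h <- 12 / (N * (N + 1)) * sum(sizes * (rbar - (N + 1) / 2)^2)
  ties <- table(pooled)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (corr == 0) 0 else h / corr
}

# --- exact permutation mid-P of the KW statistic: enumerate all
# assignments of the pooled observations to the group sizes. Mid-P
# (P(H > h) + 0.5 P(H = h)) is the standard continuity correction when a
# continuous approximation (chi-square) is compared to a discrete
# permutation distribution.
oracle_kw_perm_midp <- function(groups) {
  pooled <- unlist(groups)
  sizes <- lengths(groups)
  h_obs <- oracle_kw_h(groups)
  n_gt <- 0L
  n_eq <- 0L
  total <- 0L
  assign_rec <- function(remaining, g) {
    if (g == length(sizes)) {
      gs <- split(pooled[c(unlist(acc), remaining)],
                  rep(seq_along(sizes), sizes))
      h <- oracle_kw_h(gs)
      total <<- total + 1L
      if (h > h_obs + 1e-9) n_gt <<- n_gt + 1L
      else if (h >= h_obs - 1e-9) n_eq <<- n_eq + 1L
      return(invisible())
    }
    for (pick in utils::combn(remaining, sizes[g], simplify = FALSE)) {
      acc[[g]] <<- pick
      assign_rec(setdiff(remaining, pick), g + 1L)
    }
  }
  acc <- vector("list", length(sizes) - 1L)
  assign_rec(seq_along(pooled), 1L)
  (n_gt + 0.5 * n_eq) / total
}

# --- plug-in MI by direct cell-wise summation over the binned contingency
# table (same equal-frequency binning definition, independent summation)
oracle_mi <- function(x, y, B) {
  bx <- ceiling(rank(x, ties.method = "first") * B / length(x))
  by <- ceiling(rank(y, ties.method = "first") * B / length(y))
  n <- length(x)
  mi <- 0
  for (a in 1:B) for (b in 1:B) {
    pab <- sum(bx == a & by == b) / n
    if (pab > 0) {
      mi <- mi + pab * log(pab / ((sum(bx == a) / n) * (sum(by == b) / n)))
    }
  }
  mi
}

# --- small random simple graphs as interaction networks
random_network <- function(n_nodes, p_edge, symbols = NULL) {
  if (is.null(symbols)) symbols <- LETTERS[seq_len(n_nodes)]
  pairs <- utils::combn(symbols, 2)
  keep <- stats::runif(ncol(pairs)) < p_edge
  interaction_network(t(pairs[, keep, drop = FALSE]), nodes = symbols)
}

# --- Jaccard index between two symbol sets
jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
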