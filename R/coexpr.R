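# Mutual-information co-expression network inference in the ARACNE style:
# plug-in MI on equal-frequency bins, a permutation-null significance
# threshold, data-processing-inequality (DPI) pruning of the weakest edge
# in every MI triangle, and first-neighborhood module extraction around a
# seed gene.

#' Configuration for co-expression inference
#'
#' @param n_bins Bin count per axis for the MI estimator, or "auto" for
#'   floor(sqrt(n)).
#' @param n_permutations Permutations for the null MI threshold (>= 20).
#' @param mi_alpha Significance level for the MI threshold, in (0, 1).
#' @param dpi_tolerance DPI tolerance epsilon in [0, 1]; 0 prunes every
#'   triangle's weakest edge, 1 disables pruning.
#' @return A validated list of class `coexpr_config`.
#' @export
coexpr_config <- function(n_bins = "auto", n_permutations = 100,
                          mi_alpha = 0.05, dpi_tolerance = 0.1) {
  if (!identical(n_bins, "auto")) n_bins <- check_count(n_bins, "n_bins", min = 2)
  n_permutations <- check_count(n_permutations, "n_permutations", min = 20)
  mi_alpha <- check_fraction(mi_alpha, "mi_alpha", lo_open = TRUE, hi_open = TRUE)
  dpi_tolerance <- check_fraction(dpi_tolerance, "dpi_tolerance")
  structure(list(n_bins = n_bins, n_permutations = n_permutations,
                 mi_alpha = mi_alpha, dpi_tolerance = dpi_tolerance),
            class = "coexpr_config")
}

# Equal-frequency bin index in 1..B; ties broken by stable first-occurrence
# rank so the binning is deterministic.
equal_freq_bins <- function(x, B) {
  r <- rank(x, ties.method = "first")
  ceiling(r * B / length(x))
}

#' Plug-in mutual information on equal-frequency bins
#'
#' Both vectors are discretized into B equal-frequency bins (B = `n_bins`,
#' or floor(sqrt(n)) for "auto"); MI is the plug-in estimate
#' sum p * log(p / (px * py)) over the B x B contingency table, in nats,
#' with 0 * log 0 taken as 0. A bijective relationship yields exactly
#' log(B).
#'
#' @param x,y Equal-length numeric vectors, n >= 8, neither constant.
#' @param n_bins Bin count or "auto".
#' @return MI in nats (>= 0).
#' @export
mutual_information <- function(x, y, n_bins = "auto") {
  if (length(x) != length(y)) nm_stop("mutual_information: length mismatch")
  n <- length(x)
  if (n < 8) nm_stop("mutual_information needs n >= 8")
  if (any(!is.finite(x)) || any(!is.finite(y))) nm_stop("mutual_information requires finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    nm_stop("mutual_information undefined for a constant vector")
  }
  B <- if (identical(n_bins, "auto")) floor(sqrt(n)) else as.integer(n_bins)
  bx <- equal_freq_bins(x, B)
  by <- equal_freq_bins(y, B)
  joint <- tabulate((bx - 1L) * B + by, nbins = B * B) / n
  px <- tabulate(bx, nbins = B) / n
  py <- tabulate(by, nbins = B) / n
  expect <- as.vector(outer(py, px))  # column-major: cell (by, bx)
  nz <- joint > 0
  mi <- sum(joint[nz] * log(joint[nz] / expect[nz]))
  max(mi, 0)
}

#' Permutation-null MI significance threshold
#'
#' Builds a null MI distribution by permuting the sample labels of one
#' member of each of up to `max_pairs` randomly chosen gene pairs,
#' `n_permutations` times per pair, and returns the (1 - mi_alpha)
#' quantile of the pooled null.
#'
#' @param matrix An [expression_matrix()] with >= 8 samples.
#' @param cfg A [coexpr_config()].
#' @param max_pairs Pairs sampled for the null (capped at the number of
#'   available pairs).
#' @param seed RNG seed for pair sampling and permutations.
#' @return Threshold in nats.
#' @export
mi_threshold <- function(matrix, cfg, max_pairs = 50, seed = 1) {
  stopifnot(inherits(matrix, "expr_matrix"), inherits(cfg, "coexpr_config"))
  n <- ncol(matrix$values)
  if (n < 8) nm_stop("mi_threshold needs >= 8 samples for permutation")
  g <- nrow(matrix$values)
  if (g < 2) nm_stop("mi_threshold needs >= 2 genes")
  withr::with_seed(stream_seed(seed, "mi_threshold"), {
    n_pairs <- min(max_pairs, g * (g - 1) / 2)
    pairs <- matrix(NA_integer_, nrow = n_pairs, ncol = 2)
    seen <- character(0)
    k <- 0
    while (k < n_pairs) {
      ij <- sort(sample.int(g, 2))
      key <- paste(ij, collapse = "-")
      if (!key %in% seen) {
        k <- k + 1
        seen <- c(seen, key)
        pairs[k, ] <- ij
      }
    }
    null_mi <- numeric(n_pairs * cfg$n_permutations)
    idx <- 0
    for (r in seq_len(n_pairs)) {
      x <- matrix$values[pairs[r, 1], ]
      y <- matrix$values[pairs[r, 2], ]
      for (b in seq_len(cfg$n_permutations)) {
        idx <- idx + 1
        null_mi[idx] <- mutual_information(x, y[sample.int(n)], cfg$n_bins)
      }
    }
    unname(stats::quantile(null_mi, probs = 1 - cfg$mi_alpha))
  })
}

#' Data-processing-inequality pruning of an MI-weighted edge list
#'
#' For every triangle (i, j, k), the edge (i, j) is marked for removal when
#' MI(i,j) < min(MI(i,k), MI(j,k)) * (1 - epsilon). Marks are computed
#' against the original weights and applied only after all triangles have
#' been scanned, so the result is independent of edge processing order.
#'
#' @param edges data.frame with columns `from`, `to`, `mi`.
#' @param epsilon DPI tolerance in [0, 1].
#' @return The input with a logical `removed_by_dpi` column added.
#' @export
apply_dpi <- function(edges, epsilon) {
  epsilon <- check_fraction(epsilon, "epsilon")
  stopifnot(is.data.frame(edges), all(c("from", "to", "mi") %in% names(edges)))
  m <- nrow(edges)
  removed <- logical(m)
  if (m) {
    nodes <- unique(c(edges$from, edges$to))
    eid <- new.env(parent = emptyenv())
    key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
    for (e in seq_len(m)) assign(key(edges$from[e], edges$to[e]), e, envir = eid)
    adj <- split(c(seq_len(m), seq_len(m)), c(edges$from, edges$to))
    for (e in seq_len(m)) {
      i <- edges$from[e]; j <- edges$to[e]
      # common neighbors of i and j close a triangle with edge e
      nbr_i <- setdiff(unique(c(edges$from[adj[[i]]], edges$to[adj[[i]]])), i)
      nbr_j <- setdiff(unique(c(edges$from[adj[[j]]], edges$to[adj[[j]]])), j)
      for (k in intersect(nbr_i, nbr_j)) {
        ik <- get(key(i, k), envir = eid)
        jk <- get(key(j, k), envir = eid)
        if (edges$mi[e] < min(edges$mi[ik], edges$mi[jk]) * (1 - epsilon)) {
          removed[e] <- TRUE
          break
        }
      }
    }
  }
  edges$removed_by_dpi <- removed
  edges
}

#' Infer a co-expression network by MI threshold plus DPI pruning
#'
#' All gene pairs are scored by [mutual_information()]; pairs above the
#' permutation threshold from [mi_threshold()] become candidate edges, and
#' [apply_dpi()] removes likely indirect edges. The full per-pair audit
#' (MI, threshold flag, DPI flag) is returned alongside the surviving
#' graph.
#'
#' @param matrix An [expression_matrix()] with >= 8 samples.
#' @param cfg A [coexpr_config()].
#' @param seed RNG seed for the permutation threshold.
#' @param max_pairs Passed to [mi_threshold()].
#' @return List with `network` (an [interaction_network()] over all genes),
#'   `threshold`, and `audit` (data.frame gene1, gene2, mi,
#'   passed_threshold, removed_by_dpi).
#' @export
infer_network <- function(matrix, cfg = coexpr_config(), seed = 1,
                          max_pairs = 50) {
  stopifnot(inherits(matrix, "expr_matrix"))
  genes <- rownames(matrix$values)
  g <- length(genes)
  if (g < 2) nm_stop("infer_network needs >= 2 genes")
  thr <- mi_threshold(matrix, cfg, max_pairs = max_pairs, seed = seed)
  pairs <- utils::combn(g, 2)
  mi <- numeric(ncol(pairs))
  for (c_idx in seq_len(ncol(pairs))) {
    mi[c_idx] <- mutual_information(matrix$values[pairs[1, c_idx], ],
                                    matrix$values[pairs[2, c_idx], ],
                                    cfg$n_bins)
  }
  audit <- data.frame(gene1 = genes[pairs[1, ]],
                      gene2 = genes[pairs[2, ]],
                      mi = mi,
                      passed_threshold = mi > thr,
                      row.names = NULL)
  cand <- audit[audit$passed_threshold, , drop = FALSE]
  pruned <- apply_dpi(data.frame(from = cand$gene1, to = cand$gene2, mi = cand$mi),
                      cfg$dpi_tolerance)
  audit$removed_by_dpi <- FALSE
  audit$removed_by_dpi[audit$passed_threshold] <- pruned$removed_by_dpi
  keep <- pruned[!pruned$removed_by_dpi, c("from", "to"), drop = FALSE]
  list(network = interaction_network(keep, nodes = genes),
       threshold = thr,
       audit = audit)
}

#' Extract the seed gene's first-neighborhood module
#'
#' @param net An [interaction_network()] (typically from [infer_network()]).
#' @param seed Seed gene symbol; must be a node.
#' @return Character vector: the seed plus its direct neighbors.
#' @export
seed_module <- function(net, seed) {
  stopifnot(inherits(net, "interaction_network"))
  seed <- normalize_symbols(seed)
  if (!seed %in% net$nodes) nm_stop("seed gene '", seed, "' not in network")
  nb <- c(net$edges[net$edges[, 1] == seed, 2],
          net$edges[net$edges[, 2] == seed, 1])
  sort(unique(c(seed, nb)))
}
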