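# Differential expression: per-gene Welch t-tests on log2 values,
# Benjamini-Hochberg adjustment, and the joint significance filter
# (|logFC| strictly greater than the cut AND adjusted P below alpha).

#' Welch two-sample test for one gene
#'
#' logFC is the case-minus-control mean difference on log2 data; the P
#' value is a two-sided Welch t-test. When both groups are constant the
#' t statistic is undefined: equal means give p = 1, unequal means p = 0.
#'
#' @param case_values,ctrl_values Numeric vectors (>= 2 finite values each).
#' @return Named list with `logfc` and `p`.
#' @export
test_gene <- function(case_values, ctrl_values) {
  if (length(case_values) < 2 || length(ctrl_values) < 2) {
    nm_stop("test_gene needs >= 2 values per group")
  }
  if (any(!is.finite(case_values)) || any(!is.finite(ctrl_values))) {
    nm_stop("test_gene requires finite values")
  }
  logfc <- mean(case_values) - mean(ctrl_values)
  eps <- .Machine$double.eps
  if (stats::var(case_values) < eps && stats::var(ctrl_values) < eps) {
    return(list(logfc = logfc, p = if (abs(logfc) < sqrt(eps)) 1 else 0))
  }
  p <- stats::t.test(case_values, ctrl_values, var.equal = FALSE)$p.value
  list(logfc = logfc, p = p)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p_values Numeric vector of raw P values in [0, 1].
#' @return Adjusted P values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values) || anyNA(p_values) ||
      any(p_values < 0 | p_values > 1)) {
    nm_stop("bh_adjust requires P values in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Call differentially expressed genes between two groups
#'
#' One Welch t-test per gene, BH adjustment across all genes, and the joint
#' filter: a gene is significant when |logFC| > `logfc_cut` (strict) and
#' adjusted P < `alpha`.
#'
#' @param matrix An [expression_matrix()] with exactly two group labels; the
#'   first label in sorted order is treated as control unless a label named
#'   "case" or "control" disambiguates.
#' @param logfc_cut Absolute log2 fold-change cut (strict inequality).
#' @param alpha Adjusted-P significance level.
#' @return A `DEG table` data.frame: gene, logfc, p, p_adj, significant,
#'   direction ("up"/"down"/"none").
#' @export
call_degs <- function(matrix, logfc_cut = 0.5, alpha = 0.05) {
  stopifnot(inherits(matrix, "expr_matrix"))
  lv <- sort(unique(matrix$groups))
  if (length(lv) != 2) nm_stop("call_degs requires exactly two groups, got ", length(lv))
  # orient case vs control: recognized labels win, otherwise second sorted level is "case"
  ctrl_label <- if ("control" %in% lv) "control" else if ("ctrl" %in% lv) "ctrl" else lv[1]
  case_label <- setdiff(lv, ctrl_label)
  case_idx <- matrix$groups == case_label
  res <- apply(matrix$values, 1, function(v) {
    r <- test_gene(v[case_idx], v[!case_idx])
    c(r$logfc, r$p)
  })
  logfc <- res[1, ]
  p <- res[2, ]
  p_adj <- bh_adjust(p)
  significant <- abs(logfc) > logfc_cut & p_adj < alpha
  data.frame(gene = rownames(matrix$values),
             logfc = unname(logfc),
             p = unname(p),
             p_adj = unname(p_adj),
             significant = unname(significant),
             direction = ifelse(logfc > 0, "up", ifelse(logfc < 0, "down", "none")),
             row.names = NULL)
}
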