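# Comparative delta-delta-Ct quantification (amplification efficiency
# fixed at 2) and Kruskal-Wallis comparison across groups.

#' Per-sample delta-delta-Ct relative quantification
#'
#' delta-Ct = ct_target - ct_housekeeping per sample; delta-delta-Ct is
#' referenced to the mean delta-Ct of the calibrator group; fold change is
#' 2^(-ddct). A common shift applied to both Ct columns leaves every fold
#' unchanged.
#'
#' @param table qPCR data.frame (sample, group, ct_target, ct_housekeeping).
#' @param reference_group Calibrator group label (>= 2 samples present).
#' @return data.frame: sample, group, delta_ct, ddct, fold.
#' @export
delta_delta_ct <- function(table, reference_group) {
  stopifnot(is.data.frame(table),
            all(c("sample", "group", "ct_target", "ct_housekeeping") %in% names(table)))
  if (!reference_group %in% table$group) {
    nm_stop("reference group '", reference_group, "' absent from table")
  }
  if (sum(table$group == reference_group) < 2) {
    nm_stop("reference group '", reference_group, "' needs >= 2 samples")
  }
  delta_ct <- table$ct_target - table$ct_housekeeping
  ref_mean <- mean(delta_ct[table$group == reference_group])
  ddct <- delta_ct - ref_mean
  data.frame(sample = table$sample, group = table$group,
             delta_ct = delta_ct, ddct = ddct, fold = 2^(-ddct),
             row.names = NULL)
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected H statistic with P from the chi-square approximation on
#' (groups - 1) degrees of freedom. Globally identical values give H = 0,
#' p = 1.
#'
#' @param groups List of numeric vectors (>= 2 groups, >= 2 values each).
#' @return List with `H` and `p`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) nm_stop("kruskal_wallis needs >= 2 groups")
  if (any(lengths(groups) < 2)) nm_stop("kruskal_wallis needs >= 2 values per group")
  pooled <- unlist(groups)
  if (length(unique(pooled)) == 1) return(list(H = 0, p = 1))
  kt <- stats::kruskal.test(groups)
  list(H = unname(kt$statistic), p = kt$p.value)
}

#' Per-group fold-change summary
#'
#' Folds are log-scale quantities, so groups are summarized by the
#' geometric mean of per-sample folds — identically 2^(-mean ddct) — with
#' the SD of ddct (cycles) as the dispersion measure.
#'
#' @param results data.frame from [delta_delta_ct()].
#' @return data.frame: group, n, mean_fold, sd_ddct.
#' @export
group_fold_summary <- function(results) {
  stopifnot(is.data.frame(results), all(c("group", "ddct") %in% names(results)))
  if (!nrow(results)) nm_stop("group_fold_summary requires >= 1 group")
  groups <- unique(results$group)
  do.call(rbind, lapply(groups, function(g) {
    d <- results$ddct[results$group == g]
    data.frame(group = g, n = length(d),
               mean_fold = 2^(-mean(d)),
               sd_ddct = if (length(d) > 1) stats::sd(d) else 0,
               row.names = NULL)
  }))
}
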