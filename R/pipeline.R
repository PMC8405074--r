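# End-to-end orchestration of the two-cycle consensus biomarker pipeline:
# cycle 1 scores the signature interaction network and selects central
# genes; cycle 2 calls DEGs per compartment, intersects them across
# compartments, and intersects the shared set with the central genes.
# Downstream stages characterize the consensus gene: co-expression module,
# enrichment, survival stratification and delta-delta-Ct quantification.
# make_demo() emits a complete synthetic study with planted truth.

default_pipeline_params <- function() {
  list(logfc_cut = 0.5, alpha = 0.05,
       betweenness_quantile = 0.20,
       degree_rule = list(type = "top_k", k = 6),
       coexpr = list(n_bins = "auto", n_permutations = 50,
                     mi_alpha = 0.05, dpi_tolerance = 0.1, max_pairs = 40),
       enrich_alpha = 0.05, horizon = 5,
       qpcr_reference = "primary", seed = 1)
}

#' Generate a complete synthetic demo study with planted truth
#'
#' Emits every input the pipeline consumes: a scale-free signature network,
#' tumor and PBMC case/control expression matrices, a co-expression matrix
#' with a planted latent-factor module, a GMT library containing the module
#' as a planted term, a survival table with an expression-linked hazard,
#' and a three-group qPCR Ct table. One gene is planted simultaneously as
#' the network's top hub and as an up-regulated DEG in both compartments
#' (aliased to CCNB2), so the pipeline's consensus should name exactly that
#' gene; a second, topologically peripheral gene (aliased to PGK1) is
#' planted as an up-regulated DEG in both compartments to exercise the
#' shared-but-not-central path.
#'
#' @param seed Integer run seed.
#' @param out_dir Output directory (created if needed).
#' @param n_genes Signature universe size.
#' @param n_coexpr_genes Gene count of the co-expression matrix.
#' @param cfg Optional [synth_config()] override (its `seed` is replaced).
#' @return Invisibly, a pipeline config list (see [run_pipeline()]) with a
#'   `truth` element.
#' @export
make_demo <- function(seed = 7, out_dir = "demo", n_genes = 100,
                      n_coexpr_genes = 30, cfg = NULL) {
  seed <- check_count(seed, "seed", min = 0)
  if (is.null(cfg)) cfg <- synth_config(n_genes = n_genes, seed = seed)
  cfg$seed <- seed
  cfg$n_genes <- check_count(n_genes, "n_genes")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- default_pipeline_params()
  params$seed <- seed
  params$degree_rule$k <- cfg$hub_count

  net_out <- make_network(cfg)
  consensus_gene <- net_out$truth$hub_genes[1]
  central <- select_central(net_out$network, params$betweenness_quantile,
                            params$degree_rule)
  # peripheral shared gene: lowest betweenness, then lowest degree, outside
  # the central set
  tab <- central$table
  cand <- tab[!tab$is_central, , drop = FALSE]
  cand <- cand[order(cand$betweenness, cand$degree, cand$gene), , drop = FALSE]
  peripheral_gene <- cand$gene[1]
  alias <- c(stats::setNames("CCNB2", consensus_gene),
             stats::setNames("PGK1", peripheral_gene))
  rename <- function(x) ifelse(x %in% names(alias), alias[x], x)

  net <- interaction_network(apply(net_out$network$edges, 2, rename),
                             nodes = rename(net_out$network$nodes))

  genes <- synthetic_symbols(cfg$n_genes)
  n_extra <- max(0, floor(cfg$deg_fraction * cfg$n_genes) - 2)
  pool <- setdiff(genes, c(consensus_gene, peripheral_gene))
  extra <- withr::with_seed(stream_seed(seed, "demo_planting"), {
    sample(pool, min(2 * n_extra, length(pool)))
  })
  plant_tumor <- c(stats::setNames(c(1, 1), c(consensus_gene, peripheral_gene)),
                   stats::setNames(rep(1, n_extra), extra[seq_len(n_extra)]))
  plant_pbmc <- c(stats::setNames(c(1, 1), c(consensus_gene, peripheral_gene)),
                  stats::setNames(rep(1, n_extra),
                                  extra[n_extra + seq_len(min(n_extra, length(extra) - n_extra))]))
  tumor <- make_expression(cfg, planted = plant_tumor, stream = "expression_tumor")
  pbmc <- make_expression(cfg, planted = plant_pbmc, stream = "expression_pbmc")
  relabel_matrix <- function(m) {
    rownames(m$values) <- rename(rownames(m$values))
    m
  }
  tumor$matrix <- relabel_matrix(tumor$matrix)
  pbmc$matrix <- relabel_matrix(pbmc$matrix)

  cfg_cx <- cfg
  cfg_cx$n_genes <- check_count(n_coexpr_genes, "n_coexpr_genes")
  cfg_cx$noise_sd <- 0.3  # module loading 0.9 against unit-variance factor
  cx <- make_coexpr_data(cfg_cx, seed_gene = synthetic_symbols(cfg_cx$n_genes)[1])
  cx_alias <- stats::setNames("CCNB2", cx$truth$seed_gene)
  rownames(cx$matrix$values) <- ifelse(rownames(cx$matrix$values) %in% names(cx_alias),
                                       cx_alias[rownames(cx$matrix$values)],
                                       rownames(cx$matrix$values))
  module_genes <- sort(ifelse(cx$truth$module_genes %in% names(cx_alias),
                              cx_alias[cx$truth$module_genes], cx$truth$module_genes))

  # GMT library: the planted module as one term plus background terms
  cx_genes <- rownames(cx$matrix$values)
  gmt <- withr::with_seed(stream_seed(seed, "demo_gmt"), {
    terms <- list(PLANTED_MODULE = module_genes)
    for (i in 1:10) {
      terms[[sprintf("BACKGROUND_%02d", i)]] <-
        sort(sample(cx_genes, sample(8:15, 1)))
    }
    terms
  })

  surv <- make_survival(cfg, gene = "CCNB2")
  qpcr <- make_qpcr(cfg)

  paths <- list(
    edges = file.path(out_dir, "network.tsv"),
    tumor_expr = file.path(out_dir, "tumor_expr.tsv"),
    tumor_groups = file.path(out_dir, "tumor_groups.tsv"),
    pbmc_expr = file.path(out_dir, "pbmc_expr.tsv"),
    pbmc_groups = file.path(out_dir, "pbmc_groups.tsv"),
    coexpr_expr = file.path(out_dir, "coexpr_expr.tsv"),
    gmt = file.path(out_dir, "genesets.gmt"),
    survival = file.path(out_dir, "survival.tsv"),
    qpcr = file.path(out_dir, "qpcr.tsv")
  )
  write_edgelist(net, paths$edges)
  write_expression(tumor$matrix, paths$tumor_expr, paths$tumor_groups)
  write_expression(pbmc$matrix, paths$pbmc_expr, paths$pbmc_groups)
  write_expression(cx$matrix, paths$coexpr_expr)
  write_gmt(structure(gmt, descriptions = stats::setNames(rep("synthetic", length(gmt)),
                                                          names(gmt))),
            paths$gmt)
  write_table(surv$table, paths$survival)
  write_table(qpcr$table, paths$qpcr)

  truth <- list(consensus_gene = "CCNB2",
                shared_genes = c("CCNB2", "PGK1"),
                hub_genes = rename(net_out$truth$hub_genes),
                tumor_deg_genes = rename(names(plant_tumor)),
                pbmc_deg_genes = rename(names(plant_pbmc)),
                module_genes = module_genes,
                hazard_gene = "CCNB2",
                qpcr_reference = "primary")
  write_truth(truth, file.path(out_dir, "truth.txt"))

  config <- c(paths, params, list(truth = truth))
  yaml::write_yaml(config[setdiff(names(config), "truth")],
                   file.path(out_dir, "config.yaml"))
  invisible(config)
}

#' Read a pipeline config from YAML
#' @param path YAML path (as written by [make_demo()]).
#' @return Config list for [run_pipeline()].
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- default_pipeline_params()
  for (nm in names(defaults)) if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  cfg
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    nm_stop("stage '", name, "' failed: ", conditionMessage(e))
  })
}

#' Run the full two-cycle pipeline from a config
#'
#' Stage order: topology -> DEGs (tumor, PBMC) -> shared DEGs -> consensus
#' -> co-expression module seeded at the consensus gene -> enrichment ->
#' survival -> qPCR. Every intermediate table is written to `run_dir`
#' alongside a parameter log and a summary report naming the consensus
#' biomarker(s). With an empty consensus the seed-dependent stages
#' (co-expression, enrichment) are skipped with a warning unless
#' `force_seed_gene` is supplied.
#'
#' @param config List with input paths (`edges`, `tumor_expr`,
#'   `tumor_groups`, `pbmc_expr`, `pbmc_groups`, `coexpr_expr`, `gmt`,
#'   `survival`, `qpcr`) and parameters (`logfc_cut`, `alpha`,
#'   `betweenness_quantile`, `degree_rule`, `coexpr`, `enrich_alpha`,
#'   `horizon`, `qpcr_reference`, `seed`); see [make_demo()].
#' @param run_dir Output directory for intermediate tables and the summary.
#' @param force_seed_gene Optional symbol forcing the co-expression seed.
#' @return Invisibly, a list with all stage results plus `run_dir`.
#' @export
run_pipeline <- function(config, run_dir = "run", force_seed_gene = NULL) {
  defaults <- default_pipeline_params()
  for (nm in names(defaults)) if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  path_keys <- c("edges", "tumor_expr", "tumor_groups", "pbmc_expr",
                 "pbmc_groups", "coexpr_expr", "gmt", "survival", "qpcr")
  for (k in path_keys) {
    if (is.null(config[[k]])) nm_stop("config missing input path '", k, "'")
    if (!file.exists(config[[k]])) nm_stop("input file not found: ", config[[k]])
  }
  dir.create(run_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  log_stage <- function(name, ...) {
    log_lines <<- c(log_lines, paste0("stage=", name, " ", paste0(..., collapse = " ")))
  }

  central <- run_stage("topology", {
    net <- read_edgelist(config$edges)
    select_central(net, config$betweenness_quantile, config$degree_rule)
  })
  write_table(central$table, file.path(run_dir, "central.tsv"))
  log_stage("topology", sprintf("nodes=%d central=%d hubs=%d",
                                nrow(central$table), length(central$central),
                                length(central$hubs)))

  degs <- run_stage("dge", {
    list(tumor = call_degs(read_expression(config$tumor_expr, config$tumor_groups),
                           config$logfc_cut, config$alpha),
         pbmc = call_degs(read_expression(config$pbmc_expr, config$pbmc_groups),
                          config$logfc_cut, config$alpha))
  })
  write_table(degs$tumor, file.path(run_dir, "degs_tumor.tsv"))
  write_table(degs$pbmc, file.path(run_dir, "degs_pbmc.tsv"))
  log_stage("dge", sprintf("tumor_degs=%d pbmc_degs=%d",
                           sum(degs$tumor$significant), sum(degs$pbmc$significant)))

  consensus <- run_stage("consensus", {
    shared <- shared_degs(degs$tumor, degs$pbmc)
    consensus_with_central(shared, central)
  })
  write_table(consensus$provenance, file.path(run_dir, "consensus.tsv"))
  log_stage("consensus", sprintf("shared=%d consensus=%d",
                                 length(consensus$shared_degs),
                                 length(consensus$consensus)))

  seed_genes <- if (!is.null(force_seed_gene)) normalize_symbols(force_seed_gene) else consensus$consensus
  coexpr <- NULL
  enrichment <- NULL
  if (!length(seed_genes)) {
    warning("empty consensus: skipping co-expression and enrichment stages",
            call. = FALSE)
    log_stage("coexpr", "skipped=empty_consensus")
  } else {
    ccfg <- do.call(coexpr_config,
                    config$coexpr[setdiff(names(config$coexpr), "max_pairs")])
    coexpr <- run_stage("coexpr", {
      header <- strsplit(readLines(config$coexpr_expr, n = 1), "\t", fixed = TRUE)[[1]]
      mat <- read_expression(config$coexpr_expr,
                             stats::setNames(rep("case", length(header) - 1), header[-1]))
      inferred <- infer_network(mat, ccfg, seed = config$seed,
                                max_pairs = config$coexpr$max_pairs %||% 40)
      modules <- lapply(seed_genes, function(g) {
        if (g %in% inferred$network$nodes) seed_module(inferred$network, g) else character(0)
      })
      names(modules) <- seed_genes
      c(inferred, list(modules = modules))
    })
    write_table(coexpr$audit, file.path(run_dir, "coexpr_edges.tsv"))
    write_table(data.frame(seed = rep(names(coexpr$modules), lengths(coexpr$modules)),
                           gene = unlist(coexpr$modules, use.names = FALSE)),
                file.path(run_dir, "module.tsv"))
    log_stage("coexpr", sprintf("threshold=%.4f edges=%d module=%d",
                                coexpr$threshold, nrow(coexpr$network$edges),
                                length(coexpr$modules[[1]])))
    enrichment <- run_stage("enrich", {
      library <- read_gmt(config$gmt)
      query <- unique(unlist(coexpr$modules, use.names = FALSE))
      enrich_library(query, library, alpha = config$enrich_alpha)
    })
    write_table(enrichment, file.path(run_dir, "enrichment.tsv"))
    log_stage("enrich", sprintf("terms=%d", nrow(enrichment)))
  }

  surv <- run_stage("survival", {
    survival_by_median(read_survival(config$survival), config$horizon)
  })
  write_table(surv$km$high, file.path(run_dir, "km_high.tsv"))
  write_table(surv$km$low, file.path(run_dir, "km_low.tsv"))
  write_table(data.frame(chi2 = surv$comparison$chi2, p = surv$comparison$p,
                         hazard_ratio = surv$comparison$hazard_ratio,
                         horizon = config$horizon),
              file.path(run_dir, "survival_comparison.tsv"))
  log_stage("survival", sprintf("HR=%.3f p=%.4f", surv$comparison$hazard_ratio,
                                surv$comparison$p))

  qpcr_res <- run_stage("qpcr", {
    tab <- read_qpcr(config$qpcr)
    dd <- delta_delta_ct(tab, config$qpcr_reference)
    kw <- kruskal_wallis(split(dd$ddct, dd$group))
    list(folds = dd, summary = group_fold_summary(dd), kw = kw)
  })
  write_table(qpcr_res$folds, file.path(run_dir, "qpcr_folds.tsv"))
  write_table(qpcr_res$summary, file.path(run_dir, "qpcr_summary.tsv"))
  log_stage("qpcr", sprintf("H=%.3f p=%.4f", qpcr_res$kw$H, qpcr_res$kw$p))

  summary_lines <- c(
    "consensus biomarker discovery summary",
    sprintf("seed: %d", config$seed),
    sprintf("central genes: %d (hubs: %s)", length(central$central),
            paste(central$hubs, collapse = ", ")),
    sprintf("tumor DEGs: %d | PBMC DEGs: %d",
            sum(degs$tumor$significant), sum(degs$pbmc$significant)),
    sprintf("shared DEGs: %s", paste(consensus$shared_degs, collapse = ", ")),
    sprintf("consensus biomarker(s): %s",
            if (length(consensus$consensus)) paste(consensus$consensus, collapse = ", ") else "(none)"),
    if (!is.null(coexpr)) sprintf("co-expression module size: %d (seed %s)",
                                  length(coexpr$modules[[1]]), names(coexpr$modules)[1]),
    if (!is.null(enrichment)) sprintf("enriched terms (adj P < %g): %d",
                                      config$enrich_alpha, nrow(enrichment)),
    sprintf("survival: HR=%.3f, log-rank p=%.4f at %g-year horizon",
            surv$comparison$hazard_ratio, surv$comparison$p, config$horizon),
    sprintf("qPCR: Kruskal-Wallis H=%.3f, p=%.4f; folds vs %s: %s",
            qpcr_res$kw$H, qpcr_res$kw$p, config$qpcr_reference,
            paste(sprintf("%s=%.2f", qpcr_res$summary$group,
                          qpcr_res$summary$mean_fold), collapse = ", "))
  )
  writeLines(summary_lines, file.path(run_dir, "summary.txt"))
  writeLines(log_lines, file.path(run_dir, "log.txt"))

  invisible(list(central = central, degs = degs, consensus = consensus,
                 coexpr = coexpr, enrichment = enrichment, survival = surv,
                 qpcr = qpcr_res, run_dir = run_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
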