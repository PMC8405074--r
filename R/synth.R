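# Seeded synthetic-data generators with planted ground truth. These define
# the study conditions under which every downstream stage is exercised:
# case/control log2 expression with planted fold changes, scale-free
# interaction networks with hub truth, latent-factor co-expression modules
# around a seed gene, exponential survival with an expression-linked hazard,
# and multi-group qPCR Ct tables with planted cycle shifts.
#
# Every generator is a pure function of (cfg, seed): each call draws from
# its own RNG stream derived from the run seed and the generator name, so
# adding calls never perturbs earlier outputs.

#' Configuration for the synthetic-data generators
#'
#' Defaults mirror the study conditions the pipeline is evaluated under:
#' 20 case / 20 control arrays, planted log2 fold change of 2 against a
#' per-measurement noise SD of 0.1 log2 units, six network hubs, a
#' 12-gene co-expression module with loading 0.9, and a doubled hazard
#' (log-HR = ln 2) for high expressors.
#'
#' @param n_genes Number of genes in generated matrices/networks.
#' @param n_case,n_ctrl Samples per arm.
#' @param deg_fraction Fraction of genes planted as true DEGs.
#' @param planted_logfc Planted |log2 fold change| (> 0); sign is random per gene.
#' @param noise_sd Per-measurement Gaussian noise SD, log2 units (> 0).
#' @param hub_count Number of hub genes recorded as network truth.
#' @param module_size Co-expression module size, seed gene included.
#' @param module_loading Latent-factor loading of module genes, in (0, 1].
#' @param hazard_beta Log hazard ratio of the high-expression stratum.
#' @param baseline_hazard Baseline event rate, events per year (> 0).
#' @param censor_rate Fraction of subjects exposed to uniform censoring, in [0, 1).
#' @param n_subjects Survival-table size.
#' @param n_samples_coexpr Sample count for co-expression matrices.
#' @param seed Integer run seed.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_genes = 500, n_case = 20, n_ctrl = 20,
                         deg_fraction = 0.05, planted_logfc = 2, noise_sd = 0.1,
                         hub_count = 6, module_size = 12, module_loading = 0.9,
                         hazard_beta = log(2), baseline_hazard = 0.2,
                         censor_rate = 0.2, n_subjects = 200,
                         n_samples_coexpr = 300, seed = 1) {
  cfg <- list(
    n_genes = check_count(n_genes, "n_genes"),
    n_case = check_count(n_case, "n_case"),
    n_ctrl = check_count(n_ctrl, "n_ctrl"),
    deg_fraction = check_fraction(deg_fraction, "deg_fraction"),
    planted_logfc = check_positive(planted_logfc, "planted_logfc"),
    noise_sd = check_positive(noise_sd, "noise_sd"),
    hub_count = check_count(hub_count, "hub_count"),
    module_size = check_count(module_size, "module_size", min = 2),
    module_loading = check_fraction(module_loading, "module_loading", lo_open = TRUE),
    hazard_beta = as.numeric(hazard_beta),
    baseline_hazard = check_positive(baseline_hazard, "baseline_hazard"),
    censor_rate = check_fraction(censor_rate, "censor_rate", hi_open = TRUE),
    n_subjects = check_count(n_subjects, "n_subjects", min = 4),
    n_samples_coexpr = check_count(n_samples_coexpr, "n_samples_coexpr", min = 8),
    seed = check_count(seed, "seed", min = 0)
  )
  if (cfg$hub_count > cfg$n_genes) {
    nm_stop("configuration error: 'hub_count' exceeds 'n_genes'")
  }
  if (cfg$module_size > cfg$n_genes) {
    nm_stop("configuration error: 'module_size' exceeds 'n_genes'")
  }
  structure(cfg, class = "synth_config")
}

#' Generate a case/control expression matrix with planted DEGs
#'
#' Each gene gets a baseline drawn from Normal(8, 2) log2 units; every
#' measurement adds Normal(0, noise_sd) noise. Planted DEG genes are shifted
#' by +/- `planted_logfc` in the case arm only; the truth lists exactly the
#' shifted genes with their signs.
#'
#' @param cfg A [synth_config()].
#' @param planted Optional named numeric vector of signs (+1/-1) keyed by
#'   gene symbol, overriding random DEG selection (symbols must exist).
#' @param stream Stream name suffix so two compartments generated under one
#'   seed get independent data.
#' @return List with `matrix` (an [expression_matrix()]) and `truth`
#'   (list with `deg_genes`, a signed named vector).
#' @export
make_expression <- function(cfg, planted = NULL, stream = "expression") {
  stopifnot(inherits(cfg, "synth_config"))
  genes <- synthetic_symbols(cfg$n_genes)
  withr::with_seed(stream_seed(cfg$seed, stream), {
    if (is.null(planted)) {
      n_deg <- floor(cfg$deg_fraction * cfg$n_genes)
      deg_genes <- if (n_deg > 0) sample(genes, n_deg) else character(0)
      signs <- if (n_deg > 0) sample(c(-1, 1), n_deg, replace = TRUE) else numeric(0)
      planted <- stats::setNames(signs, deg_genes)
    } else {
      if (!all(names(planted) %in% genes)) {
        nm_stop("configuration error: planted gene(s) not in matrix: ",
                paste(setdiff(names(planted), genes), collapse = ", "))
      }
      if (!all(planted %in% c(-1, 1))) nm_stop("configuration error: planted signs must be +1/-1")
    }
    n <- cfg$n_case + cfg$n_ctrl
    baseline <- stats::rnorm(cfg$n_genes, mean = 8, sd = 2)
    vals <- baseline + matrix(stats::rnorm(cfg$n_genes * n, sd = cfg$noise_sd),
                              nrow = cfg$n_genes)
    idx <- match(names(planted), genes)
    if (length(idx)) {
      vals[idx, seq_len(cfg$n_case)] <- vals[idx, seq_len(cfg$n_case)] +
        unname(planted) * cfg$planted_logfc
    }
    rownames(vals) <- genes
    colnames(vals) <- c(sprintf("case_%02d", seq_len(cfg$n_case)),
                        sprintf("ctrl_%02d", seq_len(cfg$n_ctrl)))
    groups <- stats::setNames(rep(c("case", "control"), c(cfg$n_case, cfg$n_ctrl)),
                              colnames(vals))
    list(matrix = expression_matrix(vals, groups),
         truth = list(deg_genes = planted))
  })
}

#' Generate a scale-free interaction network with hub truth
#'
#' Barabasi-Albert preferential attachment over the configured gene symbols;
#' the truth records the `hub_count` highest-degree nodes (ties broken by
#' degree then symbol, the same deterministic order the topology module
#' uses for its top-k rule).
#'
#' @param cfg A [synth_config()].
#' @param edges_per_node Edges attached by each arriving node (1 gives a tree).
#' @param stream RNG stream name.
#' @return List with `network` (an [interaction_network()]) and `truth`
#'   (list with `hub_genes`).
#' @export
make_network <- function(cfg, edges_per_node = 2, stream = "network") {
  stopifnot(inherits(cfg, "synth_config"))
  edges_per_node <- check_count(edges_per_node, "edges_per_node")
  genes <- synthetic_symbols(cfg$n_genes)
  withr::with_seed(stream_seed(cfg$seed, stream), {
    g <- igraph::sample_pa(cfg$n_genes, m = edges_per_node, directed = FALSE)
    el <- igraph::as_edgelist(g, names = FALSE)
    net <- interaction_network(cbind(genes[el[, 1]], genes[el[, 2]]), nodes = genes)
    deg <- degree_map(net)
    ord <- order(-deg, names(deg))
    list(network = net,
         truth = list(hub_genes = names(deg)[ord[seq_len(cfg$hub_count)]]))
  })
}

#' Generate expression data with a planted latent-factor co-expression module
#'
#' Module genes (the seed gene plus `module_size - 1` others) share a
#' standard-normal latent factor z per sample: value = baseline +
#' loading * z + Normal(0, noise_sd). Non-module genes are independent
#' noise around their baselines, so module membership is unambiguous for
#' recovery tests.
#'
#' @param cfg A [synth_config()].
#' @param seed_gene Symbol to place inside the module (defaults to the
#'   first synthetic symbol).
#' @param stream RNG stream name.
#' @return List with `matrix` (an [expression_matrix()], all samples
#'   labelled "case") and `truth` (list with `module_genes`, `seed_gene`).
#' @export
make_coexpr_data <- function(cfg, seed_gene = NULL, stream = "coexpr") {
  stopifnot(inherits(cfg, "synth_config"))
  genes <- synthetic_symbols(cfg$n_genes)
  if (is.null(seed_gene)) seed_gene <- genes[1]
  seed_gene <- normalize_symbols(seed_gene)
  if (!seed_gene %in% genes) nm_stop("configuration error: seed gene '", seed_gene, "' not in matrix")
  withr::with_seed(stream_seed(cfg$seed, stream), {
    module <- c(seed_gene, sample(setdiff(genes, seed_gene), cfg$module_size - 1))
    n <- cfg$n_samples_coexpr
    z <- stats::rnorm(n)
    baseline <- stats::rnorm(cfg$n_genes, mean = 8, sd = 2)
    vals <- baseline + matrix(stats::rnorm(cfg$n_genes * n, sd = cfg$noise_sd),
                              nrow = cfg$n_genes)
    idx <- match(module, genes)
    vals[idx, ] <- vals[idx, ] + cfg$module_loading * matrix(z, nrow = length(idx),
                                                             ncol = n, byrow = TRUE)
    rownames(vals) <- genes
    colnames(vals) <- sprintf("s%03d", seq_len(n))
    list(matrix = expression_matrix(vals, rep("case", n)),
         truth = list(module_genes = sort(module), seed_gene = seed_gene))
  })
}

#' Generate a survival table with an expression-linked hazard
#'
#' Expression is Normal(8, 2); subjects above the median carry hazard
#' `baseline_hazard * exp(hazard_beta)`, the rest `baseline_hazard`.
#' Event times are exponential; a `censor_rate` fraction of subjects is
#' additionally exposed to administrative-uniform censoring on
#' [0, 3 / baseline_hazard].
#'
#' @param cfg A [synth_config()].
#' @param gene Symbol recorded as the stratifying gene (metadata only).
#' @param stream RNG stream name.
#' @return List with `table` (data.frame subject/time/event/expression) and
#'   `truth` (list with `hazard_gene`, `high_subjects`).
#' @export
make_survival <- function(cfg, gene = "G0001", stream = "survival") {
  stopifnot(inherits(cfg, "synth_config"))
  withr::with_seed(stream_seed(cfg$seed, stream), {
    n <- cfg$n_subjects
    expr <- stats::rnorm(n, mean = 8, sd = 2)
    high <- expr > stats::median(expr)
    rate <- cfg$baseline_hazard * exp(cfg$hazard_beta * high)
    t_event <- stats::rexp(n, rate = rate)
    t_max <- 3 / cfg$baseline_hazard
    censored <- stats::runif(n) < cfg$censor_rate
    t_cens <- ifelse(censored, stats::runif(n, 0, t_max), Inf)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
    time <- pmax(time, 1e-6)  # strictly positive follow-up
    tab <- data.frame(subject = sprintf("subj_%03d", seq_len(n)),
                      time = time, event = event, expression = expr)
    list(table = tab,
         truth = list(hazard_gene = normalize_symbols(gene),
                      high_subjects = tab$subject[high]))
  })
}

#' Generate a multi-group qPCR Ct table with planted cycle shifts
#'
#' Housekeeping Ct is Normal(20, 0.5) per sample; target Ct adds the
#' group's planted delta-Ct shift plus Normal(0, ct_noise_sd) noise, so a
#' shift difference of -1 cycle between two groups corresponds to a
#' two-fold expression difference downstream.
#'
#' @param cfg A [synth_config()].
#' @param group_shifts Named numeric vector of per-group delta-Ct shifts
#'   (cycles). The default plants the demo contrasts: metastatic about
#'   24.8-fold and healthy about 2.6-fold above primary-stage samples.
#' @param n_per_group Samples per group.
#' @param ct_noise_sd Target-Ct noise SD (cycles).
#' @param stream RNG stream name.
#' @return List with `table` (data.frame sample/group/ct_target/
#'   ct_housekeeping) and `truth` (list with `group_shifts`).
#' @export
make_qpcr <- function(cfg,
                      group_shifts = c(healthy = 0, primary = 1.379,
                                       metastatic = 1.379 - log2(24.8)),
                      n_per_group = 8, ct_noise_sd = 0.25, stream = "qpcr") {
  stopifnot(inherits(cfg, "synth_config"))
  if (length(group_shifts) < 2 || is.null(names(group_shifts))) {
    nm_stop("configuration error: 'group_shifts' needs >= 2 named groups")
  }
  n_per_group <- check_count(n_per_group, "n_per_group", min = 2)
  ct_noise_sd <- check_positive(ct_noise_sd, "ct_noise_sd")
  withr::with_seed(stream_seed(cfg$seed, stream), {
    groups <- rep(names(group_shifts), each = n_per_group)
    n <- length(groups)
    hk <- stats::rnorm(n, mean = 20, sd = 0.5)
    target <- hk + group_shifts[groups] + stats::rnorm(n, sd = ct_noise_sd)
    tab <- data.frame(sample = sprintf("%s_%02d", groups,
                                       sequence(rep(n_per_group, length(group_shifts)))),
                      group = groups,
                      ct_target = unname(target),
                      ct_housekeeping = hk)
    list(table = tab, truth = list(group_shifts = group_shifts))
  })
}
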