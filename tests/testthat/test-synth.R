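test_that("generators are pure functions of (cfg, seed) with independent streams", {
  cfg <- synth_config(n_genes = 50, seed = 11)
  a <- make_expression(cfg)
  b <- make_expression(cfg)
  expect_identical(a$matrix$values, b$matrix$values)
  expect_identical(a$truth, b$truth)
  expect_identical(make_coexpr_data(cfg)$matrix$values,
                   make_coexpr_data(cfg)$matrix$values)
  expect_identical(make_qpcr(cfg)$table, make_qpcr(cfg)$table)
  # different seeds give different data
  cfg2 <- synth_config(n_genes = 50, seed = 12)
  expect_false(identical(a$matrix$values, make_expression(cfg2)$matrix$values))
  # streams are independent: expression output does not depend on whether
  # other generators were called in between
  c1 <- make_expression(cfg)
  invisible(make_network(cfg)); invisible(make_survival(cfg))
  c2 <- make_expression(cfg)
  expect_identical(c1$matrix$values, c2$matrix$values)
})

test_that("planted expression effects are measurable and truth is consistent", {
  cfg <- synth_config(n_genes = 40, n_case = 30, n_ctrl = 30,
                      planted_logfc = 2, noise_sd = 0.01, seed = 3)
  out <- make_expression(cfg, planted = c(G0007 = 1))
  m <- out$matrix
  diff <- mean(m$values["G0007", m$groups == "case"]) -
    mean(m$values["G0007", m$groups == "control"])
  expect_equal(diff, 2, tolerance = 0.02)
  expect_identical(names(out$truth$deg_genes), "G0007")
  # no planting when deg_fraction = 0
  cfg0 <- synth_config(n_genes = 40, deg_fraction = 0, seed = 3)
  expect_length(make_expression(cfg0)$truth$deg_genes, 0)
  # truth symbols always exist in the matrix
  cfg5 <- synth_config(n_genes = 200, deg_fraction = 0.1, seed = 9)
  out5 <- make_expression(cfg5)
  expect_true(all(names(out5$truth$deg_genes) %in% rownames(out5$matrix$values)))
  expect_error(make_expression(cfg, planted = c(NOPE = 1)), "NOPE")
})

test_that("generated networks are simple, scale-free-shaped, with hub truth on top", {
  cfg <- synth_config(n_genes = 5, hub_count = 1, module_size = 2, seed = 2)
  tree <- make_network(cfg, edges_per_node = 1)
  expect_equal(nrow(tree$network$edges), 4)  # tree on 5 nodes
  cfg2 <- synth_config(n_genes = 300, hub_count = 6, seed = 4)
  out <- make_network(cfg2)
  net <- out$network
  # simple graph: no self-loops, no duplicate unordered pairs
  expect_true(all(net$edges[, 1] != net$edges[, 2]))
  key <- paste(pmin(net$edges[, 1], net$edges[, 2]),
               pmax(net$edges[, 1], net$edges[, 2]))
  expect_false(any(duplicated(key)))
  deg <- degree_map(net)
  expect_true(names(which.max(deg)) %in% out$truth$hub_genes)
  # heavy tail: positive sample skewness of the degree sequence at n = 2000
  cfg3 <- synth_config(n_genes = 2000, seed = 5)
  d <- degree_map(make_network(cfg3)$network)
  skew <- mean((d - mean(d))^3) / stats::sd(d)^3
  expect_gt(skew, 0)
  expect_error(synth_config(n_genes = 4, hub_count = 5), "hub_count")
})

test_that("latent-factor co-expression plants tight modules and independent background", {
  cfg <- synth_config(n_genes = 20, module_size = 5, module_loading = 1,
                      noise_sd = 0.01, n_samples_coexpr = 200, seed = 6)
  out <- make_coexpr_data(cfg, seed_gene = "G0001")
  expect_true("G0001" %in% out$truth$module_genes)
  v <- out$matrix$values
  mod <- out$truth$module_genes
  cors <- stats::cor(t(v[mod, ]))
  expect_true(all(cors[upper.tri(cors)] > 0.95))
  non_mod <- setdiff(rownames(v), mod)[1:2]
  expect_lt(abs(stats::cor(v[non_mod[1], ], v[non_mod[2], ])), 0.2)
  expect_error(synth_config(n_genes = 4, hub_count = 2, module_size = 5),
               "module_size")
})

test_that("survival generator plants the configured hazard structure", {
  cfg0 <- synth_config(censor_rate = 0, n_subjects = 50, seed = 8)
  out0 <- make_survival(cfg0)
  expect_true(all(out0$table$event == 1))  # no censoring
  # hazard_beta = 0: group mean event times agree within 10% at n = 2000
  cfg_null <- synth_config(hazard_beta = 0, censor_rate = 0, n_subjects = 2000, seed = 8)
  outn <- make_survival(cfg_null)
  hi <- outn$table$subject %in% outn$truth$high_subjects
  expect_equal(mean(outn$table$time[hi]), mean(outn$table$time[!hi]), tolerance = 0.1)
  # hazard_beta = ln 2: empirical event-rate ratio near 2 at n = 2000
  cfg2 <- synth_config(hazard_beta = log(2), censor_rate = 0, n_subjects = 2000, seed = 8)
  out2 <- make_survival(cfg2)
  hi <- out2$table$subject %in% out2$truth$high_subjects
  rate_ratio <- (1 / mean(out2$table$time[hi])) / (1 / mean(out2$table$time[!hi]))
  expect_equal(rate_ratio, 2, tolerance = 0.2)
  expect_error(synth_config(censor_rate = 1), "censor_rate")
})

test_that("qPCR generator plants group shifts that map to the expected folds", {
  cfg <- synth_config(seed = 10)
  out <- make_qpcr(cfg, group_shifts = c(ref = 0, treat = -1),
                   n_per_group = 10, ct_noise_sd = 0.01)
  dd <- delta_delta_ct(out$table, "ref")
  summ <- group_fold_summary(dd)
  expect_equal(summ$mean_fold[summ$group == "treat"], 2, tolerance = 0.02)
  # all shifts equal: folds near 1
  flat <- make_qpcr(cfg, group_shifts = c(a = 1, b = 1), n_per_group = 10,
                    ct_noise_sd = 0.01)
  ddf <- delta_delta_ct(flat$table, "a")
  expect_equal(group_fold_summary(ddf)$mean_fold, c(1, 1), tolerance = 0.02)
  expect_error(make_qpcr(cfg, group_shifts = c(only = 0)), "2 named groups")
})
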