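triangle <- interaction_network(cbind(c("A", "B", "A"), c("B", "C", "C")))
star6 <- interaction_network(cbind("HUB", paste0("L", 1:6)))
path3 <- interaction_network(cbind(c("A", "B"), c("B", "C")))

test_that("degree_map satisfies hand cases and the handshake lemma", {
  expect_equal(unname(degree_map(triangle)), c(2, 2, 2))
  deg_star <- degree_map(star6)
  expect_equal(deg_star[["HUB"]], 6)
  expect_true(all(deg_star[paste0("L", 1:6)] == 1))
  withr::with_seed(7, {
    for (i in 1:10) {
      net <- random_network(sample(4:9, 1), stats::runif(1, 0.2, 0.8))
      expect_equal(sum(degree_map(net)), 2 * nrow(net$edges))
    }
  })
})

test_that("betweenness uses the classic convention and matches the enumeration oracle", {
  b <- betweenness_map(path3)
  expect_equal(unname(b[c("A", "B", "C")]), c(0, 1, 0))
  b_star <- betweenness_map(star6)
  expect_equal(b_star[["HUB"]], choose(6, 2))
  withr::with_seed(13, {
    for (i in 1:25) {
      net <- random_network(sample(3:7, 1), stats::runif(1, 0.15, 0.9))
      expect_equal(betweenness_map(net), oracle_betweenness(net), tolerance = 1e-9)
    }
  })
})

test_that("power-law R-squared is exact on log-linear data and 0 on flat histograms", {
  # frequency exactly proportional to degree^(-2) over degrees 1, 2, 4, 8
  degs <- rep(c(1, 2, 4, 8), c(64, 16, 4, 1))
  expect_equal(powerlaw_r2(degs), 1, tolerance = 1e-12)
  expect_equal(powerlaw_r2(rep(c(1, 2, 3), each = 5)), 0)
  expect_error(powerlaw_r2(rep(c(1, 2), 5)), "3 distinct")
  # preferential-attachment degree sequences fit a power law better than
  # matched uniform-random graphs
  cfg <- synth_config(n_genes = 2000, seed = 17)
  pa <- make_network(cfg)$network
  r2_pa <- powerlaw_r2(degree_map(pa))
  gnm <- withr::with_seed(17, {
    g <- igraph::sample_gnm(2000, nrow(pa$edges))
    el <- igraph::as_edgelist(g, names = FALSE)
    syms <- netmark:::synthetic_symbols(2000)
    interaction_network(cbind(syms[el[, 1]], syms[el[, 2]]), nodes = syms)
  })
  expect_gt(r2_pa, powerlaw_r2(degree_map(gnm)))
})

test_that("tail_inclusive_quantile selects at least the top q fraction, ties included", {
  expect_equal(sum(c(5, 4, 3, 2, 1) >= tail_inclusive_quantile(c(5, 4, 3, 2, 1), 0.2)), 1)
  v <- c(5, 5, 3, 2, 1)
  expect_equal(sum(v >= tail_inclusive_quantile(v, 0.2)), 2)  # both fives
  expect_equal(sum(v >= tail_inclusive_quantile(v, 1)), 5)
  expect_error(tail_inclusive_quantile(v, 0), "\\(0, 1\\]")
})

test_that("select_central unions hubs with the top betweenness quantile", {
  cen <- select_central(star6, 0.2, list(type = "threshold", value = 6))
  expect_identical(cen$central, "HUB")
  expect_identical(cen$hubs, "HUB")
  # fractional threshold above the max integer degree selects nothing
  expect_warning(
    cen14 <- select_central(star6, 0.2, list(type = "threshold", value = 14.29)),
    "no hubs")
  expect_length(cen14$hubs, 0)
  expect_identical(cen14$central, cen14$high_betweenness)
  # central = hubs U high_betweenness always
  withr::with_seed(23, {
    for (i in 1:10) {
      net <- random_network(sample(5:9, 1), 0.4)
      cen_i <- select_central(net, 0.3, list(type = "top_k", k = 2))
      expect_setequal(cen_i$central, union(cen_i$hubs, cen_i$high_betweenness))
      expect_true(all(cen_i$hubs %in% net$nodes))
    }
  })
})

test_that("top-k hub selection recovers planted hubs and is label-invariant", {
  for (s in 1:5) {
    cfg <- synth_config(n_genes = 500, hub_count = 6, seed = 100 + s)
    out <- make_network(cfg)
    cen <- select_central(out$network, 0.2, list(type = "top_k", k = 6))
    expect_setequal(cen$hubs, out$truth$hub_genes)
  }
  # node relabeling permutes but does not change the selection
  cfg <- synth_config(n_genes = 60, seed = 41)
  net <- make_network(cfg)$network
  relabel <- withr::with_seed(5, sample(net$nodes))
  map <- stats::setNames(relabel, net$nodes)
  net2 <- interaction_network(cbind(map[net$edges[, 1]], map[net$edges[, 2]]),
                              nodes = unname(map))
  cen1 <- select_central(net, 0.2, list(type = "top_k", k = 5))
  cen2 <- select_central(net2, 0.2, list(type = "top_k", k = 5))
  expect_setequal(unname(map[cen1$high_betweenness]), cen2$high_betweenness)
  expect_setequal(sort(unname(cen1$table$degree)), sort(unname(cen2$table$degree)))
})
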