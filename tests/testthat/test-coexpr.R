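test_that("mutual information is symmetric, non-negative, and exact on bijections", {
  withr::with_seed(3, {
    for (i in 1:15) {
      n <- sample(c(16, 36, 100), 1)
      x <- stats::rnorm(n); y <- stats::rnorm(n)
      mi_xy <- mutual_information(x, y)
      expect_identical(mi_xy, mutual_information(y, x))
      expect_gte(mi_xy, 0)
      expect_equal(mi_xy, oracle_mi(x, y, floor(sqrt(n))), tolerance = 1e-12)
    }
    # bijection: MI = log(B) exactly when B divides n
    for (B in c(4, 5, 8)) {
      x <- stats::rnorm(B * 10)
      expect_equal(mutual_information(x, exp(x), n_bins = B), log(B), tolerance = 1e-9)
      expect_equal(mutual_information(x, -x, n_bins = B), log(B), tolerance = 1e-9)
    }
    # independence: MI shrinks toward 0 at large n with fixed bins
    x <- stats::rnorm(10000); y <- stats::rnorm(10000)
    expect_lt(mutual_information(x, y, n_bins = 2), 0.02)
  })
  expect_error(mutual_information(1:10, 1:9), "length")
  expect_error(mutual_information(rep(1, 10), 1:10), "constant")
  expect_error(mutual_information(1:5, 1:5), "n >= 8")
})

test_that("DPI removes the weakest triangle edge, honors epsilon, and is order-invariant", {
  tri <- data.frame(from = c("A", "B", "A"), to = c("B", "C", "C"),
                    mi = c(0.5, 0.4, 0.1))
  out <- apply_dpi(tri, 0)
  expect_identical(out$removed_by_dpi, c(FALSE, FALSE, TRUE))
  expect_true(all(!apply_dpi(tri, 1)$removed_by_dpi))  # epsilon 1 disables pruning
  # mark-then-sweep: result invariant to edge row order
  withr::with_seed(11, {
    for (i in 1:20) {
      net <- random_network(sample(4:6, 1), 0.7)
      if (!nrow(net$edges)) next
      edges <- data.frame(from = net$edges[, 1], to = net$edges[, 2],
                          mi = stats::runif(nrow(net$edges)))
      eps <- sample(c(0, 0.1, 0.2), 1)
      got <- apply_dpi(edges, eps)
      expect_identical(got$removed_by_dpi, oracle_dpi(edges, eps))
      perm <- sample(nrow(edges))
      got_perm <- apply_dpi(edges[perm, ], eps)
      expect_identical(got_perm$removed_by_dpi, got$removed_by_dpi[perm])
    }
  })
  expect_error(apply_dpi(tri, 1.5), "epsilon")
})

test_that("the permutation MI threshold is seeded-deterministic and falls with n at fixed bins", {
  cfg <- coexpr_config(n_bins = 8, n_permutations = 40)
  cfg_small <- synth_config(n_genes = 10, module_size = 3, n_samples_coexpr = 40,
                            seed = 2)
  m_small <- make_coexpr_data(cfg_small)$matrix
  t1 <- mi_threshold(m_small, cfg, seed = 5)
  expect_identical(t1, mi_threshold(m_small, cfg, seed = 5))
  cfg_big <- synth_config(n_genes = 10, module_size = 3, n_samples_coexpr = 400,
                          seed = 2)
  t_big <- mi_threshold(make_coexpr_data(cfg_big)$matrix, cfg, seed = 5)
  expect_lt(t_big, t1)  # estimator bias (B-1)^2/2n shrinks with n
  expect_error(coexpr_config(n_permutations = 5), "n_permutations")
  expect_error(coexpr_config(mi_alpha = 0), "mi_alpha")
})

test_that("infer_network keeps direct chain edges, prunes the indirect one, and finds planted modules", {
  cfg <- coexpr_config(n_permutations = 30)
  ok <- 0
  for (s in 1:5) {
    withr::with_seed(700 + s, {
      n <- 500
      x <- stats::rnorm(n); y <- x + stats::rnorm(n, sd = 0.5)
      z <- y + stats::rnorm(n, sd = 0.5)
      v <- rbind(X = x, Y = y, Z = z)
      colnames(v) <- paste0("s", seq_len(n))
      m <- expression_matrix(v, rep("case", n))
    })
    res <- infer_network(m, cfg, seed = s, max_pairs = 3)
    edges <- paste(res$network$edges[, 1], res$network$edges[, 2])
    if (all(c("X Y", "Y Z") %in% edges) && !"X Z" %in% edges) ok <- ok + 1
  }
  expect_gte(ok, 4)
  # independent genes: essentially no surviving edges
  null_cfg <- synth_config(n_genes = 15, module_size = 2, module_loading = 0.01,
                           noise_sd = 1, n_samples_coexpr = 200, seed = 33)
  null_m <- make_coexpr_data(null_cfg)$matrix
  res0 <- infer_network(null_m, cfg, seed = 1)
  expect_lte(nrow(res0$network$edges), 5)
  # planted module genes are mutually connected before DPI
  mod_cfg <- synth_config(n_genes = 15, module_size = 5, module_loading = 0.9,
                          noise_sd = 0.3, n_samples_coexpr = 300, seed = 44)
  mod_out <- make_coexpr_data(mod_cfg)
  res_m <- infer_network(mod_out$matrix, cfg, seed = 2)
  aud <- res_m$audit
  in_mod <- aud$gene1 %in% mod_out$truth$module_genes &
    aud$gene2 %in% mod_out$truth$module_genes
  expect_true(all(aud$passed_threshold[in_mod]))
  # audit invariant: removed_by_dpi implies passed_threshold
  expect_true(all(!aud$removed_by_dpi | aud$passed_threshold))
})

test_that("seed_module returns the seed plus its first neighbors", {
  star <- interaction_network(cbind("S", paste0("L", 1:4)))
  expect_setequal(seed_module(star, "S"), c("S", paste0("L", 1:4)))
  iso <- interaction_network(cbind("A", "B"), nodes = c("A", "B", "LONE"))
  expect_identical(seed_module(iso, "LONE"), "LONE")
  expect_error(seed_module(star, "MISSING"), "MISSING")
})
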