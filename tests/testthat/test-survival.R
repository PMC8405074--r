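test_that("median stratification uses a strict cut with ties going low", {
  tab <- data.frame(subject = paste0("s", 1:4), time = 1:4, event = 1,
                    expression = c(1, 2, 3, 4))
  expect_identical(as.character(stratify_by_median(tab)),
                   c("low", "low", "high", "high"))  # median 2.5
  tab$expression <- c(1, 2, 2, 3)
  expect_identical(as.character(stratify_by_median(tab)),
                   c("low", "low", "low", "high"))  # ties at median 2 go low
  perm <- c(3, 1, 4, 2)
  expect_identical(stratify_by_median(tab)[perm],
                   stratify_by_median(tab[perm, ]))
  tab$expression <- 5
  expect_error(stratify_by_median(tab), "identical")
})

test_that("the KM product-limit estimate matches hand-computed cases", {
  km <- km_curve(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(km$n_risk, c(3, 2, 1))
  # censoring at t=2 shrinks the risk set without an event step; at t=3 the
  # sole remaining subject fails: S = (1 - 1/3) * (1 - 1/1) = 0
  km2 <- km_curve(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km2$time, c(1, 3))
  expect_equal(km2$n_risk, c(3, 1))
  expect_equal(km2$survival, c(2 / 3, 0))
  # all censored: no event steps, survival stays 1
  expect_equal(nrow(km_curve(c(1, 2, 3), c(0, 0, 0))), 0)
  # horizon administratively censors later follow-up
  km5 <- km_curve(c(1, 2, 8), c(1, 1, 1), horizon = 5)
  expect_equal(km5$time, c(1, 2))
  expect_equal(km5$survival, c(2 / 3, 1 / 3))
  # subject order invariance
  withr::with_seed(4, {
    t <- stats::rexp(30); e <- stats::rbinom(30, 1, 0.7)
    perm <- sample(30)
    expect_equal(km_curve(t, e), km_curve(t[perm], e[perm]))
  })
  expect_error(km_curve(numeric(0), numeric(0)), "at least one")
  expect_error(km_curve(c(0, 1), c(1, 1)), "> 0")
})

test_that("log-rank matches the 2x2-table arithmetic and symmetry laws", {
  g1 <- data.frame(time = c(1, 2), event = 1)
  g2 <- data.frame(time = c(3, 4), event = 1)
  # hand computation over the four event times
  risk1 <- c(2, 1, 0, 0); risk2 <- c(2, 2, 2, 1); d1 <- c(1, 1, 0, 0)
  N <- risk1 + risk2; d <- c(1, 1, 1, 1)
  E1 <- d * risk1 / N
  V <- risk1 * risk2 * d * (N - d) / (N^2 * (N - 1))
  chi2_hand <- sum(d1 - E1)^2 / sum(V, na.rm = TRUE)
  res <- logrank(g1, g2)
  expect_equal(res$chi2, chi2_hand, tolerance = 1e-9)
  expect_equal(res$observed, c(2, 2))
  expect_equal(res$expected[1], sum(E1), tolerance = 1e-9)
  # identical groups: chi2 = 0, HR = 1
  same <- data.frame(time = c(1, 2, 3), event = c(1, 0, 1))
  res_same <- logrank(same, same)
  expect_equal(res_same$chi2, 0, tolerance = 1e-12)
  expect_equal(res_same$hazard_ratio, 1, tolerance = 1e-12)
  # swapping groups inverts HR and preserves chi2
  withr::with_seed(9, {
    a <- data.frame(time = stats::rexp(40, 1), event = stats::rbinom(40, 1, 0.8))
    b <- data.frame(time = stats::rexp(40, 2), event = stats::rbinom(40, 1, 0.8))
  })
  ab <- logrank(a, b); ba <- logrank(b, a)
  expect_equal(ab$chi2, ba$chi2, tolerance = 1e-9)
  expect_equal(ab$hazard_ratio, 1 / ba$hazard_ratio, tolerance = 1e-9)
  expect_error(logrank(data.frame(time = 1, event = 0),
                       data.frame(time = 2, event = 0)), "no events")
})

test_that("median-stratified analysis ties the pieces together", {
  cfg <- synth_config(hazard_beta = log(3), n_subjects = 300, seed = 77)
  out <- make_survival(cfg)
  res <- survival_by_median(out$table, horizon = 5)
  expect_named(res$km, c("high", "low"))
  expect_gt(res$comparison$hazard_ratio, 1)  # high expressors die faster
  expect_lt(res$comparison$p, 0.05)
  # strata agree with the generator's truth
  expect_setequal(out$table$subject[res$strata == "high"], out$truth$high_subjects)
})
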