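# Distribution fitting and the probabilistic sensitivity analysis.

test_that("method-of-moments fits match their closed forms", {
  # beta: point 0.78, range (0.68, 0.87) read as a 95% interval
  f <- fit_distribution(uparam(0.78, 0.68, 0.87, "beta"))
  sd <- (0.87 - 0.68) / 3.92
  ab <- 0.78 * 0.22 / sd^2 - 1
  expect_equal(f$shape1, 0.78 * ab, tolerance = 1e-12)
  expect_equal(f$shape1 + f$shape2, ab, tolerance = 1e-12)
  expect_equal(f$shape1 + f$shape2, 72.04, tolerance = 1e-3)
  expect_equal(f$shape1, 56.19, tolerance = 1e-3)
  expect_equal(dist_mean(f), 0.78, tolerance = 1e-12)
  expect_equal(dist_sd(f), sd, tolerance = 1e-12)

  # gamma: moment matching preserves the mean exactly
  g <- fit_distribution(uparam(1445, 532, 2736, "gamma"))
  expect_equal(dist_mean(g), 1445, tolerance = 1e-12)
  expect_equal(dist_sd(g), (2736 - 532) / 3.92, tolerance = 1e-12)

  # log-normal likewise
  l <- fit_distribution(uparam(27295, 1380, 78887, "lognormal"))
  expect_equal(dist_mean(l), 27295, tolerance = 1e-9)
  expect_equal(dist_sd(l), (78887 - 1380) / 3.92, tolerance = 1e-9)

  # fixed: point mass
  fx <- fit_distribution(uparam(42))
  expect_equal(sample_distribution(fx, 5), rep(42, 5))
})

test_that("every sampled fixture parameter keeps its mean (closed form)", {
  p <- tpl_parameters()
  tab <- parameter_table(p)
  for (i in seq_len(nrow(tab))) {
    if (tab$family[i] == "fixed") next
    f <- fit_distribution(uparam(tab$point[i], tab$low[i], tab$high[i],
                                 tab$family[i]))
    expect_lt(abs(dist_mean(f) - tab$point[i]) / tab$point[i], 0.02)
  }
})

test_that("an impossible beta range is rejected with guidance", {
  expect_error(fit_distribution(uparam(0.5, -3, 4, "beta")),
               regexp = "range", class = "tpl_fit_error")
})

test_that("alternative range readings are available", {
  u <- uparam(10, 8, 12, "gamma")
  expect_equal(dist_sd(fit_distribution(u, range_rule = "se")), 2)
  un <- fit_distribution(u, range_rule = "uniform")
  expect_equal(un$family, "uniform")
  draws <- sample_distribution(un, 100)
  expect_true(all(draws >= 8 & draws <= 12))
})

test_that("the PSA is deterministic given its seed", {
  p <- tpl_parameters()
  a <- run_psa(p, n_iter = 25, seed = 99)
  b <- run_psa(p, n_iter = 25, seed = 99)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- run_psa(p, n_iter = 25, seed = 100)
  expect_false(identical(a$cost, c$cost))
})

test_that("with every parameter fixed the draws equal the base case", {
  p <- tpl_parameters()
  for (id in names(p$strategies)) {
    p$strategies[[id]]$sensitivity$family <- "fixed"
    p$strategies[[id]]$specificity$family <- "fixed"
  }
  for (sn in names(p$strata)) {
    p$strata[[sn]]$p_death$family <- "fixed"
    p$strata[[sn]]$p_morbidity$family <- "fixed"
    for (cn in names(p$strata[[sn]]$costs)) {
      p$strata[[sn]]$costs[[cn]]$family <- "fixed"
    }
  }
  draws <- run_psa(p, n_iter = 2, seed = 1)
  base <- evaluate_strategies(p)
  joined <- dplyr::left_join(as.data.frame(draws), base,
                             by = c("strategy", "scope"),
                             suffix = c("_draw", "_base"))
  expect_equal(joined$cost_draw, joined$cost_base, tolerance = 1e-12)
  expect_equal(joined$adverse_draw, joined$adverse_base, tolerance = 1e-12)
})

test_that("PSA draw means stay near the base case under mean-preserving fits", {
  p <- tpl_parameters()
  draws <- run_psa(p, n_iter = 400, seed = 5)
  base <- evaluate_strategies(p)
  means <- dplyr::summarise(
    dplyr::group_by(as.data.frame(draws), strategy, scope),
    cost = mean(cost), adverse = mean(adverse), .groups = "drop")
  joined <- dplyr::left_join(means, base, by = c("strategy", "scope"),
                             suffix = c("_psa", "_base"))
  expect_true(all(abs(joined$cost_psa - joined$cost_base) /
                    joined$cost_base < 0.10))
})

test_that("quadrant classification matches a manual count", {
  de <- c(-1, -1, -2, 1, 1, 2, -3, 0, 4, -5)
  dc <- c(-10, 5, -1, -2, 3, 4, -9, 0, -1, 2)
  draws <- dplyr::bind_rows(
    tibble::tibble(iteration = 1:10, strategy = "A", scope = "24-27",
                   cost = 100 + dc, adverse = 0.5 + de / 100),
    tibble::tibble(iteration = 1:10, strategy = "B", scope = "24-27",
                   cost = 100, adverse = 0.5))
  qs <- quadrant_summary(draws, referent = "A", alternative = "B",
                         scope = "24-27")
  # manual: SW {1,3,7,8}, NW {2,10}, SE {4,9}, NE {5,6}
  expect_equal(qs$sw, 40)
  expect_equal(qs$nw, 20)
  expect_equal(qs$se, 20)
  expect_equal(qs$ne, 20)
  expect_equal(qs$sw + qs$nw + qs$se + qs$ne, 100)
  expect_equal(qs$boundary_n, 1)
})

test_that("a strategy compared with itself sits on the origin", {
  p <- tpl_parameters()
  draws <- run_psa(p, n_iter = 10, seed = 2)
  qs <- quadrant_summary(draws, "S7", "S7", "24-27")
  expect_equal(qs$sw, 100)  # boundary ties count with the negative side
  expect_equal(qs$boundary_n, 10)
  expect_equal(qs$sw + qs$nw + qs$se + qs$ne, 100)
})

test_that("quadrant proportions always sum to 100", {
  p <- tpl_parameters()
  draws <- run_psa(p, n_iter = 40, seed = 8)
  qt <- quadrant_table(draws, referent = "S7")
  expect_equal(nrow(qt), 6 * 3)
  expect_equal(qt$sw + qt$nw + qt$se + qt$ne, rep(100, nrow(qt)))
  expect_error(quadrant_summary(draws, "S7", "S99"),
               class = "tpl_lookup_error")
})
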