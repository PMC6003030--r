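# Decision-tree roll-back and gestational-age aggregation.

test_that("degenerate limit: perfect test, no treatment effect, absorbing home", {
  p <- no_treatment_params()
  ov <- list(strata = list())
  for (sn in c("24-27", "28-31", "32-34")) {
    ov$strata[[sn]] <- list(p_home_followup = uparam(1),
                            p_subsequent_hosp = uparam(0))
  }
  for (id in c("S_ref", "S7")) {
    ov$strategies[[id]] <- list(sensitivity = uparam(1, 1, 1, "beta"),
                                specificity = uparam(1, 1, 1, "beta"))
  }
  p <- tpl_parameters(c(ov, list(treatment = list(rr_death_treated = 1,
                                                  rr_morbidity_treated = 1))))
  res <- evaluate_strategies(p, strategies = "S7")
  for (sn in c("24-27", "28-31", "32-34")) {
    s <- p$strata[[sn]]
    expected <- 0.097 * (s$p_death$point + s$p_morbidity$point)
    got <- res$adverse[res$scope == sn]
    expect_equal(got, expected, tolerance = 1e-12, info = sn)
  }
})

test_that("with no treatment effect all strategies have identical adverse risk", {
  p <- no_treatment_params()
  res <- evaluate_strategies(p)
  agg <- res[res$scope == "24-34", ]
  expect_equal(max(agg$adverse) - min(agg$adverse), 0, tolerance = 1e-12)
  for (sn in c("24-27", "28-31", "32-34")) {
    st <- res[res$scope == sn, ]
    expect_equal(max(st$adverse) - min(st$adverse), 0, tolerance = 1e-12)
  }
})

test_that("adverse risk decreases with sensitivity when treatment helps", {
  sens_grid <- c(0.5, 0.6, 0.7, 0.8, 0.9, 1.0)
  adv <- vapply(sens_grid, function(s) {
    p <- tpl_parameters(list(strategies = list(S_ref = list(
      sensitivity = uparam(s, 0.5, 1, "beta")))))
    evaluate_strategy(p, "S_ref", "24-34")$adverse
  }, 0)
  expect_true(all(diff(adv) < 0))
})

test_that("cost decreases with specificity (default parameters)", {
  spec_grid <- c(0.5, 0.6, 0.7, 0.8, 0.9, 1.0)
  cost <- vapply(spec_grid, function(s) {
    p <- tpl_parameters(list(strategies = list(S_ref = list(
      specificity = uparam(s, 0.5, 1, "beta")))))
    evaluate_strategy(p, "S_ref", "24-34")$cost
  }, 0)
  expect_true(all(diff(cost) <= 0))
})

test_that("a more sensitive strategy avoids more events than the reference", {
  p <- tpl_parameters()  # rr < 1 by default
  res <- evaluate_strategies(p, strategies = c("S_ref", "S7"))
  for (sc in c("24-27", "28-31", "32-34", "24-34")) {
    expect_lt(res$adverse[res$strategy == "S7" & res$scope == sc],
              res$adverse[res$strategy == "S_ref" & res$scope == sc])
  }
})

test_that("the aggregate scope is the weighted mean of the stratum scopes", {
  p <- tpl_parameters()
  res <- evaluate_strategies(p)
  w <- p$ga_weights
  for (id in unique(res$strategy)) {
    st <- res[res$strategy == id & res$scope != "24-34", ]
    agg <- res[res$strategy == id & res$scope == "24-34", ]
    expect_equal(agg$cost, sum(st$cost * w[st$scope]), tolerance = 1e-9)
    expect_equal(agg$adverse, sum(st$adverse * w[st$scope]), tolerance = 1e-9)
  }
})

test_that("aggregate_ga computes weighted means, honours degenerate weights, is linear", {
  res <- tibble::tibble(
    strategy = "X", scope = c("24-27", "28-31", "32-34"),
    cost = c(100, 200, 300), adverse = c(0.01, 0.02, 0.03))
  agg <- aggregate_ga(res, c(0.2, 0.3, 0.5))
  expect_equal(agg$cost, 230)
  expect_equal(agg$adverse, 0.023)

  agg1 <- aggregate_ga(res, c(1, 0, 0))
  expect_equal(agg1$cost, 100)
  expect_equal(agg1$adverse, 0.01)

  res2 <- dplyr::mutate(res, cost = cost * 3, adverse = adverse * 3)
  agg2 <- aggregate_ga(res2, c(0.2, 0.3, 0.5))
  expect_equal(agg2$cost, 3 * agg$cost)
  expect_equal(agg2$adverse, 3 * agg$adverse)

  expect_error(aggregate_ga(res, c(0.5, 0.5, 0.5)),
               class = "tpl_validation_error")
})

test_that("cohort payoffs agree with the microsimulation oracle (spot checks)", {
  p <- tpl_parameters()
  cells <- list(c("S7", "24-27"), c("S6", "32-34"), c("S_ref", "28-31"))
  for (cell in cells) {
    co <- evaluate_strategy(p, cell[1], scope = cell[2])
    ms <- simulate_cohort(p, cell[1], cell[2], n = 40000, seed = 11)
    expect_lt(abs(ms$cost_mean - co$cost), 3 * ms$cost_se)
    expect_lt(abs(ms$adverse_mean - co$adverse), 3 * ms$adverse_se)
  }
})

test_that("calibration self-consistency: model-generated targets give ~zero residual", {
  p <- tpl_parameters()
  self <- evaluate_strategies(p)
  targets <- self[self$scope == "24-34", c("strategy", "cost", "adverse")]
  cal <- calibrate_parameters(p, targets = targets, n_starts = 1, seed = 1,
                              maxit = 400)
  expect_lt(cal$objective, 1e-8)
  expect_true(cal$within_ceiling)
})
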