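# Individual-level microsimulation: determinism, internal consistency,
# agreement with the analytic contingency structure.

test_that("trajectories are reproducible for a fixed seed", {
  p <- tpl_parameters()
  a <- simulate_trajectories(p, "S7", "32-34", n = 500, seed = 42)
  b <- simulate_trajectories(p, "S7", "32-34", n = 500, seed = 42)
  expect_identical(a, b)
  w1 <- simulate_woman(p, "S7", "32-34", seed = 3)
  w2 <- simulate_woman(p, "S7", "32-34", seed = 3)
  expect_identical(w1$path, w2$path)
  expect_identical(w1$cost_eur, w2$cost_eur)
})

test_that("trajectory fields are internally consistent", {
  p <- tpl_parameters()
  traj <- simulate_trajectories(p, "S_ref", "24-27", n = 4000, seed = 9)
  # term deliveries never carry an adverse outcome
  expect_true(all(traj$outcome[traj$delivery_week >= 37] == "none"))
  # 7-day deliverers deliver at the entry week
  expect_true(all(traj$delivery_week[traj$true_delivery_within_7d] == 25))
  # treated flag equals the positive test
  expect_identical(traj$treated, traj$test_positive)
  # delivery week within the model horizon
  expect_true(all(traj$delivery_week >= 25 & traj$delivery_week <= 37))
  # exact cost for the closed-form pathways (deliverers within 7 days)
  costs <- p$strata$`24-27`$costs
  neo <- c(death = costs$perinatal_death$point,
           severe_morbidity = costs$neonatal_hosp_with_morbidity$point,
           none = costs$neonatal_hosp_no_morbidity$point)
  del <- traj[traj$true_delivery_within_7d, ]
  expected <- ifelse(del$test_positive, costs$prenatal_hosp_tpl$point, 0) +
    costs$preterm_labor_hosp$point + neo[del$outcome]
  expect_equal(del$cost_eur, unname(expected))
})

test_that("one woman's cost equals the sum of her priced path events", {
  p <- tpl_parameters()
  costs <- p$strata$`28-31`$costs
  for (seed in 1:25) {
    w <- simulate_woman(p, "S2", "28-31", seed = seed)
    path <- w$path
    expected <- 0
    if (w$test_positive) expected <- expected + costs$prenatal_hosp_tpl$point
    if (w$true_delivery_within_7d) {
      expected <- expected + costs$preterm_labor_hosp$point
    } else {
      follow <- path[-1, ]  # weekly rows after presentation
      states <- follow$state
      # home follow-up cost for each cycle started at home
      prev <- c("HOME", states[-length(states)])
      expected <- expected + 42 * sum(prev == "HOME")
      # admissions: each HOME -> REHOSP move, priced at the week's stratum
      moves <- which(prev == "HOME" & states == "REHOSP")
      for (m in moves) {
        sw <- c("24-27", "28-31", "32-34")[min(max(
          findInterval(follow$week[m], c(24, 28, 32)), 1), 3)]
        expected <- expected + p$strata[[sw]]$costs$prenatal_hosp_tpl$point
      }
      final <- states[length(states)]
      if (final == "DELIVERED_PRETERM") {
        wk <- follow$week[length(states)]
        sw <- c("24-27", "28-31", "32-34")[min(max(
          findInterval(wk, c(24, 28, 32)), 1), 3)]
        expected <- expected + p$strata[[sw]]$costs$preterm_labor_hosp$point
      } else {
        expected <- expected + costs$term_delivery$point
      }
    }
    if (w$outcome != "none" || (w$delivery_week < 37)) {
      if (w$delivery_week < 37) {
        sw <- c("24-27", "28-31", "32-34")[min(max(
          findInterval(w$delivery_week, c(24, 28, 32)), 1), 3)]
        neo <- c(death = p$strata[[sw]]$costs$perinatal_death$point,
                 severe_morbidity =
                   p$strata[[sw]]$costs$neonatal_hosp_with_morbidity$point,
                 none = p$strata[[sw]]$costs$neonatal_hosp_no_morbidity$point)
        expected <- expected + unname(neo[w$outcome])
      }
    }
    expect_equal(w$cost_eur, expected, info = paste("seed", seed))
  }
})

test_that("empirical test-positive rate matches the contingency table", {
  p <- tpl_parameters()
  n <- 100000
  traj <- simulate_trajectories(p, "S_ref", "28-31", n = n, seed = 123)
  cl <- classify(0.097, 0.78, 0.71)
  emp <- mean(traj$test_positive)
  se <- sqrt(cl$p_positive * (1 - cl$p_positive) / n)
  expect_lt(abs(emp - cl$p_positive), 3 * se)
  # joint cells within binomial error too
  for (cell in list(c(TRUE, TRUE, cl$p_tp), c(TRUE, FALSE, cl$p_fn),
                    c(FALSE, TRUE, cl$p_fp), c(FALSE, FALSE, cl$p_tn))) {
    emp <- mean(traj$true_delivery_within_7d == cell[1] &
                  traj$test_positive == cell[2])
    se <- sqrt(cell[3] * (1 - cell[3]) / n)
    expect_lt(abs(emp - cell[3]), 3.5 * se)
  }
})

test_that("simulate_cohort summarises its own trajectories", {
  p <- tpl_parameters()
  s <- simulate_cohort(p, "S4", "32-34", n = 1, seed = 5, keep = TRUE)
  women <- attr(s, "women")
  expect_equal(nrow(women), 1)
  expect_equal(s$cost_mean, women$cost_eur)
  expect_equal(s$adverse_mean, as.numeric(women$outcome != "none"))

  s2 <- simulate_cohort(p, "S4", "32-34", n = 2000, seed = 5, keep = TRUE)
  w2 <- attr(s2, "women")
  expect_equal(s2$cost_mean, mean(w2$cost_eur))
  expect_equal(s2$cost_se, sd(w2$cost_eur) / sqrt(2000))
})

test_that("with no treatment effect, strategies differ only via timing pathways", {
  p <- no_treatment_params()
  for (id in c("S3", "S7")) {
    co <- evaluate_strategy(p, id, scope = "28-31")
    ms <- simulate_cohort(p, id, "28-31", n = 30000, seed = 17)
    expect_lt(abs(ms$adverse_mean - co$adverse), 3 * ms$adverse_se)
    expect_lt(abs(ms$cost_mean - co$cost), 3 * ms$cost_se)
  }
})
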