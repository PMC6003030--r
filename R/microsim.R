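# Individual-level microsimulation: woman-by-woman trajectories under the
# exact probabilistic structure the cohort model assumes. Serves as the
# brute-force oracle for evaluate_strategies() and as a synthetic-data
# generator (no external data).

#' Simulate individual woman-by-woman trajectories
#'
#' Draws, for each of `n` women presenting with threatened preterm labor in
#' the given stratum: the true delivery-within-7-days status
#' (Bernoulli(incidence)), the test result conditioned on that status,
#' routing through the decision tree, weekly Markov follow-up draws for
#' non-deliverers, the neonatal outcome at the realised delivery week
#' (treatment-adjusted on test-positive pathways) and the accrued cost under
#' the same price set as the cohort model. Deterministic given `seed`: draws
#' are consumed in a fixed, stage-by-stage vectorised order.
#'
#' @param params A [tpl_parameters()] object.
#' @param strategy Strategy id.
#' @param stratum Gestational-age stratum.
#' @param n Number of women.
#' @param seed RNG seed.
#' @return A tibble with one row per woman: `strategy`, `stratum`, `woman`,
#'   `true_delivery_within_7d`, `test_positive`, `treated`, `delivery_week`,
#'   `outcome` (`"death"`, `"severe_morbidity"`, `"none"`) and `cost_eur`.
#' @export
#' @examples
#' simulate_trajectories(tpl_parameters(), "S7", "32-34", n = 5, seed = 1)
simulate_trajectories <- function(params, strategy, stratum, n, seed = 1) {
  stopifnot(inherits(params, "tpl_parameters"), n >= 1)
  stratum <- match.arg(stratum, STRATA)
  pk <- build_pack(params)
  if (!strategy %in% names(pk$sens)) {
    abort(sprintf("Unknown strategy id `%s`.", strategy))
  }
  outc_prob <- list(pd = cbind(pk$p_death, pk$p_death * pk$rr_d),
                    pm = cbind(pk$p_morb, pk$p_morb * pk$rr_m))
  si <- match(stratum, STRATA)
  sens <- pk$sens[[strategy]]; spec <- pk$spec[[strategy]]

  set.seed(seed)
  true7 <- runif(n) < pk$inc
  u_test <- runif(n)
  positive <- ifelse(true7, u_test < sens, u_test < 1 - spec)

  cost <- numeric(n)
  delivery_week <- rep(NA_real_, n)
  outcome <- rep("none", n)

  cost[positive] <- cost[positive] + pk$prenatal[si]

  # stage 1: deliveries within 7 days, at the entry week
  del <- which(true7)
  if (length(del)) {
    delivery_week[del] <- pk$entry[si]
    cost[del] <- cost[del] + pk$deliv_adm[si]
    outcome[del] <- draw_outcomes(length(del), si, positive[del], pk, outc_prob)
    cost[del] <- cost[del] + neonatal_cost(outcome[del], si, pk)
  }

  # stage 2: weekly Markov follow-up for non-deliverers
  fol <- which(!true7)
  if (length(fol)) {
    p_dgr <- ifelse(positive[fol], pk$pdgr_t, pk$pdgr_u)
    state <- rep(0L, length(fol))  # 0 = HOME, 1 = REHOSP, 2 = delivered
    week_of <- rep(NA_real_, length(fol))
    K <- pk$K[si]
    for (t in seq_len(K)) {
      week <- pk$entry[si] + t
      active <- which(state < 2L)
      if (!length(active)) break
      at_home <- active[state[active] == 0L]
      cost[fol[at_home]] <- cost[fol[at_home]] + pk$weekly[si]
      if (week < pk$horizon) {
        sw <- stratum_of_week(week)
        u <- runif(length(active))
        is_home <- state[active] == 0L
        to_rehosp <- active[is_home & u >= pk$p_home[si] &
                             u < pk$p_home[si] + pk$q[si]]
        del_home <- active[is_home & u >= pk$p_home[si] + pk$q[si]]
        del_rehosp <- active[!is_home & u < p_dgr[active]]
        back_home <- active[!is_home & u >= p_dgr[active]]
        state[to_rehosp] <- 1L
        cost[fol[to_rehosp]] <- cost[fol[to_rehosp]] + pk$prenatal[sw]
        delivered <- c(del_home, del_rehosp)
        state[delivered] <- 2L
        week_of[delivered] <- week
        cost[fol[delivered]] <- cost[fol[delivered]] + pk$deliv_adm[sw]
        state[back_home] <- 0L
      } else {
        cost[fol[active]] <- cost[fol[active]] + pk$term[si]
        week_of[active] <- pk$horizon
        state[active] <- 2L
      }
    }
    delivery_week[fol] <- week_of
    pre <- which(week_of < pk$horizon)
    if (length(pre)) {
      swv <- stratum_of_week(week_of[pre])
      outc <- draw_outcomes_by_week(swv, positive[fol[pre]], pk, outc_prob)
      outcome[fol[pre]] <- outc
      cost[fol[pre]] <- cost[fol[pre]] + neonatal_cost(outc, swv, pk)
    }
  }

  tibble(strategy = strategy, stratum = stratum, woman = seq_len(n),
         true_delivery_within_7d = true7, test_positive = positive,
         treated = positive, delivery_week = delivery_week,
         outcome = outcome, cost_eur = cost)
}

draw_outcomes <- function(n, si, treated, pk, outc_prob) {
  draw_outcomes_by_week(rep(si, n), treated, pk, outc_prob)
}

draw_outcomes_by_week <- function(swv, treated, pk, outc_prob) {
  col <- ifelse(treated, 2L, 1L)
  pd <- outc_prob$pd[cbind(swv, col)]
  pm <- outc_prob$pm[cbind(swv, col)]
  u <- runif(length(swv))
  ifelse(u < pd, "death", ifelse(u < pd + pm, "severe_morbidity", "none"))
}

neonatal_cost <- function(outcome, swv, pk) {
  ifelse(outcome == "death", pk$c_death[swv],
         ifelse(outcome == "severe_morbidity", pk$c_morb[swv],
                pk$c_nomorb[swv]))
}

#' Simulate one woman's trajectory with her weekly state path
#'
#' Scalar companion of [simulate_trajectories()]: returns the full weekly
#' state path alongside the summary fields.
#'
#' @inheritParams simulate_trajectories
#' @return A list of class `tpl_trajectory` with the summary fields of
#'   [simulate_trajectories()] plus `path`, a tibble of `(week, state)` rows.
#' @export
simulate_woman <- function(params, strategy, stratum, seed = 1) {
  traj <- simulate_trajectories(params, strategy, stratum, n = 1, seed = seed)
  pk <- build_pack(params)
  si <- match(stratum, STRATA)
  # replay the same draws to recover the weekly path
  set.seed(seed)
  true7 <- runif(1) < pk$inc
  u_test <- runif(1)
  positive <- if (true7) u_test < pk$sens[[strategy]] else
    u_test < 1 - pk$spec[[strategy]]
  path <- tibble(week = pk$entry[si], state = if (positive) "REHOSP" else "HOME")
  if (true7) {
    path <- bind_rows(path, tibble(week = pk$entry[si],
                                   state = "DELIVERED_PRETERM"))
  } else {
    p_dgr <- if (positive) pk$pdgr_t else pk$pdgr_u
    state <- 0L
    for (t in seq_len(pk$K[si])) {
      week <- pk$entry[si] + t
      if (week < pk$horizon) {
        u <- runif(1)
        if (state == 0L) {
          state <- if (u < pk$p_home[si]) 0L
                   else if (u < pk$p_home[si] + pk$q[si]) 1L else 2L
        } else {
          state <- if (u < p_dgr) 2L else 0L
        }
        path <- bind_rows(path, tibble(
          week = week,
          state = c("HOME", "REHOSP", "DELIVERED_PRETERM")[state + 1L]))
        if (state == 2L) break
      } else {
        path <- bind_rows(path, tibble(week = week, state = "DELIVERED_TERM"))
      }
    }
  }
  structure(c(as.list(traj), list(path = path)), class = "tpl_trajectory")
}

#' @export
print.tpl_trajectory <- function(x, ...) {
  cat(sprintf("Woman trajectory (%s, GA %s): %s, delivered week %s, outcome %s, cost %.0f EUR\n",
              x$strategy, x$stratum,
              if (x$test_positive) "test positive" else "test negative",
              format(x$delivery_week), x$outcome, x$cost_eur))
  print(x$path)
  invisible(x)
}

#' Empirical cohort payoffs by microsimulation
#'
#' Means and Monte-Carlo standard errors of cost and of the serious
#' adverse-event indicator over `n` simulated women - the brute-force oracle
#' for [evaluate_strategy()].
#'
#' @inheritParams simulate_trajectories
#' @param keep Return the per-woman tibble as attribute `"women"`.
#' @return A one-row tibble: `strategy`, `stratum`, `n`, `cost_mean`,
#'   `cost_se`, `adverse_mean`, `adverse_se`.
#' @export
simulate_cohort <- function(params, strategy, stratum, n, seed = 1,
                            keep = FALSE) {
  women <- simulate_trajectories(params, strategy, stratum, n, seed)
  adverse <- women$outcome != "none"
  out <- tibble(
    strategy = strategy, stratum = stratum, n = n,
    cost_mean = mean(women$cost_eur),
    cost_se = stats::sd(women$cost_eur) / sqrt(n),
    adverse_mean = mean(adverse),
    adverse_se = stats::sd(adverse) / sqrt(n))
  if (keep) attr(out, "women") <- women
  out
}
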