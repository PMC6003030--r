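# Weekly Markov follow-up of women who did not deliver within 7 days.
#
# States: HOME (transient), REHOSP (transient), DELIVERED_PRETERM and
# DELIVERED_TERM (absorbing). One cycle = one gestational week; at the
# 37-week horizon all remaining mass is absorbed into DELIVERED_TERM.

MARKOV_STATES <- c("HOME", "REHOSP", "DELIVERED_PRETERM", "DELIVERED_TERM")

# stratum index (1..3) whose outcome/cost parameters apply to a delivery in
# gestational week w; weeks 35-36 reuse the 32-34 values
stratum_of_week <- function(w) {
  ifelse(w <= 27, 1L, ifelse(w <= 31, 2L, 3L))
}

# Cumulative probability of at least one re-hospitalization before delivery
# or term, under weekly hazard q from HOME. Once a woman leaves the
# never-re-admitted HOME mass she cannot re-enter it, so the recursion only
# tracks that mass.
cumulative_rehosp <- function(q, p_home, n_weeks) {
  h <- 1
  cum <- 0
  for (t in seq_len(n_weeks)) {
    cum <- cum + q * h
    h <- h * p_home
  }
  cum
}

#' Weekly re-hospitalization hazard
#'
#' Solves, by root bisection, the constant weekly hazard `q` of moving from
#' home follow-up to a new hospitalization such that the cumulative
#' probability of at least one re-admission over the remaining weeks to the
#' 37-week horizon equals the target `p_subsequent_hosp`.
#'
#' @param p_home_followup Weekly probability of remaining in home follow-up.
#' @param p_subsequent_hosp Target cumulative re-admission probability.
#' @param n_weeks Number of weekly cycles to the horizon.
#' @param tol Root tolerance (default `1e-10`).
#' @return The weekly hazard `q`, with `p_home_followup + q <= 1`.
#' @export
#' @examples
#' rehosp_hazard(0.94, 0.13, 12)
rehosp_hazard <- function(p_home_followup, p_subsequent_hosp, n_weeks,
                          tol = 1e-10) {
  stopifnot(n_weeks >= 1,
            p_home_followup >= 0, p_home_followup <= 1,
            p_subsequent_hosp >= 0, p_subsequent_hosp <= 1)
  if (p_subsequent_hosp == 0) return(0)
  q_max <- 1 - p_home_followup
  if (q_max <= 0 || cumulative_rehosp(q_max, p_home_followup, n_weeks) <
      p_subsequent_hosp - tol) {
    abort(sprintf(paste0(
      "Infeasible weekly transitions: home-follow-up probability %g leaves ",
      "no room for a weekly re-admission hazard reaching a cumulative %g ",
      "over %d weeks."), p_home_followup, p_subsequent_hosp, n_weeks),
      class = "tpl_calibration_infeasible_error")
  }
  f <- function(q) cumulative_rehosp(q, p_home_followup, n_weeks) -
    p_subsequent_hosp
  uniroot(f, c(0, q_max), tol = tol)$root
}

#' Weekly transition rows of the follow-up Markov model
#'
#' Transition probabilities applied when moving from gestational week `week`
#' to `week + 1` for a given stratum. From HOME a woman stays with the weekly
#' home-follow-up probability, is re-hospitalized with the solved weekly
#' hazard, and otherwise delivers preterm; from REHOSP she delivers with the
#' (treated- or untreated-pathway) tuning probability and otherwise returns
#' home. At the horizon all transient mass moves to DELIVERED_TERM. Absorbing
#' states self-loop.
#'
#' @param params A [tpl_parameters()] object.
#' @param stratum One of `"24-27"`, `"28-31"`, `"32-34"`.
#' @param week Gestational week the cycle starts from (`entry_week <= week <
#'   horizon_week`).
#' @param treated Whether the woman is on a treated (test-positive) pathway.
#' @return A tibble with columns `from`, `to`, `probability`; probabilities
#'   out of each state sum to 1.
#' @export
weekly_transition <- function(params, stratum, week, treated = FALSE) {
  stopifnot(inherits(params, "tpl_parameters"))
  stratum <- match.arg(stratum, STRATA)
  s <- params$strata[[stratum]]
  horizon <- params$horizon_week
  if (week < s$entry_week || week >= horizon) {
    abort(sprintf("`week` must lie in [%d, %d).", s$entry_week, horizon))
  }
  p_home <- s$p_home_followup$point
  K <- horizon - s$entry_week
  q <- rehosp_hazard(p_home, s$p_subsequent_hosp$point, K)
  p_dgr <- if (treated) params$markov_tuning$p_deliver_given_rehosp_treated
           else params$markov_tuning$p_deliver_given_rehosp_untreated
  if (week + 1 < horizon) {
    rows <- tibble(
      from = c("HOME", "HOME", "HOME", "REHOSP", "REHOSP"),
      to = c("HOME", "REHOSP", "DELIVERED_PRETERM", "DELIVERED_PRETERM", "HOME"),
      probability = c(p_home, q, 1 - p_home - q, p_dgr, 1 - p_dgr))
  } else {
    rows <- tibble(
      from = c("HOME", "REHOSP"),
      to = c("DELIVERED_TERM", "DELIVERED_TERM"),
      probability = c(1, 1))
  }
  bind_rows(rows, tibble(
    from = c("DELIVERED_PRETERM", "DELIVERED_TERM"),
    to = c("DELIVERED_PRETERM", "DELIVERED_TERM"),
    probability = c(1, 1)))
}

# ---- internal numeric pack -------------------------------------------------
# Flat numeric representation of the parameters used by all hot loops (base
# case, scenarios, calibration, PSA). Point values unless `values` supplies
# sampled replacements.

build_pack <- function(params) {
  s3 <- params$strata
  deliv_item <- params$delivery_admission_cost
  pk <- list(
    inc = params$incidence$point,
    horizon = params$horizon_week,
    entry = vapply(s3, function(s) as.numeric(s$entry_week), 0),
    p_home = vapply(s3, function(s) s$p_home_followup$point, 0),
    p_subs = vapply(s3, function(s) s$p_subsequent_hosp$point, 0),
    p_death = vapply(s3, function(s) s$p_death$point, 0),
    p_morb = vapply(s3, function(s) s$p_morbidity$point, 0),
    weekly = vapply(s3, function(s) s$costs$weekly_home_followup$point, 0),
    prenatal = vapply(s3, function(s) s$costs$prenatal_hosp_tpl$point, 0),
    deliv_adm = vapply(s3, function(s) s$costs[[deliv_item]]$point, 0),
    c_death = vapply(s3, function(s) s$costs$perinatal_death$point, 0),
    c_nomorb = vapply(s3, function(s) s$costs$neonatal_hosp_no_morbidity$point, 0),
    c_morb = vapply(s3, function(s) s$costs$neonatal_hosp_with_morbidity$point, 0),
    term = vapply(s3, function(s) s$costs$term_delivery$point, 0),
    sens = vapply(params$strategies, function(st) st$sensitivity$point, 0),
    spec = vapply(params$strategies, function(st) st$specificity$point, 0),
    w = as.numeric(params$ga_weights),
    rr_d = params$treatment$rr_death_treated,
    rr_m = params$treatment$rr_morbidity_treated,
    pdgr_t = params$markov_tuning$p_deliver_given_rehosp_treated,
    pdgr_u = params$markov_tuning$p_deliver_given_rehosp_untreated)
  pk$K <- as.integer(pk$horizon - pk$entry)
  pk$q <- vapply(1:3, function(i)
    rehosp_hazard(pk$p_home[i], pk$p_subs[i], pk$K[i]), 0)
  infeasible <- pk$p_home + pk$q > 1 + 1e-12
  if (any(infeasible)) {
    abort(sprintf("Weekly transitions infeasible in stratum %s.",
                  paste(STRATA[infeasible], collapse = ", ")),
          class = "tpl_calibration_infeasible_error")
  }
  pk
}

# 3x2 matrices of delivery outcomes by stratum-of-delivery and pathway:
# column 1 untreated, column 2 treated
pack_outcomes <- function(pk) {
  pd_u <- pk$p_death; pm_u <- pk$p_morb
  pd_t <- pd_u * pk$rr_d; pm_t <- pm_u * pk$rr_m
  if (any(pd_u + pm_u > 1 + 1e-12) || any(pd_t + pm_t > 1 + 1e-12)) {
    abort("Death + morbidity probability exceeds 1 at a delivery node.",
          class = "tpl_domain_error")
  }
  adv <- cbind(untreated = pd_u + pm_u, treated = pd_t + pm_t)
  neo <- cbind(
    untreated = pd_u * pk$c_death + pm_u * pk$c_morb +
      (1 - pd_u - pm_u) * pk$c_nomorb,
    treated = pd_t * pk$c_death + pm_t * pk$c_morb +
      (1 - pd_t - pm_t) * pk$c_nomorb)
  list(adv = adv, neo = neo)
}

# Forward cohort recursion for one stratum/pathway. Weekly home-follow-up cost
# accrues to women in HOME at the start of each cycle; an admission cost is
# charged on each entry into REHOSP; deliveries are priced at the
# stratum-of-delivery-week. No discounting, no half-cycle correction.
markov_core <- function(pk, si, treated, outc = pack_outcomes(pk),
                        detail = FALSE) {
  col <- if (treated) 2L else 1L
  p_dgr <- if (treated) pk$pdgr_t else pk$pdgr_u
  p_home <- pk$p_home[si]; q <- pk$q[si]
  p_del_home <- 1 - p_home - q
  entry <- pk$entry[si]; K <- pk$K[si]; horizon <- pk$horizon
  h <- 1; r <- 0; cost <- 0; adv <- 0; pp <- 0
  weeks <- if (detail) numeric(K) else NULL
  for (t in seq_len(K)) {
    week <- entry + t
    cost <- cost + h * pk$weekly[si]
    if (week < horizon) {
      sw <- stratum_of_week(week)
      del <- p_del_home * h + p_dgr * r
      to_r <- q * h
      cost <- cost + to_r * pk$prenatal[sw] +
        del * (pk$deliv_adm[sw] + outc$neo[sw, col])
      adv <- adv + del * outc$adv[sw, col]
      pp <- pp + del
      if (detail) weeks[t] <- del
      h_new <- p_home * h + (1 - p_dgr) * r
      r <- to_r
      h <- h_new
    } else {
      cost <- cost + (h + r) * pk$term[si]
      h <- 0; r <- 0
    }
  }
  out <- c(cost = unname(cost), adverse = unname(adv),
           p_preterm = unname(pp), p_term = 1 - unname(pp))
  if (detail) attr(out, "delivery_weeks") <- setNames(weeks, entry + seq_len(K))
  out
}

#' Expected payoffs of the weekly follow-up model
#'
#' Rolls the weekly Markov cohort model forward from presentation to the
#' 37-week horizon for women who did not deliver within 7 days, and returns
#' the expected cost and expected probability of a serious neonatal adverse
#' event (perinatal death or severe neonatal morbidity), together with the
#' preterm/term delivery split.
#'
#' @param params A [tpl_parameters()] object.
#' @param stratum Gestational-age stratum at presentation.
#' @param treated Whether later preterm deliveries follow the treated
#'   (test-positive) pathway.
#' @return A one-row tibble with columns `stratum`, `treated`, `cost`,
#'   `adverse`, `p_preterm`, `p_term`.
#' @export
#' @examples
#' evaluate_markov(tpl_parameters(), "24-27", treated = FALSE)
evaluate_markov <- function(params, stratum, treated = FALSE) {
  stopifnot(inherits(params, "tpl_parameters"))
  stratum <- match.arg(stratum, STRATA)
  pk <- build_pack(params)
  si <- match(stratum, STRATA)
  m <- markov_core(pk, si, treated)
  leak <- 1 - (m[["p_preterm"]] + m[["p_term"]])
  if (abs(leak) > 1e-9) {
    abort(sprintf("Markov mass leak %.3g at the horizon.", leak),
          class = "tpl_internal_consistency_error")
  }
  tibble(stratum = stratum, treated = treated,
         cost = m[["cost"]], adverse = m[["adverse"]],
         p_preterm = m[["p_preterm"]], p_term = m[["p_term"]])
}
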