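# Decision-tree roll-back per strategy and stratum, on top of the weekly
# Markov follow-up model.

# expected (cost, adverse) for one strategy in one stratum, given
# pre-computed markov payoffs mt/mu (treated/untreated) and entry-week
# outcome matrices
strategy_core <- function(pk, si, sens, spec, mt, mu, outc) {
  inc <- pk$inc
  p_tp <- inc * sens
  p_fn <- inc * (1 - sens)
  p_fp <- (1 - inc) * (1 - spec)
  p_tn <- (1 - inc) * spec
  cost <- p_tp * (pk$prenatal[si] + pk$deliv_adm[si] + outc$neo[si, 2L]) +
    p_fn * (pk$deliv_adm[si] + outc$neo[si, 1L]) +
    p_fp * (pk$prenatal[si] + mt[["cost"]]) +
    p_tn * mu[["cost"]]
  adverse <- p_tp * outc$adv[si, 2L] + p_fn * outc$adv[si, 1L] +
    p_fp * mt[["adverse"]] + p_tn * mu[["adverse"]]
  c(cost = unname(cost), adverse = unname(adverse))
}

# all strategies x strata as a plain list of matrices; shared by the tibble
# API, the calibration objective and the PSA loop
evaluate_pack <- function(pk) {
  outc <- pack_outcomes(pk)
  mt <- lapply(1:3, function(si) markov_core(pk, si, TRUE, outc))
  mu <- lapply(1:3, function(si) markov_core(pk, si, FALSE, outc))
  nstrat <- length(pk$sens)
  cost <- matrix(0, nstrat, 3, dimnames = list(names(pk$sens), STRATA))
  adverse <- cost
  for (si in 1:3) {
    for (k in seq_len(nstrat)) {
      v <- strategy_core(pk, si, pk$sens[k], pk$spec[k], mt[[si]], mu[[si]], outc)
      cost[k, si] <- v[["cost"]]
      adverse[k, si] <- v[["adverse"]]
    }
  }
  list(cost = cost, adverse = adverse,
       agg_cost = as.vector(cost %*% pk$w),
       agg_adverse = as.vector(adverse %*% pk$w))
}

#' Expected cost and adverse-event probability per strategy
#'
#' Rolls back the decision tree for each diagnostic strategy: test-positive
#' women are hospitalized (and treated); those delivering within 7 days incur
#' a treated preterm delivery at the entry week, the rest enter the weekly
#' Markov follow-up on the treated pathway. Test-negative women delivering
#' within 7 days incur an untreated preterm delivery; the rest enter the
#' follow-up untreated and without an initial admission. Per-stratum payoffs
#' are combined into the 24-34 aggregate with the gestational-age mix
#' weights.
#'
#' @param params A [tpl_parameters()] object.
#' @param strategies Strategy ids to evaluate (default: all seven).
#' @return A tibble with columns `strategy`, `scope` (`"24-27"`, `"28-31"`,
#'   `"32-34"`, `"24-34"`), `cost` (euros per mother-child) and `adverse`
#'   (probability of perinatal death or severe neonatal morbidity).
#' @export
#' @examples
#' evaluate_strategies(tpl_parameters(), strategies = "S7")
evaluate_strategies <- function(params, strategies = NULL) {
  stopifnot(inherits(params, "tpl_parameters"))
  ev <- evaluate_pack(build_pack(params))
  ids <- rownames(ev$cost)
  out <- bind_rows(
    tidyr::expand_grid(strategy = ids, scope = STRATA) |>
      mutate(cost = as.vector(t(ev$cost)),
             adverse = as.vector(t(ev$adverse))),
    tibble(strategy = ids, scope = "24-34",
           cost = ev$agg_cost, adverse = ev$agg_adverse))
  if (!is.null(strategies)) {
    unknown <- setdiff(strategies, ids)
    if (length(unknown)) {
      abort(sprintf("Unknown strategy id(s): %s.",
                    paste(unknown, collapse = ", ")))
    }
    out <- filter(out, .data$strategy %in% strategies)
  }
  arrange(out, match(.data$strategy, ids), match(.data$scope, c(STRATA, "24-34")))
}

#' Evaluate one strategy in one stratum (or aggregated)
#'
#' @param params A [tpl_parameters()] object.
#' @param strategy Strategy id (e.g. `"S7"`).
#' @param scope A stratum name or `"24-34"` for the weighted aggregate.
#' @return A one-row tibble with `strategy`, `scope`, `cost`, `adverse`.
#' @export
evaluate_strategy <- function(params, strategy, scope = "24-34") {
  scope <- match.arg(scope, c(STRATA, "24-34"))
  filter(evaluate_strategies(params, strategies = strategy),
         .data$scope == !!scope)
}

#' Aggregate per-stratum payoffs over the gestational-age mix
#'
#' Weighted arithmetic mean of costs and adverse-event probabilities over the
#' three gestational-age strata (the "proportion of mothers" adjustment).
#'
#' @param results A tibble with columns `strategy`, `scope`, `cost`,
#'   `adverse` containing the three stratum rows per strategy.
#' @param weights Three nonnegative weights summing to 1, in stratum order
#'   24-27, 28-31, 32-34.
#' @return A tibble with one `scope = "24-34"` row per strategy.
#' @export
aggregate_ga <- function(results, weights) {
  if (length(weights) != 3 || any(weights < 0) || abs(sum(weights) - 1) > 1e-9) {
    abort("`weights` must be three nonnegative values summing to 1.",
          class = "tpl_validation_error")
  }
  w <- setNames(as.numeric(weights), STRATA)
  missing <- setdiff(STRATA, unique(results$scope))
  if (length(missing)) {
    abort(sprintf("Missing stratum rows: %s.", paste(missing, collapse = ", ")))
  }
  results |>
    filter(.data$scope %in% STRATA) |>
    group_by(.data$strategy) |>
    summarise(cost = sum(.data$cost * w[.data$scope]),
              adverse = sum(.data$adverse * w[.data$scope]),
              .groups = "drop") |>
    mutate(scope = "24-34", .after = "strategy")
}
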