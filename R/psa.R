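# Probabilistic sensitivity analysis: method-of-moments distribution fits to
# (point, range, family), seeded Monte-Carlo propagation through the full
# model, and cost-effectiveness-plane quadrant summaries.

#' Fit a sampling distribution to an uncertain parameter
#'
#' The default rule reads the published range as a central 95% interval, so
#' the standard deviation is `(high - low) / 3.92`, and fits the stated
#' family by method of moments with the mean pinned at the point estimate:
#' beta via `(mean, sd) -> (alpha, beta)`, gamma via `shape = mean^2/sd^2`,
#' `scale = sd^2/mean`, log-normal by matching the mean and sd of the
#' positive variate. Alternative range readings are available: `"se"` treats
#' the range as point +/- one standard error, `"uniform"` samples uniformly
#' on `[low, high]`. A degenerate range or `family = "fixed"` yields a point
#' mass.
#'
#' @param param An [uparam()] (or the four fields given separately).
#' @param low,high,family See [uparam()]; ignored when `param` is an uparam.
#' @param range_rule `"ci95"` (default), `"se"` or `"uniform"`.
#' @return An object of class `tpl_dist` with closed-form `mean`/`sd` fields;
#'   see [dist_mean()].
#' @export
#' @examples
#' fit_distribution(uparam(0.78, 0.68, 0.87, "beta"))
fit_distribution <- function(param, low = NULL, high = NULL, family = NULL,
                             range_rule = c("ci95", "se", "uniform")) {
  range_rule <- match.arg(range_rule)
  if (!is_uparam(param)) {
    param <- uparam(param, low %||% param, high %||% param,
                    family %||% "fixed")
  }
  m <- param$point
  sd <- switch(range_rule,
               ci95 = (param$high - param$low) / 3.92,
               se = (param$high - param$low) / 2,
               uniform = (param$high - param$low) / sqrt(12))
  if (param$family == "fixed" || sd == 0) {
    return(structure(list(family = "fixed", mean = m, sd = 0, point = m),
                     class = "tpl_dist"))
  }
  if (range_rule == "uniform") {
    return(structure(list(family = "uniform", mean = (param$low + param$high) / 2,
                          sd = sd, low = param$low, high = param$high),
                     class = "tpl_dist"))
  }
  v <- sd^2
  fit <- switch(param$family,
    beta = {
      if (v >= m * (1 - m)) {
        abort(sprintf(paste0(
          "Range [%g, %g] implies variance %.3g >= mean(1-mean) = %.3g: ",
          "no beta distribution has these moments; review the range."),
          param$low, param$high, v, m * (1 - m)),
          class = "tpl_fit_error")
      }
      ab <- m * (1 - m) / v - 1
      list(family = "beta", mean = m, sd = sd,
           shape1 = m * ab, shape2 = (1 - m) * ab)
    },
    gamma = {
      if (m <= 0) abort("Gamma fit requires a positive mean.",
                        class = "tpl_fit_error")
      list(family = "gamma", mean = m, sd = sd,
           shape = m^2 / v, scale = v / m)
    },
    lognormal = {
      if (m <= 0) abort("Log-normal fit requires a positive mean.",
                        class = "tpl_fit_error")
      s2 <- log(1 + v / m^2)
      list(family = "lognormal", mean = m, sd = sd,
           meanlog = log(m) - s2 / 2, sdlog = sqrt(s2))
    },
    abort(sprintf("Cannot fit family `%s`.", param$family),
          class = "tpl_fit_error"))
  structure(fit, class = "tpl_dist")
}

#' Closed-form mean and standard deviation of a fitted distribution
#'
#' @param fit A `tpl_dist` from [fit_distribution()].
#' @return The analytic mean (resp. sd) of the fitted distribution.
#' @export
dist_mean <- function(fit) {
  stopifnot(inherits(fit, "tpl_dist"))
  switch(fit$family,
         fixed = fit$point,
         uniform = (fit$low + fit$high) / 2,
         beta = fit$shape1 / (fit$shape1 + fit$shape2),
         gamma = fit$shape * fit$scale,
         lognormal = exp(fit$meanlog + fit$sdlog^2 / 2))
}

#' @rdname dist_mean
#' @export
dist_sd <- function(fit) {
  stopifnot(inherits(fit, "tpl_dist"))
  switch(fit$family,
         fixed = 0,
         uniform = (fit$high - fit$low) / sqrt(12),
         beta = {
           a <- fit$shape1; b <- fit$shape2
           sqrt(a * b / ((a + b)^2 * (a + b + 1)))
         },
         gamma = sqrt(fit$shape) * fit$scale,
         lognormal = sqrt((exp(fit$sdlog^2) - 1) *
                            exp(2 * fit$meanlog + fit$sdlog^2)))
}

#' Draw from a fitted distribution
#'
#' @param fit A `tpl_dist`.
#' @param n Number of draws.
#' @return A numeric vector of length `n`.
#' @export
sample_distribution <- function(fit, n = 1) {
  stopifnot(inherits(fit, "tpl_dist"))
  switch(fit$family,
         fixed = rep(fit$point, n),
         uniform = runif(n, fit$low, fit$high),
         beta = rbeta(n, fit$shape1, fit$shape2),
         gamma = rgamma(n, shape = fit$shape, scale = fit$scale),
         lognormal = rlnorm(n, fit$meanlog, fit$sdlog))
}

# Sampling plan: every parameter with a non-fixed family, in a fixed
# documented order (strategies S_ref..S7 sensitivity then specificity;
# strata 24-27, 28-31, 32-34: p_death, p_morbidity, then the Table 2 cost
# rows top to bottom). Parameters without a stated distribution stay at
# their point value.
psa_plan <- function(params, range_rule = "ci95") {
  plan <- list()
  add <- function(u, field, index, name) {
    fit <- fit_distribution(u, range_rule = range_rule)
    if (fit$family == "fixed") return()
    plan[[length(plan) + 1]] <<- list(fit = fit, field = field,
                                      index = index, name = name)
  }
  for (k in seq_along(params$strategies)) {
    st <- params$strategies[[k]]
    add(st$sensitivity, "sens", k, paste0(st$strategy_id, ".sensitivity"))
    add(st$specificity, "spec", k, paste0(st$strategy_id, ".specificity"))
  }
  deliv_item <- params$delivery_admission_cost
  cost_fields <- c(weekly_home_followup = "weekly",
                   prenatal_hosp_tpl = "prenatal",
                   preterm_labor = NA, preterm_labor_hosp = NA,
                   perinatal_death = "c_death",
                   neonatal_hosp_no_morbidity = "c_nomorb",
                   neonatal_hosp_with_morbidity = "c_morb",
                   term_delivery = "term")
  cost_fields[[deliv_item]] <- "deliv_adm"
  for (si in seq_along(params$strata)) {
    s <- params$strata[[si]]
    add(s$p_death, "p_death", si, paste0(s$stratum, ".p_death"))
    add(s$p_morbidity, "p_morb", si, paste0(s$stratum, ".p_morbidity"))
    add(s$p_subsequent_hosp, "p_subs", si, paste0(s$stratum, ".p_subsequent_hosp"))
    add(s$p_home_followup, "p_home", si, paste0(s$stratum, ".p_home_followup"))
    for (cn in names(cost_fields)) {
      field <- cost_fields[[cn]]
      if (is.na(field)) field <- "unused"  # drawn for stream stability, discarded
      add(s$costs[[cn]], field, si, paste0(s$stratum, ".cost.", cn))
    }
  }
  plan
}

#' Run the probabilistic sensitivity analysis
#'
#' Samples every parameter carrying a distribution independently from its
#' fitted distribution (see [fit_distribution()]) in each iteration, rebuilds
#' the payoffs of all strategies in all strata plus the 24-34 aggregate, and
#' returns the draws. Deterministic given `(params, n_iter, seed)`.
#'
#' @param params A [tpl_parameters()] object (typically calibrated).
#' @param n_iter Number of Monte-Carlo iterations (default 5000).
#' @param seed RNG seed.
#' @param range_rule Range reading passed to [fit_distribution()].
#' @return A `tpl_psa` tibble with columns `iteration`, `strategy`, `scope`,
#'   `cost`, `adverse` and attributes `n_iter`, `seed`, `base` (the base-case
#'   payoff table).
#' @export
run_psa <- function(params, n_iter = 5000, seed = 20180614,
                    range_rule = c("ci95", "se", "uniform")) {
  stopifnot(inherits(params, "tpl_parameters"), n_iter >= 1)
  range_rule <- match.arg(range_rule)
  pk0 <- build_pack(params)
  plan <- psa_plan(params, range_rule = range_rule)
  ids <- names(pk0$sens)
  nstrat <- length(ids)
  scopes <- c(STRATA, "24-34")
  cost_arr <- array(NA_real_, c(n_iter, nstrat, 4))
  adv_arr <- cost_arr
  transitions_sampled <- any(vapply(plan, function(p)
    p$field %in% c("p_home", "p_subs"), TRUE))
  set.seed(seed)
  for (it in seq_len(n_iter)) {
    pk <- pk0
    ok <- tryCatch({
      for (p in plan) {
        val <- sample_distribution(p$fit, 1)
        if (p$field != "unused") pk[[p$field]][p$index] <- val
      }
      if (transitions_sampled) {
        pk$q <- vapply(1:3, function(i)
          rehosp_hazard(pk$p_home[i], pk$p_subs[i], pk$K[i]), 0)
      }
      ev <- evaluate_pack(pk)
      cost_arr[it, , 1:3] <- ev$cost
      adv_arr[it, , 1:3] <- ev$adverse
      cost_arr[it, , 4] <- ev$agg_cost
      adv_arr[it, , 4] <- ev$agg_adverse
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok)) {
      abort(sprintf("PSA iteration %d failed: %s", it, conditionMessage(ok)),
            class = "tpl_psa_iteration_error")
    }
  }
  draws <- tidyr::expand_grid(iteration = seq_len(n_iter), strategy = ids,
                              scope = scopes) |>
    mutate(cost = as.vector(aperm(cost_arr, c(3, 2, 1))),
           adverse = as.vector(aperm(adv_arr, c(3, 2, 1))))
  base <- evaluate_strategies(params)
  structure(draws, class = c("tpl_psa", class(draws)),
            n_iter = n_iter, seed = seed, range_rule = range_rule,
            base = base)
}

#' Quadrant summary of one pairwise comparison
#'
#' Classifies each Monte-Carlo draw of the incremental pair
#' `referent - alternative` into a quadrant of the cost-effectiveness plane.
#' With adverse events as the effect measure, the southwest quadrant
#' (`delta_adverse < 0` and `delta_cost < 0`) is where the referent strictly
#' dominates. Boundary draws (`delta == 0`, measure-zero under continuous
#' fits) are counted deterministically with the negative side and reported
#' in `boundary_n`.
#'
#' @param draws A `tpl_psa` object (or tibble of draws with the same columns).
#' @param referent,alternative Strategy ids to compare.
#' @param scope Stratum or `"24-34"`.
#' @return A one-row tibble: `referent`, `alternative`, `scope`, quadrant
#'   percentages `sw`, `nw`, `se`, `ne` (summing to 100), `n`, `boundary_n`.
#' @export
quadrant_summary <- function(draws, referent = "S7", alternative = "S6",
                             scope = "24-27") {
  stopifnot(all(c("iteration", "strategy", "scope", "cost", "adverse") %in%
                  names(draws)))
  scope <- match.arg(scope, c(STRATA, "24-34"))
  present <- unique(draws$strategy)
  missing <- setdiff(c(referent, alternative), present)
  if (length(missing)) {
    abort(sprintf("Strategy id(s) not in draws: %s.",
                  paste(missing, collapse = ", ")),
          class = "tpl_lookup_error")
  }
  a <- filter(as_tibble(draws), .data$scope == !!scope,
              .data$strategy == referent) |> arrange(.data$iteration)
  b <- filter(as_tibble(draws), .data$scope == !!scope,
              .data$strategy == alternative) |> arrange(.data$iteration)
  de <- a$adverse - b$adverse
  dc <- a$cost - b$cost
  n <- length(de)
  sw <- de <= 0 & dc <= 0
  nw <- de <= 0 & dc > 0
  se <- de > 0 & dc <= 0
  ne <- de > 0 & dc > 0
  tibble(referent = referent, alternative = alternative, scope = scope,
         sw = 100 * sum(sw) / n, nw = 100 * sum(nw) / n,
         se = 100 * sum(se) / n, ne = 100 * sum(ne) / n,
         n = n, boundary_n = sum(de == 0 | dc == 0))
}

#' Quadrant table over all comparators and strata
#'
#' The shape of the published probabilistic table: referent versus each other
#' strategy, by gestational-age stratum.
#'
#' @inheritParams quadrant_summary
#' @param scopes Scopes to include (default the three strata).
#' @return A tibble with one row per comparator x scope.
#' @export
quadrant_table <- function(draws, referent = "S7", scopes = STRATA) {
  alternatives <- setdiff(unique(draws$strategy), referent)
  purrr::map(scopes, function(sc) {
    purrr::map(alternatives, function(alt) {
      quadrant_summary(draws, referent = referent, alternative = alt,
                       scope = sc)
    }) |> bind_rows()
  }) |> bind_rows()
}

#' @exportS3Method generics::tidy
tidy.tpl_psa <- function(x, ...) as_tibble(x)

#' @exportS3Method generics::glance
glance.tpl_psa <- function(x, ...) {
  tibble(n_iter = attr(x, "n_iter"), seed = attr(x, "seed"),
         range_rule = attr(x, "range_rule"),
         n_strategies = length(unique(x$strategy)))
}

#' @export
print.tpl_psa <- function(x, ...) {
  cat(sprintf("PSA draws: %d iterations x %d strategies (seed %s)\n",
              attr(x, "n_iter"), length(unique(x$strategy)),
              format(attr(x, "seed"))))
  print(as_tibble(x))
  invisible(x)
}

#' Cost-effectiveness plane of one PSA comparison
#'
#' @param object A `tpl_psa` object.
#' @param referent,alternative,scope As in [quadrant_summary()].
#' @param ... Unused.
#' @return A ggplot of the incremental draws with quadrant proportions.
#' @exportS3Method ggplot2::autoplot
autoplot.tpl_psa <- function(object, referent = "S7", alternative = "S6",
                             scope = "24-27", ...) {
  a <- filter(as_tibble(object), .data$scope == !!scope,
              .data$strategy == referent) |> arrange(.data$iteration)
  b <- filter(as_tibble(object), .data$scope == !!scope,
              .data$strategy == alternative) |> arrange(.data$iteration)
  df <- tibble(delta_adverse = a$adverse - b$adverse,
               delta_cost = a$cost - b$cost)
  qs <- quadrant_summary(object, referent, alternative, scope)
  ggplot2::ggplot(df, ggplot2::aes(.data$delta_adverse, .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.6) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey40") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey40") +
    ggplot2::labs(
      title = sprintf("%s vs %s, GA %s", referent, alternative, scope),
      subtitle = sprintf("SW %.0f%%  NW %.0f%%  SE %.0f%%  NE %.0f%%",
                         qs$sw, qs$nw, qs$se, qs$ne),
      x = expression(Delta * " adverse events"),
      y = expression(Delta * " cost (2012 €)")) +
    ggplot2::theme_minimal()
}
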