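#' Uncertain model parameter
#'
#' A point estimate together with a plausibility range and the distribution
#' family used when the parameter is sampled in the probabilistic sensitivity
#' analysis. Ranges are read as central 95% intervals by default (see
#' [fit_distribution()]).
#'
#' @param point Point estimate (base-case value).
#' @param low,high Range bounds; default to `point` (a fixed parameter).
#' @param family One of `"beta"`, `"gamma"`, `"lognormal"`, `"fixed"`.
#' @return A list of class `tpl_uparam` with fields `point`, `low`, `high`,
#'   `family`.
#' @export
#' @examples
#' uparam(0.78, 0.68, 0.87, "beta")
uparam <- function(point, low = point, high = point, family = "fixed") {
  fam <- match.arg(family, c("beta", "gamma", "lognormal", "fixed"))
  structure(list(point = as.numeric(point), low = as.numeric(low),
                 high = as.numeric(high), family = fam),
            class = "tpl_uparam")
}

is_uparam <- function(x) inherits(x, "tpl_uparam")

#' @export
print.tpl_uparam <- function(x, ...) {
  cat(sprintf("<uparam> %g [%g, %g] %s\n", x$point, x$low, x$high, x$family))
  invisible(x)
}

# GA strata used throughout; order matters (weights, packing, aggregation).
STRATA <- c("24-27", "28-31", "32-34")
STRATEGIES <- c("S_ref", "S2", "S3", "S4", "S5", "S6", "S7")

strategy_labels <- c(
  S_ref = "CL < 25 mm",
  S2    = "Qualitative fFN",
  S3    = "Quantitative fFN",
  S4    = "Cervical IL-6",
  S5    = "Combination CL < 18 mm, plasma RANTES, plasma IL-10",
  S6    = "CL < 15 mm",
  S7    = "CL < 15 mm or CL 16-30 mm and qualitative fFN"
)

# Built-in base-case inputs: diagnostic performances, per-stratum outcome and
# transition probabilities, and 2012 euro costs, each with range and sampling
# family. Parameters without a stated distribution are fixed.
default_parameter_list <- function() {
  list(
    incidence = uparam(0.097, 0.05, 0.15, "fixed"),
    strategies = list(
      S_ref = list(
        strategy_id = "S_ref", label = strategy_labels[["S_ref"]],
        sensitivity = uparam(0.78, 0.68, 0.87, "beta"),
        specificity = uparam(0.71, 0.67, 0.74, "beta")),
      S2 = list(
        strategy_id = "S2", label = strategy_labels[["S2"]],
        sensitivity = uparam(0.75, 0.66, 0.83, "beta"),
        specificity = uparam(0.76, 0.73, 0.79, "beta")),
      S3 = list(
        strategy_id = "S3", label = strategy_labels[["S3"]],
        sensitivity = uparam(0.59, 0.36, 0.95, "beta"),
        specificity = uparam(0.94, 0.91, 0.97, "beta")),
      S4 = list(
        strategy_id = "S4", label = strategy_labels[["S4"]],
        sensitivity = uparam(0.83, 0.53, 1.00, "beta"),
        specificity = uparam(0.94, 0.89, 0.99, "beta")),
      S5 = list(
        strategy_id = "S5", label = strategy_labels[["S5"]],
        sensitivity = uparam(0.74, 0.63, 0.85, "beta"),
        specificity = uparam(0.86, 0.79, 0.93, "beta")),
      S6 = list(
        strategy_id = "S6", label = strategy_labels[["S6"]],
        sensitivity = uparam(0.60, 0.53, 0.67, "beta"),
        specificity = uparam(0.90, 0.89, 0.92, "beta")),
      S7 = list(
        strategy_id = "S7", label = strategy_labels[["S7"]],
        sensitivity = uparam(0.89, 0.83, 0.95, "beta"),
        specificity = uparam(0.70, 0.67, 0.73, "beta"))
    ),
    strata = list(
      `24-27` = list(
        stratum = "24-27", entry_week = 25,
        p_death            = uparam(0.392, 0.35, 0.44, "beta"),
        p_morbidity        = uparam(0.303, 0.25, 0.36, "beta"),
        p_subsequent_hosp  = uparam(0.13),
        p_home_followup    = uparam(0.94),
        costs = list(
          weekly_home_followup         = uparam(42),
          prenatal_hosp_tpl            = uparam(1445, 532, 2736, "gamma"),
          preterm_labor                = uparam(2877, 1327, 11570, "lognormal"),
          preterm_labor_hosp           = uparam(2890, 1332, 11594, "lognormal"),
          perinatal_death              = uparam(1867, 323, 80068, "lognormal"),
          neonatal_hosp_no_morbidity   = uparam(27295, 1380, 78887, "lognormal"),
          neonatal_hosp_with_morbidity = uparam(58775, 2406, 79591, "gamma"),
          term_delivery                = uparam(0))),
      `28-31` = list(
        stratum = "28-31", entry_week = 29,
        p_death            = uparam(0.078, 0.05, 0.10, "beta"),
        p_morbidity        = uparam(0.085, 0.059, 0.11, "beta"),
        p_subsequent_hosp  = uparam(0.17),
        p_home_followup    = uparam(0.938),
        costs = list(
          weekly_home_followup         = uparam(42),
          prenatal_hosp_tpl            = uparam(1762, 532, 5370, "gamma"),
          preterm_labor                = uparam(3606, 1318, 11525, "lognormal"),
          preterm_labor_hosp           = uparam(3639, 1328, 11626, "lognormal"),
          perinatal_death              = uparam(1235, 323, 18976, "lognormal"),
          neonatal_hosp_no_morbidity   = uparam(19748, 1380, 79394, "lognormal"),
          neonatal_hosp_with_morbidity = uparam(40419, 2150, 79690, "gamma"),
          term_delivery                = uparam(0))),
      `32-34` = list(
        stratum = "32-34", entry_week = 33,
        p_death            = uparam(0.033, 0.009, 0.057, "beta"),
        p_morbidity        = uparam(0.016, 0, 0.034, "beta"),
        p_subsequent_hosp  = uparam(0.27),
        p_home_followup    = uparam(0.916),
        costs = list(
          weekly_home_followup         = uparam(42),
          prenatal_hosp_tpl            = uparam(2113, 532, 11625, "gamma"),
          preterm_labor                = uparam(4482, 1334, 11625, "lognormal"),
          preterm_labor_hosp           = uparam(4517, 1343, 11821, "lognormal"),
          perinatal_death              = uparam(1606, 323, 57387, "lognormal"),
          neonatal_hosp_no_morbidity   = uparam(10907, 1380, 61756, "lognormal"),
          neonatal_hosp_with_morbidity = uparam(20331, 1380, 36321, "gamma"),
          term_delivery                = uparam(0)))
    ),
    # pooled 24-34 outcome rows; carried for completeness, not used by the model
    pooled_outcomes = list(
      p_death     = uparam(0.109, 0.09, 0.13),
      p_morbidity = uparam(0.07, 0.054, 0.086)
    ),
    ga_weights = c(`24-27` = 1 / 3, `28-31` = 1 / 3, `32-34` = 1 / 3),
    treatment = list(rr_death_treated = 0.7, rr_morbidity_treated = 0.7),
    markov_tuning = list(p_deliver_given_rehosp_treated = 0.5,
                         p_deliver_given_rehosp_untreated = 0.5),
    horizon_week = 37,
    # which Table 2 row prices the maternal delivery admission
    delivery_admission_cost = "preterm_labor_hosp"
  )
}

#' Model parameters for the threatened-preterm-labor model
#'
#' Returns the full parameter set of the decision model: incidence of delivery
#' within 7 days, the seven diagnostic strategies with their sensitivity and
#' specificity, the three gestational-age strata with outcome probabilities,
#' weekly-transition inputs and 2012 euro cost sets, the gestational-age mix
#' weights, the treatment relative risks and the Markov tuning knobs. Called
#' with no arguments it returns the built-in base-case set; `overrides` (a
#' nested list mirroring the parameter structure) replaces any subset of
#' values.
#'
#' @param overrides Optional nested list of overrides. Scalars replace scalars;
#'   an [uparam()] (or a list with fields `point`/`low`/`high`/`family`)
#'   replaces an uncertain parameter; a bare number given for an uncertain
#'   parameter replaces its point estimate only.
#' @param validate Stop on invariant violations (default `TRUE`).
#' @return An object of class `tpl_parameters`.
#' @seealso [load_parameters()], [validate_parameters()], [parameter_table()]
#' @export
#' @examples
#' p <- tpl_parameters()
#' p$incidence$point
#' p5 <- tpl_parameters(list(incidence = 0.05))
#' p5$incidence$point
tpl_parameters <- function(overrides = NULL, validate = TRUE) {
  params <- default_parameter_list()
  if (!is.null(overrides)) {
    if (!is.list(overrides)) {
      abort("`overrides` must be a nested list of parameter values.")
    }
    params <- deep_merge(params, overrides, path = "")
  }
  class(params) <- "tpl_parameters"
  if (validate) assert_valid_parameters(params)
  params
}

# Recursive override merge. Unknown keys are configuration errors; a bare
# number offered for an uncertain parameter overrides only its point (and
# collapses the range onto it when the range would no longer bracket it).
deep_merge <- function(base, override, path) {
  for (key in names(override)) {
    here <- if (nzchar(path)) paste0(path, "$", key) else key
    if (!key %in% names(base)) {
      abort(sprintf("Unknown configuration key: `%s`.", here),
            class = "tpl_config_error")
    }
    value <- override[[key]]
    current <- base[[key]]
    if (is_uparam(current)) {
      base[[key]] <- coerce_uparam(current, value, here)
    } else if (is.list(current) && is.list(value)) {
      base[[key]] <- deep_merge(current, value, here)
    } else if (is.list(current) && !is.list(value)) {
      abort(sprintf("Key `%s` expects a nested list.", here),
            class = "tpl_config_error")
    } else {
      if (is.null(names(current)) || is.null(names(value))) {
        base[[key]] <- value
      } else {
        base[[key]] <- modifyList(as.list(current), as.list(value)) |>
          unlist()
      }
    }
  }
  base
}

coerce_uparam <- function(current, value, path) {
  if (is_uparam(value)) return(value)
  if (is.numeric(value) && length(value) == 1) {
    low <- min(current$low, value)
    high <- max(current$high, value)
    return(uparam(value, low, high, current$family))
  }
  if (is.list(value)) {
    fields <- setdiff(names(value), c("point", "low", "high", "family"))
    if (length(fields)) {
      abort(sprintf("Unknown field(s) %s for uncertain parameter `%s`.",
                    paste0("`", fields, "`", collapse = ", "), path),
            class = "tpl_config_error")
    }
    merged <- modifyList(unclass(current), value)
    return(uparam(merged$point, merged$low, merged$high, merged$family))
  }
  abort(sprintf("Cannot interpret value for uncertain parameter `%s`.", path),
        class = "tpl_config_error")
}

#' Load model parameters from a configuration file
#'
#' Reads a YAML (or JSON) configuration whose keys mirror the parameter
#' structure of [tpl_parameters()] in snake_case; any key not present falls
#' back to the built-in base-case value. An empty configuration therefore
#' reproduces `tpl_parameters()` exactly.
#'
#' @param source Path to a `.yaml`/`.yml`/`.json` file, or a nested list.
#' @return A validated `tpl_parameters` object.
#' @export
load_parameters <- function(source) {
  if (is.character(source) && length(source) == 1) {
    if (!file.exists(source)) {
      abort(sprintf("Configuration file not found: %s", source),
            class = "tpl_config_error")
    }
    ext <- tolower(tools::file_ext(source))
    raw <- switch(ext,
      yaml = , yml = yaml::read_yaml(source),
      json = jsonlite::fromJSON(source, simplifyVector = TRUE,
                                simplifyDataFrame = FALSE,
                                simplifyMatrix = FALSE),
      abort(sprintf("Unsupported configuration format `%s` (use YAML or JSON).",
                    ext), class = "tpl_config_error"))
  } else if (is.list(source) || is.null(source)) {
    raw <- source
  } else {
    abort("`source` must be a file path or a nested list.",
          class = "tpl_config_error")
  }
  raw <- restore_uparams(raw)
  tpl_parameters(overrides = raw)
}

# YAML round-trips uparams as plain lists; restore their class so merging
# treats them atomically.
restore_uparams <- function(x) {
  if (!is.list(x)) return(x)
  nm <- names(x)
  if (!is.null(nm) && all(c("point", "low", "high", "family") %in% nm)) {
    return(uparam(x$point, x$low, x$high, x$family))
  }
  if (!is.null(nm) && identical(sort(nm[nzchar(nm)]), sort(nm)) &&
      "point" %in% nm && !"family" %in% nm) {
    x$family <- "fixed"
    return(uparam(x$point, x$low %||% x$point, x$high %||% x$point, x$family))
  }
  lapply(x, restore_uparams)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write model parameters to a YAML configuration
#'
#' The written file round-trips: [load_parameters()] on the result yields a
#' value-identical parameter set.
#'
#' @param params A `tpl_parameters` object.
#' @param path Output file path (YAML).
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "tpl_parameters"))
  # named atomic vectors must become maps, or YAML drops their names
  listify <- function(x) {
    if (is.list(x)) lapply(x, listify)
    else if (!is.null(names(x)) && length(x) > 1) as.list(x)
    else x
  }
  yaml::write_yaml(listify(unclass(params)), path, precision = 15)
  invisible(path)
}

#' Validate model parameters
#'
#' Checks every type invariant of the parameter set and reports violations as
#' a tibble; an empty result means the parameters are valid. This is a
#' reporting operation and never throws.
#'
#' @param params A `tpl_parameters` object (or plain list with the same shape).
#' @return A tibble with columns `field`, `rule`, `message`; zero rows when
#'   all invariants hold.
#' @export
#' @examples
#' nrow(validate_parameters(tpl_parameters()))  # 0
validate_parameters <- function(params) {
  v <- list()
  bad <- function(field, rule, message) {
    v[[length(v) + 1]] <<- tibble(field = field, rule = rule, message = message)
  }
  chk_up <- function(u, field, probability = FALSE) {
    if (!is_uparam(u)) { bad(field, "type", "not an uncertain parameter"); return() }
    if (!(u$low <= u$point && u$point <= u$high)) {
      bad(field, "range_order",
          sprintf("requires low <= point <= high, got [%g, %g, %g]",
                  u$low, u$point, u$high))
    }
    if (u$family == "beta" && (u$low < 0 || u$high > 1)) {
      bad(field, "beta_support",
          sprintf("beta family requires range within [0, 1], got [%g, %g]",
                  u$low, u$high))
    }
    if (probability && (u$point < 0 || u$point > 1)) {
      bad(field, "probability_bound",
          sprintf("probability must lie in [0, 1], got %g", u$point))
    }
  }

  inc <- params$incidence
  chk_up(inc, "incidence", probability = TRUE)
  if (is_uparam(inc) && (inc$point <= 0 || inc$point >= 1)) {
    bad("incidence", "open_interval", "incidence must lie strictly in (0, 1)")
  }

  for (id in names(params$strategies)) {
    st <- params$strategies[[id]]
    for (fld in c("sensitivity", "specificity")) {
      u <- st[[fld]]
      chk_up(u, paste0("strategies$", id, "$", fld), probability = TRUE)
      if (is_uparam(u) && (u$point <= 0 || u$point > 1)) {
        bad(paste0("strategies$", id, "$", fld), "open_unit_interval",
            sprintf("%s must lie in (0, 1], got %g", fld, u$point))
      }
    }
  }

  if (length(params$strata) != 3) {
    bad("strata", "stratum_count",
        sprintf("exactly three gestational-age strata expected, got %d",
                length(params$strata)))
  }
  stratum_bounds <- list(`24-27` = c(24, 27), `28-31` = c(28, 31),
                         `32-34` = c(32, 34))
  for (sn in names(params$strata)) {
    s <- params$strata[[sn]]
    pre <- paste0("strata$", sn, "$")
    chk_up(s$p_death, paste0(pre, "p_death"), probability = TRUE)
    chk_up(s$p_morbidity, paste0(pre, "p_morbidity"), probability = TRUE)
    chk_up(s$p_subsequent_hosp, paste0(pre, "p_subsequent_hosp"), probability = TRUE)
    chk_up(s$p_home_followup, paste0(pre, "p_home_followup"), probability = TRUE)
    if (is_uparam(s$p_death) && is_uparam(s$p_morbidity) &&
        s$p_death$point + s$p_morbidity$point > 1) {
      bad(paste0(pre, "p_death"), "death_morbidity_sum",
          sprintf("death + morbidity > 1 (%g + %g) in stratum %s",
                  s$p_death$point, s$p_morbidity$point, sn))
    }
    b <- stratum_bounds[[sn]]
    if (!is.null(b) && (s$entry_week < b[1] || s$entry_week > b[2])) {
      bad(paste0(pre, "entry_week"), "entry_week_bounds",
          sprintf("entry week %g outside stratum %s", s$entry_week, sn))
    }
    for (cn in names(s$costs)) {
      u <- s$costs[[cn]]
      chk_up(u, paste0(pre, "costs$", cn))
      if (is_uparam(u) && u$point < 0) {
        bad(paste0(pre, "costs$", cn), "nonnegative_cost",
            sprintf("cost must be >= 0, got %g", u$point))
      }
    }
    cm <- s$costs$neonatal_hosp_with_morbidity
    cn0 <- s$costs$neonatal_hosp_no_morbidity
    if (is_uparam(cm) && is_uparam(cn0) && cm$point < cn0$point) {
      bad(paste0(pre, "costs$neonatal_hosp_with_morbidity"), "morbidity_cost_order",
          "neonatal hospitalization with morbidity should cost at least as much as without")
    }
  }

  w <- params$ga_weights
  if (length(w) != 3 || any(w < 0) || abs(sum(w) - 1) > 1e-9) {
    bad("ga_weights", "simplex",
        sprintf("ga_weights must be three nonnegative values summing to 1, got (%s)",
                paste(signif(w, 6), collapse = ", ")))
  }

  for (fld in c("rr_death_treated", "rr_morbidity_treated")) {
    rr <- params$treatment[[fld]]
    if (!is.numeric(rr) || rr <= 0 || rr > 1) {
      bad(paste0("treatment$", fld), "relative_risk_bound",
          sprintf("relative risk must lie in (0, 1], got %s", format(rr)))
    }
  }
  for (fld in c("p_deliver_given_rehosp_treated",
                "p_deliver_given_rehosp_untreated")) {
    pv <- params$markov_tuning[[fld]]
    if (!is.numeric(pv) || pv < 0 || pv > 1) {
      bad(paste0("markov_tuning$", fld), "probability_bound",
          sprintf("must lie in [0, 1], got %s", format(pv)))
    }
  }
  if (!identical(params$horizon_week, 37) && !identical(params$horizon_week, 37L)) {
    bad("horizon_week", "horizon_fixed", "the model horizon is 37 weeks of gestation")
  }
  if (!params$delivery_admission_cost %in% c("preterm_labor_hosp", "preterm_labor")) {
    bad("delivery_admission_cost", "cost_switch",
        "must be 'preterm_labor_hosp' or 'preterm_labor'")
  }

  if (length(v)) bind_rows(v) else
    tibble(field = character(), rule = character(), message = character())
}

assert_valid_parameters <- function(params) {
  v <- validate_parameters(params)
  if (nrow(v)) {
    abort(paste0("Invalid model parameters:\n",
                 paste0("- ", v$field, ": ", v$message, collapse = "\n")),
          class = "tpl_validation_error")
  }
  invisible(params)
}

#' Tabulate model parameters
#'
#' Flattens the parameter set into a tibble with one row per scalar parameter,
#' suitable for CSV export and for table-driven checks of the base-case inputs.
#'
#' @param params A `tpl_parameters` object.
#' @return A tibble with columns `name`, `point`, `low`, `high`, `family`,
#'   `source`.
#' @export
parameter_table <- function(params) {
  stopifnot(inherits(params, "tpl_parameters"))
  rows <- list()
  add <- function(name, u, source) {
    rows[[length(rows) + 1]] <<- tibble(
      name = name, point = u$point, low = u$low, high = u$high,
      family = u$family, source = source)
  }
  add("incidence", params$incidence, "epidemiology")
  for (id in names(params$strategies)) {
    st <- params$strategies[[id]]
    add(paste0(id, ".sensitivity"), st$sensitivity, "diagnostic_performance")
    add(paste0(id, ".specificity"), st$specificity, "diagnostic_performance")
  }
  for (sn in names(params$strata)) {
    s <- params$strata[[sn]]
    for (fld in c("p_death", "p_morbidity", "p_subsequent_hosp",
                  "p_home_followup")) {
      add(paste0(sn, ".", fld), s[[fld]], "outcome_transition")
    }
    for (cn in names(s$costs)) {
      add(paste0(sn, ".cost.", cn), s$costs[[cn]], "costs_2012_eur")
    }
  }
  add("pooled_24-34.p_death", params$pooled_outcomes$p_death, "outcome_transition")
  add("pooled_24-34.p_morbidity", params$pooled_outcomes$p_morbidity,
      "outcome_transition")
  bind_rows(rows)
}

#' @exportS3Method generics::tidy
tidy.tpl_parameters <- function(x, ...) parameter_table(x)

#' @export
print.tpl_parameters <- function(x, ...) {
  cat("Threatened-preterm-labor decision model parameters\n")
  cat(sprintf("  incidence of delivery within 7 days: %.3f\n", x$incidence$point))
  cat(sprintf("  strategies: %s\n", paste(names(x$strategies), collapse = ", ")))
  cat(sprintf("  GA strata: %s (entry weeks %s)\n",
              paste(names(x$strata), collapse = ", "),
              paste(vapply(x$strata, function(s) s$entry_week, 0), collapse = ", ")))
  cat(sprintf("  GA weights: %s\n", paste(signif(x$ga_weights, 4), collapse = ", ")))
  cat(sprintf("  treatment RR (death, morbidity): %.3f, %.3f\n",
              x$treatment$rr_death_treated, x$treatment$rr_morbidity_treated))
  cat(sprintf("  P(deliver | re-hospitalized) treated/untreated: %.3f / %.3f\n",
              x$markov_tuning$p_deliver_given_rehosp_treated,
              x$markov_tuning$p_deliver_given_rehosp_untreated))
  invisible(x)
}
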