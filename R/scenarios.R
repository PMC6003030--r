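# Deterministic sensitivity analyses: named scenario overrides re-running
# the full base-case pipeline. Calibrated free parameters are frozen across
# scenarios.

new_scenario <- function(name, label, incidence = NULL, diagnostics = NULL) {
  structure(list(name = name, label = label,
                 incidence = incidence, diagnostics = diagnostics),
            class = "tpl_scenario")
}

#' @export
print.tpl_scenario <- function(x, ...) {
  cat(sprintf("<scenario> %s: %s\n", x$name, x$label))
  invisible(x)
}

#' The four deterministic sensitivity-analysis scenarios
#'
#' Two scenarios move every strategy's sensitivity and specificity jointly to
#' their range bounds (minimum sensitivity with maximum specificity, and the
#' reverse); two fix the incidence of delivery within 7 days at 5% and 15%.
#'
#' @return A named list of four `tpl_scenario` objects.
#' @export
#' @examples
#' names(paper_scenarios())
paper_scenarios <- function() {
  list(
    min_sens_max_spec = new_scenario(
      "min_sens_max_spec",
      "Minimum values of sensitivity and maximum values of specificity",
      diagnostics = "min_sens_max_spec"),
    max_sens_min_spec = new_scenario(
      "max_sens_min_spec",
      "Maximum values of sensitivity and minimum values of specificity",
      diagnostics = "max_sens_min_spec"),
    incidence_5 = new_scenario(
      "incidence_5", "Incidence of preterm birth of 5%", incidence = 0.05),
    incidence_15 = new_scenario(
      "incidence_15", "Incidence of preterm birth of 15%", incidence = 0.15))
}

#' Apply a scenario's overrides to a parameter set
#'
#' Pure: the input parameters are returned modified by value; applying a
#' scenario and reverting its overrides restores the original object.
#'
#' @param params A [tpl_parameters()] object.
#' @param scenario A `tpl_scenario` (see [paper_scenarios()]) or the name of
#'   one of the four built-in scenarios.
#' @return A `tpl_parameters` object with the overrides applied.
#' @export
apply_scenario <- function(params, scenario) {
  stopifnot(inherits(params, "tpl_parameters"))
  scenario <- resolve_scenario(scenario)
  if (!is.null(scenario$incidence)) {
    params$incidence$point <- scenario$incidence
  }
  if (!is.null(scenario$diagnostics)) {
    for (id in names(params$strategies)) {
      st <- params$strategies[[id]]
      if (scenario$diagnostics == "min_sens_max_spec") {
        st$sensitivity$point <- st$sensitivity$low
        st$specificity$point <- st$specificity$high
      } else if (scenario$diagnostics == "max_sens_min_spec") {
        st$sensitivity$point <- st$sensitivity$high
        st$specificity$point <- st$specificity$low
      } else {
        abort(sprintf("Unknown diagnostics override `%s`.", scenario$diagnostics))
      }
      params$strategies[[id]] <- st
    }
  }
  assert_valid_parameters(params)
  params
}

resolve_scenario <- function(scenario) {
  if (inherits(scenario, "tpl_scenario")) return(scenario)
  if (is.character(scenario) && length(scenario) == 1) {
    all <- paper_scenarios()
    if (!scenario %in% names(all)) {
      abort(sprintf("Unknown scenario `%s`; valid names: %s.", scenario,
                    paste(names(all), collapse = ", ")),
            class = "tpl_lookup_error")
    }
    return(all[[scenario]])
  }
  abort("`scenario` must be a tpl_scenario or a built-in scenario name.")
}

#' Run one deterministic scenario
#'
#' Evaluates all strategies under the scenario's overrides (free calibrated
#' parameters are NOT re-calibrated) and ranks them.
#'
#' @inheritParams apply_scenario
#' @param scope Scope to rank (default the 24-34 aggregate).
#' @return A `tpl_cea` table with a `"scenario"` attribute.
#' @export
run_scenario <- function(params, scenario, scope = "24-34") {
  scenario <- resolve_scenario(scenario)
  scope <- match.arg(scope, c(STRATA, "24-34"))
  res <- evaluate_strategies(apply_scenario(params, scenario)) |>
    filter(.data$scope == !!scope)
  out <- rank_strategies(res)
  attr(out, "scenario") <- scenario$name
  out
}

#' Run all four deterministic scenarios
#'
#' @inheritParams run_scenario
#' @return A tibble stacking the four ranked scenario tables with a
#'   `scenario` column.
#' @export
run_scenarios <- function(params, scope = "24-34") {
  purrr::map(paper_scenarios(), function(sc) {
    run_scenario(params, sc, scope = scope) |>
      as_tibble() |>
      mutate(scenario = sc$name, .before = 1)
  }) |>
    bind_rows()
}
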