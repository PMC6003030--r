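# Ranking, dominance and incremental cost-effectiveness ratios.
#
# Effectiveness convention: the effect measure is the probability of a
# serious neonatal adverse event, so FEWER events = MORE effective; ICERs are
# euros per additional adverse event and carry the sign of delta-cost /
# delta-events.

#' Incremental cost-effectiveness ratio
#'
#' `icer()` compares outcome `a` against outcome `b` (the comparator):
#' `delta_cost = cost_a - cost_b`, `delta_adverse = adverse_a - adverse_b`,
#' and `icer = delta_cost / delta_adverse` when the effect difference is
#' non-zero. A zero effect difference yields an undefined ICER flag, not an
#' error. Vectorised.
#'
#' @param cost_a,adverse_a Payoffs of the strategy of interest.
#' @param cost_b,adverse_b Payoffs of the comparator.
#' @return A tibble with columns `delta_cost`, `delta_adverse`, `icer`
#'   (`NA` when undefined) and `defined`.
#' @export
#' @examples
#' icer(4718, 0.0275, 3237, 0.0233)  # 352,619 euros per additional event
icer <- function(cost_a, adverse_a, cost_b, adverse_b) {
  n <- max(length(cost_a), length(adverse_a), length(cost_b), length(adverse_b))
  delta_cost <- rep_len(cost_a, n) - rep_len(cost_b, n)
  delta_adverse <- rep_len(adverse_a, n) - rep_len(adverse_b, n)
  defined <- delta_adverse != 0
  tibble(delta_cost = delta_cost, delta_adverse = delta_adverse,
         icer = ifelse(defined, delta_cost / delta_adverse, NA_real_),
         defined = defined)
}

#' Rank strategies and apply simple and extended dominance
#'
#' Strategies are sorted from least to most costly (ties broken by fewer
#' adverse events). A strategy is simply dominated when some other strategy
#' costs no more and causes no more adverse events, with at least one strict
#' inequality; exact ties in both payoffs are co-frontier. Extended dominance
#' is then applied iteratively along the cost-ordered frontier: a strategy
#' whose incremental ratio against the previous frontier point exceeds the
#' next frontier point's ratio is removed and ratios are recomputed. Every
#' non-cheapest row additionally reports its ICER against the overall
#' least-costly strategy, the convention of the published tables.
#'
#' @param results A tibble with columns `strategy`, `cost`, `adverse` (one
#'   row per strategy; a `scope` column, if present, must be constant).
#' @return A `tpl_cea` tibble with columns `strategy`, `cost`, `adverse`,
#'   `status` (`"frontier"`, `"dominated"`, `"extended_dominated"`),
#'   `icer_frontier` (euros per additional adverse event between consecutive
#'   frontier points) and `icer_vs_cheapest`.
#' @export
#' @examples
#' rank_strategies(table3_targets())
rank_strategies <- function(results) {
  stopifnot(all(c("strategy", "cost", "adverse") %in% names(results)))
  if (anyDuplicated(results$strategy)) {
    abort("Each strategy must appear exactly once (filter to one scope first).")
  }
  if ("scope" %in% names(results) && length(unique(results$scope)) > 1) {
    abort("`results` mixes scopes; filter to one scope first.")
  }
  scope <- if ("scope" %in% names(results)) unique(results$scope) else NA_character_
  tbl <- results |>
    select("strategy", "cost", "adverse") |>
    arrange(.data$cost, .data$adverse)
  n <- nrow(tbl)

  status <- rep("frontier", n)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    dom <- tbl$cost[others] <= tbl$cost[i] & tbl$adverse[others] <= tbl$adverse[i] &
      (tbl$cost[others] < tbl$cost[i] | tbl$adverse[others] < tbl$adverse[i])
    if (any(dom)) status[i] <- "dominated"
  }

  # extended dominance on the cost-ordered frontier candidates
  cand <- which(status == "frontier")
  repeat {
    if (length(cand) < 3) break
    # ratio of euros per adverse event avoided between consecutive points
    ratios <- vapply(seq_along(cand)[-1], function(k) {
      i <- cand[k]; j <- cand[k - 1]
      (tbl$cost[i] - tbl$cost[j]) / (tbl$adverse[j] - tbl$adverse[i])
    }, 0)
    worse <- which(head(ratios, -1) > ratios[-1])
    if (!length(worse)) break
    drop <- cand[worse[1] + 1]
    status[drop] <- "extended_dominated"
    cand <- setdiff(cand, drop)
  }

  icer_frontier <- rep(NA_real_, n)
  if (length(cand) > 1) {
    for (k in seq_along(cand)[-1]) {
      i <- cand[k]; j <- cand[k - 1]
      icer_frontier[i] <- (tbl$cost[i] - tbl$cost[j]) /
        (tbl$adverse[i] - tbl$adverse[j])
    }
  }
  cheapest <- 1L
  icer_vs_cheapest <- icer(tbl$cost, tbl$adverse,
                           tbl$cost[cheapest], tbl$adverse[cheapest])$icer
  icer_vs_cheapest[cheapest] <- NA_real_

  out <- tbl |>
    mutate(status = status, icer_frontier = icer_frontier,
           icer_vs_cheapest = icer_vs_cheapest)
  structure(out, class = c("tpl_cea", class(out)),
            scope = scope, cheapest = tbl$strategy[cheapest])
}

#' Headline incremental summaries against a reference strategy
#'
#' For each comparator: absolute cost saving of the reference (euros per
#' mother-child), serious adverse events avoided per 1000 newborns, relative
#' cost saving and relative adverse-event reduction (percent of the
#' comparator's values). Rounded columns use the published precision
#' (whole percent, one decimal per 1000).
#'
#' @param results A `tpl_cea` table or any tibble with `strategy`, `cost`,
#'   `adverse`.
#' @param reference Reference strategy id (default `"S7"`).
#' @return A tibble with one row per comparator.
#' @export
#' @examples
#' headline_summaries(table3_targets(), reference = "S7")
headline_summaries <- function(results, reference = "S7") {
  stopifnot(all(c("strategy", "cost", "adverse") %in% names(results)))
  if (!reference %in% results$strategy) {
    abort(sprintf("Reference strategy `%s` not present.", reference),
          class = "tpl_lookup_error")
  }
  ref <- filter(results, .data$strategy == reference)
  comp <- filter(results, .data$strategy != reference)
  tibble(
    reference = reference,
    comparator = comp$strategy,
    cost_saving_eur = comp$cost - ref$cost,
    events_avoided_per_1000 = round((comp$adverse - ref$adverse) * 1000, 1),
    rel_cost_saving_pct = round(100 * (comp$cost - ref$cost) / comp$cost),
    rel_event_reduction_pct = round(100 * (comp$adverse - ref$adverse) /
                                      comp$adverse))
}

#' @exportS3Method generics::tidy
tidy.tpl_cea <- function(x, ...) as_tibble(x)

#' @exportS3Method generics::glance
glance.tpl_cea <- function(x, ...) {
  tibble(n_strategies = nrow(x),
         n_frontier = sum(x$status == "frontier"),
         n_dominated = sum(x$status == "dominated"),
         n_extended_dominated = sum(x$status == "extended_dominated"),
         cheapest = attr(x, "cheapest"),
         scope = attr(x, "scope"))
}

#' @export
print.tpl_cea <- function(x, ...) {
  scope <- attr(x, "scope")
  cat("Cost-effectiveness ranking",
      if (!is.na(scope)) sprintf(" (GA %s)", scope) else "", "\n", sep = "")
  shown <- as_tibble(x) |>
    mutate(cost = round(.data$cost),
           adverse = round(.data$adverse, 4),
           icer_frontier = round(.data$icer_frontier),
           icer_vs_cheapest = round(.data$icer_vs_cheapest))
  print(shown, n = nrow(shown))
  invisible(x)
}

#' Cost-effectiveness plane of a ranked strategy table
#'
#' @param object A `tpl_cea` table.
#' @param ... Unused.
#' @return A ggplot: adverse-event probability against cost, points coloured
#'   by dominance status, frontier connected.
#' @exportS3Method ggplot2::autoplot
autoplot.tpl_cea <- function(object, ...) {
  df <- as_tibble(object)
  frontier <- df |> filter(.data$status == "frontier") |> arrange(.data$cost)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$adverse, y = .data$cost)) +
    ggplot2::geom_line(data = frontier, colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$status), size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$strategy),
                       vjust = -0.8, size = 3) +
    ggplot2::labs(x = "P(serious neonatal adverse event)",
                  y = "Cost per mother-child (2012 €)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
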