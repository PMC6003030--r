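# CSV/manifest emission tying the stages into the four published analyses:
# base case per GA scope, deterministic scenarios, probabilistic analysis.

scope_slug <- function(scope) gsub("-", "_", scope)

#' Write a run manifest
#'
#' Records command, configuration digest, seed, package version, timestamp
#' and the emitted files; a run is reproducible from its manifest (same
#' digest + seed gives identical outputs).
#'
#' @param out_dir Output directory.
#' @param command Command name.
#' @param params The parameters the run used.
#' @param files Character vector of emitted file paths.
#' @param seed Seed used (or `NA`).
#' @param extra Named list folded into the manifest.
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(out_dir, command, params, files, seed = NA,
                           extra = list()) {
  manifest <- c(list(
    command = command,
    config_digest = rlang::hash(unclass(params)),
    seed = seed,
    package = "tplcea",
    version = as.character(utils::packageVersion("tplcea")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = basename(files)), extra)
  path <- file.path(out_dir, paste0("manifest_", command, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Run the base-case cost-effectiveness analysis and write its tables
#'
#' Emits one ranked cost-effectiveness CSV per gestational-age scope (the
#' three strata and the 24-34 aggregate) plus a manifest.
#'
#' @param params A [tpl_parameters()] object.
#' @param out_dir Output directory (created if needed).
#' @param ga `"all"` or one scope.
#' @return Tibble of all emitted rows, invisibly.
#' @export
run_base_case <- function(params = tpl_parameters(), out_dir, ga = "all") {
  ga <- match.arg(ga, c("all", STRATA, "24-34"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scopes <- if (ga == "all") c(STRATA, "24-34") else ga
  res <- evaluate_strategies(params)
  files <- character()
  rows <- list()
  for (sc in scopes) {
    cea <- rank_strategies(filter(res, .data$scope == sc))
    out <- as_tibble(cea) |>
      mutate(scope = sc, .before = 1) |>
      rename(cost_eur = "cost", adverse_prob = "adverse",
             icer_vs_cheapest_eur = "icer_vs_cheapest")
    path <- file.path(out_dir, paste0("cea_", scope_slug(sc), ".csv"))
    readr::write_csv(out, path)
    files <- c(files, path)
    rows[[sc]] <- out
  }
  write_manifest(out_dir, "base_case", params, files)
  invisible(bind_rows(rows))
}

#' Run the four deterministic scenarios and write their tables
#'
#' @inheritParams run_base_case
#' @param scope Scope the scenario tables rank (default `"24-34"`).
#' @return Tibble of all emitted rows, invisibly.
#' @export
run_dsa <- function(params = tpl_parameters(), out_dir, scope = "24-34") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  rows <- list()
  for (sc in paper_scenarios()) {
    cea <- run_scenario(params, sc, scope = scope)
    out <- as_tibble(cea) |>
      mutate(scenario = sc$name, scope = scope, .before = 1) |>
      rename(cost_eur = "cost", adverse_prob = "adverse",
             icer_vs_cheapest_eur = "icer_vs_cheapest")
    path <- file.path(out_dir, paste0("dsa_", sc$name, ".csv"))
    readr::write_csv(out, path)
    files <- c(files, path)
    rows[[sc$name]] <- out
  }
  write_manifest(out_dir, "dsa", params, files)
  invisible(bind_rows(rows))
}

#' Run the probabilistic analysis and write quadrant and scatter tables
#'
#' @inheritParams run_base_case
#' @param n_iter Monte-Carlo iterations (default 5000; runs below 1000 are
#'   flagged `low_precision` in the manifest).
#' @param seed RNG seed.
#' @param referent Referent strategy for the pairwise comparisons.
#' @return The quadrant tibble, invisibly.
#' @export
run_psa_report <- function(params = tpl_parameters(), out_dir,
                           n_iter = 5000, seed = 20180614, referent = "S7") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  draws <- run_psa(params, n_iter = n_iter, seed = seed)
  quad <- quadrant_table(draws, referent = referent)
  qpath <- file.path(out_dir, "psa_quadrants.csv")
  readr::write_csv(quad, qpath)

  scatter <- purrr::map(setdiff(unique(draws$strategy), referent),
                        function(alt) {
    purrr::map(STRATA, function(sc) {
      a <- filter(as_tibble(draws), .data$scope == sc,
                  .data$strategy == referent) |> arrange(.data$iteration)
      b <- filter(as_tibble(draws), .data$scope == sc,
                  .data$strategy == alt) |> arrange(.data$iteration)
      tibble(iteration = a$iteration, comparator = alt, scope = sc,
             delta_cost_eur = a$cost - b$cost,
             delta_adverse = a$adverse - b$adverse)
    }) |> bind_rows()
  }) |> bind_rows()
  spath <- file.path(out_dir, "psa_scatter.csv")
  readr::write_csv(scatter, spath)

  write_manifest(out_dir, "psa", params, c(qpath, spath), seed = seed,
                 extra = list(n_iter = n_iter,
                              low_precision = n_iter < 1000,
                              referent = referent))
  invisible(quad)
}
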