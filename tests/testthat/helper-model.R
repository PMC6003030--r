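# Shared fixtures and slow shared computations (built once per test run).

.cache <- new.env(parent = emptyenv())

# Calibrated parameter set against the published base-case table; the
# calibration is deterministic given (n_starts, seed).
calibrated_fit <- function() {
  if (is.null(.cache$cal)) {
    .cache$cal <- suppressWarnings(
      calibrate_parameters(tpl_parameters(), n_starts = 20, seed = 1))
  }
  .cache$cal
}

# Parameters with the home state absorbing (no re-admission, no delivery from
# follow-up): every non-7-day deliverer reaches term.
absorbing_home_params <- function(base = tpl_parameters()) {
  ov <- list(strata = list())
  for (sn in c("24-27", "28-31", "32-34")) {
    ov$strata[[sn]] <- list(p_home_followup = uparam(1),
                            p_subsequent_hosp = uparam(0))
  }
  tpl_parameters(ov)
}

# Treatment with no effect (relative risks 1)
no_treatment_params <- function(base_overrides = NULL) {
  ov <- c(base_overrides,
          list(treatment = list(rr_death_treated = 1,
                                rr_morbidity_treated = 1)))
  tpl_parameters(ov)
}
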