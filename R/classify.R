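#' Branch probabilities of a diagnostic strategy
#'
#' Computes the 2x2 contingency structure of a test for delivery within 7 days
#' from the incidence (prevalence among women presenting with threatened
#' preterm labor) and the test's sensitivity and specificity. The joint
#' probabilities are `p_tp = incidence * sens`, `p_fn = incidence * (1 -
#' sens)`, `p_fp = (1 - incidence) * (1 - spec)`, `p_tn = (1 - incidence) *
#' spec`; the predictive values condition on the test result.
#'
#' All arguments are vectorised and recycled to a common length.
#'
#' @param incidence Probability of delivery within 7 days, strictly in (0, 1).
#' @param sensitivity,specificity Test operating characteristics in (0, 1].
#' @return A tibble with columns `p_positive`, `p_negative`, `ppv`, `npv`,
#'   `p_tp`, `p_fp`, `p_tn`, `p_fn`.
#' @export
#' @examples
#' classify(0.097, 0.78, 0.71)  # CL < 25 mm reference strategy
classify <- function(incidence, sensitivity, specificity) {
  n <- max(length(incidence), length(sensitivity), length(specificity))
  incidence <- rep_len(incidence, n)
  sensitivity <- rep_len(sensitivity, n)
  specificity <- rep_len(specificity, n)
  if (any(incidence <= 0 | incidence >= 1)) {
    abort("`incidence` must lie strictly in (0, 1).", class = "tpl_domain_error")
  }
  if (any(sensitivity < 0 | sensitivity > 1 | specificity < 0 | specificity > 1)) {
    abort("sensitivity and specificity must lie in [0, 1].",
          class = "tpl_domain_error")
  }
  p_tp <- incidence * sensitivity
  p_fn <- incidence * (1 - sensitivity)
  p_fp <- (1 - incidence) * (1 - specificity)
  p_tn <- (1 - incidence) * specificity
  p_positive <- p_tp + p_fp
  p_negative <- p_tn + p_fn
  if (any(p_positive == 0)) {
    abort("Degenerate test: P(positive) = 0, predictive values undefined.",
          class = "tpl_degenerate_test_error")
  }
  tibble(
    p_positive = p_positive, p_negative = p_negative,
    ppv = p_tp / p_positive, npv = p_tn / p_negative,
    p_tp = p_tp, p_fp = p_fp, p_tn = p_tn, p_fn = p_fn)
}

#' Expected 2x2 contingency counts
#'
#' Scales the joint classification probabilities to a cohort of `n` women.
#'
#' @inheritParams classify
#' @param n Cohort size (>= 1).
#' @return A tibble with columns `test_result` (`"positive"`/`"negative"`),
#'   `delivery_within_7d` (logical) and `expected_count`; the four counts sum
#'   to `n`.
#' @export
#' @examples
#' contingency_counts(0.097, 0.78, 0.71, n = 1000)
contingency_counts <- function(incidence, sensitivity, specificity, n = 1) {
  stopifnot(length(n) == 1, n >= 1)
  if (incidence <= 0 || incidence >= 1) {
    abort("`incidence` must lie strictly in (0, 1).", class = "tpl_domain_error")
  }
  if (sensitivity < 0 || sensitivity > 1 || specificity < 0 || specificity > 1) {
    abort("sensitivity and specificity must lie in [0, 1].",
          class = "tpl_domain_error")
  }
  joints <- c(tp = incidence * sensitivity,
              fn = incidence * (1 - sensitivity),
              fp = (1 - incidence) * (1 - specificity),
              tn = (1 - incidence) * specificity)
  tibble(
    test_result = c("positive", "negative", "positive", "negative"),
    delivery_within_7d = c(TRUE, TRUE, FALSE, FALSE),
    expected_count = n * unname(joints[c("tp", "fn", "fp", "tn")]))
}
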