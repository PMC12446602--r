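# QALY accrual, discounting, and comparative economics (ICER classification
# and net monetary benefit).

#' Discount factor
#'
#' @param elapsed_years Time since model start (>= 0).
#' @param rate Annual discount rate (> -1); 0.035 in the base case.
#' @return `(1 + rate)^(-elapsed_years)`.
#' @export
discount_factor <- function(elapsed_years, rate) {
  if (any(elapsed_years < 0)) stop("elapsed_years must be >= 0")
  if (rate <= -1) stop("rate must be > -1")
  (1 + rate)^(-elapsed_years)
}

#' QALYs accrued over one cycle
#'
#' Occupancy-weighted utility times the cycle length; both on- and
#' off-treatment compartments of an OFF-time stratum share its utility, and
#' death contributes nothing.
#'
#' @param occupancy Named mass per compartment (order of
#'   [compartment_names()]).
#' @param utilities List with `u_lt25`, `u_ge25`.
#' @param cycle_years Cycle length in years.
#' @return QALYs for the cycle (undiscounted).
#' @export
cycle_qalys <- function(occupancy, utilities, cycle_years) {
  if (any(occupancy < 0)) stop("occupancy masses must be >= 0")
  occ <- setNames(as.numeric(occupancy), compartment_names())
  cycle_years * (
    (occ[["LT25_ON"]] + occ[["LT25_OFF"]]) * utilities$u_lt25 +
      (occ[["GE25_ON"]] + occ[["GE25_OFF"]]) * utilities$u_ge25
  )
}

as_cost_qaly <- function(x) {
  if (!is.null(x$discounted_cost)) {
    list(cost = x$discounted_cost, qalys = x$discounted_qalys)
  } else if (!is.null(x$cost)) {
    list(cost = x$cost, qalys = x$qalys)
  } else {
    stop("expected an arm result or a list with cost and qalys")
  }
}

#' Compare two arms: dominance, ICER, and net monetary benefit
#'
#' Deltas are reference minus comparator. The reference is dominant when it
#' costs less and yields more QALYs, dominated in the opposite pattern, and
#' otherwise an ICER `delta_cost / delta_qaly` is reported. The net monetary
#' benefit is `threshold * delta_qaly - delta_cost`. With zero QALY
#' difference the ICER is undefined and classification follows the cost
#' sign.
#'
#' @param reference,comparator Arm results (from [accrue_outcomes()]) or
#'   lists with `cost` and `qalys`.
#' @param threshold Willingness to pay, GBP per QALY.
#' @param name Comparator label for the result.
#' @return List with `comparator`, `delta_cost`, `delta_qaly`, `icer_class`
#'   (`"dominant"`, `"dominated"`, or `"icer_value"`), `icer_value`, `nmb`.
#' @examples
#' compare_arms(list(cost = 147948, qalys = 6.00),
#'              list(cost = 155093, qalys = 5.94), threshold = 20000)
#' @export
compare_arms <- function(reference, comparator, threshold, name = NULL) {
  r <- as_cost_qaly(reference)
  c_ <- as_cost_qaly(comparator)
  dc <- r$cost - c_$cost
  dq <- r$qalys - c_$qalys
  nmb <- threshold * dq - dc
  if (dc < 0 && dq > 0) {
    cls <- "dominant"
    icer <- NA_real_
  } else if (dc > 0 && dq < 0) {
    cls <- "dominated"
    icer <- NA_real_
  } else if (dq == 0) {
    icer <- NA_real_
    cls <- if (dc < 0) "dominant" else if (dc > 0) "dominated" else "icer_value"
  } else {
    cls <- "icer_value"
    icer <- dc / dq
  }
  list(comparator = if (is.null(name)) comparator$arm %||% NA_character_ else name,
       delta_cost = dc, delta_qaly = dq,
       icer_class = cls, icer_value = icer, nmb = nmb)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
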