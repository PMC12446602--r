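# Markov cohort trace, discounted accrual, the deterministic base case,
# and an individual-level microsimulation oracle.

build_arm_matrices <- function(arm, config) {
  starts <- cycle_start_times(config$schedule)
  ages <- config$cohort$start_age + starts
  lapply(seq_along(starts), function(i) {
    build_transition_matrix(arm, i, ages[i], config)
  })
}

#' Run the cohort trace for one arm
#'
#' Starts the cohort on treatment at the initial OFF-time split and
#' propagates it through the per-cycle transition matrices. Boundary 0 is
#' the initial distribution; boundary i the occupancy after cycle i.
#'
#' @param arm Arm specification from the configuration.
#' @param config Model configuration.
#' @return List with `occupancy` (a `(n_cycles + 1) x 5` matrix, rows
#'   labelled `boundary_0` onwards) and `arm`.
#' @export
run_cohort_trace <- function(arm, config) {
  matrices <- build_arm_matrices(arm, config)
  n <- length(matrices)
  occ <- matrix(0, n + 1, 5,
                dimnames = list(paste0("boundary_", 0:n), compartment_names()))
  occ[1, ] <- c(config$cohort$initial_lt25_fraction,
                config$cohort$initial_ge25_fraction, 0, 0, 0)
  for (i in seq_len(n)) {
    occ[i + 1, ] <- occ[i, ] %*% matrices[[i]]
  }
  structure(list(occupancy = occ, arm = arm$name), class = "parkcem_trace")
}

# Reference arm for the off-treatment resource-use schedule when
# options$off_treatment_hcru == "entacapone".
off_treatment_hcru_arm <- function(arm, config) {
  if (identical(config$options$off_treatment_hcru, "entacapone")) {
    is_ent <- vapply(config$arms, function(a)
      identical(a$preparation_class, "entacapone_standalone"), logical(1))
    if (any(is_ent)) return(config$arms[[which(is_ent)[1]]])
  }
  arm
}

# Per-cycle, per-compartment cost components (applied to the costing
# occupancy), QALY weights (applied to the outcome occupancy), and discount
# factors. Everything downstream -- cohort accrual and the
# microsimulation -- consumes these same building blocks, so the two agree
# by construction up to Monte-Carlo error in the trace itself.
arm_cycle_components <- function(arm, config) {
  lens <- config$schedule$cycle_lengths
  n <- length(lens)
  starts <- cycle_start_times(config$schedule)
  uc <- config$unit_costs
  op <- config$options
  off_arm <- off_treatment_hcru_arm(arm, config)

  comp <- compartment_names()
  zero <- matrix(0, n, 5, dimnames = list(NULL, comp))
  pharma <- trt <- state <- ae <- zero
  qaly <- zero
  for (i in seq_len(n)) {
    len <- lens[i]
    day_on <- daily_pharmaceutical_cost(arm, i, TRUE, uc, op)
    day_off <- daily_pharmaceutical_cost(arm, i, FALSE, uc, op)
    pharma[i, ] <- c(rep(day_on * 365.25 * len, 2),
                     rep(day_off * 365.25 * len, 2), 0)
    trt_on <- treatment_hcru_cycle_cost(arm, i, uc)
    trt_off <- treatment_hcru_cycle_cost(off_arm, i, uc)
    trt[i, ] <- c(trt_on, trt_on, trt_off, trt_off, 0)
    st_lt <- state_hcru_cycle_cost("lt25", len, config$state_resource_use, uc,
                                   op$los_multiplier)
    st_ge <- state_hcru_cycle_cost("ge25", len, config$state_resource_use, uc,
                                   op$los_multiplier)
    state[i, ] <- c(st_lt, st_ge, st_lt, st_ge, 0)
    ae_on <- expected_ae_cycle_cost(arm, i, TRUE, uc, len)
    ae[i, ] <- c(ae_on, ae_on, 0, 0, 0)
    qaly[i, ] <- len * c(config$utilities$u_lt25, config$utilities$u_ge25,
                         config$utilities$u_lt25, config$utilities$u_ge25, 0)
  }
  t_disc <- if (identical(op$discount_timing, "midpoint")) {
    starts + lens / 2
  } else {
    starts
  }
  df <- discount_factor(t_disc, config$econ$discount_rate_annual)
  list(pharma = pharma, trt = trt, state = state, ae = ae, qaly = qaly, df = df)
}

#' Accrue discounted costs and QALYs over a trace
#'
#' Costs are charged to the occupancy at cycle start (who-pays-at-entry;
#' `options$cost_timing = "mid"` charges the start/end mean instead) and
#' QALYs to the end-of-cycle occupancy (`options$half_cycle_correction`
#' switches to the start/end mean). Both streams are discounted at the
#' cycle-start time by default (`options$discount_timing = "midpoint"` uses
#' the cycle midpoint) and summed over the schedule.
#'
#' @param trace A trace from [run_cohort_trace()].
#' @param arm The arm that produced the trace.
#' @param config Model configuration.
#' @return List with `discounted_cost`, `discounted_qalys`,
#'   `cost_breakdown` (pharmaceutical, treatment_hcru, state_hcru,
#'   adverse_events, total), `trace`, and `arm`.
#' @export
accrue_outcomes <- function(trace, arm, config) {
  parts <- arm_cycle_components(arm, config)
  n <- length(config$schedule$cycle_lengths)
  if (nrow(trace$occupancy) != n + 1) {
    stop("trace does not match the configuration's schedule")
  }
  occ_start <- trace$occupancy[1:n, , drop = FALSE]
  occ_end <- trace$occupancy[2:(n + 1), , drop = FALSE]
  occ_cost <- if (identical(config$options$cost_timing, "mid")) {
    (occ_start + occ_end) / 2
  } else {
    occ_start
  }
  occ_qaly <- if (isTRUE(config$options$half_cycle_correction)) {
    (occ_start + occ_end) / 2
  } else {
    occ_end
  }
  disc_sum <- function(weights, mat) sum(parts$df * rowSums(weights * mat))
  breakdown <- c(
    pharmaceutical = disc_sum(occ_cost, parts$pharma),
    treatment_hcru = disc_sum(occ_cost, parts$trt),
    state_hcru = disc_sum(occ_cost, parts$state),
    adverse_events = disc_sum(occ_cost, parts$ae)
  )
  breakdown <- c(breakdown, total = sum(breakdown))
  list(
    discounted_cost = unname(breakdown[["total"]]),
    discounted_qalys = disc_sum(occ_qaly, parts$qaly),
    cost_breakdown = breakdown,
    trace = trace,
    arm = arm$name
  )
}

#' Run one arm end to end
#'
#' @inheritParams accrue_outcomes
#' @return The arm result of [accrue_outcomes()].
#' @export
run_arm <- function(arm, config) {
  accrue_outcomes(run_cohort_trace(arm, config), arm, config)
}

#' Deterministic base case across all arms
#'
#' Runs every arm, then compares the opicapone arm pairwise against each
#' entacapone comparator at the configured threshold.
#'
#' @param config Model configuration.
#' @return List with `arm_results` (one per arm), `reference` (the
#'   opicapone arm's key), and `comparisons`, a data.frame with one row per
#'   comparator: its discounted cost and QALYs, the deltas
#'   (reference minus comparator), ICER classification and value, and NMB.
#' @export
run_deterministic_case <- function(config) {
  assert_valid_config(config)
  arm_results <- lapply(config$arms, run_arm, config = config)
  is_ref <- vapply(config$arms, function(a)
    identical(a$preparation_class, "opicapone"), logical(1))
  ref_key <- names(config$arms)[which(is_ref)]
  ref <- arm_results[[ref_key]]
  comp_keys <- setdiff(names(config$arms), ref_key)
  rows <- lapply(comp_keys, function(k) {
    cmp <- compare_arms(ref, arm_results[[k]],
                        config$econ$threshold_gbp_per_qaly,
                        name = config$arms[[k]]$name)
    data.frame(
      comparator = cmp$comparator,
      cost_per_patient = arm_results[[k]]$discounted_cost,
      qalys_per_patient = arm_results[[k]]$discounted_qalys,
      delta_cost = cmp$delta_cost,
      delta_qaly = cmp$delta_qaly,
      icer_class = cmp$icer_class,
      icer_value = cmp$icer_value,
      nmb = cmp$nmb,
      stringsAsFactors = FALSE
    )
  })
  comparisons <- do.call(rbind, rows)
  rownames(comparisons) <- comp_keys
  list(arm_results = arm_results, reference = ref_key,
       comparisons = comparisons)
}

#' Individual-level microsimulation oracle
#'
#' Simulates individuals through the same per-cycle transition matrices and
#' accrual rules as the cohort trace, with pseudo-random draws. Serves as
#' an independent check that the cohort trace is the large-n limit of the
#' individual-level process. Supports the default accrual conventions
#' (costs at cycle start, QALYs at cycle end).
#'
#' @param arm Arm specification.
#' @param config Model configuration.
#' @param n_individuals Number of simulated individuals.
#' @param seed RNG seed.
#' @return List with `mean_cost`, `mean_qalys`, Monte-Carlo standard errors
#'   `se_cost` and `se_qalys`, `n_individuals`, and `seed`.
#' @export
run_microsimulation_oracle <- function(arm, config, n_individuals, seed) {
  if (n_individuals <= 0) stop("n_individuals must be > 0")
  if (!identical(config$options$cost_timing, "start") ||
      isTRUE(config$options$half_cycle_correction)) {
    stop("the microsimulation oracle supports the default accrual conventions")
  }
  set.seed(seed)
  matrices <- build_arm_matrices(arm, config)
  parts <- arm_cycle_components(arm, config)
  cost_mat <- parts$pharma + parts$trt + parts$state + parts$ae
  n_cyc <- length(matrices)

  state <- ifelse(runif(n_individuals) < config$cohort$initial_lt25_fraction,
                  1L, 2L)
  cost <- numeric(n_individuals)
  qaly <- numeric(n_individuals)
  for (i in seq_len(n_cyc)) {
    cost <- cost + parts$df[i] * cost_mat[i, state]
    P <- matrices[[i]]
    cur <- state
    for (s in 1:4) {
      idx <- which(cur == s)
      if (length(idx)) {
        state[idx] <- sample.int(5, length(idx), replace = TRUE, prob = P[s, ])
      }
    }
    qaly <- qaly + parts$df[i] * parts$qaly[i, state]
  }
  list(
    mean_cost = mean(cost),
    mean_qalys = mean(qaly),
    se_cost = stats::sd(cost) / sqrt(n_individuals),
    se_qalys = stats::sd(qaly) / sqrt(n_individuals),
    n_individuals = n_individuals,
    seed = seed
  )
}
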