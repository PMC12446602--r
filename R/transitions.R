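# Per-arm, per-cycle transition matrices over the five compartments
# {LT25_ON, GE25_ON, LT25_OFF, GE25_OFF, DEAD}.
#
# Events within a cycle are composed in a fixed order: (i) treatment
# discontinuation at the cycle start (model years 2-6 only), (ii) death at
# the life-table probability under the disease hazard ratio, (iii) among
# survivors, OFF-time movement -- the cycle-1 treatment response for the
# >=25% state, or natural decline from cycle 2 onwards. Returning from
# >=25% to <25% OFF-time is only possible in cycle 1, and no compartment
# moves from off-treatment back on.

#' Annual probability of natural OFF-time decline
#'
#' The progression rate from <25% to >=25% OFF-time is estimated as the
#' reciprocal of the difference in mean levodopa-treatment duration between
#' the two OFF-time strata, and is assumed independent of adjuvant therapy.
#'
#' @param duration_lt25 Mean years of levodopa treatment, <25% OFF-time
#'   stratum (default 5.53).
#' @param duration_ge25 Mean years, >=25% stratum (default 11.38).
#' @return Annual transition probability `1 / (duration_ge25 - duration_lt25)`.
#' @examples
#' derive_decline_probability(5.53, 11.38)  # ~0.17
#' @export
derive_decline_probability <- function(duration_lt25 = 5.53,
                                       duration_ge25 = 11.38) {
  diff <- duration_ge25 - duration_lt25
  if (diff <= 0) stop("duration_ge25 must exceed duration_lt25")
  1 / diff
}

#' Convert a probability between durations
#'
#' Re-expresses a probability defined over `from_duration` on a
#' `to_duration` basis under a constant-rate (exponential) assumption:
#' `1 - (1 - p)^(to/from)`. Used to convert the annual decline and mortality
#' probabilities and the 3-month adverse-event probabilities to the 3-month,
#' 9-month, and 12-month cycle lengths.
#'
#' @param p Probability in `[0, 1]`.
#' @param from_duration,to_duration Durations in years (> 0).
#' @return The converted probability.
#' @export
convert_probability <- function(p, from_duration, to_duration) {
  if (any(p < 0 | p > 1)) stop("p must be in [0, 1]")
  if (from_duration <= 0 || to_duration <= 0) stop("durations must be > 0")
  if (any(p == 1)) {
    if (to_duration < from_duration) {
      stop("p = 1 over a shorter duration is undefined under a constant rate")
    }
    return(ifelse(p == 1, 1, 1 - (1 - p)^(to_duration / from_duration)))
  }
  1 - (1 - p)^(to_duration / from_duration)
}

#' Cohort-weighted annual background mortality
#'
#' The general-population annual death probability at an age, weighted by
#' the cohort's sex distribution.
#'
#' @param life_table Data.frame with columns `age`, `q_male`, `q_female`.
#' @param age Age in years; the integer-age row at `floor(age)` is used.
#' @param male_fraction Fraction of the cohort that is male.
#' @return Annual probability of death.
#' @export
annual_background_mortality <- function(life_table, age, male_fraction) {
  row <- match(floor(age), life_table$age)
  if (is.na(row)) stop(sprintf("age %s outside life table", format(age)))
  male_fraction * life_table$q_male[row] +
    (1 - male_fraction) * life_table$q_female[row]
}

#' Per-cycle death probability under the disease hazard ratio
#'
#' The annual background probability is multiplied by the Parkinson's
#' mortality hazard ratio (capped at 1) and converted to the cycle length.
#' The multiplicative application to the probability follows the source
#' model's wording; at very old ages this differs from scaling the hazard.
#'
#' @param annual_q Annual background death probability.
#' @param hazard_ratio Disease mortality hazard ratio (default 1.61).
#' @param cycle_years Cycle length in years.
#' @return Probability of death within the cycle.
#' @export
cycle_death_probability <- function(annual_q, hazard_ratio, cycle_years) {
  q <- min(annual_q * hazard_ratio, 1)
  if (q >= 1) return(1)
  convert_probability(q, 1, cycle_years)
}

#' Redistribution of discontinuing patients
#'
#' Discontinuation forfeits all therapeutic benefit: patients leaving
#' treatment from the <25% OFF-time state are redistributed to the
#' off-treatment compartments at the baseline OFF-time split (9.5% remain
#' <25%, 90.5% move to >=25%); patients discontinuing from >=25% OFF-time
#' stay in that state (off treatment) while alive.
#'
#' @param origin `"LT25_ON"` or `"GE25_ON"`.
#' @param d Discontinuation probability for the year.
#' @param baseline_split Length-2 vector `(lt25, ge25)` baseline OFF-time
#'   distribution.
#' @return Named distribution over the five compartments.
#' @export
discontinuation_split <- function(origin, d,
                                  baseline_split = c(0.095, 0.905)) {
  if (!origin %in% c("LT25_ON", "GE25_ON")) {
    stop("discontinuation only applies to on-treatment compartments")
  }
  if (d < 0 || d > 1) stop("d must be in [0, 1]")
  out <- setNames(numeric(5), compartment_names())
  out[origin] <- 1 - d
  if (origin == "LT25_ON") {
    out["LT25_OFF"] <- d * baseline_split[[1]]
    out["GE25_OFF"] <- d * baseline_split[[2]]
  } else {
    out["GE25_OFF"] <- d
  }
  out
}

#' Cycle start times of a schedule
#'
#' @param schedule A `schedule` list with `cycle_lengths`.
#' @return Numeric vector of elapsed years at each cycle start.
#' @export
cycle_start_times <- function(schedule) {
  len <- schedule$cycle_lengths
  cumsum(c(0, len))[seq_along(len)]
}

# Discontinuation probability applying at the start of a given cycle: the
# year-specific probability for model years 2-6, applied once per year at
# the first cycle starting in that year; zero in year 1 (full compliance)
# and beyond year 6.
cycle_discontinuation_prob <- function(arm, cycle_index, schedule) {
  starts <- cycle_start_times(schedule)
  bucket <- floor(starts + 1e-9)
  first_in_year <- !duplicated(bucket)
  b <- bucket[cycle_index]
  if (first_in_year[cycle_index] && b >= 1 && b <= 5) {
    arm$discontinuation_by_year[[b]]
  } else {
    0
  }
}

#' Build the transition matrix for one arm and cycle
#'
#' Composes discontinuation, death, and OFF-time movement in that order
#' into a row-stochastic 5x5 matrix. Cycle 1 applies the arm's treatment
#' response (>=25% to <25% OFF-time, on treatment) and no natural decline;
#' later cycles apply natural decline (converted to the cycle length) to
#' both <25% compartments; >=25% off-treatment mass remains in place while
#' alive; death is absorbing.
#'
#' @param arm An arm specification from the configuration.
#' @param cycle_index Cycle number (1-based).
#' @param age_at_cycle_start Cohort age at the cycle start.
#' @param config The model configuration.
#' @return A 5x5 matrix with compartment dimnames and attributes
#'   `cycle_index` and `arm`.
#' @export
build_transition_matrix <- function(arm, cycle_index, age_at_cycle_start,
                                    config) {
  n_cycles <- length(config$schedule$cycle_lengths)
  if (cycle_index < 1 || cycle_index > n_cycles) {
    stop(sprintf("cycle_index must be in 1..%d", n_cycles))
  }
  len <- config$schedule$cycle_lengths[[cycle_index]]
  q_annual <- annual_background_mortality(config$mortality$life_table,
                                          age_at_cycle_start,
                                          config$cohort$male_fraction)
  q <- cycle_death_probability(q_annual, config$mortality$pd_hazard_ratio, len)
  d <- cycle_discontinuation_prob(arm, cycle_index, config$schedule)
  split <- config$natural_history$offtime_baseline_split
  s_lt <- split[[1]]
  s_ge <- split[[2]]
  if (cycle_index == 1) {
    r <- arm$cycle1_response_prob
    p <- 0
  } else {
    r <- 0
    p <- convert_probability(config$natural_history$annual_decline_prob, 1, len)
  }

  cn <- compartment_names()
  P <- matrix(0, 5, 5, dimnames = list(cn, cn))
  # LT25_ON: stay on and possibly decline; or discontinue and be
  # redistributed at the baseline split, declining off treatment
  P["LT25_ON", ] <- c(
    (1 - d) * (1 - q) * (1 - p),
    (1 - d) * (1 - q) * p,
    d * s_lt * (1 - q) * (1 - p),
    (1 - q) * (d * s_lt * p + d * s_ge),
    q
  )
  # GE25_ON: cycle-1 response to LT25_ON; thereafter stable on treatment
  P["GE25_ON", ] <- c(
    (1 - d) * (1 - q) * r,
    (1 - d) * (1 - q) * (1 - r),
    0,
    d * (1 - q),
    q
  )
  P["LT25_OFF", ] <- c(0, 0, (1 - q) * (1 - p), (1 - q) * p, q)
  P["GE25_OFF", ] <- c(0, 0, 0, 1 - q, q)
  P["DEAD", ] <- c(0, 0, 0, 0, 1)

  attr(P, "cycle_index") <- cycle_index
  attr(P, "arm") <- arm$name
  P
}
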