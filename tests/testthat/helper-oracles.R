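# Shared fixtures and independent oracles, built in code.

# Life table with zero mortality everywhere.
zero_mortality_table <- function(max_age = 130) {
  data.frame(age = 0:max_age, q_male = 0, q_female = 0)
}

# Base configuration stripped of stochastic attrition: annual cycles, no
# mortality, no discontinuation, no cycle-1 response, no discounting.
flat_annual_config <- function(horizon = 25) {
  cfg <- default_config()
  cfg$schedule$cycle_lengths <- rep(1, horizon)
  cfg$econ$horizon_years <- horizon
  cfg$econ$discount_rate_annual <- 0
  cfg$mortality$life_table <- zero_mortality_table()
  for (k in names(cfg$arms)) {
    cfg$arms[[k]]$discontinuation_by_year <- rep(0, 5)
    cfg$arms[[k]]$cycle1_response_prob <- 0
  }
  cfg
}

# Independent event-tree oracle for one transition-matrix row: exhaustive
# enumeration over the ordered events (discontinue -> die -> move), written
# as explicit path bookkeeping rather than algebra.
event_tree_row <- function(origin, d, q, r, p, split) {
  dest <- stats::setNames(numeric(5), compartment_names())
  add <- function(comp, pr) dest[comp] <<- dest[comp] + pr
  branches <- switch(origin,
    LT25_ON = list(list(comp = "LT25_ON", pr = 1 - d),
                   list(comp = "LT25_OFF", pr = d * split[[1]]),
                   list(comp = "GE25_OFF", pr = d * split[[2]])),
    GE25_ON = list(list(comp = "GE25_ON", pr = 1 - d),
                   list(comp = "GE25_OFF", pr = d)),
    DEAD = list(list(comp = "DEAD", pr = 1)),
    list(list(comp = origin, pr = 1))
  )
  for (b in branches) {
    if (b$comp == "DEAD") {
      add("DEAD", b$pr)
      next
    }
    add("DEAD", b$pr * q)
    surv <- b$pr * (1 - q)
    move <- switch(b$comp,
      LT25_ON = c(LT25_ON = 1 - p, GE25_ON = p),
      GE25_ON = c(LT25_ON = r, GE25_ON = 1 - r),
      LT25_OFF = c(LT25_OFF = 1 - p, GE25_OFF = p),
      GE25_OFF = c(GE25_OFF = 1)
    )
    for (nm in names(move)) add(nm, surv * move[[nm]])
  }
  dest
}

# Every probability-valued field of a configuration, for brute-force range
# scans over randomly generated parameter sets.
all_probability_fields <- function(cfg) {
  out <- c(cfg$cohort$male_fraction, cfg$cohort$initial_lt25_fraction,
           cfg$cohort$initial_ge25_fraction,
           cfg$natural_history$annual_decline_prob,
           cfg$natural_history$offtime_baseline_split,
           unlist(cfg$mortality$life_table[c("q_male", "q_female")]))
  for (a in cfg$arms) {
    out <- c(out, a$cycle1_response_prob, a$discontinuation_by_year,
             a$ae_3month_probs)
  }
  unname(out)
}
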