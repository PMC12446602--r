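test_that("identity dynamics freeze the initial occupancy", {
  cfg <- flat_annual_config()
  cfg$natural_history$annual_decline_prob <- 0
  trace <- run_cohort_trace(cfg$arms$opicapone, cfg)
  for (b in seq_len(nrow(trace$occupancy))) {
    expect_equal(unname(trace$occupancy[b, ]),
                 c(0.095, 0.905, 0, 0, 0), tolerance = 1e-12)
  }
})

test_that("near-certain death empties the cohort in one cycle", {
  cfg <- default_config()
  cfg$mortality$life_table <- data.frame(age = 0:130, q_male = 1, q_female = 1)
  trace <- run_cohort_trace(cfg$arms$opicapone, cfg)
  expect_equal(unname(trace$occupancy[2, "DEAD"]), 1, tolerance = 1e-12)
})

test_that("pure decline follows geometric decay", {
  cfg <- flat_annual_config()
  cfg$cohort$initial_lt25_fraction <- 1
  cfg$cohort$initial_ge25_fraction <- 0
  trace <- run_cohort_trace(cfg$arms$opicapone, cfg)
  # cycle 1 carries no decline; each later annual cycle removes 17%
  expect_equal(unname(trace$occupancy[7, "LT25_ON"]), 0.83^5,
               tolerance = 1e-12)
  expect_equal(round(0.83^5, 4), 0.3939)
  expect_true(all(diff(trace$occupancy[, "DEAD"]) >= 0))
  expect_equal(unname(rowSums(trace$occupancy)), rep(1, 26), tolerance = 1e-10)
})

test_that("accrual handles degenerate and single-cycle cases", {
  cfg <- default_config()
  cfg$schedule$cycle_lengths <- 1
  cfg$econ$horizon_years <- 1
  cfg$econ$discount_rate_annual <- 0
  cfg$mortality$life_table <- zero_mortality_table()
  cfg$cohort$initial_lt25_fraction <- 1
  cfg$cohort$initial_ge25_fraction <- 0
  # silence every stream except OFF-time-dependent resource use
  cfg$unit_costs$levodopa_pack_price <- 0
  cfg$unit_costs$consultant_visit <- 0
  cfg$unit_costs$outpatient_visit <- 0
  cfg$unit_costs$ae_dept_visit <- 0
  cfg$unit_costs$ae[] <- 0
  arm <- cfg$arms$opicapone
  arm$pack_price <- 0
  res <- run_arm(arm, cfg)
  expect_equal(res$discounted_cost, 3830.409, tolerance = 1e-3)
  expect_equal(unname(res$cost_breakdown[["state_hcru"]]), res$discounted_cost)

  # an all-dead cohort accrues nothing
  dead <- cfg
  dead$mortality$life_table <- data.frame(age = 0:130, q_male = 1, q_female = 1)
  trace <- run_cohort_trace(arm, dead)
  trace$occupancy[1, ] <- c(0, 0, 0, 0, 1)
  res0 <- accrue_outcomes(trace, arm, dead)
  expect_equal(res0$discounted_cost, 0)
  expect_equal(res0$discounted_qalys, 0)
})

test_that("discounted cost is linear in unit costs", {
  cfg <- default_config()
  cfg2 <- cfg
  for (nm in c("levodopa_pack_price", "hospital_day", "consultant_visit",
               "gp_visit", "outpatient_visit", "ae_dept_visit",
               "pd_nurse_visit")) {
    cfg2$unit_costs[[nm]] <- 2 * cfg$unit_costs[[nm]]
  }
  cfg2$unit_costs$ae <- 2 * cfg$unit_costs$ae
  for (k in names(cfg2$arms)) {
    cfg2$arms[[k]]$pack_price <- 2 * cfg$arms[[k]]$pack_price
  }
  r1 <- run_arm(cfg$arms$opicapone, cfg)
  r2 <- run_arm(cfg2$arms$opicapone, cfg2)
  expect_equal(r2$discounted_cost, 2 * r1$discounted_cost, tolerance = 1e-12)
  expect_equal(r2$discounted_qalys, r1$discounted_qalys)
})

test_that("QALYs are bounded by the horizon at the best utility", {
  cfg <- default_config()
  res <- run_arm(cfg$arms$opicapone, cfg)
  expect_lt(res$discounted_qalys, 25 * cfg$utilities$u_lt25)

  flat <- flat_annual_config()
  flat$natural_history$annual_decline_prob <- 0
  flat$cohort$initial_lt25_fraction <- 1
  flat$cohort$initial_ge25_fraction <- 0
  res_flat <- run_arm(flat$arms$opicapone, flat)
  expect_equal(res_flat$discounted_qalys, 25 * flat$utilities$u_lt25,
               tolerance = 1e-10)
})

test_that("the deterministic case compares all arms against opicapone", {
  det <- run_deterministic_case(default_config())
  expect_equal(det$reference, "opicapone")
  expect_equal(nrow(det$comparisons), 6)
  # identical clinical inputs leave all entacapone QALYs equal
  expect_equal(diff(range(det$comparisons$qalys_per_patient)), 0,
               tolerance = 1e-12)
  expect_equal(det$comparisons$nmb,
               20000 * det$comparisons$delta_qaly - det$comparisons$delta_cost,
               tolerance = 1e-9)

  # arms with identical parameters yield zero deltas (comparators kept in a
  # stand-alone class so the levodopa costing rule matches the reference)
  cfg <- default_config()
  opi <- cfg$arms$opicapone
  for (k in setdiff(names(cfg$arms), "opicapone")) {
    keep <- cfg$arms[[k]]["name"]
    cfg$arms[[k]] <- opi
    cfg$arms[[k]]["name"] <- keep
    cfg$arms[[k]]$preparation_class <- "entacapone_standalone"
  }
  det0 <- run_deterministic_case(cfg)
  expect_equal(det0$comparisons$delta_cost, rep(0, 6), tolerance = 1e-9)
  expect_equal(det0$comparisons$delta_qaly, rep(0, 6), tolerance = 1e-12)
})

test_that("a dearer comparator raises opicapone's NMB monotonically", {
  cfg <- default_config()
  nmbs <- vapply(c(1, 1.5, 2, 3), function(mult) {
    c2 <- cfg
    c2$arms$entacapone_generic$pack_price <- mult * 21.07
    det <- run_deterministic_case(c2)
    det$comparisons["entacapone_generic", "nmb"]
  }, numeric(1))
  expect_true(all(diff(nmbs) > 0))
})

test_that("microsimulation reproduces degenerate dynamics exactly", {
  cfg <- flat_annual_config()
  cfg$natural_history$annual_decline_prob <- 0
  cfg$cohort$initial_lt25_fraction <- 1
  cfg$cohort$initial_ge25_fraction <- 0
  res <- run_arm(cfg$arms$opicapone, cfg)
  ms <- run_microsimulation_oracle(cfg$arms$opicapone, cfg, 50, 1)
  expect_equal(ms$mean_cost, res$discounted_cost, tolerance = 1e-10)
  expect_equal(ms$mean_qalys, res$discounted_qalys, tolerance = 1e-10)
  expect_equal(ms$se_cost, 0)
})

test_that("microsimulation is reproducible per seed", {
  cfg <- default_config()
  a <- run_microsimulation_oracle(cfg$arms$opicapone, cfg, 2000, 5)
  b <- run_microsimulation_oracle(cfg$arms$opicapone, cfg, 2000, 5)
  expect_identical(a, b)
  c_ <- run_microsimulation_oracle(cfg$arms$opicapone, cfg, 2000, 6)
  expect_false(identical(a$mean_cost, c_$mean_cost))
})

test_that("cohort trace sits inside the microsimulation confidence band", {
  cfg <- default_config()
  res <- run_arm(cfg$arms$entacapone_generic, cfg)
  ms <- run_microsimulation_oracle(cfg$arms$entacapone_generic, cfg, 20000, 12)
  expect_lt(abs(ms$mean_cost - res$discounted_cost), 3 * ms$se_cost)
  expect_lt(abs(ms$mean_qalys - res$discounted_qalys), 3 * ms$se_qalys)
})
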