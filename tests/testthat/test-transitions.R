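test_that("decline probability is the reciprocal treatment-duration gap", {
  expect_equal(round(derive_decline_probability(5.53, 11.38), 2), 0.17)
  expect_equal(derive_decline_probability(5, 6), 1.0)
  expect_equal(derive_decline_probability(0, 4), 0.25)
  expect_error(derive_decline_probability(6, 5), "exceed")
})

test_that("probability duration conversion follows the constant-rate form", {
  expect_equal(convert_probability(0.3, 2, 2), 0.3)
  expect_equal(convert_probability(0, 1, 7), 0)
  expect_equal(convert_probability(0.17, 1, 0.75), 1 - 0.83^0.75,
               tolerance = 1e-15)
  expect_equal(round(convert_probability(0.17, 1, 0.75), 4), 0.1304)
  expect_equal(convert_probability(1, 1, 2), 1)
  expect_error(convert_probability(1, 1, 0.5), "undefined")
  expect_error(convert_probability(1.2, 1, 1), "\\[0, 1\\]")
})

test_that("background mortality is the sex-weighted life-table probability", {
  lt <- data.frame(age = 60:70, q_male = 0.02, q_female = 0.01)
  expect_equal(annual_background_mortality(lt, 64, 1), 0.02)
  expect_equal(annual_background_mortality(lt, 64, 0.5), 0.015)
  expect_equal(annual_background_mortality(lt, 64, 0.591), 0.01591)
  expect_equal(annual_background_mortality(lt, 64.9, 0.591), 0.01591)
  expect_error(annual_background_mortality(lt, 120, 0.5), "outside")
})

test_that("cycle death probability applies the hazard ratio then converts", {
  expect_equal(cycle_death_probability(0.04, 1, 1), 0.04)
  expect_equal(cycle_death_probability(0.02, 1.61, 1), 0.0322)
  expect_equal(cycle_death_probability(0.02, 1.61, 0.25),
               1 - (1 - 0.0322)^0.25, tolerance = 1e-15)
  expect_equal(round(cycle_death_probability(0.02, 1.61, 0.25), 6), 0.008149)
  # cap at 1
  expect_equal(cycle_death_probability(0.9, 5, 0.25), 1)
})

test_that("discontinuation redistributes at the baseline OFF-time split", {
  id <- discontinuation_split("LT25_ON", 0)
  expect_equal(unname(id["LT25_ON"]), 1)
  expect_equal(sum(id), 1)
  full <- discontinuation_split("LT25_ON", 1, c(0.095, 0.905))
  expect_equal(unname(full[c("LT25_OFF", "GE25_OFF")]), c(0.095, 0.905))
  half <- discontinuation_split("GE25_ON", 0.5)
  expect_equal(unname(half[c("GE25_ON", "GE25_OFF")]), c(0.5, 0.5))
  expect_error(discontinuation_split("LT25_OFF", 0.5), "on-treatment")
  expect_error(discontinuation_split("DEAD", 0.5), "on-treatment")
})

test_that("transition matrix rows compose death-first movement", {
  cfg <- default_config()
  cfg$mortality$life_table <- data.frame(age = 0:120, q_male = 0.01,
                                         q_female = 0.01)
  cfg$mortality$pd_hazard_ratio <- 1
  arm <- cfg$arms$opicapone
  arm$discontinuation_by_year <- rep(0, 5)

  # annual cycle beyond discontinuation, decline 0.17, death 0.01
  P <- build_transition_matrix(arm, 10, 73, cfg)
  expect_equal(unname(P["LT25_ON", ]),
               c(0.99 * 0.83, 0.99 * 0.17, 0, 0, 0.01), tolerance = 1e-12)
  expect_equal(unname(P["DEAD", ]), c(0, 0, 0, 0, 1))

  # cycle 1: response only, no decline
  cfg0 <- cfg
  cfg0$mortality$life_table <- zero_mortality_table()
  arm$cycle1_response_prob <- 0.25
  P1 <- build_transition_matrix(arm, 1, 64, cfg0)
  expect_equal(unname(P1["GE25_ON", ]), c(0.25, 0.75, 0, 0, 0))
  expect_equal(unname(P1["LT25_ON", "LT25_ON"]), 1)

  expect_error(build_transition_matrix(arm, 0, 64, cfg), "cycle_index")
  expect_error(build_transition_matrix(arm, 27, 64, cfg), "cycle_index")
})

test_that("discontinuation applies once per model year, years 2-6 only", {
  cfg <- default_config()
  cfg$mortality$life_table <- zero_mortality_table()
  arm <- cfg$arms$entacapone_generic  # d = 0.15, 0.08 x 4
  starts <- cycle_start_times(cfg$schedule)
  for (i in seq_along(cfg$schedule$cycle_lengths)) {
    P <- build_transition_matrix(arm, i, 64 + starts[i], cfg)
    leak <- P["GE25_ON", "GE25_OFF"]
    expected <- if (i >= 3 && i <= 7) arm$discontinuation_by_year[i - 2] else 0
    expect_equal(unname(leak), expected, tolerance = 1e-12)
  }
})

test_that("matrices are row-stochastic with the structural zeros", {
  for (s in 1:10) {
    cfg <- generate_random_config(s)
    starts <- cycle_start_times(cfg$schedule)
    for (k in names(cfg$arms)) {
      for (i in seq_along(cfg$schedule$cycle_lengths)) {
        P <- build_transition_matrix(cfg$arms[[k]], i,
                                     cfg$cohort$start_age + starts[i], cfg)
        expect_true(all(P >= 0 & P <= 1))
        expect_equal(unname(rowSums(P)), rep(1, 5), tolerance = 1e-12)
        # off-treatment mass never returns to treatment
        expect_true(all(P[c("LT25_OFF", "GE25_OFF"), c("LT25_ON", "GE25_ON")] == 0))
        expect_equal(unname(P["DEAD", ]), c(0, 0, 0, 0, 1))
        if (i >= 2) {
          expect_true(all(P[c("GE25_ON", "GE25_OFF"),
                            c("LT25_ON", "LT25_OFF")] == 0))
        }
      }
    }
  }
})

test_that("death inflow is monotone in the hazard ratio", {
  cfg <- generate_random_config(11)
  starts <- cycle_start_times(cfg$schedule)
  cfg_hi <- cfg
  cfg_hi$mortality$pd_hazard_ratio <- cfg$mortality$pd_hazard_ratio * 1.5
  for (i in c(1, 2, 5, 15, 26)) {
    P_lo <- build_transition_matrix(cfg$arms$opicapone, i,
                                    cfg$cohort$start_age + starts[i], cfg)
    P_hi <- build_transition_matrix(cfg_hi$arms$opicapone, i,
                                    cfg$cohort$start_age + starts[i], cfg_hi)
    expect_true(all(P_hi[, "DEAD"] >= P_lo[, "DEAD"]))
  }
})

test_that("matrix entries match exhaustive event-tree enumeration", {
  set.seed(404)
  for (rep in 1:50) {
    cfg <- generate_random_config(rep + 200)
    i <- sample(seq_along(cfg$schedule$cycle_lengths), 1)
    k <- sample(names(cfg$arms), 1)
    arm <- cfg$arms[[k]]
    starts <- cycle_start_times(cfg$schedule)
    age <- cfg$cohort$start_age + starts[i]
    len <- cfg$schedule$cycle_lengths[[i]]
    P <- build_transition_matrix(arm, i, age, cfg)

    q <- cycle_death_probability(
      annual_background_mortality(cfg$mortality$life_table, age,
                                  cfg$cohort$male_fraction),
      cfg$mortality$pd_hazard_ratio, len)
    bucket <- floor(starts + 1e-9)
    d <- 0
    if (!duplicated(bucket)[i] && bucket[i] >= 1 && bucket[i] <= 5) {
      d <- arm$discontinuation_by_year[[bucket[i]]]
    }
    r <- if (i == 1) arm$cycle1_response_prob else 0
    p <- if (i == 1) 0 else {
      convert_probability(cfg$natural_history$annual_decline_prob, 1, len)
    }
    split <- cfg$natural_history$offtime_baseline_split
    for (origin in compartment_names()) {
      expect_equal(P[origin, ], event_tree_row(origin, d, q, r, p, split),
                   tolerance = 1e-12)
    }
  }
})
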