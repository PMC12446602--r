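test_that("tablet cost is the pack price over the pack size", {
  expect_equal(tablet_cost(59.00, 30), 59 / 30)
  expect_equal(round(tablet_cost(59.00, 30), 4), 1.9667)
  expect_equal(tablet_cost(21.07, 100), 0.2107)
  expect_equal(tablet_cost(0, 10), 0)
  expect_error(tablet_cost(10, 0), "pack_size")
})

test_that("daily pharmaceutical cost covers COMT inhibitor plus levodopa", {
  cfg <- default_config()
  uc <- cfg$unit_costs
  op <- cfg$options
  mg <- 6.67 / (100 * 100)

  opi1 <- daily_pharmaceutical_cost(cfg$arms$opicapone, 1, TRUE, uc, op)
  expect_equal(opi1, 59 / 30 + 724 * mg, tolerance = 1e-12)
  expect_equal(round(opi1, 4), 2.4496)

  ent3 <- daily_pharmaceutical_cost(cfg$arms$entacapone_generic, 3, TRUE, uc, op)
  expect_equal(ent3, 5 * 0.2107 + 847 * mg, tolerance = 1e-12)
  expect_equal(round(ent3, 4), 1.6184)

  # combination preparations already contain the levodopa
  combo <- daily_pharmaceutical_cost(cfg$arms$combo_generic, 2, TRUE, uc, op)
  expect_equal(combo, 5 * 0.2972, tolerance = 1e-12)

  # off treatment: levodopa only, at the reversion dose
  off <- daily_pharmaceutical_cost(cfg$arms$opicapone, 5, FALSE, uc, op)
  expect_equal(off, 847 * mg, tolerance = 1e-12)
  expect_equal(off, daily_pharmaceutical_cost(cfg$arms$combo_stalevo, 5, FALSE,
                                              uc, op))
})

test_that("treatment-dependent resource cost is the priced visit schedule", {
  cfg <- default_config()
  uc <- cfg$unit_costs
  opi1 <- treatment_hcru_cycle_cost(cfg$arms$opicapone, 1, uc)
  expect_equal(opi1, 0.50 * 324.39 + 0.99 * 164.17 + 0.15 * 242.03,
               tolerance = 1e-12)
  ent4 <- treatment_hcru_cycle_cost(cfg$arms$entacapone_generic, 9, uc)
  expect_equal(ent4, 1.60 * 324.39 + 3.81 * 164.17 + 1.03 * 242.03,
               tolerance = 1e-12)
  expect_equal(round(ent4, 2), 1393.80)

  none <- cfg$arms$opicapone
  none$neurology_visits <- none$other_outpatient_visits <-
    none$ae_dept_visits <- rep(0, 4)
  expect_equal(treatment_hcru_cycle_cost(none, 1, uc), 0)
})

test_that("OFF-time-dependent cost scales with cycle length and stay length", {
  cfg <- default_config()
  uc <- cfg$unit_costs
  sru <- cfg$state_resource_use
  lt <- state_hcru_cycle_cost("lt25", 1, sru, uc)
  expect_equal(lt, 0.47 * 14 * 512.57 + 3.29 * 42 + 2.70 * 118.34,
               tolerance = 1e-12)
  expect_equal(round(lt, 2), 3830.41)
  expect_equal(state_hcru_cycle_cost("ge25", 0, sru, uc), 0)
  ge_q <- state_hcru_cycle_cost("ge25", 0.25, sru, uc)
  expect_equal(ge_q, 0.25 * (1.12 * 20.48 * 512.57 + 4.16 * 42 + 3.87 * 118.34),
               tolerance = 1e-12)
  # linear in cycle length and in the length-of-stay multiplier
  expect_equal(state_hcru_cycle_cost("lt25", 2, sru, uc), 2 * lt,
               tolerance = 1e-12)
  hosp <- 0.47 * 14 * 512.57
  expect_equal(state_hcru_cycle_cost("lt25", 1, sru, uc, los_multiplier = 0.8),
               lt - 0.2 * hosp, tolerance = 1e-9)
})

test_that("expected adverse-event cost converts 3-month probabilities", {
  cfg <- default_config()
  uc <- cfg$unit_costs
  arm <- cfg$arms$opicapone
  arm$ae_3month_probs[] <- 0
  expect_equal(expected_ae_cycle_cost(arm, 1, TRUE, uc, 0.25), 0)

  arm$ae_3month_probs[] <- 0
  arm$ae_3month_probs["dyskinesias"] <- 0.1
  # same duration: probability passes through
  expect_equal(expected_ae_cycle_cost(arm, 1, TRUE, uc, 0.25), 0.1 * 10.50,
               tolerance = 1e-12)
  # 12-month cycle: 1 - 0.9^4
  expect_equal(expected_ae_cycle_cost(arm, 3, TRUE, uc, 1),
               (1 - 0.9^4) * 10.50, tolerance = 1e-12)
  # off treatment accrues nothing
  expect_equal(expected_ae_cycle_cost(arm, 3, FALSE, uc, 1), 0)
})

test_that("adverse-event unit costs reproduce the published table at 2 dp", {
  ae <- ae_unit_cost_table()
  expect_equal(round(unname(ae), 2), c(10.50, 0.00, 2.45, 0.00, 0.06, 0.32))
  expect_equal(names(ae), c("dyskinesias", "insomnia", "constipation",
                            "diarrhea", "nausea", "hallucinations"))
})

test_that("consultant visit cost is the stated tariff weighting", {
  expect_equal(consultant_visit_weighted_cost(221.61, 392.91, 0.40), 324.39,
               tolerance = 1e-12)
  expect_equal(consultant_visit_weighted_cost(100, 100, 0.3), 100)
  expect_equal(consultant_visit_weighted_cost(100, 200, 0.5), 150)
  expect_error(consultant_visit_weighted_cost(1, 2, 1.2), "weight")
})

test_that("cost outputs are homogeneous of degree one in unit costs", {
  cfg <- generate_random_config(5)
  uc <- cfg$unit_costs
  set.seed(99)
  for (mult in runif(3, 0.5, 4)) {
    uc2 <- uc
    for (nm in c("levodopa_pack_price", "hospital_day", "consultant_visit",
                 "gp_visit", "outpatient_visit", "ae_dept_visit",
                 "pd_nurse_visit")) {
      uc2[[nm]] <- uc[[nm]] * mult
    }
    uc2$ae <- uc$ae * mult
    arm <- cfg$arms$entacapone_generic
    expect_equal(treatment_hcru_cycle_cost(arm, 2, uc2),
                 mult * treatment_hcru_cycle_cost(arm, 2, uc), tolerance = 1e-12)
    expect_equal(state_hcru_cycle_cost("ge25", 1, cfg$state_resource_use, uc2),
                 mult * state_hcru_cycle_cost("ge25", 1, cfg$state_resource_use, uc),
                 tolerance = 1e-12)
    expect_equal(expected_ae_cycle_cost(arm, 3, TRUE, uc2, 1),
                 mult * expected_ae_cycle_cost(arm, 3, TRUE, uc, 1),
                 tolerance = 1e-12)
  }
})

test_that("entacapone dosing arithmetic matches the stated derivation", {
  expect_equal(entacapone_daily_mg(4.3, 200), 860)
  expect_equal(entacapone_ddd_doses(1000, 200), 5)
})
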