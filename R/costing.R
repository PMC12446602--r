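# Per-cycle, per-compartment expected costs: pharmaceuticals (COMT
# inhibitor + levodopa via LEDD), treatment-dependent resource use,
# OFF-time-dependent resource use, and adverse-event management.

#' Cost per tablet
#'
#' @param pack_price Pack price in GBP.
#' @param pack_size Tablets per pack (> 0).
#' @return GBP per tablet.
#' @export
tablet_cost <- function(pack_price, pack_size) {
  if (pack_size <= 0) stop("pack_size must be > 0")
  pack_price / pack_size
}

levodopa_cost_per_mg <- function(unit_costs) {
  unit_costs$levodopa_pack_price /
    (unit_costs$levodopa_pack_size * unit_costs$levodopa_tablet_mg)
}

ledd_for_cycle <- function(arm, cycle_index) {
  arm$ledd_mg_by_cycle[[min(cycle_index, 4L)]]
}

#' Daily pharmaceutical cost
#'
#' On treatment, stand-alone arms pay for the COMT-inhibitor tablets plus
#' levodopa at the cycle's levodopa-equivalent daily dose (LEDD), priced
#' per mg from the 100 mg x 100-tablet pack; combination
#' levodopa/carbidopa/entacapone arms pay for their tablets only, since the
#' preparation already contains the levodopa. Off treatment, only levodopa
#' at `options$off_treatment_ledd_mg` is paid (benefit foregone implies
#' reversion to non-opicapone levodopa requirements).
#'
#' @param arm Arm specification.
#' @param cycle_index Cycle number; LEDD uses the cycle-4+ value beyond 4.
#' @param on_treatment Logical.
#' @param unit_costs The `unit_costs` block of the configuration.
#' @param options The `options` block of the configuration.
#' @return GBP per day.
#' @export
daily_pharmaceutical_cost <- function(arm, cycle_index, on_treatment,
                                      unit_costs, options) {
  mg_cost <- levodopa_cost_per_mg(unit_costs)
  if (!on_treatment) {
    return(options$off_treatment_ledd_mg * mg_cost)
  }
  comt <- arm$daily_doses * tablet_cost(arm$pack_price, arm$pack_size)
  if (identical(arm$preparation_class, "entacapone_combination")) {
    comt
  } else {
    comt + ledd_for_cycle(arm, cycle_index) * mg_cost
  }
}

#' Treatment-dependent resource-use cost per cycle
#'
#' Neurology outpatient visits priced at the consultant-led specialist
#' rate, other outpatient visits at the generic outpatient rate, and
#' accident & emergency attendances at the A&E rate. The schedules are per
#' cycle (the cycle-1 values cover the 3-month cycle) and identical across
#' OFF-time states.
#'
#' @inheritParams daily_pharmaceutical_cost
#' @return GBP per cycle.
#' @export
treatment_hcru_cycle_cost <- function(arm, cycle_index, unit_costs) {
  i <- min(cycle_index, 4L)
  arm$neurology_visits[[i]] * unit_costs$consultant_visit +
    arm$other_outpatient_visits[[i]] * unit_costs$outpatient_visit +
    arm$ae_dept_visits[[i]] * unit_costs$ae_dept_visit
}

#' OFF-time-dependent resource-use cost per cycle
#'
#' Annual hospital admissions (times length of stay), GP visits, and
#' Parkinson's-nurse visits for one OFF-time stratum, scaled to the cycle
#' length. `los_multiplier` scales the admission length (0.8 in the
#' reduced-admission scenario).
#'
#' @param state `"lt25"` or `"ge25"`.
#' @param cycle_years Cycle length in years.
#' @param resource_use The `state_resource_use` block of the configuration.
#' @param unit_costs The `unit_costs` block.
#' @param los_multiplier Length-of-stay multiplier (> 0).
#' @return GBP per cycle.
#' @export
state_hcru_cycle_cost <- function(state, cycle_years, resource_use, unit_costs,
                                  los_multiplier = 1) {
  if (cycle_years < 0) stop("cycle_years must be >= 0")
  if (los_multiplier <= 0) stop("los_multiplier must be > 0")
  ru <- resource_use[[state]]
  cycle_years * (
    ru$hospital_admissions_per_year * ru$admission_length_days *
      los_multiplier * unit_costs$hospital_day +
      ru$gp_visits_per_year * unit_costs$gp_visit +
      ru$pd_nurse_visits_per_year * unit_costs$pd_nurse_visit
  )
}

#' Expected adverse-event management cost per cycle
#'
#' Each arm's 3-month adverse-event probabilities are converted to the
#' cycle length under the constant-rate assumption and multiplied by the
#' per-event management cost. Adverse events accrue to on-treatment
#' patients only; off treatment the cost is zero.
#'
#' @inheritParams daily_pharmaceutical_cost
#' @param cycle_years Cycle length in years.
#' @return GBP per cycle.
#' @export
expected_ae_cycle_cost <- function(arm, cycle_index, on_treatment, unit_costs,
                                   cycle_years) {
  if (!on_treatment) return(0)
  p3m <- arm$ae_3month_probs
  ae_cost <- unit_costs$ae[names(p3m)]
  p_cycle <- vapply(p3m, convert_probability, numeric(1),
                    from_duration = 0.25, to_duration = cycle_years)
  sum(p_cycle * ae_cost)
}

#' Per-event adverse-event management costs
#'
#' Derived from clinician-elicited management patterns: dyskinesias cost a
#' GP appointment for 25% of patients; insomnia and diarrhea carry no
#' incremental cost (captured by GP visits and discontinuation,
#' respectively); constipation costs one laxative pack; nausea a
#' domperidone course for 30% of patients; hallucinations a quetiapine
#' course for 20%.
#'
#' @param gp_visit GP visit cost.
#' @param constipation_pack_price Laxative (ispaghula) pack price.
#' @param domperidone_pack_price Domperidone pack price.
#' @param quetiapine_pack_price Quetiapine pack price.
#' @param gp_fraction,nausea_fraction,hallucination_fraction Fractions of
#'   patients incurring the respective resource.
#' @return Named numeric vector of GBP per event, one entry per
#'   adverse-event type.
#' @examples
#' round(ae_unit_cost_table(), 2)
#' @export
ae_unit_cost_table <- function(gp_visit = 42.00,
                               constipation_pack_price = 2.45,
                               domperidone_pack_price = 0.20,
                               quetiapine_pack_price = 1.58,
                               gp_fraction = 0.25,
                               nausea_fraction = 0.30,
                               hallucination_fraction = 0.20) {
  c(dyskinesias = gp_fraction * gp_visit,
    insomnia = 0,
    constipation = constipation_pack_price,
    diarrhea = 0,
    nausea = nausea_fraction * domperidone_pack_price,
    hallucinations = hallucination_fraction * quetiapine_pack_price)
}

#' Weighted consultant-led visit cost
#'
#' The consultant-led specialist visit price is a weighted average of two
#' consultant-led service tariffs (40% / 60% in the defaults).
#'
#' @param cost_a,cost_b Tariffs in GBP.
#' @param weight_a Weight on `cost_a`, in `[0, 1]`.
#' @return GBP per visit.
#' @examples
#' consultant_visit_weighted_cost(221.61, 392.91, 0.40)  # 324.39
#' @export
consultant_visit_weighted_cost <- function(cost_a = 221.61, cost_b = 392.91,
                                           weight_a = 0.40) {
  if (weight_a < 0 || weight_a > 1) stop("weight_a must be in [0, 1]")
  weight_a * cost_a + (1 - weight_a) * cost_b
}

#' Entacapone dosing arithmetic
#'
#' `entacapone_daily_mg()` gives the entacapone intake implied by the mean
#' number of daily levodopa intakes (each co-administered with one 200 mg
#' entacapone tablet); `entacapone_ddd_doses()` gives the number of 200 mg
#' doses in the WHO defined daily dose of 1 g. The trial mean of 4.3 daily
#' intakes implies 860 mg/day, rounded up to the DDD of five whole tablets
#' in the base case.
#'
#' @param mean_daily_intakes Mean levodopa intakes per day.
#' @param dose_mg Entacapone per tablet, mg.
#' @param ddd_mg WHO defined daily dose, mg.
#' @return Milligrams per day, or tablets per day.
#' @export
entacapone_daily_mg <- function(mean_daily_intakes = 4.3, dose_mg = 200) {
  mean_daily_intakes * dose_mg
}

#' @rdname entacapone_daily_mg
#' @export
entacapone_ddd_doses <- function(ddd_mg = 1000, dose_mg = 200) {
  ceiling(ddd_mg / dose_mg)
}
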