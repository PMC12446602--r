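# Probabilistic sensitivity analysis: method-of-moments distribution
# fitting, seeded parameter sampling, probability of cost-effectiveness,
# and the scenario analyses.

#' Fit a parameter distribution by method of moments
#'
#' Gamma distributions are used for cost and resource-use parameters, beta
#' for probabilities and utilities, and lognormal for the mortality hazard
#' ratio. Natural parameters are derived from the target mean and standard
#' deviation: gamma `shape = mean^2/sd^2`, `scale = sd^2/mean`; beta
#' `alpha = mean * nu`, `beta = (1 - mean) * nu` with
#' `nu = mean(1 - mean)/sd^2 - 1` (requires `sd^2 < mean(1 - mean)`);
#' lognormal `sdlog = sqrt(log(1 + (sd/mean)^2))` (or a given `sdlog`) and
#' `meanlog = log(mean) - sdlog^2/2`, so the fitted mean equals the target.
#' Invalid moment combinations fail at fit time rather than silently
#' truncating.
#'
#' @param family `"gamma"`, `"beta"`, `"lognormal"`, or `"fixed"`.
#' @param mean Target mean.
#' @param sd Target standard deviation (ignored for `"fixed"`).
#' @param sdlog Optional lognormal sdlog, overriding `sd`.
#' @return A `parkcem_distribution` list with `family`, `mean`, `sd`, and
#'   the natural parameters in `pars`.
#' @examples
#' fit_distribution("gamma", 100, 20)$pars   # shape 25, scale 4
#' fit_distribution("beta", 0.5, 0.1)$pars   # alpha = beta = 12
#' @export
fit_distribution <- function(family = c("gamma", "beta", "lognormal", "fixed"),
                             mean, sd = NULL, sdlog = NULL) {
  family <- match.arg(family)
  pars <- switch(family,
    fixed = list(value = mean),
    gamma = {
      if (mean <= 0) stop("gamma requires a positive mean")
      if (is.null(sd) || sd <= 0) stop("gamma requires a positive sd")
      list(shape = mean^2 / sd^2, scale = sd^2 / mean)
    },
    beta = {
      if (mean <= 0 || mean >= 1) stop("beta requires mean in (0, 1)")
      if (is.null(sd) || sd <= 0) stop("beta requires a positive sd")
      if (sd^2 >= mean * (1 - mean)) {
        stop("beta requires sd^2 < mean * (1 - mean)")
      }
      nu <- mean * (1 - mean) / sd^2 - 1
      list(alpha = mean * nu, beta = (1 - mean) * nu)
    },
    lognormal = {
      if (mean <= 0) stop("lognormal requires a positive mean")
      if (is.null(sdlog)) {
        if (is.null(sd) || sd <= 0) stop("lognormal requires sd or sdlog")
        sdlog <- sqrt(log(1 + (sd / mean)^2))
      }
      list(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
    }
  )
  structure(list(family = family, mean = mean, sd = sd, pars = pars),
            class = "parkcem_distribution")
}

#' Draw from a fitted parameter distribution
#'
#' @param dist A `parkcem_distribution` from [fit_distribution()].
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
sample_distribution <- function(dist, n = 1) {
  p <- dist$pars
  switch(dist$family,
    fixed = rep(p$value, n),
    gamma = rgamma(n, shape = p$shape, scale = p$scale),
    beta = rbeta(n, p$alpha, p$beta),
    lognormal = rlnorm(n, p$meanlog, p$sdlog)
  )
}

dist_entry <- function(path, family, mean, sd = NULL, sdlog = NULL) {
  if (family != "fixed" && (is.null(sd) || identical(sd, 0)) && is.null(sdlog)) {
    family <- "fixed"
  }
  if (family %in% c("gamma", "lognormal") && mean == 0) family <- "fixed"
  if (family == "beta" && (mean <= 0 || mean >= 1)) family <- "fixed"
  list(path = path, dist = fit_distribution(family, mean, sd = sd, sdlog = sdlog))
}

#' Default PSA distribution assignments
#'
#' Assigns gamma distributions to every cost and resource-use parameter,
#' beta to probabilities and utilities, and lognormal to the mortality
#' hazard ratio (with `options$psa$hr_sdlog`). Dispersions default to a
#' coefficient of variation from `options$psa` (20% of the mean). Clinical
#' parameters are sampled once for the stand-alone entacapone arm and
#' copied to every entacapone preparation, so health outcomes, state costs,
#' and adverse-event costs stay identical across the entacapone comparators
#' within an iteration; pack prices are sampled per arm.
#'
#' @param config Model configuration.
#' @return List of entries, each with a `path` (see [config_get()]) and a
#'   fitted `dist`.
#' @export
default_distributions <- function(config) {
  psa <- config$options$psa
  entries <- list()
  add <- function(path, family, mean, sd = NULL, sdlog = NULL) {
    entries[[length(entries) + 1]] <<- dist_entry(path, family, mean, sd, sdlog)
  }

  add(c("utilities", "u_lt25"), "beta", config$utilities$u_lt25,
      psa$utility_cv * config$utilities$u_lt25)
  add(c("utilities", "u_ge25"), "beta", config$utilities$u_ge25,
      psa$utility_cv * config$utilities$u_ge25)
  p_dec <- config$natural_history$annual_decline_prob
  add(c("natural_history", "annual_decline_prob"), "beta", p_dec,
      psa$prob_cv * p_dec)
  add(c("mortality", "pd_hazard_ratio"), "lognormal",
      config$mortality$pd_hazard_ratio, sdlog = psa$hr_sdlog)

  for (nm in c("levodopa_pack_price", "hospital_day", "consultant_visit",
               "gp_visit", "outpatient_visit", "ae_dept_visit",
               "pd_nurse_visit")) {
    m <- config$unit_costs[[nm]]
    add(c("unit_costs", nm), "gamma", m, psa$cost_cv * m)
  }
  for (nm in names(config$unit_costs$ae)) {
    m <- config$unit_costs$ae[[nm]]
    add(c("unit_costs", "ae", nm), "gamma", m, psa$cost_cv * m)
  }
  for (st in c("lt25", "ge25")) {
    for (nm in names(config$state_resource_use[[st]])) {
      m <- config$state_resource_use[[st]][[nm]]
      add(c("state_resource_use", st, nm), "gamma", m, psa$resource_cv * m)
    }
  }
  for (arm_key in names(config$arms)) {
    m <- config$arms[[arm_key]]$pack_price
    add(c("arms", arm_key, "pack_price"), "gamma", m, psa$cost_cv * m)
  }

  # clinical and schedule parameters: opicapone plus one shared entacapone
  is_ent <- vapply(config$arms, function(a)
    a$preparation_class != "opicapone", logical(1))
  ent_key <- names(config$arms)[which(is_ent)[1]]
  opi_key <- names(config$arms)[which(!is_ent)[1]]
  for (arm_key in c(opi_key, ent_key)) {
    a <- config$arms[[arm_key]]
    add(c("arms", arm_key, "cycle1_response_prob"), "beta",
        a$cycle1_response_prob, psa$prob_cv * a$cycle1_response_prob)
    for (y in seq_along(a$discontinuation_by_year)) {
      m <- a$discontinuation_by_year[[y]]
      add(c("arms", arm_key, "discontinuation_by_year", as.character(y)),
          "beta", m, psa$prob_cv * m)
    }
    for (nm in names(a$ae_3month_probs)) {
      m <- a$ae_3month_probs[[nm]]
      add(c("arms", arm_key, "ae_3month_probs", nm), "beta", m, psa$prob_cv * m)
    }
    for (fld in c("ledd_mg_by_cycle", "neurology_visits",
                  "other_outpatient_visits", "ae_dept_visits")) {
      for (i in 1:4) {
        m <- config$arms[[arm_key]][[fld]][[i]]
        add(c("arms", arm_key, fld, as.character(i)), "gamma", m,
            psa$resource_cv * m)
      }
    }
  }
  entries
}

# Copy the shared entacapone clinical and resource-use fields from the
# first stand-alone entacapone arm to every other entacapone-class arm.
copy_shared_entacapone <- function(config) {
  is_ent <- vapply(config$arms, function(a)
    a$preparation_class != "opicapone", logical(1))
  keys <- names(config$arms)[is_ent]
  if (length(keys) < 2) return(config)
  src <- config$arms[[keys[1]]]
  shared <- c("cycle1_response_prob", "discontinuation_by_year",
              "ae_3month_probs", "ledd_mg_by_cycle", "neurology_visits",
              "other_outpatient_visits", "ae_dept_visits")
  for (k in keys[-1]) {
    config$arms[[k]][shared] <- src[shared]
  }
  config
}

psa_iteration_seed <- function(seed, iteration) {
  s <- (abs(as.numeric(seed)) %% 2147483647) * 48271 + as.numeric(iteration) * 8191
  as.integer(s %% 2147483647) + 1L
}

#' Sample one PSA parameter set
#'
#' Draws every assigned distribution with an RNG stream derived from
#' `(rng_seed, iteration)`, so iterations are order-independent, then
#' propagates the shared entacapone clinical draws to every entacapone
#' preparation and validates the result.
#'
#' @param base Base configuration.
#' @param distributions Distribution assignments
#'   (from [default_distributions()]).
#' @param rng_seed Integer PSA seed.
#' @param iteration Iteration number (1-based).
#' @return A validated sampled configuration.
#' @export
sample_config <- function(base, distributions, rng_seed, iteration) {
  set.seed(psa_iteration_seed(rng_seed, iteration))
  cfg <- base
  for (e in distributions) {
    cfg <- config_set(cfg, e$path, sample_distribution(e$dist, 1))
  }
  cfg <- copy_shared_entacapone(cfg)
  assert_valid_config(cfg)
  cfg
}

#' Run the probabilistic sensitivity analysis
#'
#' For each iteration, samples a parameter set, runs the deterministic case
#' on it, and records the net monetary benefit of opicapone against each
#' comparator at the configured threshold. Reports the average NMB and the
#' probability of cost-effectiveness (fraction of iterations with positive
#' NMB) per comparator.
#'
#' @param config Base configuration.
#' @param n_iterations Number of iterations (default
#'   `config$options$psa$n_iterations`, 2500).
#' @param seed Integer seed.
#' @param distributions Distribution assignments; defaults to
#'   [default_distributions()].
#' @return A `parkcem_psa` list: `summary` (comparator, average_nmb,
#'   prob_cost_effective), `nmb_draws` (iterations x comparators),
#'   `n_iterations`, `seed`.
#' @export
run_psa <- function(config, n_iterations = config$options$psa$n_iterations,
                    seed = 1, distributions = default_distributions(config)) {
  if (n_iterations < 1) stop("n_iterations must be >= 1")
  assert_valid_config(config)
  nmb_draws <- NULL
  for (it in seq_len(n_iterations)) {
    cfg <- sample_config(config, distributions, seed, it)
    det <- run_deterministic_case(cfg)
    nmb <- setNames(det$comparisons$nmb, rownames(det$comparisons))
    if (is.null(nmb_draws)) {
      nmb_draws <- matrix(NA_real_, n_iterations, length(nmb),
                          dimnames = list(NULL, names(nmb)))
    }
    nmb_draws[it, ] <- nmb
  }
  display <- vapply(colnames(nmb_draws),
                    function(k) config$arms[[k]]$name, character(1))
  summary <- data.frame(
    comparator = unname(display),
    average_nmb = colMeans(nmb_draws),
    prob_cost_effective = colMeans(nmb_draws > 0),
    row.names = colnames(nmb_draws),
    stringsAsFactors = FALSE
  )
  structure(list(summary = summary, nmb_draws = nmb_draws,
                 n_iterations = n_iterations, seed = seed),
            class = "parkcem_psa")
}

#' @export
print.parkcem_psa <- function(x, ...) {
  cat(sprintf("parkcem PSA: %d iterations, seed %s\n", x$n_iterations,
              format(x$seed)))
  s <- x$summary
  s$average_nmb <- round(s$average_nmb)
  s$prob_cost_effective <- sprintf("%.1f%%", 100 * s$prob_cost_effective)
  print(s, row.names = FALSE)
  invisible(x)
}

#' Scenario configurations
#'
#' The four scenario analyses as targeted overrides of a base
#' configuration: cohort starting age raised to 75; entacapone daily intake
#' at the 10-dose maximum; entacapone intake reduced to 4 doses; hospital
#' admission length reduced by 20%.
#'
#' @param base Base configuration.
#' @return Named list of four configurations.
#' @export
scenario_configs <- function(base = default_config()) {
  set_ent_doses <- function(cfg, doses) {
    for (k in names(cfg$arms)) {
      if (cfg$arms[[k]]$preparation_class != "opicapone") {
        cfg$arms[[k]]$daily_doses <- doses
      }
    }
    cfg
  }
  age75 <- base
  age75$cohort$start_age <- 75
  los80 <- base
  los80$options$los_multiplier <- 0.8
  list(
    start_age_75 = age75,
    entacapone_10_doses = set_ent_doses(base, 10),
    entacapone_4_doses = set_ent_doses(base, 4),
    admission_length_minus_20pct = los80
  )
}

#' Run the scenario analyses
#'
#' @param base Base configuration.
#' @return List with `results` (one [run_deterministic_case()] output per
#'   scenario) and `table`, the combined comparison table with a `scenario`
#'   column.
#' @export
run_scenarios <- function(base = default_config()) {
  cfgs <- scenario_configs(base)
  results <- lapply(cfgs, run_deterministic_case)
  tabs <- lapply(names(results), function(nm) {
    tb <- results[[nm]]$comparisons
    cbind(scenario = nm, tb, row.names = NULL)
  })
  list(results = results, table = do.call(rbind, tabs))
}
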