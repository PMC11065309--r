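## re-evaluate the deterministic comparison with one input changed.
## Device-cost changes propagate into the intervention arm's hospital cost
## as an additive per-patient adjustment from the base per-patient device
## cost (the episode costs already embed the base device cost).
modified_model <- function(params, parameter, value, lambda = 20000,
                           device_method = "straight_line") {
  p2 <- params
  base_dev <- device_cost_per_patient(params$device_prices,
                                      params$resource_use,
                                      arm = "intervention",
                                      method = device_method,
                                      discount_rate = params$discount_rate)
  if (parameter %in% c("product_life", "cableless_rate")) {
    p2$resource_use[[parameter]] <- value
  } else if (parameter == "ward_mix") {
    p2$resource_use$ward_mix_pulmonology <- value
  } else if (parameter == "discount_rate") {
    p2$discount_rate <- value
  } else {
    stop("unknown sensitivity parameter '", parameter, "'", call. = FALSE)
  }
  new_dev <- device_cost_per_patient(p2$device_prices, p2$resource_use,
                                     arm = "intervention",
                                     method = device_method,
                                     discount_rate = p2$discount_rate)
  p2$episode_costs$intervention["mean"] <-
    p2$episode_costs$intervention["mean"] +
    (new_dev$per_patient - base_dev$per_patient)
  ce_model(p2, lambda = lambda)
}

#' One-way deterministic sensitivity analysis
#'
#' Re-evaluates the deterministic comparison across a grid of values of a
#' single input. Supported parameters: `product_life` (years),
#' `cableless_rate` (proportion of intervention patients using a cableless
#' sensor), `ward_mix` (proportion of admissions to the respiratory ward)
#' and `discount_rate`. Device-cost consequences enter the intervention
#' arm's hospital cost additively relative to the base per-patient device
#' cost; the discount rate propagates through the equivalent-annual-cost
#' device price.
#'
#' @param params a `ce_parameters` object.
#' @param parameter name of the input to vary.
#' @param values numeric grid.
#' @param lambda willingness-to-pay, GBP per QALY.
#' @return data frame with one row per value: lifetime `delta_cost`,
#'   `delta_qaly`, short-term `delta_cost_short`, `icer` (NA under
#'   dominance), `dominance`, `nmb`.
#' @export
#' @examples
#' one_way_sensitivity(load_parameters(), "product_life", c(5, 10, 15))
one_way_sensitivity <- function(params, parameter, values,
                                lambda = 20000) {
  method <- if (parameter == "discount_rate") "equivalent_annual_cost"
    else "straight_line"
  rows <- lapply(values, function(v) {
    m <- modified_model(params, parameter, v, lambda = lambda,
                        device_method = method)
    data.frame(parameter = parameter, value = v,
               delta_cost = m$lifetime$delta_cost,
               delta_qaly = m$lifetime$delta_effect,
               delta_cost_short = m$short_term$delta_cost,
               icer = m$lifetime$icer,
               dominance = m$lifetime$dominance,
               nmb = m$lifetime$nmb)
  })
  do.call(rbind, rows)
}

#' Cableless-sensor dominance boundary
#'
#' The cableless-sensor usage rate at which the intervention stops being
#' cost saving during the inpatient episode (short-term incremental
#' hospital cost crosses zero). The incremental cost is affine in the
#' rate, so the root is unique; it is located by bisection to `tol`.
#'
#' @param params a `ce_parameters` object.
#' @param lower,upper search interval for the rate.
#' @param tol bisection tolerance, default 0.001.
#' @return the boundary rate, or `NA` with a warning when the incremental
#'   cost does not change sign on the interval.
#' @export
cableless_dominance_boundary <- function(params, lower = 0, upper = 1,
                                         tol = 0.001) {
  short_delta <- function(rate)
    modified_model(params, "cableless_rate", rate)$short_term$delta_cost
  f_lo <- short_delta(lower)
  f_hi <- short_delta(upper)
  if (sign(f_lo) == sign(f_hi)) {
    warning("short-term incremental cost does not change sign on [",
            lower, ", ", upper, "]", call. = FALSE)
    return(NA_real_)
  }
  while (upper - lower > tol) {
    mid <- (lower + upper) / 2
    if (sign(short_delta(mid)) == sign(f_lo)) {
      lower <- mid
    } else {
      upper <- mid
    }
  }
  (lower + upper) / 2
}

#' Define a subgroup strategy
#'
#' A named strategy carrying its own complete parameter set (typically
#' re-estimated from stratified patient-level data via
#' [subgroup_parameters()], or supplied directly).
#'
#' @param name strategy label.
#' @param params a `ce_parameters` object for the stratum.
#' @return object of class `subgroup_spec`.
#' @export
subgroup_spec <- function(name, params) {
  if (!inherits(params, "ce_parameters")) {
    stop("subgroup '", name, "' needs a ce_parameters object",
         call. = FALSE)
  }
  viol <- validate_parameters(params)
  if (length(viol)) {
    stop("incomplete/invalid parameter set for subgroup '", name, "':\n  - ",
         paste(viol, collapse = "\n  - "), call. = FALSE)
  }
  structure(list(name = name, params = params), class = "subgroup_spec")
}

#' Build per-stratum parameter sets from a stratified cohort
#'
#' Stratifies a patient-level cohort by age band (17-74 / 75+), NEWS band
#' (0-2 / 3-5 / 6+) or ward (gastroenterology / pulmonology, standing in
#' for the digestive/respiratory primary-diagnosis chapters), re-estimates
#' the stratum-specific inputs (discharge-state probabilities,
#' principal-event distributions, adjusted mean episode costs and event
#' counts) with covariate-free estimation, and carries the base-case
#' lifetime states, device prices and resource use over unchanged unless
#' supplied per stratum.
#'
#' @param cohort a `ce_cohort` data frame.
#' @param params the base-case `ce_parameters` object.
#' @param stratifier one of `"age_band"`, `"news_band"`, `"ward"`.
#' @return named list of [subgroup_spec()] objects (strata are exhaustive
#'   and mutually exclusive).
#' @export
subgroup_parameters <- function(cohort, params,
                                stratifier = c("age_band", "news_band",
                                               "ward")) {
  stratifier <- match.arg(stratifier)
  strata <- switch(stratifier,
    age_band = factor(ifelse(cohort$age >= 75, "75+", "17-74"),
                      levels = c("17-74", "75+")),
    news_band = cut(cohort$news_admission, c(-Inf, 2, 5, Inf),
                    labels = c("NEWS 0-2", "NEWS 3-5", "NEWS 6+")),
    ward = cohort$ward)
  specs <- lapply(levels(strata), function(lv) {
    d <- cohort[strata == lv, , drop = FALSE]
    est <- estimate_model_inputs(d, covariates = character(0))
    p2 <- params
    for (a in ARMS) {
      pr <- est$states$probabilities[[a]]
      p2$probabilities[[a]]$p <- pr
      p2$probabilities[[a]]$dirichlet_counts <-
        unname(pr) * sum(cohort$arm == a & strata == lv)
      pe <- est$states$principal[[a]]
      if (!any(is.na(pe))) {
        p2$principal_events[[a]]$probability[] <- pe
        p2$principal_events[[a]]$concentration[] <-
          pe * sum(d$arm == a & !d$died_inpatient &
                     d$principal_event != "none")
      }
      m <- est$costs$adjusted_means[[a]]
      p2$episode_costs[[a]] <- c(mean = m, low = m * 0.9, high = m * 1.1)
      me <- est$events$adjusted_means[[a]]
      p2$event_rates[[a]] <- c(mean = me, low = me * 0.5, high = me * 1.5)
    }
    subgroup_spec(paste0(stratifier, ": ", lv), p2)
  })
  stats::setNames(specs, levels(strata))
}

#' Net-benefit league table over subgroup strategies
#'
#' Evaluates the lifetime comparison for each strategy and ranks them by
#' net monetary benefit at the chosen willingness-to-pay (ranking by net
#' health benefit is identical at any single threshold).
#'
#' @param specs list of [subgroup_spec()] objects.
#' @param lambda willingness-to-pay, GBP per QALY, default 20000.
#' @return data frame of class `ce_league`: one row per strategy with
#'   `delta_cost`, `delta_qaly`, `icer`, `dominance`, `quadrant`, `nmb`,
#'   `nhb`, sorted by decreasing NMB (ties share a rank).
#' @export
run_subgroups <- function(specs, lambda = 20000) {
  rows <- lapply(specs, function(s) {
    if (!inherits(s, "subgroup_spec")) {
      stop("run_subgroups() expects subgroup_spec objects", call. = FALSE)
    }
    m <- ce_model(s$params, lambda = lambda)
    data.frame(strategy = s$name,
               delta_cost = m$lifetime$delta_cost,
               delta_qaly = m$lifetime$delta_effect,
               icer = m$lifetime$icer,
               dominance = m$lifetime$dominance,
               quadrant = m$lifetime$quadrant,
               nmb = m$lifetime$nmb,
               nhb = m$lifetime$nhb)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$nmb), , drop = FALSE]
  tab$rank <- rank(-tab$nmb, ties.method = "min")
  rownames(tab) <- NULL
  class(tab) <- c("ce_league", "data.frame")
  tab
}

#' Scenario analysis of the assumed parameter-uncertainty scale
#'
#' Re-runs the probabilistic sensitivity analysis at alternative values of
#' the sd-to-mean fraction assumed for the lifetime cost and QALE
#' distributions, using the same seed for every scenario, and reports the
#' probability of cost-effectiveness at the chosen threshold.
#'
#' @param params a `ce_parameters` object.
#' @param fractions sd fractions to test, default `c(0.1, 0.2, 0.4)`.
#' @param cfg base [psa_config()] supplying draws, seed and lambda grid.
#' @param lambda threshold at which to read the CEAC, default 20000.
#' @return data frame with one row per fraction: `ceac_at_lambda`, mean
#'   and central range of incremental cost and QALYs.
#' @export
scenario_sd <- function(params, fractions = c(0.1, 0.2, 0.4),
                        cfg = psa_config(), lambda = 20000) {
  stopifnot(all(fractions >= 0))
  rows <- lapply(fractions, function(f) {
    cfg_f <- cfg
    cfg_f$sd_fraction <- f
    res <- run_psa(params, cfg_f)
    cc <- ceac(res, lambda)
    data.frame(sd_fraction = f,
               ceac_at_lambda = cc$probability,
               mean_delta_cost = res$summary$mean[1],
               low_delta_cost = res$summary$low[1],
               high_delta_cost = res$summary$high[1],
               mean_delta_qaly = res$summary$mean[2])
  })
  do.call(rbind, rows)
}
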