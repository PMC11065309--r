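#' Lifetime outcome of the "no event" discharge state
#'
#' Patients discharged without a serious adverse event are assigned a
#' ward-mix weighted average of the chronic-condition profiles of the two
#' study wards: `mix * ward2 + (1 - mix) * ward1` for both discounted
#' lifetime cost and QALE, where `mix` is the proportion admitted to the
#' respiratory (pulmonology) ward.
#'
#' @param states the lifetime health-state table of a `ce_parameters`
#'   object (must contain rows `ward1_gastroenterology` and
#'   `ward2_respiratory`).
#' @param ward_mix_pulmonology proportion of admissions to the respiratory
#'   ward, in \[0, 1\].
#' @return named numeric vector `c(lifetime_cost, qale)`.
#' @export
#' @examples
#' no_event_outcome(load_parameters()$states, 0.56)
no_event_outcome <- function(states, ward_mix_pulmonology) {
  if (ward_mix_pulmonology < 0 || ward_mix_pulmonology > 1) {
    stop("ward mix must be in [0,1]", call. = FALSE)
  }
  for (w in c("ward1_gastroenterology", "ward2_respiratory")) {
    if (!w %in% rownames(states)) {
      stop("missing ward state '", w, "'", call. = FALSE)
    }
  }
  w1 <- states["ward1_gastroenterology", ]
  w2 <- states["ward2_respiratory", ]
  m <- ward_mix_pulmonology
  c(lifetime_cost = (1 - m) * w1$lifetime_cost + m * w2$lifetime_cost,
    qale = (1 - m) * w1$qale + m * w2$qale)
}

## shared expectation over the one-shot decision tree:
## p(no event) * no-event payoff + p(event survive) * E_pi[event payoff]
## + p(death) * 0. For costs, states flagged use_no_event_cost (pulmonary
## embolism) take the no-event cost in place of their own.
lifetime_expectation <- function(arm_probs, event_dist, states, ward_mix) {
  if (abs(sum(arm_probs) - 1) > 1e-9) {
    stop("discharge-state probabilities do not sum to 1", call. = FALSE)
  }
  if (abs(sum(event_dist) - 1) > 1e-6) {
    stop("principal-event distribution is not normalized", call. = FALSE)
  }
  ne <- no_event_outcome(states, ward_mix)
  ev <- states[names(event_dist), ]
  if (any(is.na(ev$qale))) {
    stop("principal-event categories missing from the state table",
         call. = FALSE)
  }
  ev_cost <- ifelse(ev$use_no_event_cost, ne["lifetime_cost"],
                    ev$lifetime_cost)
  c(lifetime_cost = unname(arm_probs["no_event"] * ne["lifetime_cost"] +
      arm_probs["event_survive"] * sum(event_dist * ev_cost)),
    qale = unname(arm_probs["no_event"] * ne["qale"] +
      arm_probs["event_survive"] * sum(event_dist * ev$qale)))
}

#' Expected lifetime QALE of one arm
#'
#' Probability-weighted quality-adjusted life expectancy over the discharge
#' states: no event (ward-mix weighted), each surviving principal event
#' (weighted by the within-survivor event distribution), and inpatient
#' death (QALE zero).
#'
#' @param arm_probs named vector with `no_event`, `event_survive`,
#'   `inpatient_death` summing to 1.
#' @param event_dist named probability vector over the principal-event
#'   categories (sums to 1).
#' @param states lifetime health-state table.
#' @param ward_mix proportion admitted to the respiratory ward.
#' @return expected discounted QALYs.
#' @export
expected_lifetime_qale <- function(arm_probs, event_dist, states, ward_mix) {
  lifetime_expectation(arm_probs, event_dist, states, ward_mix)[["qale"]]
}

#' Expected lifetime cost of one arm
#'
#' Same expectation structure as [expected_lifetime_qale()] with death
#' costing zero. Event states whose published lifetime cost is below the
#' no-event cost do not carry their own cost forward: in the base-case
#' inputs only pulmonary embolism is assigned the no-event (ward-mix
#' weighted) cost instead of its own.
#'
#' @inheritParams expected_lifetime_qale
#' @return expected discounted lifetime cost in GBP.
#' @export
expected_lifetime_cost <- function(arm_probs, event_dist, states, ward_mix) {
  lifetime_expectation(arm_probs, event_dist, states,
                       ward_mix)[["lifetime_cost"]]
}

#' Discounted quality-adjusted life expectancy
#'
#' QALE implied by a constant annual utility over a remaining life
#' expectancy, discounted as an annuity: `annual_utility *
#' annuity_factor(life_expectancy, rate)`.
#'
#' @param annual_utility health-state utility, in \[0, 1.2\].
#' @param life_expectancy remaining life expectancy in years (> 0).
#' @param rate annual discount rate.
#' @return discounted QALYs.
#' @export
#' @examples
#' discounted_qale(0.75, 17.74, 0.035)
discounted_qale <- function(annual_utility, life_expectancy, rate) {
  if (annual_utility < 0 || annual_utility > 1.2) {
    stop("annual_utility must be in [0, 1.2]", call. = FALSE)
  }
  annual_utility * annuity_factor(life_expectancy, rate)
}

#' Evaluate one model arm
#'
#' Combines the arm's adjusted inpatient episode cost (device cost already
#' included), its expected discounted lifetime cost and QALE from the
#' decision tree, and its adjusted expected serious-adverse-event count.
#'
#' @param params a `ce_parameters` object.
#' @param arm `"intervention"` or `"control"`.
#' @return object of class `ce_arm`: list with `arm`, `hospital_cost`,
#'   `lifetime_cost`, `total_cost`, `expected_events`, `qale`.
#' @export
evaluate_arm <- function(params, arm = c("intervention", "control")) {
  arm <- match.arg(arm)
  exp_lt <- lifetime_expectation(
    params$probabilities[[arm]]$p,
    params$principal_events[[arm]]$probability,
    params$states,
    params$resource_use$ward_mix_pulmonology
  )
  hosp <- unname(params$episode_costs[[arm]]["mean"])
  structure(list(
    arm = arm,
    hospital_cost = hosp,
    lifetime_cost = unname(exp_lt["lifetime_cost"]),
    total_cost = hosp + unname(exp_lt["lifetime_cost"]),
    expected_events = unname(params$event_rates[[arm]]["mean"]),
    qale = unname(exp_lt["qale"])
  ), class = "ce_arm")
}

#' @export
print.ce_arm <- function(x, ...) {
  cat(sprintf("%s arm\n", x$arm))
  cat(sprintf("  hospital cost   GBP %9.2f\n", x$hospital_cost))
  cat(sprintf("  lifetime cost   GBP %9.2f\n", x$lifetime_cost))
  cat(sprintf("  total cost      GBP %9.2f\n", x$total_cost))
  cat(sprintf("  expected events     %9.4f per patient\n",
              x$expected_events))
  cat(sprintf("  QALE                %9.4f QALYs\n", x$qale))
  invisible(x)
}

#' Incremental comparison of two arms
#'
#' Computes incremental cost and effect of arm `a` over arm `b`, the
#' cost-effectiveness plane quadrant, dominance classification, the ICER
#' where defined (effect difference non-zero, north-east or south-west
#' quadrant), and net monetary / net health benefit at willingness-to-pay
#' `lambda`.
#'
#' @param a,b `ce_arm` results (same effect units).
#' @param lambda willingness-to-pay threshold in GBP per effect unit,
#'   default 20000.
#' @param effect `"qale"` (lifetime cost-utility, effect = QALYs, cost =
#'   total cost) or `"events"` (short-term analysis, effect = events
#'   avoided = reduction in expected events, cost = hospital cost).
#' @return object of class `ce_incremental`: list with `delta_cost`,
#'   `delta_effect`, `quadrant`, `dominance`, `icer`, `nmb`, `nhb`,
#'   `lambda`, `effect_units`.
#' @export
compare_arms <- function(a, b, lambda = 20000,
                         effect = c("qale", "events")) {
  effect <- match.arg(effect)
  if (effect == "qale") {
    d_cost <- a$total_cost - b$total_cost
    d_eff <- a$qale - b$qale
    units <- "QALYs"
  } else {
    d_cost <- a$hospital_cost - b$hospital_cost
    d_eff <- b$expected_events - a$expected_events  # events avoided
    units <- "events avoided"
  }
  quadrant <- paste0(if (d_cost >= 0) "N" else "S",
                     if (d_eff >= 0) "E" else "W")
  dominance <- if (d_cost < 0 && d_eff > 0) "dominant"
    else if (d_cost > 0 && d_eff < 0) "dominated"
    else "non-dominated"
  icer <- if (d_eff != 0 && quadrant %in% c("NE", "SW")) d_cost / d_eff
    else NA_real_
  nmb <- lambda * d_eff - d_cost
  structure(list(
    delta_cost = d_cost, delta_effect = d_eff,
    quadrant = quadrant, dominance = dominance, icer = icer,
    nmb = nmb, nhb = nmb / lambda,
    lambda = lambda, effect_units = units
  ), class = "ce_incremental")
}

#' @export
print.ce_incremental <- function(x, ...) {
  cat(sprintf("Incremental result (%s)\n", x$effect_units))
  cat(sprintf("  delta cost    GBP %9.2f\n", x$delta_cost))
  cat(sprintf("  delta effect      %9.4f %s\n", x$delta_effect,
              x$effect_units))
  cat(sprintf("  quadrant %s — %s\n", x$quadrant, x$dominance))
  if (is.finite(x$icer)) {
    cat(sprintf("  ICER          GBP %9.2f per %s\n", x$icer,
                sub("s$", "", x$effect_units)))
  } else {
    cat("  ICER          not defined (dominance or zero effect)\n")
  }
  cat(sprintf("  NMB at GBP %d: %9.2f   NHB: %.4f\n", x$lambda, x$nmb,
              x$nhb))
  invisible(x)
}

#' Fit the base-case decision model
#'
#' Evaluates both arms of the one-shot decision tree and their incremental
#' comparison on the lifetime cost-utility scale (cost per QALY) and the
#' short-term cost-effectiveness scale (cost per event avoided), together
#' with the per-arm device-cost breakdown. This is the package's central
#' model object: `summary()` prints the per-arm and incremental table,
#' `simulate()` runs the probabilistic sensitivity analysis.
#'
#' @param params a `ce_parameters` object, default the bundled base case.
#' @param lambda willingness-to-pay threshold in GBP per QALY.
#' @return object of class `ce_model`.
#' @seealso [simulate.ce_model()], [one_way_sensitivity()]
#' @export
#' @examples
#' m <- ce_model()
#' summary(m)
ce_model <- function(params = load_parameters(), lambda = 20000) {
  arms <- lapply(stats::setNames(ARMS, ARMS), evaluate_arm,
                 params = params)
  device <- lapply(stats::setNames(ARMS, ARMS), function(a)
    device_cost_per_patient(params$device_prices, params$resource_use,
                            arm = a, discount_rate = params$discount_rate))
  structure(list(
    parameters = params,
    arms = arms,
    device = device,
    lifetime = compare_arms(arms$intervention, arms$control,
                            lambda = lambda, effect = "qale"),
    short_term = compare_arms(arms$intervention, arms$control,
                              lambda = lambda, effect = "events"),
    lambda = lambda
  ), class = "ce_model")
}

#' @export
print.ce_model <- function(x, ...) {
  lt <- x$lifetime
  cat("Decision model: automated monitoring vs spot-check monitoring\n")
  cat(sprintf("  lifetime: delta cost GBP %.2f, delta QALY %.4f (%s)\n",
              lt$delta_cost, lt$delta_effect, lt$dominance))
  cat(sprintf("  short term: delta cost GBP %.2f, events avoided %.4f\n",
              x$short_term$delta_cost, x$short_term$delta_effect))
  cat(sprintf("  NMB at GBP %d/QALY: %.2f\n", lt$lambda, lt$nmb))
  invisible(x)
}

#' @export
summary.ce_model <- function(object, ...) {
  a <- object$arms$intervention
  b <- object$arms$control
  tab <- data.frame(
    quantity = c("Hospital cost (GBP, short-term)", "Lifetime cost (GBP)",
                 "Total cost (GBP)", "Expected events per patient",
                 "QALE (lifetime QALYs)"),
    intervention = c(a$hospital_cost, a$lifetime_cost, a$total_cost,
                     a$expected_events, a$qale),
    control = c(b$hospital_cost, b$lifetime_cost, b$total_cost,
                b$expected_events, b$qale)
  )
  tab$incremental <- tab$intervention - tab$control
  structure(list(table = tab, lifetime = object$lifetime,
                 short_term = object$short_term,
                 device = object$device), class = "summary.ce_model")
}

#' @export
print.summary.ce_model <- function(x, ...) {
  tab <- x$table
  money <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  for (col in c("intervention", "control", "incremental")) {
    tab[[col]] <- ifelse(money, sprintf("%.2f", tab[[col]]),
                         sprintf("%.4f", tab[[col]]))
  }
  print(tab, row.names = FALSE, right = FALSE)
  cat(sprintf("\nLifetime comparison: %s; NMB at GBP %d/QALY = %.2f\n",
              x$lifetime$dominance, x$lifetime$lambda, x$lifetime$nmb))
  cat(sprintf("Device cost per patient: intervention GBP %.2f, control GBP %.2f\n",
              x$device$intervention$per_patient,
              x$device$control$per_patient))
  invisible(x)
}
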