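#' Annual patient throughput of a ward
#'
#' Number of patient episodes a ward can carry per year given its bed count
#' and mean length of stay: `(365 / mean_los) * beds * occupancy`. The value
#' is returned unrounded and used unrounded in all downstream division.
#'
#' @param beds number of beds (> 0).
#' @param mean_los mean length of stay in days (> 0).
#' @param occupancy annual bed occupancy as a fraction, default 1 (the ward
#'   is assumed full year-round).
#' @return patients per year (numeric scalar).
#' @export
#' @examples
#' annual_patients(54, 8.62) # ~2287 patients per year
annual_patients <- function(beds, mean_los, occupancy = 1) {
  if (beds <= 0) stop("beds must be positive", call. = FALSE)
  if (mean_los <= 0) stop("mean_los must be positive", call. = FALSE)
  if (occupancy <= 0 || occupancy > 1) {
    stop("occupancy must be in (0, 1]", call. = FALSE)
  }
  365 / mean_los * beds * occupancy
}

#' Annuity factor
#'
#' Present value of one monetary unit per year for `n_years` at annual
#' discount `rate`: `(1 - (1 + rate)^-n) / rate`, with the zero-rate limit
#' equal to `n_years`. Used both for equivalent-annual-cost annualization of
#' the device purchase price and for discounting a constant annual utility
#' stream over remaining life expectancy.
#'
#' @param n_years horizon in years (> 0, need not be an integer).
#' @param rate annual discount rate (>= 0).
#' @return the annuity factor.
#' @export
#' @examples
#' annuity_factor(5, 0.035) # 4.515
annuity_factor <- function(n_years, rate) {
  if (n_years <= 0) stop("n_years must be positive", call. = FALSE)
  if (rate < 0) stop("rate must be non-negative", call. = FALSE)
  if (rate == 0) return(n_years)
  (1 - (1 + rate)^(-n_years)) / rate
}

#' Monitoring-device cost per patient episode
#'
#' Annualizes the fixed purchase price of the monitoring equipment over its
#' product life (straight-line depreciation, or equivalent annual cost using
#' the annuity factor at the model discount rate), adds the annual variable
#' cost of cableless sensors (intervention arm only: one sensor per
#' monitored patient episode, `cableless_rate * annual_patients *
#' sensor_unit`), and divides by the annual patient throughput.
#'
#' @param prices device-price list with `fixed_intervention`, `sensor_unit`,
#'   `fixed_control` (GBP); see [load_parameters()].
#' @param resource_use resource-use list with `beds`, per-arm `mean_los`,
#'   `cableless_rate`, `product_life`, `occupancy`.
#' @param arm `"intervention"` or `"control"`.
#' @param method `"straight_line"` (default) or `"equivalent_annual_cost"`.
#' @param discount_rate annual rate used by the equivalent-annual-cost
#'   method, default 0.035.
#' @param sensors_per_patient sensors consumed per monitored patient
#'   episode, default 1.
#' @return an object of class `device_cost`: list with `annual_total`,
#'   `per_bed_year`, `per_patient` (GBP), `annual_patients` and `method`.
#' @export
#' @examples
#' p <- load_parameters()
#' device_cost_per_patient(p$device_prices, p$resource_use, "intervention")
device_cost_per_patient <- function(prices, resource_use,
                                    arm = c("intervention", "control"),
                                    method = c("straight_line",
                                               "equivalent_annual_cost"),
                                    discount_rate = 0.035,
                                    sensors_per_patient = 1) {
  arm <- match.arg(arm)
  method <- match.arg(method)
  ru <- resource_use
  n_pat <- annual_patients(ru$beds, ru$mean_los[[arm]], ru$occupancy)
  fixed <- if (arm == "intervention") prices$fixed_intervention else
    prices$fixed_control
  annual_fixed <- switch(method,
    straight_line = fixed / ru$product_life,
    equivalent_annual_cost = fixed / annuity_factor(ru$product_life,
                                                    discount_rate))
  annual_variable <- if (arm == "intervention") {
    ru$cableless_rate * n_pat * prices$sensor_unit * sensors_per_patient
  } else 0
  annual_total <- annual_fixed + annual_variable
  structure(list(
    annual_total = annual_total,
    per_bed_year = annual_total / ru$beds,
    per_patient = annual_total / n_pat,
    annual_patients = n_pat,
    arm = arm,
    method = method
  ), class = "device_cost")
}

#' @export
print.device_cost <- function(x, ...) {
  cat(sprintf("Device cost (%s, %s)\n", x$arm, x$method))
  cat(sprintf("  total per year   GBP %10.2f\n", x$annual_total))
  cat(sprintf("  per bed-year     GBP %10.2f\n", x$per_bed_year))
  cat(sprintf("  per patient      GBP %10.2f  (%.0f patients/year)\n",
              x$per_patient, x$annual_patients))
  invisible(x)
}

#' Threshold device cost per patient
#'
#' The intervention per-patient device cost at which the short-term
#' incremental hospital cost (intervention minus control episode cost, with
#' device costs already embedded in the episode costs) reaches zero, holding
#' every other input fixed. Because the per-patient device cost enters the
#' episode cost additively, the threshold is the base per-patient device
#' cost plus the base per-patient hospital saving. When the intervention is
#' already more costly at baseline the returned value is the baseline cost
#' minus the excess, flagged via the `"already_more_costly"` attribute.
#'
#' @param params a `ce_parameters` object.
#' @param method annualization method passed to [device_cost_per_patient()].
#' @return threshold cost in GBP per patient, with attribute
#'   `already_more_costly` (logical).
#' @export
threshold_device_cost <- function(params, method = "straight_line") {
  base <- device_cost_per_patient(params$device_prices,
                                  params$resource_use,
                                  arm = "intervention", method = method,
                                  discount_rate = params$discount_rate)
  delta_hosp <- unname(params$episode_costs$intervention["mean"] -
                       params$episode_costs$control["mean"])
  structure(base$per_patient - delta_hosp,
            already_more_costly = delta_hosp > 0)
}
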