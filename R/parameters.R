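ARMS <- c("intervention", "control")

#' Load a model-parameter bundle
#'
#' Reads the complete set of decision-model inputs from a plain-text YAML
#' configuration: per-arm discharge-state probabilities (no event /
#' event-survive / inpatient death) with Dirichlet effective counts,
#' per-arm distributions over the seven non-fatal principal events,
#' lifetime cost and quality-adjusted life expectancy (QALE) per discharge
#' health state with their probabilistic-sensitivity-analysis distribution
#' specifications, ward resource use, monitoring-device prices, per-arm
#' inpatient episode costs and adjusted serious-adverse-event rates with
#' 95% central ranges, and discounting constants.
#'
#' The default path is the bundled base-case fixture `vital2_basecase.yaml`,
#' which reproduces the published model inputs for an automated vital-signs
#' monitoring and notification system versus spot-check monitoring on two
#' general wards of a UK district general hospital (2020/21 GBP, lifetime
#' values discounted at 3.5% a year).
#'
#' @param path path to a YAML parameter file; defaults to the bundled
#'   base-case fixture.
#' @return an object of class `ce_parameters` (a validated nested list).
#' @seealso [validate_parameters()], [write_parameters()], [ce_model()]
#' @export
#' @examples
#' p <- load_parameters()
#' p$probabilities$intervention$p["no_event"]
load_parameters <- function(path = ce_fixture_path()) {
  if (!file.exists(path)) {
    stop("parameter file not found: ", path, call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  p <- build_parameters(raw)
  viol <- validate_parameters(p)
  if (length(viol)) {
    stop("invalid parameter set:\n  - ", paste(viol, collapse = "\n  - "),
         call. = FALSE)
  }
  p
}

#' Path to the bundled base-case parameter fixture
#' @return file path of `vital2_basecase.yaml` inside the installed package.
#' @export
ce_fixture_path <- function() {
  system.file("extdata", "vital2_basecase.yaml", package = "monitorCE",
              mustWork = TRUE)
}

need <- function(x, field, where) {
  if (is.null(x[[field]])) {
    stop(sprintf("missing field '%s' in section '%s'", field, where),
         call. = FALSE)
  }
  x[[field]]
}

## assemble the in-memory representation from parsed YAML; structural
## (schema) errors raise here, value (invariant) errors are reported by
## validate_parameters().
build_parameters <- function(raw) {
  for (s in c("probabilities", "principal_events", "lifetime",
              "resource_use", "device_prices", "episode_costs",
              "event_rates", "discounting")) {
    if (is.null(raw[[s]])) stop("missing section '", s, "'", call. = FALSE)
  }

  probs <- lapply(ARMS, function(a) {
    x <- need(raw$probabilities, a, "probabilities")
    list(
      p = c(no_event = need(x, "no_event", a),
            event_survive = need(x, "event_survive", a),
            inpatient_death = need(x, "inpatient_death", a)),
      dirichlet_counts = as.numeric(need(x, "dirichlet_counts", a))
    )
  })
  names(probs) <- ARMS

  cats <- as.character(need(raw$principal_events, "categories",
                            "principal_events"))
  principal <- lapply(ARMS, function(a) {
    x <- need(raw$principal_events, a, "principal_events")
    pr <- as.numeric(need(x, "probability", a))
    cc <- as.numeric(need(x, "concentration", a))
    if (length(pr) != length(cats) || length(cc) != length(cats)) {
      stop("principal event vectors for '", a,
           "' do not match the category list", call. = FALSE)
    }
    list(probability = stats::setNames(pr, cats),
         concentration = stats::setNames(cc, cats))
  })
  names(principal) <- ARMS

  st <- need(raw$lifetime, "states", "lifetime")
  states <- do.call(rbind, lapply(st, function(s) {
    data.frame(
      name = need(s, "name", "lifetime$states"),
      lifetime_cost = need(s, "lifetime_cost", "lifetime$states"),
      qale = need(s, "qale", "lifetime$states"),
      gamma_alpha = need(s, "gamma", "lifetime$states")[[1]],
      gamma_beta = s$gamma[[2]],
      normal_mean = need(s, "normal", "lifetime$states")[[1]],
      normal_sd = s$normal[[2]],
      use_no_event_cost = isTRUE(s$use_no_event_cost),
      stringsAsFactors = FALSE
    )
  }))
  rownames(states) <- states$name

  ru <- raw$resource_use
  resource_use <- list(
    beds = need(ru, "beds", "resource_use"),
    mean_los = c(intervention = need(ru, "mean_los_intervention",
                                     "resource_use"),
                 control = need(ru, "mean_los_control", "resource_use")),
    cableless_rate = need(ru, "cableless_rate", "resource_use"),
    product_life = need(ru, "product_life", "resource_use"),
    ward_mix_pulmonology = need(ru, "ward_mix_pulmonology", "resource_use"),
    occupancy = if (is.null(ru$occupancy)) 1.0 else ru$occupancy
  )

  dp <- raw$device_prices
  device_prices <- list(
    fixed_intervention = need(dp, "fixed_intervention", "device_prices"),
    sensor_unit = need(dp, "sensor_unit", "device_prices"),
    fixed_control = need(dp, "fixed_control", "device_prices")
  )

  rng3 <- function(sec, a, where) {
    x <- need(sec, a, where)
    c(mean = need(x, "mean", paste0(where, "$", a)),
      low = need(x, "low", paste0(where, "$", a)),
      high = need(x, "high", paste0(where, "$", a)))
  }
  episode_costs <- lapply(ARMS, rng3, sec = raw$episode_costs,
                          where = "episode_costs")
  names(episode_costs) <- ARMS
  event_rates <- lapply(ARMS, rng3, sec = raw$event_rates,
                        where = "event_rates")
  names(event_rates) <- ARMS

  dc <- raw$discounting
  structure(list(
    probabilities = probs,
    principal_events = principal,
    states = states,
    resource_use = resource_use,
    device_prices = device_prices,
    episode_costs = episode_costs,
    event_rates = event_rates,
    discount_rate = need(dc, "discount_rate", "discounting"),
    healthy_qale = need(dc, "healthy_qale", "discounting"),
    life_expectancy = need(dc, "life_expectancy", "discounting"),
    unit_costs = raw$unit_costs
  ), class = "ce_parameters")
}

#' Validate a model-parameter bundle
#'
#' Checks every structural invariant of the parameter set and returns a
#' character vector describing all violations found (empty when the set is
#' valid). Reports rather than raises, so callers can collect a complete
#' list of problems: probabilities in \[0, 1\] summing to one (tolerance
#' 1e-9 for discharge states, 1e-6 for the principal-event distribution,
#' which is stored at 8 printed decimals), non-negative Dirichlet counts and
#' concentrations, non-negative costs and QALEs, Gamma-mean consistency
#' (alpha x beta within 0.5% of the stated lifetime cost), positive resource
#' use with rates in \[0, 1\], ordered episode-cost and event-rate central
#' ranges, and a discount rate in \[0, 1).
#'
#' @param p a `ce_parameters` object (or compatible list).
#' @return character vector of violation descriptions; `character(0)` if
#'   everything holds.
#' @export
validate_parameters <- function(p) {
  v <- character(0)
  add <- function(cond, msg) if (isTRUE(cond)) c(v, msg) else v

  for (a in ARMS) {
    pr <- p$probabilities[[a]]$p
    v <- add(any(pr < 0 | pr > 1),
             paste0(a, ": discharge probabilities outside [0,1]"))
    v <- add(abs(sum(pr) - 1) > 1e-9,
             paste0(a, ": discharge probabilities sum to ",
                    format(sum(pr)), ", not 1"))
    v <- add(any(p$probabilities[[a]]$dirichlet_counts < 0),
             paste0(a, ": negative Dirichlet counts"))
    pe <- p$principal_events[[a]]
    v <- add(any(pe$probability < 0),
             paste0(a, ": negative principal-event probabilities"))
    v <- add(abs(sum(pe$probability) - 1) > 1e-6,
             paste0(a, ": principal-event probabilities sum to ",
                    format(sum(pe$probability)), ", not 1"))
    v <- add(any(pe$concentration < 0),
             paste0(a, ": negative principal-event concentrations"))
  }

  s <- p$states
  v <- add(any(s$lifetime_cost < 0), "negative lifetime cost")
  v <- add(any(s$qale < 0), "negative QALE")
  gm <- s$gamma_alpha * s$gamma_beta
  bad <- abs(gm - s$lifetime_cost) > 0.005 * s$lifetime_cost
  if (any(bad)) {
    v <- c(v, paste0("Gamma mean inconsistent with lifetime cost for: ",
                     paste(s$name[bad], collapse = ", ")))
  }

  ru <- p$resource_use
  v <- add(ru$beds <= 0, "beds must be positive")
  v <- add(any(ru$mean_los <= 0), "mean length of stay must be positive")
  v <- add(ru$cableless_rate < 0 || ru$cableless_rate > 1,
           "cableless rate outside [0,1]")
  v <- add(ru$product_life <= 0, "product life must be positive")
  v <- add(ru$ward_mix_pulmonology < 0 || ru$ward_mix_pulmonology > 1,
           "ward mix outside [0,1]")
  v <- add(ru$occupancy <= 0 || ru$occupancy > 1,
           "occupancy outside (0,1]")

  v <- add(any(unlist(p$device_prices) < 0), "negative device price")

  for (a in ARMS) {
    ec <- p$episode_costs[[a]]
    v <- add(any(ec <= 0), paste0(a, ": episode costs must be positive"))
    v <- add(ec["low"] > ec["mean"] || ec["mean"] > ec["high"],
             paste0(a, ": episode cost range does not bracket its mean"))
    er <- p$event_rates[[a]]
    v <- add(er["mean"] < 0, paste0(a, ": negative event rate"))
    v <- add(er["low"] > er["mean"] || er["mean"] > er["high"],
             paste0(a, ": event rate range does not bracket its mean"))
  }

  v <- add(p$discount_rate < 0 || p$discount_rate >= 1,
           "discount rate outside [0,1)")
  v <- add(p$healthy_qale < 0, "negative healthy-population QALE")
  v <- add(p$life_expectancy <= 0, "life expectancy must be positive")
  v
}

#' Write a model-parameter bundle back to YAML
#'
#' Inverse of [load_parameters()]: the written file re-loads to an
#' identical parameter set (full numeric precision is retained).
#'
#' @param p a `ce_parameters` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(p, path) {
  stopifnot(inherits(p, "ce_parameters"))
  s <- p$states
  raw <- list(
    probabilities = stats::setNames(lapply(ARMS, function(a) list(
      no_event = unname(p$probabilities[[a]]$p["no_event"]),
      event_survive = unname(p$probabilities[[a]]$p["event_survive"]),
      inpatient_death = unname(p$probabilities[[a]]$p["inpatient_death"]),
      dirichlet_counts = p$probabilities[[a]]$dirichlet_counts
    )), ARMS),
    principal_events = c(
      list(categories = rownames(s)[-(1:2)]),
      stats::setNames(lapply(ARMS, function(a) list(
        probability = unname(p$principal_events[[a]]$probability),
        concentration = unname(p$principal_events[[a]]$concentration)
      )), ARMS)
    ),
    lifetime = list(states = lapply(seq_len(nrow(s)), function(i) list(
      name = s$name[i],
      lifetime_cost = s$lifetime_cost[i],
      qale = s$qale[i],
      gamma = c(s$gamma_alpha[i], s$gamma_beta[i]),
      normal = c(s$normal_mean[i], s$normal_sd[i]),
      use_no_event_cost = s$use_no_event_cost[i]
    ))),
    resource_use = list(
      beds = p$resource_use$beds,
      mean_los_intervention = unname(p$resource_use$mean_los["intervention"]),
      mean_los_control = unname(p$resource_use$mean_los["control"]),
      cableless_rate = p$resource_use$cableless_rate,
      product_life = p$resource_use$product_life,
      ward_mix_pulmonology = p$resource_use$ward_mix_pulmonology,
      occupancy = p$resource_use$occupancy
    ),
    device_prices = p$device_prices,
    episode_costs = lapply(p$episode_costs, as.list),
    event_rates = lapply(p$event_rates, as.list),
    discounting = list(
      discount_rate = p$discount_rate,
      healthy_qale = p$healthy_qale,
      life_expectancy = p$life_expectancy
    )
  )
  if (!is.null(p$unit_costs)) raw$unit_costs <- p$unit_costs
  yaml::write_yaml(raw, path, precision = 15)
  invisible(path)
}

#' @export
print.ce_parameters <- function(x, ...) {
  cat("Cost-effectiveness model parameters\n")
  for (a in ARMS) {
    pr <- x$probabilities[[a]]$p
    cat(sprintf("  %-12s p(no event) %.4f  p(event survive) %.4f  p(death) %.4f\n",
                a, pr["no_event"], pr["event_survive"], pr["inpatient_death"]))
  }
  cat(sprintf("  %d lifetime health states; discount rate %.1f%%; life expectancy %.2f y\n",
              nrow(x$states), 100 * x$discount_rate, x$life_expectancy))
  cat(sprintf("  episode cost (GBP): intervention %.2f, control %.2f\n",
              x$episode_costs$intervention["mean"],
              x$episode_costs$control["mean"]))
  invisible(x)
}
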