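DEFAULT_COVARIATES <- c("age", "sex", "ward", "news_admission")

est_formula <- function(response, covariates) {
  stats::as.formula(paste(response, "~",
                          paste(c("arm", covariates), collapse = " + ")))
}

## drop covariates with no variation (they make the design singular)
usable_covariates <- function(cohort, covariates) {
  keep <- vapply(covariates, function(v)
    length(unique(cohort[[v]])) > 1, logical(1))
  if (any(!keep)) {
    warning("dropping zero-variance covariate(s): ",
            paste(covariates[!keep], collapse = ", "), call. = FALSE)
  }
  covariates[keep]
}

## recycled-prediction (counterfactual) standardization: predict every
## patient under each arm and average on the response scale. With no
## covariates this reduces exactly to the raw per-arm means.
recycled_means <- function(fit, cohort) {
  vapply(stats::setNames(ARMS, ARMS), function(a) {
    d <- cohort
    d$arm <- factor(a, levels = ARMS)
    mean(stats::predict(fit, newdata = d, type = "response"))
  }, numeric(1))
}

#' Fit the serious-adverse-event count model
#'
#' Negative-binomial regression (log link, NB2 variance `mu + mu^2/theta`)
#' of the per-patient event count on arm and baseline covariates, with
#' per-arm adjusted mean counts by recycled-prediction standardization:
#' every patient is predicted under each arm counterfactually and the
#' predictions averaged.
#'
#' @param cohort a `ce_cohort` data frame.
#' @param covariates baseline adjustment covariates; zero-variance
#'   covariates are dropped with a warning. An empty vector gives raw
#'   per-arm means.
#' @return object of class `ce_count_fit`: list with the `MASS::glm.nb`
#'   fit (`fit`), `coefficients`, `theta`, and `adjusted_means` (named
#'   per-arm vector).
#' @export
fit_event_count_model <- function(cohort,
                                  covariates = DEFAULT_COVARIATES) {
  if (all(cohort$event_count == 0)) {
    stop("degenerate cohort: all event counts are zero; event rate 0, ",
         "dispersion undefined", call. = FALSE)
  }
  covariates <- usable_covariates(cohort, covariates)
  fit <- tryCatch(
    suppressWarnings(MASS::glm.nb(est_formula("event_count", covariates),
                                  data = cohort)),
    error = function(e) stop("negative-binomial fit failed: ",
                             conditionMessage(e), call. = FALSE))
  structure(list(fit = fit,
                 coefficients = stats::coef(fit),
                 theta = fit$theta,
                 adjusted_means = recycled_means(fit, cohort)),
            class = "ce_count_fit")
}

#' Fit the inpatient episode cost model
#'
#' Gamma-family generalized linear model with log link for patient-level
#' hospital costs, adjusted for arm and baseline covariates; per-arm
#' adjusted mean costs by recycled predictions.
#'
#' @inheritParams fit_event_count_model
#' @return object of class `ce_cost_fit`: list with the `glm` fit,
#'   `coefficients`, and `adjusted_means`.
#' @export
fit_cost_model <- function(cohort, covariates = DEFAULT_COVARIATES) {
  if (any(cohort$episode_cost <= 0)) {
    stop("episode costs must be strictly positive for the gamma model",
         call. = FALSE)
  }
  covariates <- usable_covariates(cohort, covariates)
  fit <- stats::glm(est_formula("episode_cost", covariates),
                    data = cohort, family = stats::Gamma(link = "log"))
  if (!fit$converged) stop("gamma GLM did not converge", call. = FALSE)
  structure(list(fit = fit,
                 coefficients = stats::coef(fit),
                 adjusted_means = recycled_means(fit, cohort)),
            class = "ce_cost_fit")
}

#' Fit the discharge-state model
#'
#' Multinomial-logit fit of the three discharge states (no event /
#' survived a principal event / inpatient death) on arm and baseline
#' covariates, with per-arm state probabilities by recycled predictions.
#' The within-survivor principal-event distribution is estimated per arm
#' as the normalized empirical frequencies among event survivors (empty
#' categories get probability 0 with a warning).
#'
#' @inheritParams fit_event_count_model
#' @return object of class `ce_state_fit`: list with `probabilities`
#'   (per-arm named vectors over no_event/event_survive/inpatient_death),
#'   `principal` (per-arm distributions over the event categories),
#'   and the underlying `nnet::multinom` fit (`fit`, `NULL` when the
#'   outcome is single-category).
#' @export
fit_discharge_state_model <- function(cohort,
                                      covariates = DEFAULT_COVARIATES) {
  state <- ifelse(cohort$died_inpatient, "inpatient_death",
                  ifelse(cohort$principal_event != "none",
                         "event_survive", "no_event"))
  lev <- c("no_event", "event_survive", "inpatient_death")
  state <- factor(state, levels = lev)
  present <- lev[lev %in% unique(as.character(state))]
  if (length(present) == 1) {
    probs <- lapply(stats::setNames(ARMS, ARMS), function(a)
      stats::setNames(as.numeric(lev == present), lev))
    fit <- NULL
  } else {
    covariates <- usable_covariates(cohort, covariates)
    d <- cohort
    d$.state <- droplevels(state)
    fit <- nnet::multinom(est_formula(".state", covariates), data = d,
                          trace = FALSE, maxit = 500)
    probs <- lapply(stats::setNames(ARMS, ARMS), function(a) {
      nd <- d
      nd$arm <- factor(a, levels = ARMS)
      pr <- stats::predict(fit, newdata = nd, type = "probs")
      if (is.null(dim(pr))) pr <- cbind(1 - pr, pr)  # two-level outcome
      colnames(pr) <- levels(d$.state)
      out <- stats::setNames(numeric(length(lev)), lev)
      out[colnames(pr)] <- colMeans(pr)
      out
    })
  }

  principal <- lapply(stats::setNames(ARMS, ARMS), function(a) {
    surv <- cohort$arm == a & !cohort$died_inpatient &
      cohort$principal_event != "none"
    tab <- table(factor(cohort$principal_event[surv],
                        levels = EVENT_LEVELS))
    if (sum(tab) == 0) {
      return(stats::setNames(rep(NA_real_, length(EVENT_LEVELS)),
                             EVENT_LEVELS))
    }
    if (any(tab == 0)) {
      warning("empty principal-event categor(ies) in arm ", a, ": ",
              paste(names(tab)[tab == 0], collapse = ", "),
              call. = FALSE)
    }
    stats::setNames(as.numeric(tab) / sum(tab), EVENT_LEVELS)
  })
  structure(list(probabilities = probs, principal = principal, fit = fit),
            class = "ce_state_fit")
}

#' Non-parametric bootstrap 95% central range
#'
#' Resamples patients with replacement `B` times, evaluates `statistic` on
#' each resample, and returns the 2.5th and 97.5th percentiles of the
#' bootstrap distribution. A resample on which the statistic fails (for
#' example a model that does not converge) is redrawn, up to `max_retry`
#' consecutive failures.
#'
#' @param cohort a `ce_cohort` data frame.
#' @param statistic function taking a resampled cohort and returning a
#'   numeric scalar.
#' @param B number of bootstrap replications (>= 2), default 10000.
#' @param seed integer seed for reproducibility.
#' @param max_retry consecutive failure cap per replication.
#' @return numeric vector `c(low, high)`, with attributes `estimates`
#'   (all `B` bootstrap statistics) and `failures` (number of redrawn
#'   resamples).
#' @export
bootstrap_central_range <- function(cohort, statistic, B = 10000,
                                    seed = NULL, max_retry = 10) {
  stopifnot(B >= 2)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(cohort)
  est <- numeric(B)
  failures <- 0L
  for (b in seq_len(B)) {
    ok <- FALSE
    for (try in seq_len(max_retry)) {
      res <- tryCatch(statistic(cohort[sample.int(n, n, replace = TRUE),
                                       , drop = FALSE]),
                      error = function(e) NULL)
      if (!is.null(res) && is.finite(res)) {
        est[b] <- res
        ok <- TRUE
        break
      }
      failures <- failures + 1L
    }
    if (!ok) {
      stop("bootstrap statistic failed ", max_retry,
           " consecutive times at replication ", b, call. = FALSE)
    }
  }
  structure(unname(stats::quantile(est, c(0.025, 0.975))),
            names = c("low", "high"), estimates = est,
            failures = failures)
}

#' Recover model inputs from a patient-level cohort
#'
#' Umbrella estimation mirroring how the decision model's inputs are
#' derived from patient-level data: adjusted per-arm mean event counts
#' (negative-binomial regression), adjusted per-arm mean episode costs
#' (gamma GLM), discharge-state probabilities and principal-event
#' distributions (multinomial logit plus empirical survivor frequencies),
#' optionally with bootstrap 95% central ranges for the adjusted means.
#'
#' @param cohort a `ce_cohort` data frame.
#' @param covariates baseline adjustment covariates.
#' @param B bootstrap replications for the central ranges (0 skips the
#'   bootstrap; full analyses use 10000).
#' @param seed bootstrap seed.
#' @return object of class `ce_estimates`: list with `events`, `costs`,
#'   `states` (the three fit objects) and, when `B > 0`, `event_range`
#'   and `cost_range` (per-arm low/high matrices).
#' @export
estimate_model_inputs <- function(cohort, covariates = DEFAULT_COVARIATES,
                                  B = 0, seed = NULL) {
  events <- fit_event_count_model(cohort, covariates)
  costs <- fit_cost_model(cohort, covariates)
  states <- fit_discharge_state_model(cohort, covariates)
  out <- list(events = events, costs = costs, states = states)
  if (B > 0) {
    for (what in c("event", "cost")) {
      fitter <- if (what == "event") fit_event_count_model else
        fit_cost_model
      rng <- vapply(stats::setNames(ARMS, ARMS), function(a)
        bootstrap_central_range(cohort, function(d)
          suppressWarnings(fitter(d, covariates))$adjusted_means[[a]],
          B = B, seed = seed), numeric(2))
      out[[paste0(what, "_range")]] <- rng
    }
  }
  structure(out, class = "ce_estimates")
}

#' @export
print.ce_estimates <- function(x, ...) {
  cat("Recovered model inputs\n")
  cat(sprintf("  adjusted events/pt: intervention %.4f, control %.4f\n",
              x$events$adjusted_means["intervention"],
              x$events$adjusted_means["control"]))
  cat(sprintf("  adjusted cost (GBP): intervention %.2f, control %.2f\n",
              x$costs$adjusted_means["intervention"],
              x$costs$adjusted_means["control"]))
  for (a in ARMS) {
    pr <- x$states$probabilities[[a]]
    cat(sprintf("  %-12s p(no event) %.4f  p(event) %.4f  p(death) %.4f\n",
                a, pr["no_event"], pr["event_survive"],
                pr["inpatient_death"]))
  }
  invisible(x)
}
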