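EVENT_LEVELS <- c("acute_myocardial_infarction", "pulmonary_embolism",
                  "acute_pulmonary_oedema", "respiratory_failure",
                  "severe_sepsis", "icu_admission",
                  "cardiopulmonary_arrest")

## discrete pmf of the age distribution: age = round(reflect - X) with
## X ~ Gamma(shape, scale), clamped to [lo, hi]. Left-skewed, matching a
## median of 71 with IQR 59-81 at the default calibration.
age_pmf <- function(shape, scale, reflect = 101, lo = 17, hi = 100) {
  a <- lo:hi
  upper <- stats::pgamma(reflect - a + 0.5, shape, scale = scale)
  lower <- stats::pgamma(reflect - a - 0.5, shape, scale = scale)
  p <- upper - lower
  p[a == hi] <- stats::pgamma(reflect - hi + 0.5, shape, scale = scale)
  p[a == lo] <- 1 - stats::pgamma(reflect - lo - 0.5, shape, scale = scale)
  stats::setNames(p / sum(p), a)
}

## truncated, discretized negative binomial for the admission NEWS score
news_pmf <- function(mu, size, max_score = 20) {
  p <- stats::dnbinom(0:max_score, mu = mu, size = size)
  stats::setNames(p / sum(p), 0:max_score)
}

## E[exp(b * X)] for a discrete pmf (names are the support)
pmf_mgf <- function(pmf, b) {
  sum(pmf * exp(b * as.numeric(names(pmf))))
}

## joint covariate grid (independent covariates) with cell weights and the
## covariate part of a log-link linear predictor; used for exact intercept
## and dispersion calibration by enumeration.
covariate_grid <- function(cfg) {
  g <- expand.grid(age = as.numeric(names(cfg$age_pmf)),
                   news = as.numeric(names(cfg$news_pmf)),
                   female = c(0, 1), pulmonology = c(0, 1))
  w <- cfg$age_pmf[as.character(g$age)] *
    cfg$news_pmf[as.character(g$news)] *
    ifelse(g$female == 1, cfg$p_female, 1 - cfg$p_female) *
    ifelse(g$pulmonology == 1, cfg$p_pulmonology, 1 - cfg$p_pulmonology)
  g$weight <- as.numeric(w)
  g
}

lin_pred <- function(coef, age, female, pulmonology, news) {
  coef[["age"]] * age + coef[["female"]] * female +
    coef[["pulmonology"]] * pulmonology + coef[["news"]] * news
}

## intercept such that the marginal mean of exp(intercept + eta) hits the
## target; exact because the covariates are independent and discrete.
calibrate_intercept <- function(target_mean, coef, cfg) {
  if (target_mean == 0) return(-Inf)
  log_mgf <- log(pmf_mgf(cfg$age_pmf, coef[["age"]])) +
    log(pmf_mgf(cfg$news_pmf, coef[["news"]])) +
    log((1 - cfg$p_female) + cfg$p_female * exp(coef[["female"]])) +
    log((1 - cfg$p_pulmonology) +
          cfg$p_pulmonology * exp(coef[["pulmonology"]]))
  log(target_mean) - log_mgf
}

## negative-binomial size such that the marginal P(count = 0) over the
## covariate grid equals the target no-event probability
calibrate_size <- function(intercept, coef, cfg, target_p0) {
  grid <- covariate_grid(cfg)
  mu <- exp(intercept + lin_pred(coef, grid$age, grid$female,
                                 grid$pulmonology, grid$news))
  p0 <- function(size) {
    sum(grid$weight * (size / (size + mu))^size) - target_p0
  }
  lo <- 1e-4
  if (p0(lo) < 0) stop("no-event probability target unattainable",
                       call. = FALSE)
  stats::uniroot(p0, c(lo, 1e3), tol = 1e-10)$root
}

#' Configuration of the synthetic patient-level cohort generator
#'
#' Builds a fully calibrated generator configuration emulating the
#' statistical structure the model's estimation stage assumes: a
#' left-skewed age distribution (median 71, IQR 59-81, range 17-100), 52%
#' female, 56% admitted to the pulmonology ward, admission NEWS from a
#' truncated discretized negative binomial (mean 3.15, sd 2.82), serious
#' adverse event counts from a negative-binomial log-link regression on
#' arm, age, sex, ward and NEWS, discharge states from the per-arm
#' multinomial of the parameter bundle, principal events from the per-arm
#' event distributions, gamma-distributed episode costs with a log-link
#' covariate model, and gamma-distributed ward length of stay.
#'
#' Per-arm regression intercepts are calibrated exactly (by enumeration
#' over the discrete covariate grid) so the marginal mean event counts and
#' episode costs equal the targets in `params`; the per-arm
#' negative-binomial dispersion is calibrated so the probability of a
#' zero count equals the arm's no-event probability, which couples the
#' count model to the discharge-state multinomial (a patient has an event
#' or dies in hospital if and only if the event count is positive).
#'
#' @param params a `ce_parameters` object supplying the per-arm targets
#'   (discharge-state probabilities, principal-event distributions, mean
#'   event counts, mean episode costs, mean lengths of stay).
#' @param n total cohort size, default 3787.
#' @param p_intervention probability a patient is in the intervention arm.
#' @param event_coef,cost_coef named log-link covariate coefficients
#'   (`age`, `female`, `pulmonology`, `news`) of the count and cost models.
#' @param cost_shape gamma shape of patient-level episode costs (shape 0.5
#'   gives the heavy right skew typical of hospital costs and reproduces
#'   central ranges of the published width at this sample size).
#' @param los_shape gamma shape of ward length of stay (1.2 puts the
#'   median near 6 days for a mean of 8.6-8.9).
#' @param icu_mean mean ICU days for patients whose principal event is an
#'   emergency ICU admission.
#' @param age_shape,age_scale,age_reflect gamma parameters of the
#'   reflected age distribution (`age = round(age_reflect - X)`).
#' @param p_female,p_pulmonology covariate proportions.
#' @param news_mu,news_size,news_max NEWS distribution parameters.
#' @param seed default seed used by [generate_cohort()].
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(params = load_parameters(), n = 3787,
                          p_intervention = 0.5,
                          event_coef = c(age = 0.010, female = -0.10,
                                         pulmonology = 0.10, news = 0.12),
                          cost_coef = c(age = 0.002, female = 0,
                                        pulmonology = 0.05, news = 0.03),
                          cost_shape = 0.5, los_shape = 1.2, icu_mean = 3,
                          age_shape = 3.5991, age_scale = 9.1691,
                          age_reflect = 101,
                          p_female = 0.52, p_pulmonology = 0.56,
                          news_mu = 3.15, news_size = 2.066,
                          news_max = 20, seed = NULL) {
  stopifnot(n >= 1, p_intervention >= 0, p_intervention <= 1,
            p_female >= 0, p_female <= 1,
            p_pulmonology >= 0, p_pulmonology <= 1,
            cost_shape > 0, los_shape > 0)
  cfg <- list(
    n = n, p_intervention = p_intervention,
    age_pmf = age_pmf(age_shape, age_scale, age_reflect),
    news_pmf = news_pmf(news_mu, news_size, news_max),
    p_female = p_female, p_pulmonology = p_pulmonology,
    event_coef = event_coef, cost_coef = cost_coef,
    cost_shape = cost_shape, los_shape = los_shape, icu_mean = icu_mean,
    seed = seed
  )
  cfg$event_mean <- vapply(ARMS, function(a)
    unname(params$event_rates[[a]]["mean"]), numeric(1))
  cfg$cost_mean <- vapply(ARMS, function(a)
    unname(params$episode_costs[[a]]["mean"]), numeric(1))
  cfg$los_mean <- params$resource_use$mean_los
  cfg$discharge <- lapply(params$probabilities, `[[`, "p")
  cfg$principal <- lapply(params$principal_events, `[[`, "probability")

  cfg$event_intercept <- vapply(ARMS, function(a)
    calibrate_intercept(cfg$event_mean[[a]], event_coef, cfg), numeric(1))
  cfg$cost_intercept <- vapply(ARMS, function(a)
    calibrate_intercept(cfg$cost_mean[[a]], cost_coef, cfg), numeric(1))
  cfg$event_size <- vapply(ARMS, function(a) {
    if (!is.finite(cfg$event_intercept[[a]])) return(NA_real_)
    calibrate_size(cfg$event_intercept[[a]], event_coef, cfg,
                   unname(cfg$discharge[[a]]["no_event"]))
  }, numeric(1))
  structure(cfg, class = "cohort_config")
}

#' Generate a synthetic patient-level cohort
#'
#' Draws a reproducible cohort of patient records from a
#' [cohort_config()]. Record-level structure: `event_count > 0` if and
#' only if the patient either survives a principal serious adverse event
#' or dies in hospital; patients with multiple events are represented by
#' their principal (worst) event category only; deaths carry
#' `principal_event = "none"` with `died_inpatient = TRUE`.
#'
#' @param cfg a [cohort_config()].
#' @param seed integer seed (defaults to `cfg$seed`); identical seed and
#'   configuration give a byte-identical cohort.
#' @return a `data.frame` of class `ce_cohort` with columns `patient_id`,
#'   `arm`, `age`, `sex`, `ward`, `news_admission`, `event_count`,
#'   `principal_event`, `died_inpatient`, `los_ward`, `icu_days`,
#'   `episode_cost`.
#' @export
#' @examples
#' cfg <- cohort_config(load_parameters(), n = 500)
#' coh <- generate_cohort(cfg, seed = 1)
#' summarize_cohort(coh)
generate_cohort <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- cfg$n
  arm <- ifelse(stats::runif(n) < cfg$p_intervention,
                "intervention", "control")
  age <- as.numeric(sample(names(cfg$age_pmf), n, replace = TRUE,
                           prob = cfg$age_pmf))
  sex <- ifelse(stats::runif(n) < cfg$p_female, "female", "male")
  ward <- ifelse(stats::runif(n) < cfg$p_pulmonology,
                 "pulmonology", "gastroenterology")
  news <- as.numeric(sample(names(cfg$news_pmf), n, replace = TRUE,
                            prob = cfg$news_pmf))
  female <- as.numeric(sex == "female")
  pulmo <- as.numeric(ward == "pulmonology")

  idx <- match(arm, ARMS)
  eta <- cfg$event_intercept[idx] +
    lin_pred(cfg$event_coef, age, female, pulmo, news)
  mu <- exp(eta)
  count <- integer(n)
  pos_rate <- mu > 0
  if (any(pos_rate)) {
    count[pos_rate] <- stats::rnbinom(sum(pos_rate),
                                      mu = mu[pos_rate],
                                      size = cfg$event_size[idx[pos_rate]])
  }

  principal <- rep("none", n)
  died <- rep(FALSE, n)
  for (a in ARMS) {
    sel <- which(arm == a & count > 0)
    if (!length(sel)) next
    p <- cfg$discharge[[a]]
    q <- c(unname(p["event_survive"]) * cfg$principal[[a]],
           death = unname(p["inpatient_death"]))
    q <- q / sum(q)
    draw <- sample(names(q), length(sel), replace = TRUE, prob = q)
    died[sel] <- draw == "death"
    principal[sel] <- ifelse(draw == "death", "none", draw)
  }

  cost_mu <- exp(cfg$cost_intercept[idx] +
                   lin_pred(cfg$cost_coef, age, female, pulmo, news))
  episode_cost <- stats::rgamma(n, shape = cfg$cost_shape,
                                scale = cost_mu / cfg$cost_shape)
  los <- stats::rgamma(n, shape = cfg$los_shape,
                       scale = cfg$los_mean[idx] / cfg$los_shape)
  icu <- ifelse(principal == "icu_admission",
                stats::rgamma(n, shape = 1, scale = cfg$icu_mean), 0)

  structure(data.frame(
    patient_id = seq_len(n),
    arm = factor(arm, levels = ARMS),
    age = age,
    sex = factor(sex, levels = c("male", "female")),
    ward = factor(ward, levels = c("gastroenterology", "pulmonology")),
    news_admission = news,
    event_count = count,
    principal_event = factor(principal, levels = c("none", EVENT_LEVELS)),
    died_inpatient = died,
    los_ward = los,
    icu_days = icu,
    episode_cost = episode_cost
  ), class = c("ce_cohort", "data.frame"))
}

#' Summarize a patient-level cohort
#'
#' Marginal descriptive statistics: median age with IQR, proportion
#' female, proportion on the pulmonology ward, NEWS mean and sd, and
#' per-arm sample size, mean event count, proportions with no event and
#' with inpatient death, mean length of stay and mean episode cost.
#'
#' @param cohort a `ce_cohort` data frame.
#' @return object of class `cohort_summary` (a list).
#' @export
summarize_cohort <- function(cohort) {
  if (!nrow(cohort)) stop("empty cohort", call. = FALSE)
  per_arm <- lapply(split(cohort, cohort$arm), function(d) {
    if (!nrow(d)) return(NULL)
    list(n = nrow(d),
         mean_events = mean(d$event_count),
         p_no_event = mean(d$event_count == 0),
         p_death = mean(d$died_inpatient),
         mean_los = mean(d$los_ward),
         mean_cost = mean(d$episode_cost))
  })
  structure(list(
    n = nrow(cohort),
    age_median = stats::median(cohort$age),
    age_iqr = unname(stats::quantile(cohort$age, c(0.25, 0.75))),
    p_female = mean(cohort$sex == "female"),
    p_pulmonology = mean(cohort$ward == "pulmonology"),
    news_mean = mean(cohort$news_admission),
    news_sd = stats::sd(cohort$news_admission),
    arms = per_arm
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort of %d patients\n", x$n))
  cat(sprintf("  age median %g (IQR %g-%g); %.1f%% female; %.1f%% pulmonology\n",
              x$age_median, x$age_iqr[1], x$age_iqr[2],
              100 * x$p_female, 100 * x$p_pulmonology))
  cat(sprintf("  NEWS on admission: mean %.2f (sd %.2f)\n",
              x$news_mean, x$news_sd))
  for (a in names(x$arms)) {
    s <- x$arms[[a]]
    if (is.null(s)) next
    cat(sprintf("  %-12s n=%d  events/pt %.4f  P(no event) %.4f  P(death) %.4f  LOS %.2f  cost %.2f\n",
                a, s$n, s$mean_events, s$p_no_event, s$p_death,
                s$mean_los, s$mean_cost))
  }
  invisible(x)
}

#' Write / read a cohort as CSV
#'
#' Plain-CSV persistence for cohort tables; `read_cohort()` restores the
#' column types of [generate_cohort()].
#'
#' @param cohort a `ce_cohort` data frame.
#' @param path CSV file path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()`
#'   returns a `ce_cohort` data frame.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$arm <- factor(d$arm, levels = ARMS)
  d$sex <- factor(d$sex, levels = c("male", "female"))
  d$ward <- factor(d$ward, levels = c("gastroenterology", "pulmonology"))
  d$principal_event <- factor(d$principal_event,
                              levels = c("none", EVENT_LEVELS))
  d$died_inpatient <- as.logical(d$died_inpatient)
  class(d) <- c("ce_cohort", "data.frame")
  d
}
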