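#' Probabilistic sensitivity analysis configuration
#'
#' @param n_draws number of Monte-Carlo parameter draws, default 10000.
#' @param seed integer seed; `NULL` leaves the RNG state untouched.
#' @param sd_fraction assumed standard deviation of each lifetime cost and
#'   QALE as a fraction of its mean point estimate, default 0.2 (scenario
#'   analyses use 0.1 and 0.4). Gamma shapes are `1/sd_fraction^2` (0.2
#'   gives the published alpha = 25) and Normal sds are
#'   `sd_fraction * mean`.
#' @param lambda_grid ascending willingness-to-pay grid for the CEAC, GBP
#'   per QALY, default 0 to 50000 in steps of 1000.
#' @param compound if `TRUE`, discharge-state probabilities are drawn by
#'   compound Dirichlet-multinomial resampling (a Dirichlet draw followed by
#'   a multinomial of the original sample size, renormalized); the default
#'   samples the Dirichlet probability vector directly.
#' @param degenerate_tol principal-event concentration vectors whose total
#'   falls below this are not sampled; the point estimates are used.
#' @return object of class `psa_config`.
#' @export
psa_config <- function(n_draws = 10000, seed = NULL, sd_fraction = 0.2,
                       lambda_grid = seq(0, 50000, by = 1000),
                       compound = FALSE, degenerate_tol = 1e-6) {
  stopifnot(n_draws >= 1, sd_fraction >= 0, !is.unsorted(lambda_grid))
  structure(list(n_draws = n_draws, seed = seed,
                 sd_fraction = sd_fraction, lambda_grid = lambda_grid,
                 compound = compound, degenerate_tol = degenerate_tol),
            class = "psa_config")
}

## n draws from Dirichlet(alpha) as an n x k matrix. Gamma variates with
## very small shapes underflow to zero harmlessly; an all-zero row (only
## possible when every alpha is tiny) falls back to alpha/sum(alpha).
rdirichlet_mat <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), n, k)
  tot <- rowSums(x)
  bad <- tot == 0
  if (any(bad)) {
    x[bad, ] <- matrix(rep(alpha / sum(alpha), each = sum(bad)),
                       sum(bad), k)
    tot[bad] <- 1
  }
  x / tot
}

## Normal truncated at zero by resampling negatives
rnorm_pos <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  while (any(neg <- x < 0)) x[neg] <- stats::rnorm(sum(neg), mean, sd)
  x
}

## gamma draws moment-matched to a mean and sd
rgamma_ms <- function(n, mean, sd) {
  shape <- (mean / sd)^2
  stats::rgamma(n, shape = shape, scale = mean / shape)
}

## sample every uncertain parameter, n draws at once. One draw per input
## row of the parameter table: health-state costs/QALEs are shared between
## arms (same states); discharge-state and principal-event distributions
## and episode costs are arm-specific. Returns a list of matrices.
psa_sample <- function(params, cfg, n = cfg$n_draws) {
  f <- cfg$sd_fraction
  st <- params$states
  ns <- nrow(st)
  if (f == 0) {
    state_cost <- matrix(st$lifetime_cost, n, ns, byrow = TRUE)
    state_qale <- matrix(st$qale, n, ns, byrow = TRUE)
  } else {
    shape <- 1 / f^2
    state_cost <- sapply(st$lifetime_cost, function(m)
      stats::rgamma(n, shape = shape, scale = m / shape))
    state_qale <- sapply(st$qale, function(m) rnorm_pos(n, m, f * m))
    if (n == 1) {
      state_cost <- matrix(state_cost, 1)
      state_qale <- matrix(state_qale, 1)
    }
  }
  colnames(state_cost) <- colnames(state_qale) <- st$name

  draw_probs <- function(arm) {
    counts <- params$probabilities[[arm]]$dirichlet_counts
    if (f == 0) {
      # degenerate limit: the whole draw collapses to the point estimates
      pr <- matrix(params$probabilities[[arm]]$p, n, 3, byrow = TRUE)
      colnames(pr) <- c("no_event", "event_survive", "inpatient_death")
      return(pr)
    }
    pr <- rdirichlet_mat(n, counts)
    if (cfg$compound) {
      size <- round(sum(counts))
      cts <- t(apply(pr, 1, function(p) stats::rmultinom(1, size, p)))
      pr <- cts / size
    }
    colnames(pr) <- c("no_event", "event_survive", "inpatient_death")
    pr
  }
  draw_events <- function(arm) {
    conc <- params$principal_events[[arm]]$concentration
    if (sum(conc) < cfg$degenerate_tol || f == 0) {
      m <- matrix(params$principal_events[[arm]]$probability, n,
                  length(conc), byrow = TRUE)
    } else {
      m <- rdirichlet_mat(n, conc)
    }
    colnames(m) <- names(params$principal_events[[arm]]$probability)
    m
  }
  draw_episode <- function(arm) {
    ec <- params$episode_costs[[arm]]
    if (f == 0) return(rep(unname(ec["mean"]), n))
    sd <- unname(ec["high"] - ec["low"]) / 3.92
    rgamma_ms(n, unname(ec["mean"]), sd)
  }

  list(
    state_cost = state_cost, state_qale = state_qale,
    probs = lapply(stats::setNames(ARMS, ARMS), draw_probs),
    events = lapply(stats::setNames(ARMS, ARMS), draw_events),
    episode = lapply(stats::setNames(ARMS, ARMS), draw_episode)
  )
}

## vectorized decision-tree evaluation of sampled parameters
psa_evaluate <- function(smp, params) {
  mix <- params$resource_use$ward_mix_pulmonology
  ne_cost <- (1 - mix) * smp$state_cost[, "ward1_gastroenterology"] +
    mix * smp$state_cost[, "ward2_respiratory"]
  ne_qale <- (1 - mix) * smp$state_qale[, "ward1_gastroenterology"] +
    mix * smp$state_qale[, "ward2_respiratory"]
  cats <- colnames(smp$events$intervention)
  ev_cost <- smp$state_cost[, cats, drop = FALSE]
  cf <- params$states[cats, "use_no_event_cost"]
  ev_cost[, cf] <- ne_cost
  ev_qale <- smp$state_qale[, cats, drop = FALSE]

  per_arm <- function(arm) {
    pr <- smp$probs[[arm]]
    lt_cost <- pr[, "no_event"] * ne_cost +
      pr[, "event_survive"] * rowSums(smp$events[[arm]] * ev_cost)
    qale <- pr[, "no_event"] * ne_qale +
      pr[, "event_survive"] * rowSums(smp$events[[arm]] * ev_qale)
    list(total = smp$episode[[arm]] + lt_cost, qale = qale)
  }
  int <- per_arm("intervention")
  ctl <- per_arm("control")
  data.frame(delta_cost = int$total - ctl$total,
             delta_qaly = int$qale - ctl$qale)
}

#' Draw one probabilistic realization of the parameter set
#'
#' Samples a single realization of all uncertain model inputs from their
#' assigned distributions — discharge-state probabilities from a Dirichlet
#' over the effective counts, principal-event distributions from a
#' Dirichlet over the published concentrations (falling back to the point
#' estimates when the concentration total is degenerate), lifetime costs
#' from Gamma and QALEs from zero-truncated Normal specifications with sd
#' equal to `sd_fraction` of the mean, and episode costs from a Gamma
#' moment-matched to the published mean and 95% central range — and
#' substitutes them into a copy of the parameter set. With
#' `sd_fraction = 0` the point estimates are returned unchanged.
#'
#' @param params a `ce_parameters` object.
#' @param cfg a [psa_config()].
#' @return a `ce_parameters` realization (not re-validated: sampled
#'   Gamma/Normal specs retain the base-case descriptions).
#' @export
sample_parameter_draw <- function(params, cfg = psa_config()) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  smp <- psa_sample(params, cfg, n = 1)
  out <- params
  out$states$lifetime_cost <- as.numeric(smp$state_cost[1, ])
  out$states$qale <- as.numeric(smp$state_qale[1, ])
  for (a in ARMS) {
    out$probabilities[[a]]$p <- smp$probs[[a]][1, ]
    out$principal_events[[a]]$probability[] <- smp$events[[a]][1, ]
    out$episode_costs[[a]]["mean"] <- smp$episode[[a]][1]
  }
  out
}

#' Run the probabilistic sensitivity analysis
#'
#' Monte-Carlo propagation of parameter uncertainty through the lifetime
#' cost-utility comparison: each draw samples every uncertain input (see
#' [sample_parameter_draw()]) and re-evaluates the decision tree, giving a
#' joint sample of incremental cost and incremental QALYs. Summaries
#' include means, 95% central ranges, cost-effectiveness plane quadrant
#' proportions, and the cost-effectiveness acceptability curve over the
#' configured willingness-to-pay grid.
#'
#' @param params a `ce_parameters` object.
#' @param cfg a [psa_config()].
#' @return object of class `ce_psa`: list with `draws` (data frame of
#'   `delta_cost`, `delta_qaly`), `summary` (means and 2.5/97.5
#'   percentiles), `quadrants` (named proportions), `ceac` (data frame
#'   `lambda`, `probability`), `config`.
#' @seealso [ceac()], [plot.ce_psa()], [simulate.ce_model()]
#' @export
run_psa <- function(params, cfg = psa_config()) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  smp <- psa_sample(params, cfg)
  draws <- psa_evaluate(smp, params)
  q <- c(
    NE = mean(draws$delta_qaly >= 0 & draws$delta_cost >= 0),
    SE = mean(draws$delta_qaly >= 0 & draws$delta_cost < 0),
    SW = mean(draws$delta_qaly < 0 & draws$delta_cost < 0),
    NW = mean(draws$delta_qaly < 0 & draws$delta_cost >= 0)
  )
  summ <- data.frame(
    quantity = c("delta_cost", "delta_qaly"),
    mean = c(mean(draws$delta_cost), mean(draws$delta_qaly)),
    low = c(stats::quantile(draws$delta_cost, 0.025),
            stats::quantile(draws$delta_qaly, 0.025)),
    high = c(stats::quantile(draws$delta_cost, 0.975),
             stats::quantile(draws$delta_qaly, 0.975)),
    row.names = NULL
  )
  res <- structure(list(draws = draws, summary = summ, quadrants = q,
                        ceac = NULL, config = cfg), class = "ce_psa")
  res$ceac <- ceac(res, cfg$lambda_grid)
  res
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of PSA draws with
#' positive net monetary benefit (`lambda * delta_qaly - delta_cost > 0`).
#' At `lambda = 0` this is the probability of cost saving; as `lambda`
#' grows it approaches the probability of a QALY gain.
#'
#' @param result a `ce_psa` object.
#' @param lambda_grid willingness-to-pay values (GBP per QALY).
#' @return data frame with columns `lambda` and `probability`.
#' @export
ceac <- function(result, lambda_grid = result$config$lambda_grid) {
  stopifnot(nrow(result$draws) > 0)
  pr <- vapply(lambda_grid, function(l)
    mean(l * result$draws$delta_qaly - result$draws$delta_cost > 0),
    numeric(1))
  data.frame(lambda = lambda_grid, probability = pr)
}

#' @export
print.ce_psa <- function(x, ...) {
  n <- nrow(x$draws)
  cat(sprintf("Probabilistic sensitivity analysis: %d draws\n", n))
  if (n == 0) {
    cat("  (zero draws; nothing to summarize)\n")
    return(invisible(x))
  }
  s <- x$summary
  cat(sprintf("  mean delta cost GBP %.2f (95%% CR %.2f to %.2f)\n",
              s$mean[1], s$low[1], s$high[1]))
  cat(sprintf("  mean delta QALY %.4f (95%% CR %.4f to %.4f)\n",
              s$mean[2], s$low[2], s$high[2]))
  cat(sprintf("  quadrants: NE %.1f%%  SE %.1f%%  SW %.1f%%  NW %.1f%%\n",
              100 * x$quadrants["NE"], 100 * x$quadrants["SE"],
              100 * x$quadrants["SW"], 100 * x$quadrants["NW"]))
  for (l in c(20000, 30000)) {
    if (any(x$ceac$lambda == l)) {
      cat(sprintf("  P(cost-effective at GBP %d/QALY) = %.1f%%\n", l,
                  100 * x$ceac$probability[x$ceac$lambda == l]))
    }
  }
  invisible(x)
}

#' Plot PSA results
#'
#' `type = "plane"` draws the cost-effectiveness plane (incremental QALYs
#' against incremental cost, one point per draw); `type = "ceac"` draws the
#' cost-effectiveness acceptability curve.
#'
#' @param x a `ce_psa` object.
#' @param type `"plane"` or `"ceac"`.
#' @param ... further arguments passed to the base plotting functions.
#' @return `x`, invisibly.
#' @export
plot.ce_psa <- function(x, type = c("plane", "ceac"), ...) {
  type <- match.arg(type)
  if (type == "plane") {
    graphics::plot(x$draws$delta_qaly, x$draws$delta_cost,
                   pch = 16, cex = 0.3, col = "#00000040",
                   xlab = "Incremental QALYs",
                   ylab = "Incremental cost (GBP)",
                   main = "Cost-effectiveness plane", ...)
    graphics::abline(h = 0, v = 0, col = "grey40")
  } else {
    graphics::plot(x$ceac$lambda, x$ceac$probability, type = "l",
                   ylim = c(0, 1),
                   xlab = "Willingness to pay (GBP per QALY)",
                   ylab = "P(cost-effective)",
                   main = "Cost-effectiveness acceptability curve", ...)
    graphics::abline(h = c(0, 1), col = "grey80", lty = 3)
  }
  invisible(x)
}

#' Simulate method for the decision model: run the PSA
#'
#' @param object a [ce_model()] fit.
#' @param nsim number of parameter draws.
#' @param seed integer seed.
#' @param ... further arguments passed to [psa_config()].
#' @return a `ce_psa` object.
#' @export
simulate.ce_model <- function(object, nsim = 10000, seed = NULL, ...) {
  run_psa(object$parameters, psa_config(n_draws = nsim, seed = seed, ...))
}
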