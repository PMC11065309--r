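test_that("one-way sensitivity is the identity at the base-case value", {
  m <- ce_model(base_params)
  tab <- one_way_sensitivity(base_params, "cableless_rate", 0.123)
  expect_equal(tab$delta_cost, m$lifetime$delta_cost, tolerance = 1e-9)
  expect_equal(tab$delta_qaly, m$lifetime$delta_effect, tolerance = 1e-12)
  expect_equal(tab$delta_cost_short, m$short_term$delta_cost,
               tolerance = 1e-9)
  expect_error(one_way_sensitivity(base_params, "beds", 54), "unknown")
})

test_that("the comparison stays dominant across product lives 5/10/15", {
  tab <- one_way_sensitivity(base_params, "product_life", c(5, 10, 15))
  expect_identical(tab$dominance, rep("dominant", 3))
  # longer product life can only cheapen the intervention
  expect_true(all(diff(tab$delta_cost) < 0))
})

test_that("cableless-rate sensitivity crosses cost neutrality near 0.23", {
  tab <- one_way_sensitivity(base_params, "cableless_rate",
                             c(0, 0.123, 0.23, 0.5, 1))
  # short-term incremental cost is affine in the rate with the sensor
  # price as slope
  slope <- diff(tab$delta_cost_short) / diff(tab$value)
  expect_equal(slope, rep(base_params$device_prices$sensor_unit, 4),
               tolerance = 1e-9)
  expect_lt(abs(tab$delta_cost_short[tab$value == 0.23]), 1.5)

  boundary <- cableless_dominance_boundary(base_params, tol = 0.001)
  analytic <- 0.123 + 12.17 / base_params$device_prices$sensor_unit
  expect_equal(boundary, analytic, tolerance = 0.001 / analytic)
})

test_that("the dominance boundary reports when no crossing exists", {
  p <- base_params
  p$episode_costs$intervention["mean"] <-
    p$episode_costs$control["mean"] - 500  # saving too large to erode
  expect_warning(b <- cableless_dominance_boundary(p), "does not change sign")
  expect_true(is.na(b))
})

test_that("league table ranks strategies by net monetary benefit", {
  base <- subgroup_spec("base case", base_params)
  tab <- run_subgroups(list(base, subgroup_spec("copy", base_params)))
  expect_s3_class(tab, "ce_league")
  # NMB identity holds row-wise and ties share a rank
  expect_equal(tab$nmb, 20000 * tab$delta_qaly - tab$delta_cost)
  expect_equal(tab$nhb, tab$nmb / 20000)
  expect_identical(tab$rank, c(1L, 1L))
  # arithmetic from the published table: 20000 x 0.0287 + 55.35 ~ 629
  expect_equal(tab$nmb[1], 629, tolerance = 0.01)

  # a cheaper-but-less-effective stratum is SW, not dominant
  p_sw <- base_params
  p_sw$probabilities$intervention$p <-
    c(no_event = 0.9300, event_survive = 0.0106, inpatient_death = 0.0594)
  p_sw$episode_costs$intervention <- c(mean = 1800, low = 1700,
                                       high = 1900)
  sw <- run_subgroups(list(subgroup_spec("sw stratum", p_sw)))
  expect_identical(sw$quadrant, "SW")
  expect_identical(sw$dominance, "non-dominated")

  expect_error(run_subgroups(list(base_params)), "subgroup_spec")
  bad <- base_params
  bad$resource_use$beds <- -1
  expect_error(subgroup_spec("bad", bad), "invalid")
})

test_that("stratified parameter sets pool back to the whole-cohort result", {
  coh <- generate_cohort(cohort_config(base_params, n = 30000), seed = 91)
  specs <- suppressWarnings(
    subgroup_parameters(coh, base_params, "age_band"))
  expect_named(specs, c("17-74", "75+"))
  tab <- suppressWarnings(run_subgroups(specs))

  whole <- suppressWarnings(
    subgroup_parameters(coh, base_params, "ward"))  # any full partition
  # pooled check against direct whole-cohort estimation
  est <- suppressWarnings(
    estimate_model_inputs(coh, covariates = character(0)))
  p_all <- base_params
  for (a in c("intervention", "control")) {
    p_all$probabilities[[a]]$p <- est$states$probabilities[[a]]
    m <- est$costs$adjusted_means[[a]]
    p_all$episode_costs[[a]] <- c(mean = m, low = m * 0.9, high = m * 1.1)
  }
  m_all <- ce_model(p_all)
  w <- vapply(names(specs), function(lv) {
    if (lv == "75+") mean(coh$age >= 75) else mean(coh$age < 75)
  }, numeric(1))
  pooled_dq <- sum(w * tab$delta_qaly[match(paste0("age_band: ",
                                                   names(specs)),
                                            tab$strategy)])
  # strata recombine to the whole-cohort incremental QALYs within
  # estimation error (the lifetime expectation is linear in the
  # estimated probabilities)
  expect_equal(pooled_dq, m_all$lifetime$delta_effect, tolerance = 0.35)
})

test_that("CEAC at the threshold is stable across assumed sd fractions", {
  tab <- scenario_sd(base_params, fractions = c(0.1, 0.2, 0.4),
                     cfg = psa_config(n_draws = 3000, seed = 55))
  expect_equal(tab$sd_fraction, c(0.1, 0.2, 0.4))
  expect_true(all(tab$ceac_at_lambda > 0.70 & tab$ceac_at_lambda < 0.90))
  # wider assumed uncertainty widens the incremental-cost central range;
  # because state draws are shared between arms the effect is second
  # order, so only the extreme fractions are separable at this n
  width <- tab$high_delta_cost - tab$low_delta_cost
  expect_gt(width[3], width[1])
  # direction matches the published scenario spread: smaller sd, higher
  # probability of cost-effectiveness
  expect_gt(tab$ceac_at_lambda[1], tab$ceac_at_lambda[3])

  # degenerate limit: the CEAC becomes the 0/1 step of the deterministic
  # net monetary benefit
  step <- scenario_sd(base_params, fractions = 0,
                      cfg = psa_config(n_draws = 50, seed = 56))
  m <- ce_model(base_params)
  expect_identical(step$ceac_at_lambda,
                   as.numeric(m$lifetime$nmb > 0))
})
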