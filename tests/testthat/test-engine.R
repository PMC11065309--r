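test_that("no-event outcome is the ward-mix convex combination", {
  st <- base_params$states
  ne <- no_event_outcome(st, 0.56)
  expect_equal(unname(ne["qale"]), 0.44 * 7.4965 + 0.56 * 7.9866)
  expect_equal(unname(ne["lifetime_cost"]), 0.44 * 28694 + 0.56 * 10555)
  expect_equal(unname(no_event_outcome(st, 0)["qale"]), 7.4965)
  expect_equal(unname(no_event_outcome(st, 1)["lifetime_cost"]), 10555)
  expect_error(no_event_outcome(st, 1.3), "ward mix")
  expect_error(no_event_outcome(st[-1, ], 0.5), "missing ward state")
})

test_that("expected lifetime QALE and cost reproduce the published base case", {
  p <- base_params
  mix <- p$resource_use$ward_mix_pulmonology
  qi <- expected_lifetime_qale(p$probabilities$intervention$p,
                               p$principal_events$intervention$probability,
                               p$states, mix)
  qc <- expected_lifetime_qale(p$probabilities$control$p,
                               p$principal_events$control$probability,
                               p$states, mix)
  expect_equal(qi, 7.3702, tolerance = 0.001 / 7.3702)
  expect_equal(qc, 7.3415, tolerance = 0.001 / 7.3415)
  expect_equal(qi - qc, 0.0287, tolerance = 0.0005 / 0.0287)

  ci <- expected_lifetime_cost(p$probabilities$intervention$p,
                               p$principal_events$intervention$probability,
                               p$states, mix)
  cc <- expected_lifetime_cost(p$probabilities$control$p,
                               p$principal_events$control$probability,
                               p$states, mix)
  expect_equal(ci, 17644.52, tolerance = 0.001)
  expect_equal(cc, 17687.70, tolerance = 0.001)
})

test_that("degenerate discharge distributions hit the tree's leaves", {
  p <- base_params
  pe <- p$principal_events$intervention$probability
  ne <- no_event_outcome(p$states, 0.56)
  all_no_event <- c(no_event = 1, event_survive = 0, inpatient_death = 0)
  expect_equal(expected_lifetime_qale(all_no_event, pe, p$states, 0.56),
               unname(ne["qale"]))
  all_death <- c(no_event = 0, event_survive = 0, inpatient_death = 1)
  expect_equal(expected_lifetime_qale(all_death, pe, p$states, 0.56), 0)
  expect_equal(expected_lifetime_cost(all_death, pe, p$states, 0.56), 0)
  bad <- c(no_event = 0.5, event_survive = 0.1, inpatient_death = 0.1)
  expect_error(expected_lifetime_qale(bad, pe, p$states, 0.56),
               "sum to 1")
  expect_error(expected_lifetime_qale(all_no_event, pe * 0.5, p$states,
                                      0.56), "not normalized")
})

test_that("pulmonary embolism carries the no-event cost forward", {
  p <- base_params
  # a survivor cohort that is all pulmonary embolism costs the same as
  # the no-event state, not the state's own (lower) published cost
  pe <- p$principal_events$intervention$probability
  pe[] <- 0
  pe["pulmonary_embolism"] <- 1
  probs <- c(no_event = 0, event_survive = 1, inpatient_death = 0)
  expect_equal(expected_lifetime_cost(probs, pe, p$states, 0.56),
               unname(no_event_outcome(p$states, 0.56)["lifetime_cost"]))
  # but its QALE is still its own
  expect_equal(expected_lifetime_qale(probs, pe, p$states, 0.56), 6.9533)
})

test_that("arm evaluation composes hospital and lifetime costs additively", {
  p <- base_params
  int <- evaluate_arm(p, "intervention")
  ctl <- evaluate_arm(p, "control")
  expect_equal(int$total_cost, 19691.52, tolerance = 0.001)
  expect_equal(ctl$total_cost, 19746.86, tolerance = 0.001)
  for (a in list(int, ctl)) {
    expect_equal(a$hospital_cost + a$lifetime_cost, a$total_cost,
                 tolerance = 1e-9)
  }
  expect_equal(int$expected_events, 0.0666)
  p0 <- p
  p0$states$lifetime_cost[] <- 0
  p0$states$gamma_beta[] <- 0
  z <- evaluate_arm(p0, "intervention")
  expect_equal(z$total_cost, z$hospital_cost)
})

test_that("incremental comparison classifies dominance and quadrants", {
  p <- base_params
  int <- evaluate_arm(p, "intervention")
  ctl <- evaluate_arm(p, "control")
  lt <- compare_arms(int, ctl, lambda = 20000, effect = "qale")
  expect_equal(lt$delta_cost, -55.35, tolerance = 0.05)
  expect_equal(lt$delta_effect, 0.0287, tolerance = 0.02)
  expect_identical(lt$dominance, "dominant")
  expect_identical(lt$quadrant, "SE")
  expect_true(is.na(lt$icer))
  expect_equal(lt$nmb, 20000 * lt$delta_effect - lt$delta_cost)
  expect_equal(lt$nhb, lt$nmb / 20000)
  # dominant in the SE quadrant implies positive NMB
  expect_gt(lt$nmb, 0)

  st <- compare_arms(int, ctl, lambda = 20000, effect = "events")
  expect_equal(st$delta_cost, -12.17, tolerance = 1e-9)
  expect_equal(st$delta_effect, 0.0267, tolerance = 1e-9)

  a <- mk_arm("intervention", 1000, 9000, 0.05, 5.2)
  b <- mk_arm("control", 900, 8900, 0.05, 5.0)
  ne <- compare_arms(a, b)  # costlier, more effective
  expect_identical(ne$quadrant, "NE")
  expect_identical(ne$dominance, "non-dominated")
  expect_equal(ne$icer, 200 / 0.2)
  nw <- compare_arms(b, mk_arm("x", 800, 8900, 0.05, 5.1))
  expect_identical(nw$dominance, "dominated")
  expect_true(is.na(nw$icer))

  same <- compare_arms(a, a)
  expect_equal(same$delta_cost, 0)
  expect_equal(same$delta_effect, 0)
  expect_true(is.na(same$icer))
  expect_equal(same$nmb, 0)
})

test_that("discounted QALE is utility times the annuity factor", {
  expect_equal(discounted_qale(1, 10, 0), 10)
  expect_equal(discounted_qale(0.5, 17.74, 0.035),
               0.5 * annuity_factor(17.74, 0.035))
  # utility implied by the healthy-population QALE of 9.7732
  u <- base_params$healthy_qale / annuity_factor(17.74, 0.035)
  expect_equal(u, 0.749, tolerance = 0.001)
  expect_equal(discounted_qale(u, 17.74, 0.035), 9.7732,
               tolerance = 1e-9)
  expect_error(discounted_qale(1.5, 10, 0), "annual_utility")
})

test_that("expected outcomes stay inside the convex hull of state values", {
  set.seed(402)
  st <- base_params$states
  ne_states <- c("ward1_gastroenterology", "ward2_respiratory")
  for (i in 1:25) {
    p <- random_params()
    mix <- p$resource_use$ward_mix_pulmonology
    for (a in c("intervention", "control")) {
      q <- expected_lifetime_qale(p$probabilities[[a]]$p,
                                  p$principal_events[[a]]$probability,
                                  st, mix)
      cost <- expected_lifetime_cost(p$probabilities[[a]]$p,
                                     p$principal_events[[a]]$probability,
                                     st, mix)
      expect_gte(q, 0)            # death leaf pins the lower bound at 0
      expect_lte(q, max(st$qale))
      expect_gte(cost, 0)
      expect_lte(cost, max(st$lifetime_cost))
    }
  }
})

test_that("QALE is strictly decreasing in inpatient mortality", {
  p <- base_params
  pe <- p$principal_events$intervention$probability
  q_at <- function(p_death) {
    rest <- 1 - p_death
    probs <- c(no_event = rest * 0.99, event_survive = rest * 0.01,
               inpatient_death = p_death)
    expected_lifetime_qale(probs, pe, p$states, 0.56)
  }
  qs <- vapply(seq(0, 0.5, by = 0.05), q_at, numeric(1))
  expect_true(all(diff(qs) < 0))
})
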