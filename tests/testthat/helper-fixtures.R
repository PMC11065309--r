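# shared fixtures: the bundled base case is loaded once per test session
base_params <- load_parameters()

# small synthetic arm results for classification tests
mk_arm <- function(arm, hospital, lifetime, events, qale) {
  structure(list(arm = arm, hospital_cost = hospital,
                 lifetime_cost = lifetime,
                 total_cost = hospital + lifetime,
                 expected_events = events, qale = qale),
            class = "ce_arm")
}

# perturb the base case into a random but valid parameter set (for
# property-style loops); keeps the state table, rescales probabilities
random_params <- function() {
  p <- base_params
  for (a in c("intervention", "control")) {
    pr <- stats::runif(3)
    pr <- pr / sum(pr)
    # keep the same tree but random weights
    p$probabilities[[a]]$p[] <- pr
    pe <- stats::rgamma(7, shape = 1)
    p$principal_events[[a]]$probability[] <- pe / sum(pe)
  }
  p$resource_use$ward_mix_pulmonology <- stats::runif(1)
  p
}
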