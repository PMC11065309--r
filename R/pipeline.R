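PIPELINE_STAGES <- c("simulate", "estimate", "basecase", "psa",
                     "sensitivity", "subgroups")

## each stage gets a deterministic child seed so stages are independently
## reproducible: child = seed + 1000 * (position in the canonical order)
stage_seed <- function(seed, stage) {
  seed + 1000L * match(stage, PIPELINE_STAGES)
}

fmt_gbp <- function(x) sprintf("%.2f", x)
fmt_qaly <- function(x) sprintf("%.4f", x)

#' Run the full reproducible analysis pipeline
#'
#' Executes the requested stages in dependency order — `simulate`
#' (synthetic cohort), `estimate` (input recovery from the cohort),
#' `basecase` (deterministic engine), `psa` (probabilistic sensitivity
#' analysis with CEAC), `sensitivity` (one-way product-life and
#' cableless-rate analyses plus the threshold device cost), `subgroups`
#' (league table over age-band strata of the simulated cohort) — writing
#' every numeric result as CSV/JSON into `out_dir` together with a run
#' manifest. A single global seed is fanned out to stage-specific child
#' seeds (`seed + 1000 * stage_index`), so identical inputs reproduce
#' every stochastic artifact exactly.
#'
#' @param config_path parameter YAML (default: the bundled base case).
#' @param stages subset of the stage names above; an empty vector writes
#'   only the manifest.
#' @param seed global integer seed.
#' @param out_dir output directory (created if missing).
#' @param n_cohort size of the simulated cohort.
#' @param n_draws PSA draws.
#' @param lambda willingness-to-pay, GBP per QALY.
#' @return the manifest (list), invisibly; side effect: files in
#'   `out_dir` (`cohort.csv`, `estimates.json`, `basecase.csv`,
#'   `basecase.json`, `psa_draws.csv`, `ceac.csv`,
#'   `sensitivity_<parameter>.csv`, `threshold.json`, `subgroups.csv`,
#'   `manifest.json`).
#' @export
run_pipeline <- function(config_path = NULL,
                         stages = c("basecase", "psa"),
                         seed = 1L, out_dir = tempfile("ce_run_"),
                         n_cohort = 3787, n_draws = 10000,
                         lambda = 20000) {
  unknown <- setdiff(stages, PIPELINE_STAGES)
  if (length(unknown)) {
    stop("unknown stage(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  params <- if (is.null(config_path)) load_parameters() else
    load_parameters(config_path)
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  outputs <- character(0)
  emit <- function(name) {
    outputs <<- c(outputs, name)
    file.path(out_dir, name)
  }

  run_stage <- function(stage, expr) {
    message("[pipeline] stage ", stage, " (seed ",
            stage_seed(seed, stage), ")")
    tryCatch(expr, error = function(e) {
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  cohort <- NULL
  if ("simulate" %in% stages) {
    run_stage("simulate", {
      cfg <- cohort_config(params, n = n_cohort)
      cohort <- generate_cohort(cfg, seed = stage_seed(seed, "simulate"))
      write_cohort(cohort, emit("cohort.csv"))
    })
  }
  if ("estimate" %in% stages) {
    run_stage("estimate", {
      if (is.null(cohort)) {
        cfg <- cohort_config(params, n = n_cohort)
        cohort <- generate_cohort(cfg,
                                   seed = stage_seed(seed, "simulate"))
      }
      est <- estimate_model_inputs(cohort)
      jsonlite::write_json(list(
        adjusted_event_means = as.list(est$events$adjusted_means),
        adjusted_cost_means = as.list(est$costs$adjusted_means),
        discharge_probabilities = lapply(est$states$probabilities,
                                         as.list),
        principal_events = lapply(est$states$principal, as.list)
      ), emit("estimates.json"), auto_unbox = TRUE, digits = NA)
    })
  }

  model <- NULL
  if ("basecase" %in% stages) {
    run_stage("basecase", {
      model <- ce_model(params, lambda = lambda)
      s <- summary(model)
      utils::write.csv(s$table, emit("basecase.csv"), row.names = FALSE)
      jsonlite::write_json(list(
        arms = lapply(model$arms, unclass),
        lifetime = unclass(model$lifetime),
        short_term = unclass(model$short_term),
        device_per_patient = lapply(model$device,
                                    function(d) d$per_patient)
      ), emit("basecase.json"), auto_unbox = TRUE, digits = NA)
    })
  }
  if ("psa" %in% stages) {
    run_stage("psa", {
      cfg <- psa_config(n_draws = n_draws,
                        seed = stage_seed(seed, "psa"))
      res <- run_psa(params, cfg)
      utils::write.csv(res$draws, emit("psa_draws.csv"),
                       row.names = FALSE)
      utils::write.csv(res$ceac, emit("ceac.csv"), row.names = FALSE)
    })
  }
  if ("sensitivity" %in% stages) {
    run_stage("sensitivity", {
      for (spec in list(list("product_life", c(5, 10, 15)),
                        list("cableless_rate", seq(0, 1, by = 0.1)))) {
        tab <- one_way_sensitivity(params, spec[[1]], spec[[2]],
                                   lambda = lambda)
        utils::write.csv(tab,
                         emit(paste0("sensitivity_", spec[[1]], ".csv")),
                         row.names = FALSE)
      }
      thr <- threshold_device_cost(params)
      jsonlite::write_json(list(
        threshold_device_cost = as.numeric(thr),
        cableless_boundary = cableless_dominance_boundary(params)
      ), emit("threshold.json"), auto_unbox = TRUE, digits = NA)
    })
  }
  if ("subgroups" %in% stages) {
    run_stage("subgroups", {
      if (is.null(cohort)) {
        cfg <- cohort_config(params, n = n_cohort)
        cohort <- generate_cohort(cfg,
                                   seed = stage_seed(seed, "simulate"))
      }
      specs <- subgroup_parameters(cohort, params, "age_band")
      tab <- run_subgroups(specs, lambda = lambda)
      utils::write.csv(tab, emit("subgroups.csv"), row.names = FALSE)
    })
  }

  manifest <- list(
    package = "monitorCE",
    version = as.character(utils::packageVersion("monitorCE")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = if (is.null(config_path)) "bundled:vital2_basecase" else
      config_path,
    config_sha = unname(tools::md5sum(
      if (is.null(config_path)) ce_fixture_path() else config_path)),
    seed = seed,
    stage_seeds = as.list(stats::setNames(
      vapply(stages, stage_seed, numeric(1), seed = seed), stages)),
    stages = stages,
    outputs = outputs
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Render a human-readable base-case report
#'
#' Formats the per-arm and incremental results of a fitted [ce_model()]
#' in the conventional layout of a cost-utility results table: GBP to two
#' decimals, QALYs and probabilities to four. Machine outputs written by
#' [run_pipeline()] retain full precision.
#'
#' @param model a `ce_model` object.
#' @return character vector of report lines (also printed).
#' @export
render_report <- function(model) {
  stopifnot(inherits(model, "ce_model"))
  a <- model$arms$intervention
  b <- model$arms$control
  lt <- model$lifetime
  st <- model$short_term
  lines <- c(
    "Cost effectiveness of automated monitoring vs spot-check monitoring",
    sprintf("%-38s %12s %12s %12s", "", "Intervention", "Control",
            "Incremental"),
    sprintf("%-38s %12s %12s %12s", "Hospital costs (GBP, short-term)",
            fmt_gbp(a$hospital_cost), fmt_gbp(b$hospital_cost),
            fmt_gbp(st$delta_cost)),
    sprintf("%-38s %12s %12s %12s", "Lifetime costs (GBP)",
            fmt_gbp(a$lifetime_cost), fmt_gbp(b$lifetime_cost),
            fmt_gbp(a$lifetime_cost - b$lifetime_cost)),
    sprintf("%-38s %12s %12s %12s", "Total cost (GBP)",
            fmt_gbp(a$total_cost), fmt_gbp(b$total_cost),
            fmt_gbp(lt$delta_cost)),
    sprintf("%-38s %12s %12s %12s", "Predicted events per patient",
            fmt_qaly(a$expected_events), fmt_qaly(b$expected_events),
            fmt_qaly(-st$delta_effect)),
    sprintf("%-38s %12s %12s %12s", "QALE (lifetime)",
            fmt_qaly(a$qale), fmt_qaly(b$qale),
            fmt_qaly(lt$delta_effect)),
    sprintf("Lifetime comparison: %s; NMB at GBP %d/QALY = %s",
            lt$dominance, lt$lambda, fmt_gbp(lt$nmb))
  )
  cat(lines, sep = "\n")
  invisible(lines)
}
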