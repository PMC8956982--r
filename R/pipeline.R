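# End-to-end orchestration: simulate -> build-cohort -> group/fit -> evaluate
# -> compare, with file artifacts and run manifests.

PIPELINE_STAGES <- c("simulate", "build_cohort", "fit", "evaluate", "compare")

.default_pipeline_config <- function() {
  list(
    seed = 1L,
    out_dir = "dxi_run",
    sim = list(),                       # sim_config overrides
    validation_share = 0.10,
    outcome = "total_topcoded",
    models = list(
      age_sex = character(0),
      hcc     = "hcc_like",
      ccsr    = "ccsr_like",
      dxi     = c("ccsr_like", "dxi")
    ),
    stepwise = FALSE,
    entry_p = 1e-4,
    percentile_edges = c(50, 75, 90, 95, 99)
  )
}

#' Read and validate a pipeline configuration
#'
#' Accepts a YAML or JSON file (by extension) or an R list. Unknown top-level
#' keys are rejected before any work is done; omitted keys take the
#' documented defaults.
#'
#' @param config path or list; `NULL` gives the defaults.
#' @return Validated config list.
#' @export
read_pipeline_config <- function(config = NULL) {
  defaults <- .default_pipeline_config()
  if (is.null(config)) return(defaults)
  if (is.character(config)) {
    stopifnot(file.exists(config))
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stop("reading YAML configs requires the 'yaml' package; use JSON instead")
      }
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  out <- utils::modifyList(defaults, config)
  # a user-supplied model set replaces the default tiers rather than merging
  if (!is.null(config$models)) out$models <- config$models
  if (is.list(out$models)) out$models <- lapply(out$models, as.character)
  out
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Simulates a study (or any subset of stages), builds the weighted
#' enrollee-year cohort with source-filtered diagnoses, fits one weighted
#' least-squares model per configured classification tier (optionally
#' stepwise for the richest tier), evaluates every model on the validation
#' sample, and writes a side-by-side comparison. Every stage writes its
#' artifacts under `out_dir` together with a run manifest (config hash, seed,
#' row counts per stage, package version, timestamps); reruns with the same
#' config and seed reproduce all artifacts except timestamps.
#'
#' @param config pipeline configuration (path or list), see
#'   [read_pipeline_config()].
#' @param stages subset of stages to run, in order (default: all).
#' @return Invisibly, a list with the in-memory artifacts (`sim`, `cohort`,
#'   `split`, `fits`, `reports`, `comparison`, `manifest`).
#' @export
run_pipeline <- function(config = NULL, stages = PIPELINE_STAGES) {
  cfg <- read_pipeline_config(config)
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()
  artifacts <- list()

  message("[simulate] generating synthetic study (seed ", cfg$seed, ")")
  sim <- do.call(sim_config, c(list(seed = cfg$seed), cfg$sim))
  sim <- simulate_claims(sim)
  artifacts$sim <- sim
  counts$spans <- nrow(sim$spans)
  counts$claims <- nrow(sim$claims)
  if ("simulate" %in% stages) {
    fwrite(sim$spans, file.path(cfg$out_dir, "spans.csv"))
    fwrite(sim$claims, file.path(cfg$out_dir, "claims.csv"))
    fwrite(sim$filter_rules, file.path(cfg$out_dir, "filter_rules.tsv"), sep = "\t")
    for (nm in names(sim$mappings)) {
      write_mapping(sim$mappings[[nm]], file.path(cfg$out_dir, paste0("mapping_", nm, ".tsv")),
                    hierarchy_path = if (nrow(sim$mappings[[nm]]$hierarchy)) {
                      file.path(cfg$out_dir, paste0("hierarchy_", nm, ".tsv"))
                    })
    }
    write_json_file(list(true_beta = as.list(sim$ground_truth$true_beta),
                         cell_coefficients = as.list(sim$ground_truth$cell_coefficients),
                         newborn_effect = sim$ground_truth$newborn_effect,
                         expected_shock = sim$ground_truth$expected_shock),
                    file.path(cfg$out_dir, "ground_truth.json"))
  }

  message("[build_cohort] filtering diagnoses and annualizing outcomes")
  dx <- filter_diagnoses(sim$claims, sim$filter_rules)
  cohort <- build_enrollee_years(sim$spans, sim$claims, diagnoses = dx,
                                 deflators = sim$config$deflators)
  parts <- split_sample(cohort, cfg$validation_share, seed = cfg$seed)
  artifacts$cohort <- cohort
  artifacts$split <- parts
  counts$enrollee_years <- nrow(cohort$years)
  counts$development_years <- nrow(parts$development$years)
  counts$validation_years <- nrow(parts$validation$years)
  if ("build_cohort" %in% stages) {
    fwrite(cohort$years, file.path(cfg$out_dir, "enrollee_years.csv"))
    fwrite(cohort$diagnoses, file.path(cfg$out_dir, "diagnoses.csv"))
    write_json_file(c(cohort$report, attr(dx, "report")["n_removed"]),
                    file.path(cfg$out_dir, "cohort_report.json"))
  }

  fits <- list()
  reports <- list()
  if (any(c("fit", "evaluate", "compare") %in% stages)) {
    message("[fit] estimating ", length(cfg$models), " model tiers on the development sample")
    val_designs <- list()
    for (nm in names(cfg$models)) {
      spec <- model_spec(cfg$outcome, systems = c("age_sex", cfg$models[[nm]]))
      dev <- build_design(parts$development, sim$mappings, spec)
      forced <- grep("^as_", colnames(dev$X), value = TRUE)
      fit <- if (cfg$stepwise && nm == utils::tail(names(cfg$models), 1L)) {
        stepwise_fit(dev$X, dev$y, dev$w, entry_p = cfg$entry_p,
                     forced = forced, model_id = nm)
      } else {
        wls_fit(dev$X, dev$y, dev$w, model_id = nm)
      }
      fits[[nm]] <- fit
      val_designs[[nm]] <- build_design(parts$validation, sim$mappings, spec,
                                        columns = colnames(dev$X))
      if ("fit" %in% stages) {
        write_fit(fit, file.path(cfg$out_dir, paste0("fit_", nm, ".json")))
      }
    }
    artifacts$fits <- fits

    message("[evaluate] scoring on the validation sample (n=",
            counts$validation_years, ")")
    for (nm in names(fits)) {
      reports[[nm]] <- evaluate_model(fits[[nm]], val_designs[[nm]],
                                      percentile_edges = cfg$percentile_edges)
      if ("evaluate" %in% stages) {
        fwrite(reports[[nm]]$percentile_table,
               file.path(cfg$out_dir, paste0("percentiles_", nm, ".csv")))
      }
    }
    artifacts$reports <- reports

    if ("compare" %in% stages) {
      comparison <- compare_models(reports)
      fwrite(comparison, file.path(cfg$out_dir, "model_comparison.csv"))
      artifacts$comparison <- comparison
      message("[compare] validated weighted R2: ",
              paste(sprintf("%s=%.3f", comparison$model, comparison$weighted_r2),
                    collapse = ", "))
    }
  }

  cfg_for_hash <- cfg
  manifest <- list(
    config_hash = fnv1a(jsonlite::toJSON(cfg_for_hash, auto_unbox = TRUE, digits = NA)),
    seed = cfg$seed,
    stages = stages,
    out_dir = cfg$out_dir,
    counts = counts,
    tool_version = as.character(utils::packageVersion("dxitools")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  write_json_file(manifest, file.path(cfg$out_dir, "manifest.json"))
  artifacts$manifest <- manifest
  invisible(artifacts)
}
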