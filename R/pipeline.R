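#' Read and validate a pipeline configuration
#'
#' Configurations are YAML with two optional branches:
#'
#' ```yaml
#' seed: 1
#' cohort:
#'   preset: smoke            # see ?cohort_preset
#'   n_stacks_per_case: 2     # optional size overrides
#' coloc:
#'   min_overlap_fraction: 0.25
#'   denominator_rule: min_object
#' stats:
#'   outcome: coloc_volume_um3
#'   fixed_terms: [group]
#' kinetics:
#'   preset: astro-ad-vs-control
#' ```
#'
#' Validation checks that a seed is present whenever simulation is
#' requested and that referenced presets exist.
#'
#' @param path YAML file path, or a list already in that shape.
#' @return Validated config list (class `PipelineConfig`).
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  if (!is.list(cfg)) stop("config must be a YAML mapping", call. = FALSE)
  simulating <- !is.null(cfg$cohort) || !is.null(cfg$kinetics)
  if (simulating && is.null(cfg$seed))
    stop("config requests simulation but has no 'seed' field", call. = FALSE)
  if (!is.null(cfg$cohort$preset))
    cohort_preset(cfg$cohort$preset)            # errors on unknown preset
  if (!is.null(cfg$kinetics$preset))
    kinetics_preset(cfg$kinetics$preset)
  if (!is.null(cfg$coloc)) {
    ok <- c("min_overlap_fraction", "denominator_rule", "plaque_distance_um")
    bad <- setdiff(names(cfg$coloc), ok)
    if (length(bad))
      stop("unknown coloc option(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  structure(cfg, class = "PipelineConfig")
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(cfg), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

write_csv_plain <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full pipeline from a configuration
#'
#' Executes simulate -> segment -> colocalize -> metrics -> stats for the
#' cohort branch and/or the kinetics branch (index -> control
#' normalization -> AUC), writing CSV outputs and a machine-readable run
#' record (JSON) to `out_dir`. Every output table carries the config
#' hash and seed, and re-running the same config reproduces every table.
#' Stage failures abort with a stage-named diagnostic.
#'
#' @param config A [read_pipeline_config()] result, a YAML path, or a
#'   config list.
#' @param out_dir Output directory (created if needed).
#' @param progress Progress messages.
#' @return Invisible list of the output tables (`metrics`, `stats`,
#'   `contrasts`, `curves`, `auc` as applicable) plus `run_record`.
#' @export
run_pipeline <- function(config, out_dir, progress = FALSE) {
  if (!inherits(config, "PipelineConfig"))
    config <- read_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  seed <- as.integer(config$seed)
  out <- list()
  stamp <- function(df) {
    df$config_hash <- hash
    df$seed <- seed
    df
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  if (!is.null(config$cohort)) {
    design <- stage("simulate", {
      if (is.null(config$cohort$preset))
        stop("cohort config needs a 'preset' field")
      d <- cohort_preset(config$cohort$preset)
      # size overrides, e.g. for quick reruns of a preset at reduced scale
      for (fld in c("n_cases_per_group", "n_stacks_per_case", "case_cv"))
        if (!is.null(config$cohort[[fld]]))
          d[[fld]] <- if (fld == "case_cv") config$cohort[[fld]]
                      else as.integer(config$cohort[[fld]])
      d
    })
    cohort <- stage("simulate", generate_cohort(design, seed))
    cpar <- do.call(coloc_params, config$coloc %||% list())
    met <- stage("segment/colocalize/metrics",
                 cohort_metrics(cohort, params = cpar, progress = progress))
    out$metadata <- stamp(cohort$metadata)
    out$metrics <- stamp(met)
    write_csv_plain(out$metadata, file.path(out_dir, "cohort_metadata.csv"))
    write_csv_plain(out$metrics, file.path(out_dir, "stack_metrics.csv"))

    st <- config$stats
    if (!is.null(st) && !any(duplicated(met$case_id))) {
      message("stats stage skipped: need repeated stacks per case for a ",
              "random case intercept")
      st <- NULL
    }
    if (!is.null(st) && length(unique(met$group)) >= 2L) {
      fitres <- stage("stats", fit_group_model(
        met, outcome = st$outcome %||% "coloc_volume_um3",
        fixed_terms = st$fixed_terms %||% "group",
        random_group = st$random_group %||% "case_id"))
      out$stats <- stamp(fitres$anova)
      ctr <- stage("stats", pairwise_contrasts(
        fitres, (st$fixed_terms %||% "group")[1]))
      out$contrasts <- stamp(ctr)
      write_csv_plain(out$stats, file.path(out_dir, "stats_anova.csv"))
      write_csv_plain(out$contrasts, file.path(out_dir, "stats_contrasts.csv"))
      out$transform <- if (!is.null(fitres$transform))
        list(lambda = fitres$transform$lambda,
             shift = fitres$transform$shift)
    }
  }

  if (!is.null(config$kinetics)) {
    kdesign <- stage("kinetics-simulate", {
      if (!is.null(config$kinetics$preset))
        kinetics_preset(config$kinetics$preset)
      else stop("kinetics config needs a 'preset' field")
    })
    ts <- stage("kinetics-simulate", generate_timeseries(kdesign, seed))
    curves <- stage("kinetics-analyse",
                    normalize_to_final_control(phago_index(ts)))
    aucs <- stage("kinetics-analyse", auc_table(curves))
    out$curves <- stamp(curves)
    out$auc <- stamp(aucs)
    write_csv_plain(out$curves, file.path(out_dir, "phago_curves.csv"))
    write_csv_plain(out$auc, file.path(out_dir, "phago_auc.csv"))
  }

  record <- list(config = unclass(config), config_hash = hash, seed = seed,
                 package_version = as.character(utils::packageVersion("gliaEngulf")),
                 r_version = R.version.string,
                 outputs = names(out),
                 transform = out$transform)
  jsonlite::write_json(record, file.path(out_dir, "run_record.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  out$run_record <- record
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
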