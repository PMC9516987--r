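#' Pipeline run configuration
#'
#' One configuration object drives the whole analysis: simulate (or load)
#' data, describe, fit the disease-mapping and multilevel models, diagnose,
#' and report. Each stage has its own seed, derived deterministically from
#' `base_seed`, so any stage can be re-run in isolation and reproduce its
#' output exactly.
#'
#' @param out_dir Output directory for all stage artifacts.
#' @param base_seed Integer; per-stage seeds are `base_seed + stage offset`.
#' @param n_wards,n_children,n_preschools,cohorts Simulation sizes.
#' @param contamination Rates passed to [inject_exclusions()] (`NULL` to
#'   skip contamination).
#' @param dm,ml Lists of options for the two fits: `spec` plus MCMC
#'   settings (`n_iter`, `n_burnin`, `n_adapt`, `n_chains`).
#' @param forward_build Run DIC forward builds instead of fitting the given
#'   specs directly?
#' @param always_participating_only Sensitivity refit restricted to
#'   preschools present in every cohort?
#' @param median_outcome_dm Also fit the Gaussian ward-median variant?
#' @param n_residual_sims Posterior-predictive replicates per observation.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir,
                       base_seed = 1L,
                       n_wards = 21, n_children = 5000, n_preschools = 60,
                       cohorts = 2010:2017,
                       contamination = NULL,
                       dm = list(), ml = list(),
                       forward_build = FALSE,
                       always_participating_only = FALSE,
                       median_outcome_dm = FALSE,
                       n_residual_sims = 200) {
  dm_defaults <- list(spec = dm_spec(covariates = c("prop_off_age",
                                                    "prop_most_deprived",
                                                    "prop_boys")),
                      n_iter = 2000, n_burnin = 1000, n_adapt = 500,
                      n_chains = 2)
  ml_defaults <- list(spec = ml_spec(), n_iter = 800, n_burnin = 500,
                      n_adapt = 300, n_chains = 2)
  structure(list(
    out_dir = out_dir, base_seed = as.integer(base_seed),
    n_wards = n_wards, n_children = n_children,
    n_preschools = n_preschools, cohorts = cohorts,
    contamination = contamination,
    dm = modifyList(dm_defaults, dm), ml = modifyList(ml_defaults, ml),
    forward_build = forward_build,
    always_participating_only = always_participating_only,
    median_outcome_dm = median_outcome_dm,
    n_residual_sims = n_residual_sims,
    seeds = list(simulate = base_seed, dm = base_seed + 101L,
                 ml = base_seed + 202L, diagnose = base_seed + 303L)
  ), class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields of [run_config()] can be set in a YAML file; `dm` and `ml`
#' accept `n_iter`, `n_burnin`, `n_adapt`, `n_chains` plus `covariates`,
#' `include_slopes` (and `include_preschool`, `zero_inflation` for `ml`).
#'
#' @param path YAML file; see
#'   `system.file("extdata", "example-config.yaml", package = "sdqmap")` for
#'   a complete example.
#' @param out_dir Output directory (overrides any `out_dir` in the file).
#' @return A `run_config`.
#' @export
read_run_config <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  build_spec <- function(opts, ctor) {
    spec_fields <- intersect(names(opts), names(formals(ctor)))
    spec <- do.call(ctor, opts[spec_fields])
    mcmc <- opts[setdiff(names(opts), spec_fields)]
    c(list(spec = spec), mcmc)
  }
  args <- y[intersect(names(y), names(formals(run_config)))]
  if (!is.null(y$dm)) args$dm <- build_spec(y$dm, dm_spec)
  if (!is.null(y$ml)) args$ml <- build_spec(y$ml, ml_spec)
  if (!is.null(y$contamination)) args$contamination <- unlist(y$contamination)
  if (!is.null(out_dir)) args$out_dir <- out_dir
  if (is.null(args$out_dir)) abort("`out_dir` must be given in the file or the call.")
  do.call(run_config, args)
}

#' Run the end-to-end analysis pipeline
#'
#' Executes simulate, describe, fit-dm, fit-ml, diagnose and report stages
#' in order, writing every artifact to `config$out_dir` and finishing with
#' a `manifest.json` recording the configuration, per-stage seeds and MD5
#' hashes of all text outputs. Identical configurations produce identical
#' manifests. The `always_participating_only` sensitivity restricts the
#' data to preschools that contributed in every cohort before refitting
#' both models; `median_outcome_dm` additionally fits the Gaussian
#' ward-median disease-mapping variant.
#'
#' @param config A [run_config()].
#' @param stages Subset of stages to run (artifacts of earlier stages must
#'   exist in `out_dir`).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "describe", "fit-dm",
                                    "fit-ml", "diagnose", "report")) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  od <- function(...) file.path(config$out_dir, ...)
  run_stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(force(expr), error = function(e) {
      abort(sprintf("Pipeline stage `%s` failed: %s", name, conditionMessage(e)))
    })
    message(sprintf("[%s] done in %.1fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }

  if ("simulate" %in% stages) {
    run_stage("simulate", {
      geo <- simulate_geography(config$n_wards, seed = config$seeds$simulate)
      rec <- simulate_children(geo, n_children = config$n_children,
                               n_preschools = config$n_preschools,
                               cohorts = config$cohorts,
                               seed = config$seeds$simulate + 1L)
      if (!is.null(config$contamination)) {
        rec <- inject_exclusions(rec, rates = config$contamination,
                                 seed = config$seeds$simulate + 2L)
      }
      write_geography_geojson(geo, od("wards.geojson"))
      write_adjacency_csv(geo$adjacency, od("adjacency.csv"))
      write_children_csv(rec, od("records.csv"))
      write_truth_ledger(rec, od("truth.json"))
    })
  }

  records <- read_children_csv(od("records.csv"))
  geo <- read_geography_geojson(od("wards.geojson"))
  retained <- apply_exclusions(records)
  if (config$always_participating_only) {
    retained <- filter_always_participating(retained, config$cohorts)
  }
  counts <- aggregate_ward_year(retained)

  if ("describe" %in% stages) {
    run_stage("describe", {
      tally <- exclusion_tally(apply_exclusions(records))
      utils::write.csv(tally, od("exclusions.csv"), row.names = FALSE)
      desc <- describe_sdq(retained,
                           by = c("age_band", "sex", "deprivation", "cohort", "ward"))
      utils::write.csv(desc, od("descriptives.csv"), row.names = FALSE)
      writeLines(describe_markdown(desc), od("descriptives.md"))
      utils::write.csv(counts, od("counts.csv"), row.names = FALSE)
    })
  }

  dm_fits <- NULL
  if ("fit-dm" %in% stages) {
    dm_fits <- run_stage("fit-dm", {
      mc <- config$dm
      unadj <- fit_dm(counts, dm_spec(priors = mc$spec$priors),
                      seed = config$seeds$dm + 1L,
                      n_iter = mc$n_iter, n_burnin = mc$n_burnin,
                      n_adapt = mc$n_adapt, n_chains = mc$n_chains)
      if (config$forward_build) {
        fb <- forward_build_dm(counts, seed = config$seeds$dm,
                               n_iter = mc$n_iter, n_burnin = mc$n_burnin,
                               n_adapt = mc$n_adapt, n_chains = mc$n_chains)
        utils::write.csv(fb$ledger, od("dm_dic_ledger.csv"), row.names = FALSE)
        fit <- fb$fit
      } else {
        fit <- fit_dm(counts, mc$spec, seed = config$seeds$dm,
                      n_iter = mc$n_iter, n_burnin = mc$n_burnin,
                      n_adapt = mc$n_adapt, n_chains = mc$n_chains)
      }
      utils::write.csv(rr_summaries(fit, force = TRUE), od("dm_rr.csv"),
                       row.names = FALSE)
      utils::write.csv(rr_summaries(unadj, force = TRUE),
                       od("dm_rr_unadjusted.csv"), row.names = FALSE)
      jsonlite::write_json(c(as.list(glance(fit)),
                             list(tidy = tidy(fit))),
                           od("dm_fit.json"), auto_unbox = TRUE, digits = NA)
      if (config$median_outcome_dm) {
        med <- fit_dm_median(counts, seed = config$seeds$dm + 50L,
                             n_chains = config$dm$n_chains)
        utils::write.csv(med$ward_variance, od("dm_median_ward_variance.csv"),
                         row.names = FALSE)
      }
      list(adjusted = fit, unadjusted = unadj)
    })
  }

  ml_fits <- NULL
  if ("fit-ml" %in% stages) {
    ml_fits <- run_stage("fit-ml", {
      mc <- config$ml
      unadj_spec <- ml_spec(include_preschool = mc$spec$include_preschool,
                            covariates = character(),
                            zero_inflation = mc$spec$zero_inflation,
                            priors = mc$spec$priors)
      unadj <- fit_ml(retained, unadj_spec, seed = config$seeds$ml + 1L,
                      n_iter = mc$n_iter, n_burnin = mc$n_burnin,
                      n_adapt = mc$n_adapt, n_chains = mc$n_chains)
      if (config$forward_build) {
        fb <- forward_build_ml(retained, seed = config$seeds$ml,
                               n_iter = mc$n_iter, n_burnin = mc$n_burnin,
                               n_adapt = mc$n_adapt, n_chains = mc$n_chains)
        utils::write.csv(fb$ledger, od("ml_dic_ledger.csv"), row.names = FALSE)
        fit <- fb$fit
      } else {
        fit <- fit_ml(retained, mc$spec, seed = config$seeds$ml,
                      n_iter = mc$n_iter, n_burnin = mc$n_burnin,
                      n_adapt = mc$n_adapt, n_chains = mc$n_chains)
      }
      utils::write.csv(rr_summaries(fit, force = TRUE), od("ml_rr.csv"),
                       row.names = FALSE)
      utils::write.csv(rr_summaries(unadj, force = TRUE),
                       od("ml_rr_unadjusted.csv"), row.names = FALSE)
      utils::write.csv(ml_variances(fit), od("ml_variances.csv"),
                       row.names = FALSE)
      jsonlite::write_json(c(as.list(glance(fit)), list(tidy = tidy(fit))),
                           od("ml_fit.json"), auto_unbox = TRUE, digits = NA)
      list(adjusted = fit, unadjusted = unadj)
    })
  }

  if ("diagnose" %in% stages) {
    run_stage("diagnose", {
      diag <- list()
      if (!is.null(dm_fits)) {
        res <- scaled_residuals(dm_fits$adjusted,
                                n_sim = config$n_residual_sims,
                                seed = config$seeds$diagnose, force = TRUE)
        scr <- residual_moran_screen(res$residual, res$ward_id,
                                     geo$adjacency,
                                     seed = config$seeds$diagnose + 1L)
        diag$dm <- as.list(scr)
      }
      if (!is.null(ml_fits)) {
        res <- scaled_residuals(ml_fits$adjusted,
                                n_sim = config$n_residual_sims,
                                seed = config$seeds$diagnose + 2L, force = TRUE)
        scr <- residual_moran_screen(res$residual, res$ward_id,
                                     geo$adjacency,
                                     seed = config$seeds$diagnose + 3L)
        diag$ml <- as.list(scr)
      }
      jsonlite::write_json(diag, od("diagnostics.json"), auto_unbox = TRUE,
                           digits = NA)
    })
  }

  if ("report" %in% stages) {
    # four panels per model, mirroring the before/after-adjustment figures:
    # RR and exceedance for the unadjusted and the adjusted fit
    run_stage("report", {
      for (src in list(list(fits = dm_fits, tag = "dm"),
                       list(fits = ml_fits, tag = "ml"))) {
        if (is.null(src$fits)) next
        for (which in names(src$fits)) {
          rr <- rr_summaries(src$fits[[which]], force = TRUE)
          wards <- rr[rr$type == "ward", ]
          layer <- tibble::tibble(
            ward_id = as.integer(sub("ward_", "", wards$term)),
            rr = wards$rr, exceedance = wards$exceedance)
          render_choropleth(geo, layer, "rr",
                            od(sprintf("map_%s_rr_%s.png", src$tag, which)),
                            breaks = "quantile")
          render_choropleth(geo, layer, "exceedance",
                            od(sprintf("map_%s_exceedance_%s.png", src$tag, which)),
                            breaks = "exceedance")
        }
      }
      build_report(config$out_dir)
    })
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("sdqmap")),
    seeds = config$seeds,
    config = config[c("n_wards", "n_children", "n_preschools",
                      "forward_build", "always_participating_only",
                      "median_outcome_dm", "n_residual_sims")],
    hashes = text_output_hashes(config$out_dir)
  )
  jsonlite::write_json(manifest, od("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}

# MD5 hashes of the run's text artifacts (maps are PNG and excluded; their
# sidecar CSVs carry the plotted values)
text_output_hashes <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.(csv|json|md|geojson)$"))
  files <- setdiff(files, "manifest.json")
  h <- tools::md5sum(file.path(dir, files))
  as.list(setNames(unname(h), files))
}

#' Restrict records to preschools that participated in every cohort
#'
#' Sensitivity-analysis filter: keeps only children attending preschools
#' that contributed records in all `cohorts`.
#'
#' @param records Child records.
#' @param cohorts Cohort years that define full participation (default: all
#'   cohorts present in `records`).
#' @return Filtered records.
#' @export
filter_always_participating <- function(records, cohorts = NULL) {
  cohorts <- cohorts %||% sort(unique(records$cohort))
  years_per_pre <- records |>
    dplyr::distinct(.data$preschool_id, .data$cohort) |>
    dplyr::count(.data$preschool_id)
  keep <- years_per_pre$preschool_id[years_per_pre$n == length(cohorts)]
  dplyr::filter(records, .data$preschool_id %in% keep)
}
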