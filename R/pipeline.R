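# End-to-end orchestration: simulate (or load) -> match -> PPMR -> models ->
# classification -> ordination -> report, with a manifest recording what ran.

#' Replicate-seed parameter recovery for a generator preset
#'
#' Simulates a preset, runs the full matching + PPMR + model-fitting path,
#' and collects the estimates across replicate seeds. This is the engine
#' behind the recovery checks: the mean estimate across seeds should sit
#' within Monte-Carlo error of the preset's true coefficients.
#'
#' @param preset Preset name for [ppmr_preset()].
#' @param n_stomachs Stomachs per replicate.
#' @param seeds Integer vector of replicate seeds.
#' @param response Response model to fit (see [fit_ppmr_model()]).
#' @param fishing Fit the temperature-by-effort interaction model and report
#'   conditional slopes at the effort-tercile medians.
#' @param ... Extra overrides for [ppmr_preset()].
#' @return A tibble with one row per seed: `intercept`, `temp_slope` (and
#'   their standard errors), plus `slope_low` / `slope_high` (conditional
#'   slopes at the low/high effort-tercile medians) when `fishing = TRUE`.
#' @export
run_recovery <- function(preset, n_stomachs = 5000, seeds = 1:10,
                         response = "log10_ppmr", fishing = FALSE, ...) {
  rows <- lapply(seeds, function(s) {
    sim <- simulate_ppmr_data(ppmr_preset(preset, n_stomachs = n_stomachs,
                                          seed = s, ...))
    matched <- match_covariates(sim$stomachs, sim$sst, sim$effort)
    tab <- if (response == "log10_prey_mass") matched else compute_ppmr(matched)
    fit <- suppressMessages(
      fit_ppmr_model(tab, response = response, fishing = fishing)
    )
    cf <- fit$coefficients
    get <- function(term, what) {
      i <- match(term, cf$term)
      if (is.na(i)) NA_real_ else cf[[what]][i]
    }
    out <- tibble(
      seed = s,
      intercept = get("(Intercept)", "estimate"),
      intercept_se = get("(Intercept)", "std_error"),
      temp_slope = get("temp", "estimate"),
      temp_slope_se = get("temp", "std_error"),
      singular = fit$singular
    )
    if (fishing) {
      terc <- effort_terciles(fit$data$effort_hours)
      lines <- stratified_trendlines(fit, terc)
      out$interaction <- get("temp:effort_std", "estimate")
      out$interaction_se <- get("temp:effort_std", "std_error")
      out$slope_low <- lines$slope[lines$stratum == "low"]
      out$slope_high <- lines$slope[lines$stratum == "high"]
      out$intercept_low <- lines$intercept[lines$stratum == "low"]
      out$intercept_high <- lines$intercept[lines$stratum == "high"]
    }
    out
  })
  bind_rows(rows)
}

#' Summarise fitted models as percent change across the gradient
#'
#' For each fit, back-transforms the temperature slope into percent change
#' per degree and compounded across the stated temperature span (via
#' [pct_change_per_degree()] / [pct_change_over_gradient()]); fits with an
#' effort interaction additionally get one row per effort stratum with the
#' conditional slope.
#'
#' @param fits A named list of `ppmr_fit` objects.
#' @param gradient Temperature span in degrees C.
#' @return A tibble with one row per model (and per effort stratum for
#'   interaction models).
#' @export
report_fits <- function(fits, gradient) {
  stopifnot(gradient > 0)
  if (inherits(fits, "ppmr_fit")) fits <- list(fits)
  if (is.null(names(fits))) {
    names(fits) <- vapply(fits, function(f) f$response, character(1))
  }
  rows <- lapply(names(fits), function(nm) {
    fit <- fits[[nm]]
    cf <- fit$coefficients
    b <- unname(cf$estimate[match("temp", cf$term)])
    se <- unname(cf$std_error[match("temp", cf$term)])
    base <- tibble(
      model = nm, stratum = "overall", slope = b, std_error = se,
      pct_per_degree = pct_change_per_degree(b),
      pct_over_gradient = pct_change_over_gradient(b, gradient)
    )
    if (fit$spec$fishing && "temp:effort_std" %in% cf$term) {
      terc <- effort_terciles(fit$data$effort_hours)
      lines <- stratified_trendlines(fit, terc)
      strat <- tibble(
        model = nm, stratum = as.character(lines$stratum),
        slope = lines$slope, std_error = NA_real_,
        pct_per_degree = pct_change_per_degree(lines$slope),
        pct_over_gradient = pct_change_over_gradient(lines$slope, gradient)
      )
      base <- bind_rows(base, strat)
    }
    base
  })
  bind_rows(rows)
}

#' Configuration for an end-to-end pipeline run
#'
#' Either a generator `preset` (with `n_stomachs` and `seed`) or the three
#' input paths must be supplied -- never neither.
#'
#' @param preset Generator preset name, or `NULL` to read CSVs.
#' @param stomachs_path,sst_path,effort_path Input CSV paths (used when
#'   `preset` is `NULL`; `effort_path` may be `NULL`).
#' @param out_dir Output directory (created if needed).
#' @param n_stomachs,seed Generator settings when simulating.
#' @param fishing Fit the effort-interaction models.
#' @param alpha Significance level for species classification.
#' @param min_n Minimum per-species observations for classification.
#' @param gradient Temperature span for percent-change reporting; defaults
#'   to the span of matched temperatures.
#' @param stages Stage names to run, in order.
#' @return A list of class `ppmr_run_config`.
#' @export
ppmr_run_config <- function(preset = NULL, stomachs_path = NULL,
                            sst_path = NULL, effort_path = NULL,
                            out_dir, n_stomachs = 2000, seed = 1,
                            fishing = TRUE, alpha = 0.05, min_n = 30,
                            gradient = NULL,
                            stages = c("simulate", "match", "ppmr", "fit",
                                       "classify", "ordinate", "report")) {
  if (is.null(preset) && (is.null(stomachs_path) || is.null(sst_path))) {
    stop_ppmr("supply either a preset or input paths (stomachs + sst)")
  }
  structure(list(
    preset = preset, stomachs_path = stomachs_path, sst_path = sst_path,
    effort_path = effort_path, out_dir = out_dir,
    n_stomachs = n_stomachs, seed = seed, fishing = fishing, alpha = alpha,
    min_n = min_n, gradient = gradient, stages = stages
  ), class = "ppmr_run_config")
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order, writing intermediate CSVs and fit
#' JSONs into `config$out_dir`, and returns a manifest recording per-stage
#' row counts, outputs, and any failure. Re-running with an identical config
#' reproduces identical outputs.
#'
#' @param config A [ppmr_run_config()].
#' @return The manifest (list of class `ppmr_manifest`): `config_hash`,
#'   `stages` tibble, `outputs`, and the in-memory `results`.
#' @export
run_ppmr_pipeline <- function(config) {
  stopifnot(inherits(config, "ppmr_run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- list()
  outputs <- character(0)
  results <- list()
  failed <- FALSE

  note <- function(name, rows, outs = character(0), status = "ok") {
    stages[[length(stages) + 1]] <<- tibble(stage = name, status = status,
                                            rows = as.integer(rows))
    outputs <<- c(outputs, outs)
  }
  run_stage <- function(name, expr) {
    if (failed || !name %in% config$stages) return(invisible(NULL))
    tryCatch(expr, error = function(e) {
      failed <<- TRUE
      note(name, NA, status = paste0("failed: ", conditionMessage(e)))
    })
  }
  save_csv <- function(x, name) {
    p <- file.path(config$out_dir, name)
    readr::write_csv(x, p)
    p
  }

  run_stage("simulate", {
    if (!is.null(config$preset)) {
      sim <- simulate_ppmr_data(ppmr_preset(config$preset,
                                            n_stomachs = config$n_stomachs,
                                            seed = config$seed))
      results$stomachs <- sim$stomachs
      results$sst <- sim$sst
      results$effort <- sim$effort
      results$truth <- sim$truth
      outs <- c(save_csv(sim$stomachs, "stomachs.csv"),
                save_csv(sim$sst, "sst.csv"),
                save_csv(sim$effort, "effort.csv"))
      note("simulate", nrow(sim$stomachs), outs)
    } else {
      results$stomachs <- read_stomach_table(config$stomachs_path)
      results$sst <- read_sst_table(config$sst_path)
      results$effort <- if (!is.null(config$effort_path)) {
        read_effort_table(config$effort_path)
      }
      note("simulate", nrow(results$stomachs))
    }
  })

  run_stage("match", {
    m <- match_covariates(results$stomachs, results$sst, results$effort)
    results$matched <- m
    note("match", nrow(m), save_csv(m, "matched.csv"))
  })

  run_stage("ppmr", {
    obs <- compute_ppmr(results$matched)
    results$ppmr <- obs
    note("ppmr", nrow(obs), save_csv(obs, "ppmr.csv"))
  })

  run_stage("fit", {
    fits <- list()
    fits$log10_ppmr <- suppressMessages(
      fit_ppmr_model(results$ppmr, "log10_ppmr"))
    fits$log10_predator_mass <- suppressMessages(
      fit_ppmr_model(results$ppmr, "log10_predator_mass"))
    fits$log10_prey_mass <- suppressMessages(
      fit_ppmr_model(results$matched, "log10_prey_mass"))
    fits$log10_prey_count <- suppressMessages(
      fit_ppmr_model(results$ppmr, "log10_prey_count"))
    fits$log10_richness <- suppressMessages(
      fit_ppmr_model(results$ppmr, "log10_richness"))
    if (config$fishing && !is.null(results$effort)) {
      fits$log10_ppmr_fishing <- suppressMessages(
        fit_ppmr_model(results$ppmr, "log10_ppmr", fishing = TRUE))
    }
    results$fits <- fits
    outs <- vapply(names(fits), function(nm) {
      p <- file.path(config$out_dir, paste0("fit_", nm, ".json"))
      f <- fits[[nm]]
      jsonlite::write_json(list(
        response = f$response, n = f$n, aic = f$aic, loglik = f$loglik,
        r2 = f$r2, coefficients = f$coefficients, varcor = f$varcor,
        dropped = f$dropped, singular = f$singular, messages = f$messages
      ), p, auto_unbox = TRUE, digits = NA)
      p
    }, character(1))
    note("fit", length(fits), outs)
  })

  run_stage("classify", {
    cls <- list(
      prey = classify_species_responses(results$matched, "prey",
                                        alpha = config$alpha,
                                        min_n = config$min_n),
      predator = classify_species_responses(results$matched, "predator",
                                            alpha = config$alpha,
                                            min_n = config$min_n)
    )
    results$classification <- cls
    outs <- c(save_csv(cls$prey$summary, "classification_prey.csv"),
              save_csv(cls$predator$summary, "classification_predator.csv"))
    note("classify", nrow(cls$prey$species) + nrow(cls$predator$species), outs)
  })

  run_stage("ordinate", {
    comm <- suppressMessages(build_community_matrix(results$matched))
    ord <- run_nmds(comm, seed = config$seed)
    vecs <- fit_env_vectors(ord, comm$covariates[
      c("mean_mass", "mean_temp", "mean_effort")], seed = config$seed)
    results$ordination <- list(community = comm, nmds = ord, vectors = vecs)
    pts <- as_tibble(ord$points, rownames = "prey_family")
    outs <- c(save_csv(pts, "nmds_points.csv"),
              save_csv(vecs, "nmds_vectors.csv"))
    note("ordinate", nrow(pts), outs)
  })

  run_stage("report", {
    grad <- config$gradient %||% diff(range(results$ppmr$sst_c, na.rm = TRUE))
    rep <- report_fits(results$fits, grad)
    results$report <- rep
    note("report", nrow(rep), save_csv(rep, "report.csv"))
  })

  manifest <- structure(list(
    config = config,
    # hash the scientific settings only, not machine-specific paths
    config_hash = rlang::hash(unclass(config)[
      setdiff(names(config), c("out_dir", "stomachs_path", "sst_path",
                               "effort_path"))]),
    stages = bind_rows(stages),
    outputs = outputs,
    results = results
  ), class = "ppmr_manifest")
  jsonlite::write_json(
    list(config_hash = manifest$config_hash, stages = manifest$stages,
         outputs = basename(outputs)),
    file.path(config$out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  manifest
}

#' @export
print.ppmr_manifest <- function(x, ...) {
  cat("<ppmr_manifest>", x$config_hash, "\n")
  print(x$stages)
  invisible(x)
}
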