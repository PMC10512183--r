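# Configuration-driven orchestration: simulate (or load) -> preprocess ->
# quantify -> group stats -> classify, with seeded reproducibility and a
# machine-readable run report.

default_run_config <- function() {
  list(
    seed = 1L,
    synthetic = list(),          # overrides for synthetic_cohort_config()
    files = NULL,                # list(cohort_csv, metadata_csv) for real data
    preprocess = list(),         # overrides for preprocess_params()
    stats = list(p_adjust = "none"),
    chemometrics = list(grid = c(5, 10, 20, 40, 60, 80), ncomp_max = 3,
                        folds = 3, repeats = 50, scale = TRUE),
    peak_regions = c("amide_I", "amide_II", "acyl_chain")
  )
}

modify_defaults <- function(defaults, overrides) {
  if (!length(overrides)) return(defaults)
  utils::modifyList(defaults, overrides)
}

#' Validate and normalize a run configuration
#'
#' Reads a YAML or JSON document (or takes a list), fills every default,
#' and cross-checks the fields. All violations are collected and reported
#' together rather than failing at the first one. An empty document yields
#' the default synthetic run configuration.
#'
#' @param config Path to a YAML/JSON file, or a configuration list.
#' @return A normalized configuration list of class `ftir_run_config`;
#'   errors (if any) abort with the full list of messages.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
    if (is.null(config)) config <- list()
  }
  if (!is.list(config)) stop("configuration must be a mapping", call. = FALSE)
  cfg <- modify_defaults(default_run_config(), config)
  errors <- character(0)

  if (!is.null(cfg$files)) {
    for (f in unlist(cfg$files)) {
      if (!file.exists(f)) errors <- c(errors, paste0("input file not found: ", f))
    }
  }
  synth <- tryCatch(do.call(synthetic_cohort_config,
                            modify_defaults(list(seed = cfg$seed), cfg$synthetic)),
                    error = function(e) {
                      errors <<- c(errors, paste0("synthetic: ", conditionMessage(e)))
                      NULL
                    })
  pp <- tryCatch(do.call(preprocess_params, cfg$preprocess),
                 error = function(e) {
                   errors <<- c(errors, paste0("preprocess: ", conditionMessage(e)))
                   NULL
                 })
  if (!is.null(synth) && !is.null(pp)) {
    if (pp$excise_lo <= synth$axis_lo || pp$excise_hi >= synth$axis_hi) {
      errors <- c(errors, sprintf(
        "excision interval %g-%g must lie strictly inside the axis span %g-%g",
        pp$excise_lo, pp$excise_hi, synth$axis_lo, synth$axis_hi))
    }
  }
  ch <- cfg$chemometrics
  if (any(ch$grid < 1)) errors <- c(errors, "chemometrics grid entries must be >= 1")
  if (!is.null(synth)) {
    p_max <- length(config_axis(synth))
    if (any(ch$grid > p_max)) {
      errors <- c(errors, sprintf("keepX grid entries exceed the number of variables (%d)", p_max))
    }
  }
  if (ch$folds < 2) errors <- c(errors, "folds must be >= 2")
  if (length(errors)) {
    stop("invalid configuration:\n  - ", paste(errors, collapse = "\n  - "),
         call. = FALSE)
  }
  cfg$synthetic_config <- synth
  cfg$preprocess_params <- pp
  class(cfg) <- "ftir_run_config"
  cfg
}

write_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or load) -> preprocess -> band quantification ->
#' group statistics -> sPLS-DA classification, writing every intermediate
#' table under `outdir` plus a JSON and a plain-text run report. Every
#' random stage consumes a stage-specific child seed derived from the
#' global seed, so two runs with the same configuration produce identical
#' numeric outputs.
#'
#' @param config An [validate_config()] result, a configuration list, or a
#'   path to a YAML/JSON configuration.
#' @param outdir Output directory (created if missing).
#' @return The run report, invisibly (list of class `ftir_run_report`).
#' @export
run_pipeline <- function(config = list(), outdir = tempfile("ftir_run_")) {
  if (!inherits(config, "ftir_run_config")) config <- validate_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = config$seed, stages = list(), warnings = character(0))
  log_warn <- function(w) {
    report$warnings <<- c(report$warnings, conditionMessage(w))
    invokeRestart("muffleWarning")
  }

  withCallingHandlers({
    # --- simulate ------------------------------------------------------
    synth <- config$synthetic_config
    cohort_raw <- generate_cohort(synth)
    wn <- config_axis(synth)
    reference <- generate_reference_spectrum(wn, seed = synth$seed + 1L)
    write_table(cohort_raw$metadata, file.path(outdir, "metadata.csv"))
    report$stages$simulate <- list(n_samples = nrow(cohort_raw$metadata),
                                   n_pixels = synth$n_rows * synth$n_cols,
                                   axis_points = length(wn))

    # --- preprocess ----------------------------------------------------
    pp <- config$preprocess_params
    records <- lapply(cohort_raw$samples, function(s) {
      tryCatch(preprocess_sample(s$image, reference, pp),
               error = function(e) stop("preprocess failed for sample ",
                                        s$truth$sample_id, ": ",
                                        conditionMessage(e), call. = FALSE))
    })
    cohort <- cohort_table(records)
    write_spectral_matrix(cohort, file.path(outdir, "mean_absorbance.csv"))
    d2mat <- cohort_matrix(cohort, "second_derivative")
    utils::write.csv(data.frame(sample_id = rownames(d2mat), d2mat,
                                check.names = FALSE),
                     file.path(outdir, "second_derivative.csv"),
                     row.names = FALSE, quote = FALSE)
    report$stages$preprocess <- list(
      n_records = length(records),
      axis_points_after = length(axis_of(cohort)))

    # --- quantify ------------------------------------------------------
    panel <- compute_ratio_panel(cohort)
    write_table(data.frame(sample_id = rownames(panel$values),
                           group = panel$groups, panel$values,
                           check.names = FALSE),
                file.path(outdir, "ratios.csv"))
    peaks <- do.call(rbind, lapply(config$peak_regions, function(rg) {
      pk <- compare_peak_positions(cohort, rg)
      cbind(region = rg, pk$per_sample)
    }))
    write_table(peaks, file.path(outdir, "peaks.csv"))
    report$stages$quantify <- list(n_ratios = ncol(panel$values),
                                   n_peak_regions = length(config$peak_regions))

    # --- stats ---------------------------------------------------------
    st <- ratio_panel_stats(panel, p_adjust = config$stats$p_adjust)
    write_table(st$anova, file.path(outdir, "stats_anova.csv"))
    write_table(st$tukey, file.path(outdir, "stats_tukey.csv"))
    write_table(st$diagnostics, file.path(outdir, "stats_diagnostics.csv"))
    report$stages$stats <- list(
      n_significant = sum(st$anova$p < 0.05),
      ratios = stats::setNames(st$anova$p, st$anova$ratio))

    # --- classify ------------------------------------------------------
    ch <- config$chemometrics
    X <- d2mat
    y <- cohort_groups(cohort)
    tune <- tune_splsda(X, y, grid = ch$grid, ncomp_max = ch$ncomp_max,
                        folds = ch$folds, repeats = ch$repeats,
                        seed = config$seed + 101L, scale = ch$scale)
    write_table(tune$errors, file.path(outdir, "tuning.csv"))
    model <- splsda_fit(X, y, n_components = tune$chosen_ncomp,
                        keepX = tune$chosen_keepX, scale = ch$scale)
    arts <- export_model_artifacts(model, X)
    write_table(arts$scores, file.path(outdir, "scores.csv"))
    write_table(arts$loadings, file.path(outdir, "loadings.csv"))
    roc <- cv_auroc(X, y, n_components = tune$chosen_ncomp,
                    keepX = tune$chosen_keepX, folds = ch$folds,
                    repeats = min(ch$repeats, 20L),
                    seed = config$seed + 202L, scale = ch$scale)
    write_table(data.frame(class = names(roc$auc), auroc = as.numeric(roc$auc)),
                file.path(outdir, "auroc.csv"))
    report$stages$classify <- list(chosen_ncomp = tune$chosen_ncomp,
                                   chosen_keepX = tune$chosen_keepX,
                                   auroc = as.list(roc$auc))
  }, warning = log_warn)

  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  txt <- c("fibrospec pipeline report",
           sprintf("seed: %d", report$seed),
           sprintf("samples: %d", report$stages$simulate$n_samples),
           sprintf("significant ratios (ANOVA p < 0.05): %d",
                   report$stages$stats$n_significant),
           sprintf("sPLS-DA: ncomp = %d, keepX = %s",
                   report$stages$classify$chosen_ncomp,
                   paste(report$stages$classify$chosen_keepX, collapse = "/")),
           sprintf("AUROC: %s",
                   paste(sprintf("%s = %.3f",
                                 names(report$stages$classify$auroc),
                                 unlist(report$stages$classify$auroc)),
                         collapse = ", ")),
           if (length(report$warnings)) c("warnings:", paste(" -", report$warnings)))
  writeLines(txt, file.path(outdir, "report.txt"))
  class(report) <- "ftir_run_report"
  attr(report, "outdir") <- outdir
  invisible(report)
}

#' Cross-validated one-vs-rest AUROC for an sPLS-DA configuration
#'
#' Repeated stratified cross-validation: per repeat, each sample's
#' per-class decision values (negative centroid distances) come from the
#' fold in which it was held out; AUROC is computed per repeat and
#' averaged. Decision values rather than indicator predictions are ranked
#' so that a class whose centroid lies between the others remains rankable
#' even in a one-component model.
#'
#' @param X,y Data and labels.
#' @param n_components,keepX,scale Model settings (see [splsda_fit()]).
#' @param folds,repeats,seed Cross-validation settings.
#' @return An `ftir_roc` (curves from the last repeat; `auc` averaged over
#'   repeats).
#' @export
cv_auroc <- function(X, y, n_components, keepX, folds = 3, repeats = 10,
                     seed = 1L, scale = TRUE) {
  X <- as.matrix(X); y <- as.character(y)
  lev <- sort(unique(y))
  aucs <- matrix(NA_real_, repeats, length(lev), dimnames = list(NULL, lev))
  last <- NULL
  withr::with_seed(seed, {
    for (r in seq_len(repeats)) {
      fl <- stratified_folds(y, folds)
      yhat <- matrix(NA_real_, nrow(X), length(lev), dimnames = list(NULL, lev))
      for (f in seq_len(folds)) {
        test <- fl == f
        fit <- splsda_fit(X[!test, , drop = FALSE], y[!test],
                          n_components = n_components, keepX = keepX,
                          scale = scale)
        yhat[test, ] <- splsda_predict(fit, X[test, , drop = FALSE])$decision
      }
      roc <- auroc(yhat, y)
      aucs[r, ] <- roc$auc[lev]
      last <- roc
    }
  })
  last$auc <- colMeans(aucs)
  last$auc_per_repeat <- aucs
  last
}
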