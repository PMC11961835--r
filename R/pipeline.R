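#' Pipeline run configuration
#'
#' One object holding every tunable parameter of an end-to-end run, so the
#' emitted manifest makes the run reconstructible. Input is either a
#' [cohort_spec()] (simulated cohort) or a list with `scans` (data frame
#' with columns `patient_id, timepoint, volume, mask` of NIfTI paths) and
#' `cohort_csv` (path for [read_cohort_table()]).
#'
#' @param input A [cohort_spec()] or a `list(scans = , cohort_csv = )`.
#' @param discretisation A [discretisation_config()].
#' @param stratification A [stratification_config()].
#' @param schemes Stratification schemes to run.
#' @param time_origin Outcome time origin: `"diagnosis"` (default) or
#'   `"treatment_end"` (requires a `months_to_treatment_end` column, which
#'   is subtracted from follow-up).
#' @param out_dir Output directory for CSVs and the manifest; `NULL`
#'   returns the bundle without writing.
#' @param seed Overrides the cohort spec seed when given.
#' @return An object of class `run_config`.
#' @export
run_config <- function(input, discretisation = discretisation_config(),
                       stratification = stratification_config(),
                       schemes = c("mtv_csh", "p16_csh"),
                       time_origin = c("diagnosis", "treatment_end"),
                       out_dir = NULL, seed = NULL) {
  time_origin <- match.arg(time_origin)
  if (!inherits(input, "cohort_spec")) {
    if (!is.list(input) || is.null(input$scans) || is.null(input$cohort_csv))
      stopf("input must be a cohort_spec or list(scans=, cohort_csv=)")
    if (!file.exists(input$cohort_csv))
      stopf("cohort table not found: %s", input$cohort_csv)
    missing_files <- c(input$scans$volume, input$scans$mask)
    missing_files <- missing_files[!file.exists(missing_files)]
    if (length(missing_files))
      stopf("missing scan file(s): %s",
            paste(utils::head(missing_files, 3), collapse = ", "))
  } else if (!is.null(seed)) {
    input$seed <- as.integer(seed)
  }
  structure(list(input = input, discretisation = discretisation,
                 stratification = stratification,
                 schemes = match.arg(schemes, several.ok = TRUE),
                 time_origin = time_origin, out_dir = out_dir,
                 seed = seed),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the end-to-end mid-treatment PET analysis
#'
#' Feature extraction (or simulation) at both timepoints, delta features,
#' risk stratification, and the survival layer: per-group Kaplan-Meier
#' curves, 2-year recurrence-free survival, log-rank comparison, and
#' univariate + adjusted Cox regression of the delta features. Outcome
#' data never enter the feature or stratification stages. When `out_dir`
#' is set, every stage's table and a JSON manifest of all parameters are
#' written; a rerun with the same config reproduces them bit-identically.
#'
#' @param config A [run_config()].
#' @return An object of class `pipeline_result` (list of tables and fitted
#'   summaries), invisibly when written to disk.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))

  if (inherits(config$input, "cohort_spec")) {
    sim <- stage("simulate",
                 simulate_cohort(config$input, images = TRUE,
                                 config = config$discretisation))
    features <- sim$features
    deltas <- sim$deltas
    cohort <- as_patient_records(sim$cohort)
  } else {
    cohort <- stage("cohort_io", read_cohort_table(config$input$cohort_csv))
    scans <- config$input$scans
    features <- stage("features", {
      rows <- lapply(seq_len(nrow(scans)), function(i) {
        r <- scans[i, ]
        tryCatch({
          vol <- read_suv_volume(r$volume, scan_id = r$patient_id,
                                 timepoint = r$timepoint)
          msk <- read_roi_mask(r$mask, vol)
          f <- as.data.frame(extract_features(vol, msk,
                                              config$discretisation))
          f$patient_id <- r$patient_id
          f
        }, error = function(e)
          stopf("patient %s (%s): %s", r$patient_id, r$timepoint,
                conditionMessage(e)))
      })
      do.call(rbind, rows)
    })
    deltas <- stage("deltas", delta_table(features))
  }

  if (config$time_origin == "treatment_end") {
    if (is.null(cohort$months_to_treatment_end))
      stopf("time_origin 'treatment_end' needs a months_to_treatment_end column")
    cohort$followup_months <-
      pmax(cohort$followup_months - cohort$months_to_treatment_end, 0)
  }

  schemes <- config$schemes
  if ("p16_csh" %in% schemes &&
      !any(cohort$p16 %in% c("positive", "negative"))) {
    warnf("all patients have unknown p16; skipping p16_csh stratification")
    schemes <- setdiff(schemes, "p16_csh")
    if (!length(schemes)) stopf("no stratification scheme can run")
  }
  groups <- stage("stratify",
                  stratify_cohort(deltas, cohort, scheme = schemes,
                                  config = config$stratification))

  surv <- stage("survival", {
    merged <- merge(groups, cohort, by = "patient_id")
    out <- list()
    for (sc in unique(merged$scheme)) {
      m <- merged[merged$scheme == sc, ]
      km <- lapply(sort(unique(m$group_label)), function(g) {
        sub <- m[m$group_label == g, ]
        km_fit(sub$followup_months, sub$lrr_event)
      })
      names(km) <- sort(unique(m$group_label))
      lr <- if (length(km) >= 2)
        logrank_test(m$followup_months, m$lrr_event, m$group_label)
      else NULL
      lrrfs2 <- vapply(km, function(k)
        suppressWarnings(survival_at(k, 24)), numeric(1))
      out[[sc]] <- list(km = km, logrank = lr, lrrfs_2yr = lrrfs2)
    }
    out
  })

  cox <- stage("cox", {
    dat <- merge(deltas, cohort, by = "patient_id")
    for (cc in c("p16", "tnm_stage", "chemo"))
      if (!is.null(dat[[cc]])) dat[[cc]] <- factor(dat[[cc]])
    covs <- intersect(unname(delta_feature_names), names(dat))
    covs <- covs[vapply(covs, function(cv) stats::sd(dat[[cv]]) > 0,
                        logical(1))]
    if (sum(dat$lrr_event) == 0 || !length(covs)) NULL
    else list(univariate = cox_fit(dat, covs, multivariate = FALSE),
              multivariate = tryCatch(
                cox_fit(dat, covs, multivariate = TRUE),
                error = function(e) {
                  warnf("multivariate Cox skipped: %s", conditionMessage(e))
                  NULL
                }))
  })

  manifest <- list(
    package = "cshpet",
    version = as.character(utils::packageVersion("cshpet")),
    seed = if (inherits(config$input, "cohort_spec"))
      config$input$seed else config$seed,
    input = if (inherits(config$input, "cohort_spec")) "simulated" else "files",
    n_patients = nrow(cohort),
    bin_width_suv = config$discretisation$bin_width_suv,
    bin_anchor = config$discretisation$anchor,
    csh_values = config$discretisation$values,
    csh_integration = config$discretisation$integration,
    mtv_cutoff_pct = config$stratification$mtv_cutoff_pct,
    csh_cutoff_pct = config$stratification$csh_cutoff_pct,
    schemes = schemes,
    time_origin = config$time_origin,
    group_counts = attr(groups, "counts"))

  res <- structure(list(features = features, deltas = deltas,
                        cohort = cohort, groups = groups,
                        survival = surv, cox = cox, manifest = manifest),
                   class = "pipeline_result")
  if (!is.null(config$out_dir)) {
    write_pipeline_result(res, config$out_dir)
    return(invisible(res))
  }
  res
}

write_pipeline_result <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name)
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  if (!is.null(res$features)) wr(res$features, "features.csv")
  wr(res$deltas, "deltas.csv")
  wr(res$cohort, "cohort.csv")
  wr(res$groups, "groups.csv")
  km_rows <- list(); lr_rows <- list(); s2_rows <- list()
  for (sc in names(res$survival)) {
    s <- res$survival[[sc]]
    for (g in names(s$km)) {
      tab <- s$km[[g]]$table
      tab$scheme <- sc; tab$group <- g
      km_rows[[paste(sc, g)]] <- tab
    }
    if (!is.null(s$logrank))
      lr_rows[[sc]] <- data.frame(scheme = sc,
                                  chi_square = s$logrank$chi_square,
                                  df = s$logrank$df,
                                  p_value = s$logrank$p_value)
    s2_rows[[sc]] <- data.frame(scheme = sc, group = names(s$lrrfs_2yr),
                                lrrfs_2yr = unname(s$lrrfs_2yr))
  }
  wr(do.call(rbind, km_rows), "km_curves.csv")
  if (length(lr_rows)) wr(do.call(rbind, lr_rows), "logrank.csv")
  wr(do.call(rbind, s2_rows), "lrrfs_2yr.csv")
  if (!is.null(res$cox)) {
    cx <- rbind(cbind(model = "univariate", res$cox$univariate$table),
                if (!is.null(res$cox$multivariate))
                  cbind(model = "multivariate", res$cox$multivariate$table))
    wr(cx, "cox.csv")
  }
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d patient(s), schemes: %s\n",
              nrow(x$cohort), paste(x$manifest$schemes, collapse = ", ")))
  for (sc in names(x$survival)) {
    s <- x$survival[[sc]]
    cat(sprintf("  %s: 2-yr LRRFS %s%s\n", sc,
                paste(sprintf("%.1f%%", 100 * s$lrrfs_2yr), collapse = " / "),
                if (!is.null(s$logrank))
                  sprintf(", log-rank p = %.3g", s$logrank$p_value) else ""))
  }
  invisible(x)
}
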