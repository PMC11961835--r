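#' Pre-specified response cut-offs
#'
#' @param mtv_cutoff_pct Favourable metabolic-volume response is a
#'   reduction of at least this many percent (default 50, boundary
#'   inclusive): signed `d_mtv <= -mtv_cutoff_pct`.
#' @param csh_cutoff_pct Favourable heterogeneity response is a change in
#'   AUC-CSH strictly greater than this (default 0): `d_auc_csh > 0`.
#' @return An object of class `stratification_config`.
#' @export
stratification_config <- function(mtv_cutoff_pct = 50, csh_cutoff_pct = 0) {
  if (mtv_cutoff_pct <= 0) stopf("mtv_cutoff_pct must be positive")
  structure(list(mtv_cutoff_pct = mtv_cutoff_pct,
                 csh_cutoff_pct = csh_cutoff_pct),
            class = "stratification_config")
}

#' Binary imaging-response classification
#'
#' `binary_mtv_response()` labels a metabolic tumour volume reduction of at
#' least the cut-off (default 50%) as favourable; `binary_csh_response()`
#' labels a strictly positive change in AUC-CSH (falling heterogeneity) as
#' favourable.
#'
#' @param d_mtv,d_auc_csh Signed percentage changes (week 3 vs week 0).
#' @param config A [stratification_config()].
#' @return `"favourable"` or `"unfavourable"` (vectorised).
#' @examples
#' binary_mtv_response(c(-60, -50, 10))
#' binary_csh_response(c(24, 0, -5))
#' @export
binary_mtv_response <- function(d_mtv, config = stratification_config()) {
  if (anyNA(d_mtv)) stopf("d_mtv undefined")
  ifelse(d_mtv <= -config$mtv_cutoff_pct, "favourable", "unfavourable")
}

#' @rdname binary_mtv_response
#' @export
binary_csh_response <- function(d_auc_csh, config = stratification_config()) {
  if (anyNA(d_auc_csh)) stopf("d_auc_csh undefined")
  ifelse(d_auc_csh > config$csh_cutoff_pct, "favourable", "unfavourable")
}

p16_csh_group_names <- c(
  "p16 positive + favourable dAUC-CSH",
  "p16 negative",
  "p16 positive + unfavourable dAUC-CSH")

mtv_csh_group_names <- c(
  "favourable dMTV",
  "unfavourable dMTV + favourable dAUC-CSH",
  "unfavourable dMTV + unfavourable dAUC-CSH")

#' Three-group risk stratification schemes
#'
#' Both schemes combine the heterogeneity response with one other marker
#' and order the groups from best to worst expected locoregional control.
#'
#' `stratify_p16_csh()`: group 1 = p16-positive with favourable dAUC-CSH,
#' group 2 = p16-negative (not subdivided), group 3 = p16-positive with
#' unfavourable dAUC-CSH. Patients with unknown p16 are excluded (`NA` with
#' a message).
#'
#' `stratify_mtv_csh()`: group 1 = favourable dMTV (regardless of
#' dAUC-CSH), group 2 = unfavourable dMTV with favourable dAUC-CSH,
#' group 3 = both unfavourable.
#'
#' @param p16 Character vector in `{"positive","negative","unknown"}`.
#' @param d_auc_csh,d_mtv Signed percentage changes.
#' @param config A [stratification_config()].
#' @return Integer group labels 1-3 (`NA` for excluded patients), with the
#'   scheme's human-readable group names attached as the `"group_names"`
#'   attribute.
#' @examples
#' stratify_p16_csh(c("positive", "negative", "positive"), c(20, 20, -5))
#' stratify_mtv_csh(c(-60, -30, -30), c(-10, 10, -10))
#' @export
stratify_p16_csh <- function(p16, d_auc_csh,
                             config = stratification_config()) {
  if (length(p16) != length(d_auc_csh))
    stopf("p16 and d_auc_csh lengths differ")
  csh <- binary_csh_response(d_auc_csh, config)
  g <- rep(NA_integer_, length(p16))
  g[p16 == "negative"] <- 2L
  g[p16 == "positive" & csh == "favourable"] <- 1L
  g[p16 == "positive" & csh == "unfavourable"] <- 3L
  n_unknown <- sum(!(p16 %in% c("positive", "negative")))
  if (n_unknown > 0)
    message(sprintf(
      "stratify_p16_csh: excluded %d patient(s) with unknown p16 status",
      n_unknown))
  structure(g, group_names = p16_csh_group_names)
}

#' @rdname stratify_p16_csh
#' @export
stratify_mtv_csh <- function(d_mtv, d_auc_csh,
                             config = stratification_config()) {
  if (length(d_mtv) != length(d_auc_csh))
    stopf("d_mtv and d_auc_csh lengths differ")
  mtv <- binary_mtv_response(d_mtv, config)
  csh <- binary_csh_response(d_auc_csh, config)
  g <- ifelse(mtv == "favourable", 1L,
              ifelse(csh == "favourable", 2L, 3L))
  structure(as.integer(g), group_names = mtv_csh_group_names)
}

#' Tabulate risk groups for a cohort delta table
#'
#' Applies one (or both) stratification schemes to a per-patient delta
#' table and returns long-format labels plus per-group counts. p16 status
#' is taken from `cohort` (matched on `patient_id`) for the p16 scheme.
#'
#' @param deltas Data frame from [delta_table()].
#' @param cohort Optional cohort data frame with `patient_id` and `p16`
#'   (required for the `p16_csh` scheme).
#' @param scheme `"mtv_csh"`, `"p16_csh"`, or both.
#' @param config A [stratification_config()].
#' @return Data frame with `patient_id, scheme, group_label, group_name`
#'   (excluded patients omitted); per-scheme group counts in the
#'   `"counts"` attribute.
#' @export
stratify_cohort <- function(deltas, cohort = NULL,
                            scheme = c("mtv_csh", "p16_csh"),
                            config = stratification_config()) {
  scheme <- match.arg(scheme, several.ok = TRUE)
  out <- list(); counts <- list()
  if ("mtv_csh" %in% scheme) {
    g <- stratify_mtv_csh(deltas$d_mtv, deltas$d_auc_csh, config)
    out$mtv_csh <- data.frame(
      patient_id = deltas$patient_id, scheme = "mtv_csh",
      group_label = as.integer(g),
      group_name = mtv_csh_group_names[g], stringsAsFactors = FALSE)
    counts$mtv_csh <- tabulate(g, nbins = 3L)
  }
  if ("p16_csh" %in% scheme) {
    if (is.null(cohort) || !all(c("patient_id", "p16") %in% names(cohort)))
      stopf("p16_csh scheme needs a cohort table with patient_id and p16")
    p16 <- cohort$p16[match(deltas$patient_id, cohort$patient_id)]
    p16[is.na(p16)] <- "unknown"
    g <- stratify_p16_csh(p16, deltas$d_auc_csh, config)
    keep <- !is.na(g)
    out$p16_csh <- data.frame(
      patient_id = deltas$patient_id[keep], scheme = "p16_csh",
      group_label = as.integer(g[keep]),
      group_name = p16_csh_group_names[g[keep]], stringsAsFactors = FALSE)
    counts$p16_csh <- tabulate(g[keep], nbins = 3L)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, counts = counts)
}
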