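delta_feature_names <- c(suv_max = "d_suv_max", suv_mean = "d_suv_mean",
                         mtv_ml = "d_mtv", tlg = "d_tlg",
                         auc_csh = "d_auc_csh")

#' Percentage-change (delta) features between paired timepoints
#'
#' For each of the five parameters, the relative change from baseline is
#' delta = (week3 - week0) / week0 * 100, on the percentage scale
#' (-50 means halving). Defined only when the week-0 value is positive.
#'
#' @param week0,week3 [extract_features()] results (or plain lists carrying
#'   `suv_max`, `suv_mean`, `mtv_ml`, `tlg`, `auc_csh`) for the same
#'   patient's baseline and mid-treatment scans.
#' @param patient_id Optional identifier attached to the result.
#' @return An object of class `delta_feature_set` with fields `d_suv_max`,
#'   `d_suv_mean`, `d_mtv`, `d_tlg`, `d_auc_csh` (signed percentages).
#' @examples
#' w0 <- list(suv_max = 10, suv_mean = 5, mtv_ml = 20, tlg = 100,
#'            auc_csh = 0.5)
#' w3 <- list(suv_max = 6, suv_mean = 4, mtv_ml = 10, tlg = 40,
#'            auc_csh = 0.62)
#' delta_features(w0, w3)
#' @export
delta_features <- function(week0, week3, patient_id = "") {
  out <- list(patient_id = as.character(patient_id))
  for (f in names(delta_feature_names)) {
    v0 <- week0[[f]]; v3 <- week3[[f]]
    if (is.null(v0) || is.null(v3))
      stopf("feature '%s' missing from a timepoint", f)
    if (!is.finite(v0) || v0 <= 0)
      stopf("delta undefined for '%s': week-0 value %s is not positive",
            f, format(v0))
    out[[delta_feature_names[[f]]]] <- (v3 - v0) / v0 * 100
  }
  structure(out, class = "delta_feature_set")
}

#' @export
print.delta_feature_set <- function(x, ...) {
  cat(sprintf("<delta_feature_set> %s\n",
              if (nzchar(x$patient_id)) x$patient_id else "(unnamed)"))
  for (f in delta_feature_names)
    cat(sprintf("  %-10s %+.2f%%\n", f, x[[f]]))
  invisible(x)
}

#' Pair per-scan features into a per-patient delta table
#'
#' `features` holds one row per scan with a `patient_id`, a `timepoint`
#' (`week0`/`week3`) and the five feature columns. Patients missing either
#' timepoint are dropped with a message (no imputation).
#'
#' @param features Data frame of per-scan features (e.g. row-bound
#'   [as.data.frame.feature_set()] outputs).
#' @return Data frame with columns `patient_id, d_suv_max, d_suv_mean,
#'   d_mtv, d_tlg, d_auc_csh`.
#' @export
delta_table <- function(features) {
  need <- c("patient_id", "timepoint", names(delta_feature_names))
  missing_cols <- setdiff(need, names(features))
  if (length(missing_cols))
    stopf("feature table missing column(s): %s",
          paste(missing_cols, collapse = ", "))
  ids <- unique(features$patient_id)
  rows <- lapply(ids, function(id) {
    w0 <- features[features$patient_id == id &
                     features$timepoint == "week0", , drop = FALSE]
    w3 <- features[features$patient_id == id &
                     features$timepoint == "week3", , drop = FALSE]
    if (nrow(w0) != 1L || nrow(w3) != 1L) return(NULL)
    d <- delta_features(as.list(w0), as.list(w3), patient_id = id)
    as.data.frame(unclass(d), stringsAsFactors = FALSE)
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0)
    message(sprintf("delta_table: dropped %d patient(s) missing a timepoint",
                    dropped))
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' Spearman redundancy screen over a feature table
#'
#' Pairwise Spearman rank correlations between feature columns; pairs with
#' |Rs| above `threshold` are flagged "very strong" (redundant) per the
#' conventional band labels (very strong 0.81-1.00, strong 0.61-0.80,
#' moderate 0.41-0.60, weak 0.21-0.40, negligible 0.00-0.20). Constant
#' columns have undefined rank correlations and are reported as `NA`.
#'
#' @param features Data frame whose numeric columns are screened (>= 3 rows).
#' @param threshold Flagging threshold on |Rs| (default 0.80, flag when
#'   strictly above).
#' @return An object of class `correlation_screen`: the symmetric `rho`
#'   matrix, a logical `redundant` matrix and a data frame of flagged pairs.
#' @export
redundancy_screen <- function(features, threshold = 0.80) {
  num <- features[vapply(features, is.numeric, logical(1))]
  if (nrow(num) < 3L) stopf("redundancy screen needs >= 3 patients")
  if (ncol(num) < 2L) stopf("redundancy screen needs >= 2 numeric features")
  constant <- vapply(num, function(x) stats::sd(x) == 0, logical(1))
  rho <- suppressWarnings(
    stats::cor(num, method = "spearman", use = "pairwise.complete.obs"))
  rho[constant, ] <- NA_real_
  rho[, constant] <- NA_real_
  diag(rho) <- ifelse(constant, NA_real_, 1)
  redundant <- !is.na(rho) & abs(rho) > threshold
  diag(redundant) <- FALSE
  pairs <- which(upper.tri(redundant) & redundant, arr.ind = TRUE)
  flagged <- data.frame(
    feature_a = rownames(rho)[pairs[, 1]],
    feature_b = colnames(rho)[pairs[, 2]],
    rho = rho[pairs], stringsAsFactors = FALSE)
  structure(list(rho = rho, redundant = redundant, flagged = flagged,
                 threshold = threshold),
            class = "correlation_screen")
}

#' @export
print.correlation_screen <- function(x, ...) {
  cat(sprintf("<correlation_screen> %d feature(s), threshold |Rs| > %.2f\n",
              ncol(x$rho), x$threshold))
  if (nrow(x$flagged) == 0) cat("  no redundant pairs\n")
  else for (i in seq_len(nrow(x$flagged)))
    cat(sprintf("  %s ~ %s: Rs = %.3f (very strong)\n",
                x$flagged$feature_a[i], x$flagged$feature_b[i],
                x$flagged$rho[i]))
  invisible(x)
}
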