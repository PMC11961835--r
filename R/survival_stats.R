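#' Kaplan-Meier product-limit estimator
#'
#' The product-limit estimate of locoregional recurrence-free survival
#' (or any right-censored time-to-event outcome). At each distinct event
#' time the survival multiplier is `1 - events / at_risk`; subjects
#' censored at an event time remain at risk for that time's events
#' (events precede censorings, the standard convention).
#'
#' @param times Non-negative follow-up times (months).
#' @param events 0/1 event indicators (1 = locoregional recurrence).
#' @return An object of class `km_curve`: a per-distinct-time table with
#'   `time, n_risk, n_event, n_censor, survival`.
#' @examples
#' km_fit(c(1, 2, 3), c(1, 0, 1))
#' @export
km_fit <- function(times, events) {
  if (length(times) == 0L) stopf("empty survival input")
  if (length(times) != length(events)) stopf("times/events lengths differ")
  if (anyNA(times) || any(times < 0)) stopf("times must be non-negative")
  if (!all(events %in% c(0, 1))) stopf("events must be 0/1")
  ut <- sort(unique(times))
  n <- length(times)
  n_event <- vapply(ut, function(t) sum(times == t & events == 1), numeric(1))
  n_censor <- vapply(ut, function(t) sum(times == t & events == 0), numeric(1))
  n_risk <- vapply(ut, function(t) sum(times >= t), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  structure(list(
    table = data.frame(time = ut, n_risk = n_risk, n_event = n_event,
                       n_censor = n_censor, survival = surv),
    n = n, n_events = sum(events), max_time = max(times)),
    class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> n = %d, events = %d, max follow-up %.1f\n",
              x$n, x$n_events, x$max_time))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' @export
summary.km_curve <- function(object, times = 24, ...) {
  data.frame(time = times,
             survival = vapply(times, function(t)
               suppressWarnings(survival_at(object, t)), numeric(1)))
}

#' Plot a Kaplan-Meier curve
#'
#' @param x A [km_curve()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot.km_curve <- function(x, ...) {
  graphics::plot(c(0, x$table$time), c(1, x$table$survival), type = "s",
                 ylim = c(0, 1), xlab = "time (months)", ylab = "survival",
                 ...)
  invisible(x)
}

#' Evaluate a Kaplan-Meier curve at a time point
#'
#' Right-continuous step-function lookup; `survival_at(curve, 24)` is the
#' 2-year recurrence-free survival. Evaluation beyond the last observed
#' follow-up returns the final estimate with an extrapolation warning.
#'
#' @param curve A [km_curve()].
#' @param t Time (months), >= 0.
#' @return Survival probability in \[0, 1\].
#' @export
survival_at <- function(curve, t) {
  if (!is.finite(t) || t < 0) stopf("time must be non-negative")
  if (t > curve$max_time)
    warnf("time %.1f beyond last follow-up %.1f; returning last estimate",
          t, curve$max_time)
  tab <- curve$table
  idx <- findInterval(t, tab$time)
  if (idx == 0) 1 else tab$survival[idx]
}

#' k-group log-rank (Mantel-Cox) test
#'
#' The standard observed-minus-expected chi-square over pooled event
#' times, with the hypergeometric variance for ties; the statistic is the
#' quadratic form over the first k-1 groups and df = k - 1.
#'
#' @param times,events As in [km_fit()], pooled across groups.
#' @param group Group membership vector (>= 2 non-empty groups).
#' @return An object of class `logrank_result` with `chi_square`, `df`,
#'   `p_value`, and per-group `observed` / `expected` event counts.
#' @export
logrank_test <- function(times, events, group) {
  if (length(times) != length(events) || length(times) != length(group))
    stopf("times, events and group must have equal length")
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2L) stopf("need >= 2 non-empty groups")
  group <- droplevels(group)
  k <- nlevels(group)
  ev_times <- sort(unique(times[events == 1]))
  O <- vapply(levels(group), function(g) sum(events[group == g]), numeric(1))
  E <- numeric(k)
  V <- matrix(0, k, k)
  for (t in ev_times) {
    at_risk <- times >= t
    nj <- sum(at_risk)
    dj <- sum(events == 1 & times == t)
    ngj <- vapply(levels(group), function(g) sum(at_risk & group == g),
                  numeric(1))
    E <- E + dj * ngj / nj
    if (nj > 1) {
      frac <- ngj / nj
      v <- dj * (nj - dj) / (nj - 1) *
        (diag(frac, k) - tcrossprod(frac))
      V <- V + v
    }
  }
  d <- (O - E)[-k]
  Vk <- V[-k, -k, drop = FALSE]
  if (max(abs(O - E)) < 1e-12) {
    chi <- 0
  } else {
    inv <- tryCatch(solve(Vk), error = function(e) pinv(Vk))
    chi <- max(0, as.numeric(t(d) %*% inv %*% d))
  }
  structure(list(chi_square = chi, df = k - 1L,
                 p_value = stats::pchisq(chi, df = k - 1L,
                                         lower.tail = FALSE),
                 observed = O, expected = E, n = as.vector(table(group))),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("<logrank_result> chi-square = %.4f, df = %d, p = %.4g\n",
              x$chi_square, x$df, x$p_value))
  print(data.frame(group = names(x$observed), n = x$n,
                   observed = x$observed, expected = x$expected),
        row.names = FALSE)
  invisible(x)
}

#' Cox proportional-hazards regression for the cohort
#'
#' Partial-likelihood fit delegated to [survival::coxph()]. Hazard ratios
#' for delta features are reported per percentage point (the delta scale is
#' never re-normalised). In multivariate mode every model additionally
#' adjusts for the a-priori clinical trio (p16 status, TNM stage,
#' chemotherapy), one imaging feature at a time.
#'
#' @param data Cohort data frame containing the outcome columns and
#'   covariates.
#' @param covariates Character vector of imaging covariate column names.
#' @param adjust Character vector of a-priori adjustment covariates used
#'   when `multivariate = TRUE` (default `c("p16", "tnm_stage", "chemo")`).
#' @param multivariate Adjust for the a-priori trio? Default `FALSE`
#'   (univariate).
#' @param time_col,event_col Outcome column names.
#' @return An object of class `cox_result`: one row per imaging covariate
#'   with `hr`, `ci_lo`, `ci_hi`, `p_value`, plus model metadata.
#' @export
cox_fit <- function(data, covariates, adjust = c("p16", "tnm_stage", "chemo"),
                    multivariate = FALSE, time_col = "followup_months",
                    event_col = "lrr_event") {
  if (!all(c(time_col, event_col) %in% names(data)))
    stopf("outcome columns %s / %s not found", time_col, event_col)
  if (sum(data[[event_col]]) == 0) stopf("no events: Cox model undefined")
  missing_cov <- setdiff(covariates, names(data))
  if (length(missing_cov))
    stopf("covariate(s) not in data: %s", paste(missing_cov, collapse = ", "))
  adj <- if (multivariate) intersect(adjust, names(data)) else character(0)
  if (multivariate && length(adj) < length(adjust))
    warnf("a-priori covariate(s) missing from data: %s",
          paste(setdiff(adjust, adj), collapse = ", "))
  degenerate <- vapply(adj, function(a)
    length(unique(data[[a]])) < 2L, logical(1))
  if (any(degenerate)) {
    message(sprintf("cox_fit: dropping single-level adjustment covariate(s): %s",
                    paste(adj[degenerate], collapse = ", ")))
    adj <- adj[!degenerate]
  }
  rows <- lapply(covariates, function(cv) {
    if (is.numeric(data[[cv]]) && stats::sd(data[[cv]]) == 0)
      stopf("covariate '%s' is constant", cv)
    rhs <- paste(c(cv, adj), collapse = " + ")
    fml <- stats::as.formula(sprintf("survival::Surv(%s, %s) ~ %s",
                                     time_col, event_col, rhs))
    fit <- survival::coxph(fml, data = data)
    if (!is.null(fit$info) || any(!is.finite(stats::coef(fit))))
      stopf("Cox fit for '%s' did not converge", cv)
    s <- summary(fit)
    i <- grep(paste0("^", cv), rownames(s$coefficients))[1]
    data.frame(covariate = cv,
               hr = s$conf.int[i, "exp(coef)"],
               ci_lo = s$conf.int[i, "lower .95"],
               ci_hi = s$conf.int[i, "upper .95"],
               p_value = s$coefficients[i, "Pr(>|z|)"],
               stringsAsFactors = FALSE)
  })
  structure(list(table = do.call(rbind, rows),
                 multivariate = multivariate, adjust = adj),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("<cox_result> %s Cox regression%s\n",
              if (x$multivariate) "multivariate" else "univariate",
              if (length(x$adjust))
                sprintf(" (adjusted for %s)", paste(x$adjust, collapse = ", "))
              else ""))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.cox_result <- function(object, ...) {
  stats::setNames(log(object$table$hr), object$table$covariate)
}

#' Paired week-0 vs week-3 comparison (Wilcoxon signed-rank)
#'
#' @param week0,week3 Paired numeric vectors (length >= 2).
#' @return List with the signed-rank statistic `V`, `p_value`, and the
#'   cohort `mean_pct_change`.
#' @export
paired_compare <- function(week0, week3) {
  if (length(week0) != length(week3)) stopf("unpaired inputs")
  if (length(week0) < 2L) stopf("paired comparison needs n >= 2")
  mean_pct <- mean((week3 - week0) / week0 * 100)
  if (all(week3 == week0))
    return(list(statistic = 0, p_value = 1, mean_pct_change = mean_pct,
                note = "all paired differences are zero"))
  wt <- suppressWarnings(stats::wilcox.test(week3, week0, paired = TRUE,
                                            exact = FALSE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       mean_pct_change = mean_pct)
}

#' Two-group comparison (Mann-Whitney U)
#'
#' @param a,b Non-empty numeric vectors (e.g. a feature split by p16
#'   status).
#' @return List with the Mann-Whitney `U` statistic and `p_value`.
#' @export
group_compare <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stopf("empty group")
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
  list(U = unname(wt$statistic), p_value = wt$p.value)
}
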