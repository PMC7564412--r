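#' Survival analysis for the therapy study
#'
#' Event times are days from tumor engraftment; `event = 1` marks a death or
#' a sacrifice meeting the predefined criteria (weight loss > 20%,
#' paraplegia, extramedullary lesions), `event = 0` an animal censored —
#' administratively at study end (day 150/160) for survivors. The
#' product-limit (Kaplan-Meier) estimator and the Mantel-Cox log-rank test
#' are implemented here from their definitions; no continuity correction is
#' applied.
#'
#' @name survival_analysis
NULL

validate_survival <- function(records) {
  need <- c("time", "event")
  missing <- setdiff(need, names(records))
  if (length(missing)) {
    stop("survival records missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(records) == 0L) stop("no survival records", call. = FALSE)
  if (any(!is.finite(records$time)) || any(records$time <= 0)) {
    stop("event times must be positive and finite (days)", call. = FALSE)
  }
  if (!all(records$event %in% c(0, 1))) {
    stop("'event' must be 0 (censored) or 1 (event)", call. = FALSE)
  }
  invisible(records)
}

#' Kaplan-Meier product-limit curve
#'
#' S(t) = prod over event times t_i <= t of (1 - d_i / n_i), with d_i events
#' among n_i at risk. At tied times, deaths are processed before censorings
#' (a censoring at t is still at risk for the death at t). Censored times do
#' not step the curve.
#'
#' @param records data.frame with columns `time` (days, > 0) and `event`
#'   (1 = event, 0 = censored).
#' @return A `km_curve`: data.frame of the distinct event times with columns
#'   `time`, `n_risk`, `n_event`, `n_censor`, `survival`; S(0) = 1 is
#'   implicit.
#' @export
km_curve <- function(records) {
  validate_survival(records)
  time <- records$time; event <- records$event
  times <- sort(unique(time))
  n_risk <- vapply(times, function(tt) sum(time >= tt), numeric(1))
  n_event <- vapply(times, function(tt) sum(time == tt & event == 1), numeric(1))
  n_censor <- vapply(times, function(tt) sum(time == tt & event == 0), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  structure(data.frame(time = times, n_risk = n_risk, n_event = n_event,
                       n_censor = n_censor, survival = surv),
            class = c("km_curve", "data.frame"))
}

#' Median survival from a product-limit curve
#'
#' The smallest time at which the survival function reaches 0.5 or below.
#' When the curve never falls to 0.5 (more than half the group survives to
#' the end of follow-up) the median is undefined and `NA` is returned.
#'
#' @param curve A `km_curve`.
#' @return Median survival in days, or `NA` if undefined.
#' @export
median_survival <- function(curve) {
  stopifnot(inherits(curve, "km_curve"))
  hit <- which(curve$survival <= 0.5 + 1e-12)
  if (!length(hit)) return(NA_real_)
  curve$time[hit[1L]]
}

#' Mantel-Cox log-rank test for two groups
#'
#' At each distinct event time the observed events in group A are compared
#' with the expectation under the null (events distributed across groups in
#' proportion to the numbers at risk), with the hypergeometric variance
#' d (n_A/n) (1 - n_A/n) (n - d)/(n - 1). The statistic
#' (sum(O - E))^2 / sum(V) is referred to chi-squared with 1 df. Symmetric in
#' the group labels; no continuity correction.
#'
#' @param group_a,group_b data.frames with `time` and `event` columns.
#' @return A `logrank_result`: list with `chisq`, `df`, `p_value`,
#'   `observed`, `expected` (per group), `defined` (FALSE when the groups
#'   contain no events, in which case the test is undefined and `p_value`
#'   is `NA`).
#' @export
logrank_test <- function(group_a, group_b) {
  validate_survival(group_a); validate_survival(group_b)
  time <- c(group_a$time, group_b$time)
  event <- c(group_a$event, group_b$event)
  grp <- rep(c(0L, 1L), c(nrow(group_a), nrow(group_b)))
  etimes <- sort(unique(time[event == 1]))
  if (!length(etimes)) {
    return(structure(list(chisq = NA_real_, df = 1L, p_value = NA_real_,
                          observed = c(0, 0), expected = c(0, 0),
                          defined = FALSE),
                     class = "logrank_result"))
  }
  o_minus_e <- 0; v <- 0; obs <- c(0, 0); expd <- c(0, 0)
  for (tt in etimes) {
    at_risk <- time >= tt
    n <- sum(at_risk)
    n_a <- sum(at_risk & grp == 0L)
    d <- sum(time == tt & event == 1)
    d_a <- sum(time == tt & event == 1 & grp == 0L)
    e_a <- d * n_a / n
    o_minus_e <- o_minus_e + (d_a - e_a)
    if (n > 1) v <- v + d * (n_a / n) * (1 - n_a / n) * (n - d) / (n - 1)
    obs <- obs + c(d_a, d - d_a)
    expd <- expd + c(e_a, d - e_a)
  }
  chisq <- if (v > 0) o_minus_e^2 / v else 0
  structure(list(chisq = chisq, df = 1L,
                 p_value = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
                 observed = obs, expected = expd, defined = TRUE),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  if (!x$defined) {
    cat("<logrank_result> undefined (no events)\n")
    return(invisible(x))
  }
  cat(sprintf("<logrank_result> chisq = %.4g on %d df, p = %.4g\n",
              x$chisq, x$df, x$p_value))
  cat(sprintf("  observed %g vs %g, expected %.2f vs %.2f\n",
              x$observed[1], x$observed[2], x$expected[1], x$expected[2]))
  invisible(x)
}

#' Overall survival percentage
#'
#' @param alive Number of animals surviving.
#' @param total Group size (> 0).
#' @param digits Rounding of the percentage; `0` gives report-style integer
#'   percent, `NULL` none.
#' @return 100 * alive / total.
#' @examples
#' survival_percent(11, 17, digits = 0) # 65
#' @export
survival_percent <- function(alive, total, digits = NULL) {
  stopifnot(length(alive) == 1L, length(total) == 1L)
  if (!is.finite(total) || total <= 0) stop("'total' must be > 0", call. = FALSE)
  if (!is.finite(alive) || alive < 0 || alive > total) {
    stop("'alive' must lie in [0, total]", call. = FALSE)
  }
  p <- 100 * alive / total
  if (!is.null(digits)) p <- round(p, digits)
  p
}

#' Group-wise survival summary
#'
#' KM median, events, censorings and end-of-study survival percentage for
#' every group in an event table.
#'
#' @param records data.frame with `group`, `time`, `event` columns.
#' @return data.frame, one row per group: `group`, `n`, `events`,
#'   `censored`, `median_days` (NA if undefined), `surviving`,
#'   `percent_surviving`.
#' @export
survival_summary <- function(records) {
  stopifnot("group" %in% names(records))
  validate_survival(records)
  out <- do.call(rbind, lapply(split(records, records$group), function(g) {
    surv_n <- sum(g$event == 0)
    data.frame(group = g$group[1L], n = nrow(g), events = sum(g$event == 1),
               censored = surv_n,
               median_days = median_survival(km_curve(g)),
               surviving = surv_n,
               percent_surviving = survival_percent(surv_n, nrow(g), digits = 0),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
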