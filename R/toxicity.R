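#' Hematologic and enzymatic toxicity metrics
#'
#' Radioimmunotherapy transiently depresses blood counts: white blood cells
#' reach their nadir around day 3 after injection and platelets around day
#' 10, both recovering by about day 25. The headline metric is the nadir
#' percent decrease from the pre-treatment baseline, summarised per activity
#' group. Liver-enzyme panels (ASAT/ALAT, plus creatinine for renal
#' function) are flagged against configured normal ranges; no numeric limit
#' is hard-coded because ranges are strain- and laboratory-specific.
#'
#' @name toxicity
NULL

default_nadir_windows <- function() {
  list(wbc = c(1, 7), platelets = c(5, 15), rbc = c(1, 30))
}

#' Nadir percent decrease from baseline
#'
#' Baseline is the last sample at day <= 0 (pre-treatment); the nadir is the
#' minimum count inside the search window. The decrease is
#' 100 * (baseline - nadir) / baseline, floored at 0 when counts only rise.
#'
#' @param days,counts Sampling days (day 0 = treatment) and counts per mm3,
#'   equal length; a baseline sample at day <= 0 is required.
#' @param window Two-element day range searched for the nadir; defaults to
#'   the whole post-treatment series.
#' @return List with `percent_decrease`, `nadir_day`, `baseline`, `nadir`.
#' @export
nadir_percent_decrease <- function(days, counts, window = NULL) {
  stopifnot(length(days) == length(counts))
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("counts must be finite and >= 0", call. = FALSE)
  }
  if (is.unsorted(days)) {
    ord <- order(days); days <- days[ord]; counts <- counts[ord]
  }
  base_i <- which(days <= 0)
  if (!length(base_i)) {
    stop("no baseline sample (day <= 0) present", call. = FALSE)
  }
  baseline <- counts[max(base_i)]
  if (baseline <= 0) stop("baseline count is zero", call. = FALSE)
  if (is.null(window)) window <- c(min(days[days > 0], Inf), Inf)
  in_w <- days >= window[1L] & days <= window[2L]
  if (!any(in_w)) {
    stop("no samples inside the nadir window [", window[1L], ", ",
         window[2L], "]", call. = FALSE)
  }
  nadir_i <- which(in_w)[which.min(counts[in_w])]
  nadir <- counts[nadir_i]
  list(percent_decrease = max(0, 100 * (baseline - nadir) / baseline),
       nadir_day = days[nadir_i], baseline = baseline, nadir = nadir)
}

#' Per-group nadir-decrease summary
#'
#' Computes each animal's nadir percent decrease, then the group mean and
#' sample SD (per-animal first, then averaged). Groups with a single animal
#' report the mean with `sd = NA`. When groups are labelled by injected
#' activity (numeric-prefixed labels such as "370kBq"), the summary also
#' reports whether mean decreases are non-decreasing with activity.
#'
#' @param series data.frame with columns `animal`, `group`, `analyte`,
#'   `day`, `value` (counts per mm3).
#' @param analyte Analyte to summarise (`"wbc"`, `"platelets"`, `"rbc"`).
#' @param window Nadir search window; default per-analyte
#'   (`default_nadir_windows()`).
#' @return List with `summary` (data.frame: `group`, `n`, `mean`, `sd`,
#'   `mean_nadir_day`) and `monotone_in_activity` (logical or NA when group
#'   labels carry no activity).
#' @export
group_decrease_summary <- function(series, analyte, window = NULL) {
  need <- c("animal", "group", "analyte", "day", "value")
  missing <- setdiff(need, names(series))
  if (length(missing)) {
    stop("series missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  sub <- series[series$analyte == analyte, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no records for analyte '", analyte, "'",
                            call. = FALSE)
  if (is.null(window)) window <- default_nadir_windows()[[analyte]]
  per_animal <- do.call(rbind, lapply(
    split(sub, interaction(sub$group, sub$animal, drop = TRUE)),
    function(a) {
      nd <- nadir_percent_decrease(a$day, a$value, window)
      data.frame(group = a$group[1L], animal = a$animal[1L],
                 decrease = nd$percent_decrease, nadir_day = nd$nadir_day,
                 stringsAsFactors = FALSE)
    }))
  summary <- do.call(rbind, lapply(split(per_animal, per_animal$group),
    function(g) {
      data.frame(group = g$group[1L], n = nrow(g), mean = mean(g$decrease),
                 sd = if (nrow(g) > 1L) stats::sd(g$decrease) else NA_real_,
                 mean_nadir_day = mean(g$nadir_day),
                 stringsAsFactors = FALSE)
    }))
  rownames(summary) <- NULL
  act <- suppressWarnings(as.numeric(sub("^([0-9.]+).*$", "\\1",
                                         summary$group)))
  monotone <- if (any(is.na(act)) || length(act) < 2L) NA else {
    ord <- order(act)
    all(diff(summary$mean[ord]) >= 0)
  }
  list(summary = summary, monotone_in_activity = monotone)
}

#' Flag an enzyme value against a configured normal range
#'
#' Limits are inclusive: a value equal to either bound is `"normal"`.
#'
#' @param value Measured value (IU/L for ASAT/ALAT; the kit's units for
#'   creatinine).
#' @param analyte Analyte name, looked up in `limits`.
#' @param limits Named list: `limits[[analyte]]` is `c(lower, upper)`
#'   (use `0` for a one-sided upper limit).
#' @return `"below"`, `"normal"` or `"above"`.
#' @export
range_flag <- function(value, analyte, limits) {
  if (is.null(limits[[analyte]])) {
    stop("no normal range configured for analyte '", analyte, "'",
         call. = FALSE)
  }
  lim <- limits[[analyte]]
  stopifnot(length(lim) == 2L, lim[1L] <= lim[2L])
  vapply(value, function(v) {
    if (v < lim[1L]) "below" else if (v > lim[2L]) "above" else "normal"
  }, character(1))
}
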