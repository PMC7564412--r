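#' Biodistribution tables
#'
#' A biodistribution study records, for each sacrificed animal, the activity
#' retained in each organ at the sacrifice time, expressed as percent of the
#' injected dose per gram of tissue (%ID/g), or as percent of injected dose
#' (%ID) for organs counted whole (the neck, standing in for the thyroid).
#' Records carry a `decay_corrected` flag: gamma-counter output is normally
#' corrected back to injection time for physical decay, whereas dosimetry
#' integrates the UNcorrected curve so that physical decay is part of the
#' effective clearance.
#'
#' The container is a long-format data.frame of class `biodist_table` with
#' columns `animal`, `organ`, `time_h`, `value`, `unit`
#' (`"percent_id_per_gram"` or `"percent_id"`) and `decay_corrected`
#' (logical), plus attributes `injected_mbq`, `nuclide` and `study`.
#'
#' @name biodist
NULL

biodist_columns <- c("animal", "organ", "time_h", "value", "unit",
                     "decay_corrected")

new_biodist_table <- function(df, injected_mbq = NA_real_,
                              nuclide = "At-211", study = "") {
  structure(df,
            injected_mbq = injected_mbq, nuclide = nuclide, study = study,
            class = c("biodist_table", "data.frame"))
}

validate_biodist <- function(df) {
  missing <- setdiff(biodist_columns, names(df))
  if (length(missing)) {
    stop("biodistribution table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.finite(df$value) | df$value < 0)
  if (length(bad)) {
    stop("negative or non-finite value at row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.finite(df$time_h) | df$time_h < 0)
  if (length(bad)) {
    stop("negative or non-finite time_h at row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  ok_units <- c("percent_id_per_gram", "percent_id")
  if (!all(df$unit %in% ok_units)) {
    stop("unit must be one of: ", paste(ok_units, collapse = ", "),
         call. = FALSE)
  }
  invisible(df)
}

#' Read a biodistribution CSV
#'
#' Long ("tidy") layout, header `animal,organ,time_h,value,unit,
#' decay_corrected`. A wide dialect (one column per organ, rows
#' `animal,time_h,...`) is also supported; wide tables are assumed %ID/g and
#' decay-corrected unless stated via arguments.
#'
#' @param path CSV file path.
#' @param dialect `"long"` (default) or `"wide"`.
#' @param unit,decay_corrected Defaults applied when the dialect does not
#'   carry the column (wide dialect only).
#' @param injected_mbq,nuclide,study Metadata attached to the table.
#' @return A `biodist_table`.
#' @export
read_biodistribution <- function(path, dialect = c("long", "wide"),
                                 unit = "percent_id_per_gram",
                                 decay_corrected = TRUE,
                                 injected_mbq = NA_real_, nuclide = "At-211",
                                 study = "") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop("cannot parse ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  if (nrow(df) == 0L || ncol(df) == 0L) {
    stop("empty biodistribution file: ", path, call. = FALSE)
  }
  if (dialect == "wide") {
    id <- intersect(c("animal", "time_h"), names(df))
    if (length(id) < 2L) {
      stop("wide dialect requires columns 'animal' and 'time_h'", call. = FALSE)
    }
    organs <- setdiff(names(df), id)
    df <- data.frame(
      animal = rep(df$animal, times = length(organs)),
      organ = rep(organs, each = nrow(df)),
      time_h = rep(df$time_h, times = length(organs)),
      value = unlist(df[organs], use.names = FALSE),
      unit = unit,
      decay_corrected = decay_corrected,
      stringsAsFactors = FALSE
    )
  }
  if ("decay_corrected" %in% names(df)) {
    df$decay_corrected <- as.logical(df$decay_corrected)
  }
  validate_biodist(df)
  new_biodist_table(df, injected_mbq = injected_mbq, nuclide = nuclide,
                    study = study)
}

#' Write a biodistribution table as CSV
#'
#' @param table A `biodist_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_biodistribution <- function(table, path) {
  validate_biodist(table)
  utils::write.csv(as.data.frame(table)[biodist_columns], path,
                   row.names = FALSE, quote = FALSE)
  message(sprintf("wrote %d biodistribution records to %s", nrow(table), path))
  invisible(path)
}

#' Per-organ, per-timepoint summary
#'
#' Arithmetic mean, sample SD (n - 1 denominator) and animal count for every
#' (organ, time) group, the summary a biodistribution figure displays.
#'
#' @param table A `biodist_table`.
#' @return data.frame with columns `organ`, `time_h`, `unit`, `n`, `mean`,
#'   `sd` (NA when n = 1).
#' @export
summarize_biodistribution <- function(table) {
  validate_biodist(table)
  df <- as.data.frame(table)
  key <- interaction(df$organ, df$time_h, drop = TRUE)
  out <- do.call(rbind, lapply(split(df, key), function(g) {
    data.frame(organ = g$organ[1L], time_h = g$time_h[1L], unit = g$unit[1L],
               n = nrow(g), mean = mean(g$value),
               sd = if (nrow(g) > 1L) stats::sd(g$value) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$organ, out$time_h), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Convert between decay-corrected and uncorrected scales
#'
#' Decay-corrected values are rescaled to the time of injection; uncorrected
#' values reflect the physically decayed activity actually present at
#' sacrifice. Converting corrected -> uncorrected multiplies each value by
#' exp(-lambda * time); the reverse divides. The conversion is exactly
#' invertible.
#'
#' @param table A `biodist_table` with a uniform `decay_corrected` flag.
#' @param lambda Physical decay constant, h^-1 (> 0).
#' @param target Desired `decay_corrected` state (TRUE/FALSE).
#' @return A `biodist_table` on the requested scale.
#' @export
set_decay_correction <- function(table, lambda, target) {
  validate_biodist(table)
  stopifnot(is.numeric(lambda), length(lambda) == 1L, lambda > 0,
            is.logical(target), length(target) == 1L, !is.na(target))
  state <- unique(table$decay_corrected)
  if (length(state) != 1L) {
    stop("table mixes decay-corrected and uncorrected records; ",
         "split before converting", call. = FALSE)
  }
  if (identical(state, target)) return(table)
  f <- decay_factor(table$time_h, lambda)
  table$value <- if (state && !target) table$value * f else table$value / f
  table$decay_corrected <- target
  table
}

#' @export
print.biodist_table <- function(x, ...) {
  cat(sprintf("<biodist_table> %d records, %d organs, %d timepoints (%s)\n",
              nrow(x), length(unique(x$organ)), length(unique(x$time_h)),
              if (all(x$decay_corrected)) "decay-corrected"
              else if (!any(x$decay_corrected)) "uncorrected" else "mixed"))
  print(utils::head(as.data.frame(x), 6L), row.names = FALSE)
  if (nrow(x) > 6L) cat(sprintf("  ... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}
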