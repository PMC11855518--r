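#' Apply the cohort inclusion filter
#'
#' Retains complete, non-traumatic, adult (age >= 18) OHCA records whose
#' ambulance response time is within 20 minutes (<= 1200 s, inclusive).
#' The response-time restriction reflects both the therapeutic window for
#' defibrillation and data-entry reliability of manually recorded times.
#' Input order is preserved; the filter is idempotent.
#'
#' @param events event data.frame (see [simulate_events()]).
#' @param max_response_s inclusion cut-off in seconds (default 1200).
#' @return the retained rows, order preserved.
#' @export
filter_ohca <- function(events, max_response_s = 1200) {
  need <- c("age", "traumatic", "response_time_s", "complete")
  miss <- setdiff(need, names(events))
  if (length(miss))
    stop("events missing required columns: ", paste(miss, collapse = ", "))
  keep <- events$complete & !events$traumatic & events$age >= 18 &
    events$response_time_s <= max_response_s
  keep[is.na(keep)] <- FALSE
  events[keep, , drop = FALSE]
}

#' Descriptive cohort summary
#'
#' Summarises a filtered OHCA cohort: medians with interquartile ranges
#' (linear interpolation between order statistics, quantile type 7) for
#' age, response time, dispatch time and CPR duration; absolute and
#' relative frequencies for bystander CPR, sex, death and shockable
#' rhythm; response-time bins 0-5 / 5-10 / >10 min (left-closed,
#' [0,300), [300,600), [600,1200]); and the shockable-rhythm breakdown
#' across those bins (percents against the shockable denominator).
#'
#' @param events filtered event data.frame (non-empty).
#' @return object of class \code{cohort_summary}.
#' @examples
#' s <- cohort_summary(reference_cohort())
#' s$frequencies$bystander_cpr
#' @export
cohort_summary <- function(events) {
  if (is.null(events) || nrow(events) == 0)
    stop("cannot summarise an empty cohort")
  n <- nrow(events)

  med_iqr <- function(x) {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    c(median = q[2], q1 = q[1], q3 = q[3])
  }
  medians_iqr <- list(
    age = med_iqr(events$age),
    response_time_s = med_iqr(events$response_time_s),
    dispatch_time_s = med_iqr(events$dispatch_time_s),
    cpr_duration_s = med_iqr(events$cpr_duration_s)
  )

  freq_tab <- function(x, levels) {
    cnt <- vapply(levels, function(l) sum(x == l), integer(1))
    data.frame(level = levels, count = cnt,
               percent = round(100 * cnt / n, 2),
               stringsAsFactors = FALSE)
  }
  frequencies <- list(
    bystander_cpr = freq_tab(events$bystander_cpr, c("yes", "no", "unknown")),
    sex = freq_tab(events$sex, c("male", "female")),
    death = freq_tab(ifelse(events$death, "yes", "no"), c("yes", "no")),
    shockable = freq_tab(ifelse(events$shockable, "yes", "no"),
                         c("yes", "no"))
  )

  bin <- response_bin(events$response_time_s)
  bins <- c("0-5 min", "5-10 min", ">10 min")
  bin_cnt <- vapply(bins, function(b) sum(bin == b), integer(1))
  response_bins <- data.frame(
    bin = bins, count = bin_cnt, percent = round(100 * bin_cnt / n, 2),
    stringsAsFactors = FALSE
  )

  sh <- events$shockable
  n_sh <- sum(sh)
  sh_cnt <- vapply(bins, function(b) sum(bin == b & sh), integer(1))
  shockable_by_bin <- data.frame(
    bin = bins, count = sh_cnt,
    percent = if (n_sh > 0) round(100 * sh_cnt / n_sh, 2) else rep(NA_real_, 3),
    stringsAsFactors = FALSE
  )

  structure(list(
    n = n,
    medians_iqr = medians_iqr,
    frequencies = frequencies,
    response_bins = response_bins,
    shockable_by_bin = shockable_by_bin
  ), class = "cohort_summary")
}

# left-closed response-time bins in seconds
response_bin <- function(t_s) {
  ifelse(t_s < 300, "0-5 min", ifelse(t_s < 600, "5-10 min", ">10 min"))
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("OHCA cohort summary (n = %d)\n", x$n))
  for (v in names(x$medians_iqr)) {
    m <- x$medians_iqr[[v]]
    cat(sprintf("  %-16s median %.1f (IQR %.1f-%.1f)\n", v, m[1], m[2], m[3]))
  }
  for (v in names(x$frequencies)) {
    f <- x$frequencies[[v]]
    cat(sprintf("  %s: %s\n", v,
                paste(sprintf("%s %d (%.2f%%)", f$level, f$count, f$percent),
                      collapse = ", ")))
  }
  rb <- x$response_bins
  cat("  response bins:",
      paste(sprintf("%s %d (%.2f%%)", rb$bin, rb$count, rb$percent),
            collapse = ", "), "\n")
  sb <- x$shockable_by_bin
  cat("  shockable by bin:",
      paste(sprintf("%s %d (%.2f%%)", sb$bin, sb$count, sb$percent),
            collapse = ", "), "\n")
  invisible(x)
}

#' Serialise a cohort summary to JSON
#'
#' @param x a \code{cohort_summary}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_summary_json <- function(x, path) {
  stopifnot(inherits(x, "cohort_summary"))
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
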