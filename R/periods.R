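#' Observation periods of the pre-post design
#'
#' The design surveys utilization retrospectively at four interviews:
#' baseline covers the 6 months before first contact (\code{pre6m}), and the
#' three follow-up interviews cover the intervals baseline to 3 months
#' (\code{fu1}), 3 to 6 months (\code{fu2}) and 6 to 12 months (\code{fu3}),
#' so the follow-ups jointly cover the 12 months under study. Periods map to
#' the two reporting windows: the (annualized) year before counseling
#' (\code{pre12m}) and the study year (\code{post12m}).
#'
#' @return A data.frame with columns \code{period}, \code{months},
#'   \code{window} and \code{visit} (the interview index closing the period).
#' @examples
#' period_table()
#' @export
period_table <- function() {
  data.frame(
    period = c("pre6m", "fu1", "fu2", "fu3"),
    months = c(6, 3, 3, 6),
    window = c("pre12m", "post12m", "post12m", "post12m"),
    visit  = c(0L, 1L, 2L, 3L),
    stringsAsFactors = FALSE
  )
}

PERIODS <- c("pre6m", "fu1", "fu2", "fu3")
FOLLOWUP_PERIODS <- c("fu1", "fu2", "fu3")

period_months <- function(period) {
  pt <- period_table()
  pt$months[match(period, pt$period)]
}

check_period <- function(period, name = "period") {
  bad <- setdiff(unique(period), PERIODS)
  if (length(bad))
    stop_("'%s' contains unknown period(s): %s (allowed: %s)", name,
          paste(bad, collapse = ", "), paste(PERIODS, collapse = ", "))
  invisible(period)
}
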