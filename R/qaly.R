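#' Area-under-the-curve QALYs for the study year
#'
#' Integrates the utility trajectory over the 12 months under study,
#' assuming a linear change between the survey dates (trapezoid rule). The
#' default visit times are the nominal interview dates at 0, 3, 6 and 12
#' months, expressed in years.
#'
#' @param utilities Numeric utilities at the visit times (complete, i.e.
#'   post-LOCF).
#' @param visit_times Strictly increasing times in years, starting at 0 and
#'   ending at 1 (one-year horizon).
#' @return The QALY accrued over the year (a single number).
#' @examples
#' qaly_post(c(0.5, 0.5, 0.5, 0.5))            # 0.5
#' qaly_post(c(0, 1), visit_times = c(0, 1))   # 0.5 (linear ramp)
#' @export
qaly_post <- function(utilities, visit_times = c(0, 0.25, 0.5, 1)) {
  if (length(utilities) != length(visit_times))
    stop_("utilities and visit_times must have equal length")
  if (anyNA(utilities))
    stop_("incomplete trajectory: impute first (see impute_qol_locf)")
  if (length(visit_times) < 2 || any(diff(visit_times) <= 0))
    stop_("visit_times must be strictly increasing")
  if (visit_times[1] != 0 || visit_times[length(visit_times)] != 1)
    stop_("visit_times must span one year (start 0, end 1)")
  dt <- diff(visit_times)
  sum(dt * (utilities[-length(utilities)] + utilities[-1]) / 2)
}

#' Pre-period QALY from the baseline utility
#'
#' The health-state utility measured at baseline is assumed stable during
#' the year before first contact, so the pre-period QALY equals the
#' baseline utility times one year.
#'
#' @param baseline_utility Utility in (0, 1].
#' @return QALY over the year before baseline.
#' @examples
#' qaly_pre(0.6051)
#' @export
qaly_pre <- function(baseline_utility) {
  if (any(!is.finite(baseline_utility) | baseline_utility <= 0 |
            baseline_utility > 1))
    stop_("baseline utility must lie in (0, 1]")
  baseline_utility
}

#' Pair pre- and post-period QALYs and their difference
#'
#' \code{delta = qaly_post - qaly_pre}, the QALYs gained over the study
#' year relative to the stable-baseline counterfactual.
#'
#' @param qaly_pre,qaly_post Per-client QALYs over one year each.
#' @param client_id Optional client identifiers.
#' @return Data.frame \code{client_id}, \code{qaly_pre}, \code{qaly_post},
#'   \code{delta}.
#' @examples
#' qaly_pair(0.6050, 0.6618)$delta  # 0.0568
#' @export
qaly_pair <- function(qaly_pre, qaly_post, client_id = NULL) {
  if (length(qaly_pre) != length(qaly_post))
    stop_("qaly_pre and qaly_post must have equal length")
  if (is.null(client_id)) client_id <- as.character(seq_along(qaly_pre))
  data.frame(client_id = as.character(client_id),
             qaly_pre = qaly_pre, qaly_post = qaly_post,
             delta = qaly_post - qaly_pre, stringsAsFactors = FALSE)
}

#' Per-client QALY pairs from completed utility trajectories
#'
#' Computes, for every client, the pre-period QALY (stable baseline
#' utility) and the post-period QALY (trapezoid area under the utility
#' trajectory), and their difference. QALYs are computed per client and
#' then averaged; with shared nominal visit times this coincides with the
#' area under the mean trajectory.
#'
#' @param trajectories Completed trajectories
#'   (\code{\link{impute_qol_locf}} output).
#' @param visit_times Interview times in years (see
#'   \code{\link{qaly_post}}).
#' @return Data.frame of \code{\link{qaly_pair}} rows; cohort means are
#'   attached as attribute \code{"means"}.
#' @export
qaly_pairs <- function(trajectories, visit_times = c(0, 0.25, 0.5, 1)) {
  check_columns(trajectories, c("client_id", "visit", "utility"),
                "trajectories")
  if (anyNA(trajectories$utility))
    stop_("incomplete trajectories: impute first (see impute_qol_locf)")
  tr <- trajectories[order(trajectories$client_id, trajectories$visit), ]
  ids <- unique(tr$client_id)
  pre <- post <- numeric(length(ids))
  for (i in seq_along(ids)) {
    u <- tr$utility[tr$client_id == ids[i]]
    if (length(u) != length(visit_times))
      stop_("client %s has %d visits, expected %d", ids[i], length(u),
            length(visit_times))
    pre[i] <- qaly_pre(u[1])
    post[i] <- qaly_post(u, visit_times)
  }
  out <- qaly_pair(pre, post, client_id = ids)
  attr(out, "means") <- c(qaly_pre = mean(pre), qaly_post = mean(post),
                          delta = mean(post - pre))
  out
}
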