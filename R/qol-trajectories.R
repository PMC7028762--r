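#' Build per-client utility trajectories from SF-12 responses
#'
#' Scores each client-visit into an SF-6D state and applies the preference
#' tariff. Visits without a complete response (including visits after a
#' client left the study) are \code{NA} and flagged unobserved; complete
#' trajectories are obtained with \code{\link{impute_qol_locf}}.
#'
#' @param responses SF-12 response data.frame (one row per client-visit).
#' @param tariff An \code{\link{sf6d_tariff}}.
#' @return Data.frame with one row per client and visit 0..3:
#'   \code{client_id}, \code{visit}, \code{utility}, \code{observed},
#'   \code{imputed}.
#' @export
utility_trajectories <- function(responses, tariff = sf6d_tariff()) {
  states <- sf12_to_sf6d(responses)
  states$utility <- sf6d_utility(states, tariff)
  ids <- unique(states$client_id)
  grid <- expand.grid(client_id = ids, visit = 0:3,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  m <- merge(grid, states[, c("client_id", "visit", "utility")],
             by = c("client_id", "visit"), all.x = TRUE)
  dup <- duplicated(m[, c("client_id", "visit")])
  if (any(dup)) stop_("duplicate client-visit responses")
  m$observed <- !is.na(m$utility)
  m$imputed <- FALSE
  m[order(m$client_id, m$visit), , drop = FALSE]
}

#' Complete utility trajectories by last observation carried forward
#'
#' Missing follow-up utilities are replaced by the client's most recent
#' observed utility, carried forward until the 12-month follow-up. The
#' baseline utility must be observed for every client (clients without a
#' scorable baseline are excluded upstream); baseline is never imputed.
#'
#' @param trajectories Output of \code{\link{utility_trajectories}}.
#' @return Same shape, with \code{utility} complete and \code{imputed}
#'   flags set on carried-forward visits. Idempotent, and independent of
#'   client order.
#' @export
impute_qol_locf <- function(trajectories) {
  check_columns(trajectories, c("client_id", "visit", "utility"),
                "trajectories")
  tr <- trajectories[order(trajectories$client_id, trajectories$visit), ,
                     drop = FALSE]
  if (!"imputed" %in% names(tr)) tr$imputed <- FALSE
  base <- tr$visit == 0
  if (any(is.na(tr$utility[base]))) {
    off <- tr$client_id[base & is.na(tr$utility)]
    stop_("missing baseline utility for client(s): %s",
          paste(off, collapse = ", "))
  }
  for (cid in unique(tr$client_id)) {
    i <- which(tr$client_id == cid)
    u <- tr$utility[i]
    miss <- is.na(u)
    for (k in seq_along(u)[-1]) if (is.na(u[k])) u[k] <- u[k - 1]
    tr$utility[i] <- u
    tr$imputed[i] <- tr$imputed[i] | miss
  }
  rownames(tr) <- NULL
  tr
}
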