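#' SF-12 item metadata
#'
#' The 12-item short-form health survey (version 1) items used throughout
#' the package, with their admissible response ranges and raw coding. Item
#' columns in response tables must use these names.
#'
#' \describe{
#'   \item{gh1}{general health, 1 = excellent .. 5 = poor}
#'   \item{pf02, pf04}{moderate activities / climbing stairs,
#'     1 = limited a lot .. 3 = not limited}
#'   \item{rp2, rp3}{role-physical: accomplished less / limited in kind of
#'     work, 1 = yes, 2 = no}
#'   \item{re2, re3}{role-emotional: accomplished less / less careful,
#'     1 = yes, 2 = no}
#'   \item{bp2}{pain interference, 1 = not at all .. 5 = extremely}
#'   \item{mh3, vt2}{calm and peaceful / energy,
#'     1 = all of the time .. 6 = none of the time}
#'   \item{mh4}{downhearted and blue, 1 = all of the time .. 6 = none}
#'   \item{sf2}{social interference, 1 = all of the time .. 5 = none}
#' }
#'
#' @return Data.frame with columns \code{item}, \code{n_levels},
#'   \code{best_level} (the response level denoting best health).
#' @export
sf12_items <- function() {
  data.frame(
    item = c("gh1", "pf02", "pf04", "rp2", "rp3", "re2", "re3",
             "bp2", "mh3", "vt2", "mh4", "sf2"),
    n_levels = c(5L, 3L, 3L, 2L, 2L, 2L, 2L, 5L, 6L, 6L, 6L, 5L),
    best_level = c(1L, 3L, 3L, 2L, 2L, 2L, 2L, 1L, 1L, 1L, 6L, 5L),
    stringsAsFactors = FALSE
  )
}

#' Load SF-12 component-summary scoring weights
#'
#' Norm-based PCS-12 / MCS-12 scoring: item responses are expanded into
#' level indicators, multiplied by published regression weights, summed and
#' shifted by published constants so that the general population scores a
#' mean of 50 (SD 10) on both components. The shipped default is the public
#' US 1998 weight set for SF-12 version 1; alternative weight files (e.g. a
#' national adaptation) with the same layout can be supplied.
#'
#' @param path CSV with columns \code{item}, \code{level},
#'   \code{pcs_weight}, \code{mcs_weight}; the row with
#'   \code{item == "_constant"} carries the two regression constants.
#'   \code{NULL} loads the shipped default.
#' @return Object of class \code{"sf12_weights"}: list with \code{weights},
#'   \code{constants}, \code{path}, \code{checksum} (md5 of the file).
#' @export
sf12_weights <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "sf12_weights_us1998.csv",
                        package = "prepostCEA", mustWork = TRUE)
  if (!file.exists(path)) stop_("SF-12 weight file not found: %s", path)
  w <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  check_columns(w, c("item", "level", "pcs_weight", "mcs_weight"),
                "SF-12 weights")
  const <- w[w$item == "_constant", , drop = FALSE]
  if (nrow(const) != 1L)
    stop_("SF-12 weight file must contain exactly one '_constant' row")
  w <- w[w$item != "_constant", , drop = FALSE]
  meta <- sf12_items()
  miss <- setdiff(meta$item, unique(w$item))
  if (length(miss))
    stop_("SF-12 weight file lacks item(s): %s", paste(miss, collapse = ", "))
  structure(list(weights = w,
                 constants = c(pcs = const$pcs_weight,
                               mcs = const$mcs_weight),
                 path = path, checksum = file_md5(path)),
            class = "sf12_weights")
}

check_sf12_responses <- function(responses) {
  meta <- sf12_items()
  check_columns(responses, c("client_id", "visit", meta$item), "responses")
  if (any(!responses$visit %in% 0:3))
    stop_("'visit' must be in 0..3")
  for (i in seq_len(nrow(meta))) {
    v <- responses[[meta$item[i]]]
    bad <- !is.na(v) & (v < 1 | v > meta$n_levels[i] | v != round(v))
    if (any(bad))
      stop_("item '%s' has out-of-range responses (admissible 1..%d)",
            meta$item[i], meta$n_levels[i])
  }
  invisible(responses)
}

#' Score SF-12 responses into PCS and MCS component summaries
#'
#' Complete-case per visit: a response with any missing item yields
#' \code{NA} scores, signalling the caller to treat the visit as unobserved
#' (handled downstream by LOCF on utilities).
#'
#' @param responses Data.frame with \code{client_id}, \code{visit} and the
#'   twelve item columns of \code{\link{sf12_items}}.
#' @param weights An \code{\link{sf12_weights}} object.
#' @return Data.frame \code{client_id}, \code{visit}, \code{pcs},
#'   \code{mcs}.
#' @export
score_sf12 <- function(responses, weights = sf12_weights()) {
  check_sf12_responses(responses)
  if (!inherits(weights, "sf12_weights"))
    stop_("'weights' must be an sf12_weights object")
  meta <- sf12_items()
  n <- nrow(responses)
  pcs <- rep(weights$constants[["pcs"]], n)
  mcs <- rep(weights$constants[["mcs"]], n)
  complete <- rep(TRUE, n)
  w <- weights$weights
  for (it in meta$item) {
    v <- responses[[it]]
    complete <- complete & !is.na(v)
    wi <- w[w$item == it, , drop = FALSE]
    k <- match(v, wi$level)
    unk <- !is.na(v) & is.na(k)
    if (any(unk))
      stop_("no weight for item '%s' level(s) %s", it,
            paste(unique(v[unk]), collapse = ", "))
    pw <- wi$pcs_weight[k]
    mw <- wi$mcs_weight[k]
    pw[is.na(pw)] <- 0
    mw[is.na(mw)] <- 0
    pcs <- pcs + pw
    mcs <- mcs + mw
  }
  pcs[!complete] <- NA_real_
  mcs[!complete] <- NA_real_
  data.frame(client_id = as.character(responses$client_id),
             visit = responses$visit, pcs = pcs, mcs = mcs,
             stringsAsFactors = FALSE)
}
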