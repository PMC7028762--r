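#' SF-6D dimension metadata (SF-12 variant)
#'
#' The SF-6D health-state classification derivable from SF-12 responses has
#' six dimensions; level 1 is always the best level.
#'
#' @return Data.frame with columns \code{dimension}, \code{n_levels}.
#' @export
sf6d_dimensions <- function() {
  data.frame(dimension = c("pf", "rl", "sf", "pain", "mh", "vit"),
             n_levels = c(3L, 4L, 5L, 5L, 5L, 5L),
             stringsAsFactors = FALSE)
}

#' Classify SF-12 responses into SF-6D health states
#'
#' Deterministic item-to-dimension mapping of the SF-6D (SF-12 variant):
#' physical functioning from moderate-activity limitation (\code{pf02});
#' role limitation from the two accomplished-less items (\code{rp2},
#' \code{re2}: neither / physical / emotional / both); social functioning
#' from \code{sf2} (reversed); pain from \code{bp2}; mental health from
#' \code{mh4} (reversed; the two middle frequency levels collapse to one);
#' vitality from \code{vt2} (middle levels collapsed likewise). Rows with a
#' missing required item yield an all-\code{NA} state (missing-state
#' signal).
#'
#' @param responses SF-12 response data.frame (see
#'   \code{\link{score_sf12}}).
#' @return Data.frame \code{client_id}, \code{visit}, \code{pf}, \code{rl},
#'   \code{sf}, \code{pain}, \code{mh}, \code{vit}.
#' @export
sf12_to_sf6d <- function(responses) {
  check_sf12_responses(responses)
  pf02 <- responses$pf02; rp2 <- responses$rp2; re2 <- responses$re2
  sf2 <- responses$sf2; bp2 <- responses$bp2
  mh4 <- responses$mh4; vt2 <- responses$vt2

  pf <- c(3L, 2L, 1L)[pf02]                       # limited a lot -> level 3
  rl <- ifelse(rp2 == 1 & re2 == 1, 4L,
        ifelse(re2 == 1, 3L, ifelse(rp2 == 1, 2L, 1L)))
  sf <- 6L - sf2                                  # none of the time -> 1
  pain <- bp2                                     # not at all -> 1
  mh <- c(5L, 4L, 3L, 3L, 2L, 1L)[mh4]            # all of the time -> 5
  vit <- c(1L, 2L, 3L, 3L, 4L, 5L)[vt2]           # all of the time -> 1

  st <- data.frame(client_id = as.character(responses$client_id),
                   visit = responses$visit,
                   pf = pf, rl = as.integer(rl), sf = as.integer(sf),
                   pain = as.integer(pain), mh = mh, vit = vit,
                   stringsAsFactors = FALSE)
  dims <- sf6d_dimensions()$dimension
  incomplete <- rowSums(is.na(st[dims])) > 0
  st[incomplete, dims] <- NA_integer_
  st
}

#' Load an SF-6D preference tariff
#'
#' The tariff is an additive-decrement model: utility equals 1 minus the sum
#' of the level decrements of the six dimensions, minus a single
#' \code{most} penalty applied when any dimension is at its most severe
#' level. The shipped default file is a SYNTHETIC stand-in with the
#' published model structure (monotone decrements, floor 0.345) because the
#' licensed Sheffield preference weights are not redistributable; supply a
#' licensed coefficient file with the same layout for substantive use.
#'
#' @param path CSV with columns \code{dimension}, \code{level},
#'   \code{decrement}; the row with \code{dimension == "most"} carries the
#'   severe-state penalty. \code{NULL} loads the shipped synthetic default.
#' @return Object of class \code{"sf6d_tariff"}: list with
#'   \code{decrements} (matrix lookup), \code{most}, \code{floor},
#'   \code{path}, \code{checksum}.
#' @export
sf6d_tariff <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "sf6d_sf12_tariff_synthetic.csv",
                        package = "prepostCEA", mustWork = TRUE)
  if (!file.exists(path)) stop_("SF-6D tariff file not found: %s", path)
  tf <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  check_columns(tf, c("dimension", "level", "decrement"), "SF-6D tariff")
  most <- tf$decrement[tf$dimension == "most"]
  if (length(most) != 1L)
    stop_("tariff must contain exactly one 'most' row")
  dims <- sf6d_dimensions()
  dec <- vector("list", nrow(dims))
  names(dec) <- dims$dimension
  for (i in seq_len(nrow(dims))) {
    d <- dims$dimension[i]
    rows <- tf[tf$dimension == d, , drop = FALSE]
    rows <- rows[order(rows$level), , drop = FALSE]
    if (!identical(rows$level, seq_len(dims$n_levels[i])))
      stop_("tariff dimension '%s' must have levels 1..%d", d,
            dims$n_levels[i])
    if (rows$decrement[1] != 0)
      stop_("tariff level 1 of '%s' must have decrement 0", d)
    if (is.unsorted(rows$decrement))
      stop_("tariff decrements of '%s' must be nondecreasing in level", d)
    dec[[d]] <- rows$decrement
  }
  floor_u <- 1 - sum(vapply(dec, max, 0)) - most
  structure(list(decrements = dec, most = most, floor = floor_u,
                 path = path, checksum = file_md5(path)),
            class = "sf6d_tariff")
}

#' Preference-weighted utility of SF-6D health states
#'
#' Applies the additive-decrement model of the loaded tariff. The best
#' state (all dimensions at level 1) has utility 1; every emitted utility
#' lies in \code{[tariff floor, 1]}.
#'
#' @param states Data.frame with the six dimension columns of
#'   \code{\link{sf6d_dimensions}} (e.g. output of
#'   \code{\link{sf12_to_sf6d}}); all-\code{NA} rows yield \code{NA}.
#' @param tariff An \code{\link{sf6d_tariff}}.
#' @return Numeric vector of utilities, one per row of \code{states}.
#' @export
sf6d_utility <- function(states, tariff = sf6d_tariff()) {
  if (!inherits(tariff, "sf6d_tariff"))
    stop_("'tariff' must be an sf6d_tariff object")
  dims <- sf6d_dimensions()
  check_columns(states, dims$dimension, "states")
  n <- nrow(states)
  u <- rep(1, n)
  any_worst <- rep(FALSE, n)
  ok <- rep(TRUE, n)
  for (i in seq_len(nrow(dims))) {
    d <- dims$dimension[i]
    lev <- states[[d]]
    ok <- ok & !is.na(lev)
    valid <- !is.na(lev)
    if (any(valid & (lev < 1 | lev > dims$n_levels[i])))
      stop_("dimension '%s' has levels outside 1..%d", d, dims$n_levels[i])
    u[valid] <- u[valid] - tariff$decrements[[d]][lev[valid]]
    any_worst[valid] <- any_worst[valid] | lev[valid] == dims$n_levels[i]
  }
  u <- u - tariff$most * any_worst
  u[!ok] <- NA_real_
  u
}
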