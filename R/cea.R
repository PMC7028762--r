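#' Per-client total costs in the two 12-month windows
#'
#' Collapses an expenditure table to one row per client with the
#' (annualized) pre-window and post-window totals, zero-filled for clients
#' without any recorded cost.
#'
#' @param expenditure Expenditure table (after LOCF and counseling fee).
#' @param clients Client data.frame with \code{client_id} (or a vector of
#'   ids).
#' @param annualize Double the 6-month pre period (default \code{TRUE}).
#' @return Data.frame \code{client_id}, \code{cost_pre}, \code{cost_post}.
#' @export
client_total_costs <- function(expenditure, clients, annualize = TRUE) {
  ids <- if (is.data.frame(clients)) as.character(clients$client_id)
         else as.character(clients)
  cw <- client_window_costs(expenditure, ids, annualize = annualize)
  tot <- stats::aggregate(eur ~ client_id + window, data = cw, FUN = sum)
  pre <- tot[tot$window == "pre12m", c("client_id", "eur")]
  post <- tot[tot$window == "post12m", c("client_id", "eur")]
  m <- merge(pre, post, by = "client_id", suffixes = c("_pre", "_post"))
  names(m) <- c("client_id", "cost_pre", "cost_post")
  m[match(ids, m$client_id), , drop = FALSE]
}

#' Per-client pre-post differences of costs and QALYs
#'
#' Pairs each client's cost difference (post 12 months minus annualized pre
#' 12 months, EUR) with the QALY difference, keeping the within-client
#' correlation that the bootstrap relies on.
#'
#' @param costs Data.frame \code{client_id}, \code{cost_pre},
#'   \code{cost_post} (see \code{\link{client_total_costs}}).
#' @param qalys Data.frame of \code{\link{qaly_pairs}}.
#' @return Data.frame \code{client_id}, \code{delta_cost},
#'   \code{delta_qaly}; cohort means attached as attribute \code{"means"}.
#' @export
client_deltas <- function(costs, qalys) {
  check_columns(costs, c("client_id", "cost_pre", "cost_post"), "costs")
  check_columns(qalys, c("client_id", "delta"), "qalys")
  a <- setdiff(costs$client_id, qalys$client_id)
  b <- setdiff(qalys$client_id, costs$client_id)
  if (length(a) || length(b))
    stop_("client sets differ between costs and QALYs%s%s",
          if (length(a)) paste0("; only in costs: ",
                                paste(a, collapse = ", ")) else "",
          if (length(b)) paste0("; only in QALYs: ",
                                paste(b, collapse = ", ")) else "")
  m <- merge(costs, qalys[, c("client_id", "delta")], by = "client_id")
  out <- data.frame(client_id = m$client_id,
                    delta_cost = m$cost_post - m$cost_pre,
                    delta_qaly = m$delta, stringsAsFactors = FALSE)
  attr(out, "means") <- c(delta_cost = mean(out$delta_cost),
                          delta_qaly = mean(out$delta_qaly))
  out
}

#' Classify a point on the cost-effectiveness plane
#'
#' Quadrants of the (\eqn{\Delta}QALY, \eqn{\Delta}cost) plane:
#' \code{"dominant"} (more effect, lower cost; no ICER), \code{"northeast"}
#' (more effect, higher cost; ICER = \eqn{\Delta}cost/\eqn{\Delta}QALY),
#' \code{"dominated"} (less effect, higher cost), \code{"southwest"} (less
#' effect, lower cost; ICER reported with its quadrant label). A zero
#' effect difference leaves the ICER undefined.
#'
#' @param delta_cost Mean cost difference (EUR).
#' @param delta_qaly Mean QALY difference.
#' @return List with \code{quadrant}, \code{icer} (\code{NA} when
#'   undefined or dominant/dominated) and \code{icer_defined}.
#' @examples
#' classify_quadrant(-1482, 0.0568)$quadrant  # "dominant"
#' classify_quadrant(568, 0.0568)$icer        # 10000
#' @export
classify_quadrant <- function(delta_cost, delta_qaly) {
  check_number(delta_cost, "delta_cost")
  check_number(delta_qaly, "delta_qaly")
  if (delta_qaly == 0)
    return(list(quadrant = if (delta_cost >= 0) "no effect, higher cost"
                           else "no effect, lower cost",
                icer = NA_real_, icer_defined = FALSE))
  q <- if (delta_qaly > 0 && delta_cost < 0) "dominant"
       else if (delta_qaly > 0 && delta_cost >= 0) "northeast"
       else if (delta_qaly < 0 && delta_cost > 0) "dominated"
       else "southwest"
  icer <- if (q %in% c("northeast", "southwest"))
    delta_cost / delta_qaly else NA_real_
  list(quadrant = q, icer = icer, icer_defined = !is.na(icer))
}

#' Bootstrap the cost-effectiveness plane
#'
#' Nonparametric client-level bootstrap: each replicate resamples the n
#' clients with replacement (n out of n), keeping each client's
#' (\eqn{\Delta}cost, \eqn{\Delta}QALY) pair intact, and records the
#' resampled means. Deterministic for a fixed seed.
#'
#' @param deltas \code{\link{client_deltas}} output.
#' @param B Number of bootstrap replicates (>= 1).
#' @param seed Integer seed for the resampling.
#' @return Data.frame with \code{B} rows: \code{draw},
#'   \code{delta_cost}, \code{delta_qaly}.
#' @export
bootstrap_ce <- function(deltas, B = 1000, seed = 1L) {
  check_columns(deltas, c("delta_cost", "delta_qaly"), "deltas")
  check_number(B, "B", lower = 1, integer = TRUE)
  n <- nrow(deltas)
  if (n < 1L) stop_("at least one client required")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  dc <- dq <- numeric(B)
  for (b in seq_len(B)) {
    i <- sample.int(n, n, replace = TRUE)
    dc[b] <- mean(deltas$delta_cost[i])
    dq[b] <- mean(deltas$delta_qaly[i])
  }
  data.frame(draw = seq_len(B), delta_cost = dc, delta_qaly = dq)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay threshold \eqn{\lambda}, the probability of
#' cost-effectiveness is the fraction of bootstrap replicates with positive
#' net monetary benefit, \eqn{\lambda \Delta QALY - \Delta cost > 0}
#' (strict inequality; ties count as not cost-effective).
#'
#' @param draws Bootstrap draws (\code{\link{bootstrap_ce}} output or a
#'   fitted \code{\link{cea}} object).
#' @param lambda Nonnegative thresholds, EUR per QALY.
#' @return Data.frame \code{lambda}, \code{probability}.
#' @export
ceac <- function(draws, lambda = seq(0, 100000, by = 1000)) {
  if (inherits(draws, "cea")) draws <- draws$draws
  check_columns(draws, c("delta_cost", "delta_qaly"), "draws")
  if (length(lambda) == 0L) stop_("empty willingness-to-pay grid")
  if (any(!is.finite(lambda) | lambda < 0))
    stop_("willingness-to-pay thresholds must be finite and >= 0")
  p <- vapply(lambda, function(l)
    mean(l * draws$delta_qaly - draws$delta_cost > 0), 0)
  data.frame(lambda = lambda, probability = p)
}

#' Fit the pre-post cost-effectiveness summary
#'
#' The central estimator: combines per-client cost and QALY differences
#' into the descriptive cost-effectiveness result — mean differences,
#' quadrant/ICER classification, a client-level bootstrap of the
#' cost-effectiveness plane, and the cost-effectiveness acceptability
#' curve.
#'
#' @param deltas \code{\link{client_deltas}} output (one paired row per
#'   client).
#' @param B Bootstrap replicates (default 1000).
#' @param lambda Willingness-to-pay grid in EUR per QALY (default 0 to
#'   100,000 in steps of 1,000).
#' @param seed Integer seed; recorded in the result.
#' @return Object of class \code{"cea"} with elements \code{n}, \code{B},
#'   \code{seed}, \code{deltas}, \code{delta_cost}, \code{delta_qaly}
#'   (cohort means), \code{quadrant}, \code{icer}, \code{draws},
#'   \code{ceac}.
#' @examples
#' d <- data.frame(client_id = 1:4, delta_cost = c(-900, -2100, 300, -800),
#'                 delta_qaly = c(0.05, 0.08, -0.01, 0.09))
#' fit <- cea(d, B = 200, seed = 42)
#' fit
#' coef(fit)
#' @export
cea <- function(deltas, B = 1000, lambda = seq(0, 100000, by = 1000),
                seed = 1L) {
  check_columns(deltas, c("delta_cost", "delta_qaly"), "deltas")
  draws <- bootstrap_ce(deltas, B = B, seed = seed)
  mdc <- mean(deltas$delta_cost)
  mdq <- mean(deltas$delta_qaly)
  cls <- classify_quadrant(mdc, mdq)
  structure(list(call = match.call(), n = nrow(deltas),
                 B = as.integer(B), seed = as.integer(seed),
                 deltas = deltas, delta_cost = mdc, delta_qaly = mdq,
                 quadrant = cls$quadrant, icer = cls$icer,
                 draws = draws, ceac = ceac(draws, lambda)),
            class = "cea")
}

#' @export
print.cea <- function(x, ...) {
  cat("Pre-post cost-effectiveness analysis\n")
  cat(sprintf("  n = %d clients, B = %d bootstrap replicates (seed %d)\n",
              x$n, x$B, x$seed))
  cat(sprintf("  mean Δcost: %s EUR; mean ΔQALY: %.4f\n",
              formatC(x$delta_cost, format = "f", digits = 0,
                      big.mark = ","), x$delta_qaly))
  cat(sprintf("  quadrant: %s%s\n", x$quadrant,
              if (!is.na(x$icer))
                sprintf("; ICER = %s EUR/QALY",
                        formatC(x$icer, format = "f", digits = 0,
                                big.mark = ",")) else ""))
  invisible(x)
}

#' @export
coef.cea <- function(object, ...) {
  c(delta_cost = object$delta_cost, delta_qaly = object$delta_qaly)
}

#' @export
summary.cea <- function(object, wtp = 50000, ...) {
  qs <- function(v) stats::quantile(v, c(0.025, 0.975), names = FALSE)
  ci_c <- qs(object$draws$delta_cost)
  ci_q <- qs(object$draws$delta_qaly)
  p_wtp <- ceac(object$draws, wtp)$probability
  p_dom <- mean(object$draws$delta_cost < 0 & object$draws$delta_qaly > 0)
  out <- list(fit = object, wtp = wtp, p_wtp = p_wtp, p_dominant = p_dom,
              ci_cost = ci_c, ci_qaly = ci_q)
  class(out) <- "summary.cea"
  out
}

#' @export
print.summary.cea <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  bootstrap 2.5-97.5%% Δcost: [%s, %s] EUR\n",
              formatC(x$ci_cost[1], format = "f", digits = 0, big.mark = ","),
              formatC(x$ci_cost[2], format = "f", digits = 0, big.mark = ",")))
  cat(sprintf("  bootstrap 2.5-97.5%% ΔQALY: [%.4f, %.4f]\n",
              x$ci_qaly[1], x$ci_qaly[2]))
  cat(sprintf("  P(dominant quadrant): %.3f\n", x$p_dominant))
  cat(sprintf("  P(cost-effective at %s EUR/QALY): %.3f\n",
              formatC(x$wtp, format = "d", big.mark = ","), x$p_wtp))
  invisible(x)
}

#' Plot the cost-effectiveness plane and acceptability curve
#'
#' @param x A fitted \code{\link{cea}} object.
#' @param which \code{"plane"}, \code{"ceac"}, or both.
#' @param ... Passed to the underlying plot calls.
#' @return \code{x}, invisibly.
#' @export
plot.cea <- function(x, which = c("plane", "ceac"), ...) {
  which <- match.arg(which, several.ok = TRUE)
  if (length(which) > 1) {
    op <- graphics::par(mfrow = c(1, length(which)))
    on.exit(graphics::par(op))
  }
  if ("plane" %in% which) {
    graphics::plot(x$draws$delta_qaly, x$draws$delta_cost,
                   pch = 16, cex = 0.4, col = grDevices::grey(0.4),
                   xlab = expression(Delta ~ "QALY"),
                   ylab = expression(Delta ~ "cost (EUR)"),
                   main = "Cost-effectiveness plane", ...)
    graphics::abline(h = 0, v = 0, lty = 2)
    graphics::points(x$delta_qaly, x$delta_cost, pch = 3, col = 2, cex = 1.5)
  }
  if ("ceac" %in% which) {
    graphics::plot(x$ceac$lambda, x$ceac$probability, type = "l",
                   ylim = c(0, 1),
                   xlab = "Willingness to pay (EUR per QALY)",
                   ylab = "Probability cost-effective",
                   main = "Acceptability curve", ...)
  }
  invisible(x)
}

#' Write cost-effectiveness plane, CEAC and summary files
#'
#' Emits \code{ce_plane.csv} (one row per bootstrap draw),
#' \code{ceac.csv} (one row per willingness-to-pay threshold) and
#' \code{ce_summary.json} (means, quadrant, ICER or dominance, B, seed).
#'
#' @param fit A fitted \code{\link{cea}} object.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_ce_outputs <- function(fit, dir) {
  stopifnot(inherits(fit, "cea"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  plane <- file.path(dir, "ce_plane.csv")
  curve <- file.path(dir, "ceac.csv")
  summ <- file.path(dir, "ce_summary.json")
  pl <- fit$draws
  names(pl) <- c("draw_index", "delta_cost_eur", "delta_qaly")
  utils::write.csv(pl, plane, row.names = FALSE)
  cc <- fit$ceac
  names(cc) <- c("lambda_eur_per_qaly", "probability")
  utils::write.csv(cc, curve, row.names = FALSE)
  jsonlite::write_json(
    list(n_clients = fit$n, B = fit$B, seed = fit$seed,
         mean_delta_cost_eur = fit$delta_cost,
         mean_delta_qaly = fit$delta_qaly,
         quadrant = fit$quadrant,
         icer_eur_per_qaly = if (is.na(fit$icer)) NULL else fit$icer),
    summ, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(plane = plane, ceac = curve, summary = summ))
}
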