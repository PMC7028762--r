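#' Cost service-utilization records against a unit-cost table
#'
#' Applies the stepwise expenditure calculation: each reported amount of
#' service use is multiplied by its unit-cost assumption. Records whose
#' \code{service_item} is one of the direct-amount categories
#' (\code{"medication"}, \code{"complementary"}, \code{"other_contacts"})
#' pass their \code{eur_amount} through unchanged, since no per-unit price
#' exists for such spend.
#'
#' @param utilization Data.frame with columns \code{client_id},
#'   \code{period} (one of \code{pre6m}, \code{fu1}, \code{fu2}, \code{fu3}),
#'   \code{service_item}, \code{units}, and (for direct-amount records)
#'   \code{eur_amount}.
#' @param costs A \code{\link{unit_cost_table}}.
#' @return Expenditure data.frame: one row per input row with columns
#'   \code{client_id}, \code{period}, \code{service_item}, \code{cost_item}
#'   (reporting category), \code{eur}, \code{imputed}, \code{imputed_from}.
#' @examples
#' uc <- unit_cost_table()
#' u <- data.frame(client_id = "c1", period = "pre6m",
#'                 service_item = "psychiatric_inpatient_day", units = 5)
#' cost_records(u, uc)$eur  # 5 x 386 = 1930
#' @export
cost_records <- function(utilization, costs = unit_cost_table()) {
  check_columns(utilization, c("client_id", "period", "service_item",
                               "units"), "utilization")
  check_period(utilization$period, "utilization$period")
  if (!inherits(costs, "unit_cost_table")) stop_("'costs' must be a unit_cost_table")

  idx <- match(utilization$service_item, costs$item)
  direct <- utilization$service_item %in% names(DIRECT_CATEGORIES)
  bad <- is.na(idx) & !direct
  if (any(bad)) {
    off <- utilization[bad, , drop = FALSE]
    stop_("unresolvable service item(s): %s",
          paste(sprintf("'%s' (client %s)", off$service_item, off$client_id),
                collapse = "; "))
  }

  units <- utilization$units
  bad_units <- !direct
  bad_units[!direct] <- !is.finite(units[!direct]) | units[!direct] < 0
  if (any(bad_units))
    stop_("'units' must be finite and >= 0 for tabled items")

  eur <- rep(NA_real_, nrow(utilization))
  eur[!direct] <- units[!direct] * costs$unit_cost_eur[idx[!direct]]
  if (any(direct)) {
    if (!"eur_amount" %in% names(utilization))
      stop_("direct-amount records present but no 'eur_amount' column")
    amt <- utilization$eur_amount[direct]
    if (any(!is.finite(amt) | amt < 0))
      stop_("direct 'eur_amount' must be finite and >= 0")
    eur[direct] <- amt
  }

  cost_item <- ifelse(direct,
                      DIRECT_CATEGORIES[utilization$service_item],
                      costs$category[idx])
  data.frame(client_id = as.character(utilization$client_id),
             period = utilization$period,
             service_item = utilization$service_item,
             cost_item = unname(cost_item),
             eur = eur,
             imputed = FALSE,
             imputed_from = NA_character_,
             stringsAsFactors = FALSE)
}

check_expenditure <- function(x, name = "expenditure") {
  check_columns(x, c("client_id", "period", "cost_item", "eur"), name)
  check_period(x$period, paste0(name, "$period"))
  if (!"imputed" %in% names(x)) x$imputed <- FALSE
  if (!"imputed_from" %in% names(x)) x$imputed_from <- NA_character_
  x
}

#' Complete missing follow-up costs by last observation carried forward
#'
#' Costs of follow-up intervals a client did not report (because the client
#' left the study after interview \code{last_observed_visit}) are imputed by
#' carrying the per-item costs of that client's last complete follow-up
#' interval forward, rescaled to the missing interval's length (a 3-month
#' interval carried into the 6-month final interval is doubled, so the
#' carried-forward monthly spending rate is preserved). Clients observed at
#' baseline only have no complete follow-up; their pre-period rates are
#' carried forward instead and flagged distinctly
#' (\code{imputed_from = "pre6m"}).
#'
#' The operation is idempotent: periods that already contain rows for a
#' client are never re-imputed.
#'
#' @param expenditure Output of \code{\link{cost_records}}.
#' @param clients Data.frame with columns \code{client_id} and
#'   \code{last_observed_visit} (0 = baseline only, 3 = completer).
#' @return The expenditure table with imputed rows appended
#'   (\code{imputed = TRUE}, \code{imputed_from} = source period).
#' @export
impute_cost_locf <- function(expenditure, clients) {
  expenditure <- check_expenditure(expenditure)
  check_columns(clients, c("client_id", "last_observed_visit"), "clients")
  lov <- clients$last_observed_visit
  if (any(!lov %in% 0:3))
    stop_("'last_observed_visit' must be in 0..3")

  pt <- period_table()
  out <- list(expenditure)
  for (i in seq_len(nrow(clients))) {
    cid <- as.character(clients$client_id[i])
    k <- lov[i]
    if (k >= 3L) next
    rows_c <- expenditure[expenditure$client_id == cid, , drop = FALSE]
    src_period <- if (k >= 1L) FOLLOWUP_PERIODS[k] else "pre6m"
    src <- rows_c[rows_c$period == src_period & !rows_c$imputed, ,
                  drop = FALSE]
    for (j in (k + 1L):3L) {
      tgt <- FOLLOWUP_PERIODS[j]
      if (any(rows_c$period == tgt)) next  # already present: no re-imputation
      if (nrow(src) == 0L) next            # zero use in source period
      imp <- src
      scale <- period_months(tgt) / period_months(src_period)
      imp$period <- tgt
      imp$eur <- imp$eur * scale
      imp$imputed <- TRUE
      imp$imputed_from <- src_period
      out[[length(out) + 1L]] <- imp
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Annualize pre-period quantities
#'
#' The pre period is surveyed over 6 months; extrapolation to the 12 months
#' before baseline multiplies every pre-period quantity by 2.
#'
#' @param x Either a numeric vector of 6-month pre-period quantities, or an
#'   expenditure data.frame (rows with \code{period == "pre6m"} are doubled).
#' @return Same shape as the input, annualized.
#' @examples
#' annualize_pre(2916)  # 5832
#' @export
annualize_pre <- function(x) {
  if (is.numeric(x)) return(2 * x)
  x <- check_expenditure(x)
  pre <- x$period == "pre6m"
  x$eur[pre] <- 2 * x$eur[pre]
  x
}

#' Add the flat counseling fee of the outreach clinic
#'
#' Counseling at the outreach clinic is remunerated with one flat fee per
#' client (default 100 EUR), booked once in the study (post) window. Apply
#' after \code{\link{impute_cost_locf}} so the fee is not carried forward.
#'
#' @param expenditure Expenditure table (post-period rows present).
#' @param clients Client data.frame (or a vector of client ids).
#' @param fee_per_client Flat fee in EUR; must be >= 0.
#' @return The expenditure table with one fee row per client appended.
#' @export
add_counseling_fee <- function(expenditure, clients, fee_per_client = 100) {
  expenditure <- check_expenditure(expenditure)
  check_number(fee_per_client, "fee_per_client", lower = 0)
  ids <- if (is.data.frame(clients)) {
    check_columns(clients, "client_id", "clients")
    as.character(clients$client_id)
  } else as.character(clients)
  if (anyDuplicated(ids)) stop_("duplicate client ids in 'clients'")
  if (fee_per_client == 0) return(expenditure)
  fee <- data.frame(client_id = ids, period = "fu1",
                    service_item = COUNSELING_ITEM,
                    cost_item = COUNSELING_CATEGORY,
                    eur = fee_per_client,
                    imputed = FALSE, imputed_from = NA_character_,
                    stringsAsFactors = FALSE)
  res <- rbind(expenditure, fee)
  rownames(res) <- NULL
  res
}

CATEGORY_ORDER <- c("Inpatient care", "Psychiatric day care",
                    "Outpatient care", "Medication", "Complementary care",
                    "Other contacts",
                    "Counseling at the outreach clinic")
OVERALL_LABEL <- "Overall costs"

# per client x window x cost_item totals on the common client list,
# zero-filled so per-client statistics include non-users
client_window_costs <- function(expenditure, client_ids, annualize = TRUE) {
  expenditure <- check_expenditure(expenditure)
  if (annualize) expenditure <- annualize_pre(expenditure)
  pt <- period_table()
  expenditure$window <- pt$window[match(expenditure$period, pt$period)]
  items <- intersect(CATEGORY_ORDER, unique(expenditure$cost_item))
  extra <- setdiff(unique(expenditure$cost_item), items)
  items <- c(items, extra)
  grid <- expand.grid(client_id = as.character(client_ids),
                      window = c("pre12m", "post12m"),
                      cost_item = items,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  agg <- stats::aggregate(eur ~ client_id + window + cost_item,
                          data = expenditure, FUN = sum)
  m <- merge(grid, agg, all.x = TRUE,
             by = c("client_id", "window", "cost_item"))
  m$eur[is.na(m$eur)] <- 0
  m[order(match(m$cost_item, items), m$window, m$client_id), , drop = FALSE]
}

#' Aggregate expenditures into the per-user / per-client / total layout
#'
#' For every reporting category and 12-month window, computes the number of
#' users (clients with positive cost on the item), the mean cost per user,
#' the mean cost per client, normal-approximation 95\% confidence intervals
#' (mean +/- 1.96 SE; the per-user interval is suppressed when fewer than
#' two users exist), and the total. An overall row sums the categories, and
#' a difference column reports post-window minus pre-window totals per item.
#' The pre window is annualized (doubled) from the 6-month survey period.
#'
#' @param expenditure Expenditure table covering both windows (after cost
#'   LOCF and the counseling fee).
#' @param clients Client data.frame with \code{client_id} (the per-client
#'   denominator), or a positive integer number of clients when the
#'   expenditure table already contains one row set per client.
#' @param annualize Double pre-period costs into a 12-month window
#'   (default \code{TRUE}).
#' @return Object of class \code{"cost_summary"}: list with elements
#'   \code{summary} (per item x window statistics), \code{differences}
#'   (per-item post minus pre totals) and \code{n_clients}.
#' @export
aggregate_costs <- function(expenditure, clients, annualize = TRUE) {
  if (is.data.frame(clients)) {
    check_columns(clients, "client_id", "clients")
    ids <- as.character(clients$client_id)
  } else {
    n <- check_number(clients, "clients", lower = 1, integer = TRUE)
    ids <- unique(as.character(expenditure$client_id))
    if (length(ids) > n)
      stop_("expenditure has %d distinct clients but n_clients = %d",
            length(ids), n)
    if (length(ids) < n)  # clients with no records at all count as zeros
      ids <- c(ids, sprintf(".zero_client_%03d", seq_len(n - length(ids))))
  }
  if (length(ids) == 0L) stop_("no clients")
  n_clients <- length(ids)

  cw <- client_window_costs(expenditure, ids, annualize = annualize)
  items <- unique(cw$cost_item)

  one <- function(eur_by_client) {
    users <- eur_by_client[eur_by_client > 0]
    pu <- if (length(users)) mean_ci95(users) else
      c(mean = NA_real_, lo = NA_real_, hi = NA_real_)
    pc <- mean_ci95(eur_by_client)
    c(n_users = length(users), per_user_mean = pu[["mean"]],
      per_user_lo = pu[["lo"]], per_user_hi = pu[["hi"]],
      per_client_mean = pc[["mean"]], per_client_lo = pc[["lo"]],
      per_client_hi = pc[["hi"]], total = sum(eur_by_client))
  }

  rows <- list()
  for (w in c("pre12m", "post12m")) {
    for (it in items) {
      v <- cw$eur[cw$window == w & cw$cost_item == it]
      rows[[length(rows) + 1L]] <-
        data.frame(cost_item = it, window = w, t(one(v)),
                   stringsAsFactors = FALSE)
    }
    # overall: per-client totals across items
    tot <- stats::aggregate(eur ~ client_id, data = cw[cw$window == w, ],
                            FUN = sum)
    rows[[length(rows) + 1L]] <-
      data.frame(cost_item = OVERALL_LABEL, window = w, t(one(tot$eur)),
                 stringsAsFactors = FALSE)
  }
  summ <- do.call(rbind, rows)
  rownames(summ) <- NULL

  pre <- summ[summ$window == "pre12m", c("cost_item", "total")]
  post <- summ[summ$window == "post12m", c("cost_item", "total")]
  diffs <- merge(pre, post, by = "cost_item", suffixes = c("_pre", "_post"))
  diffs$difference <- diffs$total_post - diffs$total_pre
  diffs <- diffs[order(match(diffs$cost_item,
                             c(items, OVERALL_LABEL))), , drop = FALSE]
  rownames(diffs) <- NULL

  structure(list(summary = summ, differences = diffs,
                 n_clients = n_clients),
            class = "cost_summary")
}

#' @export
print.cost_summary <- function(x, digits = 0, ...) {
  cat(sprintf("Cost summary (n = %d clients; EUR; 12-month windows)\n",
              x$n_clients))
  s <- x$summary
  fmt <- function(v) ifelse(is.na(v), "-",
                            formatC(v, format = "f", digits = digits,
                                    big.mark = ","))
  for (w in c("pre12m", "post12m")) {
    cat(sprintf("\n-- %s --\n", w))
    sw <- s[s$window == w, ]
    out <- data.frame(cost_item = sw$cost_item, n_users = sw$n_users,
                      per_user = fmt(sw$per_user_mean),
                      per_client = fmt(sw$per_client_mean),
                      total = fmt(sw$total))
    print(out, row.names = FALSE)
  }
  cat("\n-- difference (post - pre) --\n")
  d <- x$differences
  print(data.frame(cost_item = d$cost_item,
                   difference = fmt(d$difference)), row.names = FALSE)
  invisible(x)
}

#' Export a cost summary as CSV
#'
#' Writes the long summary (one row per cost item and window) merged with
#' the per-item difference column.
#'
#' @param x A \code{"cost_summary"}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_cost_summary <- function(x, path) {
  stopifnot(inherits(x, "cost_summary"))
  s <- merge(x$summary,
             x$differences[, c("cost_item", "difference")],
             by = "cost_item", sort = FALSE)
  s <- s[order(match(s$cost_item, unique(x$summary$cost_item)),
               s$window), ]
  utils::write.csv(s, path, row.names = FALSE)
  invisible(path)
}
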