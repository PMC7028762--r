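# shared fixture builders (all data generated in code)

# one SF-12 response row with every item at its best / worst level
sf12_row <- function(client_id = "c1", visit = 0L,
                     at = c("best", "worst")) {
  at <- match.arg(at)
  meta <- sf12_items()
  lev <- if (at == "best") meta$best_level else
    ifelse(meta$best_level == 1L, meta$n_levels,
           ifelse(meta$best_level == meta$n_levels, 1L, 1L))
  row <- as.data.frame(as.list(stats::setNames(as.integer(lev),
                                               meta$item)))
  cbind(data.frame(client_id = client_id, visit = visit,
                   stringsAsFactors = FALSE), row)
}

# utilization + clients reproducing published-style category totals exactly:
# category -> c(n_users, total EUR) per window. Pre totals are given on the
# annualized 12-month scale and are entered at half value in the 6-month
# pre period; post totals are entered in fu1.
printed_cost_fixture <- function() {
  n_clients <- 85L
  clients <- data.frame(client_id = sprintf("c%04d", 1:n_clients),
                        last_observed_visit = 3L,
                        stringsAsFactors = FALSE)
  pre <- list(  # item used as carrier, n_users, 12m total EUR
    c("psychiatric_inpatient_day", 22, 213774),
    c("day_care_day",               4,  54121),
    c("gp_visit",                  70,  49914),
    c("medication",                53,  61866),
    c("complementary",             75,  92276),
    c("other_contacts",            31,  23733))
  post <- list(
    c("psychiatric_inpatient_day", 20, 140853),
    c("day_care_day",               1,    434),
    c("gp_visit",                  74,  68204),
    c("medication",                67,  62176),
    c("complementary",             73,  70696),
    c("other_contacts",            44,  18917))
  uc <- unit_cost_table()
  direct_items <- c("medication", "complementary", "other_contacts")
  rows <- list()
  add <- function(spec, period, scale) {
    for (s in spec) {
      item <- s[1]; n_users <- as.integer(s[2]); total <- as.numeric(s[3])
      ids <- clients$client_id[seq_len(n_users)]
      if (item %in% direct_items) {
        rows[[length(rows) + 1L]] <<- data.frame(
          client_id = ids, period = period, service_item = item,
          units = NA_real_, eur_amount = total * scale / n_users,
          stringsAsFactors = FALSE)
      } else {
        price <- uc$unit_cost_eur[uc$item == item]
        rows[[length(rows) + 1L]] <<- data.frame(
          client_id = ids, period = period, service_item = item,
          units = total * scale / n_users / price, eur_amount = NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  add(pre, "pre6m", 0.5)
  add(post, "fu1", 1)
  list(clients = clients, utilization = do.call(rbind, rows))
}

# tiny deterministic client-delta table with correlated cost/QALY pairs
toy_deltas <- function(n = 12, seed = 5) {
  set.seed(seed)
  q <- stats::rnorm(n, 0.05, 0.06)
  data.frame(client_id = sprintf("d%02d", seq_len(n)),
             delta_cost = -20000 * q + stats::rnorm(n, 0, 800),
             delta_qaly = q, stringsAsFactors = FALSE)
}
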