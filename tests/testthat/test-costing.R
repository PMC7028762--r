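test_that("cost_records multiplies units by unit costs and passes direct amounts", {
  uc <- unit_cost_table()
  u <- data.frame(
    client_id = c("a", "a", "a", "b", "b"),
    period = "pre6m",
    service_item = c("psychiatric_inpatient_day", "gp_visit",
                     "psychiatrist_visit", "day_care_day", "medication"),
    units = c(5, 3, 2, 0, NA),
    eur_amount = c(NA, NA, NA, NA, 123.45))
  e <- cost_records(u, uc)
  expect_equal(nrow(e), nrow(u))
  expect_equal(e$eur, c(5 * 386, 3 * 20, 2 * 45, 0, 123.45))
  expect_equal(sum(e$eur[e$client_id == "a" &
                           e$cost_item == "Outpatient care"]), 60 + 90)
  expect_equal(e$cost_item[5], "Medication")
})

test_that("unresolvable service items are reported with client id", {
  u <- data.frame(client_id = "c9", period = "fu1",
                  service_item = "helicopter_ride", units = 1)
  expect_error(cost_records(u, unit_cost_table()),
               "helicopter_ride.*c9")
})

test_that("cost LOCF carries the last complete follow-up forward with length scaling", {
  uc <- unit_cost_table()
  u <- data.frame(client_id = "a", period = c("pre6m", "fu1", "fu2"),
                  service_item = "gp_visit", units = c(4, 2, 3))
  cl <- data.frame(client_id = "a", last_observed_visit = 2L)
  e <- impute_cost_locf(cost_records(u, uc), cl)
  fu3 <- e[e$period == "fu3", ]
  expect_equal(nrow(fu3), 1L)
  # 6-month interval imputed from a 3-month interval: costs double
  expect_equal(fu3$eur, 3 * 20 * 2)
  expect_true(fu3$imputed)
  expect_equal(fu3$imputed_from, "fu2")
})

test_that("cost LOCF is an identity for complete clients and idempotent", {
  uc <- unit_cost_table()
  u <- data.frame(client_id = c("a", "a", "b"),
                  period = c("pre6m", "fu3", "pre6m"),
                  service_item = "psychiatrist_visit", units = c(1, 2, 3))
  complete <- data.frame(client_id = c("a", "b"),
                         last_observed_visit = c(3L, 1L))
  e0 <- cost_records(u, uc)
  e1 <- impute_cost_locf(e0, complete)
  e2 <- impute_cost_locf(e1, complete)
  expect_identical(e1, e2)
  # client a fully observed: rows unchanged
  expect_identical(e1[e1$client_id == "a", ], e0[e0$client_id == "a", ])
  # all-complete cohort: totals unchanged
  allc <- data.frame(client_id = c("a", "b"),
                     last_observed_visit = 3L)
  expect_equal(sum(impute_cost_locf(e0, allc)$eur), sum(e0$eur))
})

test_that("clients without any complete follow-up fall back to pre-period rates", {
  uc <- unit_cost_table()
  u <- data.frame(client_id = "a", period = "pre6m",
                  service_item = "gp_visit", units = 6)
  cl <- data.frame(client_id = "a", last_observed_visit = 0L)
  e <- impute_cost_locf(cost_records(u, uc), cl)
  expect_setequal(e$period, c("pre6m", "fu1", "fu2", "fu3"))
  imp <- e[e$period != "pre6m", ]
  expect_true(all(imp$imputed_from == "pre6m"))
  # monthly rate preserved: 6 visits / 6 months -> 3, 3, 6 visits
  expect_equal(sum(imp$eur), 20 * (3 + 3 + 6))
})

test_that("annualization doubles pre-period quantities", {
  expect_equal(annualize_pre(2916), 5832)
  expect_equal(annualize_pre(0), 0)
  expect_equal(annualize_pre(247842), 495684)
  e <- data.frame(client_id = "a", period = c("pre6m", "fu1"),
                  cost_item = "Outpatient care", eur = c(10, 10))
  a <- annualize_pre(e)
  expect_equal(a$eur, c(20, 10))
})

test_that("the counseling fee adds one flat amount per client", {
  uc <- unit_cost_table()
  u <- data.frame(client_id = "a", period = "fu1",
                  service_item = "gp_visit", units = 1)
  e <- cost_records(u, uc)
  f <- add_counseling_fee(e, c("a", "b", "c"), 100)
  fee_rows <- f[f$cost_item == "Counseling at the outreach clinic", ]
  expect_equal(nrow(fee_rows), 3L)
  expect_equal(sum(fee_rows$eur), 300)
  expect_identical(add_counseling_fee(e, "a", 0), e)
  expect_error(add_counseling_fee(e, "a", -5), "fee_per_client")
})

test_that("aggregate_costs reproduces per-user/per-client/total identities", {
  fx <- printed_cost_fixture()
  e <- add_counseling_fee(cost_records(fx$utilization, unit_cost_table()),
                          fx$clients)
  cs <- aggregate_costs(e, fx$clients)
  s <- cs$summary
  g <- function(item, w, col) s[s$cost_item == item & s$window == w, col]
  expect_equal(g("Inpatient care", "pre12m", "n_users"), 22)
  expect_equal(g("Inpatient care", "pre12m", "per_user_mean"), 213774 / 22)
  expect_equal(g("Psychiatric day care", "pre12m", "per_user_mean"),
               54121 / 4)
  expect_equal(g("Overall costs", "post12m", "per_client_mean"),
               369780 / 85)
  expect_equal(g("Counseling at the outreach clinic", "post12m", "total"),
               8500)
  d <- cs$differences
  expect_equal(d$difference[d$cost_item == "Inpatient care"],
               140853 - 213774)
  expect_equal(d$difference[d$cost_item == "Overall costs"], -125904)
})

test_that("single-user items report a mean but no CI", {
  fx <- printed_cost_fixture()
  e <- cost_records(fx$utilization, unit_cost_table())
  cs <- aggregate_costs(e, fx$clients)
  s <- cs$summary
  dc <- s[s$cost_item == "Psychiatric day care" & s$window == "post12m", ]
  expect_equal(dc$n_users, 1)
  expect_equal(dc$per_user_mean, 434)
  expect_true(is.na(dc$per_user_lo) && is.na(dc$per_user_hi))
  expect_false(is.na(dc$per_client_lo))
  expect_true(all(s$n_users <= cs$n_clients))
})

test_that("totals are conserved and scale linearly with unit costs", {
  sim <- simulate_cohort(default_cohort_spec(n_clients = 15), seed = 3)
  uc <- unit_cost_table()
  e <- impute_cost_locf(cost_records(sim$utilization, uc), sim$clients)
  cs <- aggregate_costs(e, sim$clients)
  s <- cs$summary
  for (w in c("pre12m", "post12m")) {
    items <- s$cost_item != "Overall costs" & s$window == w
    ov <- s$cost_item == "Overall costs" & s$window == w
    expect_equal(sum(s$total[items]), s$total[ov])
    expect_equal(s$per_client_mean[ov] * cs$n_clients, s$total[ov])
  }
  # doubling every unit cost doubles every tabled-item summary
  uc2 <- uc
  uc2$unit_cost_eur <- 2 * uc2$unit_cost_eur
  tabled <- sim$utilization$service_item %in% uc$item
  e2 <- impute_cost_locf(cost_records(sim$utilization[tabled, ], uc2),
                         sim$clients)
  e1 <- impute_cost_locf(cost_records(sim$utilization[tabled, ], uc),
                         sim$clients)
  s2 <- aggregate_costs(e2, sim$clients)$summary
  s1 <- aggregate_costs(e1, sim$clients)$summary
  expect_equal(s2$total, 2 * s1$total)
  expect_equal(s2$per_client_mean, 2 * s1$per_client_mean)
})

test_that("aggregate_costs matches a brute-force per-client enumeration", {
  sim <- simulate_cohort(default_cohort_spec(n_clients = 5), seed = 8)
  uc <- unit_cost_table()
  e <- add_counseling_fee(
    impute_cost_locf(cost_records(sim$utilization, uc), sim$clients),
    sim$clients)
  cs <- aggregate_costs(e, sim$clients)
  pt <- period_table()
  # independent oracle: loop clients, sum row by row
  for (w in c("pre12m", "post12m")) {
    for (item in unique(e$cost_item)) {
      by_client <- vapply(sim$clients$client_id, function(cid) {
        rows <- e[e$client_id == cid & e$cost_item == item &
                    pt$window[match(e$period, pt$period)] == w, ]
        mult <- ifelse(rows$period == "pre6m", 2, 1)
        sum(rows$eur * mult)
      }, 0)
      srow <- cs$summary[cs$summary$cost_item == item &
                           cs$summary$window == w, ]
      expect_equal(srow$total, sum(by_client))
      expect_equal(srow$n_users, sum(by_client > 0))
      expect_equal(srow$per_client_mean, mean(by_client))
      if (srow$n_users > 0)
        expect_equal(srow$per_user_mean,
                     mean(by_client[by_client > 0]))
    }
  }
})
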