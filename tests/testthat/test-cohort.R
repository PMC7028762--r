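test_that("simulation is deterministic and has the requested cardinality", {
  spec <- default_cohort_spec(n_clients = 20)
  a <- simulate_cohort(spec, seed = 9)
  b <- simulate_cohort(spec, seed = 9)
  expect_identical(a, b)
  expect_equal(nrow(a$clients), 20L)
  expect_false(identical(a, simulate_cohort(spec, seed = 10)))
})

test_that("zero utilization means yield an empty utilization table", {
  spec <- default_cohort_spec(n_clients = 5)
  spec$utilization_params$pre_eur <- 0
  spec$utilization_params$post_eur <- 0
  sim <- simulate_cohort(spec, seed = 1)
  expect_equal(nrow(sim$utilization), 0L)
  expect_equal(nrow(sim$clients), 5L)
})

test_that("dropout censors visits as a prefix", {
  spec <- default_cohort_spec(n_clients = 60)
  spec$dropout_prob_per_followup <- 0.35  # force many dropouts
  spec <- cohort_spec(n_clients = spec$n_clients, seed = 1,
                      female_prop = spec$female_prop,
                      age_mean = spec$age_mean, age_sd = spec$age_sd,
                      age_range = spec$age_range,
                      demographics = spec$demographics,
                      utilization_params = spec$utilization_params,
                      qol_params = spec$qol_params,
                      dropout_prob_per_followup = 0.35)
  sim <- simulate_cohort(spec, seed = 2)
  pt <- period_table()
  for (i in seq_len(nrow(sim$clients))) {
    cid <- sim$clients$client_id[i]
    k <- sim$clients$last_observed_visit[i]
    visits <- sort(sim$sf12$visit[sim$sf12$client_id == cid])
    expect_equal(visits, 0:k)  # no gaps, baseline always present
    per <- sim$utilization$period[sim$utilization$client_id == cid]
    expect_true(all(pt$visit[match(per, pt$period)] <= max(k, 0)))
  }
  expect_true(any(sim$clients$last_observed_visit < 3))
})

test_that("observed female fraction sits in the binomial 99% band", {
  spec <- default_cohort_spec(n_clients = 85)
  n_seeds <- 12
  fem <- tot <- 0
  for (s in seq_len(n_seeds)) {
    cl <- simulate_cohort(spec, seed = 100 + s)$clients
    fem <- fem + sum(cl$sex == "female")
    tot <- tot + nrow(cl)
  }
  band <- stats::qbinom(c(0.005, 0.995), tot, 0.741)
  expect_gte(fem, band[1])
  expect_lte(fem, band[2])
})

test_that("per-client substreams: growing the cohort never perturbs earlier clients", {
  small <- simulate_cohort(default_cohort_spec(n_clients = 8), seed = 4)
  big <- simulate_cohort(default_cohort_spec(n_clients = 16), seed = 4)
  ids <- small$clients$client_id
  expect_identical(small$clients, big$clients[1:8, ])
  expect_identical(small$utilization,
                   big$utilization[big$utilization$client_id %in% ids, ])
  expect_identical(small$sf12, big$sf12[big$sf12$client_id %in% ids, ])
})

test_that("invalid spec fields are rejected by name", {
  good <- default_cohort_spec()
  expect_error(default_cohort_spec(n_clients = 0), "n_clients")
  bad <- good$utilization_params
  bad$dispersion[1] <- 0
  expect_error(cohort_spec(n_clients = 5, female_prop = 0.5,
                           age_mean = 40, age_sd = 10,
                           age_range = c(18, 80),
                           demographics = good$demographics,
                           utilization_params = bad,
                           qol_params = good$qol_params,
                           dropout_prob_per_followup = 0.05),
               "dispersion")
  expect_error(cohort_spec(n_clients = 5, female_prop = 1.5,
                           age_mean = 40, age_sd = 10,
                           age_range = c(18, 80),
                           demographics = good$demographics,
                           utilization_params = good$utilization_params,
                           qol_params = good$qol_params,
                           dropout_prob_per_followup = 0.05),
               "female_prop")
})

test_that("a cohort spec round-trips through YAML unchanged", {
  spec <- default_cohort_spec(n_clients = 7, seed = 3)
  path <- tempfile(fileext = ".yaml")
  write_cohort_spec(spec, path)
  back <- read_cohort_spec(path)
  expect_equal(back$utilization_params, spec$utilization_params)
  expect_equal(back$qol_params, spec$qol_params)
  expect_identical(simulate_cohort(back, seed = 5),
                   simulate_cohort(spec, seed = 5))
})

test_that("completion rate reports the completer percentage", {
  cl <- data.frame(last_observed_visit = rep(c(3L, 0L), c(73, 12)))
  expect_equal(completion_rate(cl), 100 * 73 / 85)
})
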