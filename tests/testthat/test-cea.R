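test_that("client deltas pair costs and QALYs and report cohort means", {
  costs <- data.frame(client_id = c("a", "b"),
                      cost_pre = c(1000, 2000), cost_post = c(900, 2300))
  qp <- qaly_pair(c(0.6, 0.5), c(0.7, 0.4), client_id = c("a", "b"))
  d <- client_deltas(costs, qp)
  expect_equal(d$delta_cost, c(-100, 300))
  expect_equal(d$delta_qaly, c(0.1, -0.1))
  expect_equal(attr(d, "means"),
               c(delta_cost = 100, delta_qaly = 0))
  qp2 <- qp
  qp2$client_id <- c("a", "zz")
  expect_error(client_deltas(costs, qp2), "zz")
})

test_that("quadrant classification and ICER follow the plane conventions", {
  expect_equal(classify_quadrant(-1482, 0.0568)$quadrant, "dominant")
  expect_true(is.na(classify_quadrant(-1482, 0.0568)$icer))
  ne <- classify_quadrant(568, 0.0568)
  expect_equal(ne$quadrant, "northeast")
  expect_equal(ne$icer, 10000)
  expect_equal(classify_quadrant(100, -0.01)$quadrant, "dominated")
  sw <- classify_quadrant(-100, -0.01)
  expect_equal(sw$quadrant, "southwest")
  expect_equal(sw$icer, 10000)
  z <- classify_quadrant(100, 0)
  expect_false(z$icer_defined)
  expect_true(is.na(z$icer))
})

test_that("bootstrap is deterministic and degenerate for one client", {
  one <- data.frame(client_id = "a", delta_cost = -5, delta_qaly = 0.1)
  dr <- bootstrap_ce(one, B = 25, seed = 3)
  expect_equal(nrow(dr), 25L)
  expect_true(all(dr$delta_cost == -5 & dr$delta_qaly == 0.1))
  d <- toy_deltas()
  expect_identical(bootstrap_ce(d, B = 100, seed = 7),
                   bootstrap_ce(d, B = 100, seed = 7))
  expect_false(identical(bootstrap_ce(d, B = 100, seed = 7),
                         bootstrap_ce(d, B = 100, seed = 8)))
  expect_error(bootstrap_ce(d, B = 0), "B")
})

test_that("bootstrap summaries match exhaustive enumeration on 3 clients", {
  d <- data.frame(client_id = c("a", "b", "c"),
                  delta_cost = c(-300, 150, -90),
                  delta_qaly = c(0.10, -0.02, 0.05))
  # oracle: enumerate all 27 equally likely resamples
  idx <- expand.grid(1:3, 1:3, 1:3)
  enum_means <- t(apply(idx, 1, function(i)
    c(mean(d$delta_cost[i]), mean(d$delta_qaly[i]))))
  mu <- colMeans(enum_means)
  sdv <- apply(enum_means, 2, function(x)
    sqrt(mean((x - mean(x))^2)))
  expect_equal(mu, c(mean(d$delta_cost), mean(d$delta_qaly)),
               ignore_attr = TRUE)
  B <- 1e5
  dr <- bootstrap_ce(d, B = B, seed = 11)
  # law of large numbers: draw means within 3 MC standard errors
  expect_lt(abs(mean(dr$delta_cost) - mu[1]), 3 * sdv[1] / sqrt(B))
  expect_lt(abs(mean(dr$delta_qaly) - mu[2]), 3 * sdv[2] / sqrt(B))
  expect_equal(sd(dr$delta_cost), sdv[1] * sqrt(B / (B - 1)),
               tolerance = 0.02)
  # every draw is one of the enumerated points
  key <- paste(round(enum_means[, 1], 9), round(enum_means[, 2], 9))
  expect_true(all(paste(round(dr$delta_cost, 9),
                        round(dr$delta_qaly, 9)) %in% key))
})

test_that("the acceptability curve obeys its limit identities", {
  d <- toy_deltas()
  dr <- bootstrap_ce(d, B = 400, seed = 2)
  cc <- ceac(dr, lambda = c(0, 1000, 50000, 1e7))
  expect_true(all(cc$probability >= 0 & cc$probability <= 1))
  expect_equal(cc$probability[1], mean(dr$delta_cost < 0))
  expect_equal(cc$probability[4], mean(dr$delta_qaly > 0))
  # dominant draws are cost-effective at every threshold
  dom <- data.frame(delta_cost = c(-10, -20), delta_qaly = c(0.1, 0.2),
                    draw = 1:2)
  expect_true(all(ceac(dom, c(0, 500, 1e6))$probability == 1))
  # enumeration example and the strict-inequality tie rule
  two <- data.frame(draw = 1:2, delta_cost = c(-10, 10),
                    delta_qaly = c(0.1, -0.1))
  expect_equal(ceac(two, 0)$probability, 0.5)
  tie <- data.frame(draw = 1, delta_cost = 100, delta_qaly = 0.01)
  expect_equal(ceac(tie, 10000)$probability, 0)  # NMB exactly 0: not CE
  expect_error(ceac(two, numeric()), "grid")
  expect_error(ceac(two, -5), "nonnegative|>= 0")
})

test_that("unpairing correlated deltas visibly changes the acceptability curve", {
  # negatively correlated pairs near the decision boundary: breaking the
  # pairing shrinks the variance of the bootstrap net monetary benefit and
  # shifts the curve upward
  set.seed(9)
  n <- 30
  q <- stats::rnorm(n, 0.01, 0.10)
  d <- data.frame(client_id = sprintf("d%02d", seq_len(n)),
                  delta_cost = -30000 * q + stats::rnorm(n, 0, 500),
                  delta_qaly = q)
  shuffled <- d
  set.seed(1)
  shuffled$delta_qaly <- sample(shuffled$delta_qaly)
  lam <- seq(0, 100000, by = 5000)
  p1 <- ceac(bootstrap_ce(d, B = 600, seed = 3), lam)$probability
  p2 <- ceac(bootstrap_ce(shuffled, B = 600, seed = 3), lam)$probability
  expect_equal(p1[1], p2[1])  # identical at lambda = 0 (costs unchanged)
  expect_gt(max(abs(p1 - p2)), 0.04)
})

test_that("the cea fit object carries a coherent summary", {
  d <- toy_deltas()
  fit <- cea(d, B = 300, lambda = seq(0, 100000, 10000), seed = 6)
  expect_s3_class(fit, "cea")
  expect_equal(fit$n, nrow(d))
  expect_equal(nrow(fit$draws), 300L)
  expect_equal(coef(fit),
               c(delta_cost = mean(d$delta_cost),
                 delta_qaly = mean(d$delta_qaly)))
  cls <- classify_quadrant(fit$delta_cost, fit$delta_qaly)
  expect_equal(fit$quadrant, cls$quadrant)
  s <- summary(fit)
  expect_true(s$p_wtp >= 0 && s$p_wtp <= 1)
  expect_output(print(fit), "quadrant")
  # output files
  dir <- tempfile()
  paths <- write_ce_outputs(fit, dir)
  expect_true(all(file.exists(paths)))
  plane <- read.csv(paths[["plane"]])
  expect_equal(nrow(plane), 300L)
  curve <- read.csv(paths[["ceac"]])
  expect_equal(nrow(curve), 11L)
  expect_true(all(curve$probability >= 0 & curve$probability <= 1))
})
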