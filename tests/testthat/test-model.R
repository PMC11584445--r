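test_that("parameter container validates its domain", {
  p <- coxplosive_params(0.5, 2)
  expect_s3_class(p, "coxplosive_params")
  expect_equal(p$beta, log(2))
  expect_error(coxplosive_params(1, 2), "alpha")
  expect_error(coxplosive_params(0, 2), "alpha")
  expect_error(coxplosive_params(1.2, 2), "alpha")
  expect_error(coxplosive_params(0.5, 0), "lambda")
  # numeric pair coercion used throughout the package
  expect_equal(mu_infinity(c(0.9, 50)), mu_infinity(coxplosive_params(0.9, 50)))
})

test_that("hazard rate follows the geometric law and grows with damage", {
  p <- coxplosive_params(0.5, 2)
  expect_equal(event_rate(1, p), 2)
  expect_equal(event_rate(2, p), 4)
  expect_equal(event_rate(3, p), 8)
  expect_error(event_rate(0, p), "k")
  expect_error(event_rate(1.5, p), "k")
  for (rep in 1:10) {
    rp <- random_params()
    rates <- event_rate(1:50, coxplosive_params(rp$alpha, rp$lambda))
    expect_true(all(diff(rates) > 0))
  }
})

test_that("expected increments are exponential means, strictly NBUE", {
  p <- coxplosive_params(0.5, 2)
  expect_equal(expected_increment(1, p), 0.5)
  expect_equal(expected_increment(2, p), 0.25)
  set.seed(31)
  for (rep in 1:20) {
    rp <- random_params()
    pp <- coxplosive_params(rp$alpha, rp$lambda)
    ei <- expected_increment(1:100, pp)
    expect_true(all(diff(ei) < 0))                     # NBUE, strict
    expect_equal(ei, 1 / event_rate(1:100, pp))         # mean = 1/rate
    expect_equal(ei, oracle_expected_increment(1:100, rp$alpha, rp$lambda))
  }
})

test_that("expected total strain matches the geometric series limit", {
  expect_equal(mu_infinity(coxplosive_params(0.9, 50)), 0.2)
  # single-event limit: alpha -> 0+ leaves only the first increment
  expect_equal(mu_infinity(coxplosive_params(1e-12, 4)), 0.25,
               tolerance = 1e-10)
  set.seed(7)
  for (rep in 1:10) {
    rp <- random_params()
    expect_equal(mu_infinity(coxplosive_params(rp$alpha, rp$lambda)),
                 oracle_mu_segment(0, Inf, rp$alpha, rp$lambda),
                 tolerance = 1e-12)
  }
})

test_that("segment expectations sum increments, telescope and add", {
  p <- coxplosive_params(0.5, 2)
  expect_equal(mu_segment(1, 2, p), 0.25)         # equals E(increment 2)
  expect_equal(mu_segment(0, 2, p), 0.75)          # 0.5 + 0.25 by hand
  expect_equal(mu_segment(0, Inf, coxplosive_params(0.9, 50)), 0.2)
  expect_error(mu_segment(2, 2, p), "strictly less")
  expect_error(mu_segment(-1, 2, p), "integer")
  set.seed(13)
  for (rep in 1:20) {
    rp <- random_params()
    pp <- coxplosive_params(rp$alpha, rp$lambda)
    i <- sample(0:20, 1); j <- i + sample(1:20, 1); l <- j + sample(1:20, 1)
    expect_equal(mu_segment(i, j, pp),
                 oracle_mu_segment(i, j, rp$alpha, rp$lambda),
                 tolerance = 1e-12)
    expect_equal(mu_segment(i, j, pp) + mu_segment(j, l, pp),
                 mu_segment(i, l, pp), tolerance = 1e-12)
    expect_equal(mu_segment(0, Inf, pp), mu_infinity(pp), tolerance = 1e-14)
  }
})

test_that("published-variant segment expectation is offset by one power", {
  p <- coxplosive_params(0.5, 2)
  # (alpha^1 - alpha^3) / ((1 - alpha) lambda) = (0.5 - 0.125) / 1
  expect_equal(mu_segment(1, 2, p, form = "literal"), 0.375)
  # both variants agree in the infinite limit
  expect_equal(mu_segment(0, Inf, p, form = "literal"), mu_infinity(p))
})

test_that("deterioration rate is the constant log hazard growth", {
  expect_equal(deterioration_rate(coxplosive_params(exp(-1), 3)), 1)
  expect_equal(deterioration_rate(coxplosive_params(0.5, 1)), log(2))
  expect_lt(deterioration_rate(coxplosive_params(1 - 1e-9, 1)), 1e-8)
  set.seed(3)
  for (rep in 1:10) {
    rp <- random_params()
    pp <- coxplosive_params(rp$alpha, rp$lambda)
    expect_equal(deterioration_rate(pp),
                 -log(event_rate(5, pp) / event_rate(6, pp)),
                 tolerance = 1e-12)
  }
})

test_that("simulation is reproducible and respects its stop rules", {
  p <- coxplosive_params(0.85, 100)
  s1 <- simulate_coxplosive(p, seed = 11)
  s2 <- simulate_coxplosive(p, seed = 11)
  expect_identical(s1$increments, s2$increments)
  expect_true(all(s1$increments > 0))
  expect_true(all(diff(s1$cum_strains) > 0))
  expect_true(s1$stop_reason %in% c("max_events", "increment_underflow"))
  s3 <- simulate_coxplosive(p, max_events = 5, min_increment = 0, seed = 2)
  expect_length(s3$increments, 5)
  expect_identical(s3$stop_reason, "max_events")
  # a coarse resolution floor truncates early
  s4 <- simulate_coxplosive(p, min_increment = 1e-3, seed = 2)
  expect_identical(s4$stop_reason, "increment_underflow")
  expect_lt(length(s4$increments), 100)
})

test_that("simulated first increments and totals match their expectations", {
  set.seed(101)
  p <- coxplosive_params(0.5, 2)
  d1 <- vapply(1:4000, function(i)
    simulate_coxplosive(p, max_events = 1)$increments[1L], numeric(1L))
  se <- sd(d1) / sqrt(length(d1))
  expect_lt(abs(mean(d1) - 0.5), 3 * se)

  p2 <- coxplosive_params(0.9, 50)
  tot <- vapply(1:4000, function(i) {
    s <- simulate_coxplosive(p2, max_events = 500)
    s$cum_strains[length(s$cum_strains)]
  }, numeric(1L))
  se2 <- sd(tot) / sqrt(length(tot))
  expect_lt(abs(mean(tot) - mu_infinity(p2)), 3 * se2)
  # second moment: Var(total) = sum of squared expected increments
  var_theory <- 1 / (50^2 * (1 - 0.9^2))
  expect_lt(abs(var(tot) - var_theory) / var_theory, 0.15)
})

test_that("increment distribution is memoryless given the event index", {
  # the law of increment k must not depend on the accumulated strain
  set.seed(55)
  p <- coxplosive_params(0.8, 20)
  sims <- lapply(1:3000, function(i) simulate_coxplosive(p, max_events = 4))
  inc3 <- vapply(sims, function(s) s$increments[3L], numeric(1L))
  eps2 <- vapply(sims, function(s) s$cum_strains[2L], numeric(1L))
  lo <- inc3[eps2 <= median(eps2)]
  hi <- inc3[eps2 > median(eps2)]
  expect_gt(suppressWarnings(ks.test(lo, hi)$p.value), 0.01)
})

test_that("count curve steps through events, closed at the grid point", {
  expect_equal(count_curve(c(0.1, 0.2), grid = c(0.05, 0.15, 0.25)),
               c(0, 1, 2))
  expect_equal(count_curve(numeric(0), grid = c(0.1, 0.2)), c(0, 0))
  expect_equal(count_curve(c(0.1, 0.2), grid = c(0.1, 0.2)), c(1, 2))
  expect_error(count_curve(c(0.1, 0.2), grid = c(0.3, 0.1)), "sorted")
  s <- simulate_coxplosive(coxplosive_params(0.9, 50), seed = 4)
  g <- seq(0, 0.5, length.out = 100)
  nc <- count_curve(s, g)
  expect_true(all(diff(nc) >= 0))
  expect_equal(nc[100], length(s$cum_strains))
})
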