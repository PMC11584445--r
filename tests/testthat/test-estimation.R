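test_that("penalty reproduces the hand-worked example exactly", {
  p <- coxplosive_params(0.5, 10)
  eps <- c(0.1, 0.25, 0.45)
  # term by term: (0.2 - 0.45)^2 + (0.05 - 0.15)^2 + (0.025 - 0.2)^2
  expect_equal(penalty_phi(p, eps), 0.103125, tolerance = 1e-12)
  expect_equal(oracle_penalty(0.5, 10, eps), 0.103125, tolerance = 1e-12)
})

test_that("penalty agrees with the literal re-summation oracle", {
  set.seed(17)
  for (rep in 1:25) {
    rp <- random_params()
    n <- sample(2:5, 1)
    eps <- cumsum(rexp(n, rate = rp$lambda))
    got <- penalty_phi(coxplosive_params(rp$alpha, rp$lambda), eps)
    want <- oracle_penalty(rp$alpha, rp$lambda, eps)
    expect_equal(got, want, tolerance = 1e-12)
    expect_gte(got, 0)
  }
})

test_that("penalty vanishes on an exact-expectation sequence", {
  eps <- exact_expectation_sequence(0.8, 40, n = 30)
  expect_lt(penalty_phi(coxplosive_params(0.8, 40), eps), 1e-28)
  # and the fit recovers the generating parameters to optimizer tolerance
  f <- fit_coxplosive(eps)
  expect_equal(unname(coef(f)[1]), 0.8, tolerance = 1e-4)
  expect_equal(unname(coef(f)[2]), 40, tolerance = 1e-3)
  expect_lt(f$phi_min, 1e-12)
})

test_that("penalty requires at least two events", {
  p <- coxplosive_params(0.5, 10)
  expect_error(penalty_phi(p, 0.1), "2 events")
  expect_error(fit_coxplosive(0.1), "2 events")
  # 2-event sequence: degenerate but fits per contract
  f2 <- fit_coxplosive(c(0.1, 0.18))
  expect_s3_class(f2, "coxplosive")
  expect_true(is.finite(f2$phi_min))
})

test_that("fitted object is internally consistent", {
  s <- simulate_coxplosive(coxplosive_params(0.9, 50), seed = 21)
  f <- fit_coxplosive(s$cum_strains)
  expect_true(f$converged)
  expect_equal(f$mu_inf_hat, mu_infinity(f$params))
  expect_equal(f$n_events, length(s$cum_strains))
  # optimum no worse than the re-evaluated penalty at the fitted point
  expect_equal(f$phi_min, penalty_phi(f$params, s$cum_strains),
               tolerance = 1e-10)
  expect_named(coef(f), c("alpha", "lambda"))
  # predict() returns the expected event strains, increasing to mu_inf
  # (increments underflow double precision at very large k, so strict
  # growth is only asserted while they are representable)
  pr <- predict(f, k = 1:2000)
  expect_true(all(diff(pr) >= 0))
  expect_true(all(diff(pr[1:100]) > 0))
  expect_equal(pr[2000], f$mu_inf_hat, tolerance = 1e-6)
  expect_length(residuals(f), f$n_events)
  sm <- summary(f)
  expect_equal(sm$beta, -log(coef(f)[["alpha"]]))
})

test_that("fit recovers parameters from a well-populated sequence", {
  s <- simulate_coxplosive(coxplosive_params(0.9, 50), max_events = 300,
                           min_increment = 0, seed = 33)
  f <- fit_coxplosive(s$cum_strains)
  expect_lt(abs(coef(f)[["alpha"]] - 0.9), 0.05)
})

test_that("rescaling strains leaves alpha invariant and scales lambda", {
  s <- simulate_coxplosive(coxplosive_params(0.85, 100), max_events = 200,
                           min_increment = 0, seed = 8)
  f1 <- fit_coxplosive(s$cum_strains)
  for (c_scale in c(0.25, 40)) {
    f2 <- fit_coxplosive(s$cum_strains * c_scale)
    expect_equal(coef(f2)[["alpha"]], coef(f1)[["alpha"]], tolerance = 1e-6)
    expect_equal(coef(f2)[["lambda"]], coef(f1)[["lambda"]] / c_scale,
                 tolerance = 1e-4)
  }
})

test_that("simulate() from a fit reproduces sequences deterministically", {
  f <- fit_coxplosive(exact_expectation_sequence(0.85, 80, 40))
  s1 <- simulate(f, nsim = 3, seed = 5)
  s2 <- simulate(f, nsim = 3, seed = 5)
  expect_length(s1, 3L)
  expect_identical(lapply(s1, `[[`, "increments"),
                   lapply(s2, `[[`, "increments"))
})

test_that("Hill estimator matches its closed form", {
  e <- exp(1)
  expect_equal(fit_pareto(c(e, e, e), e_m = 1)$nu, 1)        # 3 / (1+1+1)
  pf <- fit_pareto(c(2, 4, 8, 16), e_m = 1)
  expect_equal(pf$nu, 4 / sum(log(c(2, 4, 8, 16))), tolerance = 1e-12)
  expect_equal(pf$n_tail, 4L)
})

test_that("energies at or below the threshold are excluded as residual", {
  pf <- fit_pareto(c(0.5, 1, 2, 4), e_m = 1)
  expect_equal(pf$n_tail, 2L)                     # 0.5 and 1.0 dropped
  expect_error(fit_pareto(c(0.5, 2), e_m = 1), "fewer than 2")
  expect_error(fit_pareto(c(1, 1, 1), e_m = 1), "fewer than 2")
})

test_that("Hill estimate is scale invariant", {
  set.seed(12)
  e <- rpareto(400, nu = 1.3, e_m = 2)
  nu0 <- fit_pareto(e, e_m = 2)$nu
  for (c_scale in c(1e-3, 7, 1e4)) {
    expect_equal(fit_pareto(e * c_scale, e_m = 2 * c_scale)$nu, nu0,
                 tolerance = 1e-12)
  }
})

test_that("Hill estimate concentrates on the true exponent", {
  set.seed(77)
  nus <- replicate(60, fit_pareto(rpareto(500, 1.6, 1), e_m = 1)$nu)
  se <- 1.6 / sqrt(500)
  expect_lt(abs(mean(nus) - 1.6), 3 * se / sqrt(60) + 0.02)
  # the log-survival regression variant lands close to the MLE
  set.seed(78)
  e <- rpareto(2000, 1.6, 1)
  expect_lt(abs(fit_pareto(e, e_m = 1, method = "lsq")$nu -
                fit_pareto(e, e_m = 1)$nu), 0.15)
})

test_that("threshold selection follows its configured rule", {
  expect_equal(select_threshold(1:100, q = 0.05), quantile(1:100, 0.05,
                                                           names = FALSE))
  th <- select_threshold(1:100, q = 0.05)
  expect_gte(th, 1); expect_lte(th, 6)
  expect_equal(select_threshold(1:100, method = "fixed", value = 0.3), 0.3)
  expect_equal(select_threshold(42), 42)
  expect_error(select_threshold(numeric(0)), "nonempty")
})
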