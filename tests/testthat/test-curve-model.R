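test_that("all-zero counts give an identically zero AGDF with zero area", {
  rec <- make_record(rep(0, 28))
  f <- fit_agdf(rec, agdf_control(lambda = 1))
  expect_lt(max(abs(f$coefficients)), 1e-10)
  expect_lt(abs(agdf_area(f)), 1e-8)
})

test_that("constant counts are reproduced exactly (zero penalty, zero residual)", {
  rec <- make_record(rep(17, 28))
  f <- fit_agdf(rec, agdf_control(lambda = 5, anchor = FALSE))
  expect_equal(evaluate_agdf(f, c(0, 3.7, 14, 28)), rep(17, 4),
               tolerance = 1e-9)
})

test_that("penalized fit matches the dense-grid QP oracle on noisy data", {
  ctrl <- agdf_control(lambda = 1)
  knots <- seedfda:::agdf_knots(ctrl)
  set.seed(101)
  for (i in 1:3) {
    y <- logistic_counts(p = runif(1, 0.3, 1), mid = runif(1, 6, 16),
                         noise_sd = 1.5)
    rec <- make_record(y)
    f <- fit_agdf(rec, ctrl)
    b_oracle <- qp_spline_oracle(knots, 4, c(0, rec$days), c(0, y), 1)
    grid <- seq(0, 28, by = 0.05)
    rmse <- sqrt(mean((evaluate_agdf(f, grid) -
                         drop(recurrence_basis(knots, 4, grid) %*% b_oracle))^2))
    expect_lt(rmse, 1e-6)
  }
})

test_that("evaluation agrees with the Cox-de Boor recurrence definition", {
  rec <- make_record(logistic_counts(seed = 7, noise_sd = 1))
  f <- fit_agdf(rec, agdf_control(lambda = 0.5))
  ts <- c(0, 0.3, 2, 7.77, 13, 27.2, 28)
  direct <- drop(recurrence_basis(f$knots, f$degree, ts) %*% f$coefficients)
  expect_equal(evaluate_agdf(f, ts), direct, tolerance = 1e-10)
})

test_that("evaluation is linear in the coefficients and refuses extrapolation", {
  rec <- make_record(logistic_counts(seed = 3))
  f <- fit_agdf(rec, agdf_control(lambda = 1))
  f2 <- f; f2$coefficients <- 2 * f$coefficients
  expect_equal(evaluate_agdf(f2, 1:28), 2 * evaluate_agdf(f, 1:28))
  expect_error(evaluate_agdf(f, 29), "domain")
  expect_error(evaluate_agdf(f, -1), "domain")
})

test_that("trapezoid area reproduces closed forms on step and ramp series", {
  # constant 25 with (0,0) anchor: 0.5*(0+25)*1 + 25*27 = 687.5
  expect_equal(agdf_area(c(0, rep(25, 28)), 0:28), 687.5)
  # linear ramp y = t: trapezoid exact, 28^2/2 = 392
  expect_equal(agdf_area(c(0, 1:28), 0:28), 392)
  expect_equal(agdf_area(rep(0, 29), 0:28), 0)
  expect_error(agdf_area(1:3, c(1, 1, 2)), "increasing")
  expect_error(agdf_area(1:3, numeric(0)), "grid|degenerate")
})

test_that("residual sum of squares is non-increasing as lambda decreases", {
  rec <- make_record(logistic_counts(seed = 11, noise_sd = 2))
  lambdas <- 10^c(3, 1, -1, -3)
  rss <- vapply(lambdas, function(l)
    suppressWarnings(fit_agdf(rec, agdf_control(lambda = l)))$rss, numeric(1))
  expect_true(all(diff(rss) <= 1e-8))
})

test_that("penalized least squares is linear in the data", {
  y1 <- logistic_counts(seed = 21, noise_sd = 1)
  y2 <- logistic_counts(seed = 22, p = 0.4, noise_sd = 1)
  ctrl <- agdf_control(lambda = 2)
  f1 <- fit_agdf(make_record(y1), ctrl)
  f2 <- fit_agdf(make_record(y2), ctrl)
  f12 <- fit_agdf(make_record(y1 + y2, seeds = 50), ctrl)
  expect_equal(f12$coefficients, f1$coefficients + f2$coefficients,
               tolerance = 1e-8)
})

test_that("area under a near-interpolating fit matches the raw trapezoid", {
  y <- logistic_counts(seed = 31)
  ctrl <- agdf_control(lambda = 1e-8, interior_knots = 1:27)
  f <- suppressWarnings(fit_agdf(make_record(y), ctrl))
  raw <- agdf_area(c(0, y), 0:28)
  expect_lt(abs(agdf_area(f, grid = seq(0, 28, by = 0.01)) - raw) / raw, 0.005)
})

test_that("monotonicity diagnostics: near-monotone at moderate smoothing, warning and projection otherwise", {
  cfg <- simulation_config()
  st <- simulate_study(cfg, seed = 5)
  recs <- sum_replicates(st$records)[seq(1, 194, by = 13)]
  for (r in recs) {
    f <- fit_agdf(r, agdf_control(lambda = 2))
    dmin <- min(evaluate_agdf(f, seq(0, 28, by = 0.1), deriv = 1))
    expect_gte(dmin, -0.02 * r$seeds_total)
  }
  # a sharp noiseless sigmoid under GCV rings: the diagnostic must fire and
  # the isotonic projection must restore monotonicity without moving the area
  counts <- c(0, 2, 4, 13, 29, 37, 42, 44, rep(47, 20))
  rsharp <- make_record(counts, seeds = 50)
  expect_warning(f <- fit_agdf(rsharp), "decreases")
  grid <- seq(0, 28, by = 0.1)
  iso <- stats::isoreg(grid, evaluate_agdf(f, grid))$yf
  expect_true(all(diff(iso) >= 0))
  a_proj <- agdf_area(f, monotone = TRUE)
  expect_lt(abs(a_proj - agdf_area(f)) / agdf_area(f), 0.02)
})

test_that("degenerate inputs are rejected with informative errors", {
  expect_error(germination_record("A", "T25_15", 1, c(1, 2), c(5, 3), 25),
               "decrease")
  expect_error(germination_record("A", "T25_15", 1, c(2, 1), c(1, 2), 25),
               "increasing")
  expect_error(germination_record("A", "T25_15", 1, 1:3, c(0, 10, 30), 25),
               "seeds_total")
  rec1 <- germination_record("A", "T25_15", 1, 14, 10, 25)
  expect_error(fit_agdf(rec1, agdf_control(anchor = FALSE)), "2 distinct")
  # saturated basis at lambda = 0 reports rank deficiency
  rec <- make_record(c(0, 0, 5, 9, 12), days = c(1, 5, 10, 20, 28))
  expect_error(fit_agdf(rec, agdf_control(lambda = 0)), "lambda > 0")
})

test_that("classical indices match hand computations", {
  # final 20 of 25
  rec <- make_record(c(4, 8, 12, 20), days = 1:4)
  ci <- classical_indices(rec)
  expect_equal(ci$final_proportion, 0.8)
  # 50% of final = 10, crossed between day 2 (8) and day 3 (12) -> 2.5
  expect_equal(ci$lt50, 2.5)
  # increments 10 at day 2 and 10 at day 4 -> MGT = 3, CV = 100/3
  rec2 <- make_record(c(0, 10, 10, 20), days = 1:4)
  ci2 <- classical_indices(rec2)
  expect_equal(ci2$mgt, 3)
  expect_equal(ci2$cv, 100 / 3)
  # exact 50% level at an observation returns that day
  rec3 <- make_record(c(10, 15, 20), days = c(2, 5, 9))
  expect_equal(classical_indices(rec3)$lt50, 2)
  # zero germination: undefined, not zero
  ci0 <- classical_indices(make_record(rep(0, 5)))
  expect_true(all(is.na(c(ci0$lt50, ci0$mgt, ci0$cv))))
  expect_equal(ci0$final_proportion, 0)
})

test_that("smooth regression reproduces exact lines and collapses to the mean at huge lambda", {
  x <- seq(0, 10, length.out = 40)
  y <- 2 + 3 * x
  f <- smooth_regression(x, y, lambda = 1e-10)
  expect_lt(f$deviance, 1e-12)
  expect_equal(evaluate_agdf(f, c(1, 5, 9)), 2 + 3 * c(1, 5, 9),
               tolerance = 1e-5)
  # the first-derivative penalty's null space is the constants, so the
  # heavy-smoothing limit is the least-squares constant (the mean)
  set.seed(9)
  y2 <- 2 + 3 * x + rnorm(40)
  f2 <- smooth_regression(x, y2, lambda = 1e9)
  expect_equal(evaluate_agdf(f2, c(2, 8)), rep(mean(y2), 2), tolerance = 1e-3)
  expect_error(smooth_regression(rep(1, 10), rnorm(10)), "constant")
  expect_error(smooth_regression(1:4, 1:4), "at least 5")
})

test_that("smooth regression F test holds its size under the null", {
  set.seed(1234)
  reps <- 200
  hits <- 0
  for (i in seq_len(reps)) {
    x <- runif(100)
    y <- rnorm(100)
    f <- smooth_regression(x, y)
    if (f$p_value > 0.05) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.90)
})
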