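test_that("normalization and percent reduction follow their definitions", {
  expect_equal(normalize_to_control(240, 240), 100)
  expect_equal(normalize_to_control(120, 240), 50)
  expect_equal(normalize_to_control(264, 240), 110)  # supra-control allowed
  expect_error(normalize_to_control(100, 0), "positive")

  expect_equal(percent_reduction(100, 10), 90)
  expect_equal(percent_reduction(100, 100), 0)
  expect_equal(percent_reduction(100, 108.14), -8.14)
  expect_error(percent_reduction(-1, 10), "positive")
})

test_that("percent reduction is invariant under rescaling of raw units", {
  set.seed(11)
  for (i in 1:20) {
    ctrl <- runif(1, 50, 500)
    top_val <- runif(1, -0.2, 1.2) * ctrl
    k <- runif(1, 0.01, 100)
    expect_equal(percent_reduction(ctrl, top_val),
                 percent_reduction(k * ctrl, k * top_val))
    # computing on normalized values gives the same answer
    expect_equal(percent_reduction(ctrl, top_val),
                 percent_reduction(100, normalize_to_control(top_val, ctrl)))
  }
})

test_that("IC interpolation inverts the curve in closed form", {
  d <- c(1, 5, 10, 50, 100)
  f <- fit_4pl(data.frame(dose_uM = d, response = fourpl(d, 100, 0, 1, 1)))
  ic50 <- interpolate_ic(f, 50)
  ic15 <- interpolate_ic(f, 85)
  expect_false(ic50$censored)
  expect_equal(ic50$value_uM, 10, tolerance = 1e-8)
  # analytic: 10^(1 - log10(85/15))
  expect_equal(ic15$value_uM, 10^(1 - log10(85 / 15)), tolerance = 1e-8)

  # shallow curve never reaches 85% of control: IC15 right-censored
  shallow <- fit_4pl(
    data.frame(dose_uM = d, response = fourpl(d, 100, 90, 1, 1)))
  ic <- interpolate_ic(shallow, 85)
  expect_true(ic$censored)
  expect_equal(ic$limit_uM, 100)
})

test_that("IC interpolation agrees with a bisection oracle on the curve", {
  set.seed(23)
  for (i in 1:25) {
    fit <- structure(list(
      top = runif(1, 95, 110), bottom = runif(1, 0, 40),
      hill = runif(1, 0.3, 4), log_ic = runif(1, -0.5, 1.8),
      residual_sse = 0, converged = TRUE, non_informative = FALSE,
      n_doses = 5), class = "fourpl_fit")
    for (level in c(50, 85)) {
      ic <- interpolate_ic(fit, level, max_dose_uM = 1e6)
      oracle <- bisect_ic(fit, level)
      if (!ic$censored) {
        expect_lt(abs(ic$value_uM - oracle) / oracle, 1e-9)
      } else {
        expect_true(is.na(oracle) ||
                      level <= fit$bottom || level >= fit$top)
      }
    }
  }
})

test_that("IC15 <= IC50 whenever both are uncensored on a falling curve", {
  set.seed(31)
  d <- c(1, 5, 10, 50, 100)
  for (i in 1:30) {
    f <- fit_4pl(data.frame(
      dose_uM = d,
      response = fourpl(d, 100, runif(1, 0, 40), runif(1, 0.5, 3),
                        runif(1, -0.3, 1.5))))
    ic15 <- interpolate_ic(f, 85)
    ic50 <- interpolate_ic(f, 50)
    if (!ic15$censored && !ic50$censored) {
      expect_lte(ic15$value_uM, ic50$value_uM)
    }
  }
})

test_that("zero-noise fits recover the true parameters", {
  set.seed(99)
  d <- c(1, 5, 10, 50, 100)
  for (i in 1:50) {
    tp <- list(top = runif(1, 90, 110), bottom = runif(1, 0, 30),
               hill = runif(1, 0.5, 3), log_ic = runif(1, 0, 1.7))
    f <- fit_4pl(data.frame(
      dose_uM = d,
      response = fourpl(d, tp$top, tp$bottom, tp$hill, tp$log_ic)))
    expect_true(f$converged)
    expect_lt(max(abs(c(f$top - tp$top, f$bottom - tp$bottom,
                        f$hill - tp$hill, f$log_ic - tp$log_ic))), 1e-6)
  }
})

test_that("noisy fits recover the IC50 and beat a grid-search oracle", {
  tp <- list(top = 100, bottom = 0, hill = 1, log_ic = 1)
  s <- generate_series(tp, noise_sd = 0.05, n_replicates = 4, seed = 42)
  s$response <- normalize_to_control(
    s$response, mean(s$response[s$dose_uM == 0]))
  f <- fit_4pl(s)
  ic50 <- interpolate_ic(f, 50)
  expect_lt(abs(ic50$value_uM - 10) / 10, 0.20)

  # dense grid search over the parameter box as an independent optimizer
  agg <- stats::aggregate(response ~ dose_uM, s[s$dose_uM > 0, ], mean)
  x <- log10(agg$dose_uM); y <- agg$response
  sse <- function(p) sum((y - fourpl(10^x, p[1], p[2], p[3], p[4]))^2)
  grid <- expand.grid(top = seq(90, 110, 2), bottom = seq(-10, 40, 2.5),
                      hill = seq(0.25, 4, 0.25),
                      log_ic = seq(-1, 2.5, 0.05))
  oracle_sse <- min(apply(grid, 1, sse))
  expect_lte(f$residual_sse, oracle_sse + 1e-9)
})

test_that("flat series are flagged non-informative and censored", {
  d <- c(0, 1, 5, 10, 50, 100)
  flat <- data.frame(dose_uM = d, response = c(100, 99, 98, 97, 96.5, 96))
  f <- fit_4pl(flat)
  expect_true(f$non_informative)
  expect_true(interpolate_ic(f, 85)$censored)
  expect_true(interpolate_ic(f, 50)$censored)
})

test_that("degenerate series are rejected", {
  expect_error(fit_4pl(data.frame(dose_uM = c(0, 100),
                                  response = c(100, 50))),
               "insufficient")
  expect_error(fit_4pl(data.frame(dose_uM = c(1, 10, 100),
                                  response = c(100, NA, 50))),
               "non-finite")
})
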