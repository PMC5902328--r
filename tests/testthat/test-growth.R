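test_that("mu is recovered exactly on noiseless exponentials and is scale-invariant", {
  t <- seq(0, 30, by = 2)
  est <- estimate_growth_rate(list(growth_curve(t, 0.02 * exp(0.1 * t))))
  expect_equal(est$mu, 0.1, tolerance = 1e-9)
  expect_equal(est$flag, "ok")
  scaled <- estimate_growth_rate(list(growth_curve(t, 3.7 * 0.02 * exp(0.1 * t))))
  expect_equal(scaled$mu, est$mu, tolerance = 1e-9)

  expect_error(estimate_growth_rate(list(growth_curve(c(0, 2, 4),
                                                      c(0.02, 0.03, 0.04)))),
               "at least 4 points")
})

test_that("triplicate noisy curves recover the measured growth rates within their SD", {
  truth <- c(glcnac_glc = 0.122, glcnac = 0.056, galnac = 0.084,
             glcn_glc = 0.005)
  printed_sd <- c(0.036, 0.023, 0.014, 0.004)
  for (k in seq_along(truth)) {
    est <- estimate_growth_rate(simulate_growth_curve(truth[[k]],
      config = sim_config(seed = 40 + k, noise_cv = 0.03, n_replicates = 3)))
    expect_lt(abs(est$mu - truth[[k]]), printed_sd[k])
    expect_false(est$flag == "no_growth")
  }
})

test_that("mean recovered mu stays within the printed SD across many simulations", {
  truth <- c(0.122, 0.056, 0.084, 0.005)
  printed_sd <- c(0.036, 0.023, 0.014, 0.004)
  for (k in seq_along(truth)) {
    est <- vapply(1:200, function(s) estimate_growth_rate(
      simulate_growth_curve(truth[k],
        config = sim_config(s, 0.03, 3)))$mu, 0)
    expect_lt(abs(mean(est) - truth[k]), printed_sd[k])
  }
  # zero-rate conditions flag no-growth
  for (s in 1:20) {
    est <- estimate_growth_rate(simulate_growth_curve(0,
      config = sim_config(s, 0.03, 3)))
    expect_equal(est$flag, "no_growth")
    expect_equal(est$mu, 0)
  }
})

test_that("flat noisy curves yield an explicit no-growth result", {
  est <- estimate_growth_rate(simulate_growth_curve(0, od0 = 0.05,
    config = sim_config(7, 0.03, 3)))
  expect_equal(est$mu, 0)
  expect_equal(est$flag, "no_growth")
  expect_true(all(est$replicates$flag == "no_growth"))
})

test_that("SCFA ratios follow the yield stoichiometry and guard division", {
  mk <- function(ac, pr) metabolite_timeseries(
    times = 0:4,
    concentrations = data.frame(acetate = seq(0, ac, length.out = 5),
                                propionate = seq(0, pr, length.out = 5)))
  expect_equal(scfa_ratio(mk(10, 10))$ratio, 1)
  expect_equal(scfa_ratio(mk(10, 20))$ratio, 0.5)
  expect_equal(scfa_ratio(mk(20, 10))$ratio, 2)

  none <- scfa_ratio(mk(5, 0))
  expect_false(none$defined)
  expect_true(is.na(none$ratio))

  # invariant under shared dilution
  diluted <- metabolite_timeseries(0:4,
    data.frame(acetate = seq(0, 10, length.out = 5) / 3,
               propionate = seq(0, 5, length.out = 5) / 3))
  expect_equal(scfa_ratio(diluted)$ratio, 2)

  expect_error(scfa_ratio(metabolite_timeseries(0:2,
    data.frame(acetate = c(0, 1, 2)))), "missing analyte")
})

test_that("consumption rates and their equality test behave as constructed", {
  ts_eq <- simulate_fermentation(
    c(glc = 12.5, glcnac = 12.5),
    list(glc = c(acetate = 1, propionate = 1),
         glcnac = c(acetate = 1, propionate = 1)),
    c(glc = 0.5, glcnac = 0.5),
    sim_config(seed = 3, noise_cv = 0.01, grid = seq(0, 30, by = 2)))
  rates <- consumption_rates(ts_eq, c("glc", "glcnac"))
  expect_equal(rates$rate, c(0.5, 0.5), tolerance = 0.1)
  expect_true(attr(rates, "equal"))

  ts_ne <- simulate_fermentation(
    c(glc = 30, glcnac = 30),
    list(glc = c(acetate = 1, propionate = 1),
         glcnac = c(acetate = 1, propionate = 1)),
    c(glc = 1, glcnac = 2),
    sim_config(seed = 4, noise_cv = 0.005, grid = seq(0, 14, by = 2)))
  rates <- consumption_rates(ts_ne, c("glc", "glcnac"))
  expect_false(attr(rates, "equal"))

  ts_flat <- simulate_fermentation(c(glc = 10), list(glc = c(acetate = 0,
                                                             propionate = 0)),
                                   c(glc = 0), sim_config(5, 0))
  flat <- consumption_rates(ts_flat, "glc")
  expect_equal(flat$rate, 0, tolerance = 1e-9)

  expect_error(consumption_rates(ts_flat, "fructose"), "missing analyte")
})

test_that("growth and HPLC CSVs round-trip through their readers", {
  curves <- simulate_growth_curve(0.1, config = sim_config(1, 0.02, 2))
  curves <- lapply(curves, function(cu) { cu$condition <- "glcnac"; cu })
  p <- tempfile(fileext = ".csv")
  write_growth_curves(curves, p)
  back <- read_growth_curves(p)
  expect_length(back, 2)
  expect_equal(estimate_growth_rate(back)$mu, estimate_growth_rate(curves)$mu)

  ts <- simulate_fermentation(c(glcnac = 25),
    list(glcnac = c(acetate = 2, propionate = 1)), c(glcnac = 0.8),
    sim_config(2, 0.02))
  p2 <- tempfile(fileext = ".csv")
  write_hplc(list(ts), p2)
  back2 <- read_hplc(p2)
  expect_length(back2, 1)
  expect_equal(scfa_ratio(back2[[1]])$ratio, scfa_ratio(ts)$ratio)
})
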