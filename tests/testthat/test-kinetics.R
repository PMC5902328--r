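mm_series <- function(Km, Vmax, conc = exp(seq(log(0.1 * Km), log(10 * Km),
                                               length.out = 8)),
                      replicate_id = 1L) {
  assay_series("S", conc, Vmax * conc / (Km + conc),
               replicate_id = replicate_id)
}

test_that("both estimators recover noiseless Michaelis-Menten parameters exactly", {
  for (truth in list(c(5, 2), c(5.5, 2), c(41.3, 0.7), c(2.4, 3))) {
    s <- mm_series(truth[1], truth[2])
    lb <- fit_lineweaver_burk(list(s))
    expect_equal(lb$Km, truth[1], tolerance = 1e-9)
    expect_equal(lb$Vmax, truth[2], tolerance = 1e-9)
    nl <- fit_michaelis_nonlinear(list(s))
    expect_equal(nl$Km, truth[1], tolerance = 1e-9)
    expect_equal(nl$Vmax, truth[2], tolerance = 1e-9)
  }
  # half-saturation identity: v(Km) = Vmax / 2
  s <- mm_series(5, 2, conc = c(1, 5, 25))
  expect_equal(s$rates[2], 1)
})

test_that("fit preconditions are enforced", {
  s <- mm_series(5, 2)
  s$rates[1] <- 0
  expect_error(fit_lineweaver_burk(list(s)), "zero rate")
  expect_error(fit_lineweaver_burk(list(assay_series("S", c(1, 2), c(0.5, 0.9)))),
               "3 distinct")
  expect_error(compare_km(c(5, 5.5), 4), "at least 2 replicates")
})

test_that("pooled double-reciprocal Km recovers the NagB ground truths under noise", {
  truths <- c(Fru6P = 5.5, NH4 = 41.3, GlcN6P = 2.4)
  for (k in seq_along(truths)) {
    reps <- simulate_assay(truths[[k]], Vmax = 2,
                           config = sim_config(seed = 500 + k, noise_cv = 0.05,
                                               n_replicates = 3),
                           substrate_id = names(truths)[k])
    lb <- fit_lineweaver_burk(reps)
    expect_lt(abs(lb$Km - truths[[k]]) / truths[[k]], 0.15)
    expect_equal(lb$n_replicates, 3L)
    expect_true(lb$Km_se >= 0)
    nl <- fit_michaelis_nonlinear(reps)
    expect_lt(abs(nl$Km - truths[[k]]) / truths[[k]], 0.10)
  }
})

test_that("non-Michaelis-Menten data is flagged rather than silently fitted", {
  decreasing <- assay_series("S", c(1, 2, 4, 8, 16), c(2, 1.5, 1.0, 0.6, 0.3))
  expect_error(fit_michaelis_nonlinear(list(decreasing)), "failed")
  # negative double-reciprocal intercept flags the replicate invalid
  curved <- assay_series("S", c(0.5, 1, 2, 4), c(0.2, 0.45, 1.1, 3.0))
  lb <- fit_lineweaver_burk(list(curved))
  expect_false(all(lb$replicate_fits$valid))
})

test_that("double-reciprocal Km is more variable than nonlinear Km at equal noise", {
  km_lb <- numeric(60); km_nl <- numeric(60)
  for (k in seq_len(60)) {
    reps <- simulate_assay(5.5, 2, config = sim_config(seed = 1000 + k,
                                                       noise_cv = 0.05,
                                                       n_replicates = 1))
    km_lb[k] <- fit_lineweaver_burk(reps)$Km
    km_nl[k] <- fit_michaelis_nonlinear(reps)$Km
  }
  expect_gt(var(km_lb), var(km_nl))
})

test_that("Km comparison reproduces the activator null and detects real shifts", {
  expect_equal(compare_km(c(5, 5, 5), c(5, 5))$p_value, 1)

  null_p <- vapply(1:200, function(k) {
    a <- simulate_assay(5.5, 2, config = sim_config(2000 + k, 0.10, 3))
    b <- simulate_assay(5.5, 2, config = sim_config(7000 + k, 0.10, 2),
                        activator_conc = 0.25)
    compare_km(fit_lineweaver_burk(a)$replicate_fits$Km,
               fit_lineweaver_burk(b)$replicate_fits$Km)$p_value
  }, 0)
  expect_gte(mean(null_p > 0.05), 0.9)

  alt_p <- vapply(1:200, function(k) {
    a <- simulate_assay(5.5, 2, config = sim_config(3000 + k, 0.05, 3))
    b <- simulate_assay(5 * 5.5, 2, config = sim_config(8000 + k, 0.05, 3))
    compare_km(fit_lineweaver_burk(a)$replicate_fits$Km,
               fit_lineweaver_burk(b)$replicate_fits$Km)$p_value
  }, 0)
  expect_gte(mean(alt_p < 0.05), 0.9)
})

test_that("glutamine-direction activity is indistinguishable from blank", {
  set.seed(99)
  blank <- abs(rnorm(4, 0.01, 0.005))
  inactive <- abs(rnorm(4, 0.01, 0.005))
  active <- rnorm(4, 0.5, 0.02)
  expect_false(activity_above_blank(inactive, blank)$active)
  expect_true(activity_above_blank(active, blank)$active)
})

test_that("assay CSV round-trips", {
  reps <- c(simulate_assay(5.5, 2, config = sim_config(1, 0.05, 2),
                           substrate_id = "Fru6P"),
            simulate_assay(2.4, 1, config = sim_config(2, 0.05, 2),
                           substrate_id = "GlcN6P", activator_conc = 0.25))
  p <- tempfile(fileext = ".csv")
  write_assays(reps, p)
  back <- read_assays(p)
  expect_length(back, 4)
  orig_km <- fit_lineweaver_burk(reps[1:2])$Km
  back_f6p <- Filter(function(s) s$substrate_id == "Fru6P", back)
  expect_equal(fit_lineweaver_burk(back_f6p)$Km, orig_km, tolerance = 1e-9)
})
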