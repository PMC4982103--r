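test_that("zero-noise dechelation curves equal the closed-form exponential", {
  ex <- generate_dechelation_experiment(noise = noise_model(magnitude = 0),
                                        seed = 1)
  for (i in seq_along(ex$curves)) {
    cv <- ex$curves[[i]]
    c0 <- ex$truth$rates_true$conc_M[i]
    expect_equal(cv$conc_M, c0 * exp(-3.17e-5 * cv$time_s), tolerance = 1e-14)
  }
  expect_equal(ex$rates$rate_M_per_s, ex$truth$rates_true$rate_M_per_s,
               tolerance = 1e-14)
})

test_that("generators are pure functions of their arguments and seed", {
  a <- generate_dechelation_experiment(seed = 42)
  b <- generate_dechelation_experiment(seed = 42)
  expect_identical(a$rates, b$rates)
  expect_identical(a$curves, b$curves)
  expect_false(identical(a$rates,
                         generate_dechelation_experiment(seed = 43)$rates))
  t1 <- generate_chelatase_assay("fig3b-low", seed = 5)
  t2 <- generate_chelatase_assay("fig3b-low", seed = 5)
  expect_identical(t1$trace$fluor_au, t2$trace$fluor_au)
})

test_that("noisy rates never contain the truth channel values", {
  ex <- generate_dechelation_experiment(seed = 42)
  expect_true(all(ex$rates$rate_M_per_s != ex$truth$rates_true$rate_M_per_s))
})

test_that("Fig-4 preset refit recovers the generating constant within 3 SE", {
  pre <- chela_preset("fig4")
  ex <- generate_dechelation_experiment(k_true = pre$k_true_per_s,
                                        concs_M = pre$concs_M,
                                        duration_s = pre$duration_s,
                                        n_points = pre$n_points,
                                        noise = pre$noise, seed = 42)
  fit <- fit_first_order_constant(ex$rates)
  se <- fit_sampling_se(pre$k_true_per_s, pre$concs_M, pre$noise$magnitude)
  expect_lt(abs(fit$k_dechel_per_s - pre$k_true_per_s), 3 * se)
})

test_that("coverage of the through-origin estimator over 500 seeded replicates is >= 90%", {
  pre <- chela_preset("fig4")
  se <- fit_sampling_se(pre$k_true_per_s, pre$concs_M, pre$noise$magnitude)
  hits <- vapply(1:500, function(s) {
    ex <- generate_dechelation_experiment(k_true = pre$k_true_per_s,
                                          concs_M = pre$concs_M,
                                          noise = pre$noise, seed = s)
    k <- fit_first_order_constant(ex$rates)$k_dechel_per_s
    abs(k - pre$k_true_per_s) <= 2 * se
  }, logical(1))
  expect_gte(mean(hits), 0.90)
})

test_that("preset registry covers the documented experiments with unique names", {
  nms <- chela_presets()
  expect_true(all(c("fig2a", "fig2b", "fig2c", "fig2a-noregen", "fig3b-low",
                    "fig4", "gun4-fig2b") %in% nms))
  expect_identical(anyDuplicated(nms), 0L)
  expect_error(chela_preset("nope"), "unknown preset")
})

test_that("identity fluorescence mapping returns the simulated product series", {
  a <- generate_chelatase_assay("fig3b-low", gain_au_per_M = 1,
                                baseline_au = 0,
                                noise = noise_model(magnitude = 0), seed = 1)
  expect_equal(a$trace$fluor_au, a$curve$MgD_M, tolerance = 1e-14)
})

test_that("fluorescence round-trip is exact at zero noise and clips below baseline", {
  a <- generate_chelatase_assay("fig2b", gain_au_per_M = 1e8,
                                baseline_au = 50,
                                noise = noise_model(magnitude = 0), seed = 1)
  rt <- fluorescence_to_conc(a$trace)
  expect_equal(rt$conc$conc_M, a$curve$MgD_M, tolerance = 1e-12)
  expect_identical(rt$n_clipped, 0L)
  # push the baseline above the early signal: clipping must be reported
  shifted <- a$trace
  shifted$fluor_au <- shifted$fluor_au - 100
  rt2 <- fluorescence_to_conc(shifted)
  expect_gt(rt2$n_clipped, 0)
  expect_true(all(rt2$conc$conc_M >= 0))
  expect_error(fluorescence_to_conc(a$trace, gain_au_per_M = 0), "> 0")
})

test_that("round-trip error of a noisy trace is consistent with the injected noise", {
  a <- generate_chelatase_assay("fig2b", baseline_au = 50,
                                noise = noise_model(magnitude = 0.03),
                                seed = 3)
  rt <- fluorescence_to_conc(a$trace)
  keep <- a$curve$MgD_M > 1e-7
  rel <- (rt$conc$conc_M[keep] - a$curve$MgD_M[keep]) / a$curve$MgD_M[keep]
  rmse <- sqrt(mean(rel^2))
  expect_lt(rmse, 0.03 * 1.3 * 1.3)  # band includes the baseline's share
  expect_gt(rmse, 0.03 / 1.3)
})

test_that("assay preset traces have the documented shapes", {
  b <- generate_chelatase_assay("fig2b", noise = noise_model(magnitude = 0),
                                seed = 1)
  m <- steady_state_maintenance_time(b$curve)
  expect_gte(m$duration_s / 3600, 7)
  a <- generate_chelatase_assay("fig2a-noregen",
                                noise = noise_model(magnitude = 0), seed = 1)
  i <- which.max(a$curve$MgD_M)
  expect_gt(i, 1L)
  expect_lt(i, nrow(a$curve))
})

test_that("generator input validation", {
  expect_error(generate_dechelation_experiment(k_true = 0), "> 0")
  expect_error(generate_dechelation_experiment(concs_M = numeric()),
               "non-empty")
  expect_error(generate_dechelation_experiment(n_points = 1), "grid")
  expect_error(noise_model(magnitude = -1), ">= 0")
  expect_error(generate_chelatase_assay("fig4"), "not an assay")
})
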