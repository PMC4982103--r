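test_that("chelation velocity matches the hand-evaluated rate law", {
  v <- chelation_velocity(list(D_M = 8e-6, MgD_M = 0, ATP_M = 5e-3),
                          default_params(), chela_conditions())
  expect_equal(v, 7.02e-10, tolerance = 1e-3)
  # zero enzyme, zero substrate, zero nucleotide all shut the flux off
  expect_identical(
    chelation_velocity(list(D_M = 8e-6, MgD_M = 0, ATP_M = 5e-3),
                       default_params(), chela_conditions(ChlI_M = 0)), 0)
  expect_identical(
    chelation_velocity(list(D_M = 0, MgD_M = 0, ATP_M = 5e-3),
                       default_params(), chela_conditions()), 0)
  expect_identical(
    chelation_velocity(list(D_M = 8e-6, MgD_M = 0, ATP_M = 0),
                       default_params(), chela_conditions()), 0)
})

test_that("product inhibition scales the velocity by 1/(1 + MgD/Ki)", {
  st <- list(D_M = 4e-6, MgD_M = 4e-6, ATP_M = 5e-3)
  v_off <- chelation_velocity(st, default_params(), chela_conditions())
  v_on <- chelation_velocity(st, default_params(Ki_product_M = 4e-6),
                             chela_conditions())
  expect_equal(v_on, v_off / 2, tolerance = 1e-12)
})

test_that("ATP flux combines coupled stoichiometry and basal ATPase", {
  # with basal turnover off the flux is exactly n_ATP * velocity
  p <- default_params(k_basal_ATPase_per_s = 0)
  st <- list(D_M = 8e-6, MgD_M = 0, ATP_M = 5e-3)
  expect_equal(atp_flux(st, p, chela_conditions()),
               15 * chelation_velocity(st, p, chela_conditions()),
               tolerance = 1e-12)
  expect_identical(atp_flux(list(D_M = 8e-6, MgD_M = 0, ATP_M = 0),
                            default_params(), chela_conditions()), 0)
  # basal component at saturating ATP ~ k_basal * ChlI ~ 7e-8 M/s
  basal <- atp_flux(list(D_M = 0, MgD_M = 0, ATP_M = 1), default_params(),
                    chela_conditions())
  expect_equal(basal, 0.7 * 1e-7, tolerance = 1e-3)
})

test_that("with no enzyme the simulator reproduces closed-form dechelation decay", {
  cond <- chela_conditions(ChlI_M = 0, D_total_M = 2.5e-6,
                           regeneration_on = FALSE)
  pc <- simulate_progress(default_params(), cond, t_end_s = 6 * 3600,
                          n_out = 73, MgD0_M = 2.5e-6)
  expected <- 2.5e-6 * exp(-3.17e-5 * pc$time_s)
  expect_true(all(abs(pc$MgD_M - expected) <= 1e-3 * expected + 1e-15))
})

test_that("porphyrin mass is conserved along every simulated trajectory", {
  for (nm in c("fig2a", "fig2b", "fig2a-noregen", "fig3b-low")) {
    pre <- chela_preset(nm)
    pc <- simulate_progress(pre$params, pre$conditions, pre$t_end_s, 181)
    Dtot <- pre$conditions$D_total_M
    expect_lt(max(abs(pc$D_M + pc$MgD_M - Dtot)), 1e-6 * Dtot)
  }
})

test_that("nucleotide bookkeeping: ATP non-increasing without regeneration, clamped with it", {
  pre <- chela_preset("fig2a-noregen")
  pc <- simulate_progress(pre$params, pre$conditions, pre$t_end_s, 301)
  expect_true(all(diff(pc$ATP_M) <= 1e-15))
  pre2 <- chela_preset("fig2b")
  pc2 <- simulate_progress(pre2$params, pre2$conditions, pre2$t_end_s, 301)
  expect_true(all(diff(pc2$PEP_M) <= 1e-15))
  pep_left <- pc2$PEP_M > 0
  expect_true(all(abs(pc2$ATP_M[pep_left] - 1e-3) < 1e-9))
})

test_that("with an ideal ATP clamp MgD rises monotonically to the algebraic root", {
  cond <- chela_conditions(ATP0_M = 5e-3, PEP0_M = Inf)
  pc <- simulate_progress(default_params(), cond, 12 * 3600, 361)
  expect_true(all(diff(pc$MgD_M) >= -1e-12))
  ss <- find_steady_state(default_params(), cond)
  expect_equal(tail(pc$MgD_M, 1), ss$MgD_ss_M, tolerance = 5e-3)
})

test_that("rise-and-fall preset shows a single interior maximum and the dechelation tail", {
  pre <- chela_preset("fig2a-noregen")
  pc <- simulate_progress(pre$params, pre$conditions, pre$t_end_s, pre$n_out)
  i <- which.max(pc$MgD_M)
  expect_gt(i, 1L)
  expect_lt(i, nrow(pc))
  expect_true(all(diff(pc$MgD_M[i:nrow(pc)]) <= 1e-15))
  expect_lt(tail(pc$MgD_M, 1), 0.5 * max(pc$MgD_M))
  # once the nucleotide is exhausted the log-linear tail decays at -k_dechel
  tail_pts <- pc[pc$time_s >= 8 * 3600, ]
  slope <- stats::coef(stats::lm(log(tail_pts$MgD_M) ~ tail_pts$time_s))[[2]]
  expect_equal(slope, -3.17e-5, tolerance = 0.01)
})

test_that("steady-state solver matches an independent bisection oracle", {
  cond <- low_porphyrin_conditions()
  ss <- find_steady_state(default_params(), cond)
  D_oracle <- bisect_steady_state(default_params(), cond)
  expect_equal(ss$D_ss_M, D_oracle, tolerance = 1e-9)
  expect_equal(ss$MgD_ss_M, 2.32e-6, tolerance = 2e-3)
  expect_equal(ss$ratio_over_Mg_per_M, 1.3e3, tolerance = 0.03)
  # flux balance at the root
  expect_equal(ss$velocity_ss_M_per_s, 3.17e-5 * ss$MgD_ss_M,
               tolerance = 1e-10)
  expect_lt(abs(ss$D_ss_M + ss$MgD_ss_M - 2.5e-6), 1e-12)
})

test_that("steady-state boundary cases are handled analytically", {
  ss0 <- find_steady_state(default_params(),
                           chela_conditions(ChlI_M = 0))
  expect_identical(ss0$MgD_ss_M, 0)
  expect_true(ss0$boundary)
  ssk <- find_steady_state(default_params(k_dechel_per_s = 0),
                           chela_conditions(ATP0_M = 5e-3))
  expect_equal(ssk$MgD_ss_M, 8e-6)
  expect_true(ssk$boundary)
  ssa <- find_steady_state(default_params(), chela_conditions(ATP0_M = 0))
  expect_identical(ssa$MgD_ss_M, 0)
})

test_that("simulated plateau agrees with the algebraic root within 0.5%", {
  cond <- chela_conditions(ATP0_M = 1e-3, PEP0_M = Inf)
  pc <- simulate_progress(default_params(), cond, 14 * 3600, 141)
  ss <- find_steady_state(default_params(), cond)
  expect_lt(abs(tail(pc$MgD_M, 1) - ss$MgD_ss_M) / ss$MgD_ss_M, 0.005)
})

test_that("steady-state ratio is monotone in ATP and in total porphyrin", {
  r_atp <- vapply(c(2e-4, 5e-4, 1e-3, 5e-3), function(a) {
    find_steady_state(default_params(), chela_conditions(ATP0_M = a))$ratio_ss
  }, numeric(1))
  expect_true(all(diff(r_atp) >= 0))
  r_dtot <- vapply(c(2.5, 5, 10, 20) * 1e-6, function(d) {
    find_steady_state(default_params(),
                      chela_conditions(D_total_M = d, ATP0_M = 5e-3))$ratio_ss
  }, numeric(1))
  expect_true(all(diff(r_dtot) <= 0))
})

test_that("displacement factor is the ratio over the equilibrium constant", {
  th <- default_thermo()
  expect_equal(displacement_factor(5e2, th), 5e8)
  expect_equal(displacement_factor(th$K_eq_per_M, th), 1)
  ss <- find_steady_state(default_params(), low_porphyrin_conditions())
  expect_equal(displacement_factor(ss, th), 1.3e9, tolerance = 0.03)
  expect_error(displacement_factor(-1, th), "> 0")
})

test_that("maintenance time handles degenerate curves", {
  flat <- data.frame(time_s = seq(0, 100, 10), MgD_M = rep(2e-6, 11))
  m <- steady_state_maintenance_time(flat)
  expect_equal(m$duration_s, 100)
  expect_false(m$no_plateau)
  decay <- data.frame(time_s = seq(0, 100, 10),
                      MgD_M = 2e-6 * exp(-0.05 * seq(0, 100, 10)))
  m2 <- steady_state_maintenance_time(decay)
  expect_identical(m2$duration_s, 0)
  expect_true(m2$no_plateau)
})

test_that("regeneration preset maintains the plateau for at least 7 hours", {
  pre <- chela_preset("fig2b")
  pc <- simulate_progress(pre$params, pre$conditions, pre$t_end_s, pre$n_out)
  m <- steady_state_maintenance_time(pc, tolerance_fraction = 0.10)
  expect_gte(m$duration_s / 3600, 7)
})

test_that("simulator validates its inputs", {
  expect_error(simulate_progress(default_params(), chela_conditions(), -1),
               "t_end_s")
  expect_error(simulate_progress(default_params(), chela_conditions(),
                                 100, n_out = 1), "n_out")
  expect_error(simulate_progress(default_params(), chela_conditions(),
                                 100, MgD0_M = 1), "MgD0_M")
})
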