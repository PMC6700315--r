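test_that("right-hand side fixed points and degenerate limits are exact", {
  # no template, empty state: nothing moves
  p0 <- txtl_params(P70 = 0)
  E0 <- solve_free_rnap(p0)$E0
  d <- ode_rhs(c(m = 0, deGFP_dark = 0, deGFP_mat = 0), p0, E0 = E0)
  expect_equal(unname(d), c(0, 0, 0))

  # negligible degradation and translation: dm/dt = k_TX * P70, constant
  pl <- txtl_params(kd_m = 1e-12, kcat_p = 1e-12, P70 = 2)
  E0l <- solve_free_rnap(pl)$E0
  ktx <- pl$kcat_m * E0l * pl$S70_total /
    (pl$KM_70 * (pl$K70 + E0l) + E0l * pl$S70_total)
  d0 <- ode_rhs(c(m = 0, deGFP_dark = 0, deGFP_mat = 0), pl, E0 = E0l)
  d1 <- ode_rhs(c(m = 500, deGFP_dark = 0, deGFP_mat = 0), pl, E0 = E0l)
  expect_equal(d0[["m"]], ktx * 2, tolerance = 1e-9)
  expect_equal(d1[["m"]], d0[["m"]], tolerance = 1e-6)

  # dm/dt vanishes at the steady-state mRNA computed independently here
  p1 <- txtl_params(P70 = 1)
  E01 <- oracle_E0(p1)
  q <- p1$kcat_m * E01 * p1$S70_total /
    (p1$KM_70 * (p1$K70 + E01) + E01 * p1$S70_total) * p1$P70
  m_star <- p1$KM_m * q / (p1$kd_m - q)
  dss <- ode_rhs(c(m = m_star, deGFP_dark = 0, deGFP_mat = 0), p1, E0 = E01)
  expect_lt(abs(dss[["m"]]), 1e-9)
})

test_that("simulated kinetics respect conservation, positivity, monotonicity", {
  p <- txtl_params(P70 = 1)
  tr <- simulate_kinetics(p, t_end = 4 * 3600)
  expect_s3_class(tr, "txtl_trace")
  expect_equal(tr$time_s[1], 0)
  expect_true(all(tr$mrna_nM >= 0))
  expect_true(all(tr$degfp_dark_nM >= 0))
  expect_true(all(tr$degfp_mat_nM >= 0))
  # total reporter protein never decreases (no protein degradation)
  expect_true(all(diff(tr$degfp_dark_nM + tr$degfp_mat_nM) >= -1e-9))
  expect_conserved(tr, p, tol = 1e-6)
})

test_that("zero template yields an identically-zero trace", {
  tr <- simulate_kinetics(txtl_params(P70 = 0), t_end = 2 * 3600)
  expect_true(all(tr$mrna_nM == 0))
  expect_true(all(tr$degfp_mat_nM == 0))
})

test_that("late-time slope matches the analytic linear-regime rate", {
  p <- txtl_params(P70 = 1)
  tr <- simulate_kinetics(p, t_end = 4 * 3600)
  win <- tr$time_s >= 2 * 3600
  slope <- stats::coef(stats::lm(degfp_mat_nM ~ time_s, tr[win, ]))[2]
  expect_equal(unname(slope), linear_regime_protein_rate(p), tolerance = 0.05)
})

test_that("maturation rate shifts dark/mature split but conserves total", {
  p1 <- txtl_params(P70 = 1)
  p2 <- set_params(p1, k_mat = 2 * p1$k_mat)
  tr1 <- simulate_kinetics(p1, t_end = 2 * 3600)
  tr2 <- simulate_kinetics(p2, t_end = 2 * 3600)
  tot1 <- tr1$degfp_dark_nM + tr1$degfp_mat_nM
  tot2 <- tr2$degfp_dark_nM + tr2$degfp_mat_nM
  expect_equal(tot1, tot2, tolerance = 1e-6)
  expect_true(all(tr2$degfp_mat_nM >= tr1$degfp_mat_nM - 1e-9))
})

test_that("steady-state mRNA matches the worked estimates", {
  # strong-promoter approximation with a 20-min mean lifetime: 78 (~80) nM
  p <- txtl_params(kd_m = 8000 / 1200)   # kdeg_m = 1/1200 /s
  expect_equal(mrna_steady_state(p, approximate = TRUE), 78)
  # theoretical ceiling at the 0.5/s initiation cap: 600 nM
  p_max <- set_params(p, kcat_m = 0.5)
  expect_equal(mrna_steady_state(p_max, approximate = TRUE), 600)
  # the full solution (finite E0) sits a few percent below the approximation
  full <- mrna_steady_state(txtl_params())
  expect_gt(full, 70)
  expect_lt(full, 80)
  expect_equal(mrna_steady_state(txtl_params(P70 = 0)), 0)
})

test_that("linear-regime rate reproduces the worked values", {
  expect_equal(linear_regime_protein_rate(txtl_params()),
               6e-3 * 6.5e-2 / 8.25e-4)
  # theoretical ceiling: both kcats at 0.5/s, 20-min lifetime -> 300 nM/s
  p_max <- txtl_params(kcat_m = 0.5, kcat_p = 0.5, kd_m = 8000 / 1200)
  expect_equal(linear_regime_protein_rate(p_max), 300)
  expect_equal(linear_regime_protein_rate(txtl_params(P70 = 0)), 0)
})

test_that("analytic steady-state rate equals the simulated slope", {
  for (conc in c(0.5, 2, 8)) {
    p <- txtl_params(P70 = conc)
    tr <- suppressWarnings(simulate_kinetics(p, t_end = 4 * 3600))
    expect_equal(suppressWarnings(steady_state_rate(p)),
                 max_synthesis_rate(tr), tolerance = 0.05)
  }
})
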