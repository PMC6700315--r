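grid_sens <- c(0.5, 1, 2, 5, 10, 20, 30)

test_that("factor 1 reproduces the base curve, unknown parameters rejected", {
  p <- txtl_params()
  sc <- sensitivity_scan(p, "R_total", factors = 1, plasmid_grid = grid_sens)
  base <- rate_vs_plasmid(p, grid_sens, method = "steady_state")
  expect_equal(sc$max_rate_nM_per_s, base$max_rate_nM_per_s)
  expect_equal(attr(sc, "summary_metric"), 0)
  expect_error(sensitivity_scan(p, "bogus"), "unknown scan parameter")
})

test_that("rates respond monotonically to resource and degradation scans", {
  p <- txtl_params()
  for (param in c("R_total", "E_total")) {
    sc <- suppressWarnings(sensitivity_scan(p, param,
                                            plasmid_grid = grid_sens))
    wide <- tidyr::pivot_wider(tibble::as_tibble(sc),
                               names_from = "factor",
                               values_from = "max_rate_nM_per_s",
                               id_cols = "plasmid_nM")
    m <- as.matrix(wide[, -1])  # columns ordered by increasing factor
    expect_true(all(diff(t(m)) >= -1e-9),
                label = paste("rates non-decreasing in", param))
  }
  sc_deg <- suppressWarnings(sensitivity_scan(p, "kdeg_m",
                                              plasmid_grid = grid_sens))
  wide <- tidyr::pivot_wider(tibble::as_tibble(sc_deg),
                             names_from = "factor",
                             values_from = "max_rate_nM_per_s",
                             id_cols = "plasmid_nM")
  expect_true(all(diff(t(as.matrix(wide[, -1]))) <= 1e-9))
})

test_that("tenfold more ribosomes push the saturation onset ~tenfold out", {
  p <- txtl_params()
  onset1 <- saturation_onset(p)
  onset10 <- saturation_onset(set_params(p, R_total = 10 * p$R_total),
                              interval = c(0.1, 200))
  ratio <- onset10 / onset1
  expect_gt(ratio, 5)
  expect_lt(ratio, 15)
})

test_that("sigma-70 scan is quiet; Michaelis scans much weaker than ribosomes", {
  p <- txtl_params()
  sc_S70 <- sensitivity_scan(p, "S70_total", plasmid_grid = grid_sens)
  s <- attr(sc_S70, "summary")
  # adding sigma (the physiologically plausible direction) barely moves the
  # rates; starving it tenfold drops holoenzyme occupancy and does bite
  expect_lt(max(s$max_rel_change[s$factor >= 1]), 0.05)
  m_S70 <- attr(sc_S70, "summary_metric")
  m_R <- attr(suppressWarnings(
    sensitivity_scan(p, "R_total", plasmid_grid = grid_sens)),
    "summary_metric")
  expect_gt(m_R / m_S70, 3)
  m_KM70 <- attr(sensitivity_scan(p, "KM_70", plasmid_grid = grid_sens),
                 "summary_metric")
  m_KMR <- attr(sensitivity_scan(p, "KM_R", plasmid_grid = grid_sens),
                "summary_metric")
  expect_gt(m_R / m_KM70, 3)
  expect_gt(m_R / m_KMR, 3)
})

test_that("depletion profile shows the sharp ribosome drop, polymerase intact", {
  p <- txtl_params()
  prof <- resource_depletion_profile(p, seq(0, 30, by = 1))
  expect_equal(prof$R0_nM[1], p$R_total)
  # zero template: E0 from the independently solved quadratic
  b <- p$K70 + p$S70_total - p$E_total
  expect_equal(prof$E0_nM[1], (-b + sqrt(b^2 + 4 * p$E_total * p$K70)) / 2,
               tolerance = 1e-7)
  expect_true(all(diff(prof$R0_nM) < 0))
  expect_true(all(diff(prof$E0_nM) < 0))
  # ribosomes are the limiting resource: at 30 nM plasmid the free
  # polymerase pool is still ample while free ribosomes have collapsed
  expect_gt(prof$E0_nM[prof$plasmid_nM == 30], 100)
  expect_lt(prof$R0_nM[prof$plasmid_nM == 30], 0.05 * p$R_total)
  # by the saturation onset the free ribosome pool is already far below half
  onset <- saturation_onset(p)
  at_onset <- resource_depletion_profile(p, c(0, onset))
  expect_lt(at_onset$R0_nM[2], p$R_total / 2)
})
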