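test_that("exponential decay fit recovers exact and noisy rates", {
  k <- 8.25e-4
  t <- seq(0, 7200, by = 180)
  clean <- tibble::tibble(time_s = t, signal_nM = 100 * exp(-k * t))
  f <- fit_exponential_decay(clean)
  expect_equal(f$estimates$k, k, tolerance = 1e-6)
  expect_equal(f$estimates$A, 100, tolerance = 1e-6)
  expect_equal(f$estimates$mean_lifetime_s, 1 / k, tolerance = 1e-6)

  # three points on an exact exponential pin k = 1/t1
  t1 <- 1000
  three <- tibble::tibble(time_s = c(0, t1, 2 * t1),
                          signal_nM = 50 * exp(-c(0, 1, 2)))
  expect_equal(fit_exponential_decay(three)$estimates$k, 1 / t1,
               tolerance = 1e-9)

  noisy <- generate_decay_trace(k, 100, noise_model(0.05, 0, seed = 7),
                                duration = 2 * 3600)
  fn <- fit_exponential_decay(noisy)
  expect_equal(fn$estimates$k, k, tolerance = 0.1)

  expect_error(fit_exponential_decay(
    tibble::tibble(time_s = 0:5, signal_nM = rep(0, 6))), "non-positive")
  expect_error(fit_exponential_decay(clean[1:2, ]), "3 points")
})

test_that("decay fit is invariant to time-unit rescaling", {
  t <- seq(0, 7200, by = 180)
  d_s <- tibble::tibble(time_s = t, signal_nM = 80 * exp(-1e-3 * t))
  d_min <- tibble::tibble(time_s = t / 60, signal_nM = d_s$signal_nM)
  k_s <- fit_exponential_decay(d_s)$estimates$k
  k_min <- fit_exponential_decay(d_min)$estimates$k
  expect_equal(k_min, k_s * 60, tolerance = 1e-8)
})

test_that("maturation fit recovers the rate, invariant to amplitude", {
  k <- 1.2e-3
  noise0 <- noise_model(0, 0, seed = 1)
  tr <- generate_maturation_trace(k, 200, noise0)
  f <- fit_maturation(tr)
  expect_equal(f$estimates$k_mat, k, tolerance = 1e-6)

  tr10 <- tr
  tr10$signal_nM <- tr10$signal_nM * 10
  expect_equal(fit_maturation(tr10)$estimates$k_mat,
               f$estimates$k_mat, tolerance = 1e-6)

  noisy <- generate_maturation_trace(k, 200, noise_model(0.05, 0, seed = 3))
  expect_equal(fit_maturation(noisy)$estimates$k_mat, k, tolerance = 0.1)
})

test_that("steady-state inversions reproduce the worked constants", {
  # MGapt assay: 25 nM mRNA at 1 nM plasmid, 27-min lifetime -> ~1.5e-2 /s
  ktx <- ktx_from_mrna_steady_state(25, 1, 27 * 60)
  expect_equal(ktx, 25 / 1620)
  expect_equal(signif(ktx, 2), 1.5e-2)
  expect_equal(ktx_from_mrna_steady_state(0, 1, 1200), 0)
  expect_equal(ktx_from_mrna_steady_state(50, 2, 27 * 60), ktx)  # homogeneity
  expect_error(ktx_from_mrna_steady_state(25, 0, 1200), "plasmid")

  # 0.5 nM/s at 1 nM plasmid -> kcat product ~4e-4 /s^2
  prod <- kcat_product_from_rate(0.5, 1, 8.25e-4)
  expect_equal(prod, 4.125e-4)
  expect_equal(signif(prod, 1), 4e-4)
  expect_equal(kcat_product_from_rate(0, 1, 8.25e-4), 0)
  expect_equal(kcat_product_from_rate(1, 1, 8.25e-4), 2 * prod)  # linearity
})

test_that("kcat fit recovers generating constants from a noiseless curve", {
  p <- txtl_params()
  grid <- c(0.5, 1, 2, 5, 10, 20, 30)
  rc <- rate_vs_plasmid(p, grid, method = "steady_state")
  data <- tibble::tibble(plasmid_nM = grid,
                         max_rate_nM_per_s = rc$max_rate_nM_per_s)
  f <- fit_kcats_to_rate_curve(data, p)
  expect_true(f$converged)
  expect_equal(f$estimates$kcat_product, 6.5e-2 * 6e-3, tolerance = 0.02)
  expect_equal(f$estimates$kcat_m, 6.5e-2, tolerance = 0.15)
  expect_equal(f$estimates$kcat_p, 6e-3, tolerance = 0.15)
  expect_lt(f$rss, 1e-6)
  expect_null(f$note)
  td <- tidy(f)
  expect_true(all(td$estimate <= td$upper & td$estimate >= td$lower))
})

test_that("linear-only curves constrain the product and are flagged", {
  p <- txtl_params()
  weak <- set_params(p, kcat_m = 6.5e-3)
  grid <- c(0.5, 1, 2, 5, 10, 20, 30)
  rc <- rate_vs_plasmid(weak, grid, method = "steady_state")
  f <- fit_kcats_to_rate_curve(
    tibble::tibble(plasmid_nM = grid,
                   max_rate_nM_per_s = rc$max_rate_nM_per_s), p)
  expect_equal(f$estimates$kcat_product, 6.5e-3 * 6e-3, tolerance = 0.05)
  expect_match(f$note, "product")
  expect_match(glance(f)$note, "identifiable")
})

test_that("part strength table normalises to the reference construct", {
  p <- txtl_params()
  grid <- c(0.5, 1, 2)
  slope <- function(s_m, s_p) {
    q <- set_params(p, kcat_m = p$kcat_m * s_m, kcat_p = p$kcat_p * s_p)
    rc <- rate_vs_plasmid(q, grid, method = "steady_state")
    tibble::tibble(plasmid_nM = rc$plasmid_nM,
                   max_rate_nM_per_s = rc$max_rate_nM_per_s)
  }
  d <- dplyr::bind_rows(
    dplyr::mutate(slope(1, 1), promoter = "P70a", utr = "UTR1"),
    dplyr::mutate(slope(0.5, 1), promoter = "P70b", utr = "UTR1"),
    dplyr::mutate(slope(0.1, 1), promoter = "P70c", utr = "UTR1"))
  tab <- part_strength_table(d)
  ref <- tab[tab$promoter == "P70a", ]
  expect_equal(ref$relative_strength, 1)
  expect_equal(tab$relative_strength[tab$promoter == "P70b"], 0.5,
               tolerance = 0.02)
  expect_equal(tab$relative_strength[tab$promoter == "P70c"], 0.1,
               tolerance = 0.02)
  # reported in nM/h per nM plasmid
  expect_equal(ref$rate_per_plasmid_nM_h,
               attr(rate_vs_plasmid(p, grid, method = "steady_state"),
                    "slope_linear") * 3600,
               tolerance = 1e-6)
})
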