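test_that("zero noise reproduces the simulation exactly, seeds reproduce", {
  p <- txtl_params(P70 = 1)
  run <- generate_kinetics(p, noise_model(0, 0, seed = 1),
                           duration = 2 * 3600)
  truth <- attr(run, "truth")
  expect_equal(run$value_nM, truth$degfp_mat_nM)
  expect_equal(run$time_s, truth$time_s)

  a <- generate_kinetics(p, noise_model(0.05, 2, seed = 42),
                         duration = 2 * 3600)
  b <- generate_kinetics(p, noise_model(0.05, 2, seed = 42),
                         duration = 2 * 3600)
  expect_identical(a$value_nM, b$value_nM)
  c2 <- generate_kinetics(p, noise_model(0.05, 2, seed = 43),
                          duration = 2 * 3600)
  expect_false(identical(a$value_nM, c2$value_nM))

  expect_error(noise_model(0.05, 2), "seed")
})

test_that("noisy kinetics still yield the ground-truth synthesis rate", {
  p <- txtl_params(P70 = 1)
  target <- steady_state_rate(p)
  errs <- vapply(1:5, function(s) {
    run <- generate_kinetics(p, noise_model(0.05, 2, seed = s),
                             duration = 4 * 3600)
    abs(max_synthesis_rate(run) - target) / target
  }, numeric(1))
  expect_lt(stats::median(errs), 0.1)
})

test_that("decay generator matches its closed form and reparses losslessly", {
  tr0 <- generate_decay_trace(8.25e-4, 100, noise_model(0, 0, seed = 1))
  expect_equal(tr0$signal_nM, 100 * exp(-8.25e-4 * tr0$time_s))

  tr <- generate_decay_trace(8.25e-4, 100, noise_model(0.05, 1, seed = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_decay_csv(tr, path)
  back <- read_decay_csv(path)
  expect_equal(back$time_s, tr$time_s)
  expect_equal(back$signal_nM, tr$signal_nM)
  expect_true(file.exists(paste0(path, ".manifest.json")))
})

test_that("nine-combination dataset mirrors part strengths", {
  ps <- c(P70a = 1, P70b = 0.3, P70c = 0.05)
  us <- c(UTR1 = 1, UTR2 = 0.3, UTR3 = 0.05)
  d0 <- generate_nine_combo_dataset(noise_model(0, 0, seed = 1),
                                    promoter_strengths = ps,
                                    utr_strengths = us)
  expect_equal(nrow(d0), 9 * 7)
  truth <- attr(d0, "truth")$curves

  # the weakest pair never leaves the linear regime; the strongest saturates
  weak <- truth[truth$promoter == "P70c" & truth$utr == "UTR3", ]
  expect_true(all(weak$regime == "linear"))
  strong <- truth[truth$promoter == "P70a" & truth$utr == "UTR1", ]
  expect_true(any(strong$regime == "saturated"))

  # recovered strength ordering matches the generating ordering
  tab <- part_strength_table(d0[d0$utr == "UTR1", ])
  expect_equal(tab$promoter[order(-tab$relative_strength)],
               names(sort(ps, decreasing = TRUE)))
  # measured relative strengths fold in resource reallocation (a weaker
  # promoter leaves slightly more free polymerase), so they track the
  # generating strengths to ~10%, not exactly
  expect_equal(tab$relative_strength[match(names(ps), tab$promoter)],
               unname(ps), tolerance = 0.1)

  # all strengths equal: nine identical noiseless curves
  same <- generate_nine_combo_dataset(
    noise_model(0, 0, seed = 1),
    promoter_strengths = c(a = 1, b = 1, c = 1),
    utr_strengths = c(x = 1, y = 1, z = 1))
  spread <- tapply(same$max_rate_nM_per_s,
                   paste(same$promoter, same$utr), identity)
  for (k in seq_along(spread)[-1]) {
    expect_equal(spread[[k]], spread[[1]])
  }
})

test_that("generated plate runs and rate curves survive CSV round trips", {
  p <- txtl_params(P70 = 1)
  run <- generate_kinetics(p, noise_model(0.03, 5, seed = 9),
                           duration = 3600)
  path <- withr::local_tempfile(fileext = ".csv")
  write_plate_run_csv(run, path)
  back <- read_plate_run_csv(path)
  expect_equal(back$value_nM, run$value_nM)
  expect_equal(back$condition, run$condition)
  manifest <- jsonlite::read_json(paste0(path, ".manifest.json"))
  expect_equal(manifest$package, "txtlsim")
  expect_equal(manifest$parameters$R_total, 1100)

  d <- generate_nine_combo_dataset(noise_model(0.03, 0, seed = 5))
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_rate_curve_csv(d, path2)
  back2 <- read_rate_curve_csv(path2)
  expect_equal(back2$max_rate_nM_per_s, d$max_rate_nM_per_s)
  expect_equal(back2$promoter, d$promoter)
})
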