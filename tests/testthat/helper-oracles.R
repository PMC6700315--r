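# Independent oracles: plain bisection on the conservation-law residuals,
# written straight from the algebra, sharing no code with the package.

oracle_bisect <- function(f, lo, hi, tol = 1e-9, maxit = 200L) {
  flo <- f(lo)
  for (i in seq_len(maxit)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if ((hi - lo) / 2 < tol) return(mid)
    if (sign(fm) == sign(flo)) {
      lo <- mid; flo <- fm
    } else {
      hi <- mid
    }
  }
  (lo + hi) / 2
}

# residual of the core-RNAP conservation law, straight from the model algebra
oracle_E0 <- function(p, tol = 1e-9) {
  f <- function(E0) {
    E70 <- E0 * p$S70_total / (p$K70 + E0)
    Em <- E0 * p$S70_total * p$P70 * (1 + p$kcat_m * p$Lm / p$Cm) /
      (p$KM_70 * (p$K70 + E0) + E0 * p$S70_total)
    E0 + E70 + Em - p$E_total
  }
  oracle_bisect(f, 0, p$E_total, tol = tol)
}

# bisection on the ribosome conservation law
oracle_R0 <- function(p, m, tol = 1e-9) {
  beta <- 1 + p$kcat_p * p$Lm / p$Cp
  f <- function(R0) R0 + R0 * m / (p$KM_R + R0) * beta - p$R_total
  oracle_bisect(f, 0, p$R_total, tol = tol)
}

txtl_quietly <- function(expr) {
  status <- NULL
  invisible(utils::capture.output(status <- suppressMessages(expr)))
  status
}

expect_conserved <- function(trace, params, tol = 1e-6) {
  expect_true(all(abs(trace$E0_nM + trace$E70_nM + trace$Em_nM -
                        params$E_total) <= tol))
  expect_true(all(abs(trace$R0_nM + trace$Rm_nM - params$R_total) <= tol))
}
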