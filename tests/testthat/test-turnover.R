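ref_params <- function() {
  turnover_params(M = 100, M_D0 = 0, M_X0 = 0, M_S = 35,
                  C_D = 40.7 / 26.0, k_D = 1 / 26.0,
                  k_X = 1 / 259, C_X = (35 - 17.5) / 259)
}

test_that("two-pool model reproduces the double-exponential closed form", {
  p <- ref_params()
  t <- frap_time_grid()
  cf <- closed_form_recovery(p, t)
  # plateaus chosen from the 40.7/17.5 amplitudes: total recovery must equal
  # the generating double exponential
  target <- 40.7 * (1 - exp(-t / 26.0)) + 17.5 * (1 - exp(-t / 259))
  expect_lt(max(abs(cf$M_total - target)), 1e-9)
  expect_equal(cf$M_total, cf$M_D + cf$M_X, tolerance = 1e-12)

  # RK4 integration against the analytic solution
  num <- simulate_recovery(p, t, dt = 0.05)
  expect_lt(max(abs(num$M_total - cf$M_total)), 1e-8 * p$M)
})

test_that("initial condition and bafilomycin branch behave as specified", {
  p <- turnover_params(M_D0 = 10, M_X0 = 5, M_S = 35,
                       C_D = 40.7 / 26, k_D = 1 / 26, k_X = 1 / 259,
                       C_X = (35 - 17.5) / 259)
  t <- c(0, 1, 50, 330)
  expect_equal(closed_form_recovery(p, t)$M_total[1], 15)
  baf <- closed_form_recovery(p, t, bafilomycin = TRUE)
  expect_equal(baf$M_X, rep(5, 4))
  # with no unbleached pool-X content, pool X stays empty under bafilomycin
  p0 <- ref_params()
  expect_equal(simulate_recovery(p0, t, bafilomycin = TRUE)$M_X, rep(0, 4))
})

test_that("bafilomycin recovery is exactly single-exponential", {
  p <- ref_params()
  t <- seq(0, 330, by = 1)
  baf <- closed_form_recovery(p, t, bafilomycin = TRUE)
  plateau <- p$C_D / p$k_D
  resid <- log(plateau - baf$M_total[-length(t)])
  # log-residuals against the plateau must be linear in t
  lin <- lm(resid ~ t[-length(t)])
  expect_lt(max(abs(residuals(lin))), 1e-6)
})

test_that("parameter validation rejects inconsistent configurations", {
  expect_error(turnover_params(k_D = 0, C_D = 1), "unbounded")
  expect_error(turnover_params(M_D0 = 80, M_X0 = 40), "exceeds")
  expect_error(turnover_params(M_S = 1, k_X = 1 / 259, C_X = 0.01),
               "sustain")
  expect_error(turnover_params(C_D = -1), "non-negative")
})

test_that("fit-derived parameters reproduce the printed rate identities", {
  f <- fit_exponential_mixture(generate_control_trace(), 2)
  p <- params_from_fit(f)
  # 1/26.0 s^-1 is 2.31 per minute
  expect_equal(p$k_D * 60, 2.31, tolerance = 1e-3)
  expect_equal(p$k_X, 1 / 259, tolerance = 1e-3)
  expect_equal(p$C_D / p$k_D, 40.7, tolerance = 1e-3)
  expect_equal(p$M_S - p$C_X / p$k_X, 17.5, tolerance = 1e-3)

  f1 <- fit_exponential_mixture(generate_bafilomycin_trace(), 1)
  p1 <- params_from_fit(f1)
  expect_identical(p1$k_X, 0)
  expect_identical(p1$C_X, 0)
})

test_that("linearity: scaling amounts scales the whole curve", {
  p <- ref_params()
  s <- 3.7
  p2 <- turnover_params(M = p$M * s, M_D0 = 0, M_X0 = 0, M_S = p$M_S * s,
                        C_D = p$C_D * s, k_D = p$k_D, k_X = p$k_X,
                        C_X = p$C_X * s)
  t <- frap_time_grid()
  expect_equal(closed_form_recovery(p2, t)$M_total,
               s * closed_form_recovery(p, t)$M_total, tolerance = 1e-12)
})

test_that("reconstructed control/bafilomycin pair has the expected geometry", {
  cf <- fit_exponential_mixture(generate_control_trace(), 2)
  bf <- fit_exponential_mixture(generate_bafilomycin_trace(), 1)
  long_t <- c(frap_time_grid(), 1e5)
  pair <- reconstruct_recovery_pair(cf, bf, times = long_t,
                                    override_k_D = 1 / 49.0)
  n <- nrow(pair$control)
  expect_equal(pair$control$M_total[n], 58.2, tolerance = 1e-3)
  # control minus bafilomycin grows monotonically: only the slow pool differs
  pair0 <- reconstruct_recovery_pair(cf)
  d <- pair0$control$M_total - pair0$bafilomycin$M_total
  expect_true(all(diff(d) > 0))
  expect_equal(d, 17.5 * (1 - exp(-pair0$control$time_s / 259)),
               tolerance = 1e-9)
})

test_that("turnover config round-trips through JSON", {
  p <- ref_params()
  f <- withr::local_tempfile(fileext = ".json")
  write_turnover_config(p, f)
  expect_equal(read_turnover_config(f), p, tolerance = 1e-12)
})
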