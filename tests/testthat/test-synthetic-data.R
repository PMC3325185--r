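test_that("control closed form obeys its boundary values", {
  # amplitudes 40.7 + 17.5 plus floor 41.8 sum to 100, so the curve starts at 0
  expect_equal(frap_control_curve(0), 0, tolerance = 1e-12)
  # asymptote 100 - 41.8; direct evaluation of the closed form far in the tail
  expect_equal(frap_control_curve(1e4), 58.2, tolerance = 1e-8)
  # noiseless curves are non-decreasing
  tr <- generate_control_trace()
  expect_true(all(diff(tr$intensity_pct) > 0))
})

test_that("bafilomycin closed form is a single saturating exponential", {
  amp <- 40.7
  expect_equal(frap_bafilomycin_curve(0, amp = amp), 0)
  expect_equal(frap_bafilomycin_curve(49.0, 49.0, amp), amp * (1 - exp(-1)))
  expect_gte(frap_bafilomycin_curve(490, 49.0, amp), 0.9999 * amp)
})

test_that("generators validate their inputs", {
  expect_error(generate_control_trace(tau_fast = 300, tau_slow = 259),
               "ordering")
  expect_error(generate_control_trace(times = c(0, 10, 5)), "increasing")
  expect_error(generate_dataset(2, conditions = "heat_shock"), "unknown condition")
})

test_that("seeded noise is bit-reproducible and leaves the RNG state alone", {
  n <- noise_spec(sd = 2, seed = 123L)
  a <- generate_control_trace(noise = n)
  set.seed(1); before <- rnorm(1)
  b <- generate_control_trace(noise = n)
  expect_identical(a, b)
  d1 <- generate_dataset(2, noise = noise_spec(2, 7L))
  d2 <- generate_dataset(2, noise = noise_spec(2, 7L))
  expect_identical(d1, d2)
  # replicates get distinct streams
  expect_false(identical(d1$intensity_pct[d1$replicate_id == 1 & d1$condition == "control"],
                         d1$intensity_pct[d1$replicate_id == 2 & d1$condition == "control"]))
})

test_that("mean of many noisy replicates converges to the closed form", {
  n_rep <- 1000
  ds <- generate_dataset(n_rep, "control", noise = noise_spec(2, 11L))
  m <- mean_trace(ds)
  truth <- frap_control_curve(m$time_s)
  # CLT bound: 3 standard errors of the per-timepoint mean
  expect_true(all(abs(m$intensity_pct - truth) < 3 * 2 / sqrt(n_rep)))
})

test_that("control curve with zero slow amplitude matches the single-exponential form", {
  t <- frap_time_grid()
  a <- frap_control_curve(t, 26, 259, 40.7, 0, 59.3)
  b <- frap_bafilomycin_curve(t, 26, 40.7)
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("trace CSV dialect round-trips", {
  ds <- generate_dataset(2, noise = noise_spec(1, 5L))
  p <- withr::local_tempfile(fileext = ".csv")
  write_frap_csv(ds, p)
  back <- read_frap_csv(p)
  expect_equal(back$intensity_pct, ds$intensity_pct, tolerance = 1e-12)
  expect_identical(back$condition, ds$condition)
  write.csv(data.frame(a = 1), p)
  expect_error(read_frap_csv(p), "missing columns")
})
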