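test_that("factor 1 is the identity for every mode", {
  sc <- invadopodium_scenario()
  for (mode in c("turnover", "conc", "both"))
    expect_identical(apply_reduction(sc, mode, 1), sc)
  expect_error(apply_reduction(sc, "turnover", 0.5), ">= 1")
  expect_error(apply_reduction(sc, "conc", -2), ">= 1")
})

test_that("turnover reduction preserves the TIMP-2-free surface equilibria", {
  sc <- invadopodium_scenario(timp2_nM = 0, m2pro_uM = 0, fn_uM = 0)
  net <- scenario_network(sc)
  w14 <- ledger_weights(net)[, "M14"]
  mem <- net$species$type == "membrane"
  equilibrate <- function(scen, t_end) {
    res <- run_scenario(scen, t_end = t_end, dt = 0.05)
    as.numeric(res$conc[nrow(res$conc), mem] %*% w14[mem])
  }
  base <- equilibrate(sc, 2000)
  red <- equilibrate(apply_reduction(sc, "turnover", 10), 20000)
  # analytic steady state is exactly invariant; equilibration gets close
  expect_equal(red, base, tolerance = 1e-3)
  ss <- steady_surface_state(sc$rates)
  ss10 <- steady_surface_state(apply_reduction(sc, "turnover", 10)$rates)
  expect_equal(sum(ss * c(1, 2, 1, 2)), sum(ss10 * c(1, 2, 1, 2)),
               tolerance = 1e-10)
})

test_that("supply reduction rescales the surface pools as designed", {
  sc <- invadopodium_scenario(timp2_nM = 0, m2pro_uM = 0, fn_uM = 0)
  r <- sc$rates
  red <- apply_reduction(sc, "conc", 10)
  ss0 <- steady_surface_state(r)
  ss1 <- steady_surface_state(red$rates)
  # pool D scales exactly with the vesicular supply
  d0 <- ss0["M14_D"] + 2 * ss0["M14_D.M14_D"]
  d1 <- ss1["M14_D"] + 2 * ss1["M14_D.M14_D"]
  expect_equal(unname(d1 / d0), 1 / 10, tolerance = 1e-9)
  # pool X falls sublinearly: insertion is docking-site limited
  x0 <- ss0["M14_X"] + 2 * ss0["M14_X.M14_X"]
  x1 <- ss1["M14_X"] + 2 * ss1["M14_X.M14_X"]
  expect_gt(unname(x1 / x0), 1 / 10)
  expect_lt(unname(x1 / x0), 1)
  # verified dynamically by an equilibration run
  net <- scenario_network(red)
  w14 <- ledger_weights(net)[, "M14"]
  mem <- net$species$type == "membrane"
  red$surface_state <- NULL
  res <- run_scenario(red, t_end = 4000, dt = 0.05)
  expect_equal(as.numeric(res$conc[nrow(res$conc), mem] %*% w14[mem]),
               unname(d1 + x1), tolerance = 1e-2)
})

test_that("efficacy normalizes to the control and decreases with the factor", {
  sc <- invadopodium_scenario()
  eff <- efficacy_curve(sc, modes = c("turnover", "conc", "both"),
                        factors = c(1, 4, 10), dt = 0.05)
  for (mode in c("turnover", "conc", "both")) {
    e <- eff$efficacy[eff$mode == mode]
    expect_equal(e[1], 1)
    expect_true(all(diff(e) < 0))
  }
  # the combined intervention is never milder than either single one
  for (f in c(4, 10)) {
    eb <- eff$efficacy[eff$mode == "both" & eff$factor == f]
    expect_lte(eb, min(eff$efficacy[eff$mode != "both" & eff$factor == f]))
  }
  expect_error(efficacy_curve(sc, factors = c(2, 10)), "anchor")
})

test_that("synergy index implements the multiplicative null", {
  out <- data.frame(mode = rep(c("turnover", "conc", "both"), 2),
                    factor = rep(c(1, 10), each = 3),
                    efficacy = c(1, 1, 1, 0.294, 0.177, 0.294 * 0.177))
  expect_equal(synergy_index(out, 1), 1)
  expect_equal(synergy_index(out, 10), 1)
  out$efficacy[6] <- 0.0230
  expect_equal(synergy_index(out, 10), 0.0230 / (0.294 * 0.177),
               tolerance = 1e-12)
  expect_lt(synergy_index(out, 10), 1)
  out$efficacy[6] <- 0
  expect_true(is.na(synergy_index(out, 10)))
})
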