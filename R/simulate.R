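#' Well-mixed deterministic simulation of the invadopodium network
#'
#' The generated mass-action system is integrated with a fixed-step classical
#' fourth-order Runge-Kutta scheme (compiled); trajectories are sampled on a
#' 1 s output grid by default, independent of the internal step. Scalar
#' readouts follow the model's conventions: `ecm_remaining` is the fraction of
#' the initial intact fibronectin-like substrate (free or complexed, not yet
#' cleaved), the degradation rate is the summed flux through all cleavage
#' channels (uM/s), `tau_half` is the first time at which half of the ECM has
#' been degraded, and `inactivated_mt1` is the M14-weighted concentration of
#' membrane species whose every catalytic site is TIMP-2-occupied.
#'
#' @name simulate-wellmixed
NULL

compile_network <- function(network) {
  sp <- network$species$id
  idx <- function(ids) match(ids, sp) - 1L
  rx <- network$reactions
  n <- nrow(rx)
  kind <- integer(n); r1 <- integer(n); r2 <- integer(n)
  rate <- numeric(n); cap <- numeric(n)
  w_idx <- vector("list", n); w_val <- vector("list", n)
  st_idx <- vector("list", n); st_val <- vector("list", n)
  memX <- network$species$type == "membrane" & network$species$pool == "X"
  for (i in seq_len(n)) {
    lhs <- split_side(rx$reactants[i]); rhs <- split_side(rx$products[i])
    delta <- table(factor(rhs, levels = sp)) - table(factor(lhs, levels = sp))
    nz <- which(delta != 0)
    st_idx[[i]] <- as.integer(nz - 1L)
    st_val[[i]] <- as.numeric(delta[nz])
    w_idx[[i]] <- integer(0); w_val[[i]] <- numeric(0)
    rate[i] <- rx$rate_value[i] * rx$multiplicity[i]
    if (rx$kind[i] == "mass_action") {
      kind[i] <- 0L
      li <- idx(lhs)
      r1[i] <- li[1]
      r2[i] <- if (length(li) > 1L) li[2] else -1L
    } else if (rx$kind[i] == "zero_order") {
      kind[i] <- 1L; r1[i] <- 0L; r2[i] <- -1L
    } else { # saturable pool-X insertion, capacity M_S, occupancy = surface M14
      kind[i] <- 2L; r1[i] <- 0L; r2[i] <- -1L
      cap[i] <- rate_value(network$rates, "M_S")
      w_idx[[i]] <- which(memX) - 1L
      w_val[[i]] <- network$species$m14[memX]
    }
  }
  list(kind = kind, r1 = r1, r2 = r2, rate = rate, cap = cap,
       w_idx = w_idx, w_val = w_val, st_idx = st_idx, st_val = st_val)
}

intact_fn_weights <- function(network) {
  w <- ledger_weights(network)[, "fn"]
  w[network$species$id == "fn_deg"] <- 0
  w
}

new_sim_result <- function(times, conc, network) {
  sp <- network$species$id
  colnames(conc) <- sp
  wi <- intact_fn_weights(network)
  intact <- as.numeric(conc %*% wi)
  fn0 <- intact[1]
  structure(list(times = times, conc = conc, network = network,
                 fn0 = fn0,
                 ecm_remaining = if (fn0 > 0) intact / fn0 else rep(NA_real_, length(times))),
            class = "sim_result")
}

#' Integrate a reaction network (fixed-step RK4)
#'
#' @param network A `reaction_network`.
#' @param init Named numeric vector of initial concentrations (uM); species not
#'   named start at zero.
#' @param t_end End time (s).
#' @param dt Internal integration step (s).
#' @param out_dt Output sampling interval (s); must be a multiple of `dt`.
#' @param stop_frac Optional early-stop: abort the run once the intact-ECM
#'   fraction falls to this value (speeds up half-time searches).
#' @param clamp Character vector of species held constant during the run
#'   (e.g. bath species during a pre-equilibration).
#' @param check_convergence If `TRUE`, repeat the run at `dt/2` and require the
#'   final intact-ECM fraction to agree to a relative 1e-4.
#' @return A `sim_result` with `times`, the species trajectory matrix `conc`,
#'   and the derived `ecm_remaining` series.
#' @export
integrate_network <- function(network, init, t_end, dt = 0.02, out_dt = 1,
                              stop_frac = NULL, check_convergence = FALSE,
                              clamp = character(0)) {
  stopifnot(dt > 0, t_end >= dt)
  sp <- network$species$id
  y0 <- stats::setNames(numeric(length(sp)), sp)
  bad <- setdiff(names(init), sp)
  if (length(bad)) stop("unknown species in init: ", paste(bad, collapse = ", "))
  y0[names(init)] <- init
  if (any(y0 < 0)) stop("initial concentrations must be non-negative")
  comp <- compile_network(network)
  out_every <- max(1L, as.integer(round(out_dt / dt)))
  stop_idx <- integer(0); stop_weight <- numeric(0); stop_value <- -1
  if (!is.null(stop_frac)) {
    wi <- intact_fn_weights(network)
    stop_idx <- which(wi > 0) - 1L
    stop_weight <- wi[wi > 0]
    stop_value <- stop_frac * sum(stop_weight * y0[wi > 0])
  }
  clamp_idx <- match(clamp, sp)
  if (anyNA(clamp_idx)) stop("unknown species in clamp")
  raw <- rk4_integrate_cpp(comp, as.numeric(y0), dt, t_end, out_every,
                           stop_idx, stop_weight, stop_value, clamp_idx - 1L)
  res <- new_sim_result(raw$times, raw$conc, network)
  if (check_convergence) {
    raw2 <- rk4_integrate_cpp(comp, as.numeric(y0), dt / 2, t_end,
                              2L * out_every, stop_idx, stop_weight,
                              stop_value, clamp_idx - 1L)
    n <- min(length(raw$times), length(raw2$times))
    e1 <- res$ecm_remaining[n]
    e2 <- new_sim_result(raw2$times, raw2$conc, network)$ecm_remaining[n]
    rel <- abs(e1 - e2) / max(abs(e2), 1e-12)
    if (is.finite(rel) && rel >= 1e-4)
      warning(sprintf("step-halving check failed: relative change %.3g", rel))
    attr(res, "dt_converged") <- !is.finite(rel) || rel < 1e-4
  }
  res
}

#' @export
print.sim_result <- function(x, ...) {
  cat("Well-mixed simulation:", length(x$times), "samples to t =",
      max(x$times), "s;", ncol(x$conc), "species\n")
  if (!is.na(x$fn0))
    cat(sprintf("  ECM remaining at end: %.4f (tau_half = %s s)\n",
                x$ecm_remaining[length(x$times)], format(tau_half(x))))
  invisible(x)
}

#' Time to 50% ECM degradation
#'
#' First time at which the intact-ECM fraction reaches `level`, linearly
#' interpolated between output samples. Returns `Inf` (the documented
#' sentinel) when the trajectory never crosses.
#'
#' @param result A `sim_result`.
#' @param level Crossing level for the intact fraction (default 0.5).
#' @export
tau_half <- function(result, level = 0.5) {
  e <- result$ecm_remaining
  t <- result$times
  if (e[1] <= level) return(0)
  below <- which(e <= level)
  if (!length(below)) return(Inf)
  i <- below[1]
  t[i - 1] + (t[i] - t[i - 1]) * (e[i - 1] - level) / (e[i - 1] - e[i])
}

deg_rate_series <- function(result) {
  net <- result$network
  rx <- net$reactions
  deg <- which(vapply(rx$products, function(p) "fn_deg" %in% split_side(p),
                      logical(1)))
  rate <- numeric(length(result$times))
  for (i in deg) {
    sp <- split_side(rx$reactants[i])[1]
    rate <- rate + rx$rate_value[i] * rx$multiplicity[i] * result$conc[, sp]
  }
  rate
}

#' ECM degradation rate at a time point
#'
#' Summed flux through every cleavage channel, `k_fn11p` terms for membrane
#' MT1-MMP-ECM complexes plus the `k_fn2p` term for the active-MMP-2-ECM
#' complex, in uM/s.
#'
#' @param result A `sim_result`.
#' @param t Time (s) within the simulated range.
#' @export
degradation_rate <- function(result, t) {
  if (any(t < min(result$times) | t > max(result$times)))
    stop("t outside the simulated range")
  stats::approx(result$times, deg_rate_series(result), xout = t)$y
}

inactivated_weights <- function(network) {
  sp <- network$species
  w <- numeric(nrow(sp))
  sel <- sp$type == "membrane" & sp$n_free == 0 & sp$n_fn == 0
  w[sel] <- sp$m14[sel]
  w
}

#' Inactivated (fully TIMP-2-occupied) surface MT1-MMP
#'
#' M14-monomer-weighted concentration of membrane species in which every
#' catalytic site is TIMP-2-occupied; these complexes can neither cleave ECM
#' nor process proMMP-2.
#'
#' @inheritParams degradation_rate
#' @export
inactivated_mt1 <- function(result, t) {
  if (any(t < min(result$times) | t > max(result$times)))
    stop("t outside the simulated range")
  series <- as.numeric(result$conc %*% inactivated_weights(result$network))
  stats::approx(result$times, series, xout = t)$y
}

#' Turnover-only steady state of the surface pools
#'
#' Analytic steady state of the monomer/dimer turnover subsystem (no TIMP-2,
#' proMMP-2 or ECM present). Pool D balances the constant insertion flux
#' against first-order internalization of every species, so its total surface
#' content is exactly `C_D/k_D`; pool X balances docking-site-limited
#' insertion against first-order internalization, giving total
#' `k_Xins*M_S/(k_Xins + k_Xint)`. The monomer/dimer split solves the
#' dimerization balance within each pool.
#'
#' @param rates A rate table.
#' @return Named concentrations (uM) for the four bare surface species.
#' @export
steady_surface_state <- function(rates) {
  split_md <- function(total, k_int) {
    if (total <= 0) return(c(m = 0, d = 0))
    if (rates$k_dim == 0) return(c(m = total, d = 0))
    # m + 2 d = total, k_dim m^2 = (k_undim + k_int) d
    a <- 2 * rates$k_dim / (rates$k_undim + k_int)
    m <- (-1 + sqrt(1 + 4 * a * total)) / (2 * a)
    c(m = m, d = (total - m) / 2)
  }
  tot_D <- if (rates$k_D > 0) rates$C_D / rates$k_D else 0
  tot_X <- if (rates$k_Xins + rates$k_Xint > 0)
    rates$k_Xins * rates$M_S / (rates$k_Xins + rates$k_Xint) else 0
  d <- split_md(tot_D, rates$k_D)
  x <- split_md(tot_X, rates$k_Xint)
  c("M14_D" = unname(d["m"]), "M14_D.M14_D" = unname(d["d"]),
    "M14_X" = unname(x["m"]), "M14_X.M14_X" = unname(x["d"]))
}

#' Define an invadopodium simulation scenario
#'
#' Bundles the rate table, binding rules, complex-size cap and initial
#' concentrations. The surface pools start from the turnover-only steady state
#' (the FRAP-derived turnover maintains them there before TIMP-2, proMMP-2 and
#' ECM enter the problem).
#'
#' @param timp2_nM Initial TIMP-2 concentration (nM; 180 in the control
#'   scenario).
#' @param m2pro_uM Initial proMMP-2 concentration (uM).
#' @param fn_uM Initial intact-ECM (fibronectin-like substrate) concentration
#'   (uM).
#' @param ves_uM Vesicular MT1-MMP reservoir (uM); sized so the reservoir is
#'   not depleted over the simulated window.
#' @param rates Rate table (see [default_rate_table()]).
#' @param rules Binding rules.
#' @param max_m14 Complex-size cap.
#' @export
invadopodium_scenario <- function(timp2_nM = 180, m2pro_uM = 0.5,
                                  fn_uM = 0.0020279, ves_uM = 50,
                                  rates = default_rate_table(),
                                  rules = network_rules(), max_m14 = 2L) {
  structure(list(timp2_nM = timp2_nM, m2pro_uM = m2pro_uM, fn_uM = fn_uM,
                 ves_uM = ves_uM, rates = rates, rules = rules,
                 max_m14 = max_m14, surface_state = NULL),
            class = "sim_scenario")
}

#' Reaction network and initial state of a scenario
#'
#' @param scenario A `sim_scenario`.
#' @param network The scenario's network (from `scenario_network()`).
#' @export
scenario_network <- function(scenario) {
  build_network(scenario$max_m14, scenario$rates, scenario$rules)
}

#' @rdname scenario_network
#' @export
scenario_init <- function(scenario, network) {
  surf <- scenario$surface_state
  if (is.null(surf)) surf <- steady_surface_state(scenario$rates)
  surf <- surf[names(surf) %in% network$species$id]
  init <- c(surf,
            T2 = scenario$timp2_nM / 1000,
            M2pro = scenario$m2pro_uM,
            fn = scenario$fn_uM,
            M14_ves = scenario$ves_uM)
  init[names(init) %in% network$species$id]
}

#' Run a scenario with the well-mixed model
#'
#' @param scenario A `sim_scenario`.
#' @param t_end End time (s).
#' @param dt Integration step (s).
#' @param ... Passed to [integrate_network()].
#' @export
run_scenario <- function(scenario, t_end = 700, dt = 0.02, ...) {
  net <- scenario_network(scenario)
  integrate_network(net, scenario_init(scenario, net), t_end, dt = dt, ...)
}

#' Pre-equilibrate the surface with the TIMP-2 / proMMP-2 bath
#'
#' Before the degradation assay the invadopodial surface has been exposed to
#' TIMP-2 and proMMP-2 at their bath concentrations: the standing surface
#' therefore carries its steady inhibited (T2-occupied) fraction. This runs
#' the scenario without ECM, with the bath species clamped (the medium is a
#' reservoir), until the surface pools settle, and stores the resulting
#' membrane state in the scenario. The equilibration horizon scales with the
#' slowest turnover rate, so reduced-turnover scenarios equilibrate at their
#' own pace; soluble intermediates produced during equilibration (e.g. active
#' MMP-2) are discarded as washed out by the bath.
#'
#' @param scenario A `sim_scenario`.
#' @param t_eq Equilibration time (s); default 8 slow time constants.
#' @param dt Integration step (s).
#' @return The scenario with `surface_state` set.
#' @export
pre_equilibrate <- function(scenario, t_eq = NULL, dt = 0.1) {
  rates <- scenario$rates
  # respect the stiffest first-order scale among the bath-binding processes
  lam <- max(rates$kon_t2 * scenario$timp2_nM / 1000,
             rates$kon_m2t2 * scenario$timp2_nM / 1000,
             rates$kon_m2 * scenario$m2pro_uM,
             rates$k_undim, rates$k_act, rates$k_D, 1e-6)
  dt <- min(dt, 0.25 / lam)
  if (is.null(t_eq)) {
    slow <- min(c(rates$k_D, rates$k_Xint)[c(rates$k_D, rates$k_Xint) > 0],
                Inf)
    t_eq <- if (is.finite(slow)) 8 / slow else 2000
  }
  net <- scenario_network(scenario)
  init <- scenario_init(scenario, net)
  init <- init[names(init) != "fn"]
  res <- integrate_network(net, init, t_end = t_eq, dt = dt, out_dt = t_eq,
                           clamp = c("T2", "M2pro"))
  final <- res$conc[nrow(res$conc), ]
  mem <- net$species$id[net$species$type == "membrane"]
  scenario$surface_state <- final[mem][final[mem] > 0]
  scenario
}

# largest comfortable RK4 step given the stiffest bath-binding process
stable_dt <- function(scenario, dt) {
  r <- scenario$rates
  lam <- max(r$kon_t2 * scenario$timp2_nM / 1000,
             r$kon_m2t2 * scenario$timp2_nM / 1000,
             r$kon_m2 * scenario$m2pro_uM,
             r$kon_fn11 * scenario$fn_uM, r$k_undim, 1e-6)
  min(dt, 0.25 / lam)
}

ensure_equilibrated <- function(scenario) {
  if (is.null(scenario$surface_state)) pre_equilibrate(scenario) else scenario
}

#' Half-degradation time of a scenario
#'
#' Pre-equilibrates the surface with the bath (unless already equilibrated)
#' and runs the scenario until the 50% crossing (early-stopped) or `t_max`;
#' returns `Inf` when the crossing is never reached.
#'
#' @inheritParams run_scenario
#' @param t_max Longest time simulated before declaring no crossing (s).
#' @param level Intact-ECM crossing level.
#' @export
scenario_tau_half <- function(scenario, t_max = 5000, dt = 0.02, level = 0.5) {
  scenario <- ensure_equilibrated(scenario)
  res <- run_scenario(scenario, t_end = t_max, dt = dt,
                      stop_frac = 0.9 * level)
  tau_half(res, level)
}

#' Sweep the initial TIMP-2 concentration
#'
#' Runs the scenario across a TIMP-2 grid and reports, per concentration, the
#' peak active-MMP-2-ECM complex concentration (the measure of MMP-2-mediated
#' degradation activity) and the peak MT1-MMP-ECM complex concentration. The
#' grid argmax of each readout is returned as an attribute. Failures at single
#' grid points are reported and skipped.
#'
#' @param scenario A `sim_scenario` (its `timp2_nM` is overridden).
#' @param concs_nM TIMP-2 concentrations to sweep (nM).
#' @param t_end,dt Integration control.
#' @return A data frame `timp2_nM`, `peak_m2_ecm`, `peak_m14_ecm` with
#'   attributes `argmax_m2_ecm_nM` and `argmax_m14_ecm_nM`.
#' @export
timp2_sweep <- function(scenario, concs_nM = seq(0, 1000, by = 60),
                        t_end = 700, dt = 0.02) {
  stopifnot(length(concs_nM) > 0, all(concs_nM >= 0))
  net <- scenario_network(scenario)
  m14fn_w <- numeric(nrow(net$species))
  memfn <- net$species$type == "membrane"
  m14fn_w[memfn] <- net$species$n_fn[memfn]
  rows <- lapply(concs_nM, function(cc) {
    sc <- scenario
    sc$timp2_nM <- cc
    sc$surface_state <- NULL
    sc <- pre_equilibrate(sc)
    res <- tryCatch(integrate_network(net, scenario_init(sc, net), t_end,
                                      dt = stable_dt(sc, dt)),
                    error = function(e) e)
    if (inherits(res, "error")) {
      message("TIMP-2 = ", cc, " nM failed: ", conditionMessage(res))
      return(data.frame(timp2_nM = cc, peak_m2_ecm = NA_real_,
                        peak_m14_ecm = NA_real_))
    }
    m2fn <- if ("M2act.fn" %in% colnames(res$conc)) max(res$conc[, "M2act.fn"]) else 0
    data.frame(timp2_nM = cc, peak_m2_ecm = m2fn,
               peak_m14_ecm = max(as.numeric(res$conc %*% m14fn_w)))
  })
  out <- do.call(rbind, rows)
  ok <- !is.na(out$peak_m2_ecm)
  attr(out, "argmax_m2_ecm_nM") <- out$timp2_nM[ok][which.max(out$peak_m2_ecm[ok])]
  attr(out, "argmax_m14_ecm_nM") <- out$timp2_nM[ok][which.max(out$peak_m14_ecm[ok])]
  out
}

#' One-at-a-time sensitivity of the half-degradation time
#'
#' Perturbs each named rate constant multiplicatively by `1 + perturbation`
#' and `1 - perturbation` and reports the relative change in `tau_half`,
#' ranked by the larger absolute response.
#'
#' @param scenario A `sim_scenario`.
#' @param parameters Rate names to scan; defaults to every rate in the table
#'   except the pool-X capacity.
#' @param perturbation Fractional perturbation (> 0).
#' @param t_max,dt Integration control for the half-time searches.
#' @export
sensitivity_scan <- function(scenario, parameters = NULL, perturbation = 0.2,
                             t_max = 3000, dt = 0.02) {
  stopifnot(perturbation > 0)
  if (is.null(parameters))
    parameters <- setdiff(names(scenario$rates), "M_S")
  tau0 <- scenario_tau_half(scenario, t_max, dt)
  if (!is.finite(tau0)) stop("control scenario never reaches 50% degradation")
  one <- function(p, fac) {
    sc <- scenario
    sc$rates[[p]] <- sc$rates[[p]] * fac
    sc$surface_state <- NULL
    tau <- tryCatch(scenario_tau_half(sc, t_max, dt), error = function(e) NA_real_)
    (tau - tau0) / tau0
  }
  up <- vapply(parameters, one, numeric(1), fac = 1 + perturbation)
  dn <- vapply(parameters, one, numeric(1), fac = 1 - perturbation)
  out <- data.frame(parameter = parameters, dtau_rel_up = up, dtau_rel_down = dn,
                    magnitude = pmax(abs(up), abs(dn)))
  out <- out[order(-out$magnitude), ]
  rownames(out) <- NULL
  attr(out, "tau_half_control") <- tau0
  out
}

#' Scale the combined MT1-MMP turnover rate
#'
#' Divides every turnover rate and flux (`k_D`, `k_Xint`, `C_D`, `k_Xins`) by
#' `factor`, which slows insertion and internalization together while leaving
#' every surface steady-state amount unchanged.
#'
#' @param rates A rate table.
#' @param factor Reduction factor (>= 1).
#' @export
scale_turnover <- function(rates, factor) {
  stopifnot(factor >= 1)
  for (nm in c("k_D", "k_Xint", "C_D", "k_Xins"))
    rates[[nm]] <- rates[[nm]] / factor
  rates
}

#' Calibrate free rate constants against the headline simulation targets
#'
#' Bounded Nelder-Mead over log-rates minimizing a weighted squared error on:
#' completion of ECM degradation (intact fraction 0.01) at 600 s in the
#' control scenario; and the factor-10 reduction efficacies for the turnover,
#' concentration and combined interventions. Used once to produce the
#' `calibrated-default` entries of [default_rate_table()]; exported so the
#' calibration is reproducible and so a published parameter table can be
#' re-tuned or validated.
#'
#' @param scenario Scenario holding the starting rate table.
#' @param free Character vector of rate names to tune.
#' @param targets List with elements `t_complete` (s), `efficacy`
#'   (named: turnover, conc, both, at `factor`), `factor`.
#' @param maxit Nelder-Mead iteration budget.
#' @param dt Integration step used during calibration.
#' @return The scenario with tuned rates; the optimizer trace is attached as
#'   attribute `calibration`.
#' @export
calibrate_rates <- function(scenario,
                            free = c("k_act", "k_fn11p", "k_fn2p", "kon_m2",
                                     "koff_t2", "kon_t2"),
                            targets = list(t_complete = 600,
                                           efficacy = c(turnover = 0.294,
                                                        conc = 0.177,
                                                        both = 0.0230),
                                           factor = 10),
                            maxit = 60, dt = 0.05) {
  x0 <- log(unlist(scenario$rates[free]))
  objective <- function(x) {
    sc <- scenario
    for (i in seq_along(free)) sc$rates[[free[i]]] <- exp(x[i])
    err <- tryCatch({
      ctrl <- run_scenario(pre_equilibrate(sc), t_end = 1200, dt = dt,
                           stop_frac = 0.005)
      tc <- tau_half(ctrl, level = 0.01)
      tau0 <- tau_half(ctrl)
      if (!is.finite(tc) || !is.finite(tau0)) return(1e3)
      e <- (log(tc) - log(targets$t_complete))^2
      for (mode in names(targets$efficacy)) {
        sci <- apply_reduction(sc, mode, targets$factor)
        taui <- scenario_tau_half(sci, t_max = 40 * tau0 / targets$efficacy[[mode]] * 0.05 + 20 * tau0, dt = dt)
        effi <- tau0 / taui
        e <- e + (log(pmax(effi, 1e-6)) - log(targets$efficacy[[mode]]))^2
      }
      e
    }, error = function(e) 1e3)
    err
  }
  opt <- stats::optim(x0, objective, method = "Nelder-Mead",
                      control = list(maxit = maxit))
  for (i in seq_along(free)) scenario$rates[[free[i]]] <- exp(opt$par[i])
  attr(scenario, "calibration") <- opt
  scenario
}
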