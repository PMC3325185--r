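#' Exponential-mixture decomposition of FRAP recovery curves
#'
#' Recovery curves are modelled as F(t) = P - sum_i amp_i * exp(-t / tau_i),
#' where P is the recovery plateau and the non-recovering level (in percent of
#' pre-bleach) is 100 - P. Exponential mixtures are notoriously
#' ill-conditioned, so the least-squares fit uses bounded Levenberg-Marquardt
#' with multiple starts on log-spaced time-constant pairs, seeded additionally
#' by classical semi-log curve peeling.
#'
#' @name frap-fit
NULL

.tau_bounds <- c(0.5, 5000)
.amp_bounds <- c(0, 150)

exp_mix_eval <- function(t, plateau, taus, amps) {
  f <- rep(plateau, length(t))
  for (i in seq_along(taus)) f <- f - amps[i] * exp(-t / taus[i])
  f
}

new_exp_mix_fit <- function(taus, amps, plateau, rss, converged, n_obs) {
  o <- order(taus)
  structure(list(
    n_components = length(taus),
    taus = taus[o],
    amps = amps[o],
    plateau = plateau,
    asymptote = 100 - plateau,
    rss = rss,
    converged = converged,
    n_obs = n_obs
  ), class = "exp_mix_fit")
}

#' @export
print.exp_mix_fit <- function(x, ...) {
  cat("Exponential-mixture FRAP fit (", x$n_components, " component",
      if (x$n_components != 1) "s", ")\n", sep = "")
  for (i in seq_len(x$n_components))
    cat(sprintf("  tau[%d] = %.4g s   amp[%d] = %.4g %%\n", i, x$taus[i], i, x$amps[i]))
  cat(sprintf("  plateau = %.4g %%  (non-recovering %.4g %%)\n", x$plateau, x$asymptote))
  cat(sprintf("  rss = %.4g, converged = %s\n", x$rss, x$converged))
  invisible(x)
}

fit_one_start <- function(t, y, taus0, amps0, p0) {
  k <- length(taus0)
  par0 <- c(p0, amps0, log(taus0))
  lower <- c(-100, rep(.amp_bounds[1], k), rep(log(.tau_bounds[1]), k))
  upper <- c(250, rep(.amp_bounds[2], k), rep(log(.tau_bounds[2]), k))
  resid_fun <- function(par) {
    y - exp_mix_eval(t, par[1], exp(par[(k + 2):(2 * k + 1)]), par[2:(k + 1)])
  }
  res <- tryCatch(
    minpack.lm::nls.lm(par = par0, lower = lower, upper = upper, fn = resid_fun,
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL
  )
  if (is.null(res)) return(NULL)
  par <- res$par
  list(plateau = par[1], amps = par[2:(k + 1)], taus = exp(par[(k + 2):(2 * k + 1)]),
       rss = sum(resid_fun(par)^2), converged = res$info %in% 1:4)
}

multi_starts <- function(n_components, t_max) {
  if (n_components == 1L) {
    lapply(exp(seq(log(2), log(min(t_max, 1000)), length.out = 8)),
           function(tau) list(taus = tau))
  } else {
    fast <- exp(seq(log(2), log(t_max / 4), length.out = 4))
    lapply(seq_len(8), function(i) {
      f <- fast[(i - 1) %% 4 + 1]
      list(taus = c(f, f * if (i <= 4) 8 else 25))
    })
  }
}

#' Fit an exponential mixture to a FRAP trace
#'
#' Bounded trust-region least squares (Levenberg-Marquardt via
#' \pkg{minpack.lm}) with 8 multi-starts on log-spaced time-constant pairs plus
#' a curve-peeling seed; the best (lowest residual sum of squares) solution is
#' returned with components sorted by ascending time constant. Two-component
#' fits whose time constants differ by less than a factor of 2 are collapsed to
#' one component (identifiability guard).
#'
#' @param trace A `frap_trace` (single replicate or mean trace).
#' @param n_components 1 or 2.
#' @return An `exp_mix_fit` with fields `n_components`, `taus` (s, ascending),
#'   `amps` (% of pre-bleach, paired with `taus`), `plateau`, `asymptote`
#'   (non-recovering level, 100 - plateau), `rss`, `converged`.
#' @export
fit_exponential_mixture <- function(trace, n_components = 2L) {
  stopifnot(n_components %in% c(1L, 2L))
  t <- trace$time_s
  y <- trace$intensity_pct
  npar <- 1L + 2L * n_components
  if (length(t) < 3L * npar)
    stop("trace too short: need at least ", 3L * npar, " samples")

  # degenerate (constant) trace: amplitudes ~ 0, plateau = level
  if (stats::sd(y) < 1e-10 * max(1, abs(mean(y)))) {
    return(new_exp_mix_fit(taus = rep(.tau_bounds[1] * 2, n_components),
                           amps = rep(0, n_components),
                           plateau = mean(y), rss = sum((y - mean(y))^2),
                           converged = TRUE, n_obs = length(y)))
  }

  p0 <- max(y) + 0.05 * diff(range(y))
  amp_tot <- max(p0 - y[1], 1)
  starts <- multi_starts(n_components, max(t))
  peel <- tryCatch(peel_components(trace), error = function(e) NULL)
  if (!is.null(peel) && nrow(peel) >= n_components)
    starts <- c(starts, list(list(taus = sort(peel$tau)[seq_len(n_components)])))

  best <- NULL
  for (s in starts) {
    k <- length(s$taus)
    fit <- fit_one_start(t, y, s$taus, rep(amp_tot / k, k), p0)
    if (!is.null(fit) && (is.null(best) || fit$rss < best$rss)) best <- fit
  }
  if (is.null(best)) stop("all optimizer starts failed")

  if (n_components == 2L && max(best$taus) / max(min(best$taus), 1e-12) < 2) {
    one <- fit_exponential_mixture(trace, 1L)
    return(one)
  }
  new_exp_mix_fit(best$taus, best$amps, best$plateau, best$rss,
                  best$converged, length(y))
}

#' Semi-logarithmic curve peeling
#'
#' The classical graphical decomposition: fit the slow tail of the recovery
#' with a single exponential approaching the plateau (the time constant is
#' profiled, plateau and amplitude enter linearly), subtract that component,
#' and fit the early-time remainder on a semi-log scale for the fast
#' component. Used both to seed [fit_exponential_mixture()] and as an
#' independent cross-check of it.
#'
#' @param trace A `frap_trace`.
#' @param tail_fraction Fraction of the samples (from the end) used as the slow
#'   tail window.
#' @return A data frame with columns `tau` and `amp`, slowest component last.
#' @export
peel_components <- function(trace, tail_fraction = 0.4) {
  t <- trace$time_s
  y <- trace$intensity_pct
  n <- length(t)
  i_tail <- seq.int(max(1L, floor(n * (1 - tail_fraction)) + 1L), n)
  if (length(i_tail) < 5L) stop("fewer than 5 tail points available")

  tt <- t[i_tail]; yy <- y[i_tail]
  tail_rss <- function(log_tau) {
    x <- exp(-tt / exp(log_tau))
    sum(stats::lm.fit(cbind(1, x), yy)$residuals^2)
  }
  span <- max(t) - min(t)
  opt <- stats::optimize(tail_rss, interval = log(c(span / 50, span * 20)))
  tau_slow <- exp(opt$minimum)
  co <- stats::lm.fit(cbind(1, exp(-tt / tau_slow)), yy)$coefficients
  P <- co[1]
  amp_slow <- -co[2]
  d <- P - yy
  if (sum(d > 0) < 5L) stop("fewer than 5 usable tail points (P - F <= 0)")
  if (!is.finite(tau_slow) || tau_slow <= 0 || amp_slow < 0)
    stop("tail is not exponential")

  # subtract the slow component; what is left should be the fast exponential
  rem <- (P - y) - amp_slow * exp(-t / tau_slow)
  i_fast <- which(t <= stats::quantile(t, 0.35) & rem > max(rem) * 1e-6)
  if (length(i_fast) >= 3L) {
    co2 <- stats::coef(stats::lm(log(rem[i_fast]) ~ t[i_fast]))
    tau_fast <- -1 / co2[2]
    amp_fast <- exp(co2[1])
  } else {
    tau_fast <- NA_real_
    amp_fast <- 0
  }
  comps <- data.frame(tau = c(tau_fast, tau_slow), amp = c(amp_fast, amp_slow))
  comps <- comps[is.finite(comps$tau) & comps$tau > 0 & comps$amp > 1e-8, ]
  # a single-exponential trace peels into one component (the "slow" line)
  if (nrow(comps) == 2L && comps$tau[2] / comps$tau[1] < 2)
    comps <- comps[2, , drop = FALSE]
  rownames(comps) <- NULL
  comps
}

aicc <- function(rss, n, k) {
  # Gaussian log-likelihood profile + small-sample correction; k counts the
  # mean-model parameters plus the noise variance
  k <- k + 1
  n * log(rss / n + 1e-300) + 2 * k + 2 * k * (k + 1) / max(n - k - 1, 1)
}

#' Choose 1 vs 2 recovery components by small-sample-corrected AIC
#'
#' @param trace A `frap_trace`.
#' @return Integer 1 or 2.
#' @export
select_model <- function(trace) {
  f1 <- fit_exponential_mixture(trace, 1L)
  f2 <- fit_exponential_mixture(trace, 2L)
  if (!f1$converged && !f2$converged) stop("neither model converged")
  n <- f1$n_obs
  a1 <- aicc(f1$rss, n, 3)
  a2 <- if (f2$n_components == 2L) aicc(f2$rss, n, 5) else Inf
  if (!f1$converged) return(2L)
  if (!f2$converged) return(1L)
  if (a2 < a1) 2L else 1L
}

#' Fit every condition in a data set and export JSON fit records
#'
#' @param traces A `frap_trace` data frame (any number of replicates and
#'   conditions). Replicates are averaged per condition before fitting.
#' @param components `"auto"` (model selection), 1, or 2.
#' @param path Optional JSON output path.
#' @return Named list of `exp_mix_fit` objects, one per condition.
#' @export
fit_frap_dataset <- function(traces, components = "auto", path = NULL) {
  fits <- list()
  for (cond in unique(traces$condition)) {
    m <- mean_trace(traces, cond)
    nc <- if (identical(components, "auto")) select_model(m) else as.integer(components)
    fits[[cond]] <- fit_exponential_mixture(m, nc)
  }
  if (!is.null(path)) {
    rec <- lapply(fits, function(f) list(
      n_components = f$n_components, taus_s = f$taus, amps_pct = f$amps,
      asymptote_pct = f$asymptote, rss = f$rss, converged = f$converged))
    jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  }
  fits
}
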