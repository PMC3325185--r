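#' Synthetic FRAP traces for MT1-MMP turnover at invadopodia
#'
#' Fluorescence recovery after photobleaching (FRAP) of membrane-anchored
#' MT1-MMP at a single invadopodium recovers by vesicle-mediated turnover, not
#' lateral diffusion. Under control conditions the recovery is a double
#' exponential (fast and slow time constants of 26.0 s and 259 s with
#' amplitudes 40.7% and 17.5% of the pre-bleach level, plateauing 41.8% short
#' of full recovery); blocking the lysosomal delivery pathway with bafilomycin
#' A1 leaves a single-exponential recovery with a 49.0 s time constant. The
#' generators in this file emulate such traces, with intensity expressed in
#' percent of the pre-bleach level under the convention that the recovering
#' amplitudes and the non-recovering floor sum to 100%, so a fully bleached
#' spot starts at 0%.
#'
#' @name frap-data
NULL

#' Default FRAP sampling grid: 0-330 s every 3 s
#' @return Numeric vector of sample times in seconds.
#' @export
frap_time_grid <- function() seq(0, 330, by = 3)

#' Additive Gaussian measurement-noise specification
#'
#' @param sd Noise standard deviation, in percent of the pre-bleach level.
#'   `sd = 0` yields the exact noiseless curve.
#' @param seed Integer seed; identical seeds yield identical traces.
#' @export
noise_spec <- function(sd = 2, seed = 42L) {
  stopifnot(is.numeric(sd), length(sd) == 1L, sd >= 0, is.finite(sd))
  seed <- as.integer(seed)
  stopifnot(length(seed) == 1L, !is.na(seed))
  structure(list(sd = sd, seed = seed), class = "noise_spec")
}

# deterministic per-replicate stream seed below 2^31
derive_seed <- function(master, k) {
  as.integer((as.double(master) + 7919 * as.double(k)) %% 2147483647)
}

new_frap_trace <- function(times, intensity, condition, replicate_id = 1L,
                           prebleach_level = 100) {
  df <- data.frame(
    time_s = as.numeric(times),
    intensity_pct = as.numeric(intensity),
    condition = as.character(condition),
    replicate_id = as.integer(replicate_id),
    stringsAsFactors = FALSE
  )
  structure(df, prebleach_level = prebleach_level,
            class = c("frap_trace", "data.frame"))
}

check_times <- function(times) {
  if (length(times) < 2L || any(!is.finite(times)) || any(diff(times) <= 0))
    stop("`times` must be finite and strictly increasing")
  if (times[1] < 0) stop("`times` must start at or after 0")
  invisible(times)
}

#' Closed-form control recovery curve
#'
#' F(t) = (100 - floor) - amp_fast * exp(-t/tau_fast) - amp_slow * exp(-t/tau_slow),
#' the double-exponential recovery of the two-pool turnover model expressed in
#' percent of pre-bleach fluorescence.
#'
#' @param t Times in seconds.
#' @param tau_fast,tau_slow Fast and slow time constants (s), `tau_fast < tau_slow`.
#' @param amp_fast,amp_slow Component amplitudes (% of pre-bleach).
#' @param floor Non-recovering level (% of pre-bleach).
#' @return Numeric vector of intensities.
#' @export
frap_control_curve <- function(t, tau_fast = 26.0, tau_slow = 259,
                               amp_fast = 40.7, amp_slow = 17.5, floor = 41.8) {
  stopifnot(tau_fast > 0, amp_fast >= 0, amp_slow >= 0, floor >= 0)
  if (tau_fast >= tau_slow)
    stop("time-constant ordering violated: tau_fast must be < tau_slow")
  (100 - floor) - amp_fast * exp(-t / tau_fast) - amp_slow * exp(-t / tau_slow)
}

#' Closed-form bafilomycin recovery curve
#'
#' Single-exponential recovery `amp * (1 - exp(-t/tau))` above the post-bleach
#' floor, as observed when the slow, lysosome-dependent delivery pool is shut
#' down.
#'
#' @param t Times in seconds.
#' @param tau Time constant (s).
#' @param amp Recovery amplitude (% of pre-bleach).
#' @export
frap_bafilomycin_curve <- function(t, tau = 49.0, amp = 40.7) {
  stopifnot(tau > 0, amp >= 0)
  amp * (1 - exp(-t / tau))
}

add_noise <- function(signal, noise) {
  stopifnot(inherits(noise, "noise_spec"))
  if (noise$sd == 0) return(signal)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(noise$seed)
  signal + stats::rnorm(length(signal), sd = noise$sd)
}

#' Generate a control-condition FRAP trace
#'
#' @inheritParams frap_control_curve
#' @param times Sample times (s), strictly increasing from 0.
#' @param noise A [noise_spec()].
#' @param replicate_id Integer replicate label.
#' @return A `frap_trace` data frame with columns `time_s`, `intensity_pct`,
#'   `condition`, `replicate_id`.
#' @export
generate_control_trace <- function(tau_fast = 26.0, tau_slow = 259,
                                   amp_fast = 40.7, amp_slow = 17.5,
                                   floor = 41.8, times = frap_time_grid(),
                                   noise = noise_spec(0), replicate_id = 1L) {
  check_times(times)
  f <- frap_control_curve(times, tau_fast, tau_slow, amp_fast, amp_slow, floor)
  new_frap_trace(times, add_noise(f, noise), "control", replicate_id)
}

#' Generate a bafilomycin-condition FRAP trace
#'
#' @inheritParams frap_bafilomycin_curve
#' @inheritParams generate_control_trace
#' @export
generate_bafilomycin_trace <- function(tau = 49.0, amp = 40.7,
                                       times = frap_time_grid(),
                                       noise = noise_spec(0),
                                       replicate_id = 1L) {
  check_times(times)
  f <- frap_bafilomycin_curve(times, tau, amp)
  new_frap_trace(times, add_noise(f, noise), "bafilomycin", replicate_id)
}

#' Generate a replicated synthetic FRAP data set
#'
#' Each replicate gets its own noise stream derived deterministically from the
#' master seed in `noise`, so regeneration with the same arguments is
#' bit-identical.
#'
#' @param n_replicates Number of replicates per condition (>= 1).
#' @param conditions Character subset of `c("control", "bafilomycin")`.
#' @param noise A [noise_spec()]; its `seed` is the master seed.
#' @param times Sample times (s).
#' @param control_pars,baf_pars Named lists overriding the default curve
#'   parameters.
#' @return A `frap_trace` data frame with one row per (replicate, time point).
#' @export
generate_dataset <- function(n_replicates, conditions = c("control", "bafilomycin"),
                             noise = noise_spec(), times = frap_time_grid(),
                             control_pars = list(), baf_pars = list()) {
  stopifnot(n_replicates >= 1)
  known <- c("control", "bafilomycin")
  if (!all(conditions %in% known))
    stop("unknown condition label: ", paste(setdiff(conditions, known), collapse = ", "))
  out <- list()
  for (cond in conditions) {
    for (k in seq_len(n_replicates)) {
      off <- if (cond == "control") 0L else 500000L
      nk <- noise_spec(noise$sd, derive_seed(noise$seed, k + off))
      tr <- if (cond == "control") {
        do.call(generate_control_trace,
                c(control_pars, list(times = times, noise = nk, replicate_id = k)))
      } else {
        do.call(generate_bafilomycin_trace,
                c(baf_pars, list(times = times, noise = nk, replicate_id = k)))
      }
      out[[length(out) + 1L]] <- tr
    }
  }
  res <- do.call(rbind, out)
  structure(res, prebleach_level = 100, class = c("frap_trace", "data.frame"))
}

#' Average replicate traces of one condition into a mean trace
#'
#' @param traces A `frap_trace` data frame (possibly many replicates).
#' @param condition Condition to average; defaults to the single condition
#'   present.
#' @export
mean_trace <- function(traces, condition = NULL) {
  if (is.null(condition)) {
    condition <- unique(traces$condition)
    if (length(condition) != 1L)
      stop("multiple conditions present; pass `condition`")
  }
  sub <- traces[traces$condition == condition, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no rows for condition ", condition)
  agg <- stats::aggregate(intensity_pct ~ time_s, data = sub, FUN = mean)
  agg <- agg[order(agg$time_s), ]
  new_frap_trace(agg$time_s, agg$intensity_pct, condition, 0L)
}

#' Write / read FRAP traces in the package CSV dialect
#'
#' Header `time_s,intensity_pct,condition,replicate_id`, one row per sample,
#' "." decimal separator.
#'
#' @param traces A `frap_trace` data frame.
#' @param path File path.
#' @export
write_frap_csv <- function(traces, path) {
  utils::write.csv(as.data.frame(traces)[, c("time_s", "intensity_pct",
                                             "condition", "replicate_id")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_frap_csv
#' @export
read_frap_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "intensity_pct", "condition", "replicate_id")
  if (!all(need %in% names(df)))
    stop("not a FRAP trace CSV: missing columns ",
         paste(setdiff(need, names(df)), collapse = ", "))
  structure(df, prebleach_level = 100, class = c("frap_trace", "data.frame"))
}
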