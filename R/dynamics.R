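#' Local maxima of a trajectory with prominence filtering
#'
#' Detects local maxima of a densely sampled signal, measures each peak's
#' topographic prominence, discards peaks below a prominence threshold, and
#' refines peak times and heights by quadratic interpolation through the
#' three samples around each maximum.
#'
#' @param time sample times (strictly increasing).
#' @param value sampled signal (same length, at least 2 samples).
#' @param min_prominence absolute prominence threshold; defaults to 1
#'   percent of the global signal range.
#' @return data.frame with `time`, `value`, `prominence`, ordered in time
#'   (zero rows for a peak-free signal).
#' @export
find_peaks <- function(time, value, min_prominence = NULL) {
  n <- length(value)
  if (n < 2 || length(time) != n)
    stop("need at least 2 samples with matching time vector")
  rng <- diff(range(value))
  if (is.null(min_prominence)) min_prominence <- 0.01 * rng
  if (rng == 0)
    return(data.frame(time = numeric(0), value = numeric(0),
                      prominence = numeric(0)))
  idx <- which(value[2:(n - 1)] > value[1:(n - 2)] &
               value[2:(n - 1)] >= value[3:n]) + 1L
  if (!length(idx))
    return(data.frame(time = numeric(0), value = numeric(0),
                      prominence = numeric(0)))
  prominence <- vapply(idx, function(i) {
    # walk outwards until a higher point (or the boundary); the key saddle
    # is the higher of the two lowest points passed on each side
    left <- value[seq_len(i - 1)]
    hi_l <- which(left > value[i])
    min_l <- min(left[seq.int(from = if (length(hi_l)) max(hi_l) + 1 else 1,
                              to = i - 1)])
    right <- value[seq.int(i + 1, n)]
    hi_r <- which(right > value[i])
    min_r <- min(right[seq_len(if (length(hi_r)) min(hi_r) - 1 else
                                 length(right))])
    value[i] - max(min_l, min_r)
  }, numeric(1))
  keep <- prominence >= min_prominence
  idx <- idx[keep]; prominence <- prominence[keep]
  refine <- function(i) {
    t3 <- time[(i - 1):(i + 1)]; v3 <- value[(i - 1):(i + 1)]
    co <- tryCatch(solve(cbind(1, t3, t3^2), v3), error = function(e) NULL)
    if (is.null(co) || co[3] >= 0) return(c(time[i], value[i]))
    tstar <- -co[2] / (2 * co[3])
    if (tstar < t3[1] || tstar > t3[3]) return(c(time[i], value[i]))
    c(tstar, co[1] + co[2] * tstar + co[3] * tstar^2)
  }
  ref <- vapply(idx, refine, numeric(2))
  data.frame(time = ref[1, ], value = ref[2, ], prominence = prominence)
}

#' Classify the response regime under tonic TNF
#'
#' Simulates the model from the resting state with TNF switched on at
#' `onset_h` hours and held on to the horizon, then labels the nuclear
#' NF-kB response as one of `no_oscillation`, `damped_oscillations`,
#' `sustained_oscillations`, `spiky_oscillations` or
#' `near_perfect_adaptation`:
#' * sustained: the late-window (last 25 percent of the horizon)
#'   peak-to-peak amplitude persists above 1 percent of the first-peak
#'   amplitude; `spiky` if additionally the cycles are relaxation-like,
#'   returning near baseline between spikes (late-window trough below 10
#'   percent of the late-window peak);
#' * near-perfect adaptation: the response decays and the final NFkBn falls
#'   below 10 percent of the first peak (the pre-stimulus level is 0);
#' * damped: at least two decaying peaks converging to an elevated state;
#' * no oscillation: at most one peak with an elevated final level.
#'
#' @param params an [nfkb_params] vector.
#' @param onset_h TNF switch-on time, hours (default 1, so peak times are
#'   reported in absolute simulation time with stimulation from t = 1 h).
#' @param horizon_h simulation horizon, hours.
#' @param genotype `"WT"` or `"A20KO"`.
#' @param dt_min sampling step, minutes (at most 0.5).
#' @param rtol,atol integrator tolerances.
#' @return a list of class `nfkb_regime`: `label`, `low_confidence`,
#'   `metrics` (named list), `peaks` (data.frame with times in hours) and
#'   `trajectory`.
#' @examples
#' \donttest{
#' classify_response(nfkb_params("fitted"), horizon_h = 48)$label
#' }
#' @export
classify_response <- function(params, onset_h = 1, horizon_h = 48,
                              genotype = "WT", dt_min = 0.5,
                              rtol = 1e-8, atol = 1e-10) {
  if (dt_min > 0.5) stop("dt_min must be <= 0.5 min for peak detection")
  prot <- make_tonic(horizon = horizon_h * 60, onset = onset_h * 60)
  tr <- simulate_nfkb(params, prot, "WT", dt_min = dt_min,
                      rtol = rtol, atol = atol)
  if (identical(genotype, "A20KO"))
    tr <- simulate_nfkb(params, prot, "A20KO", dt_min = dt_min,
                        rtol = rtol, atol = atol)
  t_h <- tr$time_min / 60
  x <- tr$NFkBn
  pk <- find_peaks(t_h, x)
  pk <- pk[pk$time > onset_h, , drop = FALSE]
  first_amp <- if (nrow(pk)) pk$value[1] else max(x)
  late <- t_h >= 0.75 * horizon_h
  late_x <- x[late]
  late_amp <- diff(range(late_x))
  final_x <- x[length(x)]
  adaptation_index <- if (first_amp > 0) final_x / first_amp else NA_real_
  duty <- if (max(late_x) > 0)
    mean(late_x > 0.1 * max(late_x)) else NA_real_
  trough_ratio <- if (max(late_x) > 0)
    min(late_x) / max(late_x) else NA_real_
  decay_ratio <- if (nrow(pk) >= 2) pk$value[2] / pk$value[1] else NA_real_
  sustained_ratio <- if (first_amp > 0) late_amp / first_amp else 0
  if (sustained_ratio >= 0.01) {
    label <- if (!is.na(trough_ratio) && trough_ratio < 0.1)
               "spiky_oscillations"
             else "sustained_oscillations"
  } else if (!is.na(adaptation_index) && adaptation_index < 0.1 &&
             first_amp > 10 * max(final_x, .Machine$double.eps)) {
    label <- "near_perfect_adaptation"
  } else if (nrow(pk) >= 2) {
    label <- "damped_oscillations"
  } else {
    label <- "no_oscillation"
  }
  low_confidence <-
    (sustained_ratio > 0.005 && sustained_ratio < 0.02) ||
    (!is.na(adaptation_index) && adaptation_index > 0.08 &&
       adaptation_index < 0.12)
  structure(list(
    label = label, low_confidence = low_confidence,
    metrics = list(n_peaks = nrow(pk),
                   first_peak_time_h = if (nrow(pk)) pk$time[1] else NA_real_,
                   first_peak_value = if (nrow(pk)) pk$value[1] else NA_real_,
                   second_peak_time_h = if (nrow(pk) >= 2) pk$time[2]
                                        else NA_real_,
                   peak_decay_ratio = decay_ratio,
                   late_amplitude = late_amp,
                   sustained_ratio = sustained_ratio,
                   adaptation_index = adaptation_index,
                   duty_cycle = duty,
                   trough_ratio = trough_ratio,
                   final_NFkBn = final_x),
    peaks = pk, trajectory = tr), class = "nfkb_regime")
}

#' @export
print.nfkb_regime <- function(x, ...) {
  cat("Response regime:", x$label,
      if (x$low_confidence) "(low confidence)" else "", "\n")
  m <- x$metrics
  cat(sprintf("  peaks: %d; first at %.2f h (%.3f); second at %s h\n",
              m$n_peaks,
              if (is.na(m$first_peak_time_h)) NA else m$first_peak_time_h,
              if (is.na(m$first_peak_value)) NA else m$first_peak_value,
              if (is.na(m$second_peak_time_h)) "-" else
                sprintf("%.2f", m$second_peak_time_h)))
  cat(sprintf("  adaptation index: %.3g; late amplitude: %.3g; duty: %.2f\n",
              m$adaptation_index, m$late_amplitude, m$duty_cycle))
  invisible(x)
}
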