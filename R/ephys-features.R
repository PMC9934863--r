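recording_protocol <- function(recording) {
  p <- attr(recording, "protocol")
  if (is.null(p)) abort("Recording carries no `protocol` attribute.")
  p
}

sweep_current <- function(sweep) {
  cur <- sweep$current_pa[sweep$current_pa != 0]
  if (length(cur) == 0) 0 else cur[1]
}

#' Detect action potentials in a voltage trace
#'
#' Spikes are peaks whose preceding upstroke exceeds a dV/dt threshold and
#' whose peak voltage exceeds a floor; peaks closer than the refractory
#' window are merged (first kept).
#'
#' @param voltage_mv numeric voltage trace, mV.
#' @param dt_ms sampling interval, ms.
#' @param window_ms optional `c(start, end)` restricting detection, ms.
#' @param dvdt_threshold upstroke criterion, mV/ms.
#' @param peak_floor_mv minimal peak voltage, mV.
#' @param refractory_ms merge window, ms.
#' @return A tibble with `index`, `time_ms`, `peak_mv`, ordered in time.
#' @export
detect_action_potentials <- function(voltage_mv, dt_ms,
                                     window_ms = NULL,
                                     dvdt_threshold = 20,
                                     peak_floor_mv = -10,
                                     refractory_ms = 2) {
  if (length(voltage_mv) == 0) abort("Empty trace.")
  v <- voltage_mv
  n <- length(v)
  dvdt <- c(0, diff(v)) / dt_ms
  # local maxima preceded (within 2 ms) by a fast upstroke
  look <- max(1L, round(2 / dt_ms))
  is_peak <- c(FALSE, diff(v) > 0) & c(v[-n] >= v[-1], TRUE) &
    v >= peak_floor_mv
  cand <- which(is_peak)
  if (!is.null(window_ms)) {
    tt <- (cand - 1) * dt_ms
    cand <- cand[tt >= window_ms[1] & tt <= window_ms[2]]
  }
  cand <- cand[vapply(cand, function(i) {
    max(dvdt[max(1, i - look):i]) >= dvdt_threshold
  }, logical(1))]
  keep <- integer(0)
  last_t <- -Inf
  for (i in cand) {
    t_i <- (i - 1) * dt_ms
    if (t_i - last_t >= refractory_ms) {
      keep <- c(keep, i)
      last_t <- t_i
    }
  }
  tibble::tibble(index = keep, time_ms = (keep - 1) * dt_ms,
                 peak_mv = v[keep])
}

#' Spike threshold via the third derivative
#'
#' Within the 20 ms preceding the spike peak, the trace is lightly smoothed
#' (centred moving average) and the sample at the maximum of the third
#' finite difference is taken as the threshold point.
#'
#' @param voltage_mv voltage trace, mV.
#' @param peak_index sample index of the spike peak.
#' @param dt_ms sampling interval, ms.
#' @param window_ms length of the pre-peak search window, ms.
#' @param smooth_samples moving-average width (odd; 1 disables smoothing).
#' @return A list with `index` and `voltage` of the threshold point.
#' @export
ap_threshold <- function(voltage_mv, peak_index, dt_ms, window_ms = 20,
                         smooth_samples = 5) {
  w <- max(1L, round(window_ms / dt_ms))
  start <- peak_index - w
  if (start < 1) abort("Trace provides less than the pre-peak window.")
  seg <- voltage_mv[start:peak_index]
  if (smooth_samples > 1) {
    sm <- stats::filter(seg, rep(1 / smooth_samples, smooth_samples),
                        sides = 2)
    seg_s <- as.numeric(sm)
  } else {
    seg_s <- seg
  }
  d3 <- diff(seg_s, differences = 3)
  ok <- which(!is.na(d3))
  if (length(ok) == 0) abort("Window too short for the third derivative.")
  arg <- ok[which.max(d3[ok])]
  # map the forward-difference sample back onto the underlying kink point
  offset <- (smooth_samples - 1) / 2 + 2
  idx <- min(length(seg), arg + offset) + start - 1L
  list(index = idx, voltage = voltage_mv[idx])
}

interp_crossing <- function(tt, v, level, rising = TRUE) {
  if (rising) {
    k <- which(v[-length(v)] < level & v[-1] >= level)
  } else {
    k <- which(v[-length(v)] > level & v[-1] <= level)
  }
  if (length(k) == 0) return(NA_real_)
  k <- k[1]
  tt[k] + (level - v[k]) / (v[k + 1] - v[k]) * (tt[k + 1] - tt[k])
}

#' Waveform features of one action potential
#'
#' Amplitude is peak minus threshold; half-width is the time between the two
#' crossings of threshold + amplitude/2 (linear interpolation); rise time
#' runs threshold to peak, decay time peak to the first return to the
#' threshold voltage; the afterhyperpolarization (AHP) is threshold minus
#' the post-spike trough; the upstroke/downstroke ratio is max dV/dt over
#' |min dV/dt| between threshold and trough.
#'
#' @param voltage_mv voltage trace, mV.
#' @param peak_index spike peak sample index.
#' @param threshold list from [ap_threshold()].
#' @param dt_ms sampling interval, ms.
#' @param search_end_index last sample to search for the trough (defaults to
#'   end of trace; pass the next spike's threshold when analysing trains).
#' @return A one-row tibble: `amplitude`, `half_width`, `rise_time`,
#'   `decay_time`, `ahp`, `upstroke_downstroke_ratio`.
#' @export
ap_waveform_features <- function(voltage_mv, peak_index, threshold, dt_ms,
                                 search_end_index = length(voltage_mv)) {
  stopifnot(threshold$index < peak_index)
  v <- voltage_mv
  tt <- (seq_along(v) - 1) * dt_ms
  v_thr <- threshold$voltage
  amp <- v[peak_index] - v_thr
  half <- v_thr + amp / 2
  i0 <- threshold$index
  t_up <- interp_crossing(tt[i0:peak_index], v[i0:peak_index], half, TRUE)
  post <- peak_index:search_end_index
  t_down <- interp_crossing(tt[post], v[post], half, FALSE)
  half_width <- t_down - t_up
  rise_time <- tt[peak_index] - tt[i0]
  t_ret <- interp_crossing(tt[post], v[post], v_thr, FALSE)
  decay_time <- if (is.na(t_ret)) NA_real_ else t_ret - tt[peak_index]
  trough_rel <- which.min(v[post])
  trough_idx <- post[trough_rel]
  ahp <- v_thr - v[trough_idx]
  dvdt <- diff(v) / dt_ms
  span_up <- i0:(peak_index - 1)
  span_dn <- peak_index:max(peak_index, trough_idx - 1)
  tibble::tibble(
    amplitude = amp, half_width = half_width, rise_time = rise_time,
    decay_time = decay_time, ahp = ahp,
    upstroke_downstroke_ratio = max(dvdt[span_up]) / abs(min(dvdt[span_dn]))
  )
}

sweep_spikes <- function(sweep, protocol, ...) {
  dt <- 1 / protocol$sampling_khz
  detect_action_potentials(
    sweep$voltage_mv, dt,
    window_ms = c(protocol$onset_ms,
                  protocol$onset_ms + protocol$duration_ms), ...
  )
}

#' Rheobase and first-spike delay
#'
#' Rheobase is the smallest injected current eliciting at least one spike
#' during the stimulus; the delay runs from stimulus onset to the threshold
#' point of the first spike at that sweep.
#'
#' @param recording a step recording tibble (see
#'   [generate_step_recording()]) with a `protocol` attribute.
#' @return A one-row tibble `rheobase`, `ap_delay` (both `NA` when no sweep
#'   elicits spikes).
#' @export
rheobase_and_delay <- function(recording) {
  protocol <- recording_protocol(recording)
  dt <- 1 / protocol$sampling_khz
  sweeps <- split(recording, recording$sweep_id)
  currents <- vapply(sweeps, sweep_current, numeric(1))
  for (k in order(currents)) {
    if (currents[k] <= 0) next
    sp <- sweep_spikes(sweeps[[k]], protocol)
    if (nrow(sp) > 0) {
      thr <- ap_threshold(sweeps[[k]]$voltage_mv, sp$index[1], dt)
      return(tibble::tibble(
        rheobase = unname(currents[k]),
        ap_delay = (thr$index - 1) * dt - protocol$onset_ms
      ))
    }
  }
  tibble::tibble(rheobase = NA_real_, ap_delay = NA_real_)
}

#' Membrane time constant from hyperpolarizing sweeps
#'
#' Each hyperpolarizing trace is fitted, from stimulus onset to the minimal
#' potential within the first half of the stimulus, with
#' `f(t) = a * exp(-t / tau) + C` (nonlinear least squares initialized from
#' a log-linear regression of the detrended trace); the mean tau across
#' sweeps is returned.
#'
#' @inheritParams rheobase_and_delay
#' @return Mean tau in ms (`NA` when no sweep can be fitted).
#' @export
fit_membrane_time_constant <- function(recording) {
  protocol <- recording_protocol(recording)
  dt <- 1 / protocol$sampling_khz
  sweeps <- split(recording, recording$sweep_id)
  currents <- vapply(sweeps, sweep_current, numeric(1))
  hyp <- which(currents < 0)
  if (length(hyp) == 0) abort("No hyperpolarizing sweep available.")
  taus <- purrr::map_dbl(hyp, function(k) {
    v <- sweeps[[k]]$voltage_mv
    tt <- sweeps[[k]]$time_ms
    half <- tt >= protocol$onset_ms &
      tt <= protocol$onset_ms + protocol$duration_ms / 2
    idx_half <- which(half)
    i_min <- idx_half[which.min(v[idx_half])]
    i_on <- which(tt >= protocol$onset_ms)[1]
    if (i_min - i_on < 10) return(NA_real_)
    seg <- i_on:i_min
    t_rel <- tt[seg] - tt[i_on]
    y <- v[seg]
    c0 <- y[length(y)]
    amp0 <- y[1] - c0
    pos <- (y - c0) / amp0
    use <- pos > 1e-3
    tau0 <- tryCatch(-1 / coef(lm(log(pos[use]) ~ t_rel[use]))[[2]],
                     error = function(e) protocol$duration_ms / 20)
    if (!is.finite(tau0) || tau0 <= 0) tau0 <- protocol$duration_ms / 20
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a * exp(-t_rel / tau) + C,
                        start = list(a = amp0, tau = tau0, C = c0)),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      warn("Time-constant fit failed on one sweep; skipped.")
      return(NA_real_)
    }
    coef(fit)[["tau"]]
  })
  if (all(is.na(taus))) return(NA_real_)
  mean(taus, na.rm = TRUE)
}

#' Input resistance and resting membrane potential from the I-V relation
#'
#' Steady-state potentials (mean of the last `steady_window_ms` of the step)
#' of the first five negative-current sweeps are regressed on injected
#' current; the slope is the input resistance and the fitted potential at
#' zero current is the resting membrane potential.
#'
#' @inheritParams rheobase_and_delay
#' @param steady_window_ms averaging window at the end of the step, ms.
#' @return A one-row tibble `r_input` (megaohm), `rmp` (mV).
#' @export
input_resistance_rmp <- function(recording, steady_window_ms = 50) {
  protocol <- recording_protocol(recording)
  sweeps <- split(recording, recording$sweep_id)
  currents <- vapply(sweeps, sweep_current, numeric(1))
  neg <- order(currents)[currents[order(currents)] < 0]
  if (length(neg) < 2) {
    warn("Fewer than two negative sweeps; input resistance missing.")
    return(tibble::tibble(r_input = NA_real_, rmp = NA_real_))
  }
  if (length(neg) < 5) {
    warn("Fewer than five negative sweeps; using all available.")
  }
  neg <- head(neg, 5)
  off <- protocol$onset_ms + protocol$duration_ms
  vss <- purrr::map_dbl(neg, function(k) {
    tt <- sweeps[[k]]$time_ms
    mean(sweeps[[k]]$voltage_mv[tt >= off - steady_window_ms & tt < off])
  })
  ii <- currents[neg]
  if (var(ii) == 0) abort("Identical currents across sweeps: singular fit.")
  fit <- lm(vss ~ ii)
  tibble::tibble(r_input = coef(fit)[[2]] * 1e3, rmp = coef(fit)[[1]])
}

#' Firing-pattern features from the maximal-firing sweep
#'
#' The sweep with the most spikes (ties broken toward larger current) gives
#' the maximal rate (spike count over the 600 ms stimulus), the adaptive
#' index (last/first inter-spike interval), the ISI coefficient of
#' variation, and the first-to-rest amplitude and half-width ratios (first
#' spike's value over the mean of the subsequent spikes').
#'
#' @inheritParams rheobase_and_delay
#' @return A one-row tibble `max_rate` (Hz), `adaptive_index`, `cv_isi`,
#'   `amp_ratio_first_to_rest`, `hw_ratio_first_to_rest`.
#' @export
firing_features <- function(recording) {
  protocol <- recording_protocol(recording)
  dt <- 1 / protocol$sampling_khz
  sweeps <- split(recording, recording$sweep_id)
  currents <- vapply(sweeps, sweep_current, numeric(1))
  spikes <- purrr::map(sweeps, sweep_spikes, protocol = protocol)
  counts <- vapply(spikes, nrow, integer(1))
  if (all(counts == 0)) {
    return(tibble::tibble(max_rate = 0, adaptive_index = NA_real_,
                          cv_isi = NA_real_,
                          amp_ratio_first_to_rest = NA_real_,
                          hw_ratio_first_to_rest = NA_real_))
  }
  best <- which(counts == max(counts))
  best <- best[which.max(currents[best])]
  sp <- spikes[[best]]
  v <- sweeps[[best]]$voltage_mv
  stim_end <- round((protocol$onset_ms + protocol$duration_ms) *
                      protocol$sampling_khz) + 1L
  max_rate <- unname(counts[best]) / (protocol$duration_ms / 1000)
  isi <- diff(sp$time_ms)
  adaptive_index <- if (length(isi) >= 2) isi[length(isi)] / isi[1] else NA_real_
  cv_isi <- if (length(isi) >= 2) sd(isi) / mean(isi) else NA_real_
  amp_ratio <- hw_ratio <- NA_real_
  if (nrow(sp) >= 2) {
    feats <- purrr::map_dfr(seq_len(nrow(sp)), function(s) {
      lim <- if (s < nrow(sp)) sp$index[s + 1] else min(length(v), stim_end)
      thr <- ap_threshold(v, sp$index[s], dt)
      ap_waveform_features(v, sp$index[s], thr, dt, search_end_index = lim)
    })
    amp_ratio <- feats$amplitude[1] / mean(feats$amplitude[-1])
    hw_ratio <- feats$half_width[1] / mean(feats$half_width[-1])
  }
  tibble::tibble(max_rate = max_rate, adaptive_index = adaptive_index,
                 cv_isi = cv_isi, amp_ratio_first_to_rest = amp_ratio,
                 hw_ratio_first_to_rest = hw_ratio)
}

#' Extract the full intrinsic-property feature vector of one cell
#'
#' Assembles passive features (resting potential, input resistance, membrane
#' time constant), rheobase and first-spike delay, the waveform features of
#' the first spike at the rheobase sweep (threshold, amplitude, half-width,
#' rise/decay times, afterhyperpolarization, upstroke/downstroke ratio), and
#' firing-pattern features. Missing values propagate as `NA`.
#'
#' @inheritParams rheobase_and_delay
#' @return A one-row tibble (an intrinsic-feature vector).
#' @export
extract_feature_vector <- function(recording) {
  protocol <- recording_protocol(recording)
  dt <- 1 / protocol$sampling_khz
  iv <- input_resistance_rmp(recording)
  tau <- fit_membrane_time_constant(recording)
  rb <- rheobase_and_delay(recording)
  wf <- tibble::tibble(ap_threshold = NA_real_, amplitude = NA_real_,
                       half_width = NA_real_, rise_time = NA_real_,
                       decay_time = NA_real_, ahp = NA_real_,
                       upstroke_downstroke_ratio = NA_real_)
  if (!is.na(rb$rheobase)) {
    sweeps <- split(recording, recording$sweep_id)
    currents <- vapply(sweeps, sweep_current, numeric(1))
    k <- which(currents == rb$rheobase)[1]
    sp <- sweep_spikes(sweeps[[k]], protocol)
    thr <- ap_threshold(sweeps[[k]]$voltage_mv, sp$index[1], dt)
    stim_end <- round((protocol$onset_ms + protocol$duration_ms) *
                        protocol$sampling_khz) + 1L
    lim <- if (nrow(sp) >= 2) sp$index[2]
           else min(length(sweeps[[k]]$voltage_mv), stim_end)
    w <- ap_waveform_features(sweeps[[k]]$voltage_mv, sp$index[1], thr, dt,
                              search_end_index = lim)
    wf <- dplyr::bind_cols(tibble::tibble(ap_threshold = thr$voltage), w)
  }
  ff <- firing_features(recording)
  dplyr::bind_cols(
    tibble::tibble(rmp = iv$rmp, r_input = iv$r_input, tau_m = tau,
                   rheobase = rb$rheobase, ap_delay = rb$ap_delay),
    dplyr::rename(wf, ap_amplitude = "amplitude",
                  ap_half_width = "half_width"),
    ff
  )
}

#' Two-dimensional embedding of feature vectors
#'
#' Features are standardized to zero mean and unit variance and projected
#' onto their first two principal components (signs fixed so the largest
#' loading is positive), giving a deterministic 2D map for visualization and
#' cluster-separation checks.
#'
#' @param features a data frame of numeric feature columns (one row per
#'   cell); non-numeric columns are ignored.
#' @param seed accepted for interface stability; the embedding is
#'   deterministic.
#' @return A tibble with columns `dim1`, `dim2`.
#' @export
embed_features <- function(features, seed = NULL) {
  num <- features[vapply(features, is.numeric, logical(1))]
  if (nrow(num) < 3) abort("At least 3 feature vectors are required.")
  if (anyNA(num)) {
    abort("Missing values present; impute or mask incomplete features first.")
  }
  keep <- vapply(num, function(x) sd(x) > 0, logical(1))
  if (!any(keep)) {
    return(tibble::tibble(dim1 = rep(0, nrow(num)), dim2 = rep(0, nrow(num))))
  }
  x <- scale(as.matrix(num[keep]))
  pc <- prcomp(x, center = FALSE, scale. = FALSE)
  k <- min(2, ncol(pc$x))
  co <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    load <- pc$rotation[, j]
    if (load[which.max(abs(load))] < 0) co[, j] <- -co[, j]
  }
  if (k == 1) co <- cbind(co, 0)
  tibble::tibble(dim1 = co[, 1], dim2 = co[, 2])
}
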