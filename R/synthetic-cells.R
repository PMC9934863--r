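#' Per-cell physiological parameters
#'
#' Bundles the intrinsic-property parameters of one simulated noradrenergic
#' neuron. Defaults emulate the population values reported for locus
#' coeruleus neurons: depolarized resting potential near -43 mV, high input
#' resistance, slow membrane charging, wide spikes with deep
#' afterhyperpolarization, and spike-frequency adaptation.
#'
#' @param cell_type `"FF"` (fusiform) or `"MP"` (multipolar).
#' @param rmp resting membrane potential, mV.
#' @param r_input input resistance, megaohm.
#' @param tau_m membrane time constant, ms.
#' @param rheobase minimal step current eliciting a spike, pA. For exact
#'   round-trip recovery with a 10 pA step protocol this should lie on the
#'   protocol's current grid.
#' @param ap_amplitude spike amplitude from threshold to peak, mV.
#' @param ap_half_width spike width at half height, ms.
#' @param ahp_depth afterhyperpolarization depth below threshold, mV.
#' @param adaptation target ratio of last to first inter-spike interval.
#' @param spont_rate spontaneous firing rate at rest, Hz (the emulated
#'   protocol holds cells below threshold, so this does not enter traces).
#' @return A one-row tibble of class `cell_params`.
#' @export
cell_params <- function(cell_type = c("MP", "FF"),
                        rmp = -43, r_input = 250, tau_m = 30,
                        rheobase = 80, ap_amplitude = 65,
                        ap_half_width = 1.8, ahp_depth = 15,
                        adaptation = 2, spont_rate = 1.6) {
  cell_type <- match.arg(cell_type)
  check_positive(r_input)
  check_positive(tau_m)
  check_positive(ap_half_width)
  check_positive(adaptation)
  out <- tibble::tibble(
    cell_type = cell_type, rmp = rmp, r_input = r_input, tau_m = tau_m,
    rheobase = rheobase, ap_amplitude = ap_amplitude,
    ap_half_width = ap_half_width, ahp_depth = ahp_depth,
    adaptation = adaptation, spont_rate = spont_rate
  )
  class(out) <- c("cell_params", class(out))
  out
}

#' Draw random cell parameters for a morpho-electric type
#'
#' Fusiform (FF) cells get narrower, larger spikes than multipolar (MP)
#' cells, mirroring the reported type differences; passive properties are
#' drawn from ranges typical of locus coeruleus neurons. Rheobase is drawn
#' on the 10 pA protocol grid.
#'
#' @param n number of cells.
#' @param cell_type `"FF"`, `"MP"`, or a vector of length `n`.
#' @param seed optional integer seed.
#' @return A tibble with `n` rows of cell parameters.
#' @export
sample_cell_params <- function(n, cell_type = "MP", seed = NULL) {
  cell_type <- rep(cell_type, length.out = n)
  with_seed(seed, {
    ff <- cell_type == "FF"
    tibble::tibble(
      cell_type = cell_type,
      rmp = runif(n, -48, -38),
      r_input = runif(n, 150, 350),
      tau_m = runif(n, 20, 45),
      rheobase = 10 * sample(4:12, n, replace = TRUE),
      ap_amplitude = ifelse(ff, runif(n, 70, 85), runif(n, 55, 70)),
      ap_half_width = ifelse(ff, runif(n, 1.0, 1.6), runif(n, 1.8, 2.6)),
      ahp_depth = runif(n, 10, 22),
      adaptation = runif(n, 1.3, 3),
      spont_rate = pmax(0.2, rnorm(n, 1.6, 0.4))
    )
  })
}

#' Describe a current-step stimulation protocol
#'
#' @param step_pa vector of injected step amplitudes, pA (ascending).
#' @param duration_ms stimulus duration, ms (600 in the emulated protocol).
#' @param onset_ms time of stimulus onset, ms.
#' @param post_ms trace length after stimulus offset, ms.
#' @param sampling_khz sampling rate, kHz.
#' @return A list of class `step_protocol`.
#' @export
step_protocol <- function(step_pa = seq(-100, 180, by = 10),
                          duration_ms = 600, onset_ms = 100, post_ms = 200,
                          sampling_khz = 20) {
  check_positive(duration_ms)
  check_positive(sampling_khz)
  structure(
    list(step_pa = sort(step_pa), duration_ms = duration_ms,
         onset_ms = onset_ms, post_ms = post_ms, sampling_khz = sampling_khz),
    class = "step_protocol"
  )
}

# Timing constants of the piecewise action-potential template: linear rise
# from threshold to peak (snapped to the sample grid so the peak voltage is
# sampled exactly), exponential decay toward an asymptote 10% below the
# trough (so the trough is reached at finite time), exponential recovery
# from the trough toward the inter-spike baseline. The decay constant is
# solved so the measured width at half height equals `half_width` exactly
# (the rising crossing sits at t_rise / 2).
ap_timing <- function(amplitude, half_width, ahp_depth, dt) {
  t_rise <- max(2 * dt, round(0.5 * half_width / dt) * dt)
  rel_peak <- amplitude + 1.1 * ahp_depth          # peak above asymptote
  rel_half <- amplitude / 2 + 1.1 * ahp_depth
  tau_d <- (half_width - t_rise / 2) / log(rel_peak / rel_half)
  t_fall <- tau_d * log(rel_peak / (0.1 * ahp_depth))
  tau_rec <- 5
  list(t_rise = t_rise, tau_d = tau_d, t_fall = t_fall, tau_rec = tau_rec,
       footprint = t_rise + t_fall + 5 * tau_rec)
}

ap_template <- function(v_thr, amplitude, ahp_depth, v_rest, dt, timing,
                        isi_limit = Inf) {
  peak <- v_thr + amplitude
  trough <- v_thr - ahp_depth
  v_inf <- v_thr - 1.1 * ahp_depth
  t_rec <- min(5 * timing$tau_rec,
               max(isi_limit - timing$t_rise - timing$t_fall, dt))
  tt_rise <- seq(dt, timing$t_rise, by = dt)
  tt_fall <- seq(dt, timing$t_fall, by = dt)
  tt_rec <- seq(dt, t_rec, by = dt)
  c(
    v_thr + (peak - v_thr) * tt_rise / timing$t_rise,
    v_inf + (peak - v_inf) * exp(-tt_fall / timing$tau_d),
    v_rest + (trough - v_rest) * exp(-tt_rec / timing$tau_rec)
  )
}

#' Generate a synthetic current-step recording
#'
#' Simulates the voltage responses of one cell to a family of current steps.
#' Subthreshold responses follow the single-compartment charging curve
#' `V(t) = RMP + I * R * (1 - exp(-t / tau))`; spikes are inserted as
#' parametrized waveforms whenever the injected current reaches rheobase,
#' with inter-spike intervals scaled geometrically so the last/first ISI
#' ratio equals the cell's adaptation parameter. With `noise_sd_mv = 0`
#' traces are noiseless and every generator parameter is recoverable by the
#' feature-extraction functions.
#'
#' @param params a one-row tibble from [cell_params()] or
#'   [sample_cell_params()].
#' @param protocol a [step_protocol()].
#' @param noise_sd_mv additive Gaussian noise SD, mV.
#' @param seed optional integer seed (used only when `noise_sd_mv > 0`).
#' @return A tibble with columns `sweep_id`, `time_ms`, `voltage_mv`,
#'   `current_pa`, carrying the protocol as attribute `"protocol"`.
#' @export
generate_step_recording <- function(params, protocol = step_protocol(),
                                    noise_sd_mv = 0, seed = NULL) {
  p <- as.list(params[1, ])
  dt <- 1 / protocol$sampling_khz
  if (p$ap_half_width / dt < 8) {
    abort("Sampling rate too low to resolve `ap_half_width`.")
  }
  n_t <- round((protocol$onset_ms + protocol$duration_ms + protocol$post_ms) / dt)
  tt <- seq_len(n_t) * dt - dt
  onset <- protocol$onset_ms
  offset <- protocol$onset_ms + protocol$duration_ms
  # threshold potential: 90% of the steady-state depolarization at rheobase
  dv_ss_rheo <- p$rheobase * p$r_input * 1e-3
  v_thr <- p$rmp + 0.9 * dv_ss_rheo
  timing <- ap_timing(p$ap_amplitude, p$ap_half_width, p$ahp_depth, dt)
  # leave full recovery between spikes so the pre-spike baseline is flat
  min_isi <- timing$footprint + 2

  sweeps <- purrr::map(seq_along(protocol$step_pa), function(k) {
    i_pa <- protocol$step_pa[k]
    dv <- i_pa * p$r_input * 1e-3
    v <- rep(p$rmp, n_t)
    during <- tt >= onset & tt < offset
    after <- tt >= offset
    v[during] <- p$rmp + dv * (1 - exp(-(tt[during] - onset) / p$tau_m))

    if (i_pa >= p$rheobase && dv > 0) {
      # first spike where the charging curve reaches threshold
      frac <- 0.9 * dv_ss_rheo / dv
      t_first <- -p$tau_m * log(1 - frac)
      n_ap <- 1 + floor((i_pa - p$rheobase) / 10)
      times <- t_first
      if (n_ap >= 2) {
        avail <- 0.9 * (protocol$duration_ms - t_first)
        isi <- numeric(0)
        while (n_ap >= 2) {
          n_isi <- n_ap - 1
          g <- if (n_isi >= 2) p$adaptation^(1 / (n_isi - 1)) else 1
          w <- g^(seq_len(n_isi) - 1)
          isi <- avail * w / sum(w)
          if (min(isi) >= min_isi) break
          n_ap <- n_ap - 1
        }
        times <- t_first + c(0, cumsum(isi))
      }
      times <- round(times / dt) * dt
      # clamp the suprathreshold baseline at threshold once crossed
      crossed <- during & (tt - onset) >= times[1]
      v[crossed] <- pmin(v[crossed], v_thr)
      for (s in seq_along(times)) {
        isi_lim <- if (s < length(times)) times[s + 1] - times[s] else Inf
        wave <- ap_template(v_thr, p$ap_amplitude, p$ahp_depth, v_thr, dt,
                            timing, isi_lim)
        i0 <- round((onset + times[s]) / dt) + 1L
        idx <- i0 + seq_along(wave)
        keep <- idx <= n_t
        v[idx[keep]] <- wave[keep]
      }
    }
    # relaxation after stimulus offset, from the actual end-of-step voltage
    v_end <- v[max(which(during))]
    v[after] <- p$rmp + (v_end - p$rmp) * exp(-(tt[after] - offset) / p$tau_m)
    tibble::tibble(sweep_id = k, time_ms = tt, voltage_mv = v,
                   current_pa = ifelse(during, i_pa, 0))
  })
  out <- dplyr::bind_rows(sweeps)
  if (noise_sd_mv > 0) {
    out$voltage_mv <- with_seed(seed,
      out$voltage_mv + rnorm(nrow(out), 0, noise_sd_mv))
  }
  attr(out, "protocol") <- protocol
  out
}

#' Generate paired trial traces for a coupled pair
#'
#' Fixture generator for the coupling-coefficient estimator: a 600 ms
#' current step injected into one cell produces a steady-state deflection
#' `step * r_input` there and `cc_true` times that in the partner, both with
#' additive Gaussian noise. Both directions are generated.
#'
#' @param cc_true true coupling coefficient in `[0, 1]`.
#' @param n_trials trials per direction.
#' @param noise_sd_mv additive noise SD, mV.
#' @param step_pa injected current, pA (negative for hyperpolarizing).
#' @param r_input input resistance of both cells, megaohm.
#' @param tau_m membrane time constant, ms.
#' @param seed optional integer seed.
#' @param sampling_khz sampling rate, kHz.
#' @return A tibble with columns `direction` (`"ij"`/`"ji"`), `trial`,
#'   `role` (`"injected"`/`"partner"`), `time_ms`, `voltage_mv`; stimulus
#'   timing in attributes `stim_onset_ms` and `stim_duration_ms`.
#' @export
generate_coupled_pair_trials <- function(cc_true, n_trials = 10,
                                         noise_sd_mv = 0, step_pa = -50,
                                         r_input = 250, tau_m = 30,
                                         seed = NULL, sampling_khz = 5) {
  check_probability(cc_true, "cc_true")
  stopifnot(n_trials >= 1)
  onset <- 100
  dur <- 600
  dt <- 1 / sampling_khz
  tt <- seq(0, onset + dur + 100 - dt, by = dt)
  during <- tt >= onset & tt < onset + dur
  dv1 <- step_pa * r_input * 1e-3
  shape <- numeric(length(tt))
  shape[during] <- 1 - exp(-(tt[during] - onset) / tau_m)
  after <- tt >= onset + dur
  shape[after] <- (1 - exp(-dur / tau_m)) * exp(-(tt[after] - onset - dur) / tau_m)
  base <- -55
  with_seed(seed, {
    grid <- tidyr::expand_grid(direction = c("ij", "ji"),
                               trial = seq_len(n_trials),
                               role = c("injected", "partner"))
    out <- purrr::pmap_dfr(grid, function(direction, trial, role) {
      amp <- if (role == "injected") dv1 else cc_true * dv1
      v <- base + amp * shape
      if (noise_sd_mv > 0) v <- v + rnorm(length(v), 0, noise_sd_mv)
      tibble::tibble(direction = direction, trial = trial, role = role,
                     time_ms = tt, voltage_mv = v)
    })
    attr(out, "stim_onset_ms") <- onset
    attr(out, "stim_duration_ms") <- dur
    out
  })
}
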