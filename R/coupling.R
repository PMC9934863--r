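#' Steady-state voltage deflection of a current step
#'
#' Mean voltage over the last `window_ms` of the step minus the mean over an
#' equal-length pre-stimulus baseline. Invariant to common voltage offsets.
#'
#' @param voltage_mv voltage trace, mV.
#' @param time_ms matching time axis, ms.
#' @param stim_onset_ms,stim_duration_ms stimulus timing, ms.
#' @param window_ms measurement window at the end of the step (default 15,
#'   the midpoint of the 10-20 ms range used at the rig), ms.
#' @return Deflection in mV.
#' @export
steady_state_deflection <- function(voltage_mv, time_ms, stim_onset_ms,
                                    stim_duration_ms, window_ms = 15) {
  if (window_ms > stim_duration_ms) {
    abort("`window_ms` exceeds the step duration.")
  }
  if (window_ms > stim_onset_ms) {
    abort("Baseline window extends before the trace start.")
  }
  off <- stim_onset_ms + stim_duration_ms
  late <- time_ms >= off - window_ms & time_ms < off
  base <- time_ms >= stim_onset_ms - window_ms & time_ms < stim_onset_ms
  mean(voltage_mv[late]) - mean(voltage_mv[base])
}

#' Coupling coefficient for one direction
#'
#' Trials are averaged first; the coupling coefficient is the partner cell's
#' steady-state deflection divided by the injected cell's.
#'
#' @param trials a tibble of paired trial traces with columns `trial`,
#'   `role` (`"injected"`/`"partner"`), `time_ms`, `voltage_mv` (one
#'   direction of [generate_coupled_pair_trials()] output).
#' @param stim_onset_ms,stim_duration_ms stimulus timing, ms (defaults read
#'   from the attributes set by the trial generator).
#' @param window_ms steady-state window, ms.
#' @return A one-row tibble: `cc`, `v_injected`, `v_partner`, `reliable`
#'   (`FALSE` when the injected deflection is under 1 mV), `n_trials`.
#' @export
coupling_coefficient <- function(trials,
                                 stim_onset_ms = attr(trials, "stim_onset_ms"),
                                 stim_duration_ms = attr(trials, "stim_duration_ms"),
                                 window_ms = 15) {
  stopifnot(nrow(trials) > 0)
  avg <- trials |>
    dplyr::group_by(.data$role, .data$time_ms) |>
    dplyr::summarise(voltage_mv = mean(.data$voltage_mv), .groups = "drop")
  defl <- avg |>
    dplyr::group_by(.data$role) |>
    dplyr::summarise(dv = steady_state_deflection(
      .data$voltage_mv, .data$time_ms, stim_onset_ms, stim_duration_ms,
      window_ms), .groups = "drop")
  v1 <- defl$dv[defl$role == "injected"]
  v2 <- defl$dv[defl$role == "partner"]
  tibble::tibble(cc = v2 / v1, v_injected = v1, v_partner = v2,
                 reliable = abs(v1) >= 1,
                 n_trials = length(unique(trials$trial)))
}

#' Bidirectional coupling estimate for a tested pair
#'
#' @param trials output of [generate_coupled_pair_trials()] (or a tibble in
#'   the same format with a `direction` column, `"ij"`/`"ji"`).
#' @inheritParams coupling_coefficient
#' @return A one-row tibble with `cc_ij`, `cc_ji`, `cc_mean`, the four
#'   deflections, and `same_sign` (partner deflections share the injected
#'   response's sign in every tested direction).
#' @export
estimate_coupling <- function(trials, window_ms = 15) {
  dirs <- split(trials, trials$direction)
  est <- purrr::map(dirs, coupling_coefficient,
                    stim_onset_ms = attr(trials, "stim_onset_ms"),
                    stim_duration_ms = attr(trials, "stim_duration_ms"),
                    window_ms = window_ms)
  cc_ij <- if ("ij" %in% names(est)) est$ij$cc else NA_real_
  cc_ji <- if ("ji" %in% names(est)) est$ji$cc else NA_real_
  both <- !is.na(cc_ij) && !is.na(cc_ji)
  same_sign <- all(purrr::map_lgl(est, function(e) {
    e$v_partner == 0 || sign(e$v_partner) == sign(e$v_injected)
  }))
  tibble::tibble(
    cc_ij = cc_ij, cc_ji = cc_ji,
    cc_mean = if (both) (cc_ij + cc_ji) / 2 else dplyr::coalesce(cc_ij, cc_ji),
    one_sided = !both, same_sign = same_sign
  )
}

#' Classify a pair as electrically coupled
#'
#' A pair is coupled when the mean steady-state coupling coefficient reaches
#' the criterion (0.005, set by recording noise) and the partner deflection
#' has the same sign as the injected response. Pairs tested in one direction
#' are classified on that direction (flagged `one_sided` upstream).
#'
#' @param estimate a row from [estimate_coupling()] (columns `cc_mean`,
#'   `same_sign`).
#' @param cc_threshold classification criterion on the mean coefficient.
#' @return Logical vector: coupled or not.
#' @export
classify_electrical_connection <- function(estimate, cc_threshold = 0.005) {
  estimate$cc_mean >= cc_threshold & estimate$same_sign
}

#' Rectification check: regression of the two coupling directions
#'
#' Least-squares line of `cc_ji` (response) on `cc_ij` (regressor) across
#' coupled pairs; a slope near 1 indicates nonrectifying junctions.
#'
#' @param estimates a tibble of coupled-pair estimates with columns `cc_ij`,
#'   `cc_ji`.
#' @return A one-row tibble `slope`, `intercept`, `r_squared`, `n` (all `NA`
#'   when fewer than 3 pairs).
#' @export
rectification_regression <- function(estimates) {
  est <- estimates[complete.cases(estimates[, c("cc_ij", "cc_ji")]), ]
  if (nrow(est) < 3) {
    return(tibble::tibble(slope = NA_real_, intercept = NA_real_,
                          r_squared = NA_real_, n = nrow(est)))
  }
  fit <- lm(cc_ji ~ cc_ij, data = est)
  tibble::tibble(slope = coef(fit)[[2]], intercept = coef(fit)[[1]],
                 r_squared = summary(fit)$r.squared, n = nrow(est))
}

#' Detect a chemical connection from presynaptic-spike-triggered sweeps
#'
#' Postsynaptic sweeps aligned on the presynaptic action potential are
#' averaged; a connection is called when the averaged trace deviates from
#' baseline by more than `k` baseline standard deviations (of the average)
#' for at least `min_duration_ms` within a 1-15 ms post-spike window (the
#' duration requirement rejects single-sample noise excursions). Latency is
#' the first crossing time of the sustained deviation.
#'
#' @param sweeps tibble of postsynaptic sweeps with columns `sweep`,
#'   `time_ms`, `voltage_mv`; `time_ms` is relative to trace start.
#' @param ap_time_ms time of the presynaptic spike, ms.
#' @param k detection criterion in baseline SDs.
#' @param window_ms post-spike search window `c(lo, hi)`, ms.
#' @param min_duration_ms minimal sustained deviation, ms.
#' @param min_sweeps fewer sweeps flags the result unreliable.
#' @return A one-row tibble: `connected`, `latency_ms`, `amplitude_mv`,
#'   `reliable`.
#' @export
detect_chemical_connection <- function(sweeps, ap_time_ms, k = 3,
                                       window_ms = c(1, 15),
                                       min_duration_ms = 1,
                                       min_sweeps = 10) {
  n_sweeps <- length(unique(sweeps$sweep))
  avg <- sweeps |>
    dplyr::group_by(.data$time_ms) |>
    dplyr::summarise(v = mean(.data$voltage_mv), .groups = "drop") |>
    dplyr::arrange(.data$time_ms)
  base <- avg$v[avg$time_ms < ap_time_ms]
  if (length(base) < 5) abort("Insufficient pre-spike baseline.")
  mu <- mean(base)
  sdb <- sd(base)
  win <- avg$time_ms >= ap_time_ms + window_ms[1] &
    avg$time_ms <= ap_time_ms + window_ms[2]
  dev <- avg$v[win] - mu
  hit <- abs(dev) > k * sdb
  dt <- stats::median(diff(avg$time_ms))
  need <- max(1L, ceiling(min_duration_ms / dt))
  runs <- rle(hit)
  sustained <- runs$values & runs$lengths >= need
  connected <- any(sustained)
  latency <- if (connected) {
    first <- sum(runs$lengths[seq_len(which(sustained)[1] - 1)]) + 1L
    avg$time_ms[win][first] - ap_time_ms
  } else {
    NA_real_
  }
  amp <- if (connected) dev[which.max(abs(dev))] else NA_real_
  tibble::tibble(connected = connected, latency_ms = latency,
                 amplitude_mv = amp, reliable = n_sweeps >= min_sweeps)
}

#' Connectivity rates by distance bin and/or cell-type combination
#'
#' @param pairs tibble of tested pairs with logical `connected` (or another
#'   edge column) plus `distance_um` and `type_i`/`type_j` as needed.
#' @param by grouping: any of `"distance"`, `"type"`.
#' @param breaks distance bin edges, um. Defaults to `[0, 40)`, `[40, 80)`,
#'   then 40 um bins to 280.
#' @param edge_col name of the logical connection column.
#' @return A tibble of `n_coupled`, `n_tested`, `rate` (in `[0, 1]`), and
#'   `rate_pct` (percentage rounded to one decimal) per group; groups with
#'   no tested pairs report `NA` rates, never 0.
#' @export
connectivity_rates <- function(pairs, by = c("type"),
                               breaks = seq(0, 280, by = 40),
                               edge_col = "connected") {
  stopifnot(edge_col %in% names(pairs))
  g <- pairs
  keys <- character(0)
  if ("type" %in% by) {
    g$type_pair <- factor(
      toupper(sub("_", "-", pair_type_key(g$type_i, g$type_j))),
      levels = c("FF-FF", "FF-MP", "MP-MP"))
    keys <- c(keys, "type_pair")
  }
  if ("distance" %in% by) {
    g$distance_bin <- cut(g$distance_um, breaks = c(breaks, Inf),
                          right = FALSE, include.lowest = TRUE)
    keys <- c(keys, "distance_bin")
  }
  out <- g |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys)), .drop = FALSE) |>
    dplyr::summarise(n_coupled = sum(.data[[edge_col]]),
                     n_tested = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(
      rate = ifelse(.data$n_tested > 0, .data$n_coupled / .data$n_tested,
                    NA_real_),
      rate_pct = round(100 * .data$rate, 1)
    )
  out
}
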