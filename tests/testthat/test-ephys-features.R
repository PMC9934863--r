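dt <- 0.05  # 20 kHz

test_that("spike detection finds template spikes and respects refractoriness", {
  expect_equal(nrow(detect_action_potentials(rep(-43, 2000), dt)), 0)
  expect_error(detect_action_potentials(numeric(0), dt), "Empty")

  p <- cell_params(rheobase = 50, adaptation = 1.5)
  prot <- step_protocol(step_pa = seq(-50, 90, 10))
  rec <- generate_step_recording(p, prot)
  top <- rec[rec$sweep_id == max(rec$sweep_id), ]
  sp <- detect_action_potentials(top$voltage_mv, dt,
                                 window_ms = c(100, 700))
  expect_equal(nrow(sp), 5)  # 1 + floor((90 - 50) / 10)

  # two peaks one sample apart merge into one detection
  v <- rep(-60, 800)
  v[400] <- 0
  v[401] <- -1
  v[402] <- 0
  expect_equal(nrow(detect_action_potentials(v, dt)), 1)
})

test_that("third-derivative threshold lands on the construction kink", {
  # flat baseline then linear rise: kink voltage is the threshold
  n <- 1000
  v <- rep(-40, n)
  kink <- 800
  v[kink:n] <- -40 + 100 * dt * (0:(n - kink))
  peak <- n
  thr <- ap_threshold(v, peak, dt)
  expect_equal(thr$voltage, -40, tolerance = 100 * dt * 2.5)
  thr2 <- ap_threshold(v, peak, dt)
  expect_identical(thr, thr2)
  expect_error(ap_threshold(v, 100, dt), "window")

  # cubic segment: third derivative is constant and maximal at the end of
  # the window only where the cubic lives
  t_rel <- seq(0, 20, by = dt)
  v2 <- c(rep(0, 400), 1e-3 * t_rel^3)
  thr3 <- ap_threshold(v2, length(v2), dt)
  expect_gt(thr3$index, 400)
})

test_that("waveform features match template construction", {
  p <- cell_params(rheobase = 80, ap_amplitude = 60, ap_half_width = 1.2,
                   ahp_depth = 12)
  rec <- generate_step_recording(p)
  fv <- extract_feature_vector(rec)
  expect_equal(fv$ap_amplitude, 60, tolerance = 0.01)
  expect_equal(fv$ap_half_width, 1.2, tolerance = 0.01)
  expect_equal(fv$ahp, 12, tolerance = 0.05)
  expect_gt(fv$rise_time, 0)
  expect_gt(fv$decay_time, 0)
  expect_gt(fv$upstroke_downstroke_ratio, 1)  # linear rise is steeper

  # symmetric triangular spike: upstroke/downstroke ratio 1
  v <- c(rep(-60, 500), seq(-60, 0, length.out = 100),
         seq(0, -60, length.out = 100)[-1], rep(-60, 300))
  w <- ap_waveform_features(v, which.max(v), list(index = 500, voltage = -60),
                            dt)
  expect_equal(w$upstroke_downstroke_ratio, 1, tolerance = 1e-6)
  expect_equal(w$amplitude, 60)
})

test_that("rheobase, delay, and missing-value behaviour", {
  p <- cell_params(rheobase = 100, tau_m = 30)
  prot <- step_protocol(step_pa = seq(-100, 120, 10))
  rec <- generate_step_recording(p, prot)
  rb <- rheobase_and_delay(rec)
  expect_equal(rb$rheobase, 100)
  # first spike when the charging curve reaches 90% of steady state
  expect_equal(rb$ap_delay, -30 * log(0.1), tolerance = 0.5)

  sub <- generate_step_recording(p, step_protocol(step_pa = seq(-100, 90, 10)))
  rb2 <- rheobase_and_delay(sub)
  expect_true(is.na(rb2$rheobase) && is.na(rb2$ap_delay))
})

test_that("membrane time constant fit recovers tau and averages sweeps", {
  p <- cell_params(tau_m = 30, rheobase = 100)
  prot <- step_protocol(step_pa = c(-60, -50, 90))
  rec <- generate_step_recording(p, prot)
  expect_equal(fit_membrane_time_constant(rec), 30, tolerance = 0.3)

  # two sweeps with different tau average to the mean
  r20 <- generate_step_recording(cell_params(tau_m = 20, rheobase = 100),
                                 step_protocol(step_pa = -50))
  r40 <- generate_step_recording(cell_params(tau_m = 40, rheobase = 100),
                                 step_protocol(step_pa = -50))
  r40$sweep_id <- 2L
  both <- rbind(r20, r40)
  attr(both, "protocol") <- step_protocol(step_pa = c(-50, -50))
  expect_equal(fit_membrane_time_constant(both), 30, tolerance = 0.3)

  # noisy traces: within 10% across seeds
  taus <- vapply(1:20, function(s) {
    fit_membrane_time_constant(generate_step_recording(
      p, step_protocol(step_pa = c(-60, -50)), noise_sd_mv = 0.2, seed = s))
  }, numeric(1))
  expect_lt(max(abs(taus - 30) / 30), 0.1)
})

test_that("input resistance and RMP come from the I-V line", {
  p <- cell_params(rmp = -43, r_input = 250, rheobase = 100)
  rec <- generate_step_recording(p)
  iv <- input_resistance_rmp(rec)
  expect_equal(iv$r_input, 250, tolerance = 0.01)
  expect_equal(iv$rmp, -43, tolerance = 0.001)

  # exact linear relation V = -43 + 0.25 * I recovered from synthetic means
  few <- generate_step_recording(p, step_protocol(step_pa = c(-60, -50, 50)))
  expect_warning(iv2 <- input_resistance_rmp(few), "five")
  expect_equal(iv2$r_input, 250, tolerance = 0.01)

  one <- generate_step_recording(p, step_protocol(step_pa = c(-50, 50)))
  one$sweep_id[one$sweep_id == 1] <- 1L
  expect_warning(iv3 <- input_resistance_rmp(
    generate_step_recording(p, step_protocol(step_pa = c(-50, 60)))), "two")
  expect_true(is.na(iv3$r_input))
})

test_that("firing features follow their definitions", {
  # 30 spikes in 600 ms is 50 Hz; ISIs [10, 12, 20] give adaptive index 2
  p <- cell_params(rheobase = 40, adaptation = 2)
  rec <- generate_step_recording(p, step_protocol(step_pa = seq(-50, 120, 10)))
  ff <- firing_features(rec)
  sp_max <- 1 + floor((120 - 40) / 10)
  expect_equal(ff$adaptive_index, 2, tolerance = 0.01)
  expect_gt(ff$cv_isi, 0)
  expect_equal(ff$amp_ratio_first_to_rest, 1, tolerance = 0.01)
  expect_equal(ff$hw_ratio_first_to_rest, 1, tolerance = 0.01)
  expect_equal(ff$max_rate * 0.6, nrow(detect_action_potentials(
    rec$voltage_mv[rec$sweep_id == max(rec$sweep_id)], dt,
    window_ms = c(100, 700))))

  p1 <- cell_params(rheobase = 40, adaptation = 1)
  ff1 <- firing_features(generate_step_recording(
    p1, step_protocol(step_pa = seq(-50, 120, 10))))
  # spike times snap to the sampling grid, so ISIs are constant to one sample
  expect_lt(ff1$cv_isi, 1e-3)
  expect_equal(ff1$adaptive_index, 1, tolerance = 1e-2)
})

test_that("feature extraction round-trips generator parameters within 2%", {
  pp <- sample_cell_params(12, sample(c("FF", "MP"), 12, replace = TRUE),
                           seed = 99)
  for (i in seq_len(nrow(pp))) {
    fv <- extract_feature_vector(generate_step_recording(pp[i, ]))
    expect_equal(fv$rmp, pp$rmp[i], tolerance = 0.02 * abs(pp$rmp[i]))
    expect_equal(fv$r_input, pp$r_input[i], tolerance = 0.02 * pp$r_input[i])
    expect_equal(fv$tau_m, pp$tau_m[i], tolerance = 0.02 * pp$tau_m[i])
    expect_equal(fv$rheobase, pp$rheobase[i],
                 tolerance = 0.02 * pp$rheobase[i])
    expect_equal(fv$ap_amplitude, pp$ap_amplitude[i],
                 tolerance = 0.02 * pp$ap_amplitude[i])
    expect_equal(fv$ap_half_width, pp$ap_half_width[i],
                 tolerance = 0.02 * pp$ap_half_width[i])
    expect_equal(fv$ahp, pp$ahp_depth[i], tolerance = 0.02 * pp$ahp_depth[i])
    expect_equal(fv$adaptive_index, pp$adaptation[i],
                 tolerance = 0.02 * pp$adaptation[i])
  }
})

test_that("threshold-referenced features are offset invariant, RMP shifts", {
  p <- cell_params(rheobase = 80)
  rec <- generate_step_recording(p)
  shifted <- rec
  shifted$voltage_mv <- shifted$voltage_mv + 7
  attr(shifted, "protocol") <- attr(rec, "protocol")
  a <- extract_feature_vector(rec)
  b <- extract_feature_vector(shifted)
  expect_equal(b$rmp, a$rmp + 7, tolerance = 1e-6)
  for (col in c("ap_amplitude", "ap_half_width", "ahp",
                "amp_ratio_first_to_rest", "hw_ratio_first_to_rest")) {
    expect_equal(b[[col]], a[[col]], tolerance = 1e-6)
  }
})

test_that("a recording with no spikes yields passive features only", {
  p <- cell_params(rheobase = 500)
  rec <- generate_step_recording(p, step_protocol(step_pa = seq(-100, 100, 10)))
  fv <- extract_feature_vector(rec)
  expect_true(is.na(fv$rheobase) && is.na(fv$ap_amplitude))
  expect_false(is.na(fv$rmp) || is.na(fv$r_input) || is.na(fv$tau_m))
  fv2 <- extract_feature_vector(rec)
  expect_equal(fv, fv2)
})

test_that("embedding is deterministic and separates distinct classes", {
  set.seed(3)
  x <- tibble::tibble(
    f1 = c(rnorm(10, 0), rnorm(10, 8)),
    f2 = c(rnorm(10, 0), rnorm(10, 8)),
    f3 = rnorm(20)
  )
  e1 <- embed_features(x)
  e2 <- embed_features(x, seed = 99)
  expect_equal(e1, e2)
  cls <- rep(1:2, each = 10)
  cent <- sapply(1:2, function(k) colMeans(e1[cls == k, ]))
  between <- sqrt(sum((cent[, 1] - cent[, 2])^2))
  within <- mean(sqrt((e1$dim1 - cent[1, cls])^2 +
                      (e1$dim2 - cent[2, cls])^2))
  expect_gt(between, within)

  ident <- tibble::tibble(f1 = rep(1, 5), f2 = rep(2, 5))
  expect_silent(e3 <- embed_features(ident))
  expect_true(all(e3 == 0))
  x$f1[1] <- NA
  expect_error(embed_features(x), "impute|mask|Missing")
})
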