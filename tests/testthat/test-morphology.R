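test_that("ellipse fitting recovers axes, circles, and rotations", {
  th <- seq(0, 2 * pi, length.out = 21)[-21]
  f <- fit_soma_ellipse(cbind(10 * cos(th), 4 * sin(th)))
  expect_equal(f$major, 10, tolerance = 1e-6)
  expect_equal(f$minor, 4, tolerance = 1e-6)
  expect_equal(f$angle_deg, 0, tolerance = 1e-6)

  circ <- fit_soma_ellipse(cbind(5 * cos(th), 5 * sin(th)))
  expect_equal(circ$major / circ$minor, 1, tolerance = 1e-6)
  expect_true(is.finite(circ$angle_deg))

  phi <- 30 * pi / 180
  x <- 10 * cos(th); y <- 4 * sin(th)
  rot <- fit_soma_ellipse(cbind(x * cos(phi) - y * sin(phi),
                                x * sin(phi) + y * cos(phi)))
  expect_equal(rot$angle_deg, 30, tolerance = 1)
  expect_equal(rot$major, 10, tolerance = 1e-6)

  expect_error(fit_soma_ellipse(cbind(1:8, 2 * (1:8))), "ollinear|egenerate")
  expect_error(fit_soma_ellipse(cbind(1:4, c(1, 2, 1, 2))), "5")
})

make_swc <- function(stem_angles, a = 12, b = 6, reach = 100) {
  th <- seq(0, 2 * pi, length.out = 13)[-13]
  soma <- data.frame(id = 1:13, type = 1,
                     x = c(0, a * cos(th)), y = c(0, b * sin(th)), z = 0,
                     radius = 1, parent = c(-1L, rep(1L, 12)))
  dend <- purrr::map_dfr(seq_along(stem_angles), function(k) {
    ang <- stem_angles[k] * pi / 180
    base_id <- 13 + (k - 1) * 2
    data.frame(
      id = base_id + 1:2, type = 3,
      x = c(a * cos(ang), reach * cos(ang)),
      y = c(b * sin(ang), reach * sin(ang)), z = 0, radius = 0.5,
      parent = c(1L, base_id + 1L)
    )
  })
  tibble::as_tibble(rbind(soma, dend))
}

test_that("bipolarity indices follow the angular-window geometry", {
  two <- bipolarity_indices(make_swc(c(0, 180)))
  expect_equal(two$soma_bipolarity, 2, tolerance = 1e-6)
  expect_equal(two$dendritic_bipolarity, 1)

  four <- bipolarity_indices(make_swc(c(0, 90, 180, 270)))
  expect_equal(four$dendritic_bipolarity, 0.5)

  none <- make_swc(0)
  none <- none[none$type == 1, ]
  expect_true(is.na(bipolarity_indices(none)$dendritic_bipolarity))
})

test_that("synthetic FF and MP populations separate in the bipolarity plane", {
  ff <- purrr::map_dfr(1:15, ~ bipolarity_indices(generate_morphology("FF", seed = .x)))
  mp <- purrr::map_dfr(1:15, ~ bipolarity_indices(generate_morphology("MP", seed = 100 + .x)))
  expect_gt(min(ff$soma_bipolarity), max(mp$soma_bipolarity))
  expect_gt(min(ff$dendritic_bipolarity), max(mp$dendritic_bipolarity))
})

test_that("polar length profile conserves length and aligns rotations", {
  sw <- make_swc(0)  # single straight dendrite along the major (+x) axis
  pr <- polar_length_profile(sw, n_bins = 36)
  expect_equal(sum(pr$length_um), 100 - 12, tolerance = 1e-6)
  # all length in the bin(s) straddling 0 degrees (fit jitter ~1e-14 rad)
  expect_equal(sum(pr$length_um[abs(pr$bin_center_deg) <= 5]),
               sum(pr$length_um))

  sw2 <- generate_morphology("FF", seed = 8)
  pr2 <- polar_length_profile(sw2)
  seg <- sw2[sw2$type == 3 & sw2$parent != 1 & sw2$parent != -1, ]
  par <- sw2[match(seg$parent, sw2$id), ]
  total <- sum(sqrt((seg$x - par$x)^2 + (seg$y - par$y)^2))
  expect_equal(sum(pr2$length_um), total, tolerance = 1e-6)

  # rotating the whole reconstruction leaves the aligned profile unchanged
  phi <- 40 * pi / 180
  rot <- sw2
  rot$x <- sw2$x * cos(phi) - sw2$y * sin(phi)
  rot$y <- sw2$x * sin(phi) + sw2$y * cos(phi)
  pr3 <- polar_length_profile(rot)
  flipped <- rev(pr3$length_um)  # alignment fixes axis up to a 180 flip
  shift_ok <- isTRUE(all.equal(pr2$length_um, pr3$length_um,
                               tolerance = 1e-6)) ||
    isTRUE(all.equal(pr2$length_um,
                     c(pr3$length_um[19:36], pr3$length_um[1:18]),
                     tolerance = 1e-6))
  expect_true(shift_ok)
})

test_that("Sholl profiles match simple geometry and the brute-force oracle", {
  sw <- make_swc(0)  # unbranched 100 um radial dendrite
  sh <- sholl(sw, radius_step_um = 20)
  hits <- sh$n_intersections[sh$radius_um <= 100]
  expect_true(all(hits[sh$radius_um[sh$radius_um <= 100] >= 20] == 1))
  expect_equal(sum(sh$n_intersections), sum(sh$radius_um <= 100 &
                                            sh$radius_um >= 20))

  # Y-branch at 50 um with arms to 100 um: 1 crossing then 2
  y <- tibble::tibble(
    id = 1:16, type = c(rep(1, 13), 3, 3, 3),
    x = c(0, 2 * cos(seq(0, 2 * pi, length.out = 13)[-13]), 50, 100, 100),
    y = c(0, 2 * sin(seq(0, 2 * pi, length.out = 13)[-13]), 0, 30, -30),
    z = 0, radius = 0.5,
    parent = c(-1L, rep(1L, 12), 1L, 14L, 14L)
  )
  shy <- sholl(y, radius_step_um = 20)
  expect_equal(shy$n_intersections[shy$radius_um == 40], 1)
  expect_equal(shy$n_intersections[shy$radius_um == 80], 2)

  expect_equal(nrow(sholl(sw, structure = "axon")), 0)

  set.seed(21)
  for (rep in 1:40) {
    sw <- generate_morphology(sample(c("FF", "MP"), 1),
                              seed = 3000 + rep)
    got <- sholl(sw, radius_step_um = 20)
    oracle <- sholl_oracle(sw, got$radius_um)
    expect_equal(got$n_intersections, oracle)
  }
})

test_that("geometric features are invariant to rigid motion and soma scale", {
  sw <- generate_morphology("FF", seed = 5)
  bi <- bipolarity_indices(sw)
  phi <- 77 * pi / 180
  mv <- sw
  mv$x <- sw$x * cos(phi) - sw$y * sin(phi) + 40
  mv$y <- sw$x * sin(phi) + sw$y * cos(phi) - 15
  bi2 <- bipolarity_indices(mv)
  expect_equal(bi2$soma_bipolarity, bi$soma_bipolarity, tolerance = 1e-6)
  expect_equal(bi2$dendritic_bipolarity, bi$dendritic_bipolarity)
  sc <- sw
  sc$x <- sw$x * 2.5
  sc$y <- sw$y * 2.5
  expect_equal(bipolarity_indices(sc)$soma_bipolarity, bi$soma_bipolarity,
               tolerance = 1e-6)
  shol1 <- sholl(sw)$n_intersections
  shol2 <- sholl(mv)$n_intersections
  expect_equal(shol1, shol2)
})

test_that("SWC io round-trips and validation catches defects", {
  sw <- generate_morphology("MP", seed = 9)
  path <- tempfile(fileext = ".swc")
  write_swc(sw, path)
  back <- read_swc(path)
  expect_equal(back$x, sw$x, tolerance = 1e-4)
  expect_equal(back$parent, sw$parent)

  bad <- sw
  bad$parent[2] <- 999L
  expect_error(validate_swc(bad), "parent")
  two_roots <- sw
  two_roots$parent[2] <- -1L
  expect_error(validate_swc(two_roots), "root")
})

test_that("cell-type classifier is perfect on separable data, chance on noise", {
  set.seed(2)
  feats <- tibble::tibble(
    soma_bipolarity = c(runif(31, 2.2, 3.5), runif(39, 1, 1.4)),
    dendritic_bipolarity = c(runif(31, 0.8, 1), runif(39, 0.2, 0.6)),
    cell_type = rep(c("FF", "MP"), c(31, 39))
  )
  res <- classify_cell_type(feats, seed = 7)
  expect_equal(res$loo_accuracy, 1)
  soma_only <- classify_cell_type(feats, feature_cols = "soma_bipolarity",
                                  seed = 7)
  expect_gte(soma_only$loo_accuracy, res$loo_accuracy - 0.05)

  # permuted labels: accuracy near the majority-class fraction
  perm <- feats
  set.seed(8)
  perm$cell_type <- sample(perm$cell_type)
  acc <- classify_cell_type(perm, seed = 7)$loo_accuracy
  expect_lt(acc, 0.75)

  single <- feats
  single$cell_type <- "FF"
  expect_error(classify_cell_type(single), "single class")
  res2 <- classify_cell_type(feats, seed = 7)
  expect_identical(res$predictions, res2$predictions)
})
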