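test_that("double and triple counters match canonical small graphs", {
  path3 <- tibble::tibble(cell_i = c(1, 2), cell_j = c(2, 3))
  expect_equal(count_double_motifs(path3),
               tibble::tibble(chain = 1, nonchain = 0))
  disj <- tibble::tibble(cell_i = c(1, 3), cell_j = c(2, 4))
  expect_equal(count_double_motifs(disj),
               tibble::tibble(chain = 0, nonchain = 1))
  path4 <- tibble::tibble(cell_i = 1:3, cell_j = 2:4)
  expect_equal(count_triple_motifs(path4),
               tibble::tibble(chain = 1, hub = 0, circular = 0, nonchain = 0))
  tri <- tibble::tibble(cell_i = c(1, 2, 1), cell_j = c(2, 3, 3))
  expect_equal(count_triple_motifs(tri)$circular, 1)
  star <- tibble::tibble(cell_i = c(1, 1, 1), cell_j = 2:4)
  expect_equal(count_triple_motifs(star)$hub, 1)
  idx <- utils::combn(4, 2)
  k4 <- tibble::tibble(cell_i = idx[1, ], cell_j = idx[2, ])
  expect_equal(count_double_motifs(k4),
               tibble::tibble(chain = 12, nonchain = 3))
  expect_equal(count_triple_motifs(k4),
               tibble::tibble(chain = 12, hub = 4, circular = 4,
                              nonchain = 0))
})

test_that("motif counters agree with the brute-force oracle on random graphs", {
  set.seed(17)
  for (rep in 1:200) {
    n <- sample(3:8, 1)
    g <- random_edge_graph(n, runif(1, 0.05, 0.9))
    oracle <- brute_force_motifs(g)
    d <- count_double_motifs(g)
    t3 <- count_triple_motifs(g)
    expect_equal(c(d$chain, d$nonchain),
                 unname(oracle[c("chain2", "nonchain2")]))
    expect_equal(c(t3$chain, t3$hub, t3$circular, t3$nonchain),
                 unname(oracle[c("chain3", "hub3", "circular3", "nonchain3")]))
    m <- nrow(g)
    expect_equal(d$chain + d$nonchain, choose(m, 2))
    expect_equal(t3$chain + t3$hub + t3$circular + t3$nonchain, choose(m, 3))
  }
})

test_that("pairwise probabilities implement the three independent models", {
  pairs <- tibble::tibble(type_i = c("FF", "MP", "FF"),
                          type_j = c("FF", "MP", "MP"),
                          distance_um = c(30, 95, 50))
  m1 <- motif_model("M1")
  expect_equal(pairwise_probability(pairs, m1), rep(0.0438, 3))
  m2 <- motif_model("M2")
  expect_equal(pairwise_probability(pairs, m2), c(0.087, 0.053, 0.008))
  m3 <- motif_model("M3")
  expect_equal(pairwise_probability(pairs, m3), c(0.314, 0, 0.007))
  expect_error(pairwise_probability(
    tibble::tibble(type_i = "XX", type_j = "FF", distance_um = 1), m2),
    "type")
  expect_error(pairwise_probability(pairs, motif_model("M4")), "sequential")
  expect_error(motif_model("M1", p_uniform = 1.2), "probability")
})

test_that("closed-form expectations match hand counts on four nodes", {
  cells <- make_cells(4)
  pairs <- all_pairs_of(cells)
  p <- 0.1
  ex <- expected_motif_counts(pairs, motif_model("M1", p_uniform = p))
  expect_equal(ex$expected[ex$motif == "chain2"], 12 * p^2)
  expect_equal(ex$expected[ex$motif == "nonchain2"], 3 * p^2)
  expect_equal(ex$expected[ex$motif == "chain3"], 12 * p^3)
  expect_equal(ex$expected[ex$motif == "hub3"], 4 * p^3)
  expect_equal(ex$expected[ex$motif == "circular3"], 4 * p^3)
  expect_equal(ex$expected[ex$motif == "nonchain3"], 0)

  ex0 <- expected_motif_counts(pairs, motif_model("M1", p_uniform = 0))
  expect_true(all(ex0$expected == 0))

  far <- pairs
  far$distance_um <- 100
  ex3 <- expected_motif_counts(far, motif_model("M3"))
  expect_true(all(ex3$expected == 0))
})

test_that("simulation reproduces forced graphs and matches expectations", {
  cells <- make_cells(4)
  pairs <- all_pairs_of(cells)
  one <- simulate_cohort(pairs, motif_model("M1", p_uniform = 1),
                         n_runs = 5, seed = 1)
  expect_true(all(one$chain2 == 12 & one$nonchain2 == 3))
  zero <- simulate_cohort(pairs, motif_model("M1", p_uniform = 0),
                          n_runs = 5, seed = 1)
  expect_true(all(zero$chain2 == 0 & zero$nonchain3 == 0))

  coh <- generate_recording_sets(cohort_spec(n_sets = 25),
                                 motif_model("M2"), seed = 31)
  for (model in list(motif_model("M1"), motif_model("M2"),
                     motif_model("M3"))) {
    runs <- simulate_cohort(coh, model, n_runs = 1000, seed = 8)
    ex <- expected_motif_counts(coh, model)
    for (cat in ex$motif) {
      x <- runs[[cat]]
      se <- sd(x) / sqrt(length(x))
      expect_lt(abs(mean(x) - ex$expected[ex$motif == cat]),
                3 * se + 1e-9)
    }
  }
  again <- simulate_cohort(coh, motif_model("M1"), n_runs = 50, seed = 8)
  expect_identical(again,
                   simulate_cohort(coh, motif_model("M1"), n_runs = 50,
                                   seed = 8))
})

test_that("cluster index handles worked examples and degenerate counts", {
  expect_equal(cluster_index(16, 5), 3.2)
  expect_equal(cluster_index(2, 1), 2)
  expect_warning(ci <- cluster_index(3, 0), "infinite")
  expect_identical(ci, Inf)
  expect_warning(ci0 <- cluster_index(0, 0), "undefined")
  expect_true(is.na(ci0))
})

test_that("prediction summary computes intervals, p-values, and ratios", {
  obs <- tibble::tibble(chain2 = 5, nonchain2 = 5, chain3 = 1, hub3 = 0,
                        circular3 = 0, nonchain3 = 1)
  runs <- tibble::tibble(run = 1:200,
                         chain2 = rep(5, 200), nonchain2 = rep(5, 200),
                         chain3 = rep(1, 200), hub3 = 0, circular3 = 0,
                         nonchain3 = rep(1, 200))
  pred <- summarize_prediction(runs, obs)
  expect_equal(pred$ratios$p_value, c(1, 1))  # every run equals observed
  expect_equal(pred$summary$ci_lo, pred$summary$ci_hi)
  expect_true(all(pred$summary$ci_lo <= pred$summary$mc_mean &
                  pred$summary$mc_mean <= pred$summary$ci_hi))

  # observed ratio above every simulated ratio: p reported as 0
  runs2 <- runs
  runs2$chain2 <- rbinom(200, 5, 0.5)
  pred2 <- summarize_prediction(runs2, tibble::tibble(
    chain2 = 50, nonchain2 = 1, chain3 = 0, hub3 = 0, circular3 = 0,
    nonchain3 = 0))
  expect_equal(pred2$ratios$p_value[pred2$ratios$motif_order == "doubles"], 0)

  g <- glance(pred)
  expect_equal(g$cluster_index_observed, 1)
  td <- tidy(pred)
  expect_true(all(c("mc_mean", "ci_lo", "p_value") %in% names(td)))
})

test_that("chain-rule cohorts push the cluster index above M1, rising in alpha", {
  spec <- cohort_spec(n_sets = 250)
  ci_at <- function(alpha, seed) {
    m4 <- motif_model("M4", base_p = 0.0438, alpha = alpha, beta = 0.25)
    coh <- generate_recording_sets(spec, m4, seed = seed)
    obs <- count_motifs(coh$pairs)
    cluster_index(obs$chain2, obs$nonchain2)
  }
  ci1 <- mean(vapply(1:4, function(s) ci_at(1, s), numeric(1)))
  ci4 <- mean(vapply(1:4, function(s) ci_at(4, s), numeric(1)))
  ci8 <- mean(vapply(1:4, function(s) ci_at(8, s), numeric(1)))
  expect_gt(ci4, ci1)
  expect_gt(ci8, ci4)
})
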