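#' Specification of a synthetic multipatch cohort
#'
#' Describes a cohort of simultaneous recording sets (3-8 neurons each) with
#' the statistical structure of multipatch experiments in the locus
#' coeruleus: a bimodal per-set fusiform proportion (most sets are either
#' FF-poor, 0-20%, or FF-rich, 50-100%), soma positions packed so most
#' inter-soma distances fall below 150 um, and sparse electrical coupling.
#'
#' @param n_sets number of recording sets.
#' @param cells_range integer range of cells per set (within 3-8).
#' @param cells_prob sampling weights over `cells_range`; the default is
#'   centered on six cells per set.
#' @param ff_mix two-component Beta mixture for the per-set FF proportion:
#'   list with `weights` (sums to 1), `shape1`, `shape2`. Defaults place the
#'   modes near 0.07 and 0.72.
#' @param position_scale_um radius of the uniform disc from which soma
#'   positions are drawn, um.
#' @param cc_range range of true coupling coefficients assigned to
#'   ground-truth edges.
#' @param noise_sd_mv trace noise SD used by downstream trace generators.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_sets = 100, cells_range = 3:8,
                        cells_prob = c(0.08, 0.12, 0.17, 0.28, 0.20, 0.15),
                        ff_mix = list(weights = c(0.5, 0.5),
                                      shape1 = c(2, 14), shape2 = c(14, 6)),
                        position_scale_um = 100,
                        cc_range = c(0.005, 0.13), noise_sd_mv = 0.1) {
  if (any(cells_range < 3) || any(cells_range > 8)) {
    abort("`cells_range` must lie within [3, 8].")
  }
  if (abs(sum(ff_mix$weights) - 1) > 1e-8) {
    abort("`ff_mix$weights` must sum to 1.")
  }
  structure(
    list(n_sets = n_sets, cells_range = cells_range,
         cells_prob = cells_prob / sum(cells_prob), ff_mix = ff_mix,
         position_scale_um = position_scale_um, cc_range = cc_range,
         noise_sd_mv = noise_sd_mv),
    class = "cohort_spec"
  )
}

# all unordered pairs for one set of cells, with types and distances
set_pairs <- function(cells) {
  n <- nrow(cells)
  idx <- combn(n, 2)
  tibble::tibble(
    cell_i = cells$cell_id[idx[1, ]],
    cell_j = cells$cell_id[idx[2, ]],
    type_i = cells$cell_type[idx[1, ]],
    type_j = cells$cell_type[idx[2, ]],
    distance_um = sqrt((cells$x_um[idx[1, ]] - cells$x_um[idx[2, ]])^2 +
                       (cells$y_um[idx[1, ]] - cells$y_um[idx[2, ]])^2)
  )
}

# Sequential chain-rule (Model 4) edge sampling for one set. The number of
# edges is binomial at the base rate (so the overall connection rate matches
# the independent-pair models by construction); edges are then placed one at
# a time, each candidate pair weighted by `alpha` when it extends a chain
# end (exactly one endpoint connected, with degree exactly 1) and by `beta`
# when it would create a hub or close a loop (any endpoint already of
# degree >= 2, or both endpoints connected).
sample_edges_chain <- function(pairs, cells, base_p, alpha, beta) {
  n_pairs <- nrow(pairs)
  m <- rbinom(1, n_pairs, base_p)
  deg <- rep(0L, nrow(cells))
  names(deg) <- cells$cell_id
  vi <- match(pairs$cell_i, cells$cell_id)
  vj <- match(pairs$cell_j, cells$cell_id)
  conn <- logical(n_pairs)
  for (e in seq_len(m)) {
    open <- which(!conn)
    w <- vapply(open, function(k) {
      di <- deg[vi[k]]
      dj <- deg[vj[k]]
      if (di == 0 && dj == 0) {
        1
      } else if ((di == 0 && dj == 1) || (di == 1 && dj == 0)) {
        alpha
      } else {
        beta
      }
    }, numeric(1))
    k <- open[sample.int(length(open), 1, prob = w)]
    conn[k] <- TRUE
    deg[vi[k]] <- deg[vi[k]] + 1L
    deg[vj[k]] <- deg[vj[k]] + 1L
  }
  conn
}

#' Generate synthetic recording sets with ground-truth connectivity
#'
#' Draws cohorts of recording sets (cell types, 2D soma positions, tested
#' pairs) and samples ground-truth electrical connections under a pairwise
#' probability model (`M1`-`M3`, independent pairs) or the sequential
#' chain-rule model (`M4`). Ground-truth edges are stored in the `connected`
#' column of the pair table, separate from any later detected edges.
#'
#' @param spec a [cohort_spec()].
#' @param rule a [motif_model()] giving the generative connectivity rule.
#' @param seed integer seed; generation is deterministic given the seed.
#' @return A list of class `recording_cohort` with tibbles `cells`
#'   (`set_id`, `cell_id`, `cell_type`, `x_um`, `y_um`) and `pairs`
#'   (`set_id`, `cell_i`, `cell_j`, `type_i`, `type_j`, `distance_um`,
#'   `tested`, `connected`, `cc_true`).
#' @export
generate_recording_sets <- function(spec, rule, seed = 1) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(rule, "motif_model"))
  if (spec$n_sets == 0) {
    return(structure(list(
      cells = tibble::tibble(set_id = integer(), cell_id = integer(),
                             cell_type = character(), x_um = double(),
                             y_um = double()),
      pairs = tibble::tibble(set_id = integer(), cell_i = integer(),
                             cell_j = integer(), type_i = character(),
                             type_j = character(), distance_um = double(),
                             tested = logical(), connected = logical(),
                             cc_true = double())
    ), class = "recording_cohort", spec = spec, rule = rule, seed = seed))
  }
  with_seed(seed, {
    sets <- purrr::map(seq_len(spec$n_sets), function(s) {
      n <- spec$cells_range[sample.int(length(spec$cells_range), 1,
                                       prob = spec$cells_prob)]
      comp <- sample.int(length(spec$ff_mix$weights), 1,
                         prob = spec$ff_mix$weights)
      p_ff <- rbeta(1, spec$ff_mix$shape1[comp], spec$ff_mix$shape2[comp])
      types <- ifelse(runif(n) < p_ff, "FF", "MP")
      r <- spec$position_scale_um * sqrt(runif(n))
      th <- runif(n, 0, 2 * pi)
      cells <- tibble::tibble(
        set_id = s, cell_id = seq_len(n), cell_type = types,
        x_um = r * cos(th), y_um = r * sin(th)
      )
      pairs <- set_pairs(cells)
      if (rule$model == "M4") {
        conn <- sample_edges_chain(pairs, cells, rule$base_p,
                                   rule$alpha, rule$beta)
      } else {
        pr <- pairwise_probability(pairs, rule)
        conn <- runif(nrow(pairs)) < pr
      }
      pairs$set_id <- s
      pairs$tested <- TRUE
      pairs$connected <- conn
      pairs$cc_true <- ifelse(conn,
                              runif(nrow(pairs), spec$cc_range[1],
                                    spec$cc_range[2]), 0)
      list(cells = cells, pairs = pairs)
    })
    structure(list(
      cells = dplyr::bind_rows(purrr::map(sets, "cells")),
      pairs = dplyr::relocate(dplyr::bind_rows(purrr::map(sets, "pairs")),
                              "set_id")
    ), class = "recording_cohort", spec = spec, rule = rule, seed = seed)
  })
}

#' Calibrate the chain-rule model's base probability
#'
#' Finds, by bisection on simulated cohorts, the base pairwise probability
#' for the chain-rule generative model (`M4`) such that the expected overall
#' connection rate (edges / tested pairs) matches `target_rate`. The alpha
#' and beta multipliers reshape the motif structure; this rescaling keeps
#' the overall rate comparable with the independent-pair models.
#'
#' @param spec a [cohort_spec()] describing the cohort structure.
#' @param alpha,beta chain-rule multipliers (see
#'   [generate_recording_sets()]).
#' @param target_rate desired overall connection rate.
#' @param n_sim cohorts simulated per bisection step.
#' @param seed integer seed.
#' @return The calibrated base probability.
#' @export
calibrate_chain_model <- function(spec, alpha = 4, beta = 0.25,
                                  target_rate = 0.0438, n_sim = 20,
                                  seed = 1) {
  check_probability(target_rate, "target_rate")
  mean_rate <- function(base_p, k) {
    rule <- motif_model("M4", alpha = alpha, beta = beta, base_p = base_p)
    rates <- purrr::map_dbl(seq_len(n_sim), function(i) {
      coh <- generate_recording_sets(spec, rule,
                                     seed = stage_seed(seed, k * 1000 + i))
      mean(coh$pairs$connected)
    })
    mean(rates)
  }
  lo <- 0
  hi <- min(1, max(4 * target_rate, target_rate / beta))
  for (k in seq_len(12)) {
    mid <- (lo + hi) / 2
    if (mean_rate(mid, k) < target_rate) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
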