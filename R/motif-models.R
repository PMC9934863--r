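#' Pairwise connectivity models
#'
#' Constructs one of the four connectivity models used for motif-level
#' inference:
#'
#' * `M1` (random): every tested pair connects independently with one
#'   uniform probability (default 0.0438, the overall rate across
#'   recordings).
#' * `M2` (cell-type-specific): probabilities depend on the pair's
#'   morphological types (FF-FF, MP-MP, FF-MP).
#' * `M3` (cell type + distance): pairs farther apart than
#'   `distance_cutoff_um` never connect; same-type pairs use the short-range
#'   (16-40 um) rates and FF-MP pairs use a near-range rate.
#' * `M4` (chain rule, generative): edges are drawn sequentially; a
#'   candidate pair's base probability is scaled by `alpha` when it extends
#'   a chain end and by `beta` when it would create a hub or close a loop.
#'
#' @param model one of `"M1"`, `"M2"`, `"M3"`, `"M4"`.
#' @param p_uniform uniform pairwise probability (M1).
#' @param p_by_type named probabilities `ff_ff`, `mp_mp`, `ff_mp` (M2).
#' @param p_short_by_type short-range same-type probabilities (M3).
#' @param p_ff_mp_near FF-MP probability within the cutoff (M3); not a
#'   published value, override when fitting real data.
#' @param distance_cutoff_um distance beyond which M3 sets probability 0.
#' @param alpha,beta chain-rule multipliers (M4); `alpha > 1` promotes
#'   chains, `beta < 1` suppresses hubs and loops.
#' @param base_p base probability for M4 (see [calibrate_chain_model()]).
#' @return A list of class `motif_model`.
#' @export
motif_model <- function(model = c("M1", "M2", "M3", "M4"),
                        p_uniform = 0.0438,
                        p_by_type = c(ff_ff = 0.087, mp_mp = 0.053,
                                      ff_mp = 0.008),
                        p_short_by_type = c(ff_ff = 0.314, mp_mp = 0.107),
                        p_ff_mp_near = 0.007,
                        distance_cutoff_um = 80,
                        alpha = 4, beta = 0.25, base_p = NULL) {
  model <- match.arg(model)
  check_probability(p_uniform)
  check_probability(p_by_type)
  check_probability(p_short_by_type)
  check_probability(p_ff_mp_near)
  check_positive(distance_cutoff_um)
  check_positive(alpha)
  check_positive(beta)
  if (model == "M4" && is.null(base_p)) base_p <- p_uniform
  if (!is.null(base_p)) check_probability(base_p)
  structure(
    list(model = model, p_uniform = p_uniform, p_by_type = p_by_type,
         p_short_by_type = p_short_by_type, p_ff_mp_near = p_ff_mp_near,
         distance_cutoff_um = distance_cutoff_um,
         alpha = alpha, beta = beta, base_p = base_p),
    class = "motif_model"
  )
}

pair_type_key <- function(type_i, type_j) {
  ok <- type_i %in% c("FF", "MP") & type_j %in% c("FF", "MP")
  if (any(!ok)) abort("Unknown cell type; expected \"FF\" or \"MP\".")
  dplyr::case_when(
    type_i == "FF" & type_j == "FF" ~ "ff_ff",
    type_i == "MP" & type_j == "MP" ~ "mp_mp",
    TRUE ~ "ff_mp"
  )
}

#' Pairwise connection probability under a model
#'
#' @param pairs a tibble with columns `type_i`, `type_j` (M2/M3) and
#'   `distance_um` (M3).
#' @param model a [motif_model()] (`M1`-`M3`; `M4` has no independent
#'   pairwise probability).
#' @return A numeric vector of probabilities, one per row of `pairs`.
#' @export
pairwise_probability <- function(pairs, model) {
  stopifnot(inherits(model, "motif_model"))
  n <- nrow(pairs)
  switch(model$model,
    M1 = rep(model$p_uniform, n),
    M2 = {
      if (is.null(pairs$type_i) || any(is.na(pairs$type_i)) ||
          any(is.na(pairs$type_j))) {
        abort("Model M2 requires cell types for every pair.")
      }
      unname(model$p_by_type[pair_type_key(pairs$type_i, pairs$type_j)])
    },
    M3 = {
      if (is.null(pairs$distance_um) || any(is.na(pairs$distance_um))) {
        abort("Model M3 requires inter-soma distances for every pair.")
      }
      key <- pair_type_key(pairs$type_i, pairs$type_j)
      p <- ifelse(key == "ff_mp", model$p_ff_mp_near,
                  unname(model$p_short_by_type[key]))
      ifelse(pairs$distance_um > model$distance_cutoff_um, 0, p)
    },
    M4 = abort("M4 is sequential; it has no independent pairwise probability.")
  )
}

# ---- motif counting -------------------------------------------------------

# Degree-based counts for one simple graph given integer endpoint vectors.
# Doubles (pairs of edges): chain = pairs sharing a node, nonchain = the
# rest of C(m,2). Triples (sets of three edges): chain = 3-edge path, hub =
# 3-edge star, circular = triangle, nonchain = any disconnected union.
motif_counts_core <- function(ei, ej) {
  m <- length(ei)
  if (m == 0) {
    return(c(chain2 = 0, nonchain2 = 0, chain3 = 0, hub3 = 0,
             circular3 = 0, nonchain3 = 0))
  }
  nodes <- sort(unique(c(ei, ej)))
  vi <- match(ei, nodes)
  vj <- match(ej, nodes)
  deg <- tabulate(c(vi, vj), nbins = length(nodes))
  chain2 <- sum(choose(deg, 2))
  nonchain2 <- choose(m, 2) - chain2
  hub3 <- sum(choose(deg, 3))
  nbr <- lapply(seq_along(nodes), function(v) {
    c(vj[vi == v], vi[vj == v])
  })
  tri_per_edge <- vapply(seq_len(m), function(k) {
    length(intersect(nbr[[vi[k]]], nbr[[vj[k]]]))
  }, numeric(1))
  circular3 <- sum(tri_per_edge) / 3
  chain3 <- sum((deg[vi] - 1) * (deg[vj] - 1)) - 3 * circular3
  nonchain3 <- choose(m, 3) - chain3 - hub3 - circular3
  c(chain2 = chain2, nonchain2 = nonchain2, chain3 = chain3, hub3 = hub3,
    circular3 = circular3, nonchain3 = nonchain3)
}

edges_from <- function(graph) {
  if (is.data.frame(graph)) {
    g <- graph
    if ("connected" %in% names(g)) g <- g[g$connected, , drop = FALSE]
    list(ei = g$cell_i, ej = g$cell_j)
  } else {
    abort("`graph` must be a data frame of edges (`cell_i`, `cell_j`).")
  }
}

#' Count two-connection motifs in one connectivity graph
#'
#' Over all unordered pairs of distinct electrical connections: chain-like
#' if the two edges share a cell (A-B-C), non-chain-like if they are
#' vertex-disjoint (A-B, C-D). The two categories partition all C(m, 2)
#' edge pairs.
#'
#' @param graph a data frame of edges with columns `cell_i`, `cell_j`; if a
#'   `connected` column is present only `TRUE` rows are used.
#' @return A one-row tibble with `chain` and `nonchain` counts.
#' @export
count_double_motifs <- function(graph) {
  e <- edges_from(graph)
  cnt <- motif_counts_core(e$ei, e$ej)
  tibble::tibble(chain = cnt[["chain2"]], nonchain = cnt[["nonchain2"]])
}

#' Count three-connection motifs in one connectivity graph
#'
#' Over all unordered triples of distinct edges, the union is classified as
#' chain (3-edge path A-B-C-D), hub (3-edge star), circular (triangle), or
#' non-chain (any disconnected union). The four categories partition all
#' C(m, 3) edge triples.
#'
#' @inheritParams count_double_motifs
#' @return A one-row tibble with `chain`, `hub`, `circular`, `nonchain`.
#' @export
count_triple_motifs <- function(graph) {
  e <- edges_from(graph)
  cnt <- motif_counts_core(e$ei, e$ej)
  tibble::tibble(chain = cnt[["chain3"]], hub = cnt[["hub3"]],
                 circular = cnt[["circular3"]], nonchain = cnt[["nonchain3"]])
}

#' Motif counts across the recording sets of a cohort
#'
#' @param pairs a pair table with columns `set_id`, `cell_i`, `cell_j`, and
#'   a logical edge indicator column (`connected` by default).
#' @param edge_col name of the logical column marking edges.
#' @param per_set return one row per recording set instead of totals.
#' @return A tibble of motif counts (`chain2`, `nonchain2`, `chain3`,
#'   `hub3`, `circular3`, `nonchain3`).
#' @export
count_motifs <- function(pairs, edge_col = "connected", per_set = FALSE) {
  stopifnot(edge_col %in% names(pairs))
  per <- pairs |>
    dplyr::group_by(.data$set_id) |>
    dplyr::group_modify(function(g, key) {
      g <- g[g[[edge_col]], , drop = FALSE]
      tibble::as_tibble(as.list(motif_counts_core(g$cell_i, g$cell_j)))
    }) |>
    dplyr::ungroup()
  if (per_set) per else dplyr::summarise(per, dplyr::across(-"set_id", sum))
}

#' Cluster index: chain-like over non-chain-like motif counts
#'
#' @param chain,nonchain motif counts.
#' @return `chain / nonchain`; `Inf` (with a warning) when `nonchain` is 0
#'   and `chain` positive, `NA` when both are 0.
#' @export
cluster_index <- function(chain, nonchain) {
  out <- ifelse(nonchain > 0, chain / nonchain,
                ifelse(chain > 0, Inf, NA_real_))
  if (any(nonchain == 0 & chain > 0)) {
    warn("Non-chain count is 0; cluster index flagged infinite.")
  }
  if (any(nonchain == 0 & chain == 0)) {
    warn("Both motif counts are 0; cluster index undefined.")
  }
  out
}

# ---- configuration enumeration (closed-form expectations) -----------------

.config_cache <- new.env(parent = emptyenv())

# Enumerate every 2- and 3-subset of the C(n,2) node pairs of an n-node set
# and classify the shape of its union. Independent of the degree-formula
# counting route above.
motif_configurations <- function(n) {
  key <- as.character(n)
  if (!is.null(.config_cache[[key]])) return(.config_cache[[key]])
  pr <- combn(n, 2)
  np <- ncol(pr)
  classify <- function(cols) {
    nodes <- c(pr[, cols])
    nn <- length(unique(nodes))
    if (length(cols) == 2) {
      if (nn == 3) "chain" else "nonchain"
    } else {
      if (nn == 3) {
        "circular"
      } else if (nn == 4) {
        if (max(tabulate(match(nodes, unique(nodes)))) == 3) "hub" else "chain"
      } else {
        "nonchain"
      }
    }
  }
  d2 <- combn(np, 2)
  d3 <- if (np >= 3) combn(np, 3) else matrix(integer(0), nrow = 3)
  out <- list(
    pairs = pr,
    doubles = list(idx = d2,
                   cat = apply(d2, 2, classify)),
    triples = list(idx = d3,
                   cat = if (ncol(d3)) apply(d3, 2, classify) else character(0))
  )
  .config_cache[[key]] <- out
  out
}

# Map a set's pair rows onto the canonical combn enumeration, returning the
# probability (or any value) vector in canonical order; unlisted pairs get
# `fill`.
canonical_pair_values <- function(g, values, fill = 0) {
  nodes <- sort(unique(c(g$cell_i, g$cell_j)))
  n <- length(nodes)
  pr <- combn(n, 2)
  key_canon <- paste(pr[1, ], pr[2, ])
  i <- match(g$cell_i, nodes)
  j <- match(g$cell_j, nodes)
  key_g <- paste(pmin(i, j), pmax(i, j))
  out <- rep(fill, ncol(pr))
  out[match(key_g, key_canon)] <- values
  list(p = out, n = n, nodes = nodes, pairs = pr)
}

#' Closed-form expected motif counts under a pairwise model
#'
#' For each motif configuration (each unordered set of two or three node
#' pairs whose union has the category's shape) the product of the
#' configuration's pairwise connection probabilities is added; sums run over
#' all configurations of every recording set, and cohort totals sum over
#' sets. Configurations are edge subsets (no non-edge factors), matching
#' the expected-value products used in the original analysis.
#'
#' @param cohort a `recording_cohort` or its `pairs` tibble (columns
#'   `set_id`, `cell_i`, `cell_j`, `type_i`, `type_j`, `distance_um`).
#' @param model a [motif_model()] (`M1`-`M3`).
#' @return A tibble with one row per motif category and column `expected`.
#' @export
expected_motif_counts <- function(cohort, model) {
  pairs <- if (inherits(cohort, "recording_cohort")) cohort$pairs else cohort
  cats <- c("chain2", "nonchain2", "chain3", "hub3", "circular3", "nonchain3")
  tot <- setNames(numeric(6), cats)
  if (nrow(pairs) > 0) {
    pairs$.p <- pairwise_probability(pairs, model)
    for (g in split(pairs, pairs$set_id)) {
      cv <- canonical_pair_values(g, g$.p)
      cfg <- motif_configurations(cv$n)
      p <- cv$p
      d <- cfg$doubles
      prod2 <- p[d$idx[1, ]] * p[d$idx[2, ]]
      tot["chain2"] <- tot["chain2"] + sum(prod2[d$cat == "chain"])
      tot["nonchain2"] <- tot["nonchain2"] + sum(prod2[d$cat == "nonchain"])
      t3 <- cfg$triples
      if (ncol(t3$idx)) {
        prod3 <- p[t3$idx[1, ]] * p[t3$idx[2, ]] * p[t3$idx[3, ]]
        tot["chain3"] <- tot["chain3"] + sum(prod3[t3$cat == "chain"])
        tot["hub3"] <- tot["hub3"] + sum(prod3[t3$cat == "hub"])
        tot["circular3"] <- tot["circular3"] + sum(prod3[t3$cat == "circular"])
        tot["nonchain3"] <- tot["nonchain3"] + sum(prod3[t3$cat == "nonchain"])
      }
    }
  }
  tibble::tibble(motif = cats, expected = unname(tot))
}

# ---- Monte Carlo ----------------------------------------------------------

#' Monte Carlo motif-count simulation under a pairwise model
#'
#' On each run every tested pair is drawn independently with its
#' model-assigned probability, motifs are counted per recording set, and the
#' cohort totals are recorded. Reproducible given the seed.
#'
#' @inheritParams expected_motif_counts
#' @param n_runs number of Monte Carlo runs (1000 in the original analysis).
#' @param seed integer seed.
#' @return A tibble with `n_runs` rows and columns `run`, `chain2`,
#'   `nonchain2`, `chain3`, `hub3`, `circular3`, `nonchain3`.
#' @export
simulate_cohort <- function(cohort, model, n_runs = 1000, seed = 1) {
  pairs <- if (inherits(cohort, "recording_cohort")) cohort$pairs else cohort
  stopifnot(n_runs >= 1)
  cats <- c("chain2", "nonchain2", "chain3", "hub3", "circular3", "nonchain3")
  tot <- matrix(0, nrow = n_runs, ncol = 6, dimnames = list(NULL, cats))
  if (nrow(pairs) > 0) {
    pairs$.p <- pairwise_probability(pairs, model)
    cvs <- lapply(split(pairs, pairs$set_id), function(g) {
      canonical_pair_values(g, g$.p)
    })
    sizes <- vapply(cvs, function(cv) cv$n, numeric(1))
    with_seed(seed, {
      # batch all sets of one size into a single (runs x sets) x pairs draw
      for (n in sort(unique(sizes))) {
        grp <- cvs[sizes == n]
        k <- length(grp)
        np <- choose(n, 2)
        pr <- grp[[1]]$pairs
        pmat <- do.call(rbind, lapply(grp, function(cv) cv$p))
        E <- matrix(runif(n_runs * k * np), n_runs * k, np) <
          pmat[rep(seq_len(k), each = n_runs), , drop = FALSE]
        storage.mode(E) <- "double"
        A <- matrix(0, np, n)
        A[cbind(seq_len(np), pr[1, ])] <- 1
        A[cbind(seq_len(np), pr[2, ])] <- 1
        D <- E %*% A
        m <- rowSums(E)
        chain2 <- rowSums(D * (D - 1)) / 2
        hub3 <- rowSums(D * (D - 1) * (D - 2)) / 6
        # triangles via the canonical triangle configurations
        cfg <- motif_configurations(n)
        tri <- cfg$triples$idx[, cfg$triples$cat == "circular", drop = FALSE]
        circ <- numeric(nrow(E))
        if (ncol(tri)) {
          for (tcol in seq_len(ncol(tri))) {
            circ <- circ + E[, tri[1, tcol]] * E[, tri[2, tcol]] *
              E[, tri[3, tcol]]
          }
        }
        chain3 <- rowSums(E * (D[, pr[1, ], drop = FALSE] - 1) *
                            (D[, pr[2, ], drop = FALSE] - 1)) - 3 * circ
        add <- function(x) rowSums(matrix(x, nrow = n_runs))
        tot[, "chain2"] <- tot[, "chain2"] + add(chain2)
        tot[, "nonchain2"] <- tot[, "nonchain2"] +
          add(m * (m - 1) / 2 - chain2)
        tot[, "chain3"] <- tot[, "chain3"] + add(chain3)
        tot[, "hub3"] <- tot[, "hub3"] + add(hub3)
        tot[, "circular3"] <- tot[, "circular3"] + add(circ)
        tot[, "nonchain3"] <- tot[, "nonchain3"] +
          add(m * (m - 1) * (m - 2) / 6 - chain3 - hub3 - circ)
      }
    })
  }
  dplyr::bind_cols(tibble::tibble(run = seq_len(n_runs)),
                   tibble::as_tibble(tot))
}

ratio_from_counts <- function(chain, nonchain) {
  ifelse(nonchain > 0, chain / nonchain,
         ifelse(chain > 0, Inf, NA_real_))
}

#' Summarize Monte Carlo runs against observed motif counts
#'
#' Computes, per motif category, the Monte Carlo mean, SD, percentile 95%
#' interval (2.5/97.5 percentiles on the integer-valued counts), and an
#' upper-tail p-value (fraction of runs at or above the observed count; set
#' `side = "lower"` or `"two"` for the alternatives). For doubles and
#' triples the chain/non-chain ratio is summarized the same way: the ratio
#' p-value is the fraction of runs whose simulated ratio is at least the
#' observed ratio. Runs where both counts are zero have no defined ratio and
#' are excluded from the ratio p-value (their number is reported);
#' zero-denominator runs with a positive chain count count as infinite
#' ratios. Ratio p-values are reported at raw k/n resolution.
#'
#' @param runs output of [simulate_cohort()].
#' @param observed one-row tibble or named vector of observed counts
#'   (`chain2`, `nonchain2`, `chain3`, `hub3`, `circular3`, `nonchain3`),
#'   e.g. from [count_motifs()].
#' @param expected optional tibble from [expected_motif_counts()].
#' @param side tail for the count p-values.
#' @return An object of class `motif_prediction` with `tidy()` and
#'   `glance()` methods.
#' @export
summarize_prediction <- function(runs, observed, expected = NULL,
                                 side = c("upper", "lower", "two")) {
  side <- match.arg(side)
  if (nrow(runs) < 100) {
    warn("Fewer than 100 Monte Carlo runs; summaries will be coarse.")
  }
  obs <- as.list(observed)
  cats <- c("chain2", "nonchain2", "chain3", "hub3", "circular3", "nonchain3")
  summary <- purrr::map_dfr(cats, function(cat) {
    x <- runs[[cat]]
    o <- obs[[cat]]
    p <- switch(side,
      upper = mean(x >= o),
      lower = mean(x <= o),
      two = min(1, 2 * min(mean(x >= o), mean(x <= o)))
    )
    tibble::tibble(
      motif = cat, observed = o, mc_mean = mean(x), mc_sd = sd(x),
      ci_lo = unname(quantile(x, 0.025, type = 1)),
      ci_hi = unname(quantile(x, 0.975, type = 1)),
      p_value = p
    )
  })
  if (!is.null(expected)) {
    summary <- dplyr::left_join(summary, expected, by = "motif")
  }
  ratios <- purrr::map_dfr(c(doubles = "2", triples = "3"), function(k) {
    sim <- ratio_from_counts(runs[[paste0("chain", k)]],
                             runs[[paste0("nonchain", k)]])
    o <- ratio_from_counts(obs[[paste0("chain", k)]],
                           obs[[paste0("nonchain", k)]])
    valid <- !is.na(sim)
    tibble::tibble(
      motif_order = if (k == "2") "doubles" else "triples",
      observed_ratio = o,
      mc_mean_ratio = mean(sim[valid & is.finite(sim)]),
      p_value = if (is.na(o) || !any(valid)) NA_real_
                else mean(sim[valid] >= o),
      n_valid_runs = sum(valid)
    )
  })
  structure(list(summary = summary, ratios = ratios, n_runs = nrow(runs),
                 side = side),
            class = "motif_prediction")
}

#' @export
print.motif_prediction <- function(x, ...) {
  cat("Motif-model Monte Carlo prediction (", x$n_runs, " runs)\n", sep = "")
  print(x$summary)
  cat("\nChain/non-chain cluster-index comparison:\n")
  print(x$ratios)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a motif prediction into one row per motif category
#' @param x a `motif_prediction`.
#' @param ... unused.
#' @method tidy motif_prediction
#' @export
tidy.motif_prediction <- function(x, ...) x$summary

#' One-row summary of a motif prediction
#'
#' Reports the observed and predicted cluster indices (doubles), the triple
#' ratio, and their Monte Carlo p-values.
#'
#' @param x a `motif_prediction`.
#' @param ... unused.
#' @method glance motif_prediction
#' @export
glance.motif_prediction <- function(x, ...) {
  r <- x$ratios
  tibble::tibble(
    cluster_index_observed = r$observed_ratio[r$motif_order == "doubles"],
    cluster_index_predicted = r$mc_mean_ratio[r$motif_order == "doubles"],
    p_cluster_index = r$p_value[r$motif_order == "doubles"],
    triple_ratio_observed = r$observed_ratio[r$motif_order == "triples"],
    triple_ratio_predicted = r$mc_mean_ratio[r$motif_order == "triples"],
    p_triple_ratio = r$p_value[r$motif_order == "triples"],
    n_runs = x$n_runs
  )
}
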