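# Brute-force motif oracle: enumerate every 2-/3-subset of edges and
# classify the union by connected-component analysis (independent of the
# degree-formula counters and of the configuration enumeration in R/).
components_of <- function(edges) {
  nodes <- unique(c(edges$cell_i, edges$cell_j))
  comp <- seq_along(nodes)
  find <- function(i) {
    while (comp[i] != i) i <- comp[i]
    i
  }
  for (k in seq_len(nrow(edges))) {
    a <- find(match(edges$cell_i[k], nodes))
    b <- find(match(edges$cell_j[k], nodes))
    comp[a] <- b
  }
  length(unique(vapply(seq_along(nodes), find, integer(1))))
}

brute_force_motifs <- function(edges) {
  m <- nrow(edges)
  out <- c(chain2 = 0, nonchain2 = 0, chain3 = 0, hub3 = 0, circular3 = 0,
           nonchain3 = 0)
  if (m >= 2) {
    for (cols in utils::combn(m, 2, simplify = FALSE)) {
      sub <- edges[cols, ]
      if (components_of(sub) == 1) {
        out["chain2"] <- out["chain2"] + 1
      } else {
        out["nonchain2"] <- out["nonchain2"] + 1
      }
    }
  }
  if (m >= 3) {
    for (cols in utils::combn(m, 3, simplify = FALSE)) {
      sub <- edges[cols, ]
      if (components_of(sub) > 1) {
        out["nonchain3"] <- out["nonchain3"] + 1
      } else {
        nodes <- unique(c(sub$cell_i, sub$cell_j))
        degs <- table(c(sub$cell_i, sub$cell_j))
        if (length(nodes) == 3) {
          out["circular3"] <- out["circular3"] + 1
        } else if (max(degs) == 3) {
          out["hub3"] <- out["hub3"] + 1
        } else {
          out["chain3"] <- out["chain3"] + 1
        }
      }
    }
  }
  out
}

random_edge_graph <- function(n_nodes, p) {
  idx <- utils::combn(n_nodes, 2)
  keep <- stats::runif(ncol(idx)) < p
  tibble::tibble(cell_i = idx[1, keep], cell_j = idx[2, keep])
}

# Brute-force Sholl oracle: walk each segment in fine steps and count sign
# changes of (distance - r); independent of the quadratic-root counting in
# the package.
sholl_oracle <- function(swc, radii, type_code = 3) {
  soma <- swc[swc$type == 1, ]
  cx <- mean(soma$x)
  cy <- mean(soma$y)
  nodes <- swc[swc$type == type_code & swc$parent != -1, ]
  par <- swc[match(nodes$parent, swc$id), ]
  vapply(radii, function(r) {
    total <- 0L
    for (k in seq_len(nrow(nodes))) {
      tt <- seq(0, 1, length.out = 2001)
      dx <- par$x[k] + tt * (nodes$x[k] - par$x[k]) - cx
      dy <- par$y[k] + tt * (nodes$y[k] - par$y[k]) - cy
      s <- sign(sqrt(dx^2 + dy^2) - r)
      # crossings over (0, 1]: count sign changes, excluding the t = 0 point
      total <- total + sum(s[-1] != s[-length(s)] & s[-1] != 0) +
        sum(s[-1] == 0)
    }
    total
  }, integer(1))
}

make_cells <- function(n, types = rep("MP", n), set_id = 1L) {
  tibble::tibble(set_id = set_id, cell_id = seq_len(n), cell_type = types,
                 x_um = stats::runif(n, 0, 100),
                 y_um = stats::runif(n, 0, 100))
}

all_pairs_of <- function(cells) {
  idx <- utils::combn(nrow(cells), 2)
  tibble::tibble(
    set_id = cells$set_id[1],
    cell_i = cells$cell_id[idx[1, ]],
    cell_j = cells$cell_id[idx[2, ]],
    type_i = cells$cell_type[idx[1, ]],
    type_j = cells$cell_type[idx[2, ]],
    distance_um = sqrt((cells$x_um[idx[1, ]] - cells$x_um[idx[2, ]])^2 +
                       (cells$y_um[idx[1, ]] - cells$y_um[idx[2, ]])^2)
  )
}
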