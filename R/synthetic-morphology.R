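grow_branch <- function(origin, direction, n_seg, seg_len, level, max_level,
                        branch_prob, nodes, parent_id, type_code = 3) {
  pos <- origin
  dir <- direction
  pid <- parent_id
  for (s in seq_len(n_seg)) {
    dir <- dir + rnorm(1, 0, 0.15)
    pos <- pos + seg_len * c(cos(dir), sin(dir))
    id <- nrow(nodes$tbl) + 1L
    nodes$tbl <- rbind(nodes$tbl,
                       data.frame(id = id, type = type_code, x = pos[1],
                                  y = pos[2], z = 0, radius = 0.5,
                                  parent = pid))
    pid <- id
  }
  if (level < max_level && runif(1) < branch_prob) {
    for (dth in c(-0.45, 0.45)) {
      grow_branch(pos, dir + dth, max(2, n_seg - 1), seg_len, level + 1,
                  max_level, branch_prob, nodes, pid, type_code)
    }
  }
  invisible(NULL)
}

#' Generate a synthetic SWC reconstruction
#'
#' Emulates the somatodendritic geometry of the two morphological types:
#' fusiform (FF) cells get an elongated soma (high axis ratio) with primary
#' dendrites concentrated at the two poles of the major axis, multipolar
#' (MP) cells a near-round soma with 4-6 stems at near-uniform angles.
#' Dendrites grow as branching segment trees. The output is a valid
#' single-tree SWC table (type 1 soma: a root at the center plus 16 outline
#' nodes on the ellipse; type 3 dendrites).
#'
#' @param cell_type `"FF"` or `"MP"`.
#' @param params optional overrides: `axis_ratio`, `minor_um`, `n_stems`,
#'   `angle_jitter_deg`, `orientation_deg`, `seg_len_um`, `n_seg`,
#'   `branch_prob`.
#' @param seed integer seed.
#' @return An SWC tibble.
#' @export
generate_morphology <- function(cell_type = c("FF", "MP"), params = list(),
                                seed = 1) {
  cell_type <- match.arg(cell_type)
  with_seed(seed, {
    p <- utils::modifyList(list(
      axis_ratio = if (cell_type == "FF") runif(1, 2.2, 3.5)
                   else runif(1, 1.02, 1.35),
      minor_um = runif(1, 8, 12),
      n_stems = if (cell_type == "FF") sample(2:3, 1, prob = c(0.85, 0.15))
                else sample(4:6, 1),
      angle_jitter_deg = 12,
      orientation_deg = runif(1, 0, 180),
      seg_len_um = 12,
      n_seg = 8,
      branch_prob = 0.7
    ), params)
    a <- p$axis_ratio * p$minor_um
    b <- p$minor_um
    phi <- p$orientation_deg * pi / 180
    rot <- function(x, y) {
      cbind(x * cos(phi) - y * sin(phi), x * sin(phi) + y * cos(phi))
    }
    th <- seq(0, 2 * pi, length.out = 17)[-17]
    outline <- rot(a * cos(th), b * sin(th))
    tbl <- data.frame(
      id = 1:17, type = 1,
      x = c(0, outline[, 1]), y = c(0, outline[, 2]), z = 0,
      radius = c(b, rep(1, 16)), parent = c(-1L, rep(1L, 16))
    )
    if (cell_type == "FF") {
      poles <- rep(c(0, pi), length.out = p$n_stems)
      stem_angles <- poles + rnorm(p$n_stems, 0, p$angle_jitter_deg * pi / 180)
    } else {
      base <- seq(0, 2 * pi, length.out = p$n_stems + 1)[-(p$n_stems + 1)]
      stem_angles <- base + runif(p$n_stems, -0.35, 0.35)
    }
    nodes <- new.env()
    nodes$tbl <- tbl
    for (th_s in stem_angles) {
      # stem originates on the (rotated) ellipse perimeter
      start <- as.numeric(rot(a * cos(th_s), b * sin(th_s)))
      id <- nrow(nodes$tbl) + 1L
      nodes$tbl <- rbind(nodes$tbl,
                         data.frame(id = id, type = 3, x = start[1],
                                    y = start[2], z = 0, radius = 0.8,
                                    parent = 1L))
      grow_branch(start, th_s + phi, p$n_seg, p$seg_len_um, 1, 3,
                  p$branch_prob, nodes, id)
    }
    out <- tibble::as_tibble(nodes$tbl)
    attr(out, "cell_type") <- cell_type
    out
  })
}
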