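#' Read an SWC reconstruction
#'
#' Standard 7-column SWC (id, type, x, y, z, radius, parent; `#` comments).
#'
#' @param path file path.
#' @return A tibble with the seven SWC columns.
#' @export
read_swc <- function(path) {
  tbl <- utils::read.table(path, comment.char = "#",
                           col.names = c("id", "type", "x", "y", "z",
                                         "radius", "parent"))
  out <- tibble::as_tibble(tbl)
  validate_swc(out)
  out
}

#' Write an SWC reconstruction
#'
#' @param swc a tibble with columns id, type, x, y, z, radius, parent.
#' @param path file path.
#' @export
write_swc <- function(swc, path) {
  validate_swc(swc)
  writeLines(c("# id type x y z radius parent",
               sprintf("%d %d %.4f %.4f %.4f %.4f %d",
                       swc$id, swc$type, swc$x, swc$y, swc$z, swc$radius,
                       swc$parent)),
             path)
  invisible(path)
}

#' Validate an SWC node table
#'
#' Checks for exactly one root, valid parent references, and acyclicity
#' (every node reaches the root).
#'
#' @param swc an SWC tibble.
#' @return The table, invisibly; aborts on violation.
#' @export
validate_swc <- function(swc) {
  roots <- swc$id[swc$parent == -1]
  if (length(roots) != 1) abort("SWC must have exactly one root.")
  if (!all(swc$parent %in% c(-1, swc$id))) abort("Invalid parent ids.")
  parent_of <- setNames(swc$parent, swc$id)
  for (i in swc$id) {
    seen <- 0
    j <- i
    while (j != -1) {
      j <- parent_of[[as.character(j)]]
      seen <- seen + 1
      if (seen > nrow(swc)) abort("Cycle detected in SWC parent links.")
    }
  }
  invisible(swc)
}

#' Fit an ellipse to soma outline points
#'
#' Direct least-squares conic fit constrained to an ellipse, returning the
#' semantically useful parameters: axis lengths (major >= minor), center,
#' and major-axis orientation.
#'
#' @param points a two-column matrix or data frame of 2D points (>= 5).
#' @return A list `major`, `minor`, `angle_deg` (in `[0, 180)`), `center`.
#' @export
fit_soma_ellipse <- function(points) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  if (nrow(pts) < 5) abort("At least 5 soma outline points are required.")
  x <- pts[, 1] - mean(pts[, 1])
  y <- pts[, 2] - mean(pts[, 2])
  d1 <- cbind(x^2, x * y, y^2)
  d2 <- cbind(x, y, 1)
  s1 <- crossprod(d1)
  s2 <- crossprod(d1, d2)
  s3 <- crossprod(d2)
  if (abs(det(s3)) < 1e-12) abort("Degenerate (collinear) soma points.")
  tmat <- -solve(s3, t(s2))
  m <- s1 + s2 %*% tmat
  m <- rbind(m[3, ] / 2, -m[2, ], m[1, ] / 2)
  ev <- eigen(m)
  cond <- 4 * Re(ev$vectors[1, ]) * Re(ev$vectors[3, ]) -
    Re(ev$vectors[2, ])^2
  a1 <- Re(ev$vectors[, which(cond > 0)[1]])
  coefs <- c(a1, as.numeric(tmat %*% a1))  # A B C D E F (centered frame)
  A <- coefs[1]; B <- coefs[2]; C <- coefs[3]
  D <- coefs[4]; E <- coefs[5]; F0 <- coefs[6]
  ctr <- solve(matrix(c(2 * A, B, B, 2 * C), 2, 2), -c(D, E))
  f_c <- A * ctr[1]^2 + B * ctr[1] * ctr[2] + C * ctr[2]^2 +
    D * ctr[1] + E * ctr[2] + F0
  q <- matrix(c(A, B / 2, B / 2, C), 2, 2) / (-f_c)
  eq <- eigen(q, symmetric = TRUE)
  axes <- 1 / sqrt(eq$values)
  major_vec <- eq$vectors[, which.max(axes)]
  ang <- atan2(major_vec[2], major_vec[1]) * 180 / pi
  ang <- ang %% 180
  list(major = max(axes), minor = min(axes), angle_deg = ang,
       center = c(ctr[1] + mean(pts[, 1]), ctr[2] + mean(pts[, 2])))
}

soma_outline <- function(swc) {
  root <- swc$id[swc$parent == -1]
  s <- swc[swc$type == 1 & swc$id != root, ]
  if (nrow(s) < 5) abort("Too few soma outline points in reconstruction.")
  s
}

stem_nodes <- function(swc) {
  root <- swc$id[swc$parent == -1]
  swc[swc$type == 3 & swc$parent == root, ]
}

angle_to_axis <- function(theta_deg, axis_deg) {
  d <- abs((theta_deg - axis_deg) %% 180)
  pmin(d, 180 - d)
}

subtree_length <- function(swc, node_id) {
  kids <- swc$id[swc$parent == node_id]
  if (length(kids) == 0) return(0)
  sum(vapply(kids, function(k) {
    p <- swc[swc$id == node_id, ]
    c0 <- swc[swc$id == k, ]
    sqrt((c0$x - p$x)^2 + (c0$y - p$y)^2) + subtree_length(swc, k)
  }, numeric(1)))
}

#' Soma and dendritic bipolarity indices
#'
#' The soma index is the major/minor axis ratio of the fitted soma ellipse;
#' the dendritic index is the fraction of primary-dendrite origins whose
#' angle from the soma center lies within `window_deg` of either pole of the
#' major axis (stem-counted by default, optionally length-weighted).
#'
#' @param swc an SWC tibble (soma outline as type-1 nodes around the root,
#'   primary dendrites as type-3 children of the root).
#' @param window_deg angular half-window around each pole, degrees.
#' @param weight `"stem"` (count stems) or `"length"` (weight each stem by
#'   its subtree length).
#' @return A one-row tibble: `soma_bipolarity`, `dendritic_bipolarity`,
#'   `major_axis_angle`.
#' @export
bipolarity_indices <- function(swc, window_deg = 45,
                               weight = c("stem", "length")) {
  weight <- match.arg(weight)
  fit <- fit_soma_ellipse(soma_outline(swc)[, c("x", "y")])
  stems <- stem_nodes(swc)
  if (nrow(stems) == 0) {
    return(tibble::tibble(soma_bipolarity = fit$major / fit$minor,
                          dendritic_bipolarity = NA_real_,
                          major_axis_angle = fit$angle_deg))
  }
  theta <- atan2(stems$y - fit$center[2], stems$x - fit$center[1]) * 180 / pi
  inside <- angle_to_axis(theta, fit$angle_deg) <= window_deg
  w <- if (weight == "stem") {
    rep(1, nrow(stems))
  } else {
    vapply(stems$id, function(i) subtree_length(swc, i), numeric(1))
  }
  tibble::tibble(
    soma_bipolarity = fit$major / fit$minor,
    dendritic_bipolarity = sum(w[inside]) / sum(w),
    major_axis_angle = fit$angle_deg
  )
}

dendrite_segments <- function(swc, type_code = 3) {
  root <- swc$id[swc$parent == -1]
  kids <- swc[swc$type == type_code & swc$parent != -1 &
                swc$parent != root, ]
  if (nrow(kids) == 0) {
    return(tibble::tibble(x0 = double(), y0 = double(), x1 = double(),
                          y1 = double()))
  }
  par <- swc[match(kids$parent, swc$id), ]
  tibble::tibble(x0 = par$x, y0 = par$y, x1 = kids$x, y1 = kids$y)
}

#' Dendritic length by angular orientation
#'
#' After rotating the reconstruction so the soma major axis lies on the
#' x-axis, each dendritic segment's 2D length accrues to the angular bin of
#' its midpoint (angles about the soma center). The bin total equals the
#' total projected dendritic length.
#'
#' @param swc an SWC tibble.
#' @param n_bins number of angular bins over 360 degrees.
#' @return A tibble `bin_center_deg`, `length_um`.
#' @export
polar_length_profile <- function(swc, n_bins = 36) {
  fit <- fit_soma_ellipse(soma_outline(swc)[, c("x", "y")])
  seg <- dendrite_segments(swc)
  phi <- -fit$angle_deg * pi / 180
  rot <- function(x, y) {
    x0 <- x - fit$center[1]
    y0 <- y - fit$center[2]
    cbind(x0 * cos(phi) - y0 * sin(phi), x0 * sin(phi) + y0 * cos(phi))
  }
  edges <- seq(-180, 180, length.out = n_bins + 1)
  centers <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  len <- rep(0, n_bins)
  if (nrow(seg) > 0) {
    p0 <- rot(seg$x0, seg$y0)
    p1 <- rot(seg$x1, seg$y1)
    mid <- (p0 + p1) / 2
    ang <- atan2(mid[, 2], mid[, 1]) * 180 / pi
    l <- sqrt(rowSums((p1 - p0)^2))
    bin <- pmin(n_bins, findInterval(ang, edges, rightmost.closed = TRUE))
    for (k in seq_along(l)) len[bin[k]] <- len[bin[k]] + l[k]
  }
  tibble::tibble(bin_center_deg = centers, length_um = len)
}

#' Sholl analysis: intersections with concentric circles
#'
#' Counts the crossings of dendritic (or axonal) segments with circles of
#' increasing radius centred on the soma centroid, solving the exact
#' circle-segment intersection for each segment.
#'
#' @param swc an SWC tibble.
#' @param structure `"dendrite"` (SWC type 3) or `"axon"` (type 2).
#' @param radius_step_um circle spacing, um.
#' @return A tibble `radius_um`, `n_intersections` (empty when the structure
#'   is absent).
#' @export
sholl <- function(swc, structure = c("dendrite", "axon"),
                  radius_step_um = 20) {
  structure <- match.arg(structure)
  type_code <- if (structure == "dendrite") 3 else 2
  soma <- swc[swc$type == 1, ]
  cx <- mean(soma$x)
  cy <- mean(soma$y)
  nodes <- swc[swc$type == type_code, ]
  if (nrow(nodes) == 0) {
    return(tibble::tibble(radius_um = double(), n_intersections = integer()))
  }
  kids <- nodes[nodes$parent != -1, ]
  par <- swc[match(kids$parent, swc$id), ]
  x0 <- par$x - cx; y0 <- par$y - cy
  x1 <- kids$x - cx; y1 <- kids$y - cy
  rmax <- sqrt(max(c(x0^2 + y0^2, x1^2 + y1^2)))
  radii <- seq(radius_step_um, rmax + radius_step_um, by = radius_step_um)
  counts <- vapply(radii, function(r) {
    dx <- x1 - x0; dy <- y1 - y0
    a <- dx^2 + dy^2
    b <- 2 * (x0 * dx + y0 * dy)
    cc <- x0^2 + y0^2 - r^2
    disc <- b^2 - 4 * a * cc
    total <- 0L
    ok <- which(disc > 0 & a > 0)
    for (k in ok) {
      sq <- sqrt(disc[k])
      for (t in c((-b[k] - sq) / (2 * a[k]), (-b[k] + sq) / (2 * a[k]))) {
        if (t > 0 && t <= 1) total <- total + 1L
      }
    }
    total
  }, integer(1))
  tibble::tibble(radius_um = radii, n_intersections = counts)
}

#' Nonlinear classification of morphological cell types
#'
#' Trains a small single-hidden-layer neural network on the two bipolarity
#' features (or soma shape alone) and reports leave-one-out accuracy.
#' Deterministic given the seed.
#'
#' @param features tibble with numeric feature columns and a label column.
#' @param label name of the label column (two classes).
#' @param feature_cols feature column names; defaults to both bipolarity
#'   indices. Pass `"soma_bipolarity"` for the soma-only variant.
#' @param size hidden units.
#' @param seed integer seed for weight initialization.
#' @return A list with `predictions` (tibble of `truth`, `predicted`) and
#'   `loo_accuracy`.
#' @export
classify_cell_type <- function(features, label = "cell_type",
                               feature_cols = c("soma_bipolarity",
                                                "dendritic_bipolarity"),
                               size = 3, seed = 1) {
  y <- factor(features[[label]])
  if (nlevels(y) < 2) abort("Training labels contain a single class.")
  if (min(table(y)) < 10) {
    warn("Fewer than 10 labeled cells in a class; accuracy may be unstable.")
  }
  x <- as.matrix(features[, feature_cols, drop = FALSE])
  mu <- colMeans(x)
  sg <- apply(x, 2, sd)
  sg[sg == 0] <- 1
  xs <- scale(x, center = mu, scale = sg)
  n <- nrow(xs)
  pred <- factor(rep(NA_character_, n), levels = levels(y))
  for (i in seq_len(n)) {
    with_seed(stage_seed(seed, i), {
      fit <- nnet::nnet(xs[-i, , drop = FALSE], nnet::class.ind(y[-i]),
                        size = size, decay = 5e-3, maxit = 300,
                        trace = FALSE, softmax = TRUE)
      p <- predict(fit, xs[i, , drop = FALSE])
      pred[i] <- levels(y)[which.max(p)]
    })
  }
  list(
    predictions = tibble::tibble(truth = y, predicted = pred),
    loo_accuracy = mean(pred == y)
  )
}
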