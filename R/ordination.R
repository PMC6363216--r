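#' Principal component analysis of Procrustes shape coordinates
#'
#' Covariance PCA of the flattened aligned coordinates (x then y, per point).
#' Components with essentially zero variance are dropped; the sign of each
#' loading vector is fixed so that its largest-magnitude entry is positive,
#' making score signs deterministic.
#'
#' @param aligned a [gpa()] result (or a `sliding_result`, whose final GPA is
#'   used).
#' @return An object of class `shape_pca`: `scores` (n x k, zero-mean
#'   columns), `loadings` (2p x k, orthonormal), `variance_fraction`
#'   (non-increasing, sums to 1), `consensus`, `info`, `scheme`.
#' @export
shape_pca <- function(aligned) {
  if (inherits(aligned, "sliding_result")) aligned <- aligned$gpa
  stopifnot(inherits(aligned, "procrustes_result"))
  n <- dim(aligned$aligned)[3]
  if (n < 3) stop("shape PCA needs at least 3 configurations", call. = FALSE)
  p <- dim(aligned$aligned)[1]
  flat <- t(apply(aligned$aligned, 3, as.vector)) # n x 2p, columns x1..xp,y1..yp
  total_var <- sum(apply(flat, 2, stats::var))
  if (total_var < 1e-16) {
    stop("degenerate sample: zero shape variance (all configurations identical)",
         call. = FALSE)
  }
  pc <- stats::prcomp(flat, center = TRUE, scale. = FALSE)
  keep <- pc$sdev^2 / sum(pc$sdev^2) > 1e-12
  load <- pc$rotation[, keep, drop = FALSE]
  scores <- pc$x[, keep, drop = FALSE]
  # deterministic sign: largest-|entry| of each loading positive
  for (j in seq_len(ncol(load))) {
    s <- sign(load[which.max(abs(load[, j])), j])
    if (s < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  vf <- pc$sdev[keep]^2 / sum(pc$sdev[keep]^2)
  colnames(scores) <- colnames(load) <- paste0("PC", seq_len(ncol(load)))
  structure(list(
    scores = scores, loadings = load, variance_fraction = vf,
    consensus = matrix(colMeans(flat), p, 2),
    info = aligned$info, scheme = aligned$scheme
  ), class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, ...) {
  k <- min(3, length(x$variance_fraction))
  cat(sprintf("<shape_pca> %d configurations, %d components; %s\n",
              nrow(x$scores), length(x$variance_fraction),
              paste(sprintf("PC%d %.1f%%", seq_len(k),
                            100 * x$variance_fraction[seq_len(k)]),
                    collapse = ", ")))
  invisible(x)
}

#' Shape at a given score along a principal component
#'
#' Reconstructs `consensus + score * loading`, the shape the model predicts
#' at that position along the component; the endpoints of the observed score
#' range give the extreme shapes drawn on deformation grids.
#'
#' @param pca a [shape_pca()] result.
#' @param component component index.
#' @param score position along the component (0 gives the consensus).
#' @return `p x 2` matrix.
#' @export
shape_at_score <- function(pca, component, score) {
  stopifnot(inherits(pca, "shape_pca"))
  if (component < 1 || component > ncol(pca$loadings)) {
    stop("component ", component, " out of range 1..", ncol(pca$loadings),
         call. = FALSE)
  }
  p <- nrow(pca$consensus)
  pca$consensus + matrix(pca$loadings[, component] * score, p, 2)
}

#' Deformation grid for a principal component
#'
#' A regular lattice over the consensus bounding box (plus margin) warped by
#' the thin-plate spline carrying the consensus onto the shape at the
#' component's observed minimum or maximum score, visualizing where along the
#' dorsal outline the shape change concentrates.
#'
#' @param pca a [shape_pca()] result.
#' @param component component index.
#' @param extreme `"min"` or `"max"`: which end of the observed score range.
#' @param grid_density nodes along the longer axis (the shorter axis is
#'   scaled by the aspect ratio, at least 4).
#' @param margin fractional margin beyond the consensus bounding box.
#' @return An object of class `deformation_grid`: `source_grid` and
#'   `warped_grid` (node matrices with `nx`/`ny` attributes), `consensus`,
#'   `target` (the extreme shape), `component`, `extreme`, `score`.
#' @export
deformation_grid <- function(pca, component, extreme = c("min", "max"),
                             grid_density = 24, margin = 0.1) {
  extreme <- match.arg(extreme)
  stopifnot(inherits(pca, "shape_pca"))
  sc <- pca$scores[, component]
  score <- if (extreme == "min") min(sc) else max(sc)
  target <- shape_at_score(pca, component, score)
  cons <- pca$consensus
  rng_x <- range(cons[, 1])
  rng_y <- range(cons[, 2])
  pad_x <- margin * diff(rng_x)
  pad_y <- max(margin * diff(rng_y), 0.02 * diff(rng_x))
  rng_x <- rng_x + c(-pad_x, pad_x)
  rng_y <- rng_y + c(-pad_y, pad_y)
  aspect <- diff(rng_y) / diff(rng_x)
  if (diff(rng_x) >= diff(rng_y)) {
    nx <- grid_density
    ny <- max(4L, round(grid_density * aspect))
  } else {
    ny <- grid_density
    nx <- max(4L, round(grid_density / aspect))
  }
  nodes <- as.matrix(expand.grid(
    x = seq(rng_x[1], rng_x[2], length.out = nx),
    y = seq(rng_y[1], rng_y[2], length.out = ny)
  ))
  warped <- if (sum((target - cons)^2) < 1e-24) nodes else tps_warp(cons, target, nodes)
  structure(list(
    source_grid = structure(nodes, nx = nx, ny = ny),
    warped_grid = structure(warped, nx = nx, ny = ny),
    consensus = cons, target = target,
    component = component, extreme = extreme, score = score
  ), class = "deformation_grid")
}

#' Plot a deformation grid
#'
#' Draws the warped lattice with the consensus outline in grey and the
#' extreme shape in red (minimum) or blue (maximum), the colour convention
#' used for shape-change figures.
#'
#' @param x a [deformation_grid()].
#' @param ... passed to [graphics::plot()].
#' @export
plot.deformation_grid <- function(x, ...) {
  g <- x$warped_grid
  nx <- attr(g, "nx"); ny <- attr(g, "ny")
  col_ext <- if (x$extreme == "min") "red" else "blue"
  graphics::plot(g, type = "n", asp = 1, xlab = "", ylab = "", axes = FALSE,
                 main = sprintf("PC%d %s", x$component, x$extreme), ...)
  for (r in seq_len(ny)) {
    graphics::lines(g[((r - 1) * nx + 1):(r * nx), , drop = FALSE], col = "grey70")
  }
  for (c in seq_len(nx)) {
    graphics::lines(g[seq(c, nx * ny, by = nx), , drop = FALSE], col = "grey70")
  }
  graphics::lines(x$consensus, col = "grey40", lwd = 2)
  graphics::points(x$consensus, col = "grey40", pch = 16, cex = 0.6)
  graphics::lines(x$target, col = col_ext, lwd = 2)
  graphics::points(x$target, col = col_ext, pch = 16, cex = 0.6)
  invisible(x)
}
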