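#' Centroid size of a landmark configuration
#'
#' The size measure removed by Procrustes superimposition: the square root of
#' the summed squared distances of the landmarks from their centroid.
#'
#' @param config `p x 2` numeric matrix.
#' @return positive scalar.
#' @export
#' @examples
#' centroid_size(rbind(c(0, 0), c(0, 1), c(1, 1), c(1, 0))) # sqrt(2)
centroid_size <- function(config) {
  stopifnot(is.matrix(config), ncol(config) == 2, nrow(config) >= 2)
  centred <- sweep(config, 2, colMeans(config))
  cs <- sqrt(sum(centred^2))
  if (cs == 0) stop("degenerate shape: all points coincident", call. = FALSE)
  cs
}

center_config <- function(config) sweep(config, 2, colMeans(config))

#' Optimal rotation between two centered configurations
#'
#' Returns the proper (det +1) rotation angle, in radians, that minimizes the
#' summed squared distances from the rotated `source` to `target`. For planar
#' configurations this least-squares rotation has the closed form
#' `atan2(sum(x_s * y_t - y_s * x_t), sum(x_s * x_t + y_s * y_t))`.
#' Reflections are never returned: orientation is normalized beforehand with
#' [flip_horizontal()].
#'
#' @param source,target `p x 2` matrices with centroid at the origin.
#' @return rotation angle in radians, in (-pi, pi].
#' @export
optimal_rotation <- function(source, target) {
  stopifnot(nrow(source) == nrow(target))
  if (max(abs(colMeans(source))) > 1e-6 || max(abs(colMeans(target))) > 1e-6) {
    stop("configurations must be centered", call. = FALSE)
  }
  if (sum(source^2) == 0) stop("degenerate (rank-0) source configuration", call. = FALSE)
  num <- sum(source[, 1] * target[, 2] - source[, 2] * target[, 1])
  den <- sum(source[, 1] * target[, 1] + source[, 2] * target[, 2])
  atan2(num, den)
}

rotate_config <- function(config, theta) {
  # counter-clockwise rotation of row-vector coordinates by theta
  r <- matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2, 2)
  config %*% r
}

#' Generalized Procrustes Analysis
#'
#' Iteratively removes translation, scale and rotation from a sample of
#' configurations (partial Procrustes superimposition): each configuration is
#' centered and scaled to unit centroid size, rotated onto the current
#' consensus, and the consensus is re-estimated (and renormalized to unit
#' centroid size) until its relative change falls below `tol`.
#'
#' @param sample a [shape_sample()] with at least two configurations.
#' @param tol relative consensus change declaring convergence.
#' @param max_iter iteration cap; non-convergence is flagged in the result,
#'   not raised.
#' @return An object of class `procrustes_result` with elements `aligned`
#'   (`p x 2 x n` array, each at unit centroid size, centroid at the origin),
#'   `consensus` (the mean shape), `centroid_sizes`, `iterations`,
#'   `converged`, `trace` (consensus change per iteration), plus the sample's
#'   `info` and `scheme`.
#' @export
gpa <- function(sample, tol = 1e-8, max_iter = 100) {
  stopifnot(inherits(sample, "shape_sample"))
  n <- n_configurations(sample)
  if (n < 2) stop("GPA needs at least 2 configurations", call. = FALSE)
  p <- dim(sample$coords)[1]

  aligned <- array(NA_real_, dim = c(p, 2, n))
  sizes <- numeric(n)
  for (i in seq_len(n)) {
    cfg <- center_config(sample$coords[, , i])
    sizes[i] <- centroid_size(sample$coords[, , i])
    aligned[, , i] <- cfg / sizes[i]
  }

  consensus <- aligned[, , 1]
  consensus <- consensus / centroid_size(consensus)
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  X <- matrix(aligned[, 1, ], p, n)
  Y <- matrix(aligned[, 2, ], p, n)
  while (iter < max_iter) {
    iter <- iter + 1L
    # least-squares rotation of every configuration onto the consensus,
    # vectorized over configurations
    num <- drop(crossprod(X, consensus[, 2]) - crossprod(Y, consensus[, 1]))
    den <- drop(crossprod(X, consensus[, 1]) + crossprod(Y, consensus[, 2]))
    theta <- atan2(num, den)
    ct <- rep(cos(theta), each = p)
    st <- rep(sin(theta), each = p)
    X_new <- X * ct - Y * st
    Y <- X * st + Y * ct
    X <- X_new
    new_consensus <- cbind(rowMeans(X), rowMeans(Y))
    new_consensus <- new_consensus / centroid_size(new_consensus)
    change <- sqrt(sum((new_consensus - consensus)^2))
    trace <- c(trace, change)
    consensus <- new_consensus
    if (change < tol) {
      converged <- TRUE
      break
    }
  }
  # canonical orientation: baseline of the consensus (first -> last point)
  # along +x, so the result does not depend on the inputs' original
  # orientation beyond the anatomy itself
  base <- consensus[p, ] - consensus[1, ]
  phi <- -atan2(base[2], base[1])
  X_new <- X * cos(phi) - Y * sin(phi)
  Y <- X * sin(phi) + Y * cos(phi)
  X <- X_new
  aligned[, 1, ] <- X
  aligned[, 2, ] <- Y
  # reported consensus is the plain coordinate-wise mean of the aligned shapes
  consensus <- cbind(rowMeans(X), rowMeans(Y))
  structure(list(
    aligned = aligned, consensus = consensus, centroid_sizes = sizes,
    iterations = iter, converged = converged, trace = trace,
    info = sample$info, scheme = sample$scheme
  ), class = "procrustes_result")
}

#' @export
print.procrustes_result <- function(x, ...) {
  cat(sprintf(
    "<procrustes_result> %d configurations of %d points; %d iteration(s), %s\n",
    dim(x$aligned)[3], dim(x$aligned)[1], x$iterations,
    if (x$converged) "converged" else "NOT converged"
  ))
  invisible(x)
}

#' Procrustes sum of squares of an alignment
#' @param result a `procrustes_result`.
#' @return summed squared deviations of aligned shapes from the consensus.
#' @export
procrustes_ss <- function(result) {
  n <- dim(result$aligned)[3]
  sum(vapply(seq_len(n),
             function(i) sum((result$aligned[, , i] - result$consensus)^2),
             numeric(1)))
}

# sample whose coords are the aligned configurations
aligned_sample <- function(result) {
  shape_sample(result$aligned, result$info, result$scheme)
}
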