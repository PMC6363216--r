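#' Thin-plate-spline bending energy matrix
#'
#' Assembles the TPS system for a 2D reference configuration with kernel
#' `U(r) = r^2 log(r)` (with `U(0) = 0`) and returns the `k x k` bending
#' energy matrix: the upper-left block of the inverse of
#' `L = [[K, Q], [Q', 0]]` with `Q = [1, x, y]`. The matrix is symmetric,
#' positive semi-definite, and annihilates affine configurations (row sums
#' zero; products with the reference coordinates zero).
#'
#' @param reference `p x 2` matrix of reference landmarks in general position.
#' @return An object of class `bending_energy_model`: list with `reference`,
#'   `bending_matrix`, and the full inverse `L_inv` reused by [tps_warp()].
#' @export
bending_energy_matrix <- function(reference) {
  stopifnot(is.matrix(reference), ncol(reference) == 2)
  k <- nrow(reference)
  if (k < 4) stop("need at least 4 reference points", call. = FALSE)
  L <- tps_system(reference)
  L_inv <- tryCatch(solve(L), error = function(e) {
    stop("singular TPS system: reference points are degenerate (collinear or coincident)",
         call. = FALSE)
  })
  B <- L_inv[1:k, 1:k, drop = FALSE]
  B <- (B + t(B)) / 2 # enforce exact symmetry
  structure(list(reference = reference, bending_matrix = B, L_inv = L_inv),
            class = "bending_energy_model")
}

tps_kernel <- function(r2) {
  # U(r) = r^2 log r = r^2 log(r^2)/2, with U(0) = 0
  out <- ifelse(r2 > 0, r2 * log(r2) / 2, 0)
  out
}

tps_system <- function(reference) {
  k <- nrow(reference)
  d2 <- as.matrix(stats::dist(reference))^2
  K <- tps_kernel(d2)
  Q <- cbind(1, reference)
  rbind(cbind(K, Q), cbind(t(Q), matrix(0, 3, 3)))
}

#' Bending energy of a configuration relative to a reference
#'
#' The quadratic form `x' B x + y' B y` with `B` the bending matrix of the
#' reference: zero exactly when the configuration is an affine image of the
#' reference, positive otherwise. Quantifies the non-affine part of the
#' deformation carrying the reference onto the configuration.
#'
#' @param model a [bending_energy_matrix()] result (or a `p x 2` reference
#'   matrix, from which the model is built).
#' @param config `p x 2` matrix with the model's point count.
#' @return non-negative scalar.
#' @export
bending_energy <- function(model, config) {
  if (is.matrix(model)) model <- bending_energy_matrix(model)
  stopifnot(inherits(model, "bending_energy_model"))
  if (nrow(config) != nrow(model$reference)) {
    stop("configuration has ", nrow(config), " points; model expects ",
         nrow(model$reference), call. = FALSE)
  }
  B <- model$bending_matrix
  max(drop(config[, 1] %*% B %*% config[, 1]) +
      drop(config[, 2] %*% B %*% config[, 2]), 0)
}

#' Thin-plate-spline warp
#'
#' The smooth interpolating map carrying `source` landmarks exactly onto
#' `target` landmarks, evaluated at arbitrary query points. Used for
#' deformation grids and anywhere a shape difference must be extended to the
#' whole plane.
#'
#' @param source,target `p x 2` landmark matrices.
#' @param query_points `m x 2` matrix of points to map.
#' @return `m x 2` matrix of warped query points.
#' @export
tps_warp <- function(source, target, query_points) {
  stopifnot(nrow(source) == nrow(target))
  if (is.null(dim(query_points))) query_points <- matrix(query_points, ncol = 2)
  k <- nrow(source)
  L <- tps_system(source)
  rhs <- rbind(target, matrix(0, 3, 2))
  coefs <- tryCatch(solve(L, rhs), error = function(e) {
    stop("singular TPS system: source points are degenerate (collinear or coincident)",
         call. = FALSE)
  })
  W <- coefs[1:k, , drop = FALSE]
  A <- coefs[(k + 1):(k + 3), , drop = FALSE]
  # kernel distances query -> source
  d2 <- outer(rowSums(query_points^2), rowSums(source^2), `+`) -
    2 * query_points %*% t(source)
  d2[d2 < 0] <- 0
  U <- tps_kernel(d2)
  cbind(1, query_points) %*% A + U %*% W
}
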