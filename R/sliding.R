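#' Slide semilandmarks by bending-energy minimization
#'
#' Sliding semilandmarks have no exact anatomical position along the outline;
#' each is allowed to move along the local tangent of the digitized curve so
#' that the thin-plate-spline bending energy between the configuration and a
#' reference shape is minimal. Tangents are central differences of the curve
#' neighbours (one-sided at the first/last point of the region window);
#' fixed landmarks never move.
#'
#' With the bending energy `E(t) = (x + Ux t - x0)' B (x + Ux t - x0) +
#' (y + Uy t - y0)' B (y + Uy t - y0)` quadratic in the sliding magnitudes
#' `t`, the minimizer solves the linear system
#' `(Ux' B Ux + Uy' B Uy) t = -(Ux' B (x - x0) + Uy' B (y - y0))`, so each
#' sliding step can only decrease the energy toward the current reference.
#'
#' The default reference is the Procrustes consensus, recomputed after each
#' sliding pass (superimpose, slide, re-superimpose), iterated until the
#' total bending-energy drop falls below `tol` or `outer_max` passes.
#'
#' @param sample a [shape_sample()] whose scheme declares sliding indices.
#' @param reference optional `p x 2` reference shape; default: the GPA
#'   consensus, updated every outer iteration.
#' @param outer_max maximum superimpose-slide passes.
#' @param tol stop when the total bending-energy decrease of a pass is below
#'   this value.
#' @param superimpose logical; run GPA before/after each pass (default). Set
#'   to `FALSE` to slide once against a fixed `reference` without
#'   superimposition (the raw one-pass operation).
#' @return An object of class `sliding_result`: `sample` (the slid
#'   configurations as a [shape_sample()]), `gpa` (final
#'   [gpa()] result on the slid sample; `NULL` when `superimpose = FALSE`),
#'   and `trace`, a data frame with per-pass total bending energy before and
#'   after sliding.
#' @export
slide_semilandmarks <- function(sample, reference = NULL, outer_max = 5,
                                tol = 1e-6, superimpose = TRUE) {
  stopifnot(inherits(sample, "shape_sample"))
  scheme <- sample$scheme
  slid_loc <- local_index(scheme, scheme$sliding_indices)
  if (length(slid_loc) == 0) {
    res <- if (superimpose) gpa(sample) else NULL
    out_sample <- if (superimpose) aligned_sample(res) else sample
    return(structure(list(sample = out_sample, gpa = res,
                          trace = data.frame(be_before = numeric(0),
                                             be_after = numeric(0))),
                     class = "sliding_result"))
  }
  p <- dim(sample$coords)[1]
  n <- n_configurations(sample)

  coords <- sample$coords
  trace_before <- trace_after <- numeric(0)

  for (pass in seq_len(outer_max)) {
    if (superimpose) {
      g <- gpa(shape_sample(coords, sample$info, scheme))
      coords <- g$aligned
      ref <- if (is.null(reference)) g$consensus else reference
    } else {
      if (is.null(reference)) stop("reference required when superimpose = FALSE",
                                   call. = FALSE)
      ref <- reference
    }
    model <- bending_energy_matrix(ref)
    be0 <- be1 <- 0
    for (i in seq_len(n)) {
      cfg <- coords[, , i]
      be0 <- be0 + bending_energy(model, cfg)
      coords[, , i] <- slide_one(cfg, ref, model, slid_loc)
      be1 <- be1 + bending_energy(model, coords[, , i])
    }
    trace_before <- c(trace_before, be0)
    trace_after <- c(trace_after, be1)
    if (be0 - be1 < tol) break
  }

  final <- if (superimpose) gpa(shape_sample(coords, sample$info, scheme)) else NULL
  out_coords <- if (superimpose) final$aligned else coords
  structure(list(
    sample = shape_sample(out_coords, sample$info, scheme),
    gpa = final,
    trace = data.frame(be_before = trace_before, be_after = trace_after)
  ), class = "sliding_result")
}

#' @export
print.sliding_result <- function(x, ...) {
  cat(sprintf("<sliding_result> %d pass(es); total bending energy %.6g -> %.6g\n",
              nrow(x$trace),
              if (nrow(x$trace)) x$trace$be_before[1] else NA,
              if (nrow(x$trace)) x$trace$be_after[nrow(x$trace)] else NA))
  invisible(x)
}

# unit tangents at the sliding positions: central differences along the
# curve order, one-sided at the window endpoints
curve_tangents <- function(cfg, slid_loc) {
  p <- nrow(cfg)
  t_mat <- matrix(NA_real_, length(slid_loc), 2)
  for (j in seq_along(slid_loc)) {
    i <- slid_loc[j]
    lo <- max(1L, i - 1L)
    hi <- min(p, i + 1L)
    if (lo == hi) stop("sliding point ", i, " has no curve neighbours", call. = FALSE)
    v <- cfg[hi, ] - cfg[lo, ]
    nv <- sqrt(sum(v^2))
    if (nv == 0) stop("zero-length tangent at sliding point ", i, call. = FALSE)
    t_mat[j, ] <- v / nv
  }
  t_mat
}

# one configuration: closed-form tangent displacements minimizing bending
# energy toward the reference. With U the (sparse) tangent-direction design,
# U' B U reduces to B[slid, slid] scaled by the tangent outer products.
slide_one <- function(cfg, ref, model, slid_loc) {
  B <- model$bending_matrix
  tg <- curve_tangents(cfg, slid_loc)
  tx <- tg[, 1]
  ty <- tg[, 2]
  dx <- cfg[, 1] - ref[, 1]
  dy <- cfg[, 2] - ref[, 2]
  B_ss <- B[slid_loc, slid_loc, drop = FALSE]
  A <- B_ss * (outer(tx, tx) + outer(ty, ty))
  b <- -(tx * drop(B %*% dx)[slid_loc] + ty * drop(B %*% dy)[slid_loc])
  t_hat <- tryCatch(solve(A, b), error = function(e) {
    # PSD system can be rank-deficient when tangent moves lie in the affine
    # null space; the minimum-norm minimizer is used then
    qr.coef(qr(A, tol = 1e-12), b)
  })
  t_hat[is.na(t_hat)] <- 0
  cfg[, 1] <- cfg[, 1] + replace(numeric(nrow(cfg)), slid_loc, tx * t_hat)
  cfg[, 2] <- cfg[, 2] + replace(numeric(nrow(cfg)), slid_loc, ty * t_hat)
  cfg
}

#' Stabilize the head/neck articulation angle
#'
#' The balance movement of the neck is a rigid rotation of the neck-and-head
#' chain about the withers. To cancel it, the angle formed by points
#' `arm_a`-`pivot`-`arm_b` (defaults 1-15-30) is set to a common reference
#' angle in every configuration by rigidly rotating the `moved` subset
#' (defaults 16-30) about the pivot point. All other points are untouched,
#' and all pairwise distances within the moved and within the unmoved subset
#' are preserved.
#'
#' @param sample a full-outline [shape_sample()].
#' @param pivot,arm_a,arm_b anatomical indices defining the angle.
#' @param moved indices rigidly rotated about the pivot.
#' @param reference_angle common target angle in radians; default: the
#'   circular mean of the sample's angles.
#' @return A [shape_sample()] in which `angle(arm_a, pivot, arm_b)` is
#'   identical across configurations.
#' @export
stabilize_articulation_angle <- function(sample, pivot = 15, arm_a = 1,
                                         arm_b = 30, moved = 16:30,
                                         reference_angle = NULL) {
  stopifnot(inherits(sample, "shape_sample"))
  piv <- local_index(sample$scheme, pivot)
  a <- local_index(sample$scheme, arm_a)
  b <- local_index(sample$scheme, arm_b)
  mv <- local_index(sample$scheme, moved)
  n <- n_configurations(sample)
  angles <- vapply(seq_len(n), function(i) {
    articulation_angle(sample$coords[, , i], piv, a, b)
  }, numeric(1))
  if (is.null(reference_angle)) {
    reference_angle <- atan2(mean(sin(angles)), mean(cos(angles)))
  }
  out <- sample
  for (i in seq_len(n)) {
    delta <- reference_angle - angles[i]
    cfg <- out$coords[, , i]
    pv <- cfg[piv, ]
    rel <- sweep(cfg[mv, , drop = FALSE], 2, pv)
    out$coords[mv, , i] <- sweep(rotate_config(rel, delta), 2, pv, `+`)
  }
  out
}

#' Signed articulation angle of one configuration
#' @param cfg `p x 2` matrix.
#' @param pivot,arm_a,arm_b local row indices.
#' @return angle in radians from vector pivot->arm_a to vector pivot->arm_b.
#' @export
articulation_angle <- function(cfg, pivot = 15, arm_a = 1, arm_b = 30) {
  u <- cfg[arm_a, ] - cfg[pivot, ]
  v <- cfg[arm_b, ] - cfg[pivot, ]
  if (sum(u^2) == 0 || sum(v^2) == 0) {
    stop("undefined angle: pivot coincides with an arm point", call. = FALSE)
  }
  atan2(u[1] * v[2] - u[2] * v[1], sum(u * v))
}
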