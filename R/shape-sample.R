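#' Analysis scheme: fixed landmarks, sliding semilandmarks, region window
#'
#' A scheme records which of the 30 dorsal-outline points are treated as
#' anatomically fixed landmarks (LD) and which as sliding semilandmarks (SSL),
#' which region of the outline is analysed, and whether the head/neck
#' articulation angle is stabilized before superimposition.
#'
#' Two named schemes are provided. `"ssl"` fixes only the medial canthus of
#' the eye (point 30) and lets the other 29 points slide. `"mixed"` fixes the
#' eight anatomical points (the seven clay-marked skeletal cues plus the eye)
#' and lets the remaining 22 outline points slide. The exact outline indices
#' carrying the seven clay marks between croup and eye are not uniquely
#' determined by anatomy alone; the default follows their anatomical order
#' along the spine (first coccygeal vertebra = 1, lumbo-sacral junction,
#' thoraco-lumbar junction, withers = 15, atlas, temporo-mandibular joint,
#' facial crest, eye = 30) and can be overridden via `fixed_indices`.
#'
#' @param name `"ssl"` or `"mixed"`.
#' @param fixed_indices integer vector of 1-based anatomical indices treated
#'   as fixed landmarks. Defaults: `30` for `"ssl"`,
#'   `c(1, 4, 8, 15, 24, 27, 29, 30)` for `"mixed"`.
#' @param region `"full"` (points 1-30), `"back_croup"` (1-15) or
#'   `"neck_head"` (15-30; the withers point belongs to both windows).
#' @param stabilize_neck_angle logical; stabilize the angle formed by points
#'   1, 15 and 30 before superimposition (full region only).
#' @return An object of class `method_scheme`.
#' @export
#' @examples
#' method_scheme("ssl")
#' method_scheme("mixed", region = "back_croup")
method_scheme <- function(name = c("ssl", "mixed"),
                          fixed_indices = NULL,
                          region = c("full", "back_croup", "neck_head"),
                          stabilize_neck_angle = FALSE,
                          n_points = 30L) {
  name <- match.arg(name)
  region <- match.arg(region)
  n_points <- as.integer(n_points)
  if (region != "full" && n_points != 30L) {
    stop("anatomical regions are defined on the 30-point outline", call. = FALSE)
  }
  if (is.null(fixed_indices)) {
    fixed_indices <- switch(name,
      ssl   = n_points,
      mixed = c(1L, 4L, 8L, 15L, 24L, 27L, 29L, 30L)
    )
    if (name == "mixed" && n_points != 30L) {
      stop("the mixed scheme's default landmarks assume the 30-point outline; ",
           "supply fixed_indices", call. = FALSE)
    }
  }
  fixed_indices <- sort(unique(as.integer(fixed_indices)))
  if (any(fixed_indices < 1L | fixed_indices > n_points)) {
    stop("fixed_indices must lie in 1..", n_points, call. = FALSE)
  }
  window <- region_window(region, n_points)
  if (stabilize_neck_angle && region != "full") {
    stop("angle stabilization is defined for the full outline only", call. = FALSE)
  }
  fixed_in_window <- intersect(fixed_indices, window)
  scheme <- structure(
    list(
      name = name,
      fixed_indices = fixed_in_window,
      sliding_indices = setdiff(window, fixed_in_window),
      region = region,
      window = window,
      stabilize_neck_angle = stabilize_neck_angle
    ),
    class = "method_scheme"
  )
  scheme
}

region_window <- function(region, n_points = 30L) {
  switch(region,
    full       = seq_len(n_points),
    back_croup = 1:15,
    neck_head  = 15:30,
    stop("unknown region: ", region, call. = FALSE)
  )
}

#' @export
print.method_scheme <- function(x, ...) {
  cat(sprintf(
    "<method_scheme> %s, region %s (%d points), %d fixed / %d sliding%s\n",
    x$name, x$region, length(x$window),
    length(x$fixed_indices), length(x$sliding_indices),
    if (x$stabilize_neck_angle) ", neck angle stabilized" else ""
  ))
  invisible(x)
}

#' Build a shape sample
#'
#' A shape sample bundles landmark configurations (a `p x 2 x n` array),
#' per-photograph metadata, and the analysis scheme. Point order is
#' anatomical: index 1 at the first coccygeal vertebra (croup), index 15 at
#' the withers, index 30 at the medial canthus of the eye.
#'
#' @param coords numeric array `p x 2 x n` (or a list of `p x 2` matrices).
#' @param info data frame with one row per configuration; columns
#'   `horse_id`, `condition` ("standing"/"walking"), `photo_id`, `scale`
#'   are filled with defaults when absent.
#' @param scheme a [method_scheme()]; default `NULL` builds an SSL scheme
#'   sized to the configurations' point count.
#' @return An object of class `shape_sample`.
#' @export
shape_sample <- function(coords, info = NULL, scheme = NULL) {
  if (is.list(coords) && !is.array(coords)) {
    p <- nrow(coords[[1]])
    coords <- array(unlist(coords), dim = c(p, 2, length(coords)))
  }
  stopifnot(is.array(coords), length(dim(coords)) == 3, dim(coords)[2] == 2)
  n <- dim(coords)[3]
  p <- dim(coords)[1]
  if (is.null(scheme)) scheme <- method_scheme("ssl", n_points = p)
  if (!all(is.finite(coords))) stop("non-finite landmark coordinates", call. = FALSE)
  if (is.null(info)) info <- data.frame(photo_id = seq_len(n))
  info <- as.data.frame(info)
  if (nrow(info) != n) stop("info must have one row per configuration", call. = FALSE)
  if (is.null(info$horse_id)) info$horse_id <- sprintf("horse%03d", seq_len(n))
  if (is.null(info$condition)) info$condition <- "standing"
  if (is.null(info$photo_id)) info$photo_id <- seq_len(n)
  if (is.null(info$scale)) info$scale <- NA_real_
  if (p != length(scheme$window)) {
    stop(sprintf(
      "configurations have %d points but scheme region '%s' expects %d",
      p, scheme$region, length(scheme$window)
    ), call. = FALSE)
  }
  structure(list(coords = coords, info = info, scheme = scheme),
            class = "shape_sample")
}

#' @export
print.shape_sample <- function(x, ...) {
  cat(sprintf(
    "<shape_sample> %d configurations of %d points, %d individual(s); scheme %s/%s\n",
    dim(x$coords)[3], dim(x$coords)[1],
    length(unique(x$info$horse_id)), x$scheme$name, x$scheme$region
  ))
  invisible(x)
}

#' Number of configurations in a sample
#' @param sample a [shape_sample()].
#' @return integer count.
#' @export
n_configurations <- function(sample) dim(sample$coords)[3]

# local (within-window) positions of anatomical indices
local_index <- function(scheme, anatomical) {
  pos <- match(anatomical, scheme$window)
  if (anyNA(pos)) {
    stop("index ", paste(anatomical[is.na(pos)], collapse = ", "),
         " outside region window", call. = FALSE)
  }
  pos
}

#' Restrict a sample to a region of the dorsal outline
#'
#' Keeps the back-and-croup window (points 1-15) or the neck-and-head window
#' (points 15-30); the withers point (15) belongs to both. The scheme's fixed
#' and sliding sets are restricted to the window and point order is never
#' changed. Region selection is only defined on full 30-point samples.
#'
#' @param sample a full-outline [shape_sample()].
#' @param region `"back_croup"` or `"neck_head"`.
#' @return A [shape_sample()] over the selected window.
#' @export
select_region <- function(sample, region = c("back_croup", "neck_head")) {
  region <- match.arg(region)
  if (sample$scheme$region != "full") {
    stop("sample is already restricted to region '", sample$scheme$region,
         "'; region selection needs the full outline", call. = FALSE)
  }
  window <- region_window(region)
  scheme <- method_scheme(sample$scheme$name,
                          fixed_indices = sample$scheme$fixed_indices,
                          region = region,
                          stabilize_neck_angle = FALSE)
  shape_sample(sample$coords[window, , , drop = FALSE], sample$info, scheme)
}

#' Mirror configurations about a vertical axis
#'
#' Photographs of left- and right-facing horses are brought to a common
#' orientation by reflecting x about a vertical axis; point order is
#' anatomical and therefore unchanged.
#'
#' @param config a `p x 2` matrix, a `p x 2 x n` array, or a [shape_sample()].
#' @param axis_x x-coordinate of the mirror axis.
#' @return Object of the same type with `x' = 2 * axis_x - x`, y unchanged.
#' @export
flip_horizontal <- function(config, axis_x = 0) {
  if (inherits(config, "shape_sample")) {
    config$coords[, 1, ] <- 2 * axis_x - config$coords[, 1, ]
    return(config)
  }
  if (!all(is.finite(config))) stop("non-finite coordinates", call. = FALSE)
  if (is.matrix(config)) {
    config[, 1] <- 2 * axis_x - config[, 1]
  } else {
    config[, 1, ] <- 2 * axis_x - config[, 1, ]
  }
  config
}
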