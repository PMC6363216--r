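test_that("a configuration equal to the reference does not slide", {
  base <- generate_profile(profile_params())
  ref <- sweep(base, 2, colMeans(base)) / centroid_size(base)
  s <- shape_sample(list(ref, ref), scheme = method_scheme("ssl"))
  out <- slide_semilandmarks(s, reference = ref, outer_max = 1,
                             superimpose = FALSE)
  expect_equal(out$sample$coords[, , 1], ref, tolerance = 1e-10)
  expect_equal(out$sample$coords[, , 2], ref, tolerance = 1e-10)
})

test_that("sliding decreases bending energy monotonically and fixes landmarks", {
  s <- jittered_sample(n = 8, noise = 1.5, seed = 61,
                       scheme = method_scheme("mixed"))
  out <- slide_semilandmarks(s)
  expect_true(all(out$trace$be_after <= out$trace$be_before + 1e-9))
  # fixed landmarks of each configuration do not move during the sliding
  # step itself: re-run one pass without superimposition to observe it
  g <- gpa(s)
  ali <- shape_sample(g$aligned, s$info, s$scheme)
  one <- slide_semilandmarks(ali, reference = g$consensus, outer_max = 1,
                             superimpose = FALSE)
  fixed <- match(s$scheme$fixed_indices, s$scheme$window)
  expect_identical(one$sample$coords[fixed, , ], ali$coords[fixed, , ])
  # and every configuration's own energy decreased
  m <- bending_energy_matrix(g$consensus)
  for (i in 1:8) {
    expect_lte(bending_energy(m, one$sample$coords[, , i]),
               bending_energy(m, ali$coords[, , i]) + 1e-9)
  }
})

test_that("single sliding point matches the 1D grid-search minimizer", {
  ref <- toy_shape(7, seed = 71)
  cfg <- ref + matrix(rnorm(14, 0, 0.4), 7, 2)
  scheme <- method_scheme("ssl", fixed_indices = setdiff(1:30, 4))
  # build a 7-point sample by hand: only local point 4 slides
  s <- structure(list(
    coords = array(cfg, dim = c(7, 2, 1)),
    info = data.frame(horse_id = "h1", condition = "standing",
                      photo_id = 1, scale = NA_real_),
    scheme = list(name = "ssl", fixed_indices = setdiff(1:7, 4),
                  sliding_indices = 4L, region = "full", window = 1:7,
                  stabilize_neck_angle = FALSE)
  ), class = "shape_sample")
  class(s$scheme) <- "method_scheme"
  out <- slide_semilandmarks(s, reference = ref, outer_max = 1,
                             superimpose = FALSE)
  # oracle: exhaustive search over the tangent parameter
  tangent <- (cfg[5, ] - cfg[3, ]) / sqrt(sum((cfg[5, ] - cfg[3, ])^2))
  m <- bending_energy_matrix(ref)
  ts <- seq(-2, 2, by = 1e-5)
  energies <- vapply(ts, function(tt) {
    trial <- cfg
    trial[4, ] <- trial[4, ] + tt * tangent
    bending_energy(m, trial)
  }, numeric(1))
  t_best <- ts[which.min(energies)]
  moved <- out$sample$coords[4, , 1] - cfg[4, ]
  t_impl <- sum(moved * tangent)
  expect_lt(abs(t_impl - t_best), 2e-5) # within the grid resolution
  expect_lte(bending_energy(m, out$sample$coords[, , 1]), min(energies) + 1e-10)
})

test_that("angle stabilization makes the 1-15-30 angle identical across photos", {
  set.seed(81)
  spec <- population_spec(n_individuals = 5,
                          photos_per_individual = c(standing = 4),
                          neck_swing_sd = 8, seed = 81)
  s <- generate_population(spec)$sample
  st <- stabilize_articulation_angle(s)
  angles <- vapply(seq_len(n_configurations(st)), function(i) {
    articulation_angle(st$coords[, , i])
  }, numeric(1))
  expect_lt(var(angles), 1e-12)
  # back and croup untouched
  expect_identical(st$coords[1:15, , ], s$coords[1:15, , ])
})

test_that("stabilization collapses a constructed +10 degree neck rotation pair", {
  base <- generate_profile(profile_params())
  rot <- base
  pv <- rot[15, ]
  th <- 10 * pi / 180
  r <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  rot[16:30, ] <- sweep(sweep(rot[16:30, ], 2, pv) %*% r, 2, pv, `+`)
  s <- shape_sample(list(base, rot))
  st <- stabilize_articulation_angle(s)
  expect_equal(st$coords[, , 1], st$coords[, , 2], tolerance = 1e-9)
  # already at the reference angle -> unchanged
  s_same <- shape_sample(list(base, base))
  st_same <- stabilize_articulation_angle(s_same)
  expect_equal(st_same$coords, s_same$coords, tolerance = 1e-12)
})

test_that("stabilization is rigid within the moved and unmoved subsets", {
  s <- jittered_sample(n = 4, noise = 2, seed = 91)
  st <- stabilize_articulation_angle(s)
  for (i in 1:4) {
    d_moved_before <- dist(s$coords[16:30, , i])
    d_moved_after <- dist(st$coords[16:30, , i])
    expect_equal(as.vector(d_moved_after), as.vector(d_moved_before),
                 tolerance = 1e-9)
    expect_identical(st$coords[1:15, , i], s$coords[1:15, , i])
  }
})
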