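test_that("profile generation is deterministic and anatomically ordered", {
  p1 <- generate_profile(profile_params())
  p2 <- generate_profile(profile_params())
  expect_identical(p1, p2)
  expect_equal(dim(p1), c(30L, 2L))
  expect_true(all(diff(p1[, 1]) > 0)) # x strictly increasing croup -> head
})

test_that("withers prominence raises point 15 relative to its neighbours", {
  local_height <- function(w) {
    p <- generate_profile(profile_params(withers_prominence = w))
    p[15, 2] - (p[14, 2] + p[16, 2]) / 2
  }
  heights <- vapply(c(0, 3, 6, 9), local_height, numeric(1))
  expect_true(all(diff(heights) > 0))
})

test_that("doubling baseline length doubles the centroid size of the flat profile", {
  flat <- function(L) profile_params(withers_prominence = 0, neck_roundness = 0,
                                     croup_roundness = 0, baseline_length = L)
  cs1 <- centroid_size(generate_profile(flat(100)))
  cs2 <- centroid_size(generate_profile(flat(200)))
  expect_equal(cs2 / cs1, 2, tolerance = 1e-9)
})

test_that("the articulation angle of a generated profile matches its parameter", {
  for (ang in c(140, 160, 185)) {
    p <- generate_profile(profile_params(head_neck_angle = ang))
    got <- (-articulation_angle(p) * 180 / pi) %% 360 # dorsal-side opening
    expect_equal(got, ang, tolerance = 1e-6)
  }
  expect_error(profile_params(head_neck_angle = 80), "90, 270")
  expect_error(profile_params(baseline_length = -1), "> 0")
})

test_that("noise-free populations repeat the same photo per individual", {
  spec <- population_spec(n_individuals = 4,
                          photos_per_individual = c(standing = 3),
                          photo_noise_sd = 0, neck_swing_sd = 0, seed = 31)
  gen <- generate_population(spec)
  cc <- gen$sample$coords
  ids <- gen$sample$info$horse_id
  for (h in unique(ids)) {
    idx <- which(ids == h)
    for (i in idx[-1]) expect_identical(cc[, , i], cc[, , idx[1]])
  }
  # but individuals differ from each other
  expect_gt(sum((cc[, , 1] - cc[, , 4])^2), 0)
})

test_that("populations are reproducible under the master seed and group labels match", {
  spec <- population_spec(n_individuals = 6,
                          photos_per_individual = c(standing = 2), seed = 17)
  g1 <- generate_population(spec)
  g2 <- generate_population(spec)
  expect_identical(g1$sample$coords, g2$sample$coords)
  expect_identical(g1$records, g2$records)
  expect_equal(sort(unique(g1$records$sb_arb)), c(0, 1))
  # group label constant within individual in the photo table
  grp_by_photo <- tapply(g1$sample$info$group, g1$sample$info$horse_id,
                         function(v) length(unique(v)))
  expect_true(all(grp_by_photo == 1))
})

test_that("angle stabilization collapses the neck swing to the jitter level", {
  spec <- population_spec(n_individuals = 6,
                          photos_per_individual = c(standing = 8),
                          photo_noise_sd = 0.002, neck_swing_sd = 6, seed = 57)
  gen <- generate_population(spec)
  st <- stabilize_articulation_angle(gen$sample)
  ids <- gen$sample$info$horse_id
  within_var <- function(coords) {
    mean(vapply(unique(ids), function(h) {
      idx <- which(ids == h)
      neck <- coords[16:30, , idx]
      mean(apply(neck, c(1, 2), var))
    }, numeric(1)))
  }
  v_raw <- within_var(gen$sample$coords)
  v_stab <- within_var(st$coords)
  expect_lt(v_stab, v_raw / 10) # swing removed
  jitter_var <- (0.002 * 100)^2
  expect_lt(v_stab, 4 * jitter_var) # close to pure jitter
})

test_that("walking photographs are more numerous and swing more than standing", {
  spec <- population_spec(n_individuals = 3,
                          photos_per_individual = c(standing = 10, walking = 20),
                          conditions = c("standing", "walking"),
                          photo_noise_sd = 0, neck_swing_sd = 4, seed = 71)
  gen <- generate_population(spec)
  tab <- table(gen$sample$info$condition) / 3
  expect_equal(unname(tab[["standing"]]), 10)
  expect_equal(unname(tab[["walking"]]), 20)
  ang <- vapply(seq_len(n_configurations(gen$sample)), function(i) {
    articulation_angle(gen$sample$coords[, , i])
  }, numeric(1))
  sd_ang <- tapply(ang, gen$sample$info$condition, sd)
  expect_gt(sd_ang[["walking"]], sd_ang[["standing"]])
})
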