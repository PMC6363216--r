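# shared fixtures: all generated in code

# small irregular polygon, general position
toy_shape <- function(p = 10, seed = 42) {
  set.seed(seed)
  cbind(runif(p, 0, 10), runif(p, 0, 5))
}

# random similarity transform of a configuration
similarity_transform <- function(cfg, angle, scale = 1, shift = c(0, 0)) {
  r <- matrix(c(cos(angle), -sin(angle), sin(angle), cos(angle)), 2, 2)
  sweep(scale * (cfg %*% r), 2, shift, `+`)
}

# sample of jittered copies of one base profile
jittered_sample <- function(n = 6, noise = 0.5, seed = 1,
                            scheme = method_scheme("ssl")) {
  set.seed(seed)
  base <- generate_profile(profile_params())
  cfgs <- lapply(seq_len(n), function(i) base + matrix(rnorm(60, 0, noise), 30, 2))
  shape_sample(cfgs, data.frame(horse_id = sprintf("h%02d", seq_len(n))),
               scheme = scheme)
}

# ordinary (pairwise) partial Procrustes superimposition of m2 onto m1,
# independent of the package's gpa(): center, unit-size, closed-form rotation
pairwise_procrustes <- function(m1, m2) {
  c1 <- sweep(m1, 2, colMeans(m1)); c1 <- c1 / sqrt(sum(c1^2))
  c2 <- sweep(m2, 2, colMeans(m2)); c2 <- c2 / sqrt(sum(c2^2))
  num <- sum(c2[, 1] * c1[, 2] - c2[, 2] * c1[, 1])
  den <- sum(c2[, 1] * c1[, 1] + c2[, 2] * c1[, 2])
  th <- atan2(num, den)
  r <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  list(fixed = c1, rotated = c2 %*% r, distance = sqrt(sum((c1 - c2 %*% r)^2)))
}
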