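#' Parameters of a synthetic dorsal profile
#'
#' The generator draws a smooth 30-point dorsal outline from croup (point 1)
#' to the medial canthus of the eye (point 30) as a fixed baseline curve plus
#' localized smooth bumps. The parameters control the postural features the
#' analysis is meant to recover: withers prominence, roundness (vs flatness)
#' of the neck and croup arches, the head/neck articulation angle at the
#' withers, and the relative head size.
#'
#' @param withers_prominence bump amplitude at point 15, in the same units as
#'   `baseline_length`.
#' @param neck_roundness arch amplitude over points 16-29 (0 = flat neck).
#' @param croup_roundness arch amplitude over points 2-7 (0 = flat croup).
#' @param head_neck_angle degrees of the angle formed by points 1-15-30,
#'   must lie in (90, 270); larger = more open (flatter) neck carriage.
#' @param head_size relative length of the head segment (points 27-30);
#'   1 = template length.
#' @param baseline_length croup-to-head extent, > 0 (arbitrary image units).
#' @return An object of class `profile_params`.
#' @export
profile_params <- function(withers_prominence = 6,
                           neck_roundness = 10,
                           croup_roundness = 8,
                           head_neck_angle = 160,
                           head_size = 1,
                           baseline_length = 100) {
  if (baseline_length <= 0) stop("baseline_length must be > 0", call. = FALSE)
  if (head_neck_angle <= 90 || head_neck_angle >= 270) {
    stop("head_neck_angle must lie in (90, 270) degrees", call. = FALSE)
  }
  if (head_size <= 0) stop("head_size must be > 0", call. = FALSE)
  structure(list(withers_prominence = withers_prominence,
                 neck_roundness = neck_roundness,
                 croup_roundness = croup_roundness,
                 head_neck_angle = head_neck_angle,
                 head_size = head_size,
                 baseline_length = baseline_length),
            class = "profile_params")
}

#' Generate one synthetic dorsal profile
#'
#' Deterministic in its parameters. The outline is a gentle sinusoidal
#' baseline over arc length with Gaussian bumps: a croup arch (points 2-7), a
#' narrow withers bump at point 15 and a neck arch (points 16-29); the head
#' segment (points 27-30) is scaled by `head_size` and the neck-and-head
#' chain (points 16-30) is rigidly rotated about the withers so that the
#' angle formed by points 1-15-30 equals `head_neck_angle`. x is strictly
#' increasing from croup to head.
#'
#' @param params a [profile_params()].
#' @return `30 x 2` coordinate matrix.
#' @export
generate_profile <- function(params) {
  stopifnot(inherits(params, "profile_params"))
  L <- params$baseline_length
  s <- (0:29) / 29
  x <- L * s
  # gentle back hollow / rise of the template
  y <- 0.03 * L * sin(2 * pi * s - pi / 6)
  bump <- function(center, width, amp) amp * exp(-((s - center) / width)^2)
  y <- y + bump(mean(s[2:7]), 0.09, params$croup_roundness)
  y <- y + bump(s[15], 0.035, params$withers_prominence)
  y <- y + bump(mean(s[16:29]), 0.14, params$neck_roundness)
  cfg <- cbind(x = x, y = y)
  # head segment length relative to the neck
  head_idx <- 27:30
  anchor <- cfg[26, ]
  cfg[head_idx, ] <- sweep(sweep(cfg[head_idx, , drop = FALSE], 2, anchor) *
                             params$head_size, 2, anchor, `+`)
  # set the articulation angle 1-15-30 by rigidly rotating the neck chain;
  # the parameter is the dorsal-side opening: the clockwise angle from the
  # croup arm to the head arm, in (90, 270) so >180 means a reflex (hollow)
  # neck carriage
  target <- params$head_neck_angle * pi / 180
  current <- (-articulation_angle(cfg, pivot = 15, arm_a = 1, arm_b = 30)) %% (2 * pi)
  delta <- -(target - current)
  pv <- cfg[15, ]
  rel <- sweep(cfg[16:30, , drop = FALSE], 2, pv)
  cfg[16:30, ] <- sweep(rotate_config(rel, delta), 2, pv, `+`)
  if (any(diff(cfg[, 1]) <= 0)) {
    stop("parameters produce a non-monotone outline (x must increase croup -> head); ",
         "reduce amplitudes or bring head_neck_angle closer to 180", call. = FALSE)
  }
  unname(cfg)
}

#' Specification of a synthetic population
#'
#' Defines the study conditions the generator emulates: individuals
#' photographed repeatedly (10 standing / 20 walking photographs), a binary
#' group label (the poor-welfare group) shifting withers prominence upward
#' and neck roundness and head size downward by `delta` between-individual
#' standard deviations, per-individual random deviations of every profile
#' parameter, per-photo landmark jitter, and a random rigid neck swing about
#' the withers per photo (the balance movement of the neck, larger when
#' walking).
#'
#' @param n_individuals number of horses.
#' @param photos_per_individual named vector of photographs per condition.
#' @param conditions conditions to generate (`"standing"` and/or
#'   `"walking"`).
#' @param delta group shift, in units of the between-individual SD of each
#'   affected parameter.
#' @param group_fraction fraction of individuals in group 1.
#' @param between_sd named between-individual SDs of the profile parameters.
#' @param photo_noise_sd isotropic landmark jitter SD, as a fraction of
#'   `baseline_length`.
#' @param neck_swing_sd SD in degrees of the per-photo rigid neck rotation
#'   about the withers (doubled when walking).
#' @param base [profile_params()] of the population template.
#' @param seed integer master seed; all randomness derives from it.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n_individuals = 40,
                            photos_per_individual = c(standing = 10, walking = 20),
                            conditions = "standing",
                            delta = 1.5,
                            group_fraction = 0.5,
                            between_sd = c(withers_prominence = 2,
                                           neck_roundness = 2.5,
                                           croup_roundness = 2,
                                           head_neck_angle = 3,
                                           head_size = 0.08),
                            photo_noise_sd = 0.02,
                            neck_swing_sd = 5,
                            base = profile_params(),
                            seed = 1L) {
  stopifnot(n_individuals >= 2, all(conditions %in% c("standing", "walking")))
  if (any(between_sd < 0) || photo_noise_sd < 0 || neck_swing_sd < 0) {
    stop("standard deviations must be >= 0", call. = FALSE)
  }
  structure(list(n_individuals = n_individuals,
                 photos_per_individual = photos_per_individual,
                 conditions = conditions,
                 delta = delta, group_fraction = group_fraction,
                 between_sd = between_sd,
                 photo_noise_sd = photo_noise_sd,
                 neck_swing_sd = neck_swing_sd,
                 base = base, seed = as.integer(seed)),
            class = "population_spec")
}

# counter-based seed splitting: independent sub-streams from one master seed
split_seed <- function(seed, counter) {
  as.integer((as.double(seed) * 48271 + counter * 1009) %% 2147483647)
}

clamp_params <- function(pp) {
  pp$head_neck_angle <- min(max(pp$head_neck_angle, 95), 265)
  pp$head_size <- max(pp$head_size, 0.2)
  pp$baseline_length <- max(pp$baseline_length, 1e-3)
  pp
}

#' Generate a synthetic population of dorsal profiles
#'
#' Per individual, profile parameters are drawn as group mean (base
#' parameters, shifted by `delta` between-individual SDs for group 1 on
#' withers prominence (+), neck roundness (-) and head size (-)) plus
#' Gaussian between-individual deviations. Per photograph, the individual's
#' profile receives isotropic landmark jitter and a rigid rotation of the
#' neck-and-head chain about the withers (the neck balance movement).
#' Reproducible: everything derives from `spec$seed`.
#'
#' @param spec a [population_spec()].
#' @return list with `sample` (a [shape_sample()]) and `records` (a welfare
#'   record data frame whose `sb_arb` column carries the group label).
#' @export
generate_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  n <- spec$n_individuals
  n_group1 <- round(spec$group_fraction * n)
  group <- c(rep(1L, n_group1), rep(0L, n - n_group1))
  sdv <- spec$between_sd

  set.seed(split_seed(spec$seed, 1))
  ind_params <- vector("list", n)
  for (i in seq_len(n)) {
    # rejection sampling: parameter combinations whose outline folds back on
    # itself (x not strictly increasing) are anatomically impossible and are
    # redrawn; still fully reproducible under the master seed
    for (attempt in 1:100) {
      b <- spec$base
      if (group[i] == 1L) {
        b$withers_prominence <- b$withers_prominence + spec$delta * sdv[["withers_prominence"]]
        b$neck_roundness <- b$neck_roundness - spec$delta * sdv[["neck_roundness"]]
        b$head_size <- b$head_size - spec$delta * sdv[["head_size"]]
      }
      for (nm in names(sdv)) b[[nm]] <- b[[nm]] + stats::rnorm(1, 0, sdv[[nm]])
      b <- clamp_params(b)
      ok <- tryCatch({
        generate_profile(do.call(profile_params, b))
        TRUE
      }, error = function(e) FALSE)
      if (ok) break
    }
    if (!ok) stop("could not draw a valid profile for individual ", i,
                  "; lower the between-individual SDs", call. = FALSE)
    ind_params[[i]] <- b
  }

  configs <- list()
  info <- list()
  set.seed(split_seed(spec$seed, 2))
  for (i in seq_len(n)) {
    base_cfg <- generate_profile(do.call(profile_params, ind_params[[i]]))
    for (cond in spec$conditions) {
      n_photos <- spec$photos_per_individual[[cond]]
      swing_sd <- spec$neck_swing_sd * if (cond == "walking") 2 else 1
      for (ph in seq_len(n_photos)) {
        cfg <- base_cfg
        if (swing_sd > 0) {
          delta_a <- stats::rnorm(1, 0, swing_sd) * pi / 180
          pv <- cfg[15, ]
          rel <- sweep(cfg[16:30, , drop = FALSE], 2, pv)
          cfg[16:30, ] <- sweep(rotate_config(rel, delta_a), 2, pv, `+`)
        }
        if (spec$photo_noise_sd > 0) {
          cfg <- cfg + matrix(stats::rnorm(60, 0,
                                           spec$photo_noise_sd * spec$base$baseline_length),
                              30, 2)
        }
        configs[[length(configs) + 1L]] <- cfg
        info[[length(info) + 1L]] <- data.frame(
          horse_id = sprintf("horse%03d", i), condition = cond,
          photo_id = sprintf("%s_%02d", substr(cond, 1, 2), ph),
          scale = NA_real_, group = group[i]
        )
      }
    }
  }
  shapes <- shape_sample(configs, do.call(rbind, info))

  set.seed(split_seed(spec$seed, 3))
  records <- data.frame(
    horse_id = sprintf("horse%03d", seq_len(n)),
    sb_arb = group,
    depressed = stats::rbinom(n, 1, ifelse(group == 1, 0.35, 0.10)),
    ear_category = sample(c("forward", "backward", "neutral"), n,
                          replace = TRUE, prob = c(0.35, 0.3, 0.35)),
    type_of_equid = sample(c("pony", "horse"), n, replace = TRUE),
    proportion = sample(c("dolicho", "meso", "brachy"), n,
                        replace = TRUE, prob = c(0.13, 0.72, 0.15)),
    hay_meals = sample(1:4, n, replace = TRUE),
    paddock_time = round(stats::runif(n, 0, 100)),
    paddock_social = sample(c("alone", "group"), n, replace = TRUE),
    visible_conspecifics = sample(0:6, n, replace = TRUE),
    work_hours = round(stats::runif(n, 4, 14)),
    stringsAsFactors = FALSE
  )
  list(sample = shapes, records = records)
}

#' Generate behaviour observation streams consistent with welfare records
#'
#' Horses flagged `sb_arb = 1` receive an event stream satisfying the
#' scoring rule (at least 5 events of one behaviour, each of at least 3
#' successive repeats); horses flagged 0 receive streams violating it (too
#' few qualifying events or runs shorter than 3). `depressed = 1` horses get
#' at least one depressed-posture sighting. Ear scans (10 per horse) are
#' drawn to match the recorded favourite category.
#'
#' @param records welfare record data frame (columns `horse_id`, `sb_arb`,
#'   `depressed`, `ear_category`).
#' @param seed integer seed.
#' @return list of [observation_stream()], one per record row.
#' @export
generate_observation_streams <- function(records, seed = 1L) {
  set.seed(split_seed(seed, 7))
  labels <- c("weaving", "cribbing", "head tossing", "repetitive licking")
  lapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    if (r$sb_arb == 1) {
      lab <- sample(labels, 1)
      n_ev <- sample(5:9, 1)
      ev <- data.frame(label = lab, run_length = sample(3:8, n_ev, replace = TRUE))
    } else if (stats::runif(1) < 0.5) {
      # some qualifying runs, but fewer than 5 of any one behaviour
      lab <- sample(labels, 2)
      ev <- data.frame(label = rep(lab, each = 2),
                       run_length = sample(3:5, 4, replace = TRUE))
    } else {
      # frequent but short runs
      ev <- data.frame(label = sample(labels, 1),
                       run_length = sample(1:2, 7, replace = TRUE))
    }
    scans <- switch(r$ear_category,
      forward = c(rep("forward", sample(6:9, 1))),
      backward = c(rep("backward", sample(6:9, 1))),
      neutral = c(rep("forward", sample(0:5, 1)))
    )
    rest <- 10 - length(scans)
    filler <- if (r$ear_category == "neutral") {
      c(rep("backward", min(rest, 5)), rep("neutral", max(0, rest - 5)))
    } else {
      sample(setdiff(c("forward", "backward", "neutral"),
                     r$ear_category), rest, replace = TRUE)
    }
    observation_stream(
      horse_id = r$horse_id,
      events = ev,
      ear_scans = sample(c(scans, filler)),
      depressed_seen = if (r$depressed == 1) sample(1:5, 1) else 0L,
      total_hours = 18
    )
  })
}
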