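#' Specification of a synthetic scene
#'
#' Describes one frame to be generated: a list of groups (arrangement +
#' cardinality), a number of non-member singletons, the floor extent and the
#' minimum separation between group centres.  Every arrangement is built so
#' that the members' transactional-segment centres coincide at (or cluster
#' tightly around) the group's o-space centre, which makes the ground truth
#' unambiguous for a detector using the same stride.
#'
#' @param groups list of `list(arrangement, cardinality)` entries, or a data
#'   frame with columns `arrangement`, `cardinality`.  Arrangements:
#'   `"vis_a_vis"`, `"l_shape"`, `"side_by_side"` (cardinality 2) and
#'   `"circular"` (any cardinality >= 2).
#' @param n_singletons number of lone individuals.
#' @param floor width/height of the floor, same unit as `stride_D`.
#' @param min_group_separation minimum distance between group centres (and
#'   from singletons to group centres and to each other); must exceed
#'   `4 * stride_D`.
#' @param stride_D stride used to construct the arrangements.
#' @param seed integer RNG seed; generation is deterministic given the spec.
#' @return object of class `gcff_scene_spec`.
#' @export
scene_spec <- function(groups = list(), n_singletons = 0L,
                       floor = c(1000, 1000), min_group_separation = 200,
                       stride_D = 30, seed = 1L) {
  if (is.data.frame(groups)) {
    groups <- lapply(seq_len(nrow(groups)), function(i) {
      list(arrangement = as.character(groups$arrangement[i]),
           cardinality = as.integer(groups$cardinality[i]))
    })
  }
  arrangements <- c("vis_a_vis", "l_shape", "side_by_side", "circular")
  for (g in groups) {
    arr <- match.arg(g$arrangement, arrangements)
    card <- as.integer(g$cardinality)
    if (card < 2L) stop("group cardinality must be >= 2", call. = FALSE)
    if (arr != "circular" && card != 2L) {
      stop(arr, " arrangement implies cardinality 2", call. = FALSE)
    }
  }
  stopifnot(n_singletons >= 0L, length(floor) == 2L, all(floor > 0),
            stride_D > 0)
  if (min_group_separation <= 4 * stride_D) {
    stop("min_group_separation must exceed 4 * stride_D to keep the ground ",
         "truth unambiguous", call. = FALSE)
  }
  structure(list(groups = groups, n_singletons = as.integer(n_singletons),
                 floor = as.numeric(floor),
                 min_group_separation = min_group_separation,
                 stride_D = stride_D, seed = as.integer(seed)),
            class = "gcff_scene_spec")
}

# run expr under a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic scene with ground truth
#'
#' Places each group at a random location and rotation so that group centres
#' are pairwise at least `min_group_separation` apart, builds the members
#' in the requested arrangement, and scatters singletons at least the same
#' separation away from every group centre (and from each other), oriented
#' away from all group centres.  Placement uses rejection sampling with a
#' retry cap; an overcrowded floor raises a placement-failure error.
#'
#' Arrangement geometry (D = stride):
#' * circular k: members on a circle of radius D facing its centre;
#' * vis-a-vis: two members 2D apart facing each other;
#' * l_shape: two members at right angle, both D from the shared centre;
#' * side_by_side: two members facing the same way, shoulder gap D/2, both
#'   one stride behind the shared centre (TS centres D/2 apart).
#'
#' @param spec a [gcff_scene_spec].
#' @param max_retries rejection-sampling cap per placement.
#' @return a [gcff_scene] with the construction recorded as ground truth.
#' @examples
#' sp <- scene_spec(list(list(arrangement = "circular", cardinality = 3)),
#'                  n_singletons = 1, seed = 7)
#' sc <- generate_scene(sp)
#' scene_truth(sc)
#' @export
generate_scene <- function(spec, max_retries = 1000L) {
  stopifnot(inherits(spec, "gcff_scene_spec"))
  with_seed(spec$seed, {
    D <- spec$stride_D
    sep <- spec$min_group_separation
    margin <- 2 * D
    draw_point <- function() c(stats::runif(1, margin, spec$floor[1] - margin),
                               stats::runif(1, margin, spec$floor[2] - margin))
    centres <- matrix(numeric(0), 0L, 2L)
    for (g in seq_along(spec$groups)) {
      placed <- FALSE
      for (r in seq_len(max_retries)) {
        p <- draw_point()
        if (nrow(centres) == 0L ||
            all(sqrt(rowSums(sweep(centres, 2L, p)^2)) >= sep)) {
          centres <- rbind(centres, p)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop("placement failure: floor too small for the requested ",
             "separations", call. = FALSE)
      }
    }
    persons <- list()
    truth_groups <- list()
    next_id <- 1L
    take_ids <- function(k) {
      ids <- paste0("p", seq.int(next_id, next_id + k - 1L))
      next_id <<- next_id + k
      ids
    }
    for (g in seq_along(spec$groups)) {
      arr <- spec$groups[[g]]$arrangement
      k <- spec$groups[[g]]$cardinality
      ctr <- centres[g, ]
      phi <- stats::runif(1, -pi, pi)
      ids <- take_ids(k)
      members <- switch(
        arr,
        circular = {
          ang <- phi + 2 * pi * (seq_len(k) - 1L) / k
          data.frame(id = ids, x = ctr[1] + D * cos(ang),
                     y = ctr[2] + D * sin(ang), theta = norm_angle(ang + pi))
        },
        vis_a_vis = data.frame(
          id = ids,
          x = ctr[1] + D * cos(phi + c(0, pi)),
          y = ctr[2] + D * sin(phi + c(0, pi)),
          theta = norm_angle(phi + c(pi, 0))),
        l_shape = data.frame(
          id = ids,
          x = ctr[1] + D * cos(phi + c(0, pi / 2)),
          y = ctr[2] + D * sin(phi + c(0, pi / 2)),
          theta = norm_angle(phi + c(pi, -pi / 2))),
        side_by_side = {
          back <- ctr - D * c(cos(phi), sin(phi))
          lat <- (D / 4) * c(-sin(phi), cos(phi))
          data.frame(id = ids,
                     x = back[1] + c(lat[1], -lat[1]),
                     y = back[2] + c(lat[2], -lat[2]),
                     theta = norm_angle(rep(phi, 2L)))
        })
      persons[[length(persons) + 1L]] <- members
      truth_groups[[length(truth_groups) + 1L]] <- ids
    }
    singleton_ids <- character(0)
    if (spec$n_singletons > 0L) {
      spots <- matrix(numeric(0), 0L, 2L)
      for (s in seq_len(spec$n_singletons)) {
        placed <- FALSE
        for (r in seq_len(max_retries)) {
          p <- draw_point()
          others <- rbind(centres, spots)
          if (nrow(others) == 0L ||
              all(sqrt(rowSums(sweep(others, 2L, p)^2)) >= sep)) {
            spots <- rbind(spots, p)
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          stop("placement failure: floor too small for the requested ",
               "separations", call. = FALSE)
        }
      }
      singleton_ids <- take_ids(spec$n_singletons)
      theta_s <- vapply(seq_len(spec$n_singletons), function(s) {
        if (nrow(centres) == 0L) return(stats::runif(1, -pi, pi))
        away <- sweep(-centres, 2L, spots[s, ], `+`)   # spot - centre
        away <- away / sqrt(rowSums(away^2))
        dir <- colSums(away)
        atan2(dir[2], dir[1])
      }, numeric(1L))
      persons[[length(persons) + 1L]] <-
        data.frame(id = singleton_ids, x = spots[, 1L], y = spots[, 2L],
                   theta = norm_angle(theta_s))
    }
    df <- if (length(persons) > 0L) do.call(rbind, persons) else {
      data.frame(id = character(), x = numeric(), y = numeric(),
                 theta = numeric())
    }
    gcff_scene(df, unit = "cm",
               truth = gcff_groups(truth_groups, singleton_ids))
  })
}

#' The default archetype battery
#'
#' Ten scene archetypes covering all four arrangements, cardinalities 2 to
#' 6 and non-member singletons, averaging 9 individuals and 3 groups per
#' frame (90 persons / 30 groups over the ten archetypes).
#'
#' @return list of 10 lists with fields `groups` and `n_singletons`,
#'   consumable by [scene_spec()].
#' @export
default_archetypes <- function() {
  g <- function(arrangement, cardinality = 2L) {
    list(arrangement = arrangement, cardinality = as.integer(cardinality))
  }
  list(
    list(groups = list(g("vis_a_vis"), g("vis_a_vis"), g("circular", 3)),
         n_singletons = 2L),
    list(groups = list(g("l_shape"), g("side_by_side"), g("circular", 4)),
         n_singletons = 1L),
    list(groups = list(g("circular", 5), g("vis_a_vis")), n_singletons = 2L),
    list(groups = list(g("circular", 6), g("l_shape")), n_singletons = 1L),
    list(groups = list(g("vis_a_vis"), g("l_shape"), g("side_by_side")),
         n_singletons = 3L),
    list(groups = list(g("circular", 3), g("circular", 3),
                       g("side_by_side")), n_singletons = 1L),
    list(groups = list(g("circular", 4), g("circular", 3), g("vis_a_vis")),
         n_singletons = 0L),
    list(groups = list(g("vis_a_vis"), g("vis_a_vis"), g("vis_a_vis"),
                       g("circular", 3)), n_singletons = 0L),
    list(groups = list(g("circular", 3), g("l_shape"), g("side_by_side")),
         n_singletons = 2L),
    list(groups = list(g("side_by_side"), g("vis_a_vis"), g("l_shape"),
                       g("circular", 3)), n_singletons = 0L)
  )
}

#' Generate a batch of synthetic frames
#'
#' Repeats each archetype `reps` times with fresh random placements and
#' rotations ("minor variations"), yielding `length(archetypes) * reps`
#' frames.  Per-frame seeds are drawn deterministically from `seed`.
#'
#' @param archetypes list as returned by [default_archetypes()].
#' @param reps repeats per archetype.
#' @param seed master seed.
#' @inheritParams scene_spec
#' @return list of [gcff_scene] objects with ground truth.
#' @export
generate_batch <- function(archetypes = default_archetypes(), reps = 10L,
                           seed = 1L, floor = c(1000, 1000),
                           min_group_separation = 200, stride_D = 30) {
  n_frames <- length(archetypes) * reps
  frame_seeds <- with_seed(seed, sample.int(.Machine$integer.max, n_frames))
  scenes <- vector("list", n_frames)
  i <- 0L
  for (a in archetypes) {
    for (r in seq_len(reps)) {
      i <- i + 1L
      sp <- scene_spec(groups = a$groups, n_singletons = a$n_singletons,
                       floor = floor,
                       min_group_separation = min_group_separation,
                       stride_D = stride_D, seed = frame_seeds[i])
      scenes[[i]] <- generate_scene(sp)
    }
  }
  scenes
}

#' Specification of the Gaussian proxemic-noise model
#'
#' Additive zero-mean Gaussian noise scaled by an integer level `L`: each
#' coordinate receives noise with standard deviation `L * sigma` (so level 0
#' leaves the scene untouched and the spread grows linearly with the level).
#'
#' @param level noise level `L`, integer >= 0 (the reference protocol uses
#'   0..10).
#' @param sigma_x,sigma_y positional noise scale per level (default 20 cm).
#' @param sigma_theta orientation noise scale per level (default 0.1 rad).
#' @param seed integer RNG seed.
#' @return object of class `gcff_noise_spec`.
#' @export
noise_spec <- function(level, sigma_x = 20, sigma_y = 20, sigma_theta = 0.1,
                       seed = 1L) {
  stopifnot(is.numeric(level), length(level) == 1L, level >= 0,
            sigma_x >= 0, sigma_y >= 0, sigma_theta >= 0)
  structure(list(level = level, sigma_x = sigma_x, sigma_y = sigma_y,
                 sigma_theta = sigma_theta, seed = as.integer(seed)),
            class = "gcff_noise_spec")
}

#' Add proxemic noise to a scene
#'
#' Perturbs positions and/or orientations with independent Gaussian noise of
#' standard deviation `level * sigma` per coordinate.  The ground truth
#' travels unchanged: noise models measurement error, not social change.
#'
#' @param scene a [gcff_scene].
#' @param noise a [gcff_noise_spec].
#' @param mode `"both"` (default), `"position"` or `"orientation"`.
#' @return a new [gcff_scene]; with `mode = "orientation"` the positions are
#'   bit-identical to the input (and vice versa).
#' @export
add_noise <- function(scene, noise, mode = c("both", "position",
                                             "orientation")) {
  mode <- match.arg(mode)
  stopifnot(inherits(noise, "gcff_noise_spec"))
  n <- nrow(scene)
  with_seed(noise$seed, {
    df <- as.data.frame(scene)
    L <- noise$level
    if (mode %in% c("both", "position") && L > 0) {
      df$x <- df$x + stats::rnorm(n, 0, L * noise$sigma_x)
      df$y <- df$y + stats::rnorm(n, 0, L * noise$sigma_y)
    }
    if (mode %in% c("both", "orientation") && L > 0) {
      df$theta <- norm_angle(df$theta + stats::rnorm(n, 0, L * noise$sigma_theta))
    }
    gcff_scene(df, unit = attr(scene, "unit"), truth = scene_truth(scene))
  })
}

#' Noise-robustness sweep
#'
#' Runs the full protocol: for each noise level, applies Gaussian proxemic
#' noise to a batch of synthetic frames, detects groups and micro-averages
#' precision/recall/F1 at tolerance `T` against the (noise-free) ground
#' truth.
#'
#' @param levels integer noise levels (default 0:10).
#' @param reps frames per level.
#' @param mode noise mode, see [add_noise()].
#' @param params detector [gcff_params].
#' @param T evaluation tolerance.
#' @param seed master seed controlling both the base frames and the noise.
#' @param sigma_x,sigma_y,sigma_theta per-level noise scales.
#' @return data frame with one row per level: `level`, `precision`,
#'   `recall`, `f1`.
#' @export
noise_sweep <- function(levels = 0:10, reps = 50L,
                        mode = c("both", "position", "orientation"),
                        params = gcff_params(stride_D = 30, sigma = 80),
                        T = 2 / 3, seed = 1L,
                        sigma_x = 20, sigma_y = 20, sigma_theta = 0.1) {
  mode <- match.arg(mode)
  arch <- default_archetypes()
  base <- generate_batch(archetypes = rep(arch, length.out = reps),
                         reps = 1L, seed = seed,
                         stride_D = params$stride_D)
  noise_seeds <- with_seed(seed + 1L,
                           matrix(sample.int(.Machine$integer.max,
                                             length(levels) * reps),
                                  nrow = length(levels)))
  truth <- lapply(base, scene_truth)
  out <- data.frame(level = levels, precision = NA_real_, recall = NA_real_,
                    f1 = NA_real_)
  for (li in seq_along(levels)) {
    detected <- vector("list", reps)
    for (r in seq_len(reps)) {
      ns <- noise_spec(levels[li], sigma_x, sigma_y, sigma_theta,
                       seed = noise_seeds[li, r])
      noisy <- add_noise(base[[r]], ns, mode = mode)
      detected[[r]] <- gcff_detect(noisy, params)$groups
    }
    res <- evaluate_frames(detected, truth, T)
    out$precision[li] <- res[["precision"]]
    out$recall[li] <- res[["recall"]]
    out$f1[li] <- res[["f1"]]
  }
  out
}
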