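#' Assign persons to candidate o-space centres
#'
#' Given a set of candidate centres, finds the subset of centres and the
#' person-to-centre assignment minimising
#' `sum(unary + visibility penalty) + mdl_weight * |centres used|`.
#' Because every person term is unary given a centre, the optimum over a
#' fixed subset assigns each person to their cheapest selected centre, so the
#' problem is an uncapacitated facility location over candidate subsets.
#'
#' With `method = "exact"` (the default for up to `exact_max` candidates) all
#' non-empty candidate subsets are enumerated, so the result is the global
#' optimum over the candidate set.  Larger instances fall back to a greedy
#' add/drop local search whose energy is additionally floor-checked against
#' the assignment that keeps every candidate open (hence never worse than
#' one-centre-per-person initialisation when candidates are the persons' own
#' TS centres).
#'
#' @param scene a [gcff_scene].
#' @param candidates m x 2 matrix of candidate centres.
#' @param params a [gcff_params].
#' @param method `"auto"`, `"exact"` or `"greedy"`.
#' @param exact_max largest candidate count solved exactly under `"auto"`.
#' @return object of class `gcff_assignment`: list with `labels` (named
#'   integer vector person id -> label, labels re-indexed 1..k), `centres`
#'   (k x 2 matrix) and `energy`.  Ties between equally cheap centres go to
#'   the lowest label id.
#' @export
assign_labels <- function(scene, candidates, params,
                          method = c("auto", "exact", "greedy"),
                          exact_max = 12L) {
  method <- match.arg(method)
  n <- nrow(scene)
  if (n == 0L) {
    return(structure(list(labels = integer(0),
                          centres = matrix(numeric(0), 0L, 2L,
                                           dimnames = list(NULL, c("u", "v"))),
                          energy = 0),
                     class = "gcff_assignment"))
  }
  candidates <- rbind(candidates)
  m <- nrow(candidates)
  stopifnot(m >= 1L)
  M <- person_centre_costs(scene, candidates, params)
  if (method == "auto") method <- if (m <= exact_max) "exact" else "greedy"
  sel <- switch(method,
                exact = best_subset_exact(M, params$mdl_weight),
                greedy = best_subset_greedy(M, params$mdl_weight))
  finalize_assignment(scene, candidates, M, sel, params)
}

# cost matrix M[i, c] = unary(i, centre c) + visibility penalty of i under c
person_centre_costs <- function(scene, candidates, params) {
  mu <- ts_centres(scene, params = params)
  pos <- cbind(scene$x, scene$y)
  n <- nrow(mu); m <- nrow(candidates)
  M <- matrix(0, n, m)
  for (c in seq_len(m)) {
    ctr <- candidates[c, ]
    M[, c] <- (ctr[1L] - mu[, 1L])^2 + (ctr[2L] - mu[, 2L])^2 +
      vis_penalty_vec(pos, ctr, params)
  }
  M
}

# exact enumeration over candidate subsets via incremental per-person minima:
# minvec[[mask]] = pmin(minvec[[mask w/o lowest bit]], M[, lowest bit])
best_subset_exact <- function(M, mdl) {
  m <- ncol(M)
  nmask <- bitwShiftL(1L, m) - 1L
  minvec <- vector("list", nmask)
  best_cost <- Inf
  best_mask <- 0L
  popcount <- integer(nmask)
  for (mask in seq_len(nmask)) {
    low <- bitwAnd(mask, -mask)
    rest <- mask - low
    col <- M[, which_bit(low)]
    if (rest == 0L) {
      mv <- col
      popcount[mask] <- 1L
    } else {
      mv <- pmin(minvec[[rest]], col)
      popcount[mask] <- popcount[rest] + 1L
    }
    minvec[[mask]] <- mv
    cost <- sum(mv) + mdl * popcount[mask]
    if (cost < best_cost) {
      best_cost <- cost
      best_mask <- mask
    }
  }
  which(bitwAnd(best_mask, bitwShiftL(1L, seq_len(m) - 1L)) != 0L)
}

which_bit <- function(low) as.integer(round(log2(low))) + 1L

# greedy facility location: best-single start, then add/drop local search;
# floor-checked against keeping all candidates open
best_subset_greedy <- function(M, mdl) {
  m <- ncol(M)
  subset_cost <- function(sel) {
    sum(do.call(pmin, as.data.frame(M[, sel, drop = FALSE]))) +
      mdl * length(sel)
  }
  sel <- which.min(colSums(M))
  cur <- subset_cost(sel)
  repeat {
    improved <- FALSE
    for (c in setdiff(seq_len(m), sel)) {
      cand <- c(sel, c)
      cost <- subset_cost(cand)
      if (cost < cur - 1e-12) {
        sel <- cand; cur <- cost; improved <- TRUE
      }
    }
    if (length(sel) > 1L) {
      for (c in sel) {
        cand <- setdiff(sel, c)
        cost <- subset_cost(cand)
        if (cost < cur - 1e-12) {
          sel <- cand; cur <- cost; improved <- TRUE
          break
        }
      }
    }
    if (!improved) break
  }
  if (subset_cost(seq_len(m)) < cur) sel <- seq_len(m)
  sort(sel)
}

finalize_assignment <- function(scene, candidates, M, sel, params) {
  Msel <- M[, sel, drop = FALSE]
  # cheapest selected centre per person; ties -> lowest label id
  pick <- apply(Msel, 1L, which.min)
  used <- sort(unique(pick))
  relabel <- match(pick, used)
  centres <- candidates[sel[used], , drop = FALSE]
  colnames(centres) <- c("u", "v")
  rownames(centres) <- NULL
  labels <- stats::setNames(as.integer(relabel), scene$id)
  a <- structure(list(labels = labels, centres = centres, energy = NA_real_),
                 class = "gcff_assignment")
  a$energy <- scene_cost(scene, a, params)
  a
}

#' @export
print.gcff_assignment <- function(x, ...) {
  cat(sprintf("<gcff_assignment> %d person(s), %d centre(s), energy = %.6g\n",
              length(x$labels), nrow(x$centres), x$energy))
  invisible(x)
}

#' Update o-space centres to the members' mean TS centre
#'
#' For every label in use, proposes a centre at the arithmetic mean of its
#' members' transactional-segment centres (labels with no members emit
#' nothing).  When the visibility constraint is active, the previous centre
#' is kept alongside the new mean as a second proposal, so the next
#' assignment step can always fall back on the old solution and the energy
#' cannot increase even when a mean update raises a member's occlusion
#' penalty.
#'
#' @param scene a [gcff_scene].
#' @param assignment a `gcff_assignment`.
#' @param params a [gcff_params].
#' @return matrix of proposal centres (one or two rows per active label).
#' @export
update_centres <- function(scene, assignment, params) {
  labels <- assignment$labels[scene$id]
  used <- sort(unique(labels))
  mu <- ts_centres(scene, params = params)
  means <- t(vapply(used, function(l) colMeans(mu[labels == l, , drop = FALSE]),
                    numeric(2L)))
  colnames(means) <- c("u", "v")
  if (visibility_active(params)) {
    prev <- assignment$centres[used, , drop = FALSE]
    proposals <- rbind(means, prev)
    proposals <- proposals[!duplicated(round(proposals, 9L)), , drop = FALSE]
    return(proposals)
  }
  means
}

# Candidate centres for the next assignment round: the per-label proposals
# of update_centres() plus one merge proposal per pair of current groups
# whose union looks beneficial.  Re-centring alone can never merge two
# groups whose own centres are mutually too expensive (each person sticks to
# their nearer centre), so without union proposals the pair-merge boundary
# would sit at r = sigma/2 instead of the optimal sigma/sqrt(2).  Merging
# labels g, h onto the mean of their union adds
# n_g n_h / (n_g + n_h) * ||mean_g - mean_h||^2 of squared residual while
# saving one label cost; pairs for which that trade is favourable
# (ignoring visibility, which the assignment step re-checks exactly) get
# their union mean proposed.
propose_centres <- function(scene, assignment, params) {
  base <- update_centres(scene, assignment, params)
  labels <- assignment$labels[scene$id]
  used <- sort(unique(labels))
  k <- length(used)
  if (k < 2L) return(base)
  mu <- ts_centres(scene, params = params)
  sizes <- vapply(used, function(l) sum(labels == l), 1L)
  means <- t(vapply(used, function(l) colMeans(mu[labels == l, , drop = FALSE]),
                    numeric(2L)))
  merges <- NULL
  for (a in seq_len(k - 1L)) {
    for (b in seq.int(a + 1L, k)) {
      dd <- sum((means[a, ] - means[b, ])^2)
      added <- sizes[a] * sizes[b] / (sizes[a] + sizes[b]) * dd
      if (added < params$mdl_weight) {
        merges <- rbind(merges, (sizes[a] * means[a, ] + sizes[b] * means[b, ]) /
                          (sizes[a] + sizes[b]))
      }
    }
  }
  if (is.null(merges)) return(base)
  colnames(merges) <- c("u", "v")
  proposals <- rbind(base, merges)
  proposals[!duplicated(round(proposals, 9L)), , drop = FALSE]
}

# Single-person relocation refinement: try moving each person to every
# other group (or to a fresh singleton), with centres recomputed as block
# means, and accept the first energy-reducing move; sweep until no move
# helps.  Escapes the coordinate-descent local minima that the
# assignment/re-centring alternation cannot leave on its own (a person stuck
# with the wrong group because both group centres are conditionally
# optimal).
refine_partition <- function(scene, assignment, params) {
  n <- nrow(scene)
  labels <- unname(assignment$labels[scene$id])
  mu <- ts_centres(scene, params = params)
  part_assignment <- function(lab) {
    used <- sort(unique(lab))
    relab <- match(lab, used)
    centres <- t(vapply(seq_along(used), function(l) {
      colMeans(mu[relab == l, , drop = FALSE])
    }, numeric(2L)))
    colnames(centres) <- c("u", "v")
    a <- structure(list(labels = stats::setNames(as.integer(relab), scene$id),
                        centres = centres, energy = NA_real_),
                   class = "gcff_assignment")
    a$energy <- scene_cost(scene, a, params)
    a
  }
  # bisect one block by 2-means on member TS centres (farthest-pair seeding)
  split_labels <- function(lab, block) {
    members <- which(lab == block)
    pts <- mu[members, , drop = FALSE]
    dd <- as.matrix(stats::dist(pts))
    if (max(dd) < 1e-12) return(NULL)
    seed <- which(dd == max(dd), arr.ind = TRUE)[1L, ]
    ctr <- pts[seed, , drop = FALSE]
    side <- integer(length(members))
    for (iter in 1:5) {
      d1 <- rowSums(sweep(pts, 2L, ctr[1L, ])^2)
      d2 <- rowSums(sweep(pts, 2L, ctr[2L, ])^2)
      new_side <- ifelse(d2 < d1, 2L, 1L)
      if (identical(new_side, side)) break
      side <- new_side
      if (all(side == side[1L])) return(NULL)
      ctr <- rbind(colMeans(pts[side == 1L, , drop = FALSE]),
                   colMeans(pts[side == 2L, , drop = FALSE]))
    }
    cand <- lab
    cand[members[side == 2L]] <- max(lab) + 1L
    cand
  }
  best <- part_assignment(labels)
  improved_any <- FALSE
  repeat {
    improved <- FALSE
    lab <- unname(best$labels[scene$id])
    # single-person relocation moves
    for (i in seq_len(n)) {
      targets <- c(setdiff(unique(lab), lab[i]),
                   if (sum(lab == lab[i]) > 1L) max(lab) + 1L)
      for (t in targets) {
        cand <- lab
        cand[i] <- t
        a <- part_assignment(cand)
        if (a$energy < best$energy - 1e-9) {
          best <- a
          lab <- unname(a$labels[scene$id])
          improved <- TRUE
          improved_any <- TRUE
          break
        }
      }
    }
    # block bisection moves (relocation alone cannot split a group whose
    # halves each pay more to leave alone than together)
    lab <- unname(best$labels[scene$id])
    for (block in unique(lab)) {
      if (sum(lab == block) < 3L) next
      cand <- split_labels(lab, block)
      if (is.null(cand)) next
      a <- part_assignment(cand)
      if (a$energy < best$energy - 1e-9) {
        best <- a
        lab <- unname(a$labels[scene$id])
        improved <- TRUE
        improved_any <- TRUE
      }
    }
    if (!improved) break
  }
  list(assignment = best, improved = improved_any)
}

#' Detect F-formations in a scene
#'
#' Runs the full detector: every person starts with a private candidate
#' centre at their own transactional-segment centre, then the algorithm
#' alternates between (a) assigning persons to the energy-minimising subset
#' of candidate centres ([assign_labels()]) and (b) re-centring each group on
#' its members' mean TS centre ([update_centres()], enriched with
#' pairwise-merge proposals), until the energy decrease falls below
#' `cost_tol` (relative) or `max_iters` is hit; a single-person relocation
#' refinement then polishes the partition, and the alternation resumes if it
#' improved anything.  The procedure is deterministic and the recorded
#' energies never increase.
#'
#' @param scene a [gcff_scene].
#' @param params a [gcff_params].
#' @return list with `groups` (a [gcff_groups]: labels with >= 2 members as
#'   groups, the rest as singletons), `assignment` (final
#'   `gcff_assignment`), and `trace` (list: `iterations`, `energies`,
#'   `converged`).
#' @examples
#' sc <- gcff_scene(data.frame(id = c("a", "b"), x = c(-110, 110),
#'                             y = 0, theta = c(0, pi)))
#' gcff_detect(sc, gcff_params(stride_D = 110, sigma = 80))$groups
#' @export
gcff_detect <- function(scene, params = gcff_params()) {
  if (nrow(scene) == 0L) {
    empty <- assign_labels(gcff_scene(data.frame(id = character(),
                                                 x = numeric(),
                                                 y = numeric(),
                                                 theta = numeric())),
                           matrix(0, 1L, 2L), params)
    return(list(groups = gcff_groups(), assignment = empty,
                trace = list(iterations = 0L, energies = numeric(0),
                             converged = TRUE)))
  }
  candidates <- ts_centres(scene, params = params)
  energies <- numeric(0)
  prev_energy <- Inf
  converged <- FALSE
  assignment <- NULL
  it <- 0L
  while (it < params$max_iters) {
    it <- it + 1L
    assignment <- assign_labels(scene, candidates, params)
    energies <- c(energies, assignment$energy)
    if (is.finite(prev_energy) &&
        prev_energy - assignment$energy <=
          params$cost_tol * max(1, abs(assignment$energy))) {
      ref <- refine_partition(scene, assignment, params)
      if (ref$improved && it < params$max_iters) {
        assignment <- ref$assignment
        energies <- c(energies, assignment$energy)
        prev_energy <- assignment$energy
        candidates <- propose_centres(scene, assignment, params)
        next
      }
      converged <- TRUE
      break
    }
    prev_energy <- assignment$energy
    candidates <- propose_centres(scene, assignment, params)
  }
  list(groups = assignment_groups(scene, assignment),
       assignment = assignment,
       trace = list(iterations = length(energies), energies = energies,
                    converged = converged))
}

assignment_groups <- function(scene, assignment) {
  labels <- assignment$labels[scene$id]
  split_ids <- split(scene$id, labels)
  sizes <- vapply(split_ids, length, 1L)
  gcff_groups(groups = unname(split_ids[sizes >= 2L]),
              singletons = unlist(split_ids[sizes < 2L], use.names = FALSE))
}
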