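#' Transactional-segment centre of a person
#'
#' The transactional segment is the region in front of the body where sight
#' and hearing are most effective; it is modelled as an isotropic Gaussian
#' whose centre lies one stride `D` ahead of the person along the facing
#' direction: `(x + D cos(theta), y + D sin(theta))`.
#'
#' @param x,y,theta position and head orientation (radians, CCW from +x),
#'   vectorised.
#' @param D stride, > 0.
#' @return matrix with columns `u`, `v`, one row per person.
#' @examples
#' ts_centre(0, 0, pi / 2, D = 30)   # (0, 30)
#' @export
ts_centre <- function(x, y, theta, D) {
  stopifnot(is.numeric(D), length(D) == 1L, D > 0)
  if (length(x) > 0 && (any(!is.finite(x)) || any(!is.finite(y)) ||
                        any(!is.finite(theta)))) {
    stop("non-finite person coordinates", call. = FALSE)
  }
  cbind(u = x + D * cos(theta), v = y + D * sin(theta))
}

#' Transactional-segment centres of a whole scene
#' @param scene a [gcff_scene].
#' @param D stride; defaults to the value in `params` when given.
#' @param params optional [gcff_params] supplying `D`.
#' @return n x 2 matrix of TS centres, rows in scene order.
#' @export
ts_centres <- function(scene, D = NULL, params = NULL) {
  if (is.null(D)) D <- params$stride_D
  ts_centre(scene$x, scene$y, scene$theta, D)
}

#' Unary (least-squares) cost of a person under a candidate centre
#'
#' Squared Euclidean distance between a candidate o-space centre and the
#' person's transactional-segment centre.
#'
#' @param x,y,theta the person's state.
#' @param centre numeric length-2 vector `(u, v)`.
#' @param params a [gcff_params] (supplies the stride).
#' @return squared length (scalar, or vector if the person arguments are
#'   vectorised).
#' @export
unary_cost <- function(x, y, theta, centre, params) {
  mu <- ts_centre(x, y, theta, params$stride_D)
  unname((centre[1L] - mu[, 1L])^2 + (centre[2L] - mu[, 2L])^2)
}

#' Pairwise visibility (occlusion) cost
#'
#' Penalty paid by person `i` for joining a group whose candidate o-space
#' centre is occluded by person `j`: with `d_i`, `d_j` the distances of the
#' two persons' positions from the centre and `theta_ij` the angle they
#' subtend at the centre, the cost is 0 when `d_i <= d_j` (i is not behind
#' j) or `theta_ij >= theta_hat` (angularly well separated), and
#' `exp(K cos(theta_ij)) * (d_i - d_j) / d_j` otherwise.  Always >= 0.
#'
#' @param pi_xy,pj_xy length-2 position vectors of persons `i` and `j`.
#' @param centre length-2 candidate o-space centre.
#' @param params a [gcff_params] (supplies `vis_theta_hat`, `vis_K`).
#' @return dimensionless non-negative penalty.
#' @export
visibility_cost <- function(pi_xy, pj_xy, centre, params) {
  if (!visibility_active(params)) return(0)
  di <- sqrt(sum((pi_xy - centre)^2))
  dj <- sqrt(sum((pj_xy - centre)^2))
  if (di <= dj) return(0)              # ties count as "closer": no occlusion
  if (dj == 0) {
    stop("degenerate geometry: candidate centre coincides with the occluder",
         call. = FALSE)
  }
  cosang <- sum((pi_xy - centre) * (pj_xy - centre)) / (di * dj)
  ang <- acos(min(1, max(-1, cosang)))
  if (ang >= params$vis_theta_hat) return(0)
  exp(params$vis_K * cos(ang)) * (di - dj) / dj
}

# Visibility penalty of every person in the scene under one candidate
# centre, as an n-vector; vectorised over the n x n pair structure.
vis_penalty_vec <- function(pos, centre, params) {
  n <- nrow(pos)
  if (n <= 1L || !visibility_active(params)) return(numeric(n))
  V <- sweep(pos, 2L, centre)
  d <- sqrt(rowSums(V^2))
  behind <- outer(d, d, `>`)           # [i, j]: i strictly farther than j
  if (!any(behind)) return(numeric(n))
  if (any(d == 0)) {
    # someone sits exactly on the centre and occludes everyone farther out
    stop("degenerate geometry: candidate centre coincides with a person",
         call. = FALSE)
  }
  cosang <- (V %*% t(V)) / outer(d, d)
  cosang <- pmin(1, pmax(-1, cosang))
  ang <- acos(cosang)
  occluded <- behind & (ang < params$vis_theta_hat)
  if (!any(occluded)) return(numeric(n))
  pen <- exp(params$vis_K * cosang) * (outer(d, d, `-`) / rep(d, each = n))
  rowSums(ifelse(occluded, pen, 0))
}

#' Total visibility penalty of one person under a candidate centre
#'
#' Sum over all other persons `j` of [visibility_cost()]; depends only on
#' the person, the scene and the centre, so it acts as a unary term in the
#' assignment step.
#'
#' @param i index (row) of the person within `scene`.
#' @param scene a [gcff_scene].
#' @param centre length-2 candidate centre.
#' @param params a [gcff_params].
#' @return non-negative scalar.
#' @export
person_visibility_penalty <- function(i, scene, centre, params) {
  pos <- cbind(scene$x, scene$y)
  vis_penalty_vec(pos, centre, params)[i]
}

#' Total energy of an assignment
#'
#' The objective minimised by the detector:
#' sum of per-person squared residuals to their group's o-space centre,
#' plus `mdl_weight` per distinct group in use, plus the visibility
#' penalties of every person under their own group's centre.
#'
#' @param scene a [gcff_scene].
#' @param assignment a `gcff_assignment` (see [assign_labels()]): fields
#'   `labels` (named integer vector, person id -> label) and `centres`
#'   (k x 2 matrix, row l = centre of label l).
#' @param params a [gcff_params].
#' @return scalar energy (length squared units).
#' @export
scene_cost <- function(scene, assignment, params) {
  n <- nrow(scene)
  if (n == 0L) return(0)
  labels <- assignment$labels[scene$id]
  if (any(is.na(labels))) {
    stop("assignment does not cover every person in the scene", call. = FALSE)
  }
  centres <- assignment$centres
  used <- sort(unique(labels))
  if (any(used > nrow(centres)) || any(used < 1L)) {
    stop("inconsistent assignment: person carries a label with no centre",
         call. = FALSE)
  }
  mu <- ts_centres(scene, params = params)
  resid2 <- rowSums((mu - centres[labels, , drop = FALSE])^2)
  vis <- 0
  if (visibility_active(params)) {
    pos <- cbind(scene$x, scene$y)
    for (l in used) {
      members <- which(labels == l)
      vis <- vis + sum(vis_penalty_vec(pos, centres[l, ], params)[members])
    }
  }
  sum(resid2) + params$mdl_weight * length(used) + vis
}
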