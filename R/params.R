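#' Model parameters for F-formation detection
#'
#' Bundles the tunable parameters of the o-space model.  The stride `D` is
#' the distance from a person to the centre of their transactional segment;
#' `sigma` is the standard deviation of the isotropic Gaussian modelling that
#' segment, and doubles as the scale of the minimum-description-length (MDL)
#' penalty per group: the default label cost is `sigma^2`, so two people
#' merge into one group exactly when the squared residuals the merge adds
#' stay below the `sigma^2` saved by dropping a label.
#'
#' The visibility (occlusion) term penalises a person `i` whose path to a
#' candidate o-space centre is blocked by a nearer person `j`: the penalty
#' `exp(K * cos(theta_ij)) * (d_i - d_j) / d_j` applies when the angle
#' `theta_ij` subtended at the centre is below `vis_theta_hat` and `i` is
#' farther than `j`.  Set `vis_K = 0` together with `vis_theta_hat = 0` to
#' disable it entirely, or just `vis_theta_hat = 0` (empty window).
#'
#' @param stride_D stride, in the scene's length unit (cm or px); > 0.
#' @param sigma transactional-segment standard deviation, same unit; > 0.
#' @param vis_theta_hat occlusion angular window, radians in \[0, pi\].
#' @param vis_K occlusion sharpness gain, dimensionless, >= 0.
#' @param max_iters maximum assignment/update alternations.
#' @param cost_tol relative energy-decrease threshold declaring convergence.
#' @param mdl_weight per-group label cost (length squared); defaults to
#'   `sigma^2`.
#' @return object of class `gcff_params`.
#' @examples
#' p <- gcff_params(stride_D = 30, sigma = 80)   # Synthetic-style settings
#' @export
gcff_params <- function(stride_D = 30, sigma = 80,
                        vis_theta_hat = pi / 6, vis_K = 1,
                        max_iters = 100L, cost_tol = 1e-9,
                        mdl_weight = NULL) {
  stopifnot(is.numeric(stride_D), length(stride_D) == 1L, stride_D > 0,
            is.numeric(sigma), length(sigma) == 1L, sigma > 0,
            is.numeric(vis_theta_hat), length(vis_theta_hat) == 1L,
            vis_theta_hat >= 0, vis_theta_hat <= pi,
            is.numeric(vis_K), length(vis_K) == 1L, vis_K >= 0,
            max_iters >= 1, cost_tol >= 0)
  if (is.null(mdl_weight)) mdl_weight <- sigma^2
  stopifnot(is.numeric(mdl_weight), length(mdl_weight) == 1L, mdl_weight > 0)
  structure(list(stride_D = stride_D, sigma = sigma,
                 vis_theta_hat = vis_theta_hat, vis_K = vis_K,
                 max_iters = as.integer(max_iters), cost_tol = cost_tol,
                 mdl_weight = mdl_weight),
            class = "gcff_params")
}

#' @export
print.gcff_params <- function(x, ...) {
  cat(sprintf(paste0("<gcff_params> D = %g, sigma = %g (mdl = %g), ",
                     "theta_hat = %.4g rad, K = %g\n"),
              x$stride_D, x$sigma, x$mdl_weight, x$vis_theta_hat, x$vis_K))
  invisible(x)
}

visibility_active <- function(params) {
  params$vis_K > 0 && params$vis_theta_hat > 0
}
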