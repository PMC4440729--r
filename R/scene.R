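#' Build a scene (one frame of proxemic data)
#'
#' A scene is the per-frame input of the detector: one row per person with a
#' ground-plane position and a head orientation.  Orientations are stored in
#' radians, counter-clockwise from the +x axis, normalised to (-pi, pi].
#'
#' @param persons data frame with columns `id`, `x`, `y`, `theta`.  `id` is
#'   coerced to character and must be unique; `x`, `y`, `theta` must be finite
#'   numerics.
#' @param unit length unit of `x` and `y`, `"cm"` (default) or `"px"`.
#' @param truth optional ground-truth [gcff_groups] partition of the ids.
#' @return object of class `gcff_scene`: a data frame with attributes `unit`
#'   and `truth`.
#' @examples
#' sc <- gcff_scene(data.frame(id = c("a", "b"),
#'                             x = c(0, 120), y = c(0, 0),
#'                             theta = c(0, pi)))
#' @export
gcff_scene <- function(persons, unit = "cm", truth = NULL) {
  stopifnot(is.data.frame(persons))
  required <- c("id", "x", "y", "theta")
  missing_cols <- setdiff(required, names(persons))
  if (length(missing_cols) > 0L) {
    stop("scene is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  persons <- as.data.frame(persons)[required]
  persons$id <- as.character(persons$id)
  for (col in c("x", "y", "theta")) {
    v <- persons[[col]]
    if (!is.numeric(v)) {
      stop("scene column '", col, "' must be numeric", call. = FALSE)
    }
    if (nrow(persons) > 0L && any(!is.finite(v))) {
      stop("scene column '", col, "' contains non-finite values", call. = FALSE)
    }
  }
  if (anyDuplicated(persons$id)) {
    stop("duplicate person ids within the scene: ",
         paste(unique(persons$id[duplicated(persons$id)]), collapse = ", "),
         call. = FALSE)
  }
  unit <- match.arg(unit, c("cm", "px"))
  persons$theta <- norm_angle(persons$theta)
  if (!is.null(truth)) {
    truth <- as_gcff_groups(truth)
    truth_ids <- c(unlist(truth$groups, use.names = FALSE), truth$singletons)
    if (!setequal(truth_ids, persons$id)) {
      stop("ground-truth groups do not partition the scene's person ids",
           call. = FALSE)
    }
  }
  rownames(persons) <- NULL
  structure(persons, unit = unit, truth = truth,
            class = c("gcff_scene", "data.frame"))
}

#' @export
print.gcff_scene <- function(x, ...) {
  cat(sprintf("<gcff_scene> %d person(s), unit = %s%s\n",
              nrow(x), attr(x, "unit"),
              if (is.null(attr(x, "truth"))) "" else ", with ground truth"))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Ground truth attached to a scene
#' @param scene a [gcff_scene].
#' @return the [gcff_groups] ground truth, or `NULL`.
#' @export
scene_truth <- function(scene) attr(scene, "truth")

#' Normalise angles to (-pi, pi]
#' @param a numeric vector of angles in radians.
#' @return angles wrapped into (-pi, pi].
#' @export
norm_angle <- function(a) {
  r <- a %% (2 * pi)
  r[r > pi] <- r[r > pi] - 2 * pi
  r
}

#' Build a group set (partition into groups and singletons)
#'
#' A group set partitions the person ids of a frame into conversational
#' groups (cardinality >= 2) and singletons.  Lone individuals are never
#' counted as groups: detectors report them separately and the evaluation
#' metrics ignore them.
#'
#' @param groups list of character vectors, each of length >= 2.
#' @param singletons character vector of ids not in any group.
#' @return object of class `gcff_groups`.
#' @export
gcff_groups <- function(groups = list(), singletons = character()) {
  groups <- lapply(groups, function(g) sort(unique(as.character(g))))
  singletons <- sort(unique(as.character(singletons)))
  if (any(vapply(groups, length, 1L) < 2L)) {
    stop("every group must have cardinality >= 2 (use singletons for lone ids)",
         call. = FALSE)
  }
  all_ids <- c(unlist(groups, use.names = FALSE), singletons)
  if (anyDuplicated(all_ids)) {
    stop("groups and singletons must be disjoint (id appears twice): ",
         paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "),
         call. = FALSE)
  }
  # canonical order: by first member id, for deterministic serialisation
  if (length(groups) > 1L) {
    groups <- groups[order(vapply(groups, `[`, "", 1L))]
  }
  structure(list(groups = groups, singletons = singletons),
            class = "gcff_groups")
}

as_gcff_groups <- function(x) {
  if (inherits(x, "gcff_groups")) return(x)
  if (is.list(x) && !is.null(x$groups)) {
    return(gcff_groups(x$groups, x$singletons %||% character()))
  }
  stop("cannot interpret object as gcff_groups", call. = FALSE)
}

#' @export
print.gcff_groups <- function(x, ...) {
  cat(sprintf("<gcff_groups> %d group(s), %d singleton(s)\n",
              length(x$groups), length(x$singletons)))
  for (g in x$groups) cat("  {", paste(g, collapse = ", "), "}\n")
  if (length(x$singletons) > 0L) {
    cat("  singletons:", paste(x$singletons, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
format.gcff_groups <- function(x, ...) {
  paste0("{", vapply(x$groups, paste, "", collapse = ","), "}",
         collapse = " ")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
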