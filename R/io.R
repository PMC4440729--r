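#' Read per-frame proxemic data
#'
#' Canonical JSON schema:
#' ```
#' {"unit": "cm", "frames": [{"id": "f1",
#'    "persons": [{"id": "p1", "x": 0, "y": 0, "theta": 0}, ...],
#'    "groups": [["p1","p2"], ...]}]}
#' ```
#' `groups` is optional ground truth (cardinality >= 2 only; remaining ids
#' become singletons).  CSV input is one row per person with columns
#' `frame_id, person_id, x, y, theta`; ground truth, if any, lives in a
#' sibling file `<stem>_groups.csv` with columns
#' `frame_id, group_index, person_id`.
#'
#' A `.mat` reader for the published ground-plane datasets is not provided;
#' convert such data to the JSON or CSV layout above (per frame: person ids,
#' ground-plane x/y, orientation in radians, plus the annotated group
#' lists).  Requesting `format = "mat"` raises an error saying so.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"json"` or `"csv"`.
#' @param degrees if `TRUE`, `theta` is converted from degrees to radians on
#'   ingest (the stored representation is always radians).
#' @return object of class `gcff_frames`: list with `ids` (frame ids) and
#'   `frames` (list of [gcff_scene]).
#' @export
read_scenes <- function(path, format = c("auto", "json", "csv", "mat"),
                        degrees = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     json = "json", csv = "csv", mat = "mat",
                     stop("cannot infer format from extension of ", path,
                          call. = FALSE))
  }
  if (format == "mat") {
    stop("reading .mat files is not supported; export the per-frame person ",
         "states and group lists to the documented JSON or CSV layout ",
         "(see ?read_scenes)", call. = FALSE)
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  switch(format,
         json = read_scenes_json(path, degrees = degrees),
         csv = read_scenes_csv(path, degrees = degrees))
}

new_gcff_frames <- function(ids, frames, unit) {
  if (anyDuplicated(ids)) {
    stop("duplicate frame ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  structure(list(ids = as.character(ids), frames = frames, unit = unit),
            class = "gcff_frames")
}

#' @export
print.gcff_frames <- function(x, ...) {
  cat(sprintf("<gcff_frames> %d frame(s), unit = %s\n",
              length(x$frames), x$unit))
  invisible(x)
}

read_scenes_json <- function(path, degrees = FALSE) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  unit <- doc$unit %||% "cm"
  frames <- lapply(doc$frames, function(fr) {
    persons <- fr$persons %||% list()
    df <- data.frame(
      id = vapply(persons, function(p) as.character(p$id %||%
        stop("person record lacks field 'id'", call. = FALSE)), ""),
      x = vapply(persons, function(p) num_field(p, "x"), 0),
      y = vapply(persons, function(p) num_field(p, "y"), 0),
      theta = vapply(persons, function(p) num_field(p, "theta"), 0))
    if (degrees) df$theta <- df$theta * pi / 180
    truth <- NULL
    if (!is.null(fr$groups)) {
      groups <- lapply(fr$groups, function(g) unlist(g, use.names = FALSE))
      truth <- gcff_groups(groups,
                           setdiff(df$id, unlist(groups, use.names = FALSE)))
    }
    gcff_scene(df, unit = unit, truth = truth)
  })
  ids <- vapply(doc$frames, function(fr) as.character(fr$id %||%
    stop("frame record lacks field 'id'", call. = FALSE)), "")
  new_gcff_frames(ids, frames, unit)
}

num_field <- function(p, name) {
  v <- p[[name]]
  if (is.null(v) || !is.numeric(v)) {
    stop("person record lacks numeric field '", name, "'", call. = FALSE)
  }
  as.numeric(v)
}

read_scenes_csv <- function(path, degrees = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(frame_id = "character",
                                       person_id = "character"))
  required <- c("frame_id", "person_id", "x", "y", "theta")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("CSV is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("x", "y", "theta")) {
    if (!is.numeric(df[[col]])) {
      stop("CSV column '", col, "' must be numeric", call. = FALSE)
    }
  }
  gpath <- groups_sibling_path(path)
  gdf <- NULL
  if (file.exists(gpath)) {
    gdf <- utils::read.csv(gpath, stringsAsFactors = FALSE,
                           colClasses = c(frame_id = "character",
                                          person_id = "character"))
  }
  if (degrees) df$theta <- df$theta * pi / 180
  ids <- unique(df$frame_id)
  frames <- lapply(ids, function(fid) {
    sub <- df[df$frame_id == fid, ]
    truth <- NULL
    if (!is.null(gdf)) {
      gsub <- gdf[gdf$frame_id == fid, ]
      groups <- unname(split(gsub$person_id, gsub$group_index))
      truth <- gcff_groups(groups,
                           setdiff(sub$person_id,
                                   unlist(groups, use.names = FALSE)))
    }
    gcff_scene(data.frame(id = sub$person_id, x = sub$x, y = sub$y,
                          theta = sub$theta), truth = truth)
  })
  new_gcff_frames(ids, frames, "cm")
}

groups_sibling_path <- function(path) {
  sub("\\.csv$", "_groups.csv", path, ignore.case = TRUE)
}

#' Write per-frame proxemic data
#'
#' Inverse of [read_scenes()]; the JSON writer is canonical, so writing,
#' reading and writing again yields byte-identical output.
#'
#' @param frames a `gcff_frames` object, or a plain list of [gcff_scene]
#'   (frame ids then default to `"f1"`, `"f2"`, ...).
#' @param path output file.
#' @param format `"auto"` (by extension), `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_scenes <- function(frames, path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     json = "json", csv = "csv",
                     stop("cannot infer format from extension of ", path,
                          call. = FALSE))
  }
  frames <- as_gcff_frames(frames)
  switch(format,
         json = write_scenes_json(frames, path),
         csv = write_scenes_csv(frames, path))
  invisible(path)
}

as_gcff_frames <- function(frames) {
  if (inherits(frames, "gcff_frames")) return(frames)
  if (inherits(frames, "gcff_scene")) frames <- list(frames)
  if (is.list(frames) && all(vapply(frames, inherits, TRUE, "gcff_scene"))) {
    unit <- if (length(frames) > 0L) attr(frames[[1L]], "unit") else "cm"
    return(new_gcff_frames(paste0("f", seq_along(frames)), frames, unit))
  }
  stop("cannot interpret object as gcff_frames", call. = FALSE)
}

write_scenes_json <- function(frames, path) {
  doc <- list(
    unit = frames$unit,
    frames = lapply(seq_along(frames$frames), function(i) {
      sc <- frames$frames[[i]]
      fr <- list(id = frames$ids[i],
                 persons = lapply(seq_len(nrow(sc)), function(r) {
                   list(id = sc$id[r], x = sc$x[r], y = sc$y[r],
                        theta = sc$theta[r])
                 }))
      truth <- scene_truth(sc)
      if (!is.null(truth)) fr$groups <- truth$groups
      fr
    }))
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                              pretty = FALSE),
             path)
}

write_scenes_csv <- function(frames, path) {
  rows <- do.call(rbind, lapply(seq_along(frames$frames), function(i) {
    sc <- frames$frames[[i]]
    if (nrow(sc) == 0L) return(NULL)
    data.frame(frame_id = frames$ids[i], person_id = sc$id,
               x = sc$x, y = sc$y, theta = sc$theta)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  grows <- do.call(rbind, lapply(seq_along(frames$frames), function(i) {
    truth <- scene_truth(frames$frames[[i]])
    if (is.null(truth) || length(truth$groups) == 0L) return(NULL)
    do.call(rbind, lapply(seq_along(truth$groups), function(g) {
      data.frame(frame_id = frames$ids[i], group_index = g,
                 person_id = truth$groups[[g]])
    }))
  }))
  if (!is.null(grows)) {
    utils::write.csv(grows, groups_sibling_path(path), row.names = FALSE)
  }
  invisible(path)
}

#' Read / write detection results (group lists per frame)
#'
#' Detection output schema:
#' `{"frames": [{"id": "f1", "groups": [["p1","p2"]], "singletons": ["p3"]}]}`.
#'
#' @param x named list of [gcff_groups] (names = frame ids).
#' @param path file path.
#' @return `read_groups`: named list of [gcff_groups]; `write_groups`:
#'   `path`, invisibly.
#' @export
write_groups <- function(x, path) {
  doc <- list(frames = lapply(names(x), function(fid) {
    g <- as_gcff_groups(x[[fid]])
    list(id = fid, groups = g$groups, singletons = g$singletons)
  }))
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' @rdname write_groups
#' @export
read_groups <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  out <- lapply(doc$frames, function(fr) {
    gcff_groups(lapply(fr$groups, function(g) unlist(g, use.names = FALSE)),
                unlist(fr$singletons, use.names = FALSE) %||% character())
  })
  names(out) <- vapply(doc$frames, function(fr) as.character(fr$id), "")
  out
}
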