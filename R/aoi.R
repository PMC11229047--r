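#' Construct an AOI layout
#'
#' An AOI (area of interest) layout discretises the unwrapped room-wall
#' surface into labelled polygons. Two kinds of AOI are supported:
#' `"segment"` AOIs, the ordered wall segments used as the alphabet for
#' gaze-transition entropy, and `"target"` AOIs, the regions where threat
#' targets appear (used for time-to-first-target). Segment AOIs can
#' additionally carry the role tags `"near_corner"` (wall segments adjacent
#' to the entry door) and `"back_wall"` (segments on the wall opposite the
#' door), which drive the search-order compliance measure.
#'
#' Coordinates are 2D angular positions on the unwrapped wall surface:
#' `az_deg` runs around the room (the door sits at the two ends of the
#' strip) and `el_deg` is elevation. Both are in degrees.
#'
#' @param vertices A data frame with one row per polygon vertex, columns
#'   `aoi_id` (character), `kind` (`"segment"` or `"target"`), `az_deg`,
#'   `el_deg`. Vertices of each polygon must be listed in order.
#' @param roles A data frame with columns `aoi_id`, `role` tagging segment
#'   AOIs with `"near_corner"` or `"back_wall"`. May be empty.
#' @param entry_point Numeric length-2, the (az, el) reference point of the
#'   door/entry, in degrees.
#'
#' @return An object of class `aoi_layout`: a list with elements
#'   `vertices` (tibble), `roles` (tibble), `entry_point`, and `aoi_ids`
#'   (segment ids in wall order).
#' @seealso [room_layout()] for the default 12-segment room.
#' @export
aoi_layout <- function(vertices, roles = NULL, entry_point = c(180, 0)) {
  vertices <- tibble::as_tibble(vertices)
  required <- c("aoi_id", "kind", "az_deg", "el_deg")
  missing_cols <- setdiff(required, names(vertices))
  if (length(missing_cols) > 0) {
    stop("aoi_layout vertices missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!all(vertices$kind %in% c("segment", "target"))) {
    stop("AOI kind must be 'segment' or 'target'", call. = FALSE)
  }
  seg_ids <- unique(vertices$aoi_id[vertices$kind == "segment"])
  if (length(seg_ids) < 2) {
    stop("invalid layout: at least 2 segment AOIs are required", call. = FALSE)
  }
  n_vert <- table(vertices$aoi_id)
  if (any(n_vert < 3)) {
    stop("every AOI polygon needs at least 3 vertices", call. = FALSE)
  }
  if (is.null(roles)) {
    roles <- tibble::tibble(aoi_id = character(), role = character())
  }
  roles <- tibble::as_tibble(roles)
  if (nrow(roles) > 0) {
    unknown <- setdiff(roles$aoi_id, unique(vertices$aoi_id))
    if (length(unknown) > 0) {
      stop("role tags reference unknown AOI id(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  structure(
    list(
      vertices = vertices,
      roles = roles,
      entry_point = as.numeric(entry_point),
      aoi_ids = seg_ids
    ),
    class = "aoi_layout"
  )
}

#' Default 12-segment room-wall layout
#'
#' Builds the canonical room discretisation: the four walls are unwrapped
#' into an azimuth strip spanning `[-180, 180]` degrees with the entry door
#' at the two ends, divided into `n_segments` equal-width segment AOIs
#' numbered left to right from the door (segment 1 is the first area on the
#' left just inside the door; segment `n_segments` the last area on the
#' right, by the door). The outermost segments on each side are tagged
#' `near_corner` and the central segments (the wall opposite the door) are
#' tagged `back_wall`. Target AOIs are smaller boxes centred inside chosen
#' segments.
#'
#' @param n_segments Number of wall segments (default 12).
#' @param el_range Elevation extent of the wall segments, degrees.
#' @param target_segments Integer vector: segments that contain a target
#'   region. Targets are named `"T1"`, `"T2"`, ...
#' @param target_halfwidth,target_halfheight Half-extent of each target box
#'   in degrees.
#' @param n_near_corner Number of segments at each end tagged `near_corner`.
#' @param n_back_wall Number of central segments tagged `back_wall`.
#' @return An [aoi_layout()] object.
#' @examples
#' lay <- room_layout()
#' lay$aoi_ids
#' @export
room_layout <- function(n_segments = 12,
                        el_range = c(-25, 25),
                        target_segments = c(3, 7, 10),
                        target_halfwidth = 5,
                        target_halfheight = 8,
                        n_near_corner = 1,
                        n_back_wall = 2) {
  stopifnot(n_segments >= 2)
  edges <- seq(-180, 180, length.out = n_segments + 1)
  seg_vert <- purrr::map_dfr(seq_len(n_segments), function(i) {
    tibble::tibble(
      aoi_id = as.character(i),
      kind = "segment",
      az_deg = c(edges[i], edges[i + 1], edges[i + 1], edges[i]),
      el_deg = c(el_range[1], el_range[1], el_range[2], el_range[2])
    )
  })
  centres <- (edges[-1] + edges[-length(edges)]) / 2
  tgt_vert <- purrr::imap_dfr(target_segments, function(seg, k) {
    cx <- centres[seg]
    tibble::tibble(
      aoi_id = paste0("T", k),
      kind = "target",
      az_deg = cx + c(-1, 1, 1, -1) * target_halfwidth,
      el_deg = c(-1, -1, 1, 1) * target_halfheight
    )
  })
  near <- c(seq_len(n_near_corner), n_segments + 1 - seq_len(n_near_corner))
  mid <- (n_segments + 1) / 2
  back <- order(abs(seq_len(n_segments) - mid))[seq_len(n_back_wall)]
  roles <- dplyr::bind_rows(
    tibble::tibble(aoi_id = as.character(sort(near)), role = "near_corner"),
    tibble::tibble(aoi_id = as.character(sort(back)), role = "back_wall")
  )
  aoi_layout(dplyr::bind_rows(seg_vert, tgt_vert), roles,
             entry_point = c(180, 0))
}

#' @export
print.aoi_layout <- function(x, ...) {
  n_seg <- length(x$aoi_ids)
  n_tgt <- length(unique(x$vertices$aoi_id[x$vertices$kind == "target"]))
  cat("<aoi_layout> ", n_seg, " segments, ", n_tgt, " targets\n", sep = "")
  if (nrow(x$roles) > 0) {
    for (r in unique(x$roles$role)) {
      cat("  ", r, ": ",
          paste(x$roles$aoi_id[x$roles$role == r], collapse = ", "),
          "\n", sep = "")
    }
  }
  invisible(x)
}

# Polygons of a layout as a named list of (az, el) matrices, segments first
# in wall order, then targets. Assignment tie-breaks rely on this ordering.
layout_polygons <- function(layout, kind = c("segment", "target")) {
  v <- layout$vertices[layout$vertices$kind %in% kind, , drop = FALSE]
  ids <- unique(v$aoi_id)
  seg_first <- c(intersect(layout$aoi_ids, ids), setdiff(ids, layout$aoi_ids))
  purrr::map(rlang::set_names(seg_first), function(id) {
    vi <- v[v$aoi_id == id, , drop = FALSE]
    cbind(az = vi$az_deg, el = vi$el_deg)
  })
}

role_ids <- function(layout, role) {
  layout$roles$aoi_id[layout$roles$role == role]
}

#' Map gaze points to AOI labels
#'
#' Assigns each point to the AOI polygon containing it. Points on a shared
#' boundary go to the lower-numbered (earlier-ordered) AOI; when
#' `prefer_targets = TRUE`, target polygons take precedence over any segment
#' they overlap. Points outside all polygons get `NA`.
#'
#' @param az,el Numeric vectors of angular positions, degrees.
#' @param layout An [aoi_layout()].
#' @param kind Which AOI kinds to match against.
#' @param prefer_targets If `TRUE`, a point inside both a target and a
#'   segment is labelled with the target.
#' @return Character vector of AOI ids (`NA` where outside all polygons).
#' @export
match_aoi <- function(az, el, layout, kind = "segment",
                      prefer_targets = FALSE) {
  polys <- layout_polygons(layout, kind = kind)
  if (prefer_targets) {
    tgt <- names(polys)[!(names(polys) %in% layout$aoi_ids)]
    polys <- polys[c(tgt, setdiff(names(polys), tgt))]
  }
  out <- rep(NA_character_, length(az))
  todo <- is.finite(az) & is.finite(el)
  for (id in names(polys)) {
    if (!any(todo)) break
    p <- polys[[id]]
    inside <- pracma::inpolygon(az[todo], el[todo], p[, 1], p[, 2],
                                boundary = TRUE)
    hit <- which(todo)[inside]
    out[hit] <- id
    todo[hit] <- FALSE
  }
  out
}

#' Label fixations with their AOI
#'
#' Adds (or overwrites) an `aoi_id` column on a fixation table by locating
#' each fixation centroid in the layout.
#'
#' @param fixations A data frame of fixation events with columns `az_deg`,
#'   `el_deg` (centroid position).
#' @param layout An [aoi_layout()].
#' @param prefer_targets Passed to [match_aoi()]; when `TRUE`, fixations in
#'   a target region are labelled with the target id rather than the
#'   surrounding segment.
#' @return The fixation tibble with an `aoi_id` character column.
#' @export
assign_aois <- function(fixations, layout, prefer_targets = FALSE) {
  fixations <- tibble::as_tibble(fixations)
  kinds <- if (prefer_targets) c("segment", "target") else "segment"
  fixations$aoi_id <- match_aoi(fixations$az_deg, fixations$el_deg, layout,
                                kind = kinds,
                                prefer_targets = prefer_targets)
  fixations
}
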