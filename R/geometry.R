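#' Construct one face of a digitized tool
#'
#' A face holds the digitized outline of one side of a flaked stone tool
#' (dorsal or ventral), the platform anchor marking the proximal striking
#' surface, and the traced edge-damage scar polygons for that face.
#'
#' @param outline closed simple polygon (n x 2 matrix or data frame) tracing
#'   the tool perimeter in planar coordinates; units are arbitrary.
#' @param platform_anchor length-2 numeric, a point on (or within 2% of the
#'   perimeter of) the outline marking the platform midpoint.
#' @param scars list of damage scars; each scar is a list with elements
#'   `ring` (polygon matrix) and `damage_class` (character, e.g. "crushing",
#'   "snap", "rounded").
#' @return an object of class `edd_face`.
#' @export
edd_face <- function(outline, platform_anchor, scars = list()) {
  ring <- as_ring(outline)
  if (nrow(ring) < 3L) stop("outline must have at least 3 vertices")
  if (abs(ring_area(ring)) < 1e-12) stop("degenerate outline: zero area")
  anchor <- as.numeric(platform_anchor)
  if (length(anchor) != 2L) stop("platform_anchor must be a single 2D point")
  scars <- lapply(scars, function(s) {
    if (is.list(s) && !is.null(s$ring)) {
      list(ring = as_ring(s$ring),
           damage_class = if (is.null(s$damage_class)) NA_character_ else s$damage_class)
    } else {
      list(ring = as_ring(s), damage_class = NA_character_)
    }
  })
  structure(list(outline = ring, platform_anchor = anchor, scars = scars),
            class = "edd_face")
}

#' Construct a tool record
#'
#' Bundles the dorsal and ventral faces of a digitized tool with its
#' identifying metadata. Both faces are required to build the 400-position
#' damage vector.
#'
#' @param tool_id character identifier.
#' @param dorsal,ventral `edd_face` objects.
#' @param assemblage_label,raw_material character metadata.
#' @return an object of class `edd_tool`.
#' @export
edd_tool <- function(tool_id, dorsal, ventral,
                     assemblage_label = NA_character_,
                     raw_material = NA_character_) {
  stopifnot(inherits(dorsal, "edd_face"), inherits(ventral, "edd_face"))
  structure(list(tool_id = as.character(tool_id),
                 assemblage_label = as.character(assemblage_label),
                 raw_material = as.character(raw_material),
                 faces = list(dorsal = dorsal, ventral = ventral)),
            class = "edd_tool")
}

#' @export
print.edd_tool <- function(x, ...) {
  n_scars <- vapply(x$faces, function(f) length(f$scars), integer(1))
  cat("<edd_tool> ", x$tool_id,
      " (", x$assemblage_label, ", ", x$raw_material, ")\n",
      "  dorsal: ", nrow(x$faces$dorsal$outline), " outline vertices, ",
      n_scars[["dorsal"]], " scars\n",
      "  ventral: ", nrow(x$faces$ventral$outline), " outline vertices, ",
      n_scars[["ventral"]], " scars\n", sep = "")
  invisible(x)
}

#' Split a tool face perimeter into left and right platform-to-tip edges
#'
#' The tip (distal maximum) is the outline vertex at maximum Euclidean
#' distance from the platform anchor. The perimeter is split at the anchor
#' and at the tip; with the ring oriented counterclockwise, the arc running
#' counterclockwise from platform to tip is labelled "left" and the opposite
#' arc "right". Both arcs are returned in platform-to-tip vertex order. Ties
#' for the tip (equal maximum distance) are broken in favour of the vertex
#' with the smaller counterclockwise arc distance from the anchor, with a
#' warning.
#'
#' @param face_outline closed simple polygon (matrix/data frame) or an
#'   `edd_face` (its outline and anchor are used).
#' @param platform_anchor point marking the platform; ignored when
#'   `face_outline` is an `edd_face`. Snapped to the nearest boundary point
#'   when within `snap_tol` of the perimeter length, otherwise rejected.
#' @param snap_tol anchor snapping tolerance as a fraction of the perimeter
#'   (default 0.02).
#' @return list with elements `left` and `right`, each an `edd_edge` with
#'   fields `side`, `vertices` (platform to tip), `total_length` and
#'   `face_perimeter`.
#' @export
split_edges <- function(face_outline, platform_anchor = NULL, snap_tol = 0.02) {
  if (inherits(face_outline, "edd_face")) {
    platform_anchor <- face_outline$platform_anchor
    face_outline <- face_outline$outline
  }
  ring <- as_ring(face_outline)
  if (nrow(ring) < 3L) stop("degenerate polygon: fewer than 3 vertices")
  if (abs(ring_area(ring)) < 1e-12) stop("degenerate polygon: zero area")
  if (!ring_is_simple(ring)) stop("outline polygon is self-intersecting")
  ring <- ensure_ccw(ring)
  perim <- ring_perimeter(ring)

  anchor <- as.numeric(platform_anchor)
  near <- nearest_on_ring(ring, anchor)
  if (near$dist > snap_tol * perim) {
    stop(sprintf("platform anchor is %.3g units from the outline (> %.3g, %g%% of perimeter)",
                 near$dist, snap_tol * perim, 100 * snap_tol))
  }
  anchor <- near$point

  # rebuild the ring starting at the (possibly inserted) anchor point
  n <- nrow(ring)
  idx_after <- ((seq_len(n) + near$seg - 1L) %% n) + 1L  # seg+1, ..., seg (CCW)
  if (near$t <= 1e-12) {
    # anchor coincides with the segment's start vertex: rotate so it leads
    ring2 <- ring[((seq_len(n) + near$seg - 2L) %% n) + 1L, , drop = FALSE]
  } else if (near$t >= 1 - 1e-12) {
    # anchor coincides with the segment's end vertex
    ring2 <- ring[idx_after, , drop = FALSE]
  } else {
    ring2 <- rbind(anchor, ring[idx_after, , drop = FALSE])
  }

  # tip: vertex of the rebuilt ring farthest from the anchor (excluding the
  # anchor itself); counterclockwise arc distance breaks exact ties
  cum <- polyline_cumlen(rbind(ring2, ring2[1L, ]))
  d <- sqrt((ring2[, 1L] - anchor[1L])^2 + (ring2[, 2L] - anchor[2L])^2)
  dmax <- max(d)
  tied <- which(d >= dmax * (1 - 1e-9))
  if (length(tied) > 1L) {
    warning("ambiguous tip: multiple vertices at maximum distance from the platform; ",
            "using the one closest along the counterclockwise perimeter")
  }
  tip_i <- tied[which.min(cum[tied])]

  m <- nrow(ring2)
  left_idx <- seq_len(tip_i)                         # anchor -> tip, CCW
  right_idx <- c(seq(tip_i, m), 1L)                  # tip -> anchor, CCW
  left_v <- ring2[left_idx, , drop = FALSE]
  right_v <- ring2[rev(right_idx), , drop = FALSE]   # reorder platform -> tip

  mk <- function(v, side) {
    cl <- polyline_cumlen(v)
    structure(list(side = side, vertices = v,
                   total_length = cl[length(cl)],
                   cum_lengths = cl,
                   face_perimeter = perim),
              class = "edd_edge")
  }
  left <- mk(left_v, "left")
  right <- mk(right_v, "right")
  if (left$total_length <= 0 || right$total_length <= 0) {
    stop("degenerate edge arc of zero length (tip coincides with platform?)")
  }
  list(left = left, right = right)
}

#' Map an arc-length span to standardized 1..100 edge positions
#'
#' Positions are nearest-percent labels: position i covers arc-length
#' percents [i - 0.5, i + 0.5), with position 1 extended down to 0 and
#' position 100 up to 100. A span marks every position whose bin it overlaps
#' with positive length, so a 3%-long scar centered at 50% marks exactly
#' positions 49, 50 and 51.
#'
#' @param a,b span endpoints in percent of total edge length, 0 <= a <= b <= 100.
#' @return integer vector of positions in 1..100.
#' @export
span_to_positions <- function(a, b, eps = 1e-7) {
  if (b < a) { tmp <- a; a <- b; b <- tmp }
  a <- max(0, a); b <- min(100, b)
  if (b - a <= eps) return(integer(0))
  i <- seq_len(100L)
  lo <- pmax(i - 0.5, 0)
  hi <- pmin(i + 0.5, 100)
  lo[1L] <- 0; hi[100L] <- 100
  ov <- pmin(b, hi) - pmax(a, lo)
  which(ov > eps)
}

# Exact arc-length spans (in percent) where the edge polyline lies inside the
# scar polygon.
edge_scar_spans <- function(scar, edge) {
  v <- edge$vertices
  cum <- edge$cum_lengths
  total <- edge$total_length
  spans <- list()
  for (i in seq_len(nrow(v) - 1L)) {
    a1 <- v[i, ]; a2 <- v[i + 1L, ]
    seglen <- cum[i + 1L] - cum[i]
    if (seglen == 0) next
    ts <- sort(unique(c(0, 1, segment_ring_crossings(a1, a2, scar))))
    mids <- (ts[-length(ts)] + ts[-1L]) / 2
    pts <- cbind(a1[1L] + mids * (a2[1L] - a1[1L]),
                 a1[2L] + mids * (a2[2L] - a1[2L]))
    ins <- points_in_ring(pts, scar)
    for (k in which(ins)) {
      s0 <- cum[i] + ts[k] * seglen
      s1 <- cum[i] + ts[k + 1L] * seglen
      spans[[length(spans) + 1L]] <- c(s0, s1)
    }
  }
  if (length(spans) == 0) return(matrix(numeric(0), ncol = 2L))
  merge_spans(spans) / total * 100
}

# Fallback spans for scars that come within `tol` of the polyline without
# touching it, located by dense arc-length sampling.
edge_scar_spans_tol <- function(scar, edge, tol, n_sample = 2000L) {
  total <- edge$total_length
  s <- seq(0, total, length.out = n_sample + 1L)
  pts <- t(vapply(s, function(si) point_at_arc(edge$vertices, edge$cum_lengths, si),
                  numeric(2)))
  hit <- points_ring_distance(pts, scar) <= tol
  if (!any(hit)) return(matrix(numeric(0), ncol = 2L))
  r <- rle(hit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  spans <- lapply(which(r$values), function(j) c(s[starts[j]], s[ends[j]]))
  merge_spans(spans) / total * 100
}

#' Project a damage scar onto a standardized edge
#'
#' Intersects the scar polygon with the edge polyline, reduces the
#' intersection to arc-length spans in percent of total edge length, and
#' returns the standardized positions those spans mark. A scar that does not
#' reach the polyline is still counted where it comes within `tol` of it
#' (digitization slack); a scar disjoint from the edge yields an empty set.
#'
#' @param scar simple polygon (matrix/data frame) or scar list with a `ring`.
#' @param edge an `edd_edge` from [split_edges()].
#' @param tol slack distance for scars that miss the polyline; defaults to
#'   0.5% of the face perimeter.
#' @return integer vector of marked positions in 1..100 (possibly empty).
#' @export
project_damage <- function(scar, edge, tol = 0.005 * edge$face_perimeter) {
  if (is.list(scar) && !is.null(scar$ring)) scar <- scar$ring
  scar <- as_ring(scar)
  if (nrow(scar) < 3L) stop("scar polygon must have at least 3 vertices")
  stopifnot(inherits(edge, "edd_edge"))
  spans <- edge_scar_spans(scar, edge)
  if (nrow(spans) == 0 && tol > 0) {
    spans <- edge_scar_spans_tol(scar, edge, tol)
  }
  if (nrow(spans) == 0) return(integer(0))
  sort(unique(unlist(lapply(seq_len(nrow(spans)), function(i) {
    span_to_positions(spans[i, 1L], spans[i, 2L])
  }))))
}

#' Build the 400-position damage vector for a tool
#'
#' Projects every damage scar of both faces onto its platform-to-tip edges
#' and writes the union into the standardized layout: dorsal-left positions
#' 1-100, dorsal-right 101-200, ventral-left 201-300, ventral-right 301-400;
#' within each block position 1 is platform-adjacent and 100 tip-adjacent.
#'
#' @param tool an `edd_tool`.
#' @param class_filter optional character vector of damage classes to keep
#'   (e.g. to exclude post-patination classes); `NULL` keeps all scars.
#' @return integer vector of length 400 (0/1) with attribute `tool_id`.
#' @export
build_damage_vector <- function(tool, class_filter = NULL) {
  stopifnot(inherits(tool, "edd_tool"))
  faces <- tool$faces
  if (is.null(faces$dorsal) || is.null(faces$ventral)) {
    stop(sprintf("tool '%s': both dorsal and ventral faces are required", tool$tool_id))
  }
  vec <- integer(400L)
  offsets <- c(dorsal = 0L, ventral = 200L)
  for (face_name in c("dorsal", "ventral")) {
    face <- faces[[face_name]]
    edges <- split_edges(face$outline, face$platform_anchor)
    scars <- face$scars
    if (!is.null(class_filter)) {
      scars <- Filter(function(s) isTRUE(s$damage_class %in% class_filter), scars)
    }
    for (scar in scars) {
      for (side in c("left", "right")) {
        pos <- project_damage(scar$ring, edges[[side]])
        if (length(pos)) {
          off <- offsets[[face_name]] + if (side == "left") 0L else 100L
          vec[off + pos] <- 1L
        }
      }
    }
  }
  attr(vec, "tool_id") <- tool$tool_id
  vec
}
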