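# Low-level planar geometry used by the edge parameterization.
# All polygons are n x 2 numeric matrices; rings are stored open (no repeated
# final vertex) and interpreted as closed.

#' @keywords internal
as_ring <- function(x) {
  m <- as.matrix(x)
  if (!is.numeric(m) || ncol(m) != 2L) {
    stop("polygon must be an n x 2 numeric matrix of coordinates")
  }
  storage.mode(m) <- "double"
  # drop a repeated closing vertex
  n <- nrow(m)
  if (n >= 2L && isTRUE(all.equal(m[1L, ], m[n, ], check.attributes = FALSE))) {
    m <- m[-n, , drop = FALSE]
  }
  dimnames(m) <- NULL
  m
}

#' @keywords internal
ring_area <- function(ring) {
  # signed shoelace area; positive for counterclockwise rings
  x <- ring[, 1L]; y <- ring[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

#' @keywords internal
ensure_ccw <- function(ring) {
  if (ring_area(ring) < 0) ring[rev(seq_len(nrow(ring))), , drop = FALSE] else ring
}

#' @keywords internal
ring_perimeter <- function(ring) {
  closed <- rbind(ring, ring[1L, ])
  sum(sqrt(rowSums(diff(closed)^2)))
}

# Proper-intersection test between segments (p1,p2) and (p3,p4); used for the
# polygon simplicity check. Shared endpoints between adjacent ring segments are
# excluded by the caller.
#' @keywords internal
segments_cross <- function(p1, p2, p3, p4, eps = 1e-12) {
  d1 <- (p4[1] - p3[1]) * (p1[2] - p3[2]) - (p4[2] - p3[2]) * (p1[1] - p3[1])
  d2 <- (p4[1] - p3[1]) * (p2[2] - p3[2]) - (p4[2] - p3[2]) * (p2[1] - p3[1])
  d3 <- (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p2[2] - p1[2]) * (p3[1] - p1[1])
  d4 <- (p2[1] - p1[1]) * (p4[2] - p1[2]) - (p2[2] - p1[2]) * (p4[1] - p1[1])
  ((d1 > eps && d2 < -eps) || (d1 < -eps && d2 > eps)) &&
    ((d3 > eps && d4 < -eps) || (d3 < -eps && d4 > eps))
}

#' @keywords internal
ring_is_simple <- function(ring) {
  n <- nrow(ring)
  if (n < 3L) return(FALSE)
  closed <- rbind(ring, ring[1L, ])
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i + 1L) next
      if (i == 1L && j == n) next # adjacent through the closure
      if (segments_cross(closed[i, ], closed[i + 1L, ],
                         closed[j, ], closed[j + 1L, ])) {
        return(FALSE)
      }
    }
  }
  TRUE
}

# Even-odd (ray casting) point-in-polygon, vectorized over query points.
# Points on the boundary may land on either side; callers that care use
# explicit intersection instead.
#' @keywords internal
points_in_ring <- function(pts, ring) {
  pts <- matrix(as.numeric(pts), ncol = 2L)
  n <- nrow(ring)
  xs <- ring[, 1L]; ys <- ring[, 2L]
  xe <- c(xs[-1L], xs[1L]); ye <- c(ys[-1L], ys[1L])
  inside <- logical(nrow(pts))
  for (k in seq_len(nrow(pts))) {
    px <- pts[k, 1L]; py <- pts[k, 2L]
    crosses <- ((ys > py) != (ye > py))
    if (any(crosses)) {
      xint <- xs[crosses] + (py - ys[crosses]) / (ye[crosses] - ys[crosses]) *
        (xe[crosses] - xs[crosses])
      inside[k] <- (sum(xint > px) %% 2L) == 1L
    }
  }
  inside
}

# Parameter values t in [0, 1] where segment a1->a2 meets any segment of the
# (closed) ring. Collinear overlaps contribute their endpoints.
#' @keywords internal
segment_ring_crossings <- function(a1, a2, ring, eps = 1e-12) {
  n <- nrow(ring)
  b1x <- ring[, 1L]; b1y <- ring[, 2L]
  b2x <- c(b1x[-1L], b1x[1L]); b2y <- c(b1y[-1L], b1y[1L])
  rx <- a2[1L] - a1[1L]; ry <- a2[2L] - a1[2L]
  sx <- b2x - b1x; sy <- b2y - b1y
  denom <- rx * sy - ry * sx
  qpx <- b1x - a1[1L]; qpy <- b1y - a1[2L]
  tnum <- qpx * sy - qpy * sx
  unum <- qpx * ry - qpy * rx
  out <- numeric(0)
  ok <- abs(denom) > eps
  if (any(ok)) {
    tt <- tnum[ok] / denom[ok]
    uu <- unum[ok] / denom[ok]
    keep <- tt >= -eps & tt <= 1 + eps & uu >= -eps & uu <= 1 + eps
    out <- tt[keep]
  }
  # collinear ring segments: project their endpoints onto the edge segment
  col <- !ok & abs(tnum) <= eps
  if (any(col)) {
    len2 <- rx * rx + ry * ry
    if (len2 > eps) {
      for (i in which(col)) {
        t1 <- ((b1x[i] - a1[1L]) * rx + (b1y[i] - a1[2L]) * ry) / len2
        t2 <- ((b2x[i] - a1[1L]) * rx + (b2y[i] - a1[2L]) * ry) / len2
        out <- c(out, t1, t2)
      }
    }
  }
  pmin(pmax(out, 0), 1)
}

#' @keywords internal
polyline_cumlen <- function(pts) {
  if (nrow(pts) < 2L) return(0)
  c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
}

# Nearest point on a closed ring boundary to p; returns the segment index,
# position within the segment, distance and arc length from vertex 1.
#' @keywords internal
nearest_on_ring <- function(ring, p) {
  closed <- rbind(ring, ring[1L, ])
  n <- nrow(ring)
  best <- list(dist = Inf)
  cum <- polyline_cumlen(closed)
  for (i in seq_len(n)) {
    a <- closed[i, ]; b <- closed[i + 1L, ]
    d <- b - a
    len2 <- sum(d^2)
    t <- if (len2 == 0) 0 else max(0, min(1, sum((p - a) * d) / len2))
    q <- a + t * d
    dd <- sqrt(sum((p - q)^2))
    if (dd < best$dist) {
      best <- list(dist = dd, seg = i, t = t, point = q,
                   arc = cum[i] + t * sqrt(len2))
    }
  }
  best
}

# Distance from each query point to a polygon (0 inside), used by the
# digitization-slack fallback in project_damage().
#' @keywords internal
points_ring_distance <- function(pts, ring) {
  pts <- matrix(as.numeric(pts), ncol = 2L)
  n <- nrow(ring)
  ax <- ring[, 1L]; ay <- ring[, 2L]
  bx <- c(ax[-1L], ax[1L]); by <- c(ay[-1L], ay[1L])
  dx <- bx - ax; dy <- by - ay
  len2 <- dx * dx + dy * dy
  len2[len2 == 0] <- 1e-300
  d <- numeric(nrow(pts))
  for (k in seq_len(nrow(pts))) {
    px <- pts[k, 1L]; py <- pts[k, 2L]
    t <- pmin(pmax(((px - ax) * dx + (py - ay) * dy) / len2, 0), 1)
    qx <- ax + t * dx; qy <- ay + t * dy
    d[k] <- sqrt(min((px - qx)^2 + (py - qy)^2))
  }
  d[points_in_ring(pts, ring)] <- 0
  d
}

# Point at arc length s along an open polyline with cumulative lengths cum.
#' @keywords internal
point_at_arc <- function(pts, cum, s) {
  s <- max(0, min(s, cum[length(cum)]))
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  i <- min(max(i, 1L), nrow(pts) - 1L)
  seg <- cum[i + 1L] - cum[i]
  t <- if (seg == 0) 0 else (s - cum[i]) / seg
  pts[i, ] + t * (pts[i + 1L, ] - pts[i, ])
}

# Unit normal of the polyline at arc length s (left of travel direction).
#' @keywords internal
normal_at_arc <- function(pts, cum, s) {
  s <- max(0, min(s, cum[length(cum)]))
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  i <- min(max(i, 1L), nrow(pts) - 1L)
  d <- pts[i + 1L, ] - pts[i, ]
  len <- sqrt(sum(d^2))
  if (len == 0) return(c(0, 0))
  c(-d[2L], d[1L]) / len
}

#' @keywords internal
merge_spans <- function(spans) {
  # spans: list/matrix of (a, b) pairs, a <= b; returns merged matrix
  if (length(spans) == 0) return(matrix(numeric(0), ncol = 2L))
  m <- do.call(rbind, spans)
  m <- m[order(m[, 1L]), , drop = FALSE]
  out <- m[1L, , drop = FALSE]
  if (nrow(m) > 1L) {
    for (i in 2L:nrow(m)) {
      j <- nrow(out)
      if (m[i, 1L] <= out[j, 2L] + 1e-12) {
        out[j, 2L] <- max(out[j, 2L], m[i, 2L])
      } else {
        out <- rbind(out, m[i, , drop = FALSE])
      }
    }
  }
  out
}
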