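# Planar geometry primitives used by hazard intersection and snapping.
# All coordinates are assumed to live in one projected metric CRS; there is
# no geodetic math anywhere in the package. Tolerances are absolute, in
# meters, and set to 1e-9 unless noted.

.geom_eps <- 1e-9

#' @noRd
.pt_seg_dist <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1
  dy <- y2 - y1
  len2 <- dx * dx + dy * dy
  if (len2 <= .geom_eps^2) {
    return(sqrt((px - x1)^2 + (py - y1)^2))
  }
  t <- ((px - x1) * dx + (py - y1) * dy) / len2
  t <- min(1, max(0, t))
  sqrt((px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2)
}

# signed area of the triangle (a,b,c) * 2; sign gives orientation
.cross3 <- function(ax, ay, bx, by, cx, cy) {
  (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
}

.on_segment <- function(px, py, x1, y1, x2, y2, eps = .geom_eps) {
  if (abs(.cross3(x1, y1, x2, y2, px, py)) >
      eps * max(1, abs(x2 - x1) + abs(y2 - y1))) {
    return(FALSE)
  }
  px >= min(x1, x2) - eps && px <= max(x1, x2) + eps &&
    py >= min(y1, y2) - eps && py <= max(y1, y2) + eps
}

# segment-segment intersection, touching counts
.seg_seg_intersect <- function(p1x, p1y, p2x, p2y, q1x, q1y, q2x, q2y) {
  scale <- max(1, abs(p2x - p1x) + abs(p2y - p1y),
               abs(q2x - q1x) + abs(q2y - q1y))
  eps <- .geom_eps * scale
  d1 <- .cross3(q1x, q1y, q2x, q2y, p1x, p1y)
  d2 <- .cross3(q1x, q1y, q2x, q2y, p2x, p2y)
  d3 <- .cross3(p1x, p1y, p2x, p2y, q1x, q1y)
  d4 <- .cross3(p1x, p1y, p2x, p2y, q2x, q2y)
  if (((d1 > eps && d2 < -eps) || (d1 < -eps && d2 > eps)) &&
      ((d3 > eps && d4 < -eps) || (d3 < -eps && d4 > eps))) {
    return(TRUE)
  }
  if (abs(d1) <= eps && .on_segment(p1x, p1y, q1x, q1y, q2x, q2y)) return(TRUE)
  if (abs(d2) <= eps && .on_segment(p2x, p2y, q1x, q1y, q2x, q2y)) return(TRUE)
  if (abs(d3) <= eps && .on_segment(q1x, q1y, p1x, p1y, p2x, p2y)) return(TRUE)
  if (abs(d4) <= eps && .on_segment(q2x, q2y, p1x, p1y, p2x, p2y)) return(TRUE)
  FALSE
}

# minimal distance between two segments
.seg_seg_dist <- function(p1x, p1y, p2x, p2y, q1x, q1y, q2x, q2y) {
  if (.seg_seg_intersect(p1x, p1y, p2x, p2y, q1x, q1y, q2x, q2y)) return(0)
  min(.pt_seg_dist(p1x, p1y, q1x, q1y, q2x, q2y),
      .pt_seg_dist(p2x, p2y, q1x, q1y, q2x, q2y),
      .pt_seg_dist(q1x, q1y, p1x, p1y, p2x, p2y),
      .pt_seg_dist(q2x, q2y, p1x, p1y, p2x, p2y))
}

# A "ring" is an n x 2 coordinate matrix, implicitly closed. A polygon is a
# list of rings: first outer, remaining ones holes (even-odd rule makes the
# distinction irrelevant for containment).

# boundary-inclusive even-odd point-in-polygon over a list of rings
.point_in_rings <- function(px, py, rings) {
  inside <- FALSE
  for (ring in rings) {
    n <- nrow(ring)
    j <- n
    for (i in seq_len(n)) {
      x1 <- ring[j, 1]; y1 <- ring[j, 2]
      x2 <- ring[i, 1]; y2 <- ring[i, 2]
      if (.on_segment(px, py, x1, y1, x2, y2)) return(TRUE)
      if ((y1 > py) != (y2 > py)) {
        xint <- x1 + (py - y1) / (y2 - y1) * (x2 - x1)
        if (px < xint) inside <- !inside
      }
      j <- i
    }
  }
  inside
}

# does segment (p1,p2) touch or cross a polygon (list of rings)?
.seg_intersects_rings <- function(p1x, p1y, p2x, p2y, rings) {
  if (.point_in_rings(p1x, p1y, rings)) return(TRUE)
  if (.point_in_rings(p2x, p2y, rings)) return(TRUE)
  for (ring in rings) {
    n <- nrow(ring)
    j <- n
    for (i in seq_len(n)) {
      if (.seg_seg_intersect(p1x, p1y, p2x, p2y,
                             ring[j, 1], ring[j, 2], ring[i, 1], ring[i, 2])) {
        return(TRUE)
      }
      j <- i
    }
  }
  FALSE
}

# minimal distance from a segment to a polyline (n x 2 matrix)
.seg_polyline_dist <- function(p1x, p1y, p2x, p2y, line) {
  n <- nrow(line)
  if (n == 1) {
    return(.pt_seg_dist(line[1, 1], line[1, 2], p1x, p1y, p2x, p2y))
  }
  d <- Inf
  for (i in seq_len(n - 1)) {
    d <- min(d, .seg_seg_dist(p1x, p1y, p2x, p2y,
                              line[i, 1], line[i, 2],
                              line[i + 1, 1], line[i + 1, 2]))
    if (d == 0) break
  }
  d
}

# shoelace area of a single ring (absolute value)
.ring_area <- function(ring) {
  n <- nrow(ring)
  x <- as.numeric(ring[, 1]); y <- as.numeric(ring[, 2])
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# discretized buffer polygon (stadium) around one segment; arc_n vertices
# per semicircle. Used for export/area; intersection predicates use exact
# distances instead.
.segment_stadium <- function(x1, y1, x2, y2, r, arc_n = 32) {
  dx <- x2 - x1; dy <- y2 - y1
  len <- sqrt(dx * dx + dy * dy)
  if (len < .geom_eps) {
    ang <- seq(0, 2 * pi, length.out = 2 * arc_n + 1)[-(2 * arc_n + 1)]
    return(cbind(x1 + r * cos(ang), y1 + r * sin(ang)))
  }
  ux <- dx / len; uy <- dy / len       # unit direction
  nx <- -uy; ny <- ux                  # unit left normal
  th0 <- atan2(ny, nx)
  arc2 <- th0 - seq(0, pi, length.out = arc_n + 1)       # around p2
  arc1 <- th0 + pi - seq(0, pi, length.out = arc_n + 1)  # around p1
  rbind(
    cbind(x2 + r * cos(arc2), y2 + r * sin(arc2)),
    cbind(x1 + r * cos(arc1), y1 + r * sin(arc1))
  )
}

# polygon centroid of a single ring (area-weighted)
.ring_centroid <- function(ring) {
  x <- as.numeric(ring[, 1]); y <- as.numeric(ring[, 2])
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < .geom_eps) {
    return(c(mean(x), mean(y)))
  }
  c(sum((x + xn) * cr) / (6 * a), sum((y + yn) * cr) / (6 * a))
}
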