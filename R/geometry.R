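# Planar polygon primitives. All coordinates are in nanometres; polygons are
# closed implicitly (last vertex joins the first) and must be simple.
# Signed quantities follow the shoelace convention: positive area means the
# vertex sequence is counter-clockwise in the (x, y) number plane.

polygon_signed_area <- function(vx, vy) {
  n <- length(vx)
  j <- c(n, seq_len(n - 1L))
  sum(vx[j] * vy - vx * vy[j]) / 2
}

polygon_area <- function(vx, vy) abs(polygon_signed_area(vx, vy))

polygon_perimeter <- function(vx, vy) {
  n <- length(vx)
  j <- c(2:n, 1L)
  sum(sqrt((vx[j] - vx)^2 + (vy[j] - vy)^2))
}

polygon_centroid <- function(vx, vy) {
  n <- length(vx)
  j <- c(2:n, 1L)
  cr <- vx * vy[j] - vx[j] * vy
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps)
    return(c(mean(vx), mean(vy)))
  c(sum((vx + vx[j]) * cr), sum((vy + vy[j]) * cr)) / (6 * a)
}

# Central second moments per unit area: E[x^2], E[y^2], E[xy] over the
# polygon interior, about its centroid.
polygon_second_moments <- function(vx, vy) {
  ctr <- polygon_centroid(vx, vy)
  x <- vx - ctr[1]
  y <- vy - ctr[2]
  n <- length(x)
  j <- c(2:n, 1L)
  cr <- x * y[j] - x[j] * y
  a <- sum(cr) / 2
  sxx <- sum(cr * (x^2 + x * x[j] + x[j]^2)) / 12
  syy <- sum(cr * (y^2 + y * y[j] + y[j]^2)) / 12
  sxy <- sum(cr * (x * y[j] + 2 * x * y + 2 * x[j] * y[j] + x[j] * y)) / 24
  list(area = abs(a), sxx = sxx / a, syy = syy / a, sxy = sxy / a,
       centroid = ctr)
}

# Orientation of the triple (p, q, r): >0 counter-clockwise, <0 clockwise,
# 0 collinear (within a tolerance scaled to the coordinates).
.orient <- function(px, py, qx, qy, rx, ry) {
  v <- (qx - px) * (ry - py) - (qy - py) * (rx - px)
  scale <- max(abs(c(px, py, qx, qy, rx, ry)), 1)
  v[abs(v) < 1e-12 * scale^2] <- 0
  sign(v)
}

.on_segment <- function(px, py, qx, qy, rx, ry) {
  # r collinear with p-q assumed; is r within the bounding box of p-q?
  rx >= pmin(px, qx) & rx <= pmax(px, qx) &
    ry >= pmin(py, qy) & ry <= pmax(py, qy)
}

.segments_intersect <- function(p1, p2, p3, p4) {
  d1 <- .orient(p3[1], p3[2], p4[1], p4[2], p1[1], p1[2])
  d2 <- .orient(p3[1], p3[2], p4[1], p4[2], p2[1], p2[2])
  d3 <- .orient(p1[1], p1[2], p2[1], p2[2], p3[1], p3[2])
  d4 <- .orient(p1[1], p1[2], p2[1], p2[2], p4[1], p4[2])
  if (((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &&
      ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))) return(TRUE)
  if (d1 == 0 && .on_segment(p3[1], p3[2], p4[1], p4[2], p1[1], p1[2])) return(TRUE)
  if (d2 == 0 && .on_segment(p3[1], p3[2], p4[1], p4[2], p2[1], p2[2])) return(TRUE)
  if (d3 == 0 && .on_segment(p1[1], p1[2], p2[1], p2[2], p3[1], p3[2])) return(TRUE)
  if (d4 == 0 && .on_segment(p1[1], p1[2], p2[1], p2[2], p4[1], p4[2])) return(TRUE)
  FALSE
}

# A polygon is simple when no two non-adjacent edges intersect. O(n^2),
# intended for annotation-scale polygons (tens to hundreds of vertices).
polygon_is_simple <- function(vx, vy) {
  n <- length(vx)
  if (n < 3L) return(FALSE)
  if (anyDuplicated(cbind(vx, vy))) return(FALSE)
  nxt <- c(2:n, 1L)
  for (i in seq_len(n - 1L)) {
    for (k in seq.int(i + 1L, n)) {
      # skip edges sharing a vertex (adjacent, incl. wrap-around pair)
      if (k == i + 1L || (i == 1L && k == n)) next
      if (.segments_intersect(
        c(vx[i], vy[i]), c(vx[nxt[i]], vy[nxt[i]]),
        c(vx[k], vy[k]), c(vx[nxt[k]], vy[nxt[k]])
      )) return(FALSE)
    }
  }
  TRUE
}

polygon_is_convex <- function(vx, vy) {
  n <- length(vx)
  if (n < 3L) return(FALSE)
  j <- c(2:n, 1L)
  k <- c(3:n, 1L, 2L)
  s <- .orient(vx, vy, vx[j], vy[j], vx[k], vy[k])
  s <- s[s != 0]
  length(s) > 0 && all(s == s[1])
}

# Point-in-polygon, boundary-inclusive (even-odd crossing rule plus an
# explicit on-boundary test). Vectorized over points.
points_in_polygon <- function(px, py, vx, vy, boundary_eps = 1e-6) {
  n <- length(vx)
  inside <- logical(length(px))
  onb <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- vx[i]; yi <- vy[i]; xj <- vx[j]; yj <- vy[j]
    dx <- xj - xi; dy <- yj - yi
    l2 <- dx * dx + dy * dy
    tt <- if (l2 > 0) pmin(1, pmax(0, ((px - xi) * dx + (py - yi) * dy) / l2)) else 0
    d2 <- (px - (xi + tt * dx))^2 + (py - (yi + tt * dy))^2
    onb <- onb | d2 <= boundary_eps^2
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | onb
}

# Distance from each point to the polygon boundary (unsigned).
points_polygon_boundary_distance <- function(px, py, vx, vy) {
  n <- length(vx)
  best <- rep(Inf, length(px))
  j <- c(2:n, 1L)
  for (i in seq_len(n)) {
    xi <- vx[i]; yi <- vy[i]; xj <- vx[j[i]]; yj <- vy[j[i]]
    dx <- xj - xi; dy <- yj - yi
    l2 <- dx * dx + dy * dy
    tt <- if (l2 > 0) pmin(1, pmax(0, ((px - xi) * dx + (py - yi) * dy) / l2)) else 0
    d2 <- (px - (xi + tt * dx))^2 + (py - (yi + tt * dy))^2
    best <- pmin(best, d2)
  }
  sqrt(best)
}

# Convex hull of a point set, vertices returned counter-clockwise.
# Degenerate inputs (< 3 distinct points, or all collinear) return NULL.
convex_hull_ccw <- function(x, y) {
  if (length(x) < 3L) return(NULL)
  idx <- grDevices::chull(x, y)
  if (length(idx) < 3L) return(NULL)
  hx <- x[idx]; hy <- y[idx]
  a <- polygon_signed_area(hx, hy)
  if (abs(a) <= .Machine$double.eps * max(abs(c(hx, hy, 1)))^2) return(NULL)
  if (a < 0) { hx <- rev(hx); hy <- rev(hy) }
  cbind(x = hx, y = hy)
}

# Outward offset of a convex polygon by distance d (Minkowski sum with a
# disc), arcs at vertices discretized at `arc_step` radians. Exact area of
# the true offset region is A + P*d + pi*d^2; the returned polygon is a QC
# rendering, not the area authority.
offset_convex_polygon <- function(vx, vy, d, arc_step = pi / 64) {
  stopifnot(d >= 0)
  if (d == 0) return(cbind(x = vx, y = vy))
  if (polygon_signed_area(vx, vy) < 0) { vx <- rev(vx); vy <- rev(vy) }
  n <- length(vx)
  nxt <- c(2:n, 1L)
  ex <- vx[nxt] - vx; ey <- vy[nxt] - vy
  len <- sqrt(ex^2 + ey^2)
  # outward normal of a CCW polygon edge is the right-hand perpendicular
  nx <- ey / len; ny <- -ex / len
  ox <- numeric(0); oy <- numeric(0)
  for (i in seq_len(n)) {
    prev <- if (i == 1L) n else i - 1L
    a0 <- atan2(ny[prev], nx[prev])
    a1 <- atan2(ny[i], nx[i])
    da <- (a1 - a0) %% (2 * pi)
    ang <- a0 + seq(0, da, by = min(arc_step, max(da, arc_step)))
    if (ang[length(ang)] != a0 + da) ang <- c(ang, a0 + da)
    ox <- c(ox, vx[i] + d * cos(ang))
    oy <- c(oy, vy[i] + d * sin(ang))
  }
  cbind(x = ox, y = oy)
}
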