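# Independent oracles used to cross-check the implementation. These are
# deliberately naive (all-pairs, label propagation, gift wrapping, winding
# numbers) and share no code with the package internals.

# transitive closure of the strict-distance relation by iterated minimum-
# label propagation over the full adjacency matrix
oracle_partition <- function(x, y, threshold) {
  n <- length(x)
  if (!n) return(integer(0))
  d <- as.matrix(stats::dist(cbind(x, y)))
  adj <- d < threshold
  diag(adj) <- TRUE
  labels <- seq_len(n)
  repeat {
    new_labels <- vapply(seq_len(n), function(i) min(labels[adj[i, ]]),
                         numeric(1))
    if (identical(new_labels, labels)) break
    labels <- new_labels
  }
  labels
}

# relabel a partition by order of first appearance so two labelings of the
# same partition compare equal
canonical_labels <- function(labels) match(labels, unique(labels))

# convex hull area by gift wrapping (Jarvis march) + shoelace
oracle_hull_area <- function(x, y) {
  n <- length(x)
  start <- which.min(x + 1e-12 * y)
  hull <- start
  repeat {
    p <- hull[length(hull)]
    cand <- setdiff(seq_len(n), p)
    q <- cand[1]
    for (r in cand[-1]) {
      cr <- (x[q] - x[p]) * (y[r] - y[p]) - (y[q] - y[p]) * (x[r] - x[p])
      if (cr < 0 ||
          (cr == 0 && (x[r] - x[p])^2 + (y[r] - y[p])^2 >
             (x[q] - x[p])^2 + (y[q] - y[p])^2)) q <- r
    }
    if (q == start) break
    hull <- c(hull, q)
    if (length(hull) > n) stop("gift wrapping failed")
  }
  hx <- x[hull]; hy <- y[hull]
  j <- c(length(hull), seq_len(length(hull) - 1L))
  abs(sum(hx[j] * hy - hx * hy[j])) / 2
}

# point-in-polygon by winding angle (no boundary subtleties needed when
# test points are kept off the boundary)
oracle_in_polygon <- function(px, py, vx, vy) {
  vapply(seq_along(px), function(k) {
    dx <- vx - px[k]; dy <- vy - py[k]
    a <- atan2(dy, dx)
    da <- diff(c(a, a[1]))
    da <- ((da + pi) %% (2 * pi)) - pi
    abs(sum(da)) > pi
  }, logical(1))
}

# all-pairs minimum member distance between two cluster property tables
oracle_pair_gaps <- function(primary_props, partner_props) {
  vapply(seq_len(nrow(primary_props)), function(i) {
    a <- primary_props$members[[i]]
    gaps <- vapply(seq_len(nrow(partner_props)), function(j) {
      b <- partner_props$members[[j]]
      min(sqrt(outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2))
    }, numeric(1))
    if (length(gaps)) min(gaps) else Inf
  }, numeric(1))
}

# random localization table: clustered blobs plus uniform noise, in nm
random_table <- function(n, extent_nm = 1000, clustered_fraction = 0.6,
                         label = "c5") {
  nc <- round(n * clustered_fraction)
  k <- max(1L, round(nc / 30))
  cx <- runif(k, 0, extent_nm); cy <- runif(k, 0, extent_nm)
  idx <- sample.int(k, nc, replace = TRUE)
  localization_table(
    x = c(cx[idx] + rnorm(nc, 0, 40), runif(n - nc, 0, extent_nm)),
    y = c(cy[idx] + rnorm(nc, 0, 40), runif(n - nc, 0, extent_nm)),
    channel_label = label)
}

circle_roi <- function(r_nm, center = c(0, 0), n = 256L, label = "circle") {
  th <- 2 * pi * (seq_len(n) - 1L) / n
  capillary_roi(cbind(center[1] + r_nm * cos(th),
                      center[2] + r_nm * sin(th)), label = label)
}

# standard error of a ratio of two independent group means (delta method)
ratio_se <- function(num, den) {
  ratio <- mean(num) / mean(den)
  cv2 <- function(v) (stats::sd(v) / sqrt(length(v)) / mean(v))^2
  ratio * sqrt(cv2(num) + cv2(den))
}
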