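# Independent brute-force oracles used to validate the package's geometry
# and statistics implementations. These deliberately use different
# algorithms from the package code paths.

# winding-number point-in-polygon test (angle summation)
oracle_point_in_polygon <- function(px, py, v) {
  n <- nrow(v)
  ang <- 0
  for (i in seq_len(n)) {
    j <- i %% n + 1L
    a1 <- atan2(v[i, 2] - py, v[i, 1] - px)
    a2 <- atan2(v[j, 2] - py, v[j, 1] - px)
    d <- a2 - a1
    if (d > pi) d <- d - 2 * pi
    if (d < -pi) d <- d + 2 * pi
    ang <- ang + d
  }
  abs(ang) > pi
}

# gift-wrapping (Jarvis march) convex hull area of a point set, via polar
# angles from the previous edge direction; area by the cross-product sum
oracle_hull_area <- function(pts) {
  pts <- unique(pts)
  n <- nrow(pts)
  if (n < 3L) return(0)
  start <- order(pts[, 2], pts[, 1])[1]   # lowest, then leftmost
  cur <- start
  theta <- 0                               # previous edge direction
  hull <- start
  for (guard in seq_len(n + 1L)) {
    dx <- pts[, 1] - pts[cur, 1]
    dy <- pts[, 2] - pts[cur, 2]
    d2 <- dx^2 + dy^2
    cand <- which(d2 > 0)
    phi <- (atan2(dy[cand], dx[cand]) - theta) %% (2 * pi)
    best <- min(phi)
    close <- cand[phi <= best + 1e-12]
    nxt <- close[which.max(d2[close])]     # collinear: take the farthest
    if (nxt == start) break
    hull <- c(hull, nxt)
    theta <- atan2(pts[nxt, 2] - pts[cur, 2], pts[nxt, 1] - pts[cur, 1])
    cur <- nxt
  }
  h <- pts[hull, , drop = FALSE]
  m <- nrow(h)
  i2 <- c(2:m, 1L)
  abs(sum(h[, 1] * h[i2, 2] - h[i2, 1] * h[, 2])) / 2
}

# oracle projection area of a pixel set: gift-wrapping over all pixel-square
# corner points
oracle_projection_area <- function(px, pixel_size_um = 1) {
  corners <- unique(rbind(
    cbind(px[, 1], px[, 2]), cbind(px[, 1] + 1, px[, 2]),
    cbind(px[, 1], px[, 2] + 1), cbind(px[, 1] + 1, px[, 2] + 1)))
  oracle_hull_area(corners) * pixel_size_um^2
}

# hand Kruskal-Wallis H with mid-ranks and tie correction
oracle_kw_H <- function(values, groups) {
  r <- rank(values)
  N <- length(values)
  Rg <- tapply(r, groups, sum)
  ng <- tapply(r, groups, length)
  H <- 12 / (N * (N + 1)) * sum(Rg^2 / ng) - 3 * (N + 1)
  tt <- table(values)
  C <- 1 - sum(tt^3 - tt) / (N^3 - N)
  if (C > 0) H / C else 0
}

# exact permutation p-value of the KW statistic for 3 groups of 3
oracle_kw_perm_p_3x3 <- function(values) {
  stopifnot(length(values) == 9L)
  g_obs <- rep(1:3, each = 3)
  H_obs <- oracle_kw_H(values, g_obs)
  idx <- seq_len(9L)
  count <- 0L; total <- 0L
  for (a in utils::combn(idx, 3, simplify = FALSE)) {
    rest <- setdiff(idx, a)
    for (b in utils::combn(rest, 3, simplify = FALSE)) {
      g <- integer(9L)
      g[a] <- 1L; g[b] <- 2L; g[setdiff(rest, b)] <- 3L
      H <- oracle_kw_H(values, g)
      total <- total + 1L
      if (H >= H_obs - 1e-9) count <- count + 1L
    }
  }
  count / total
}

# brute-force grid-line selection: does any pixel square [i,i+1)x[j,j+1)
# intersect any line x = ox + k s or y = oy + k s?
oracle_grid_hit <- function(px, ox, oy, s, nx, ny) {
  xl <- seq(ox, nx - 1e-9, by = s)
  yl <- seq(oy, ny - 1e-9, by = s)
  for (i in seq_len(nrow(px))) {
    if (any(px[i, 1] <= xl & xl < px[i, 1] + 1)) return(TRUE)
    if (any(px[i, 2] <= yl & yl < px[i, 2] + 1)) return(TRUE)
  }
  FALSE
}

# convert a 0-based (x, y) pixel matrix to a logical image matrix
px_to_mask <- function(px, shape) {
  m <- matrix(FALSE, shape[1], shape[2])
  m[px[, 2] + 1L + px[, 1] * shape[1]] <- TRUE
  m
}

# random connected blob of pixels inside a window, for fuzzing
random_blob <- function(n_px, win = 20L) {
  x <- win %/% 2L; y <- win %/% 2L
  px <- matrix(c(x, y), 1L)
  while (nrow(px) < n_px) {
    i <- sample.int(nrow(px), 1L)
    step <- sample(list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L)), 1L)[[1]]
    cand <- px[i, ] + step
    if (all(cand >= 0L) && all(cand < win)) px <- unique(rbind(px, cand))
  }
  px
}
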