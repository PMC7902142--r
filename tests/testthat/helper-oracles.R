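# Independent brute-force oracles. Each re-derives an expected value by
# direct enumeration or direct formula evaluation, never by calling the
# implementation under test.

# Naive binary dilation with a square element (odd side), direct loops.
oracle_dilate <- function(m, k) {
  r <- (k - 1) %/% 2
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0L, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    win <- m[max(1, i - r):min(h, i + r), max(1, j - r):min(w, j + r)]
    if (any(win > 0)) out[i, j] <- 255L
  }
  out
}

# Naive binary erosion; pixels outside the image count as background.
oracle_erode <- function(m, k) {
  r <- (k - 1) %/% 2
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0L, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if (i - r < 1 || i + r > h || j - r < 1 || j + r > w) next
    win <- m[(i - r):(i + r), (j - r):(j + r)]
    if (all(win > 0)) out[i, j] <- 255L
  }
  out
}

# Closing of the foreground set: pad so the element can reach outside
# the frame, dilate, erode, crop back.
oracle_closing <- function(m, k) {
  pad <- k - 1
  p <- matrix(0L, nrow(m) + 2 * pad, ncol(m) + 2 * pad)
  p[pad + seq_len(nrow(m)), pad + seq_len(ncol(m))] <- m
  out <- oracle_erode(oracle_dilate(p, k), k)
  out[pad + seq_len(nrow(m)), pad + seq_len(ncol(m))]
}

# Greedy nearest-centroid frame selection without reuse, ties to the
# earlier frame, written independently of select_frames.
oracle_select <- function(cx, keypoints) {
  taken <- rep(FALSE, length(cx))
  picks <- integer(length(keypoints))
  for (k in seq_along(keypoints)) {
    best <- NA_integer_; bestd <- Inf
    for (i in seq_along(cx)) {
      if (taken[i]) next
      d <- abs(cx[i] - keypoints[k])
      if (d < bestd - 1e-12) { bestd <- d; best <- i }
    }
    taken[best] <- TRUE
    picks[k] <- best
  }
  picks
}

# Brute-force Otsu: scan all integer thresholds, maximize between-class
# variance of positive pixels; returns the partition-inducing threshold.
oracle_otsu_integer <- function(v) {
  v <- v[v > 0]
  best_t <- NA_real_; best <- -Inf
  for (t in seq(min(v) + 1L, max(v))) {
    lo <- v[v < t]; hi <- v[v >= t]
    if (length(lo) == 0L || length(hi) == 0L) next
    b <- (length(lo) / length(v)) * (length(hi) / length(v)) *
      (mean(lo) - mean(hi))^2
    if (b > best) { best <- b; best_t <- t }
  }
  best_t
}

wcss_of <- function(points, groups) {
  sum(vapply(split(seq_len(nrow(points)), groups), function(ix) {
    ctr <- colMeans(points[ix, , drop = FALSE])
    sum(sweep(points[ix, , drop = FALSE], 2, ctr)^2)
  }, numeric(1)))
}

constraints_ok <- function(groups, constraints) {
  ml <- constraints$must; cl <- constraints$cannot
  ok <- TRUE
  if (nrow(ml) > 0) ok <- ok && all(groups[ml[, 1]] == groups[ml[, 2]])
  if (nrow(cl) > 0) ok <- ok && all(groups[cl[, 1]] != groups[cl[, 2]])
  ok
}

# Exhaustive constrained bipartition: minimal WCSS over all 2-cluster
# assignments satisfying the constraints (point 1 fixed to cluster 1).
oracle_best_bipartition <- function(points, constraints) {
  n <- nrow(points)
  best <- Inf
  best_g <- NULL
  for (code in 0:(2^(n - 1) - 1)) {
    g <- c(1L, as.integer(intToBits(code))[seq_len(n - 1)] + 1L)
    if (!constraints_ok(g, constraints)) next
    if (length(unique(g)) < 2L) next
    w <- wcss_of(points, g)
    if (w < best) { best <- w; best_g <- g }
  }
  list(wcss = best, groups = best_g)
}

# Random constrained instance with consistent constraints derived from a
# hidden 2-class ground truth.
random_instance <- function(n, n_constraints, sep = 3) {
  truth <- sample(1:2, n, replace = TRUE)
  if (length(unique(truth)) < 2L) truth[1:2] <- 1:2
  points <- matrix(rnorm(2 * n), n, 2) + sep * (truth - 1)
  must <- matrix(integer(0), 0, 2); cannot <- matrix(integer(0), 0, 2)
  if (n_constraints > 0 && n >= 2) {
    for (q in seq_len(n_constraints)) {
      pr <- sample.int(n, 2)
      if (truth[pr[1]] == truth[pr[2]]) must <- rbind(must, sort(pr))
      else cannot <- rbind(cannot, sort(pr))
    }
    must <- unique(must); cannot <- unique(cannot)
  }
  list(points = points, truth = truth,
       constraints = list(must = must, cannot = cannot))
}

# Small silhouette factory: solid rectangle frame with given foreground.
rect_frame <- function(h, w, rows, cols) {
  m <- matrix(0L, h, w)
  m[rows, cols] <- 255L
  m
}
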