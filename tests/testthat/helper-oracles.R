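# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use plain loops / direct arithmetic, not the package's
# code paths.

oracle_confusion <- function(pred, truth) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(pred)) {
    p <- pred[i] > 0; t_ <- truth[i] > 0
    if (p && t_) tp <- tp + 1L
    else if (p && !t_) fp <- fp + 1L
    else if (!p && t_) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}

oracle_metrics <- function(cm) {
  list(iou = cm$tp / (cm$tp + cm$fp + cm$fn),
       precision = cm$tp / (cm$tp + cm$fp),
       recall = cm$tp / (cm$tp + cm$fn),
       dice = 2 * cm$tp / (2 * cm$tp + cm$fp + cm$fn))
}

# boundary voxels by explicit 6-neighbour loop
oracle_boundary <- function(mask) {
  d <- dim(mask)
  out <- NULL
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (mask[i, j, k] > 0) {
      nb <- c(
        if (i > 1) mask[i - 1, j, k] else 0,
        if (i < d[1]) mask[i + 1, j, k] else 0,
        if (j > 1) mask[i, j - 1, k] else 0,
        if (j < d[2]) mask[i, j + 1, k] else 0,
        if (k > 1) mask[i, j, k - 1] else 0,
        if (k < d[3]) mask[i, j, k + 1] else 0)
      if (any(nb == 0)) out <- rbind(out, c(i, j, k))
    }
  }
  out
}

# same percentile convention as documented for hd95, written independently:
# h = min(n, 0.95 n + 1), linear interpolation of sorted values
oracle_upper_pct <- function(d, p = 0.95) {
  s <- sort(d)
  n <- length(s)
  h <- p * n + 1
  if (h >= n) return(s[n])
  lo <- floor(h)
  s[lo] + (h - lo) * (s[lo + 1] - s[lo])
}

# all-pairs O(nA * nB) HD95 oracle
oracle_hd95 <- function(a, b, vs) {
  A <- oracle_boundary(a); B <- oracle_boundary(b)
  da <- numeric(nrow(A)); db <- numeric(nrow(B))
  for (i in seq_len(nrow(A))) {
    best <- Inf
    for (j in seq_len(nrow(B))) {
      dd <- sum(((A[i, ] - B[j, ]) * vs)^2)
      if (dd < best) best <- dd
    }
    da[i] <- sqrt(best)
  }
  for (j in seq_len(nrow(B))) {
    best <- Inf
    for (i in seq_len(nrow(A))) {
      dd <- sum(((A[i, ] - B[j, ]) * vs)^2)
      if (dd < best) best <- dd
    }
    db[j] <- sqrt(best)
  }
  max(oracle_upper_pct(da), oracle_upper_pct(db))
}

# exact (maximum) Hausdorff distance between boundary point sets
oracle_hd_exact <- function(a, b, vs) {
  A <- oracle_boundary(a); B <- oracle_boundary(b)
  dir_max <- function(P, Q) {
    worst <- 0
    for (i in seq_len(nrow(P))) {
      best <- Inf
      for (j in seq_len(nrow(Q))) {
        dd <- sum(((P[i, ] - Q[j, ]) * vs)^2)
        if (dd < best) best <- dd
      }
      if (best > worst) worst <- best
    }
    sqrt(worst)
  }
  max(dir_max(A, B), dir_max(B, A))
}

# random connected-ish blob mask for metric tests
random_blob <- function(dims, n_seeds = 2, r = 2.5) {
  m <- array(0L, dims)
  for (s in seq_len(n_seeds)) {
    ctr <- sapply(dims, function(d) runif(1, 1 + r, d - r))
    for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
      for (k in seq_len(dims[3])) {
        if (sum((c(i, j, k) - ctr)^2) <= r^2) m[i, j, k] <- 1L
      }
  }
  m
}

# small slice set with a centred bright square target, for fast training tests
toy_slices <- function(n, size = 16, off = 0.3, noise = 0.02, seed = 1) {
  withr_seed <- function(code) code
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    x <- matrix(0.4, size, size) + matrix(rnorm(size^2, 0, noise), size)
    y <- matrix(0L, size, size)
    c0 <- sample(4:(size - 7), 2)
    y[c0[1]:(c0[1] + 3), c0[2]:(c0[2] + 3)] <- 1L
    x[y == 1] <- x[y == 1] + off
    list(x = x, y = y)
  })
}
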