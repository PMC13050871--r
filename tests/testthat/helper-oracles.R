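# Independent oracles used across the suite. Each deliberately re-derives
# the quantity with brute force / enumeration, sharing no code path with
# the implementation under test.

# Kapur maximum-entropy threshold by exhaustive search: for every interior
# bin edge, recompute both partial entropies directly from the histogram.
oracle_kapur <- function(v, n_bins = 256L) {
  v <- as.numeric(v)
  breaks <- seq(min(v), max(v), length.out = n_bins + 1L)
  cnt <- numeric(n_bins)
  for (b in seq_len(n_bins)) {
    lo <- breaks[b]
    hi <- breaks[b + 1L]
    cnt[b] <- if (b < n_bins) sum(v >= lo & v < hi) else sum(v >= lo & v <= hi)
  }
  p <- cnt / sum(cnt)
  best <- -Inf
  best_t <- NA_real_
  for (t in seq_len(n_bins - 1L)) {
    pb <- p[1:t]
    pf <- p[(t + 1):n_bins]
    Pb <- sum(pb)
    Pf <- sum(pf)
    if (Pb <= 0 || Pf <= 0) next
    hb <- -sum((pb[pb > 0] / Pb) * log(pb[pb > 0] / Pb))
    hf <- -sum((pf[pf > 0] / Pf) * log(pf[pf > 0] / Pf))
    if (hb + hf > best) {
      best <- hb + hf
      best_t <- breaks[t + 1L]
    }
  }
  best_t
}

# dense 2D convolution with a sampled Gaussian kernel (no separability)
oracle_gauss_blur_2d <- function(img, sigma) {
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  off <- -r:r
  kern <- outer(off, off, function(a, b) exp(-(a^2 + b^2) / (2 * sigma^2)))
  kern <- kern / sum(kern)
  ny <- nrow(img)
  nx <- ncol(img)
  refl <- function(i, n) {
    j <- (i - 1L) %% (2L * n)
    ifelse(j < n, j + 1L, 2L * n - j)
  }
  out <- matrix(0, ny, nx)
  for (a in seq_along(off))
    for (b in seq_along(off)) {
      rows <- refl(seq_len(ny) + off[a], ny)
      cols <- refl(seq_len(nx) + off[b], nx)
      out <- out + kern[a, b] * img[rows, cols]
    }
  out
}

# O(n^2) surface distance over ALL voxel-centre pairs (the minimum over all
# pairs equals the minimum over boundary pairs); 0 on 26-adjacency/overlap
oracle_surface_distance <- function(va, vb, voxel_size) {
  vs <- voxel_size[c("y", "x", "z")]
  best <- Inf
  touch <- FALSE
  for (p in seq_len(nrow(va)))
    for (q in seq_len(nrow(vb))) {
      dv <- abs(va[p, ] - vb[q, ])
      if (all(dv <= 1)) touch <- TRUE
      d <- sqrt(sum((dv * vs)^2))
      if (d < best) best <- d
    }
  if (touch) 0 else best
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
oracle_mw_exact <- function(a, b) {
  pool <- c(a, b)
  n1 <- length(a)
  n <- length(pool)
  rk <- rank(pool)
  u_of <- function(ix) sum(rk[ix]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  combos <- combn(n, n1)
  us <- apply(combos, 2, u_of)
  mu <- n1 * (length(b)) / 2
  # two-sided: as extreme or more extreme on either side of the mean
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# brute-force 2D Euclidean distance transform (distance to nearest
# background pixel centre)
oracle_edt_2d <- function(mask) {
  fg <- which(mask, arr.ind = TRUE)
  bg <- which(!mask, arr.ind = TRUE)
  out <- matrix(0, nrow(mask), ncol(mask))
  for (t in seq_len(nrow(fg))) {
    d2 <- (bg[, 1] - fg[t, 1])^2 + (bg[, 2] - fg[t, 2])^2
    out[fg[t, 1], fg[t, 2]] <- sqrt(min(d2))
  }
  out
}

# deterministic random blobby mask for property tests
random_blob_mask <- function(seed, ny = 48, nx = 48, n_blobs = 4) {
  set.seed(seed)
  m <- matrix(FALSE, ny, nx)
  for (b in seq_len(n_blobs)) {
    ci <- runif(1, 8, ny - 8)
    cj <- runif(1, 8, nx - 8)
    r <- runif(1, 3, 7)
    g <- expand.grid(i = seq_len(ny), j = seq_len(nx))
    m <- m | matrix((g$i - ci)^2 + (g$j - cj)^2 <= r^2, ny, nx)
  }
  m
}
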