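# Internal numerical primitives: separable Gaussian smoothing with symmetric
# (reflect-including-edge) boundaries, and Kapur maximum-entropy thresholding.

# sampled, normalized 1D Gaussian kernel; radius = ceiling(4*sigma)
.gauss_kernel_1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  w <- exp(-((-r:r)^2) / (2 * sigma^2))
  w / sum(w)
}

# symmetric boundary index: ... 2 1 | 1 2 ... n | n n-1 ...
.reflect_idx <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  j <- (i - 1L) %% (2L * n)
  ifelse(j < n, j + 1L, 2L * n - j)
}

# convolve along one axis of an nd array with a symmetric kernel
.conv_axis <- function(arr, kern, axis) {
  if (length(kern) == 1L) return(arr * kern)
  d <- dim(arr)
  if (is.null(d)) d <- length(arr)
  nd <- length(d)
  perm <- c(axis, setdiff(seq_len(nd), axis))
  x <- aperm(arr, perm)
  dp <- dim(x)
  n <- dp[1L]
  dim(x) <- c(n, prod(dp[-1L]))
  r <- (length(kern) - 1L) %/% 2L
  out <- matrix(0, n, ncol(x))
  base <- seq_len(n)
  for (k in seq_along(kern)) {
    rows <- .reflect_idx(base + (k - 1L) - r, n)
    out <- out + kern[k] * x[rows, , drop = FALSE]
  }
  dim(out) <- dp
  aperm(out, order(perm))
}

# separable Gaussian smoothing; sigma_vox is per-dimension (in voxels),
# length matching dim(arr)
.gauss_smooth <- function(arr, sigma_vox) {
  d <- dim(arr)
  stopifnot(length(sigma_vox) == length(d))
  out <- arr
  for (ax in seq_along(d)) {
    if (sigma_vox[ax] > 0 && d[ax] > 1L)
      out <- .conv_axis(out, .gauss_kernel_1d(sigma_vox[ax]), ax)
  }
  out
}

# Kapur-Sahoo-Wong maximum-entropy threshold over an equal-width histogram.
# Returns the bin edge t* maximizing the summed background and foreground
# Shannon entropies; foreground = values strictly above the threshold (dark
# background convention). Ties resolved to the lowest edge.
.kapur_threshold <- function(v, n_bins = 256L) {
  v <- as.numeric(v)
  v <- v[is.finite(v)]
  rng <- range(v)
  if (length(v) < 2L || diff(rng) == 0)
    stop("degenerate input: need at least two distinct values")
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  bin <- findInterval(v, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  p <- tabulate(bin, n_bins) / length(v)
  plogp <- ifelse(p > 0, -p * log(p), 0)
  P <- cumsum(p)
  H <- cumsum(plogp)
  Htot <- H[n_bins]
  t_cand <- seq_len(n_bins - 1L)
  P0 <- P[t_cand]
  ok <- P0 > 0 & P0 < 1
  obj <- rep(-Inf, n_bins - 1L)
  obj[ok] <- log(P0[ok]) + H[t_cand][ok] / P0[ok] +
    log(1 - P0[ok]) + (Htot - H[t_cand][ok]) / (1 - P0[ok])
  tstar <- which.max(obj)
  breaks[tstar + 1L]
}
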