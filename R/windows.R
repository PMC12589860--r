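# Sliding-window statistics via 2D summed-area tables.
#
# All window means / standard deviations in the package (bright-region
# search, dark-region search, Niblack thresholding) come through here so
# the population-sd convention is applied in exactly one place.

# 2D cumulative sum with a zero border row/col prepended, so that
# rectangle sums are S[r2+1,c2+1] - S[r1,c2+1] - S[r2+1,c1] + S[r1,c1].
sat <- function(m) {
  s <- apply(m, 2, cumsum)
  s <- t(apply(s, 1, cumsum))
  rbind(0, cbind(0, s))
}

# Sums over every w x w window fully inside m; result[(i,j)] is the sum of
# the window whose top-left corner is (i, j). Dimensions (nr-w+1, nc-w+1).
window_sums <- function(m, w) {
  d <- dim(m)
  if (w > d[1] || w > d[2]) {
    stop(sprintf("window %d exceeds slice extent %d x %d", w, d[1], d[2]))
  }
  s <- sat(m)
  i <- seq_len(d[1] - w + 1L)
  j <- seq_len(d[2] - w + 1L)
  s[i + w, j + w, drop = FALSE] - s[i, j + w, drop = FALSE] -
    s[i + w, j, drop = FALSE] + s[i, j, drop = FALSE]
}

# Mean and population standard deviation of every w x w window.
# Variances are clamped at 0 to absorb floating-point cancellation.
window_stats <- function(m, w) {
  n <- as.numeric(w) * w
  mu <- window_sums(m, w) / n
  if (is.integer(m)) m <- m * 1.0
  v <- window_sums(m * m, w) / n - mu * mu
  v[v < 0] <- 0
  list(mean = mu, sd = sqrt(v))
}

# Symmetric (edge-including) reflection padding by r pixels on every side.
pad_reflect <- function(m, r) {
  d <- dim(m)
  if (r >= d[1] || r >= d[2]) {
    stop(sprintf("reflect padding %d too large for a %d x %d slice", r, d[1], d[2]))
  }
  ri <- c(r:1, seq_len(d[1]), d[1]:(d[1] - r + 1L))
  ci <- c(r:1, seq_len(d[2]), d[2]:(d[2] - r + 1L))
  m[ri, ci, drop = FALSE]
}

# Population standard deviation (divide by N).
pop_sd <- function(x) {
  mu <- mean(x)
  sqrt(max(0, mean(x * x) - mu * mu))
}

as_slice_matrix <- function(slice) {
  if (inherits(slice, "zstack")) {
    if (n_slices(slice) != 1L) stop("expected a single slice, got a stack")
    slice <- get_slice(slice, 1L)
  }
  if (!is.matrix(slice)) stop("slice must be a 2D numeric matrix")
  if (anyNA(slice)) stop("slice contains NA")
  slice
}
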