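# Exhaustive brute-force re-implementations of the windowed operations,
# written with plain loops and no shared code with the package internals.
# They serve as independent oracles for the fast implementations.

oracle_pop_sd <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  sqrt(max(0, sum(x * x) / n - m * m))
}

# Mean of every w x w window (indexed by top-left corner), by explicit loops.
oracle_window_means <- function(slice, w) {
  d <- dim(slice)
  out <- matrix(NA_real_, d[1] - w + 1L, d[2] - w + 1L)
  for (i in seq_len(nrow(out))) {
    for (j in seq_len(ncol(out))) {
      out[i, j] <- mean(slice[i:(i + w - 1L), j:(j + w - 1L)])
    }
  }
  out
}

# Greedy bright-region selection by scanning the full mean table each step.
oracle_select_bright <- function(slice, params) {
  w <- params$bright_window
  mu <- oracle_window_means(slice, w)
  cand <- data.frame(
    r = as.vector(row(mu)) + (w - 1) / 2,
    c = as.vector(col(mu)) + (w - 1) / 2,
    mu = as.vector(mu))
  cand <- cand[order(-cand$mu, cand$r, cand$c), ]
  acc <- cand[0, ]
  for (i in seq_len(nrow(cand))) {
    if (nrow(acc) >= params$n_regions) break
    ok <- TRUE
    for (j in seq_len(nrow(acc))) {
      dd <- if (params$distance == "euclidean") {
        sqrt((cand$r[i] - acc$r[j])^2 + (cand$c[i] - acc$c[j])^2)
      } else {
        max(abs(cand$r[i] - acc$r[j]), abs(cand$c[i] - acc$c[j]))
      }
      if (dd < params$min_distance) { ok <- FALSE; break }
    }
    if (ok) acc <- rbind(acc, cand[i, ])
  }
  data.frame(row = acc$r, col = acc$c, mean_intensity = acc$mu)
}

# Minimum-sd dark window inside the clamped search box, by explicit loops.
oracle_find_dark <- function(slice, center, params) {
  d <- dim(slice)
  half <- (params$search_box - 1) / 2
  r0 <- max(1L, as.integer(floor(center[1] - half)))
  c0 <- max(1L, as.integer(floor(center[2] - half)))
  r1 <- min(d[1], r0 + params$search_box - 1L)
  c1 <- min(d[2], c0 + params$search_box - 1L)
  dw <- params$dark_window
  best <- NULL
  for (i in r0:(r1 - dw + 1L)) {
    for (j in c0:(c1 - dw + 1L)) {
      win <- slice[i:(i + dw - 1L), j:(j + dw - 1L)]
      s <- oracle_pop_sd(win)
      if (is.null(best) || s < best$sd) {
        best <- list(top_left = c(row = i, col = j), sd = s, mean = mean(win))
      }
    }
  }
  best
}

# Per-pixel Niblack mask with independently constructed symmetric
# (edge-including) reflection padding.
oracle_niblack_mask <- function(slice, window) {
  r <- (window - 1L) %/% 2L
  d <- dim(slice)
  pad <- matrix(NA_real_, d[1] + 2L * r, d[2] + 2L * r)
  for (i in seq_len(nrow(pad))) {
    si <- i - r
    if (si < 1L) si <- 1L - si
    if (si > d[1]) si <- 2L * d[1] + 1L - si
    for (j in seq_len(ncol(pad))) {
      sj <- j - r
      if (sj < 1L) sj <- 1L - sj
      if (sj > d[2]) sj <- 2L * d[2] + 1L - sj
      pad[i, j] <- slice[si, sj]
    }
  }
  mask <- matrix(FALSE, d[1], d[2])
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      win <- pad[i:(i + 2L * r), j:(j + 2L * r)]
      mask[i, j] <- slice[i, j] > (mean(win) - oracle_pop_sd(win))
    }
  }
  mask
}

# Closed-form one-way ANOVA F from between/within sums of squares.
oracle_oneway_f <- function(groups) {
  k <- length(groups)
  n <- sum(lengths(groups))
  grand <- mean(unlist(groups))
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2,
                    numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  list(f = (ssb / (k - 1)) / (ssw / (n - k)), df1 = k - 1, df2 = n - k,
       ssb = ssb, ssw = ssw)
}
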