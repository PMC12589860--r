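#' Parameters of the automated bright/dark paired SNR analysis
#'
#' The per-slice SNR is built from pairs of pixel windows: small "bright"
#' windows of maximal mean intensity (taken to lie on labeled vasculature)
#' and, near each, a larger "dark" window of minimal intensity standard
#' deviation (representative of extravascular tissue). Defaults are the
#' standard analysis settings for 512 x 512 cropped slices.
#'
#' @param n_regions Number of bright/dark pairs per slice (default 15).
#' @param bright_window Side of the bright sliding window in pixels
#'   (default 5).
#' @param dark_window Side of the dark sliding window in pixels
#'   (default 20).
#' @param search_box Side of the search box centered on each bright region
#'   within which the dark window must lie (default 61). Must be at least
#'   `dark_window`.
#' @param min_distance Minimum distance in pixels between accepted bright
#'   window centers (default 75), enforced so pairs sample different
#'   vessels rather than one bright spot.
#' @param distance Distance metric for the spacing constraint:
#'   `"euclidean"` (default) or `"chebyshev"`.
#' @return An object of class `snr_params`.
#' @export
snr_params <- function(n_regions = 15L, bright_window = 5L, dark_window = 20L,
                       search_box = 61L, min_distance = 75,
                       distance = c("euclidean", "chebyshev")) {
  distance <- match.arg(distance)
  p <- list(n_regions = as.integer(n_regions),
            bright_window = as.integer(bright_window),
            dark_window = as.integer(dark_window),
            search_box = as.integer(search_box),
            min_distance = as.numeric(min_distance),
            distance = distance)
  if (any(c(p$n_regions, p$bright_window, p$dark_window, p$search_box) < 1L) ||
      p$min_distance <= 0) {
    stop("all snr_params must be positive")
  }
  if (p$dark_window > p$search_box) {
    stop("dark_window must not exceed search_box")
  }
  structure(p, class = "snr_params")
}

region_distance <- function(r1, c1, r2, c2, metric) {
  if (metric == "euclidean") sqrt((r1 - r2)^2 + (c1 - c2)^2)
  else pmax(abs(r1 - r2), abs(c1 - c2))
}

#' Select bright regions on a slice
#'
#' Greedy selection of up to `n_regions` bright windows: the first is the
#' window with the highest mean intensity anywhere on the slice; each
#' subsequent region is the brightest remaining window at least
#' `min_distance` pixels (center-to-center) from every previously accepted
#' region. Ties in window mean are broken toward the smallest (row, col)
#' top-left corner in row-major order, making the result deterministic.
#' Selection stops early when no feasible window remains; fewer than
#' `n_regions` accepted regions raises a warning (sparse vasculature),
#' zero raises an error.
#'
#' @param slice 2D numeric intensity matrix (an already-cropped slice).
#' @param params An [snr_params()].
#' @return A data.frame with one row per accepted region, in acceptance
#'   order: `row`, `col` (window center, 1-based; half-integer for
#'   even-sized windows), `mean_intensity`.
#' @export
select_bright_regions <- function(slice, params = snr_params()) {
  slice <- as_slice_matrix(slice)
  w <- params$bright_window
  mu <- window_stats(slice, w)$mean
  d <- dim(mu)
  tl_r <- rep(seq_len(d[1]), times = d[2])
  tl_c <- rep(seq_len(d[2]), each = d[1])
  ord <- order(-as.vector(mu), tl_r, tl_c)
  # centers of candidate windows, in greedy (brightness, row-major) order
  cr <- tl_r[ord] + (w - 1) / 2
  cc <- tl_c[ord] + (w - 1) / 2
  mu <- as.vector(mu)[ord]

  acc_r <- numeric(0); acc_c <- numeric(0); acc_mu <- numeric(0)
  while (length(acc_r) < params$n_regions && length(cr) > 0L) {
    acc_r <- c(acc_r, cr[1]); acc_c <- c(acc_c, cc[1]); acc_mu <- c(acc_mu, mu[1])
    keep <- region_distance(cr, cc, cr[1], cc[1], params$distance) >=
      params$min_distance
    cr <- cr[keep]; cc <- cc[keep]; mu <- mu[keep]
  }
  if (length(acc_r) == 0L) stop("no feasible bright window on slice")
  if (length(acc_r) < params$n_regions) {
    warning(sprintf("only %d of %d bright regions feasible under the %g-px spacing constraint",
                    length(acc_r), params$n_regions, params$min_distance))
  }
  data.frame(row = acc_r, col = acc_c, mean_intensity = acc_mu)
}

#' Find the dark region paired with a bright region
#'
#' Scans all `dark_window` x `dark_window` windows lying fully inside a
#' `search_box` x `search_box` box centered on the bright-region center
#' (the box is clamped at image borders; the dark window itself is never
#' shrunk) and returns the window with the lowest population standard
#' deviation of intensity. Ties are broken toward the smallest (row, col)
#' top-left corner in row-major order.
#'
#' @param slice 2D numeric intensity matrix.
#' @param bright_center Numeric (row, col) center of the bright region.
#' @param params An [snr_params()].
#' @param positive_sd_only If TRUE, restrict the scan to windows with
#'   strictly positive standard deviation and return NULL when none exists.
#'   Used to resolve degenerate (sd = 0) pairings, where the log-ratio SNR
#'   is undefined.
#' @return A list with `top_left` (row, col), `sd_intensity`,
#'   `mean_intensity`; or NULL (see `positive_sd_only`).
#' @export
find_dark_region <- function(slice, bright_center, params = snr_params(),
                             positive_sd_only = FALSE) {
  slice <- as_slice_matrix(slice)
  d <- dim(slice)
  half <- (params$search_box - 1) / 2
  r0 <- max(1L, as.integer(floor(bright_center[1] - half)))
  c0 <- max(1L, as.integer(floor(bright_center[2] - half)))
  r1 <- min(d[1], r0 + params$search_box - 1L)
  c1 <- min(d[2], c0 + params$search_box - 1L)
  dw <- params$dark_window
  if (r1 - r0 + 1L < dw || c1 - c0 + 1L < dw) {
    stop(sprintf("clamped search box (%d x %d) too small for a %d x %d dark window",
                 r1 - r0 + 1L, c1 - c0 + 1L, dw, dw))
  }
  st <- window_stats(slice[r0:r1, c0:c1, drop = FALSE], dw)
  nb <- dim(st$sd)
  tl_r <- rep(seq_len(nb[1]), times = nb[2]) + r0 - 1L
  tl_c <- rep(seq_len(nb[2]), each = nb[1]) + c0 - 1L
  sds <- as.vector(st$sd)
  mus <- as.vector(st$mean)
  if (positive_sd_only) {
    ok <- sds > 0
    if (!any(ok)) return(NULL)
    tl_r <- tl_r[ok]; tl_c <- tl_c[ok]; sds <- sds[ok]; mus <- mus[ok]
  }
  best <- order(sds, tl_r, tl_c)[1]
  list(top_left = c(row = tl_r[best], col = tl_c[best]),
       sd_intensity = sds[best], mean_intensity = mus[best])
}

#' Per-pair signal-to-noise ratio
#'
#' The SNR of one bright/dark pair is the base-10 logarithm of the bright
#' window's mean intensity over the dark window's standard deviation:
#' `SNR_i = log10(mu_bright / sd_dark)`. A zero dark-window standard
#' deviation makes the ratio undefined; such pairs are flagged invalid
#' (`NA`) rather than returned as infinity, and [slice_snr()] resolves
#' them by re-searching for a positive-sd dark window.
#'
#' @param mu_bright Bright-window mean intensity (> 0).
#' @param sd_dark Dark-window standard deviation (>= 0).
#' @return `log10(mu_bright / sd_dark)`, or `NA` when `sd_dark` is 0.
#' @examples
#' pair_snr(100, 10)  # 1
#' pair_snr(1000, 1)  # 3
#' @export
pair_snr <- function(mu_bright, sd_dark) {
  if (any(mu_bright <= 0)) stop("mu_bright must be > 0")
  if (any(sd_dark < 0)) stop("sd_dark must be >= 0")
  out <- ifelse(sd_dark == 0, NA_real_, log10(mu_bright / sd_dark))
  out
}

#' SNR of one z-slice
#'
#' Runs the full paired analysis on a slice: bright-region selection
#' ([select_bright_regions()]), dark-region search per bright region
#' ([find_dark_region()]), per-pair log-ratio SNR ([pair_snr()]), and the
#' slice SNR as the arithmetic mean of the valid per-pair values. Pairs
#' whose search box contains no window with positive standard deviation
#' are dropped with a warning. The spacing constraint between accepted
#' bright centers is re-verified on every call.
#'
#' @param slice 2D numeric intensity matrix.
#' @param params An [snr_params()].
#' @param slice_index Optional 1-based slice index recorded in the result.
#' @param depth_um Optional imaging depth recorded in the result.
#' @return An object of class `slice_snr`: list with `slice_index`,
#'   `depth_um`, `snr` (mean of valid pair SNRs), `n_pairs`, and `pairs`,
#'   a data.frame with columns `bright_row`, `bright_col`, `mu_bright`,
#'   `dark_row`, `dark_col`, `sd_dark`, `snr_i`.
#' @export
slice_snr <- function(slice, params = snr_params(), slice_index = NA_integer_,
                      depth_um = NA_real_) {
  slice <- as_slice_matrix(slice)
  bright <- select_bright_regions(slice, params)

  if (nrow(bright) > 1L) {
    for (i in seq_len(nrow(bright) - 1L)) {
      dd <- region_distance(bright$row[-seq_len(i)], bright$col[-seq_len(i)],
                            bright$row[i], bright$col[i], params$distance)
      if (any(dd < params$min_distance)) {
        stop("internal error: bright-region spacing constraint violated")
      }
    }
  }

  rows <- vector("list", nrow(bright))
  dropped <- 0L
  for (i in seq_len(nrow(bright))) {
    dark <- find_dark_region(slice, c(bright$row[i], bright$col[i]), params)
    if (dark$sd_intensity == 0) {
      dark <- find_dark_region(slice, c(bright$row[i], bright$col[i]), params,
                               positive_sd_only = TRUE)
    }
    if (is.null(dark)) { dropped <- dropped + 1L; next }
    rows[[i]] <- data.frame(
      bright_row = bright$row[i], bright_col = bright$col[i],
      mu_bright = bright$mean_intensity[i],
      dark_row = dark$top_left[["row"]], dark_col = dark$top_left[["col"]],
      sd_dark = dark$sd_intensity,
      snr_i = pair_snr(bright$mean_intensity[i], dark$sd_intensity))
  }
  pairs <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(pairs) || nrow(pairs) == 0L) {
    stop(sprintf("no valid bright/dark pair on slice %s",
                 ifelse(is.na(slice_index), "?", slice_index)))
  }
  if (dropped > 0L) {
    warning(sprintf("dropped %d pair(s) with zero-variance search box on slice %s",
                    dropped, ifelse(is.na(slice_index), "?", slice_index)))
  }
  structure(list(slice_index = slice_index, depth_um = depth_um,
                 snr = mean(pairs$snr_i), n_pairs = nrow(pairs), pairs = pairs),
            class = "slice_snr")
}

#' @export
print.slice_snr <- function(x, ...) {
  cat(sprintf("<slice_snr> slice %s, depth %s um: SNR %.4f from %d pairs\n",
              x$slice_index, x$depth_um, x$snr, x$n_pairs))
  invisible(x)
}

#' SNR of every slice of an analysis volume
#'
#' Runs [slice_snr()] on every slice at or below the designated surface
#' slice, ordered by increasing imaging depth. Slices above the surface
#' are excluded from analysis.
#'
#' @param volume An [analysis_volume()].
#' @param params An [snr_params()].
#' @return An object of class `stack_snr`: list with `summary` (data.frame
#'   of `slice_index`, `depth_um`, `n_pairs`, `snr`) and `slices` (list of
#'   [slice_snr()] results).
#' @export
stack_snr <- function(volume, params = snr_params()) {
  stopifnot(inherits(volume, "analysis_volume"))
  idx <- analysis_slice_indices(volume)
  slices <- lapply(idx, function(i) {
    tryCatch(
      slice_snr(get_slice(volume$stack, i), params, slice_index = i,
                depth_um = depth_of_slice(volume, i)),
      error = function(e) stop(sprintf("slice %d: %s", i, conditionMessage(e)),
                               call. = FALSE))
  })
  summary <- data.frame(
    slice_index = idx,
    depth_um = vapply(slices, `[[`, numeric(1), "depth_um"),
    n_pairs = vapply(slices, `[[`, integer(1), "n_pairs"),
    snr = vapply(slices, `[[`, numeric(1), "snr"))
  structure(list(summary = summary, slices = slices), class = "stack_snr")
}

#' Flatten the per-pair detail of a stack SNR result
#'
#' @param x A `stack_snr` object.
#' @return A data.frame with one row per bright/dark pair across all
#'   slices, carrying `slice_index` and `depth_um`.
#' @export
snr_pairs_table <- function(x) {
  stopifnot(inherits(x, "stack_snr"))
  do.call(rbind, lapply(x$slices, function(s) {
    cbind(slice_index = s$slice_index, depth_um = s$depth_um, s$pairs)
  }))
}
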