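#' Mean intensity of a slice
#'
#' Arithmetic mean of all pixels of an (already cropped) slice — the
#' per-depth data point of the depth-intensity profile.
#'
#' @param slice 2D numeric intensity matrix.
#' @return Scalar mean intensity.
#' @export
mean_slice_intensity <- function(slice) {
  slice <- as_slice_matrix(slice)
  if (length(slice) == 0L) stop("empty slice")
  mean(slice)
}

#' Depth-intensity (and optional SNR) profile of an analysis volume
#'
#' Computes the mean intensity of every slice at or below the surface
#' slice, indexed by imaging depth. Optionally joins the per-slice SNR
#' from [stack_snr()].
#'
#' @param volume An [analysis_volume()].
#' @param snr Optional: TRUE to compute slice SNR alongside (with
#'   `snr_params`), or a precomputed `stack_snr` object to join.
#' @param snr_params An [snr_params()], used when `snr = TRUE`.
#' @return A data.frame of class `depth_profile` with columns
#'   `slice_index`, `depth_um`, `mean_intensity`, and `snr` when requested.
#' @export
depth_profile <- function(volume, snr = FALSE, snr_params = snr_params()) {
  stopifnot(inherits(volume, "analysis_volume"))
  idx <- analysis_slice_indices(volume)
  out <- data.frame(
    slice_index = idx,
    depth_um = depth_of_slice(volume, idx),
    mean_intensity = vapply(idx, function(i)
      mean_slice_intensity(get_slice(volume$stack, i)), numeric(1)))
  if (isTRUE(snr)) snr <- stack_snr(volume, snr_params)
  if (inherits(snr, "stack_snr")) {
    out$snr <- snr$summary$snr[match(out$slice_index, snr$summary$slice_index)]
  }
  class(out) <- c("depth_profile", "data.frame")
  out
}

#' Percent relative intensity at a reference depth
#'
#' The depth-penetration summary of a stack: the mean slice intensity at a
#' reference depth, expressed as a percentage of the surface (depth 0)
#' mean intensity. The standard reference depth is 150 um; when shallower
#' stacks are compared in a batch, the deepest depth present in all of
#' them (commonly 105 um) is used instead. Values above 100% are legal:
#' sub-surface slices can be brighter than a rough surface slice.
#'
#' @param profile A [depth_profile()] data.frame (or any data.frame with
#'   `depth_um` and `mean_intensity` columns).
#' @param reference_depth Reference depth in micrometres (default 150).
#'   Must coincide with an acquired depth: no interpolation is performed.
#' @return A list of class `percent_relative_intensity`:
#'   `percent_relative_intensity` and `reference_depth_um`.
#' @examples
#' pr <- data.frame(depth_um = c(0, 150), mean_intensity = c(200, 110))
#' percent_relative_intensity(pr)$percent_relative_intensity  # 55
#' @export
percent_relative_intensity <- function(profile, reference_depth = 150) {
  stopifnot(is.data.frame(profile),
            all(c("depth_um", "mean_intensity") %in% names(profile)))
  tol <- 1e-9
  at <- function(d) {
    i <- which(abs(profile$depth_um - d) <= tol * max(1, abs(d)))
    if (length(i) != 1L) {
      stop(sprintf("profile has no unique slice at depth %g um", d))
    }
    profile$mean_intensity[i]
  }
  m0 <- at(0)
  mref <- at(reference_depth)
  if (m0 <= 0) stop("surface mean intensity must be > 0")
  structure(list(percent_relative_intensity = 100 * mref / m0,
                 reference_depth_um = reference_depth),
            class = "percent_relative_intensity")
}

#' @export
print.percent_relative_intensity <- function(x, ...) {
  cat(sprintf("percent relative intensity at %g um: %.2f%%\n",
              x$reference_depth_um, x$percent_relative_intensity))
  invisible(x)
}

#' Suggest a surface slice from foreground coverage
#'
#' The tissue surface slice (imaging depth 0) is conventionally chosen by
#' the analyst as the first slice with vasculature covering the whole
#' cropped region, because vibratome sectioning leaves a rough surface.
#' This heuristic automates a suggestion: it binarizes each slice with
#' Niblack local thresholding and returns the first slice whose foreground
#' coverage reaches `coverage_threshold` in each of the four image
#' quadrants. The suggestion is advisory; pipeline drivers always accept a
#' manual surface index. Note the Niblack rule marks most pixels in
#' noise-dominated flat regions, so the heuristic is informative on
#' structured images and on low-noise phantoms, not on pure-noise stacks.
#'
#' @param stack A [zstack()] (typically already cropped).
#' @param coverage_threshold Minimum foreground fraction required in every
#'   quadrant (default 0.02).
#' @param niblack A [niblack_params()].
#' @return A list: `surface_index` (1-based slice index, or NA when no
#'   slice qualifies) and `coverage`, a data.frame of per-slice per-quadrant
#'   foreground fractions.
#' @export
suggest_surface_slice <- function(stack, coverage_threshold = 0.02,
                                  niblack = niblack_params()) {
  stopifnot(inherits(stack, "zstack"))
  d <- dim(stack$intensities)
  hr <- d[1] %/% 2L
  hc <- d[2] %/% 2L
  cov <- t(vapply(seq_len(d[3]), function(i) {
    m <- binarize_niblack(get_slice(stack, i), niblack)$mask
    c(q1 = mean(m[seq_len(hr), seq_len(hc)]),
      q2 = mean(m[seq_len(hr), (hc + 1L):d[2]]),
      q3 = mean(m[(hr + 1L):d[1], seq_len(hc)]),
      q4 = mean(m[(hr + 1L):d[1], (hc + 1L):d[2]]))
  }, numeric(4)))
  ok <- apply(cov >= coverage_threshold, 1, all)
  list(surface_index = if (any(ok)) which(ok)[1] else NA_integer_,
       coverage = data.frame(slice_index = seq_len(d[3]), cov))
}
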