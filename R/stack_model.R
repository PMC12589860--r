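#' Voxel geometry of a confocal z-stack
#'
#' Records the physical size of a voxel: lateral sampling in the x-y plane
#' and the axial step between optical sections. All depth bookkeeping in the
#' package is expressed through these two numbers.
#'
#' @param pixel_size_xy Lateral sampling, micrometres per pixel (> 0).
#'   Typical confocal acquisitions in this workflow use 0.4 um/pixel.
#' @param z_step Axial slice spacing in micrometres (> 0). A coarse 5 um
#'   step is used for clearing-quality assessment; sub-micron steps for
#'   volumetric reconstruction.
#' @return An object of class `voxel_geometry`.
#' @examples
#' voxel_geometry(0.4, 5)
#' @export
voxel_geometry <- function(pixel_size_xy, z_step) {
  stopifnot(is.numeric(pixel_size_xy), length(pixel_size_xy) == 1L,
            is.numeric(z_step), length(z_step) == 1L)
  if (pixel_size_xy <= 0) stop("pixel_size_xy must be > 0")
  if (z_step <= 0) stop("z_step must be > 0")
  structure(list(pixel_size_xy = as.numeric(pixel_size_xy),
                 z_step = as.numeric(z_step)),
            class = "voxel_geometry")
}

#' Construct a z-stack of fluorescence intensities
#'
#' A z-stack is an ordered series of 2D optical sections at fixed axial
#' spacing. Intensities are carried at native scale (8/16-bit integer or
#' real valued) without normalization: the package's metrics (log-ratio SNR,
#' percent relative intensity, Niblack masks) are invariant to
#' multiplicative gain, so rescaling would only discard acquisition
#' information.
#'
#' @param intensities 3D numeric array, dimensions `(rows, cols, slices)`;
#'   all values must be nonnegative. A matrix is accepted as a single-slice
#'   stack.
#' @param geometry A [voxel_geometry()].
#' @param channel_label Free-text channel description (e.g. a wavelength or
#'   stain name).
#' @param acquisition Optional [optics_settings()] describing the objective
#'   and excitation used.
#' @return An object of class `zstack` with fields `intensities`,
#'   `geometry`, `channel_label`, `acquisition`.
#' @examples
#' zs <- zstack(array(runif(16 * 16 * 3), c(16, 16, 3)), voxel_geometry(0.4, 5))
#' dim(zs$intensities)
#' @export
zstack <- function(intensities, geometry, channel_label = "",
                   acquisition = NULL) {
  if (is.matrix(intensities)) {
    intensities <- array(intensities, c(dim(intensities), 1L))
  }
  if (!is.array(intensities) || length(dim(intensities)) != 3L) {
    stop("intensities must be a (rows, cols, slices) array")
  }
  if (any(dim(intensities) == 0L)) stop("empty stack dimensions")
  if (anyNA(intensities) || any(intensities < 0)) {
    stop("intensities must be nonnegative and free of NA")
  }
  stopifnot(inherits(geometry, "voxel_geometry"))
  if (!is.null(acquisition)) stopifnot(inherits(acquisition, "optics_settings"))
  structure(list(intensities = intensities, geometry = geometry,
                 channel_label = as.character(channel_label),
                 acquisition = acquisition),
            class = "zstack")
}

#' @export
print.zstack <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<zstack> %d x %d pixels, %d slices (%.3g um/px, z-step %.3g um)%s\n",
              d[1], d[2], d[3], x$geometry$pixel_size_xy, x$geometry$z_step,
              if (nzchar(x$channel_label)) paste0(" [", x$channel_label, "]") else ""))
  invisible(x)
}

n_slices <- function(stack) dim(stack$intensities)[3]

get_slice <- function(stack, i) stack$intensities[, , i]

#' Center-crop a z-stack in the x-y plane
#'
#' Every slice is cropped to a `size` x `size` region centered in the image
#' frame; this is the standard guard against vignetting at the field edges
#' and defines the region on which all quantification runs (default
#' analysis size is 512 pixels from a 1024 x 1024 acquisition). The crop is
#' an exact sub-array: no interpolation or resampling. For odd remainders
#' the origin is `floor((extent - size) / 2)` on each axis.
#'
#' @param stack A [zstack()].
#' @param size Crop side length in pixels; must not exceed either image
#'   extent.
#' @return A `zstack` whose slices are `size` x `size`, with attribute
#'   `crop_origin` giving the 1-based (row, col) of the crop's top-left
#'   corner in the source frame.
#' @examples
#' zs <- zstack(array(1, c(8, 8, 2)), voxel_geometry(0.4, 5))
#' attr(crop_center(zs, 4), "crop_origin")  # c(3, 3)
#' @export
crop_center <- function(stack, size) {
  stopifnot(inherits(stack, "zstack"), is.numeric(size), length(size) == 1L)
  size <- as.integer(size)
  d <- dim(stack$intensities)
  if (size < 1L) stop("crop size must be >= 1")
  if (size > d[1] || size > d[2]) {
    stop(sprintf("crop size %d exceeds image extent %d x %d", size, d[1], d[2]))
  }
  r0 <- (d[1] - size) %/% 2L  # 0-based offset, floor rule
  c0 <- (d[2] - size) %/% 2L
  out <- stack
  out$intensities <- stack$intensities[(r0 + 1L):(r0 + size),
                                       (c0 + 1L):(c0 + size), , drop = FALSE]
  attr(out, "crop_origin") <- c(row = r0 + 1L, col = c0 + 1L)
  out
}

#' Number of slices spanning a given imaging depth
#'
#' With slices every `z_step` micrometres and the surface slice counted at
#' depth 0, a depth of `d` micrometres spans `d / z_step + 1` slices
#' (surface inclusive): 150 um at 5-um spacing is 31 slices, 250 um is 51.
#'
#' @param depth Target depth in micrometres (>= 0); must be an integer
#'   multiple of `z_step` to within 1e-9 relative tolerance, since the
#'   package never interpolates between acquired slices.
#' @param z_step Slice spacing in micrometres (> 0).
#' @return Integer slice count.
#' @examples
#' slices_for_depth(150, 5)  # 31
#' slices_for_depth(0, 5)    # 1
#' @export
slices_for_depth <- function(depth, z_step) {
  stopifnot(is.numeric(depth), is.numeric(z_step))
  if (depth < 0) stop("depth must be >= 0")
  if (z_step <= 0) stop("z_step must be > 0")
  k <- depth / z_step
  if (abs(k - round(k)) > 1e-9 * max(1, abs(k))) {
    stop(sprintf("depth %g um is not a multiple of z_step %g um", depth, z_step))
  }
  as.integer(round(k)) + 1L
}

#' Analysis volume: a cropped stack with a designated surface slice
#'
#' The unit of all quantification: a center-cropped z-stack together with
#' the slice index taken as the tissue surface (imaging depth 0). Because
#' vibratome sectioning leaves a rough surface, the surface slice is chosen
#' by the analyst (see [suggest_surface_slice()] for an advisory
#' heuristic); depths are measured from it, not from the first slice.
#'
#' @param stack A (typically cropped) [zstack()].
#' @param surface_index 1-based slice index of imaging depth 0.
#' @param crop_origin Optional 1-based (row, col) of the crop in the source
#'   frame; taken from the `crop_origin` attribute of [crop_center()] output
#'   when present.
#' @return An object of class `analysis_volume`.
#' @export
analysis_volume <- function(stack, surface_index = 1L, crop_origin = NULL) {
  stopifnot(inherits(stack, "zstack"))
  surface_index <- as.integer(surface_index)
  if (surface_index < 1L || surface_index > n_slices(stack)) {
    stop(sprintf("surface_index %d outside stack of %d slices",
                 surface_index, n_slices(stack)))
  }
  if (is.null(crop_origin)) {
    crop_origin <- attr(stack, "crop_origin")
    if (is.null(crop_origin)) crop_origin <- c(row = 1L, col = 1L)
  }
  structure(list(stack = stack, surface_index = surface_index,
                 crop_origin = crop_origin),
            class = "analysis_volume")
}

#' Imaging depth of a slice within an analysis volume
#'
#' @param volume An [analysis_volume()].
#' @param slice_index 1-based slice index at or below the surface slice.
#' @return Depth in micrometres: `(slice_index - surface_index) * z_step`.
#' @examples
#' zs <- zstack(array(1, c(4, 4, 40)), voxel_geometry(0.4, 5))
#' vol <- analysis_volume(zs, surface_index = 4)
#' depth_of_slice(vol, 34)  # 150
#' @export
depth_of_slice <- function(volume, slice_index) {
  stopifnot(inherits(volume, "analysis_volume"))
  slice_index <- as.integer(slice_index)
  if (any(slice_index < volume$surface_index)) {
    stop("slice_index above the surface slice has no defined imaging depth")
  }
  (slice_index - volume$surface_index) * volume$stack$geometry$z_step
}

# Slice indices of an analysis volume at/below the surface, shallow to deep.
analysis_slice_indices <- function(volume) {
  seq.int(volume$surface_index, n_slices(volume$stack))
}
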