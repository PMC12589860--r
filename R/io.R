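# TIFF and JSON plumbing. Multi-page grayscale TIFF is the canonical stack
# format; vendor microscope formats are out of scope for the core and can
# be converted upstream.

#' Read a multi-page grayscale TIFF as a z-stack
#'
#' Pages are read at native bit depth (8- or 16-bit integers are kept
#' as-is, not rescaled to `[0, 1]`). Voxel geometry is supplied by the
#' caller: TIFF tags rarely carry trustworthy physical sampling.
#'
#' @param path Path to a multi-page grayscale TIFF.
#' @param geometry A [voxel_geometry()].
#' @param channel_label Optional channel description.
#' @return A [zstack()].
#' @export
read_stack <- function(path, geometry, channel_label = "") {
  if (!file.exists(path)) stop(sprintf("cannot read stack: '%s' not found", path))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(!vapply(pages, is.matrix, logical(1)))) {
    stop(sprintf("'%s' has non-grayscale pages; supply single-channel planes", path))
  }
  d <- dim(pages[[1]])
  if (any(vapply(pages, function(p) !identical(dim(p), d), logical(1)))) {
    stop(sprintf("'%s' has pages of differing sizes", path))
  }
  arr <- array(0, c(d, length(pages)))
  for (i in seq_along(pages)) arr[, , i] <- pages[[i]]
  zstack(arr, geometry, channel_label)
}

#' Write a z-stack as a multi-page grayscale TIFF
#'
#' Intensities are rounded to integers and stored at the requested bit
#' depth; values exceeding the representable range are an error (no silent
#' clipping of data).
#'
#' @param stack A [zstack()].
#' @param path Output path.
#' @param bits Bits per sample: 8 or 16 (default 16).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, bits = 16L) {
  stopifnot(inherits(stack, "zstack"), bits %in% c(8L, 16L))
  top <- 2^bits - 1
  if (max(stack$intensities) > top) {
    stop(sprintf("intensities exceed %d-bit range", bits))
  }
  pages <- lapply(seq_len(n_slices(stack)), function(i) {
    round(get_slice(stack, i)) / top
  })
  tiff::writeTIFF(pages, path, bits.per.sample = bits)
  invisible(path)
}

#' Analysis configuration
#'
#' Bundles every tunable of the analysis pipeline, with defaults equal to
#' the standard assessment settings: a 512-pixel center crop, 15 bright/
#' dark pairs with 5/20-pixel windows, a 61-pixel search box and 75-pixel
#' spacing, a 55-pixel Niblack window, 5-um z-steps at 0.4 um/pixel, and
#' a 150-um reference depth for percent relative intensity.
#'
#' @param crop_size Center-crop side in pixels.
#' @param snr An [snr_params()].
#' @param niblack A [niblack_params()].
#' @param pixel_size_xy,z_step Voxel geometry in micrometres.
#' @param surface_index Manual 1-based surface slice index, or NULL to use
#'   the [suggest_surface_slice()] heuristic.
#' @param reference_depth Reference depth (um) for percent relative
#'   intensity; falls back to the deepest acquired depth when the stack is
#'   shallower (logged in the report).
#' @param coverage_threshold Quadrant-coverage threshold of the surface
#'   heuristic.
#' @param seed RNG seed recorded in run manifests.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(crop_size = 512L, snr = snr_params(),
                            niblack = niblack_params(),
                            pixel_size_xy = 0.4, z_step = 5,
                            surface_index = NULL, reference_depth = 150,
                            coverage_threshold = 0.02, seed = NULL) {
  structure(list(crop_size = as.integer(crop_size), snr = snr,
                 niblack = niblack,
                 geometry = voxel_geometry(pixel_size_xy, z_step),
                 surface_index = if (is.null(surface_index)) NULL
                                 else as.integer(surface_index),
                 reference_depth = as.numeric(reference_depth),
                 coverage_threshold = as.numeric(coverage_threshold),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "analysis_config")
}

#' Write an analysis configuration to JSON
#' @param config An [analysis_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "analysis_config"))
  x <- list(crop_size = config$crop_size,
            snr = unclass(config$snr),
            niblack = unclass(config$niblack),
            pixel_size_xy = config$geometry$pixel_size_xy,
            z_step = config$geometry$z_step,
            surface_index = config$surface_index,
            reference_depth = config$reference_depth,
            coverage_threshold = config$coverage_threshold,
            seed = config$seed)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read an analysis configuration from JSON
#' @param path Path to a JSON file written by [write_config()] (missing
#'   fields take their defaults).
#' @return An [analysis_config()].
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  def <- analysis_config()
  snr <- do.call(snr_params, utils::modifyList(
    unclass(def$snr), as.list(x$snr %||% list())))
  nib <- do.call(niblack_params, utils::modifyList(
    unclass(def$niblack), as.list(x$niblack %||% list())))
  analysis_config(
    crop_size = x$crop_size %||% def$crop_size,
    snr = snr, niblack = nib,
    pixel_size_xy = x$pixel_size_xy %||% def$geometry$pixel_size_xy,
    z_step = x$z_step %||% def$geometry$z_step,
    surface_index = x$surface_index,
    reference_depth = x$reference_depth %||% def$reference_depth,
    coverage_threshold = x$coverage_threshold %||% def$coverage_threshold,
    seed = x$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a phantom specification to JSON
#' @param spec A [phantom_spec()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phantom_spec <- function(spec, path) {
  stopifnot(inherits(spec, "phantom_spec"))
  x <- unclass(spec)
  x$geometry <- unclass(x$geometry)
  x$attenuation <- unclass(x$attenuation)
  x$noise <- unclass(x$noise)
  if (!is.null(x$vessels)) {
    x$vessels <- lapply(x$vessels, function(v)
      list(centerline = unname(v$centerline), radius_um = v$radius_um,
           intensity = v$intensity))
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a phantom specification from JSON
#' @param path Path to a JSON file written by [write_phantom_spec()].
#' @return A [phantom_spec()].
#' @export
read_phantom_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$seed)) stop("phantom spec JSON must carry a seed")
  vessels <- NULL
  if (!is.null(x$vessels) && length(x$vessels) > 0) {
    vl <- if (is.data.frame(x$vessels)) {
      lapply(seq_len(nrow(x$vessels)), function(i) as.list(x$vessels[i, ]))
    } else x$vessels
    vessels <- lapply(vl, function(v) {
      cl <- v$centerline
      if (is.list(cl)) cl <- do.call(rbind, lapply(cl, unlist))
      vessel_spec(matrix(as.numeric(cl), ncol = 3), v$radius_um, v$intensity)
    })
  }
  def <- phantom_spec(seed = 0L)
  att <- if (is.null(x$attenuation)) def$attenuation
         else attenuation_model(x$attenuation$model, x$attenuation$rate %||% 0)
  noi <- if (is.null(x$noise)) def$noise
         else noise_model(x$noise$model, x$noise$sd %||% 0, x$noise$gain %||% 1)
  phantom_spec(
    shape = x$shape %||% def$shape,
    geometry = voxel_geometry(x$geometry$pixel_size_xy %||% 0.4,
                              x$geometry$z_step %||% 5),
    vessels = vessels,
    n_vessels = x$n_vessels %||% def$n_vessels,
    radius_mean_um = x$radius_mean_um %||% def$radius_mean_um,
    radius_sd_um = x$radius_sd_um %||% def$radius_sd_um,
    length_mean_um = x$length_mean_um %||% def$length_mean_um,
    length_sd_um = x$length_sd_um %||% def$length_sd_um,
    tilt_sd_deg = x$tilt_sd_deg %||% def$tilt_sd_deg,
    vessel_intensity = x$vessel_intensity %||% def$vessel_intensity,
    background_level = x$background_level %||% def$background_level,
    background_texture_sd = x$background_texture_sd %||% def$background_texture_sd,
    attenuation = att,
    quencher_rate = x$quencher_rate %||% def$quencher_rate,
    noise = noi,
    seed = x$seed)
}
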