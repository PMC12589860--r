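# File-in/file-out pipeline drivers. These functions are the command
# surface of the package: each takes paths or in-memory objects, runs the
# corresponding analysis modules, and writes a deterministic report bundle
# (CSV tables plus JSON summaries and a run manifest). Given identical
# inputs and configuration, reruns produce byte-identical outputs.

write_manifest <- function(output_dir, command, config_list, seed = NULL,
                           notes = character()) {
  jsonlite::write_json(
    list(package = "clariquant",
         version = as.character(utils::packageVersion("clariquant")),
         schema_version = 1L,
         command = command,
         config = config_list,
         seed = seed,
         notes = notes),
    file.path(output_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, null = "null")
}

config_as_list <- function(config) {
  list(crop_size = config$crop_size, snr = unclass(config$snr),
       niblack = unclass(config$niblack),
       pixel_size_xy = config$geometry$pixel_size_xy,
       z_step = config$geometry$z_step,
       surface_index = config$surface_index,
       reference_depth = config$reference_depth,
       coverage_threshold = config$coverage_threshold,
       seed = config$seed)
}

#' Run the full image-quality analysis on one z-stack
#'
#' Orchestrates the standard per-stack workflow: center-crop, surface
#' slice designation (manual from the config, or the advisory coverage
#' heuristic when unset), per-slice SNR, depth-intensity profile, and
#' percent relative intensity. When the configured reference depth exceeds
#' the acquired depth, the deepest acquired depth is used instead and
#' noted. Writes `snr_slices.csv`, `snr_pairs.csv`, `depth_profile.csv`,
#' `summary.json`, and `manifest.json` (which logs all decisions taken:
#' surface-index source, reference-depth fallback, dropped pairs).
#'
#' @param stack A [zstack()] or a path to a multi-page grayscale TIFF.
#' @param config An [analysis_config()].
#' @param output_dir Directory for the report bundle (created if absent).
#' @return Invisibly, a list with `volume`, `snr`, `profile`, `summary`.
#' @export
run_analyze <- function(stack, config = analysis_config(), output_dir) {
  stopifnot(inherits(config, "analysis_config"))
  if (is.character(stack)) {
    stack <- read_stack(stack, config$geometry)
  }
  stopifnot(inherits(stack, "zstack"))
  if (!is.null(config$surface_index) &&
      config$surface_index > n_slices(stack)) {
    stop(sprintf("surface_index %d beyond stack of %d slices",
                 config$surface_index, n_slices(stack)))
  }
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  notes <- character()

  cropped <- crop_center(stack, config$crop_size)
  if (is.null(config$surface_index)) {
    sug <- suggest_surface_slice(cropped, config$coverage_threshold,
                                 config$niblack)
    if (is.na(sug$surface_index)) {
      stop("no surface slice found by the coverage heuristic; set surface_index")
    }
    surface <- sug$surface_index
    notes <- c(notes, sprintf("surface_index %d from coverage heuristic", surface))
  } else {
    surface <- config$surface_index
    notes <- c(notes, sprintf("surface_index %d set manually", surface))
  }
  volume <- analysis_volume(cropped, surface)

  snr_res <- withCallingHandlers(
    stack_snr(volume, config$snr),
    warning = function(w) {
      notes <<- c(notes, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  profile <- depth_profile(volume, snr = snr_res)

  ref <- config$reference_depth
  max_depth <- max(profile$depth_um)
  if (ref > max_depth) {
    ref <- max_depth
    notes <- c(notes, sprintf(
      "reference depth %g um unavailable; fell back to deepest acquired depth %g um",
      config$reference_depth, ref))
  }
  pri <- percent_relative_intensity(profile, ref)

  summary <- list(
    percent_relative_intensity = pri$percent_relative_intensity,
    reference_depth_um = pri$reference_depth_um,
    surface_index = surface,
    n_slices_analyzed = nrow(profile),
    snr_at_surface = profile$snr[profile$depth_um == 0])
  if (!is.null(stack$acquisition)) {
    summary$lateral_resolution_nm <- lateral_resolution(stack$acquisition)
    summary$axial_resolution_nm <- axial_resolution(stack$acquisition)
    summary$nyquist_satisfied <-
      nyquist_satisfied(stack$acquisition, config$geometry$z_step)
  }

  write.csv(snr_res$summary, file.path(output_dir, "snr_slices.csv"),
            row.names = FALSE)
  write.csv(snr_pairs_table(snr_res), file.path(output_dir, "snr_pairs.csv"),
            row.names = FALSE)
  write.csv(as.data.frame(profile), file.path(output_dir, "depth_profile.csv"),
            row.names = FALSE)
  jsonlite::write_json(summary, file.path(output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  write_manifest(output_dir, "analyze", config_as_list(config),
                 seed = config$seed, notes = notes)
  invisible(list(volume = volume, snr = snr_res, profile = profile,
                 summary = summary))
}

#' Generate a phantom and write it to disk
#'
#' Runs [generate_phantom()] and writes the stack as a 16-bit multi-page
#' TIFF, the truth vessel mask as an 8-bit TIFF (0/255), and a truth JSON
#' (per-slice expected mean intensities, attenuation factors, seed).
#'
#' @param spec A [phantom_spec()] or a path to a phantom-spec JSON.
#' @param output_dir Directory for the bundle (created if absent).
#' @return Invisibly, the generated `phantom` object.
#' @export
run_simulate <- function(spec, output_dir) {
  if (is.character(spec)) spec <- read_phantom_spec(spec)
  stopifnot(inherits(spec, "phantom_spec"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  ph <- generate_phantom(spec)
  write_stack(ph$stack, file.path(output_dir, "phantom.tif"), bits = 16L)
  mask_stack <- zstack(ph$truth$vessel_mask * 255, spec$geometry,
                       channel_label = "truth_mask")
  write_stack(mask_stack, file.path(output_dir, "truth_mask.tif"), bits = 8L)
  jsonlite::write_json(
    list(expected_mean_intensity = ph$truth$expected_mean_intensity,
         attenuation_factors = ph$truth$attenuation_factors,
         attenuation = unclass(spec$attenuation),
         quencher_rate = spec$quencher_rate,
         seed = spec$seed),
    file.path(output_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  write_manifest(output_dir, "simulate", list(), seed = spec$seed)
  invisible(ph)
}

#' Run the two-channel colocalization pipeline on files
#'
#' Reads two co-registered single-plane grayscale TIFFs (or accepts
#' matrices), runs [coloc_pipeline()], writes both Niblack masks as 8-bit
#' TIFFs and a JSON report (pixel counts, DICE score, per-channel SNR).
#'
#' @param channel_a,channel_b Paths to single-plane TIFFs, or 2D matrices.
#' @param config An [analysis_config()].
#' @param output_dir Directory for the bundle (created if absent).
#' @return Invisibly, the `coloc_result`.
#' @export
run_coloc <- function(channel_a, channel_b, config = analysis_config(),
                      output_dir) {
  load_plane <- function(x) {
    if (is.character(x)) {
      s <- read_stack(x, config$geometry)
      if (n_slices(s) != 1L) stop("colocalization expects single-plane images")
      get_slice(s, 1L)
    } else as_slice_matrix(x)
  }
  a <- load_plane(channel_a)
  b <- load_plane(channel_b)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  res <- coloc_pipeline(a, b, config$niblack, config$snr)
  for (ch in c("a", "b")) {
    m <- res[[paste0("mask_", ch)]]$mask
    write_stack(zstack(m * 255, config$geometry),
                file.path(output_dir, paste0("mask_", ch, ".tif")), bits = 8L)
  }
  jsonlite::write_json(
    list(pixels_a = res$dice$pixels_a, pixels_b = res$dice$pixels_b,
         pixels_common = res$dice$pixels_common,
         dice = res$dice$score, dice_undefined = res$dice$undefined,
         snr_a = res$snr_a$snr, snr_b = res$snr_b$snr),
    file.path(output_dir, "coloc.json"), auto_unbox = TRUE, digits = NA)
  write_manifest(output_dir, "coloc", config_as_list(config))
  invisible(res)
}

#' Run condition-comparison statistics on a sample table
#'
#' Reads a CSV (or accepts a data.frame) with one row per sample, runs the
#' ANOVA ([anova_conditions()]) and per-factor Tukey HSD follow-up
#' ([tukey_hsd_conditions()]), and writes `anova.csv`, one
#' `tukey_<factor>.csv` per factor, and a human-readable `report.txt`.
#'
#' @param table Path to a CSV or a data.frame.
#' @param metric Response column name.
#' @param factors One or two factor column names.
#' @param alpha Significance level (default 0.05).
#' @param output_dir Directory for the bundle (created if absent).
#' @return Invisibly, a list with `anova` and `tukey` (named by factor).
#' @export
run_compare <- function(table, metric, factors, alpha = 0.05, output_dir) {
  if (is.character(table)) table <- read.csv(table)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  an <- anova_conditions(table, metric, factors)
  tk <- lapply(setNames(factors, factors), function(f)
    tukey_hsd_conditions(table, metric, f, alpha))
  write.csv(as.data.frame(an), file.path(output_dir, "anova.csv"),
            row.names = FALSE)
  for (f in factors) {
    write.csv(as.data.frame(tk[[f]]),
              file.path(output_dir, paste0("tukey_", f, ".csv")),
              row.names = FALSE)
  }
  lines <- c(sprintf("ANOVA on '%s' (%s sums of squares)", metric,
                     attr(an, "ss_type")),
             utils::capture.output(print.data.frame(an, row.names = FALSE)),
             "", sprintf("Tukey HSD at alpha = %g", alpha))
  for (f in factors) {
    lines <- c(lines, sprintf("-- factor %s", f),
               utils::capture.output(print.data.frame(tk[[f]], row.names = FALSE)))
  }
  lines <- c(lines, "", paste("note:", attr(an, "caveat")))
  writeLines(lines, file.path(output_dir, "report.txt"))
  write_manifest(output_dir, "compare",
                 list(metric = metric, factors = factors, alpha = alpha))
  invisible(list(anova = an, tukey = tk))
}
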