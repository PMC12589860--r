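# Phantom builders shared across tests. Tests run on reduced stacks
# (64-128 px laterally) with proportionally scaled window parameters so
# the full geometry logic is exercised at a fraction of the cost.

# Window parameters scaled for 64-128 px toy slices.
toy_snr_params <- function(n_regions = 5L) {
  snr_params(n_regions = n_regions, bright_window = 3L, dark_window = 6L,
             search_box = 15L, min_distance = 10)
}

# Vertical (z-penetrating) vessels at seeded lateral positions: every
# slice has an identical noiseless cross-section, so the unattenuated
# per-slice mean is depth-constant and the measured profile isolates the
# attenuation model exactly.
columnar_vessels <- function(n_slices, size, n_vessels, radius_um = 3.55,
                             intensity = 150, pixel_size_xy = 0.4,
                             seed = 1, margin_px = 12) {
  set.seed(seed)
  lapply(seq_len(n_vessels), function(i) {
    r <- runif(1, margin_px, size - margin_px)
    c <- runif(1, margin_px, size - margin_px)
    vessel_spec(rbind(c(1, r, c), c(n_slices, r, c)), radius_um, intensity)
  })
}

columnar_phantom_spec <- function(seed, n_slices = 31L, size = 128L,
                                  n_vessels = 8L,
                                  rate = 0.004, quencher_rate = 0,
                                  noise_sd = 0.4, texture_sd = 5,
                                  background_level = 20) {
  phantom_spec(
    shape = c(n_slices, size, size),
    geometry = voxel_geometry(0.4, 5),
    vessels = columnar_vessels(n_slices, size, n_vessels, seed = seed),
    background_level = background_level,
    background_texture_sd = texture_sd,
    attenuation = attenuation_model("exponential", rate),
    quencher_rate = quencher_rate,
    noise = if (noise_sd > 0) noise_model("gaussian", sd = noise_sd)
            else noise_model("none"),
    seed = seed)
}

# Small randomly oriented network phantom for structural tests.
toy_network_spec <- function(seed, n_slices = 9L, size = 96L, n_vessels = 6L,
                             noise = noise_model("none"),
                             attenuation = attenuation_model("none"),
                             texture_sd = 0) {
  phantom_spec(shape = c(n_slices, size, size),
               geometry = voxel_geometry(0.4, 5),
               n_vessels = n_vessels,
               length_mean_um = 40, length_sd_um = 10,
               background_level = 20, background_texture_sd = texture_sd,
               attenuation = attenuation, noise = noise, seed = seed)
}

# Dilate a logical matrix by one pixel (8-neighborhood).
dilate1 <- function(m) {
  d <- dim(m)
  out <- m
  for (dr in -1:1) for (dc in -1:1) {
    rs <- pmin(pmax(seq_len(d[1]) + dr, 1L), d[1])
    cs <- pmin(pmax(seq_len(d[2]) + dc, 1L), d[2])
    out <- out | m[rs, cs]
  }
  out
}
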