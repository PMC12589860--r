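# clariquant

Image-quality metrics for tissue-clearing confocal microscopy.

Tissue-clearing protocols (CUBIC and relatives) render thick tissue
transparent so labeled microvasculature can be imaged well below the cut
surface. Whether a protocol variant *worked* — stronger delipidation,
a different autofluorescence quencher, another label — is a quantitative
question about the resulting z-stacks. `clariquant` answers it with three
metric families computed directly from multi-page TIFF stacks:

- **Paired bright/dark SNR.** On each optical section, up to 15 bright
  5 × 5-pixel windows (on vessels) are selected greedily with a 75-pixel
  spacing constraint; each is paired with the 20 × 20 window of minimal
  intensity standard deviation inside a 61 × 61 search box (quiet
  extravascular tissue). The slice SNR is the mean of
  `SNR_i = log10(mu_bright / sigma_dark)` over pairs.
- **Depth penetration.** Per-slice mean intensity versus imaging depth,
  summarized as *percent relative intensity*:
  `100 × mean_intensity(reference depth) / mean_intensity(0)`, reference
  150 µm (or the deepest depth common to a batch, typically 105 µm).
- **Colocalization.** Niblack local thresholding (threshold
  `mu_w − sigma_w`, 55-pixel window) binarizes two co-registered
  channels; overlap is scored with `DICE = 2|A∩B| / (|A|+|B|)`.

Around these: theoretical lateral/axial resolution from acquisition
settings (Rayleigh `0.61 λ/NA`; wide-field `2 n λ/NA²`), one-way and
additive two-way ANOVA with Tukey HSD follow-up for condition
comparisons, and a seeded synthetic vascular-phantom generator with
ground truth (tubular vessels, heterogeneous background, exponential or
linear depth attenuation, quencher suppression, gaussian/Poisson noise)
so the whole chain is testable without microscope data.

## Worked example

Generate a phantom stack and run the standard analysis (a 256-pixel
stack keeps the example fast; real 512-pixel crops use the same code and
the same default window parameters):

```r
library(clariquant)

spec <- phantom_spec(shape = c(31, 256, 256), n_vessels = 15, seed = 7)
ph   <- generate_phantom(spec)

cfg <- analysis_config(crop_size = 256, surface_index = 1)
res <- run_analyze(ph$stack, cfg, "demo_out")

head(res$snr$summary, 3)
#>   slice_index depth_um n_pairs       snr
#> 1           1        0      13 0.9262244
#> 2           2        5      12 1.0016854
#> 3           3       10      12 0.9636490

percent_relative_intensity(res$profile, 150)
#> percent relative intensity at 150 um: 72.47%
```

Reading the output: the surface slice reports SNR ≈ 0.93, i.e. the
typical bright vessel window is about 10^0.93 ≈ 8.4 times the local
background standard deviation; fewer than the full 15 pairs are feasible
on a 256-pixel slice under the 75-pixel spacing rule (the analysis
proceeds with the feasible pairs and logs a note). The stack retains
72.5 % of its surface intensity at 150 µm — depth penetration a
well-cleared sample would show. `demo_out/` holds `snr_slices.csv`,
`snr_pairs.csv`, `depth_profile.csv`, `summary.json`, and a
`manifest.json` recording every decision taken (surface-index source,
reference-depth fallback, dropped pairs). Reruns on identical input are
byte-identical.

With acquisition metadata the report includes the theoretical optics:

```r
s <- optics_settings(excitation_wavelength_nm = 561,
                     numerical_aperture = 0.75, refractive_index = 1.52)
lateral_resolution(s)$nm_rounded  # 456
axial_resolution(s)$nm_rounded    # 3032
```

Condition comparison from a per-sample table:

```r
run_compare(samples, metric = "pri", factors = "quencher",
            output_dir = "stats_out")
```

writes the ANOVA table, per-factor Tukey HSD pairwise comparisons, and a
plain-text report.

See `vignettes/clearing-image-quality.Rmd` for the full account of the
methods, conventions, and the phantom generator's scope.

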