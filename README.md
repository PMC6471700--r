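# nirdr

Analysis pipeline for multiplexed-LED near-infrared (NIR) diffuse
reflectance videos acquired with a smartphone-class camera, validated by
venous-occlusion studies — together with a synthetic acquisition simulator
that replaces the physical device so the entire chain is testable at a desk.

## The problem

Low-cost NIR imaging of tissue works by shining NIR light (here 690, 800,
840 nm, time-multiplexed with a white-light reference at 2.5 Hz) on the skin
and recording the diffusely reflected light as 60 fps video. The red channel
of each frame carries the signal; reflectance at 690 nm falls as
deoxy-hemoglobin rises, so a pressure-cuff venous occlusion produces a known
physiological contrast (reflectance drops under occlusion, overshoots on
release) against which a device and its software can be validated. The raw
images, however, are dominated by specular surface glare; the subsurface
physiological signal only emerges after the glare is removed.

This package is for researchers building or evaluating such imaging
pipelines. It implements:

* **Simulation** — `acq_config()`, `tissue_phantom()`, `render_video()`,
  `render_occlusion_study()`: annotated synthetic acquisitions with a
  planted low-rank surface layer, smooth subsurface perfusion field,
  occlusion response, fiducial marker, and sensor noise.
* **Demultiplexing** — `intensity_profile()`, `segment_profile()`,
  `estimate_switching_frequency()`, `extract_wavelength_images()`: recover
  per-wavelength images from the video via the red-channel intensity
  profile (plateau thresholding, white-flash cycle delimiting).
* **Surface-noise removal** — `svd_decompose()`, `reconstruct_band()`,
  `reconstruct_series()`: for an image matrix `X = U S Vᵀ`, the eigen-band
  reconstruction `A(a:b) = Σ_{k=a..b} σ_k u_k v_kᵀ` discards the leading,
  glare-dominated singular components (band `4:15` keeps components 4-15).
* **Coregistration** — `register_images()`, `apply_transform()`:
  intensity-based regular-step gradient descent (initial step 0.02, up to
  300 iterations; translation/rigid/affine) onto the white-light
  anatomical image.
* **Occlusion statistics** — `sample_boxes()`, `summarize_timestamp()`,
  `hypothesis_counter()`, `run_study()`: seventeen 30 × 30 pixel boxes per
  region of interest, paired t-tests (df = 16) on per-box means for
  rest vs. occlusion and occlusion vs. release, and the hypothesis counter
  `H = 1{p_ro < α} + 1{p_or < α} ∈ {0, 1, 2}` at α = 0.05, repeated with
  redrawn boxes.
* **Orchestration** — `pipeline_config()`, `run_pipeline()`, and a thin
  command-line front end at `inst/cli/nirdr` with verbs
  `simulate | demux | denoise | coregister | study | run`.

## Worked example

Simulate an occlusion study with a rank-3 glare layer, analyse the 690 nm
channel across eigen bands, and read off the hypothesis counters:

```r
library(nirdr)

config  <- acq_config()                      # 60 fps, 2.5 Hz, 3 cycles
phantom <- tissue_phantom(r_surf = 3)        # occlusion 0.8 / release 1.1 at 690 nm

study <- list(
  rest      = render_wavelength_image(config, phantom, "NIR690", "REST",      seed = 11),
  occlusion = render_wavelength_image(config, phantom, "NIR690", "OCCLUSION", seed = 12),
  release   = render_wavelength_image(config, phantom, "NIR690", "RELEASE",   seed = 13),
  white     = render_white_still(phantom, seed = 14))

result <- run_study(study, base_seed = 1)
print(result)
#> Occlusion study analysis at NIR690 (alpha = 0.05, 4 repetitions per band)
#> Hypothesis counter H by eigen band and repetition:
#>      1 2 3 4
#> 1:15 2 2 2 2
#> 2:15 2 2 2 2
#> 3:15 2 2 2 2
#> 4:15 2 2 2 2
#> 5:15 0 0 0 0

summary(result)
#> Mean diffuse reflectance (normalized) and mean H by eigen band, NIR690:
#>   band mean_H mean_rest mean_occlusion mean_release
#> 1 1:15      2   0.04083        0.03255      0.04496
#> 2 2:15      2   0.46817        0.46043      0.47208
#> 3 3:15      2   0.48949        0.48192      0.49329
#> 4 4:15      2   0.19910        0.18216      0.20773
#> 5 5:15      0   0.14679        0.14674      0.14683
```

Reading the output: at every band the mean normalized reflectance dips under
occlusion and overshoots at release. With a rank-3 glare layer the
subsurface field occupies singular components 4 and beyond, so bands that
retain component 4 detect both paired comparisons in all four box redraws
(`H = 2`), while band `5:15` — which also strips the subsurface's dominant
component — loses the effect (`H = 0`). On real data the glare also varies
between acquisitions, which is what pushes the low bands toward `H = 0`
there; see the methods vignette (`vignettes/nirdr-methods.Rmd`) for what the
simulator does and does not emulate.

The same analysis runs from the shell:

```sh
Rscript inst/cli/nirdr run --seed 1 --out run_out/
```

writing the hypothesis table, per-band means ± sd, intensity profiles,
demultiplexed images, overlays, and a provenance manifest.

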