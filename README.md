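# gelmob

Quantification of enzyme mobility in pectin/cellulose gels from
time-lapse deep-UV autofluorescence images, together with a
ground-truthed synthetic acquisition simulator.

## The problem

A pectin methylesterase deposited in a channel along one edge of a
calcium/pectin gel migrates into the gel while de-esterifying it.  Its
tryptophan/tyrosine autofluorescence (275 nm excitation) makes the
enzyme visible label-free in a widefield microscope: 7 fields of view
("positions" Pos0..Pos6, 287 µm wide each) along the migration axis, 12
acquisitions at 5-min intervals, 5-plane z-stacks, 16-bit frames.  The
question — how mobile is the enzyme, and how do catalytic activity and
cellulose content change that — is answered from the mean fluorescence
per position and time.

`gelmob` provides, for users analysing such acquisitions or studying the
method itself:

* **Geometry** — the ROI layout (two contiguous fields, then every
  other field: start distances 0, 287, 861, 1436, 2010, 2584, 3158 µm)
  and pixel/physical coordinate mapping.
* **Shading correction** — `IMC = (IM − BKG)/ILL`, with BKG averaged
  from dark frames and ILL estimated from one raw frame by morphological
  opening → closing → mean filtering (105-px windows).
* **Sampling** — random measurement lines (which can dodge
  non-fluorescent cellulose particles) or centred circles; z-averaged
  mean intensities per position and time.
* **Kinetics** — normalization on the (Pos0, T0) value, intensity vs
  time and vs position tables/figures, penetration depths.
* **Synthetic data** — a reaction–diffusion + optics/camera model
  (draining reservoir with a convective loading smear, obstacles,
  vignetting, shot and read noise, defocus) that renders complete
  acquisitions with known ground truth, reproducibly from one seed.
* **Biophysics** — hydrodynamic-radius power laws
  (`Rh(Å) = 4.75·N^0.29` native, `2.21·N^0.57` denatured), closed-form
  diffusion profiles, and effective-diffusivity recovery with a
  measurement-aware fit.

## Worked example

A complete desk-scale experiment — simulate a cellulose-free gel with
active enzyme, estimate the shading model, extract random-line
intensities, normalize, and summarise:

```r
library(gelmob)
cfg <- default_run_config(out = tempfile("demo_"), seed = 1,
                          scenario = "g00_active", reduced = TRUE)
res <- run_all(cfg)
#> simulate: 7 positions x 12 times x 5 z -> .../run
#> preprocess: shading model written to .../shading
#> extract_profiles: up to 49% negative pixels in corrected frames (expected where signal ~ 0)
#> extract: 84 records -> records.csv
#> kinetics: tables and figures -> ...
#> penetration depth at 45 min:
#>   experiment gel enzyme_state time_min penetration_um
#> 1 g00_active g00       active       45       1435.648

subset(res$table, pos %in% c(0, 1, 3) & time_min %in% c(0, 45),
       select = c(pos, time_min, mean_counts, normalized_intensity))
#>    pos time_min mean_counts normalized_intensity
#> 1    0        0   708.23834           1.00000000
#> 10   0       45   641.24933           0.90541460
#> 13   1        0   336.22302           0.47473146
#> 22   1       45   485.02371           0.68483120
#> 37   3        0    22.09447           0.03119638
#> 46   3       45    49.10306           0.06933126
```

Reading the numbers: the corrected Pos0 intensity at the first time
point (708 counts) sits in the expected 600–800 band and normalizes to
exactly 1; Pos1 starts near half of Pos0 (the loading profile); by
45 min the signal has advanced so that Pos3 (1436 µm) is the farthest
position above the 5 % detection threshold — the printed penetration
depth.  With 1.5 % cellulose the active enzyme reaches Pos5–Pos6, while
the heat-inactivated enzyme never passes Pos2 (861 µm).

Protein size from the residue count:

```r
hydrodynamic_radius(314, "native")
#> native protein, N = 314 residues: Rh = 25.2 A, diameter = 5.03 nm (~5 nm)
```

A command-line front-end mirroring the pipeline stages is installed at
`inst/scripts/gelmob.R`
(`Rscript gelmob.R all --config cfg.json --seed 1`); example configs are
under `inst/extdata/`.

## Acceptance script

`scripts/acceptance.R` recomputes, from scratch against the installed
package, the reference quantities that are functions of the stated
geometry and formulas — the Pos2 start distance from the ROI layout, the
native-enzyme hydrodynamic diameter, and the (Pos0, T0) normalization
identity on a complete synthetic acquisition run through the full
chain — and writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
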