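# txmkit

Data evaluation for full-field transmission X-ray microscopy (TXM), as an R
package with a scriptable command line.

Synchrotron TXM images tens-of-µm fields of view at tens-of-nm resolution
through a Fresnel zone-plate objective, and its energy tunability turns the
microscope into a spectrometer: recording image stacks across an element's
absorption edge yields one X-ray absorption near-edge structure (XANES)
spectrum *per pixel* — up to ~10⁶ spectra per field of view. `txmkit`
provides the evaluation chain such experiments need:

* **core I/O** — TIFF series (with CSV metadata sidecars) and self-describing
  HDF5 stacks; flat-field (reference) correction; conversion to optical
  density `OD = −ln T`, which is additive in absorber thickness
  (Beer–Lambert) and therefore the working unit of every later stage.
* **registration** — zone-plate optics (`f = DΔ/λ`, so magnification varies
  with energy and is corrected from metadata by bicubic resampling) and
  translation measurement by phase correlation: the whitened cross-power
  spectrum `R = F₁F₂*/|F₁F₂*|` turns a shift into an impulse, located to
  sub-pixel precision by a separable parabolic peak fit.
* **dual-energy (2E) mapping** — `OD(above edge) − OD(below edge)` after
  magnification correction and alignment maps a single element; absorbers
  without an edge in the interval (e.g. Au fiducials, whose transmission
  changes only ~2% between 6500 and 6650 eV) cancel.
* **mosaic stitching** — motor-position seeding, phase-correlation
  refinement of every overlapping 4-neighbour tile pair, global
  least-squares placement, and feathered weighted-average blending that
  suppresses the poorer signal-to-noise of tile corners.
* **tomography** — parallel-beam filtered back projection (Ram-Lak /
  Shepp-Logan / Hann filters, ROI reconstruction) and iterative Kaczmarz
  ART (`x ← x + λ (pᵢ − ⟨aᵢ,x⟩)/‖aᵢ‖² aᵢ`), with projection-jitter
  correction that separates stage jitter from genuine parallax (harmonic
  consistency of the projected center of mass) and automatic
  rotation-center finding.
* **XANES imaging** — per-pixel edge-jump maps `J = ⟨OD⟩post − ⟨OD⟩pre`
  (proportional to areal concentration), noise filtering at `J ≥ k·σpre`,
  regression-based normalization to 0/1 with slope filtering, half-height
  edge-energy maps (linear interpolation of the first upward 0.5 crossing),
  edge-energy histogram clustering, non-negative least-squares linear
  combination fitting against reference spectra with per-pixel R-factor
  `R = Σ(μ−fit)²/Σμ²`, edge-jump vs R-factor clustering (flags phases
  missing from the reference set), and RGB phase maps intensity-weighted by
  the edge jump.
* **phantoms** — seeded generators for every input above (XANES stacks with
  known weight/edge-energy maps, mosaic tile sets with known offsets,
  projection series with known jitter, the Shepp-Logan phantom), returning
  ground truth alongside the data.

## Worked example

```r
library(txmkit)

ph  <- make_xanes_stack(xanes_phantom(seed = 42))   # 128x128, 50 energies
res <- xanes_analyze(ph$stack, ph$truth$cfg, refs = ph$truth$refs)

sum(res$combined_mask)                   # pixels surviving both filters
range(res$edge_jump[res$combined_mask])  # OD edge jump = concentration map
median(res$rfactor[res$combined_mask])   # quality of the LC fits
sapply(res$weights, function(m) mean(m[res$combined_mask]))
```

prints

```
pixels kept by combined filter: 5383 of 16384
edge-jump range (OD): 0.996 1.511
edge-energy range (eV): 7115.04 7131.02
median R-factor: 0.00214
phase1 phase2 phase3
 0.382  0.366  0.254
```

i.e. the filters keep exactly the specimen-covered third of the field of
view, the edge jump tracks the thickness dome (~1–1.5 OD), the recovered
edge energies span the three generated phases (7116/7123/7130 eV), the fits
are excellent (median R ≈ 0.002), and the mean phase fractions reflect the
two pure disks plus the mixed block of the phantom. `res$rgb` holds the
phase map with red/green/blue = phase 1/2/3, intensity = edge jump.

## Command line

```sh
TXMKIT=$(Rscript -e 'cat(system.file("cli/txmkit.R", package = "txmkit"))')
Rscript $TXMKIT simulate --kind tomo --seed 2 --out sim/
Rscript $TXMKIT tomo --input sim/series.h5 --algorithm fbp --filter ramlak --out vol.h5
Rscript $TXMKIT stitch --tiles tiles/ --metadata tiles/tiles.csv --overlap 0.2 --out mosaic.tif
Rscript $TXMKIT xanes --stack stack.h5 --pre 7080,7110 --post 7150,7200 \
        --e0 7125 --k 3 --refs ref1.txt,ref2.txt --out result.h5
```

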