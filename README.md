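# puncta

Quantification of multiplex single-molecule FISH (smFISH / RNAscope-style)
images in R.

Multiplex fluorescent in situ hybridisation renders every target mRNA
molecule as a diffraction-limited "dot" in one of several probe channels.
Most quantification practice stops at mean channel intensity or counts of
"positive" cells, discarding the single-molecule information the assay
provides. `puncta` implements the full per-molecule pipeline for
4-channel fields (three probes + DAPI) and the statistics used to relate
per-cell copy numbers to behaviour in individual-differences designs:

* **Dot detection** — difference-of-Gaussians band-pass filter
  (`blur(img, σ₁) − blur(img, σ₂)`, defaults σ₁ = 0.5 px, σ₂ = 3 px),
  local-maxima detection above independent per-channel thresholds
  (th1, th2, th4) with greedy non-maximum suppression.
* **Nuclei segmentation** — Gaussian smoothing of the DAPI channel
  (σ = 7 px), three-level Otsu quantisation (nuclei at different depths
  are not equally bright; the union of the three foreground tiers is the
  mask), a tolerance watershed on the distance transform to separate
  touching nuclei, a brightness-adaptive halo correction, and a
  minimum-area filter. Alternative segmenters (e.g. star-convex polygon
  models) plug in via `registerBackend()`.
* **Dot-to-cell assignment** — a molecule within 10 px (inclusive) of a
  nucleus mask belongs to that nucleus; nearer nucleus wins, ties to the
  lower label; the rest are counted unassigned. Per-cell copy numbers are
  exported per field, summed per animal, and cells are classified into
  the 2³ marker-positivity ensembles (e.g. TH+/zif268−/Arc+), whose
  percentages partition 100% of cells.
* **Statistics** — quartile phenotyping of drinking cohorts
  (top/bottom ⌊N/4⌋ by final-3-session mean intake), Kruskal-Wallis
  comparisons of animal-level values, and session × metric Spearman
  correlation matrices with Benjamini-Hochberg correction over each
  matrix as one family.
* **Synthetic data** — a generator of 4-channel fields with exact ground
  truth (nucleus masks, per-cell true counts, planted stray molecules)
  and of schedule-induced-polydipsia-style drinking cohorts with planted
  escalators, so the whole pipeline is testable without microscope data.

Everything is driven by one frozen configuration per assay batch, set on
a sample image and recorded verbatim with every run.

## Worked example

```r
library(puncta)

## a synthetic 512x512 field: 20 nuclei, Poisson(5) molecules per cell
## and channel, 5% stray molecules, SNR 20
fg <- generateField(fieldSpec(seed = 7))
fg$truth
#> FieldGroundTruth: 20 nuclei, 294 molecules (15 stray)

cfg <- punctaConfig()                      # th1 = th2 = th4 = 0.25, frozen
ss  <- detectFieldSpots(fg$field, cfg@thresholds)
ss
#> SpotSet: 294 puncta (ch1: 96, ch2: 97, ch4: 101)
#>   thresholds: ch1=0.25, ch2=0.25, ch4=0.25

seg <- segmentNuclei(channelImage(fg$field, 3))
seg
#> NucleusLabelMap: 20 nuclei over 512 x 512 px

cct <- assignSpots(ss, seg, maxDist = 10, fieldId = "demo_f01")
cct
#> CellCountTable [demo_f01]: 20 cells
#>   assigned copies: ch1=91, ch2=92, ch4=96
#>   unassigned: ch1=5, ch2=5, ch4=5

head(cellCounts(cct), 4)
#>   field_id nucleus        x         y area ch1 ch2 ch4
#> 1 demo_f01       1 443.9064  91.76965 4263   4   5   3
#> 2 demo_f01       2 209.1042 314.29470 4547   3   2   2
#> 3 demo_f01       3 214.0441  77.51578 4213   5   5  10
#> 4 demo_f01       4 127.7208 345.66183 4202   4   7   5
```

The detection recovered all 294 planted molecules (96 + 97 + 101), the
segmentation found all 20 nuclei, and exactly the 15 planted stray
molecules (5 per channel) ended up unassigned — the per-cell counts match
the generator's ground truth. `aggregateAnimal()` then sums an animal's
fields and computes ensemble percentages; `phenotypeQuartiles()`,
`kruskalWallis()` and `spearmanBH()` provide the cohort-level analysis.

Batch processing from the shell:

```sh
Rscript inst/scripts/puncta.R simulate --out sim --fields 8 --seed 1
Rscript inst/scripts/puncta.R tune     --field sim/field001.tif --out preview.png
Rscript inst/scripts/puncta.R run      --manifest sim/manifest.csv --out results/run
```

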