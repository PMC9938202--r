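---
title: "Quantifying multiplex smFISH images: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying multiplex smFISH images: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`puncta` quantifies multiplex single-molecule fluorescence in situ
hybridisation (smFISH / RNAscope-style) assays at the level the chemistry
supports: one diffraction-limited dot per mRNA molecule. For each imaged
field it (i) detects dots per probe channel, (ii) segments DAPI nuclei,
(iii) attributes each dot to a cell, and (iv) aggregates per-cell copy
numbers to animal-level totals and marker-combination ensemble
percentages. A statistics layer relates these quantities to behaviour
across training sessions. This vignette explains the model behind each
stage, the parameters that matter, the choices made where the design was
genuinely open, and what the synthetic tests do and do not show.

## Dot detection

An mRNA molecule appears as a diffraction-limited punctum, well modelled
by a 2-D Gaussian of width about one pixel at high magnification. The
image is band-pass filtered with a difference of Gaussians: a narrow blur
(`sigmaSmall` = 0.5 px) suppresses pixel noise and enhances the dot, a
wide blur (`sigmaLarge` = 3 px) estimates the local background, and the
second is subtracted from the first. Both kernels are explicitly sampled
at integer offsets, truncated at four standard deviations, normalised to
sum one, and applied separably with symmetric (reflective) border padding,
so a constant image maps exactly to zero and the impulse response equals
the difference of the two sampled kernels.

Detections are local maxima (8-neighbourhood) of the filtered image above
a per-channel threshold (`th1`, `th2`, `th4`). The three thresholds are
independent because probes and fluorophores differ in brightness; they
are chosen once on a sample image (`tunePreview()`) and then frozen for
the whole assay batch (`runBatch()` serialises them into the output
directory, so the run log proves a single parameter tuple). Two further
conventions were open and are fixed as follows:

* **Maxima, not connected components.** Single molecules are punctate;
  thresholded components would fuse neighbouring molecules. Candidate
  maxima closer than `minSeparation` (default 2 px) are pruned greedily,
  brighter spot first, ties broken in scan order for determinism. Whether
  near-duplicate detections should be merged or both dropped is not
  decidable from first principles; greedy suppression keeps exactly one.
* **Border.** Maxima on the 1-px image border are discarded — their
  neighbourhood is incomplete, and a molecule centred there cannot be
  localised anyway.

The threshold applies to the *filtered* intensity. With unit-amplitude
puncta of width 1 px, the DoG response at the centre is about 0.7, while
filtered background noise has a standard deviation of roughly half the
raw noise; the default `th = 0.25` sits about ten noise standard
deviations above zero at the simulated noise level and well below the
signal.

## Nuclei segmentation

Segmentation runs on the DAPI (third) channel. Nuclei sit at different
depths along the optical axis, so they are not equally bright; a single
threshold loses the dim ones. The built-in `"quantise-watershed"` backend
therefore:

1. smooths the channel with a Gaussian of `dapiSigma` = 7 px to even out
   intensity inhomogeneities;
2. quantises the smoothed image with a three-threshold Otsu search
   (exhaustive between-class-variance maximisation over a 96-bin
   histogram; the lowest class is background). The union of the three
   foreground tiers is the nucleus mask — this is where dim nuclei enter;
3. splits touching nuclei with a tolerance watershed on the smoothed
   distance transform of the mask (smoothing sigma 2 px, tolerance
   1.5 px, 8-connected maxima). The distance transform is the robust cue
   here: a dim nucleus touching a brighter one lies entirely on the
   bright nucleus' smoothed intensity slope and has *no* regional
   intensity maximum, in any tier, to seed from — an instructive failure
   of the seemingly natural per-tier seeding, which additionally produces
   spurious ring seeds along the iso-intensity skirts of bright nuclei.
   The tolerance merges the shallow maxima that the medial ridge of an
   elongated nucleus produces while keeping the deeper dip at the neck
   between touching cells;
4. corrects each label for the thresholding halo. The t-level set of a
   step edge blurred with standard deviation sigma lies
   `-sigma * qnorm(t / peak)` *outside* the true edge, so every label is
   eroded by its own predicted halo width computed from its peak smoothed
   intensity — the brightness-adapted step: dim nuclei get a small
   correction, bright ones a large one. Without it masks are dilated by
   up to ~9 px and per-nucleus overlap with truth drops to Jaccard ~0.6;
   with it the synthetic-field overlap is 0.93–0.99;
5. drops components below `minArea` (default 150 px²; the value is not
   canonical — at 63x a real neuronal nucleus covers thousands of
   pixels, so 150 px² only removes debris) and relabels contiguously.

Alternative segmenters — e.g. a star-convex polygon model run in an
external tool — plug in through `registerBackend()`; the minimum-area and
contiguous-labelling invariants are enforced on whatever a backend
returns. No deep-learning weights are bundled, so the `"star-convex"`
name is an interface that errors until a segmenter is attached, and an
externally corrected label TIFF can be supplied per field via
`readLabelMap()`.

## Dot-to-cell assignment

A molecule within 10 px of a nucleus is attributed to that nucleus. Two
readings were open:

* distance is measured to the **nearest pixel of the nucleus mask** (0
  inside), not to the centroid — nuclei are extended objects, and a
  centroid rule would starve large nuclei;
* the boundary is **inclusive** (distance exactly 10.0 assigns).

A dot in reach of several nuclei goes to the nearest; exact ties go to
the lower label, making the assignment deterministic and permutation
stable. Dots out of reach are counted per channel as unassigned, and
assigned + unassigned always equals detected (a conservation identity
asserted in the tests against an exhaustive all-pairs distance oracle).

## Aggregation and ensembles

Cells are classified by marker positivity: a cell is positive for a
marker when its copy number reaches that marker's threshold. No canonical
copy-number cut-off exists for calling a cell positive, so the default is
1 copy, exposed in the configuration and recorded in every run output —
ensemble percentages depend on it. The channel-to-marker map is a
configuration table per assay (panel A: ch1 = TH, ch2 = zif268, ch4 =
Arc; panel B: ch1 = GFAP otherwise identical); the assignment of probes
to channels is arbitrary but fixed and logged. The `2^3` positivity
combinations partition the cells, so their percentages sum to 100 by
construction. Fields of one animal are summed, and group comparisons run
on animal-level values — the animal, not the cell or the field, is the
statistical unit.

## Statistics

* **Quartile phenotyping.** Animals are ranked by mean intake over the
  last three training sessions; the top and bottom `floor(N/4)` are the
  high- and low-drinker groups. Printed group sizes in typical cohorts do
  not resolve the rounding convention, so `floor` is used and exposed.
  Boundary ties break by earlier-session mean, then animal id.
* **Kruskal-Wallis** on mid-ranks with tie correction (`kruskal.test`),
  chi-square reference with k−1 degrees of freedom. Data that are all
  identical get H = 0 with a degenerate-data flag rather than NaN.
  Pairwise follow-ups are two-group Kruskal-Wallis contrasts, unadjusted
  by default to match the common reporting style; a flag applies BH
  across contrasts.
* **Spearman/BH matrices.** Each cell of the session-by-metric matrix is
  a Spearman correlation (mid-ranks, asymptotic two-sided p, ties
  allowed) between per-animal intake in one session and one animal-level
  metric. BH runs over *all cells of one matrix as a single family* —
  the conservative reading when the family is not otherwise specified.
  Cells with a constant vector (e.g. zero-noise baseline sessions) are
  undefined and reported missing, not zero.

## The synthetic generator

Real microscope data cannot ship with the package, so every stage is
exercised on synthetic fields with exact ground truth. The generator
emulates the features the pipeline must be robust to: elliptical nuclei
(semi-major 28–40 px, axis ratio up to 1.4 — roughly 11–16 µm nuclei at
63x, where one pixel is ~0.2 µm) in three strictly ordered brightness
tiers (0.35 / 0.65 / 1.0); a configurable fraction of touching pairs,
placed tangent along the line of centres so their blurred DAPI images
fuse into one blob the watershed must split; per-cell Poisson molecule
counts (default mean 5 per channel) rendered as Gaussian puncta of width
1 px; 5% stray molecules planted out of reach of every nucleus; and
additive Gaussian background noise (default s.d. 0.05 against unit dot
amplitude, peak SNR 20). Molecule ownership at generation time uses the
same inclusive 10-px rule as the pipeline, so the ground truth is a
valid oracle end to end. Everything is bit-exactly reproducible from the
seed.

Two placement details are deliberate: owned molecules are drawn from the
nucleus *interior* (normalised ellipse coordinate ≤ 0.55) with a 4-px
same-channel spacing, so that exact count recovery is decidable — a
molecule on a mask boundary would make the "correct" owner depend on
single-pixel segmentation differences; and stray molecules are planted
more than 24 px from any nucleus so they stay out of reach even of
uncorrected, blur-widened masks.

An earlier draft used 10–16 px nuclei and could not split touching pairs
at all: with sigma = 7 smoothing the blur halo completely fills the neck
between nuclei that small. That is a genuine scale constraint of the
smoothing parameter, not an implementation artefact — the method needs
nuclei several times larger than its smoothing kernel.

What the generator does **not** emulate: 3-D z-stacks, optical
aberrations, autofluorescence, uneven illumination, nucleus shape
irregularity, or clusters of three and more touching nuclei. Passing
tests therefore show algorithmic correctness under controlled conditions,
not performance on real tissue; thresholds for real assays still need
tuning on sample images.

## Numerical choices and limitations

* Gaussian kernels truncate at 4 sigma; borders reflect (symmetric,
  edge-including). The DoG matches dense convolution with the sampled
  kernels to better than 1e-10 relative error.
* The multi-Otsu search is exhaustive over a 96-bin histogram; with three
  thresholds that is ~10^5 candidate splits, well under a second.
* Watershed constants (distance-transform smoothing 2 px, tolerance
  1.5 px) were chosen on generated touching-pair batteries; on random
  tangent geometries about 2–3% of pairs still merge (one unlucky
  configuration in ~40 full fields), which matches the known weakness of
  watershed methods on dense clusters. The star-convex backend interface
  exists precisely for such data.
* Test problem sizes: 20 fields of 512x512 px with 20 nuclei for
  end-to-end recovery, 50 two-nucleus fields for pair separation, 100
  random instances for the assignment oracle, 1000 random p-vectors for
  the BH oracle, and 10 zero-noise 48-animal cohorts for phenotyping and
  the correlation-onset pattern. These sizes keep the whole suite around
  two minutes on one CPU while leaving each property with substantial
  random coverage.
* Copy numbers are per cell in 2-D sections; no correction is attempted
  for partial nuclei at section boundaries or for molecules in
  out-of-focus planes.
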