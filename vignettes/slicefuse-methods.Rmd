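---
title: "2.5D RGB slice superposition: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{2.5D RGB slice superposition: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the method

Radiologists do not classify an abdominal lesion from one axial CT slice:
they scroll, and the way a structure evolves across neighbouring slices —
a tubular appendix crossing the slice stack versus a focal colonic
diverticulum — carries much of the diagnostic signal. 3D convolutional
networks can use that signal but are data- and compute-hungry; plain 2D
networks discard it.

The 2.5D compromise implemented here fuses three consecutive axial slices
into one colour image. For an annotated slice $i$ with rectangular lesion
box $B$, the crops of slices $i-1$, $i$ and $i+1$ — all taken at the *same*
box $B$, converted to Hounsfield units (HU), display-windowed to 8 bits and
resized to the classifier's input resolution — become the red, green and
blue channels of a single image:

$$ I(x,y) = \big(W(C_{i-1})(x,y),\; W(C_i)(x,y),\; W(C_{i+1})(x,y)\big), $$

where $C_k$ is the crop of slice $k$ at box $B$ and $W$ the window map. An
ordinary 2D CNN then "sees" inter-slice structure as colour structure: a
lesion that drifts across slices becomes a red blob and a blue blob offset
to opposite sides of the green one.

Two design points deserve emphasis:

* **Neighbours are cropped at the current slice's box.** One could instead
  crop each neighbour at its own per-slice annotation; that would re-centre
  the lesion in every channel and *erase* the inter-slice displacement,
  which is precisely the signal the method exploits. Keeping the box fixed
  preserves it.
* **At the volume boundary the missing neighbour is the edge slice
  itself** (the first slice is its own predecessor, the last its own
  successor). Duplication keeps the channel intensity statistics consistent;
  zero-filling would make boundary images a different population.

The single-slice comparison arm replicates the green channel across all
three channels, so both arms share one input shape and one classifier
architecture and differ *only* in whether the off-centre channels carry
neighbouring slices.

## Data handling

Volumes are stored values plus the DICOM linear rescale
$\mathrm{HU} = \text{slope}\cdot\text{stored} + \text{intercept}$. Display
windowing maps $[\ell - w/2,\; \ell + w/2]$ linearly onto $[0, 255]$ with
clamping; the default is the standard abdominal soft-tissue window
($\ell = 40$ HU, $w = 400$ HU), configurable because the appropriate window
is a clinical choice. All 8-bit quantisation uses half-away-from-zero
rounding, which is deterministic and matches common imaging toolchains
(127.5 becomes 128).

Coordinates follow a single convention everywhere: 0-based, top-left
origin, half-open boxes — the convention of the ImageJ rectangle ROI
format, whose big-endian binary layout (`"Iout"` magic, type byte,
top/left/bottom/right shorts) the package reads and writes directly.
Slices are ordered ascending by scan-axis position with an
instance-number fallback, so acquisition order never matters.

## Augmentation and class balancing

Training-set balancing synthesizes minority-class images by geometric
augmentation: rotation, independent width/height shifts and zoom, each
drawn uniformly from configurable ranges (defaults $\pm 15^\circ$,
$\pm 10\%$, $[0.9, 1.1]$; the ranges are a package choice since only the
transform families are prescribed by the method). Transforms compose about
the image centre with bilinear interpolation and reflect padding, applied
identically to all three channels, and are exactly the identity at the
identity parameters. Balancing targets exact parity with the majority
class, so 823 minority images against 1,959 majority images require
exactly 1,136 synthetic copies. Synthetic images are flagged and are only
ever created *after* fold splitting, from training-fold records, so they
cannot leak into any test fold.

## Patient-grouped cross-validation

Fold assignment partitions patients, never images: within each class,
patients sorted by descending image count (ties shuffled by seed) are
assigned greedily to the currently lightest fold by image count (ties to
the lowest fold index). This balances fold sizes — the greedy rule bounds
the imbalance by the largest single patient — while guaranteeing that no
patient contributes images to both the training and the test side of any
fold, the grouping that keeps per-patient correlation from inflating test
performance. Early stopping watches a validation set carved from the
training patients (15% per class, again grouped), not the test fold.

## Evaluation

Each case is tested exactly once across the $k$ folds; per-fold confusion
matrices are summed ("pooled") into one whole-dataset matrix from which
accuracy, precision and recall are computed with 95% Wilson score
intervals. Pooling is used rather than averaging per-fold metrics: it is
the reading under which the published clinical table this package checks
itself against is internally consistent (see below), and it weights every
case equally. The positive class is the appendicitis-like class
throughout ("tubular" for the phantom).

AUC is computed in the Mann–Whitney form (probability a random positive
outscores a random negative, ties half), which equals the trapezoidal area
under the ROC staircase exactly; the test suite verifies the equality to
$10^{-12}$. Correlated AUCs from the two arms on the same cases are
compared with the paired DeLong test via structural components
$V_{10}, V_{01}$; the variance estimate is cross-checked in the tests
against an independent implementation (pROC), against the empirical
sampling variance of the AUC under resimulation, and against a 200,000-draw
case bootstrap of the AUC difference.

A small integer-arithmetic oracle closes the loop on the published
clinical table: given the class totals (1,959/823) and a row's precision
and recall printed at two decimals, exhaustive search over integer
$(TP, FP)$ recovers every compatible confusion matrix. For all six
published backbone/input rows the solution is unique and its accuracy
reproduces the printed accuracy to two decimals — a strong internal
consistency check that also pins down the exact confusion matrices behind
the published metrics (e.g. the best row corresponds to
$TP=1868, FN=91, FP=132, TN=691$).

## Grad-CAM

The classifier contract exposes the last convolution block's post-ReLU
feature maps $A^k$ and the gradients of the positive-class logit with
respect to them. Grad-CAM weights each map by the global average of its
gradient, $\alpha_k = \overline{\partial z / \partial A^k}$, forms
$\mathrm{ReLU}(\sum_k \alpha_k A^k)$, upsamples bilinearly to the input
resolution and scales the maximum to 1. For the reference network the head
is global-average-pooling plus one linear unit, so the gradient of channel
$k$ is the constant $w_k / Q$ — which the tests exploit as a closed-form
check alongside a two-channel hand computation.

## The phantom: what it emulates and what it does not

Clinical CT with expert annotations cannot ship with a package, so the
synthetic phantom is designed to make the 2.5D-vs-2D question *testable*
rather than anatomically realistic. Each synthetic patient is a
24-slice, 96×96 volume of 30 HU soft-tissue-like background with Gaussian
noise ($\sigma = 8$ HU), encoded through the real stored-value path
(slope 1, intercept −1024) and written as a standard DICOM series. One
bright elliptical lesion (+60 HU, semi-axes 4–7 px) appears on 5
consecutive slices and is boxed per slice with a 6 px margin.

The construction places the class signal *only* in cross-slice structure:

* the middle lesion slice is drawn from a sampler shared by both classes —
  same centre law, same radii, same contrast — so its marginal
  distribution is identical across classes and single-slice Bayes accuracy
  is 50% by construction;
* class "tubular" moves the centre by 3 px per slice along one direction
  drawn per patient (a tube crossing the stack obliquely);
* class "focal" displaces the centre from the middle position by 3 px in a
  direction resampled independently per slice (localized inflammation with
  incoherent slice-to-slice jitter).

In a superposition image the tubular class therefore shows red and blue
blobs displaced to *opposite* sides of the green blob (collinear, equal
steps), while the focal class shows incoherent displacements — a learnable
colour-geometry feature with no single-channel counterpart.

What the phantom does not emulate: organ context, partial-volume effects,
scanner noise spectra, contrast phases, annotation noise, class imbalance
and lesion-size confounds. Passing the phantom experiment demonstrates
that the pipeline is correct and that the superposition encoding makes
cross-slice signal available to a 2D classifier; it does not certify
clinical accuracy numbers, which is why the published clinical table is
checked by integer reconstruction instead.

## The reference classifier and training schedule

No deep-learning framework is assumed: the reference classifier is a small
CNN written in vectorised R (im2col gathers feeding BLAS matrix
multiplies) — three 3×3 valid convolutions with ReLU (8/16/32 maps, 2×2
max-pooling after the first two), global average pooling and a single
logit — trained with Adam under binary cross-entropy. Inputs are scaled to
$[0,1]$ and centred by $-0.5$ inside the forward pass; with strictly
positive inputs the first layer starts ill-conditioned and optimisation
can sit on a long plateau, and centring removes that artifact without
changing the contract. Training is bit-reproducible on one CPU thread for
fixed seeds: shuffling, initialisation and augmentation draws all derive
from the configuration seed.

The configurable schedule defaults mirror the published protocol (up to
200 epochs, batch 64, learning rate $10^{-4}$ dropping to $10^{-5}$ after
epoch 30 — "after" read strictly, so epoch 30 still trains at the base
rate — and patience-10 early stopping on validation loss, restoring the
best-validation weights). The *phantom experiment* uses its own desk-scale
configuration, chosen once for the small network and dataset: input
resolution 32 px, Adam at $3\times10^{-3}$ dropping to $10^{-3}$ after
epoch 50, batch 16, at most 80 epochs, patience 15. The experiment runs
100 phantom patients per class (5 annotated slices each, 1,000 images)
under 2-fold patient-grouped cross-validation in a few minutes on one CPU.

Numerical conventions worth stating: early stopping compares the minimum
of the trailing patience window against the minimum of everything earlier
(strict improvement resets the clock); max-pooling over odd extents drops
the trailing row/column; pooling argmax ties resolve to the first quadrant
in a fixed order; zero-denominator metrics are reported as `NA`, never
fabricated; a degenerate DeLong comparison (zero variance) yields $p = 1$
when the AUC difference is exactly zero and is flagged otherwise.

## Known limitations

* The reference CNN is a deliberately small stand-in for the EfficientNet
  backbones of the full-scale protocol; transfer learning from ImageNet is
  out of scope, so clinical-scale accuracy is not reproduced here.
* The DICOM writer/reader covers explicit-VR little-endian single-frame CT
  — sufficient for phantoms and round-tripping, not a general DICOM
  implementation (conformance is cross-checked against pydicom in the
  tests).
* Only rectangle ImageJ ROIs are parsed.
* The phantom's two classes are balanced by design, so the balancing path
  is exercised by its own tests rather than by the main experiment.
* Wilson intervals are a package choice; published clinical intervals were
  produced by an unidentifiable method and are deliberately not used as
  check targets.
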