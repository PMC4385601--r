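---
title: "Morphometric quantification and rule-based grading of cervical squamous cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphometric quantification and rule-based grading of cervical squamous cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cervicell)
```

## The problem

Cytological screening of Papanicolaou-stained cervical smears grades squamous
epithelial cells on the Bethesda scale: NORMAL, LSIL and HSIL (low/high-grade
squamous intraepithelial lesion) and SCC (squamous cell carcinoma). The
diagnostic signal is largely morphometric and chromatic: lesioned cells show
an enlarged nucleus, an enlarged nucleus-to-cytoplasm (N/C) ratio, irregular
nuclear outlines, orange-red ("jacinth") keratinized cytoplasm
(hyperkeratosis, typical of LSIL), and deeply stained (hyperchromatic) nuclei
(typical of SCC). `cervicell` quantifies these descriptors from a microscopy
image plus cell and nucleus label masks produced by any segmentation
(including manual annotation, which is what the underlying screening workflow
assumes — automatic segmentation of overlapping cell clumps is explicitly out
of scope), flags abnormal cells with five ordered rules, and assigns a
preliminary grade.

## Descriptors

For a cell with nucleus area $A$ (pixels) and cell area $A_{cell}$:

* **Relative nucleus size** $\nabla A = A / A_{normal}$, with $A_{normal}$
  the calibrated normal nucleus area.
* **N/C ratio** $P = A / (A_{cell} - A)$ — nucleus over cytoplasm-only area
  (a whole-cell denominator is selectable via `nc_ratio(..., denominator =
  "cell")`), and its relative form $\nabla P = P / P_{normal}$.
* **Circularity** $C = 4\pi A / \mathrm{perimeter}^2$, 1 for an ideal disk.
* **Compactness (solidity)** $E = A / \mathrm{area(convex\ hull)}$; low for
  concave, irregular outlines. An "extent" (bounding-box) variant is
  selectable.
* **Radial shape signature**: for every traced boundary point $(x, y)$ the
  distance $d = \sqrt{(x_0-x)^2 + (y_0-y)^2}$ to the nucleus centroid
  $(x_0, y_0)$, ordered by polar angle. $N$ counts the peaks and valleys of
  a smooth fit of this curve — 0 for a disk, 4 for an ellipse, $2k$ for a
  $k$-lobed nucleus. Larger $N$ means a more complex outline.
* **Color strength** $I(R, G, B)$: per-channel 8-bit means over nucleus
  pixels and over cytoplasm (cell-minus-nucleus) pixels.

## Decision rules

A cell is **abnormal** when any of the following holds (all inequalities
strict; boundary values never trigger):

1. $\nabla P > 2$ or $\nabla A > 2.5$ (relative enlargement);
2. $C < 0.8$ or $E < 0.7$ (shape irregularity);
3. $N > 4$ (lobed outline);
4. cytoplasm mean color strictly inside all three bands
   $120 < \bar R < 170$, $70 < \bar G < 140$, $120 < \bar B < 190$
   (hyperkeratosis; possibly LSIL);
5. nucleus mean color strictly below $(90, 90, 190)$ (deep stain; possibly
   SCC).

All five are always evaluated for auditability; `first_triggered` records the
first positive rule in the screening order **1, 4, 5, 2, 3**. Abnormal cells
are then graded:

* **SCC** when nucleus $\bar R < 120$, $\bar G < 120$, $\bar B < 200$,
  $\nabla A > 2$ and $\nabla P > 10$ simultaneously;
* **LSIL** when $C < 0.8$ and $E < 0.7$, or when $\nabla P < 5$ with nucleus
  $\bar R < 170$, $\bar G < 120$, $\bar B < 200$;
* **HSIL** otherwise (the residual class).

Design choices where the published rule set is silent: the SCC rule is tested
before the LSIL rule (a vector satisfying both is graded SCC — severe grades
must not be masked); the color bands of rule 4 apply to the cytoplasm
(hyperkeratosis is a cytoplasmic phenomenon) and rule 5 plus both grading
rules to the nucleus; the grading blue bound (200) deliberately differs from
the detection bound (190) because both are printed that way at their
respective operating points — both are configurable via `normal_reference()`
and `grading_rules()`. `grade_cell()` also emits `NORMAL` for non-flagged
cells so end-to-end pipelines are total.

The bundled `grading_example_34()` table is the published evaluation of this
rule set on 34 abnormal cells; `evaluate_grading()` reproduces its 26/34 =
76.47% exact-match accuracy, and with `severity_tolerant = TRUE` reports that
the two tolerated under-calls are samples 5 and 26.

## Calibration parameters

| Parameter | Default | Unit | Meaning |
|---|---|---|---|
| `A_normal` | 900 | px | normal nucleus area; **must be calibrated** per magnification/protocol (no published value exists; 900 px matches a ~17 px-radius nucleus and is what the synthetic world uses) |
| `P_normal` | 0.1 | — | normal N/C; same caveat. 0.1 reflects the small nucleus of a mature squamous cell |
| `grad_A0`, `grad_P0` | 2.5, 2 | — | published Criterion-1 thresholds |
| `C0`, `E0`, `N0` | 0.8, 0.7, 4 | — | published Criterion-2/3 thresholds |
| `lsil_band`, `scc_dark` | see above | 8-bit | published color bounds |
| `fit_order` | 8 (Fourier) / 10 (polynomial) | — | signature fit order |
| `amp_tol` | 0.03 | fraction of mean radius | extrema amplitude tolerance |
| `min_amp` | 1 | px | absolute amplitude floor (quantization) |
| AP `damping` | 0.9 | — | message damping |
| AP `preference` | median | — | off-diagonal similarity median |

`estimate_reference()` derives `A_normal`, `P_normal`, `C0`, `E0` from a set
of screened-normal cells, area-weighted by default (a plain mean is
available; whether the published reference averaging was size-weighted is
unstated).

## Numerical choices

**Perimeter.** Circularity is extremely sensitive to the perimeter
estimator. The naive chain-code length (diagonal steps weighted $\sqrt 2$)
overestimates a digitized circle's perimeter by ~5.5%, pushing its
circularity to ~0.91 — far from the ideal 1 and dangerously close to the
0.8 threshold. The default is therefore the Vossepoel–Smeulders corrected
estimator ($0.980\,n_{straight} + 1.406\,n_{diag} - 0.091\,n_{corner}$),
which is near-unbiased on smooth digitized outlines (measured disk
circularity 1.01–1.04 for radii 10–40). The naive variant remains available
(`perimeter_method = "chain"`). Circularity is capped at 1.05 to absorb the
residual digitization overshoot; 1–2 pixel regions return $C = E = 1$ by
convention, are flagged `degenerate`, and are never judged on shape.

**Solidity.** The hull is taken over pixel *corners* (each pixel is a unit
square), which is what makes small concave shapes score correctly (the plus
pentomino: 5 pixels over a hull of area 7). The price is an $O(1/r)$
positive bias of the hull area on curved outlines: a digitized disk scores
0.957 at $r = 15$ and 0.982 at $r = 40$. The "convex $\Rightarrow E = 1 \pm
0.02$" property therefore holds at moderate scale ($r \gtrsim 40$); at
typical nucleus sizes convex shapes score $\ge 0.94$, still far above the
0.7 threshold.

**Shape signature fit.** The published procedure fits "a high-order
polynomial" to the distance-vs-angle curve. A plain polynomial fit of a
periodic signal manufactures endpoint extrema that depend on the arbitrary
traversal starting point, so the default is a truncated Fourier series
(order 8) — the same smoothing role, but periodic and start-point invariant
by construction. The literal polynomial (default order 10) is selectable.
Extrema are counted on the fitted curve after cyclic prominence pruning:
adjacent peak/valley pairs whose height difference is below
$\max(0.03 \cdot \bar d,\ 1\ \mathrm{px})$ are cancelled, smallest first.
Pruning by peak-to-valley swing (rather than distance from the mean radius)
stops digitization ripple riding near a genuine extremum from being
double-counted; the 1-px floor reflects that boundary coordinates are only
known to ±0.5 px. With these choices $N$ is exactly 0/4/6 for digitized
circles, 2:1 ellipses and 3-lobed stars, invariant under rotation in 15°
steps and under the traversal starting point.

**Region conventions.** Coordinates are 0-based $(x, y)$ with $y$ down;
centroids are sub-pixel pixel-coordinate means. Labeling uses
8-connectivity; boundary tracing is Moore-neighbor tracing with Jacob's
stopping criterion (the traced set equals the pixels 4-adjacent to the
outside). Nuclei pair to the cell with minimum centroid distance, ties to
the lower cell label; a nucleus whose centroid falls outside every cell is
still paired but flagged `outside_cell`, since manual masks are imperfect.

## Affinity propagation

Per-feature values are clustered with Frey–Dueck affinity propagation
(similarity $s(i,j) = -(v_i - v_j)^2$, damped responsibility/availability
messages, damping 0.9, convergence after 50 stable iterations, preference =
median off-diagonal similarity; none of these have published values). The
per-cluster value ranges are the "scope of feature values", and
`suggest_thresholds()` places cuts at gap midpoints snapped to a rounding
grid (0.5 for ratio features, 10 for 8-bit channels — the grids that
reproduce the published round thresholds, e.g. $\nabla A < 2$ and $B <
120$).

Two honesty notes. First, textbook message passing stalls in an unstable
all-exemplar fixed point on near-symmetric inputs; like the reference
implementations, `affinity_propagation()` breaks the degeneracy with a
~1e-16-relative perturbation — drawn from a fixed internal seed, so results
remain a pure function of `(similarity, cfg)` and the caller's RNG stream is
untouched. Second, AP is *not* an exact optimizer: the test oracle is
exhaustive k-medoids at AP's own cluster count (equal-objective partitions
counted as ties), on instances with identifiable structure (2–3 Gaussian
blobs, separation ≥ 25 sd, ≥ 3 points per blob). Measured agreement is
~99.6% over 1000 such instances; the rare failures are AP converging to a
genuinely suboptimal fixed point (e.g. two exemplars on three-blob data), a
known property of the algorithm rather than of this implementation, and on
unstructured (single-blob or uniform) data no equivalence claim is
meaningful because many partitions are near-optimal.

## The synthetic world

`make_population()` draws Papanicolaou-like scenes: elliptical pale
cytoplasm blobs with an elliptical-to-lobed nucleus, per-stage color bands
and Gaussian channel noise (sd 5 by default, a typical 8-bit camera-noise
level), placed without overlap by rejection sampling. Stage profiles are the
package's own parameterization of the qualitative TBS descriptions around
the published color bounds:

* NORMAL — $\nabla A \in [0.85, 1.15]$, $\nabla P \in [0.8, 1.3]$, round
  nucleus, pale colors chosen to sit outside every band;
* LSIL — $\nabla A \in [2.8, 3.5]$ ("at least three times the normal
  nucleus"), $\nabla P \in [2.5, 4]$, jacinth cytoplasm inside the
  Criterion-4 band, nucleus colors inside the LSIL grading disjunct;
* HSIL — $\nabla P \in [5.5, 9]$ (more enlarged N/C than LSIL, below the
  SCC bound), colors failing both the SCC and LSIL rules;
* SCC — $\nabla P \in [11, 14]$ (meganucleus), nucleus below the
  Criterion-5 dark bounds.

Ground truth (exact rasterized areas, centroids, colors, expected $N$ and
grade) is recorded per cell, and the whole scene is a deterministic function
of the seed. What the generator does **not** emulate: overlapping/aggregated
cell clumps, uneven staining gradients, chromatin texture, out-of-focus
blur. A green end-to-end test therefore establishes that measurement,
detection and grading are self-consistent at realistic geometry and noise —
not that the thresholds transfer to any particular scanner or staining
protocol, which always requires calibrating `A_normal`/`P_normal`.

## Known limitations

* PNG only for images and masks (no TIFF reader in the supported
  dependency set); label maps with more than 255 regions are written as
  RGB base-256 encodings.
* No automatic segmentation, no ASC-US/ASC-H categories, no texture
  features — all out of the method's scope.
* The published per-feature cluster memberships are not recoverable (the
  raw feature values of those 34 cells were never printed), so clustering
  is validated against oracles and synthetic data instead.
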