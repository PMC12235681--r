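---
title: "Grading single early-AMD lesions in OCT B-scans: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grading single early-AMD lesions in OCT B-scans: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(earlyamdrate)
```

## The instrument

Early AMD manifests as focal deposits in the outermost retina: drusen
between Bruch's membrane (BM) and the retinal pigment epithelium (RPE),
subretinal drusenoid deposits (SDDs) between the RPE and the
photoreceptors, and occasional lesions made of hyper-reflective material
only. In a spectral-domain OCT B-scan these deposits are visible as
deformations of, and material between, five reflectivity bands: external
limiting membrane (ELM), ellipsoid zone (EZ), interdigitation zone (IZ),
the outer RPE complex and BM.

The grading instrument implemented here describes **one lesion at a time**
through two coupled artefacts:

1. a **questionnaire** with literal field codes: scan-level flags
   (GEN-01..GEN-04), one state per layer (LAY-01..LAY-05, each graded
   A = bent/bulged down, B = unchanged, C = bent/bulged up, D = disrupted,
   E = not gradable), IZ/RPE separability (INSEP), one brightness class
   (BRI-01..BRI-05), special flags (SP-01 confluent, SP-02 trailing
   hyper-reflective material, SP-03 hyper-reflective material only) and,
   on follow-up scans, one progression state (PRO-01..PRO-06);
2. a **colour mask** painted over the greyscale B-scan. A mask must have
   at least 2 pixels and be a single 8-connected component; several
   lesions on one scan use different colours.

Manual grading remains the measurement act; this package supplies the data
model, its validation, the automated read-out of masks, the derived
morphometrics and the cohort statistics. It deliberately contains **no
lesion detector**: segmentation is the grader's judgement.

## From masks to metric phenotypes

With per-scan calibration $(w, d)$ µm (pixel width × pixel depth, taken as
reported by the device — never derived from nominal scan depth, whose
printed values are not always consistent with the row count):

* cutting area $A_{px} = |M|$, $A_{\mu m^2} = A_{px}\, w\, d$ exactly;
* projected diameter $D_{px} = \max(\mathrm{col}) - \min(\mathrm{col}) + 1$,
  $D_{\mu m} = D_{px} w$;
* centroid = arithmetic mean of the (row, col) coordinates, real-valued,
  reported to 2 decimals in exports.

Two conventions here were genuinely open and are fixed as follows.
**Projected diameter is the lateral (column) extent only**: axial and
lateral pixel scales differ by a factor of ~3 (3.87 vs ~11.27 µm), and the
transverse projection is what fundus-based AMD size cut-offs refer to;
converting pixel diameters with the pixel width alone is only coherent
under this reading. The `+1` makes a single column span one pixel width
(so a vertical two-pixel mask has diameter 1, not 0); with it,
$1 \le D_{px} \le A_{px}$ always holds. **Colour membership is "not a grey
tone"** (a pixel belongs to some mask iff its R, G, B values are not all
equal) with **exact-colour grouping at zero tolerance**. Confluent lesions
may touch, so any nearest-colour clustering would merge them; the cost of
zero tolerance is that masks must be drawn hard-edged (no anti-aliasing),
which the synthetic renderer enforces and the documentation requires of
external drawings. Extracted masks are ordered by (min column, min row,
colour bytes) so outputs are deterministic.

## Greyscale conversion

Raw OCT exports are linear intensities spanning several decades. The
classical visualization compresses them as
$g = \mathrm{round}_{\text{half-up}}\!\big(255\,(v/v_{\max})^{1/4}\big)$,
giving 256 grey levels. `fourth_root_rescale()` exposes the normalisation
constant: per-scan maximum by default, or a fixed device full-scale value.
Half-up rounding is chosen over banker's rounding so that the midpoint
maps predictably (e.g. $v = v_{\max}/16$ gives exactly 127.5 → 128); the
map is monotone, all-zero scans map to all-zero images, and enlarging the
reference can only darken pixels.

## Lesion typing, leading selection, tracking

Drusen and SDDs separate by their position relative to the outer RPE, read
off the questionnaire: RPE bent up or disrupted (LAY-04C/D) → drusen; bent
down or unchanged (LAY-04A/B) → SDD; LAY-04E → ungradable. SP-03
(hyper-reflective material only) takes **precedence** over the RPE state —
such lesions typically bend layers upwards too, and counting them inside
the drusen group would double-count the partition.

The *leading drusen* of a volume is the lesion with maximal cutting area
in any B-scan, the *leading scan* the B-scan showing it; ties break by
lowest scan index, then lowest lesion id, so selection is deterministic.

Tracking assumes baseline and follow-up scans at identical positions
(device eye-tracking) and takes lesion correspondence from **annotation
identity** — the grader reuses the same mask colour across visits. No
spatial matching is attempted: the instrument gives no registration
algorithm and automated matching is out of scope. Area deltas are computed
from unrounded micrometre areas; pipelines that round areas to integer
µm² at pixel level before differencing can disagree by ±1 µm², which is
why the package never rounds before subtraction. The progression
consistency check compares the relative change $\delta/A_{base}$ against a
configurable threshold (default 0.10, i.e. a 10% change counts as
"noticeable"): growth above, remission below $-$threshold, stationary
between, and "new" for lesions without a baseline partner. The threshold
has no canonical value — the check is **advisory only** and never
overrides the grader's tick; `UNCLEAR` and unassessed ticks are never
flagged.

## Cohort statistics

Sizes are summarised by min / median / mean ± sd / max for diameter and
area in both unit systems, excluding by default the hyper-reflective-only
lesions (their "size" is not a deposit size). Log-normal fitting uses
moments of logs — `meanlog` and `sdlog` are the sample mean and standard
deviation of $\ln x$, which are also the maximum-likelihood estimates;
quantile matching would fit the same two parameters with more variance.
Log-normality is tested by Shapiro–Wilk on $\ln x$ (base-invariant;
natural logs are used), supported for $3 \le n \le 5000$. The moment fit
itself is defined from $n \ge 2$ (its two-point closed form is a useful
check), with the test statistics reported as `NA` below $n = 3$. The
pixel-vs-metric Pearson correlation quantifies how much per-scan
calibration scatter decouples the two unit systems; with a constant
calibration it is exactly 1.

## The synthetic generator

`generate_bscan()` renders a 496 × 512 phantom: five horizontal
reflectivity bands (defaults: ELM row 330 / reflectivity 0.35, EZ 340 /
0.85, IZ 350 / 0.40, RPE 356 / 0.95, BM 361 / 0.30 on a 0.03 background,
rows 0-based from the inner retina), into which lesions are injected as
half-ellipse profiles of per-column elevation:

* **drusen** lift ELM–RPE and fill the wedge between the lifted RPE and
  BM with deposit material (mask = the deposit pixels);
* **SDDs** are mounds on an undisturbed RPE, lifting only ELM–IZ;
* **hyper-reflective foci** are bright solid blobs near the EZ.

Deposit reflectivity encodes the brightness class (0.30 / 0.55 / 0.90 for
low / moderate / high). Speckle is **multiplicative log-normal noise on
reflectivity** before fourth-root conversion — a pragmatic stand-in that
produces plausible texture, not a physical interference model. Lesion
footprints may overlap only when both lesions are marked confluent, in
which case contested columns are assigned to the nearer lesion centre,
reproducing the vertical delineation a grader draws between confluent
lesions; masks are always pairwise disjoint, hard-edged and exactly
recoverable by `extract_masks()`.

`generate_cohort()` emulates a consecutive early-AMD sample at its study
conditions: 100 patients (one leading scan each), per-scan lesion counts
$1 + \mathrm{Poisson}(0.98)$ (≈1.98 lesions/scan, ≈198 lesions per 100
patients), type mix 142 : 54 : 1 drusen : SDD : hyper-reflective focus,
log-normal diameters with median 154.8 µm and `sdlog` 0.6 (`sdlog` is not
separately reported for the reference sample; 0.6 reproduces its
min–median–max spread of roughly 32–155–568 µm within a factor consistent
with n ≈ 200), pixel widths drawn per scan from N(11.27, 0.3²) µm at fixed
3.87 µm depth, and a confluent-pair probability of 0.35 per multi-lesion
scan (≈22% of lesions confluent). Footprints are capped at 120 columns so
every lesion fits the field; the truncation affects ~0.05% of draws.
Every scan, and hence the whole cohort, is bit-reproducible from a single
seed.

What the generator does **not** emulate: real speckle statistics and
shadowing, curved or tilted retinas, anti-aliased hand drawing, grader
disagreement and mis-ticks, late-AMD features, per-type size differences
(one shared size law by default, configurable), and 3-D continuity across
a volume's B-scans. Green tests therefore demonstrate the correctness of
the data model, geometry, classification logic and statistics — not
performance on clinical images, which depends on grading quality the
instrument itself standardises but cannot guarantee.

## Numerical and degenerate-case choices

* Validation returns **violation lists, never exceptions**, so batch
  grading reports every problem at once; batch operations
  (`tabulate_occupancies()`, serialization) reject invalid records naming
  the record index.
* INSEP is tri-state (yes / no / unassessed): separability is routinely
  unassessable around small lesions, and a forced boolean would silently
  fabricate data. Progression on non-follow-up scans is represented as
  `NOT_ASSESSED` rather than absent so cohort tables stay rectangular.
* Record tables use the literal field codes as CSV/JSON keys with 0/1
  cells; parsing is strict (unknown column, duplicated code, non-boolean
  cell, no-state-ticked are errors with row and column) while in-memory
  validation is lenient — the two layers catch different failure modes.
* An all-zero raw scan with per-scan normalisation is defined to map to
  the all-zero image; a constant sample yields `st_dev` 0; an empty
  volume, an empty post-exclusion cohort and zero-variance correlation
  margins are rejected with explicit messages.
* Test problem sizes: the rendered round-trip suite uses a 110-patient
  cohort (≥200 lesions), classification agreement a 100-patient cohort,
  the test-size calibration 500 replicates of n = 197 diameters, and
  parameter recovery 10⁵ draws — sizes at which the Monte-Carlo error of
  each check is comfortably below its acceptance margin.

## Known limitations

The instrument is manual by design; nothing here measures intra- or
inter-grader variability. Sizes are raw cutting areas and projected
diameters without stereological correction, so out-of-plane lesions are
under-measured. Lesions smaller than the inter-B-scan spacing of typical
volume protocols (50–60 µm) can be missed entirely by the acquisition, a
limit no grading instrument can recover. Cross-visit identity relies on
the grader's colour discipline; a renamed colour silently breaks a track,
which the consistency check can flag but not repair.
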