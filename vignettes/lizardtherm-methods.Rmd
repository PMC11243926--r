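---
title: "Extracting body-part temperatures from dual-camera lizard recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting body-part temperatures from dual-camera lizard recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lizardtherm)
```

## The measurement problem

Lizards and other ectotherms regulate body temperature behaviourally, and
different body parts (snout, head, dorsum, tail, limbs) can sit at quite
different surface temperatures at the same moment. Thermal cameras show
those temperatures as false colour, but two practical obstacles stand
between a thermal video and a usable per-part time series:

1. A lizard at ambient temperature is nearly invisible in the thermal
   image, so the animal must be *located* in a synchronized RGB view and
   the location *transferred* into the thermal view.
2. Consumer capture setups record the thermal camera's screen output, not
   radiometric data, so temperature must be read back through the colour
   scale bar embedded in the frame.

`lizardtherm` implements the full chain for side-by-side RGB/thermal
composite frames: detect body parts in the RGB panel (through a pluggable
detector contract), reduce each bounding box to one representative pixel
guaranteed to lie on the animal, map that pixel into the thermal panel
with a four-point perspective transform, and invert the thermal pixel's
colour to degrees Celsius via the scale bar. Every measurement is logged
with date, time and class name.

## The processing model, stage by stage

### Panels and coordinates

A composite frame holds the RGB view on the left and the thermal view on
the right; `split_side_by_side()` carves both panels out as rectangular
regions of interest. All coordinates in the package are 0-based with
`x` = column and `y` = row increasing downward, and rectangles cover the
half-open block `[y, y+h) x [x, x+w)`. The panel rectangles are user
configuration: the split line depends on how the recording was laid out,
and guessing it would fail silently.

### Detection contract

The detector is deliberately a plain function `image -> detections` with
seven classes (`Lizard`, `Snout`, `Head`, `Dorsum`, `Tail`, `Leg_L`,
`Palm_L`). Detection runs only on the RGB panel — a model trained on RGB
imagery misbehaves on false-colour frames. The package ships a fixture
backend replaying scripted YOLO-format boxes and a synthetic-scene
backend returning ground truth with optional jitter; a trained network is
simply another function satisfying the contract. Confidence filtering
keeps detections with score `>=` the threshold (default 0.50), so a
detection at exactly the threshold survives. Multiple detections of one
class are processed independently; nothing downstream assumes
one-box-per-class.

### Mask refinement and the representative pixel

A bounding box always contains background as well as animal. Inside each
box the RGB pixels are converted to 8-bit luma
(`0.299 R + 0.587 G + 0.114 B`, rounded half-up) and thresholded
inverse-binary: luma at or below the threshold becomes white
(foreground — the animal is dark against a light enclosure), above it
black. The threshold (default 128) is footage-dependent and deliberately
manual — an automatic method such as Otsu would move the foreground
boundary between frames and make logs harder to interpret. Raising the
threshold can only grow the white set, which the tests check as a
monotonicity property.

The reported pixel is the box centre `(x + w %/% 2, y + h %/% 2)` when
that pixel is white; otherwise the nearest white pixel to the centre by
Euclidean distance, searched *within the box only*, with ties broken in
row-major order (smallest `y`, then smallest `x`) so results are
deterministic. Floor division for the centre of even-sized boxes and the
box-restricted search are both documented choices where convention had to
be fixed. A box whose interior contains no white pixel yields a
`no_foreground` measurement status rather than a silent drop.

### Perspective mapping

Four corresponding points in the two panels (typically the corners of the
enclosure visible in both views, in top-left, top-right, bottom-right,
bottom-left order) determine a 3x3 projective matrix via the standard
eight-unknown linear system with the ninth entry fixed at 1. A mapped
point is computed as `(x', y', w) = M (x, y, 1)`, normalised by `w`, and
rounded with `floor(v + 0.5)` — round-half-up, matching the integer
truncation convention for non-negative coordinates. Negative normalised
coordinates, or rounded coordinates beyond the thermal panel, mark the
measurement `out_of_panel`; clamping instead would read a temperature
from the wrong pixel, which is worse than a gap in the log.

Two numerical facts matter here. First, the four corners reproduce their
destinations to better than 1e-6, which the suite verifies over a
thousand random rectangle correspondences against an independent SVD
null-space fit. Second, mapping forward and back returns to the starting
pixel within one pixel *provided the destination panel is at least half
the source scale*: below that, the integer rounding performed in the
small panel is amplified past one source pixel on the return trip. The
property suite therefore draws its correspondences with scale factors in
[0.5, 2], the regime of two cameras framing the same scene; users mapping
into a drastically smaller panel should expect proportionally coarser
localisation.

### Colour-bar temperature inversion

The scale bar is described by `scale_bar(t_min, t_max, y_min, y_max,
x_med, bar_width)`: temperatures at the bar's bottom and top, the rows of
its top and bottom ends, the column of its centre, and its width (10
pixels by default). A bar row maps to temperature by linear
interpolation,

$$T(\mathrm{row}) = T_{min} + \frac{Y_{max} - \mathrm{row}}{Y_{max} - Y_{min}} \,(T_{max} - T_{min}),$$

which is strictly decreasing in the row index (hotter is higher). The
interpolation itself fixes only row-to-temperature; how a *pixel colour*
selects a row is a completion this package had to choose: the bar is
sampled once per row (averaging across its width to suppress
screen-recording compression artefacts, each channel rounded half-up) and
the pixel is assigned the row minimising Euclidean RGB distance, ties
going to the hotter row. Nearest-colour matching is the minimal faithful
rule given that scale colourmaps are monotone ramps; any metric
monotone in per-channel differences gives the same answer on an
injective ramp. Recovered temperatures always lie in
`[t_min, t_max]`, and on an injective colourmap the recovery error is
bounded by half a row step, `(t_max - t_min) / (2 (y_max - y_min))`.

The endpoint parameters are typed in per frame set-up (the package does
no OCR of the printed scale numbers), and one calibration is assumed per
run; thermal cameras that autoscale per frame need per-file overrides.

### Logging

Each surviving detection produces exactly one log line —
`YYYY-MM-DD<TAB>HH:MM:SS<TAB>label<TAB>value` — where the value is the
temperature with one decimal (the precision of the printed scale labels)
or the failure status. The clock is injectable, so tests produce
byte-identical logs; real runs use wall time. Lines are appended across
runs, like a lab notebook.

## Evaluation metrics

`iou()`, `match_detections()`, `precision_recall_f1()`,
`average_precision()` and `mean_average_precision()` implement the
standard detection metrics. Matching is greedy in descending confidence
per class — the convention of the YOLO tooling ecosystem; the suite
bounds it against an exhaustive optimal assignment on small instances.
AP integrates the monotone non-increasing precision envelope over recall
with all-point interpolation (not the older 11-point approximation), and
`mAP@0.5:0.95` averages over IoU thresholds 0.50 to 0.95 in steps of
0.05. True negatives are carried in the confusion structure for
completeness but are always zero for detection.

## Dataset bookkeeping

`split_counts()` floors the train and validation counts and gives the
remainder to test; this rounding dialect is the one consistent with a
70/20/10 split of 4306 images landing on 3014/861/431. `augmented_total()`
models augmentation as *adding* `copies_per_image` variants per training
image (two copies take 4306 to 10334). `augment_image()` applies
saturation, brightness and exposure jitter within ±10%, blur up to 1 px,
and salt-and-pepper noise on up to 1% of pixels; the three photometric
jitters are implemented in RGB space (luma-preserving saturation scaling,
multiplicative brightness, gamma-style exposure) so that zero parameters
give a bit-identical image, and all draws are seed-deterministic.

## The synthetic scene generator

`make_scene()` builds the paired fixture everything is tested on: a dark
elliptical lizard (body plus six part ellipses) on a light background in
the RGB panel, and a thermal panel rendered from a known full-precision
temperature field through `make_colourmap()`'s injective ramp, with a
10-pixel colour bar and a known rectangle-to-rectangle homography
(destination at 0.7 scale) between panels. Defaults are fixed study
conditions: scale endpoints 29.3–50.5 °C (a representative heat-lamp
enclosure frame), lizard surface 33 °C and ambient 30.5 °C (realistic for
a lacertid warming under a lamp), 160 x 120 px panels. Layout jitters
mildly with the seed; the same seed is bit-reproducible.

`curl_tail = TRUE` draws the tail as an open ring whose bounding-box
centre falls on background — the configuration that defeats naive
centre-pixel selection — so the nearest-white-pixel branch is exercised
deliberately, not incidentally. Because quantisation happens only when
the temperature field is rendered through the colourmap, the end-to-end
recovery error bound (one row step) is analytic, and the suite checks it
over 50 seeded scenes.

What the generator does *not* emulate: photometric texture on the animal,
thermal gradients across the body, sensor noise, compression artefacts,
lens distortion, or the camera's own absolute accuracy (typically ±2 °C
for the class of camera involved — a hardware property outside this
package's reach). Passing tests therefore demonstrate the correctness of
the geometry, selection and inversion logic, not field accuracy on real
footage.

`make_colourmap()` samples a fixed polyline through RGB space (dark blue
to magenta to orange to near-white) at equal arc length and guarantees
at least 4 units of Euclidean separation between consecutive colours, so
±1-per-channel perturbations cannot change the matched row. The polyline
supports about 149 steps at that guarantee; beyond it the constructor
refuses, and scenes cap their bar at 140 rows.

## Problem sizes and runtime choices

The property suites run at sizes chosen to finish comfortably on one CPU
while still being persuasive: 1000 random rectangle correspondences for
the homography bounds, 500 random 15 x 15 masks against the exhaustive
nearest-white scan, 200 random PR curves against fine-grid numeric
integration (20 000-point grid, tolerance 2e-3 against the grid's own
discretisation error), and 50 end-to-end scenes. The whole suite runs in
well under a minute.

## Known limitations

- No radiometric conversion, emissivity or reflected-temperature
  handling: the scale bar is the only temperature reference.
- MP4/AVI containers are not decoded in-process; extract frames to a
  directory (or use a multi-page TIFF) and point `iter_frames()` at it.
- One colour-scale calibration per run; per-frame autoscaling thermal
  output needs per-file configuration.
- The thresholding assumes a dark animal on a light background; inverted
  contrast requires pre-inverting the footage or an unusually high
  threshold.
- Temperatures are reported at the scale-label precision (0.1 °C); the
  physical accuracy of the source camera is not improved by any of this.
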