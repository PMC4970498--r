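---
title: "Reducing FEL pixel-detector data: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reducing FEL pixel-detector data: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(felreduce)
```

## Scope

Serial femtosecond crystallography (SFX), SAXS and single-particle imaging at
free-electron lasers record one detector frame per X-ray pulse, at rates
where most frames are empty. Before any structure-determination program
(CrystFEL, nXDS, 3D-reconstruction codes) can run, the raw frames need dark
calibration, bad-pixel handling, geometry-aware assembly, hit finding and
format conversion. felreduce implements that reduction layer as composable R
functions plus a small INI-driven pipeline runner. Everything operates
offline on frame stacks; live DAQ ingestion, viewers and cluster job
management are out of scope.

## Coordinate and unit conventions

Frames are R matrices `[row, col]`, with the row index along the slow-scan
(ss) and the column index along the fast-scan (fs) direction of the readout.
CrystFEL geometry files index pixels from 0; R objects are 1-based, converted
at parse time. Lab-frame y increases with the row index, and the direct beam
defines the lab origin. Wavelengths and q are in ångström (Å, Å⁻¹); detector
distances, pixel sizes and radii are in metres; pixel values are ADU.

## Geometry and momentum transfer

A CrystFEL geometry file describes rectangular raw-layout slabs (panels) with
fast/slow-scan direction vectors and a corner position. Per pixel,

    (x, y) = corner + i_fs * fs_vec + i_ss * ss_vec          [pixel units]

converted to metres with the panel's pixel size (`1/res`). Assembly places
each raw pixel into the lab-frame cell nearest its coordinate — deliberately
no sub-pixel interpolation, since downstream consumers either work on raw
coordinates (CrystFEL) or only need a visually faithful image. Half-way
coordinates round up (`floor(x + 0.5)`), not half-to-even, so that detectors
described on a half-integer grid (beam axis between pixels) never collide
with themselves; genuine collisions are counted and reported, and colliding
values are summed so total intensity is always conserved.

The scattering angle of a pixel at radius $r$ with detector distance $d$ is
$2\theta = \arctan(r/d)$, giving the elastic momentum transfer and Bragg
d-spacing

$$q = \frac{4\pi}{\lambda}\sin\!\Big(\tfrac{1}{2}\arctan\tfrac{r}{d}\Big),
\qquad d_\text{spacing} = \frac{\lambda}{2\sin\theta} = \frac{2\pi}{q}.$$

These canonical elastic forms are the package's choice; the identity
$q \cdot d_\text{spacing} = 2\pi$ is enforced by test to machine precision.
Radii are evaluated at pixel centres. A panel `coffset` adds to the global
detector distance for that panel's pixels.

## Dark calibration

Training computes per-pixel mean (offset) and population standard deviation
(noise) over a stored stack of dark frames, iteratively discarding values
with $|x - \mu| > n\,\sigma$ and recomputing until stable (cap: 20 passes,
default $n = 4$). "Noise" here is the population standard deviation of
single-exposure values — the spread one frame shows — not the standard error
of the mean. A rejection floor $\varepsilon = 10^{-6}$ ADU replaces
$\sigma = 0$ in the test only (never in the stored map), so perfectly
constant pixels don't reject everything.

Updating adds one frame at a time, skipping per-pixel outliers by the same
rule. The cumulative scheme is an exact running mean/variance (Welford), so
training on 100 frames and cumulatively updating with 100 more reproduces a
200-frame training exactly when nothing is rejected. The exponential scheme,

    offset   <- (1 - a) * offset + a * x
    variance <- (1 - a) * (variance + a * (x - offset_old)^2)

weights recent frames more (default `alpha = 0.01`) and is one concrete
realisation of an exponentially moving mean and variance, suited to slow
pedestal drifts (e.g. temperature).

Bad pixels are those whose offset or noise falls outside acceptance
intervals: explicit, or automatic at mean ± n·stdv of each map (default
n = 4), with the same iterative rejection applied when deriving the
boundaries so that the bad pixels themselves don't widen them. Degenerate
(constant) maps yield an all-good mask.

Two correction dialects serve the two main consumers: *crystfel* (offset
subtracted, masked pixels 0) and *nxds* (raw values kept, masked pixels set
to a negative sentinel). The four maps stack vertically —
offset/noise/counts/mask, top to bottom, a fixed order chosen here — into one
2D result and split back exactly. Calibration files are HDF5
(`/offset /noise /counts /mask` + attributes); files carrying only offset and
noise are accepted, with counts substituted by the training size and the
mask regenerated. Gain and hot-pixel calibration are not implemented; a
generic per-row-median common-mode subtraction is included as a convenience
utility only.

## Bragg-peak finding and hit classification

The peak search follows an iterative local-SNR scheme. Scanning row-major for
unmasked pixels above `pixel_threshold`, a candidate seeds a peak only if it
is the maximum of its `(2h+1)²` box (first row-major position wins ties;
boxes crossing the frame edge are skipped, since background statistics across
edges or panel gaps are meaningless). Box pixels — including the seed on the
first pass — form the background sample; pixels with SNR above
`snr_background` are stripped and the mean/stdv recomputed until none exceed
it (one-sided: Bragg intensity only adds counts). Peak members are box
pixels with SNR above `snr_peak` that are 8-connected to the seed —
8-connectivity because diffraction spots span diagonals at typical pixel
scales. With at least `min_npix` members the peak is accepted: the table row
records the intensity-weighted centroid over background-subtracted member
values, the seed's position and linear index (the "central index" is the
seed, a documented choice), the highest pixel value, the integrated
background-subtracted intensity and the member count. Accepted members are
never reused as seeds, preventing duplicate rows.

An event is a crystal hit when its peak count falls in an inclusive
user-selected range; the saturated fraction of reflections is the share of
rows whose maximum pixel exceeds a saturation threshold (undefined, not 0,
on empty tables). The virtual powder pattern is the running mean over
accepted hit frames, and the hit rate is the hit fraction over a trailing
window (default 2400 shots).

Defaults (`threshold` 20 ADU, box half-width 4, SNR cuts 3/3, `min_npix` 3)
are tuned for the synthetic study conditions used throughout the tests —
Gaussian background of σ = 3 ADU with spot amplitudes from 10× noise up —
where they recover ≥ 95 % of injected spots within one pixel while staying
silent on pure noise. Real experiments must re-tune them per sample; the
threshold in particular is the dominant sensitivity/false-positive dial.

## Radial q-profiles and single-particle diagnostics

The radial average histograms every unmasked pixel's q with the pixel value
as weight and divides per-bin by the entry count. Because pixels enter
through their true lab-frame q, detector tile gaps or masked sectors only
lower bin counts without biasing the averaged values — the property that a
naive polar projection of the assembled image lacks. Bins are uniform in q
and half-open `[lo, hi)` with the top edge closed; empty bins are `NA`,
never zero.

Particle-size feedback uses the oscillations of the sphere form factor
$I(q) \propto [3(\sin qR - qR\cos qR)/(qR)^3]^2$: the profile's first two
strict local minima ("nodes") are spaced $\Delta(qR) \approx 3.23$, so node
distance scales as 1/diameter. Node distance is exposed both in bins and in
q units, since either convention is in use. An optional window-3 moving
average can precede the minima search (off by default; noiseless profiles
don't need it and smoothing shifts shallow minima).

Autocorrelations distinguish single particles from aggregates:
Cartesian (FFT-based, periodic boundaries — documented since boundary
handling is a genuine choice; zero-shift cell equals Σx²), polar (bilinear
resampling onto radius × angle, then per-radius circular autocorrelation over
angle; n-fold symmetric scattering produces lag peaks at 2π/n), and the
centred power spectrum.

## Fluorescence and timing chains

The fluorescence chain keeps only pixels inside a single-photon ADU window
(default 18–50 ADU, carried as configuration, as is any photon-energy axis
calibration — never fitted here) and projects the region of interest onto
columns. Two normalisations are exposed: per-column division by the survivor
count (the default), and division by the fixed ROI height (`"roi"`), which
makes the spectrum proportional to the per-column photon rate; the survivor
counts are always recorded. The accumulated average spectrum is a running
mean over hit events.

The timing tool encodes the FEL/laser delay spectrally: the chain projects
the signal rows, subtracts an equally wide nearby background projection
(equal widths are required rather than rescaled), normalises against a
stored FEL-off reference (zeros in the reference are an error naming the
columns), convolves with a digital filter kernel (same-length, zero-padded;
ties in the argmax break to the first index) and returns the argmax as the
edge pixel. Delay correction is the linear map
`nominal + slope * (edge - reference_pixel)` with the slope a beamline
calibration input. On synthetic edges with realistic finite sharpness the
recovered position is exact to ≤ 1 px at noise up to 5 % of the edge depth.

## File formats

Event HDF5 output places each result at a user-chosen group/dataset (the
producing result's name by default), optionally zlib-compressed; duplicate
targets abort before anything is written. Multi-event files stack results
along the leading (slowest) file axis with an `/event_id` dataset. Writers
are byte-deterministic — verified by test — so reruns are directly
diffable. Sub-directory batching (`batched_path`) caps files per directory
for filesystem-friendly single-event output.

CBF output converts to signed 32-bit integers (rounding ties away from zero,
a documented choice) and writes the x-CBF_BYTE_OFFSET compression: per-value
deltas in 1 byte when in [−127, 127], else escape 0x80 + little-endian
int16, else escape 0x8000 + int32, else a final 64-bit escape. The header is
a miniCBF-style binary section (element type, byte order, element count,
fast/slow dimensions) and deliberately carries no experiment metadata, which
downstream integration ignores anyway. The dark offset map can be exported
as a separate CBF for use as a dark-current image.

## Pipeline

`load_chain_config()` reads INI stages (`op`, `input`, optional `condition`,
parameters) and topologically orders them, so file order never matters;
cycles and unproduced inputs are errors. `run_chain()` executes per event:
conditional stages are skipped when their gating 0D result is false,
accumulators update exactly once per processed event, per-event results
cannot leak across events, and a failing stage skips that event with a
logged reason while processing continues. Output stages collect and write
multi-event HDF5 at the end. The reference implementation is
single-threaded; the contract (accumulator updates serialised in event
order) would permit concurrent event processing.

## Synthetic study conditions

All tests run on generated data with known truth; the generators are pure in
(parameters, seed) via `withr::with_seed`, and callers derive sub-seeds as
documented offsets from one base seed. The conditions are: dark runs of 200
frames with per-pixel pedestals U(50, 150) ADU, noise U(1, 5) ADU and 0.1 %
cosmic-like spike events; 48×48 Bragg frames with Gaussian spots of
amplitude 30–300 ADU (10–100× the σ = 3 background) and width 0.8–1.5 px;
rings and sphere form factors on a 128–256 px pixel-centre-symmetric
detector at λ = 1–1.5 Å and d = 0.1–0.2 m; timing images of 1024 columns
with a smooth edge of 30 % depth and width 1.5 px; fluorescence frames with
Poisson photons at 30 ADU/photon and σ = 3 readout noise. Problem sizes in
the test suite (200 oracle frames, 500 noise frames, 1000 accumulated
spectra, 500-event chains) were chosen as the package's own verification
scale.

What passing these tests does **not** show about real data: the generators
have Gaussian noise and isolated Gaussian spots — no common mode, no
panel-dependent gain, no saturation tails, no jet streaks or ice rings, no
detector distortion. The peak-finder defaults that are provably good here
still need per-experiment tuning in the field, and the geometry module
handles only planar two-axis panel layouts (no z-tilts).

## Known limitations

- No gain/hot-pixel calibration, no facility-native raw formats, no
  single-particle hit-finder (only the diagnostics around it), no indexing
  or downstream crystallography.
- CBF support covers the byte-offset binary section with a miniCBF header,
  not the full imgCIF dictionary.
- Scalars in HDF5 output are stored as length-1 datasets rather than true
  0-d dataspaces.
- The pipeline is an offline, file-driven runner; there is no online
  (streaming) mode.
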