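---
title: "Methods: segmentation-free cell mass in trap arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmentation-free cell mass in trap arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trapmass)
```

## Model

All quantities derive from a single field: the optical thickness map
$t(x,y) = \varphi\lambda$ (µm), the phase delay of light expressed in
length units. For a uniform object, $t$ equals physical thickness times the
refractive-index difference $\Delta n$ to the surrounding medium. Three
consequences structure the pipeline:

1. A trap made of $N$ cylinders (radius $r$, channel height $h$) of a
   polymer with index difference $\Delta n$ against water has optical
   volume $\int t\,dA = N \pi r^2 h \Delta n$; with an index-matched
   polymer ($\Delta n \approx 0.024$) this stays far below a wavelength of
   phase, so DPC imaging measures it without wrap ambiguity.
2. A cell adds optical volume proportional to its dry mass:
   $m = \frac{1}{\alpha}\int t\,dA$ with the specific refractive increment
   $\alpha = 1.8\times10^{-4}\ \mathrm{m^3/kg} = 0.18\ \mathrm{\mu m^3/pg}$
   (exact unit identity, held in `mass_calibration()`).
3. Integrals over a *fixed* region do not require knowing where the cell
   is inside it. Per-trap diamonds tiled from the lattice, plus
   subtraction of the mean empty-trap optical volume, therefore replace
   cell segmentation and tracking entirely.

## DPC forward model and inversion

The measured DPC signal per axis is the normalized intensity difference of
complementary half-aperture illuminations,
$I_\mathrm{DPC} = (I_R - I_L)/(I_R + I_L)$, which in the weak-phase linear
regime is proportional to the phase gradient along that axis. The
transfer-function details of partially coherent DPC depend on the
illumination hardware; this package instead fixes a self-consistent linear
model used identically by the simulator and the reconstructor:

$$ s_x = g\,\partial_x t, \qquad s_y = g\,\partial_y t, $$

with $\partial$ the *circular central difference* per pixel (Fourier symbol
$i\sin(2\pi k/N)$) and $g$ the gradient gain. `reconstruct_phase()` solves
the least-squares integration problem per Fourier mode:

$$ \hat t(k) = \frac{\overline{D_x}\,\hat s_x/g + \overline{D_y}\,\hat
s_y/g}{|D_x|^2 + |D_y|^2 + \rho}, $$

then pins the additive constant (invisible to gradients) by zeroing the
mean over a trap-free anchor region. Dividing the signals by $g$ *before*
integration makes the gain cancel exactly in a simulate–reconstruct round
trip, a property the tests exploit.

**Regularization $\rho$.** The Tikhonov weight damps modes where
$|D|^2 = \sin^2(2\pi k_x/N_x) + \sin^2(2\pi k_y/N_y)$ is small — exactly
the lowest spatial frequencies, for which $|D|^2 \approx (2\pi k/N)^2$. On
a 1500-pixel-wide field the first mode has $|D|^2 \approx 1.5\times10^{-5}$,
so even $\rho = 10^{-4}$ visibly attenuates large-scale structure (a
128-px uniform disk loses ~5% of its interior mean). The default
$\rho = 10^{-4}$ is therefore a *noise-suppression* setting for measured
data; for noise-free synthetic data the package uses $\rho = 0$, where
only the DC mode and the shared Nyquist modes (both invisible to central
differences) are lost, the former restored by the background anchor. Round
trips then close to machine precision, which is what the closure tests
assert. Undefined signal pixels (zero total intensity) are inpainted by
the 4-neighbor mean when isolated; more than 5% undefined is an error.

## Trap mask

Three measured trap centers — one reference and its nearest neighbors
along the two lattice directions — fix origin, both basis vectors, and any
rotation of the device (`fit_lattice()`; collinear anchors are rejected at
a cross-product threshold of $10^{-6}$ px²). `render_mask()` tiles
diamonds: pixel $p$ belongs to trap $k$ iff $|a|/d_u + |b|/d_v \le 1$
where $(a,b)$ are $p$'s coordinates in the lattice unit-vector frame.
Design choices:

* Rhombic (L1-ball) tiles in lattice coordinates, half-diagonals default
  $0.45\times$ the spacings — diamonds by construction, disjoint whenever
  $d \le$ half the spacing (enforced; double assignment is also checked).
* Coordinates are 0-based (row, col) with pixel centers at integers;
  membership is decided per pixel center, no anti-aliasing (sub-pixel mask
  edges average out over a tile's ~3000 pixels).
* Traps whose tile exits the image are excluded and reported, because
  partial tiles bias optical volume.

## Measurement and occupancy

Per frame: subtract the mean over a trap-free background region (mean
only — no plane fit; shift invariance is tested), integrate
$\sum t \cdot \mathrm{px}^2$ per tile, classify occupancy, and subtract
the mean empty-trap volume $R$ from occupied traps;
$m = (V - R)/0.18$ pg. At least 3 empty traps are required for $R$.

The occupancy rule (the source data does not state one) is robust to
occupied-trap contamination: a trap is *empty* iff its volume lies within
median $\pm\,3\times$IQR of the lower half of the volumes. Cells only add
volume, so the lower half estimates the empty spread even at high
occupancy; an explicit `empty_ids` list always overrides. With strictly
Gaussian spread the $3\times$lower-IQR fence sits near $2.5\sigma$, so a
percent-level false-occupied rate is expected; such traps merely drop out
of the reference mean and acquire near-zero "cell" volumes (mass-track
extraction discards tracks whose apparent mass is not strictly positive,
and `min_mass_pg` can raise that bar). The rule relies on the lower-half
IQR being a stable spread estimate, which takes a reasonably large array —
tens of traps; on very small arrays a clustered draw can shrink the fence
severely, and an explicit `empty_ids` list is the right tool there.

## Statistics

* CV $= 100\,s/\bar x$ with the $n-1$ standard deviation; spatial CV is
  across empty traps within a frame, temporal CV across frames of the
  per-frame mean empty-trap volume (per-trap temporal CVs are a secondary
  output).
* Boxplot summaries use linear interpolation of order statistics
  (`quantile(type = 7)`, the convention fixed so the worked examples are
  stable) and the 1.5×IQR outlier fences.
* Growth: tracks are normalized by initial mass, averaged pointwise, and
  fitted by ordinary least squares on $\ln m$ vs $t$ — deterministic and
  closed-form, appropriate for a single exponential rate. Doubling time is
  reported as $\ln 2 / \mathrm{rate}$ (for 0.021 h⁻¹ that is 33.0 h; no
  rounding to coarser printed values is applied). Slopes below
  $10^{-12}$ h⁻¹ are snapped to 0 so constant input reports rate 0 with
  undefined doubling time.

## Simulator

`sim_config()` defaults describe the reference device and experiment: a
15×10 rhombic array (150 traps) at 50/40 µm pitch, two 7.5 µm cylinders
per trap with a 4 µm gap, 9.8 µm channel, $n$ = 1.3541 polymer vs 1.330
water ($\Delta n = 0.0241$), 0.5 µm pixels, 5-min frames over 18 h, cells
growing at 0.021 h⁻¹. The pitch, gap, margin and pixel size are simulator
parameters chosen to be geometrically consistent (a cylinder pair plus a
cell fits inside one diamond tile), not measured device values. Noise
terms, each a single interpretable knob:

* `trap_cv` (default 0.042): per-trap multiplicative fabrication spread —
  sets the spatial CV.
* `frame_jitter_cv` (default 0.018): per-frame multiplicative drift of the
  whole field (focus/illumination) — sets the temporal CV.
* `mult_sigma`, `add_sigma` (default 0): per-pixel intensity noise on the
  synthesized DPC images.

Cylinder footprints are rendered with *exact* circle–pixel overlap areas
(closed-form chord integrals), so the discrete integral of a rendered trap
equals $N\pi r^2 h \Delta n$ to floating point — the Eq-2-vs-Eq-3
consistency is exact by construction, and the convergence tests check the
area integral at coarser grids. Cells are spherical-cap thickness bumps,
$t(\rho) = t_\mathrm{max}\sqrt{1 - \rho^2/R^2}$, whose discrete sum is
normalized to the analytic volume $\tfrac{2}{3}\pi R^2 t_\mathrm{max}$, so
ground-truth masses (volume / 0.18) are exact by construction. Growth
scales the bump amplitude (not footprint) — volume is what matters
downstream. All draws are seeded; identical seeds give bit-identical
output, and the RNG state of the caller is restored.

What the simulator does *not* emulate: partial-coherence transfer
functions, defocus, halo/shade-off, phase wrapping (relevant for
high-index materials like PDMS), cell internal structure, or trap-to-trap
optical crosstalk. Passing closure tests therefore demonstrate the
correctness of the *processing* chain, not robustness to those physical
artifacts.

## Problem sizes and numerical choices

The test suite and the acceptance script run the full 150-trap field
(841×1521 px) once, noise-free, for the closure check — a few seconds —
and use a 3×3-trap device for the many smaller cases. Parameter-recovery
statistics use 100 seeds (spatial/temporal CV) and 200 seeds (growth
rate) at the stats level, where a seed costs microseconds. Phase TIFFs
store each page rescaled to the unit interval with the physical range in a
JSON sidecar (~1e-9 relative round-trip); DPC stacks are ordered
[frame][axis][half]. Degenerate inputs fail loudly by design: collinear
anchors, overlapping tiles, empty regions, zero-denominator DPC pixels in
bulk, fewer than 3 empty traps, non-positive masses in log fits.

## Known limitations

* The linear gradient model is an idealization; gain calibration against
  a physical instrument is out of scope, and reconstructed absolute phase
  from real data inherits whatever transfer-function mismatch exists.
* Tikhonov integration trades low-frequency fidelity for noise damping;
  with noisy data, large smooth structures are attenuated at default
  $\rho$ (see above) while per-trap volumes, which live at the lattice
  frequency and above, are far less affected.
* The empty-trap reference assumes traps are interchangeable up to the
  spread captured by the spatial CV; a systematically anomalous trap
  biases its own cell mass estimate.
* Edge traps are excluded rather than partially integrated.
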