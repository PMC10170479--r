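---
title: "Models and numerical methods in mucochip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods in mucochip}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mucochip)
```

mucochip implements the computational battery used to characterise human
bronchial epithelia cultured at the air–liquid interface on a perfused
microfluidic chip: mucus microrheology by multiple particle tracking,
impedance-based barrier monitoring, a reduced-order model of the chip's
flow and oxygen supply, ciliary beat frequency extraction, and
fluorescence morphometry. This vignette explains each model, the
parameters that matter, the numerical choices, and what the synthetic-data
generators do and do not emulate.

## Multiple-particle-tracking microrheology

### The estimators

Beads of radius $a$ (100 nm for the usual 200 nm tracers) embedded in
mucus are imaged at 20 frames/s for 5 s in at least 8 regions. For each
bead the time-averaged MSD at lag $\tau$ uses **all ordered frame pairs**,

$$\mathrm{MSD}_i(\tau) = \big\langle [x(t+\tau)-x(t)]^2 +
[y(t+\tau)-y(t)]^2 \big\rangle_t,$$

and the region curve is the unweighted mean over the beads imaged there
(`compute_msd()`). Lags are truncated at a quarter of the trajectory
length (`max_lag_fraction = 0.25`): beyond that, estimates average very
few, strongly correlated pairs. Trajectories shorter than 10 frames are
excluded (`min_length`); both limits are exposed because no universal
choice exists.

A log–log line fit gives the anomalous exponent $\alpha$
(`fit_power_law()`). With $\alpha > 0.95$ (strict) the medium is treated
as purely viscous: a through-origin fit of $\mathrm{MSD} = 4 D\tau$ gives
$D$ and the Stokes–Einstein relation $\eta = k_BT/(6\pi D a)$ the
viscosity, reported in cP. Exactly at the threshold the viscoelastic
branch is used; the boundary is documented rather than deep — $\alpha$
near the threshold means both branches give compatible viscosities, which
the tests verify.

Below the threshold, the generalized Stokes–Einstein relation converts the
MSD to a creep compliance $J(t) = \frac{3\pi a}{2k_BT}\mathrm{MSD}(t)$ and
a Maxwell element is fitted, $J(t) = 1/G + t/\eta$. Two numerical choices
matter here:

* **Inverse-variance weighting.** The time-averaged MSD's relative
  variance grows roughly linearly with the lag index (fewer pairs, more
  correlation), and the Maxwell plateau $1/G$ is an extrapolated
  intercept. An equally-weighted fit lets the noisy long lags dominate the
  intercept; weights $\propto 1/(J_k^2\, k)$ keep the estimator stable.
  With 500 beads of 100 frames, $G$ is recovered with a few percent
  scatter instead of tens of percent.
* **Static-error correction.** Centroid tracking carries a localization
  error $\sigma$ that offsets every MSD by $4\sigma^2$ (two dimensions).
  The offset is irrelevant for slopes (hence for $\eta$) but biases the
  plateau; when $\sigma$ is known — it is recorded in the generator's
  ground truth, and can be estimated from immobilized beads in real data —
  `viscosity_viscoelastic(..., localization_sd_m = )` subtracts it before
  conversion. This is the standard static-error correction of MPT.

### What the generators emulate

`simulate_brownian_trajectories()` draws per-axis Gaussian increments with
variance $2D\Delta t$, $D = k_BT/(6\pi\eta a)$, and optionally adds
independent per-frame localization noise (default 20 nm per axis, a
typical static error for bright sub-micron beads; the acquisition defaults
— 20 fps, 100 frames, room temperature 298.15 K — mirror the standard
mucus MPT protocol).

`simulate_viscoelastic_trajectories()` draws positions from the zero-mean
Gaussian process whose structure function equals the Maxwell target
$\mathrm{MSD}(t) = \frac{2k_BT}{3\pi a}(1/G + t/\eta)$ at every observable
lag, via the covariance
$C(t,s) = [m(t) + m(s) - m(|t-s|)]/2$ built from the per-axis target $m$
with $m(0)=0$ and factorized once by Cholesky (a failed factorization
falls back to a reported diagonal jitter). A mechanistic trap model is
deliberately not simulated: every downstream estimator sees only the MSD,
so matching the MSD law exactly — including its plateau — is both
sufficient and exactly controllable. Equivalently, the construction is a
Brownian path plus i.i.d. per-frame Gaussian jitter of variance
$k_BT/(6\pi a G)$ per axis.

The generators do **not** emulate spatial heterogeneity of mucus (a single
$\eta$, $G$ per region), hindered or hopping diffusion, bead–mucin
chemistry, out-of-focus loss, or drift. Passing tests therefore show the
estimators are correct for homogeneous media under the stated noise model,
not that real mucus is homogeneous. Drift correction (ensemble-mean
subtraction) is available but off by default — acquisitions are assumed
vibration-isolated.

### Tracking

Detection thresholds the frame, labels 8-connected regions, size-filters
them, and takes intensity-weighted centroids (sub-pixel; pixel centers at
integer coordinates, origin top-left, y downward). Linking follows the
proximity principle: candidate pairs within `max_displacement_um` are
accepted greedily by ascending distance, ties broken by (track, detection)
index; unmatched detections start tracks, a miss terminates a track (no
gap closing), and a global optimal assignment is noted as an extension but
not implemented — the greedy rule is the faithful reading of
closest-position linking. The gate should sit well above the expected RMS
step (about $5\times$ is a good default) and below the inter-particle
spacing; `render_spot_video()` fixtures with grid starts let the tests
verify link purity against ground truth.

## Impedance spectroscopy

The epithelium on its support is modelled as
$$Z(\omega) = R_{sol} + \frac{1}{j\omega C_{el}} +
\frac{R_{teer}}{1 + j\omega R_{teer} C_m},$$
the tight-junction resistance $R_{teer}$ in parallel with the membrane
capacitance $C_m$, in series with the medium resistance and the electrode
capacitance. The electrode interface is an ideal capacitor; a
constant-phase element would be the natural refinement for real
electrodes but adds a parameter the standard sweep cannot always resolve.

`fit_circuit()` minimizes stacked real and imaginary residuals weighted by
$1/|Z|$ — without weighting, the huge low-frequency electrode reactance
(the sweep spans 100 kHz down to 0.1 Hz, 50 log-spaced points) would
drown the barrier features. Positivity is enforced by fitting
log-parameters with Levenberg–Marquardt. Starting values come from the
asymptotes ($R_{sol}$ from the high-frequency modulus, $R_{teer}$ from the
low-frequency rise of the real part, capacitances from corner
frequencies); because multiplicative noise at the extreme frequencies can
corrupt those plateaus, the fit is restarted from a small grid of
perturbed initializations and the best converged optimum kept. Fits are
complex (not modulus-only): the phase information roughly halves the
parameter variance and the choice is recorded here. A fit whose barrier
element collapses (pure-resistor spectra) raises a boundary flag instead
of returning a spurious estimate.

TEER and capacitance are reported in Ω and nF — device-level values, not
area-normalized. `bode_modulus_at()` interpolates $|Z|$ log-log at 12 Hz,
the customary single-frequency growth monitor, and `teer_timecourse()`
flags the day of the $R_{teer}$ maximum (barrier maturation), marking
first/last-day maxima as boundary peaks.

## Chip fluidics

### Geometry reduction

The culture chip is a 15 × 4 × 1.5 mm inlet channel, a hexagonal pool
(plan area 2.08 cm², volume 0.312 cm³, hence 1.5 mm deep) holding a
6.5 mm porous insert, and a mirror outlet channel. Only the plan area and
volume of the hexagon are specified, so the pool is treated as the regular
hexagon of equal area, crossed along its long diagonal (17.9 mm); the 2D
vertical mid-plane slice then carries a segment-wise effective width —
4 mm in the channels and area/length ≈ 11.6 mm in the pool — chosen so
plan areas (hence residence volumes) are preserved. The width enters the
continuity equation only; momentum is solved in the slice. This is an
order-of-magnitude reduction of the 3D device: it cannot resolve lateral
(spanwise) structure, and the design-window checks on its outputs use
factor-of-two tolerances accordingly.

### Discretization

At the working point (40 µL/min) the Reynolds number is ≈ 0.17, so
inertia is dropped and steady Stokes flow solved: a staggered (MAC) grid
with velocities on faces and pressures in cells, assembled into one sparse
saddle-point system and solved directly. Boundary conditions: a parabolic
inlet profile normalized to carry exactly the discrete flow rate, no-slip
walls and membrane, zero-gradient velocity with zero reference pressure at
the outlet. No-slip on the tangential velocity is imposed through
*quadratic* ghost values, which makes the discrete solution exact for
parabolic profiles — the straight-channel solve reproduces the
plane-Poiseuille shear $6\mu Q/(wh^2)$ to solver precision, which the
tests use as the analytic oracle. Wall shear is evaluated with the
matching one-sided second-order difference. Mass conservation through
every cross-section holds to round-off by construction. The solution
stores the Reynolds number and warns if it leaves the creeping-flow
regime. The default mesh uses 16 cells across the 1.5 mm depth and ≈ 200
along the 48 mm domain (about 11 000 unknowns, solved in ~1 s); shear and
minimum oxygen change by < 5% under 2× refinement.

Gravity is neglected (no body force is specified for the device, and the
slice is horizontal).

### Oxygen transport

Oxygen obeys steady advection–diffusion on the same grid (finite volumes,
first-order upwind advection — unconditionally positivity-preserving at
the cell Péclet numbers involved), with inlet concentration 0.22 mol/m³,
zero-flux walls, advective outlet, and the Michaelis–Menten sink
$R = V_{max}\rho\, c/(K_m + c)$ with $V_{max} = 3.42\times10^{-16}$
mol/(cell·s), $K_m = 0.214$ mol/m³, $\rho = 7.5\times10^{13}$ cell/m³.
The consuming tissue is a 20 µm layer under the membrane — thinner than a
grid cell, so the sink is applied as the depth-integrated uptake flux
$V_{max}\sigma c/(K_m+c)$ on the top boundary of the footprint cells with
areal density $\sigma = \rho \times 20\,\mu m$. Two consistency choices:

* **Chord weighting.** The insert is a 6.5 mm disc, but the slice's
  effective pool width would turn it into an 11.6 × 6.5 mm strip and
  overstate the consuming area by ≈ 2.3×. The uptake is therefore
  weighted by the local chord of the disc, so the integrated consuming
  area equals the true insert area — the same area-preservation principle
  used for the widths.
* An alternative `"cells"` sink model derives $\sigma$ from a total
  seeded-cell count instead of the volumetric density; the layer model is
  the default.

The saturable sink is handled by Picard iteration with a semi-implicit
linearization (the matrix stays an M-matrix, so concentrations remain in
$[0, 0.22]$); the inlet/outlet/consumption budget closes to the iteration
tolerance and is reported in `oxygen_balance`.

### Readouts

`wall_shear_profile(sol, "membrane")` reports $\tau = \mu\,\partial
u/\partial n$ over the insert footprint in dyn/cm² (1 Pa = 10 dyn/cm²);
`membrane_velocity()` samples the tangential speed 50–150 µm below the
membrane (the readout height is not standardized, so a band is averaged);
`shear_uniformity()` is the coefficient of variation of a profile. For
the wide-vs-narrow channel comparison the CV is evaluated across the whole
pool interface (`surface = "pool"`): over the central footprint both
geometries are fully redeveloped in a mid-plane model, while the pool-wide
profile retains the entrance heterogeneity that distinguishes them — the
4 mm channel yields CV ≈ 0.03 against ≈ 0.09 for the 1 mm channel at the
default mesh.

## Ciliary beat frequency

`roi_trace()` averages a rectangular ROI per frame (or extracts a line
kymograph); `count_peaks_cbf()` counts local maxima whose topographic
prominence exceeds half the trace standard deviation — a threshold that
adapts to amplitude and rejects sub-noise ripples — and divides by the
duration. Acquisition is assumed at 100 frames/s; the generator enforces
Nyquist. The count is cross-checked against the dominant discrete-Fourier
frequency of the detrended trace and discrepancies beyond 20% are
flagged rather than silently averaged. Each ROI is reported separately;
averaging across ROIs is left to `compare_conditions()`.

## Fluorescence morphometry

* `count_nuclei()`: threshold (Otsu by default — the conventional choice
  when a protocol says only "thresholded"), 8-connected labelling, minimum
  area filter; optional distance-transform watershed for touching nuclei,
  off by default.
* `marker_area_per_cell()`: thresholded marker area in µm² divided by the
  nucleus count — areas are exactly foreground-pixel counts times the
  pixel area, which the tests check against brute force.
* `cell_shape_metrics()` accepts an external label image (cell selection
  is manual in practice): area; aspect ratio as the major/minor axis ratio
  of the second-moment ellipse (with the 1/12 per-pixel variance term,
  which makes rectangles exact); circularity $4\pi A/P^2$ with the
  perimeter from the Freeman-weighted chain code (0.948 per axial, 1.340
  per diagonal step) — the raw 8-connected chain overestimates smooth
  outlines by ~5% — capped at 1.
* `mucus_thickness()`: per-slice coverage fractions of the thresholded
  red (aerosolized beads) and blue (nuclei) channels; the cell-layer top
  is the highest blue slice above 1% coverage, the particle layer the
  lowest red slice above it, and the thickness the empty axial space
  between the two slice edges (floored at 0). Coverage-based detection
  makes the measurement invariant to global intensity scaling; the 1%
  default replaces the visual 3D inspection used at the microscope and is
  exposed. Recovery is exact to one z-step on synthetic stacks, including
  the 9.75/14.8/39.4 µm settings used as condition fixtures.

## Pipeline and reproducibility

`run_pipeline()` executes the selected stages on simulated inputs in
dependency order from a list or YAML configuration; every stage's seed is
derived deterministically from the run seed, so reports and output files
are bit-identical across repeats. In video mode the rheology stage starts
beads on a 12 µm grid with a 20 µm margin so rendered spots stay separated
and in-field — the fixture regime in which proximity linking is valid.
`compare_conditions()` aggregates replicate reports into group means ± SD
with effect directions; significance testing is deliberately delegated to
the standard routines (one-way ANOVA, Kruskal–Wallis for non-normal
viscosities) and reported pass-through — those tests are not this
package's contribution. The package's interface is its functions and this
vignette; no shell entry point is shipped.

## Known limitations

* The fluidics model is a width-averaged mid-plane slice: no spanwise
  secondary flows, no PDMS oxygen permeation, no transient (breathing)
  mechanics; membrane pores (0.4 µm) are treated as hydraulically closed
  but oxygen-transparent.
* First-order upwinding adds numerical diffusion along the flow; the
  oxygen minimum is grid-converged at the default mesh but sharper
  features would need a finer grid or a higher-order scheme.
* The microrheology branch point at $\alpha = 0.95$ is a convention;
  heterogeneity analysis (per-particle spread, Van Hove functions) and
  full frequency-domain moduli are out of scope.
* Morphometry assumes externally provided segmentations for per-cell
  shape; dense epithelium segmentation is not attempted.
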