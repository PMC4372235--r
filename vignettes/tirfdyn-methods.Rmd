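---
title: "Models and methods behind tirfdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tirfdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`tirfdyn` is built around a single question from bacterial cell biology:
how does a membrane-anchored protein such as RNase E move on the inner
membrane of a rod-shaped cell, and how can live-cell fluorescence
imaging measure that movement? The package supplies both halves of the
answer: a forward simulator that generates synthetic image data from an
explicit physical model, and the analysis methods used on such data —
perimeter line-scan statistics, kymograms, and continuous-photobleaching
rate estimation under TIRF illumination.

## The membrane dynamics model

Cells are idealized as the cylindrical section of a spherocylinder of
length $L$ (default 3 µm) and radius $r$ (default 0.4 µm) resting on the
coverslip. Hemispherical poles are omitted because every analyzed signal
(lateral membrane scans, kymograms, bleach traces) comes from the
cylindrical wall. A surface position is $(s, \theta)$ with axial
coordinate $s \in [0, L]$ and azimuth $\theta$ ($\theta = 0$ at the
coverslip); membrane height above the glass is $z = r(1-\cos\theta)$.

Each fluorophore-tagged protein performs Brownian motion on the unrolled
cylinder: Gaussian steps of variance $2 D\,\mathrm{d}t$ per surface
dimension, periodic in azimuth and reflecting at the axial ends. The
flat-metric approximation is valid while steps are much smaller than
$r$; `sim_config()` warns when the step size approaches the binding
capture radius.

Clustering into membrane foci is modelled as transient binding to
immobile substrate sites, encoding the hypothesis that focus formation
requires RNA substrate: sites stand in for transcripts awaiting
degradation, and the "rifampicin" preset removes them entirely
(`n_sites = 0`) to emulate substrate depletion. Binding is a hazard
process: a free particle within the capture radius of an unsaturated
site binds with probability $1-e^{-k_{on}\mathrm{d}t}$ per tick
(nearest unsaturated site wins, ties to the lowest index, at most one
event per particle per tick — all for determinism), and unbinds with
probability $1-e^{-k_{off}\mathrm{d}t}$. Bound particles diffuse with
`D_bound` (0 by default: foci are treated as stationary on the imaging
timescale).

### Default parameters and why

* `D_free = 0.05` µm²/s — in the range measured for inner-membrane
  proteins of *E. coli* by single-molecule methods; relative rates, not
  absolute calibration, are the quantity of interest.
* `n_particles = 2000` — membrane RNase E copy numbers are in the
  thousands. This matters for line-scan statistics: a focus is only
  detectable against the $\sqrt{N}$ granularity of the unclustered
  pool, and focus variance grows quadratically with occupancy while
  granularity grows linearly with copy number.
* `n_sites = 40`, `site_capacity = 40`, `capture_radius = 0.15` µm,
  `k_on = 4`/s, `k_off = 1`/s — calibrated once so that the untreated
  steady state has a bound fraction near 0.5 (the regime the
  focus-contrast checks specify) with mean focus occupancy ~25
  molecules and ~1 s focus residence ("short-lived foci"). The
  calibration follows from coverage: ~40 sites of capture area
  $\pi \rho^2$ cover about half the $2\pi r L$ surface, so the
  effective binding rate is $k_{on} \times$ coverage $\approx k_{off}$.
* One master RNG stream drives the whole simulation; a trajectory is
  byte-reproducible from its seed. (Per-particle counter-based
  substreams were considered and rejected: base R has no cheap
  counter-based generator, and the single-stream design keeps the hot
  loop vectorized. The cost is that changing `n_particles` reshuffles
  all paths, which no supported analysis relies on.)

## Image formation

`render_stack()` projects each fluorophore to the image plane (axial
position along the cell axis, lateral offset $r\sin\theta$) and forms
images as: excitation weighting, stochastic photobleaching, Poisson
photon emission, pixel-integrated Gaussian PSF, camera offset, Gaussian
read noise, integer quantization.

In TIRF mode the evanescent field decays as $w(\theta) = e^{-z/d}$ with
depth $d$ (default 0.1 µm, a typical objective-TIRF penetration depth;
the emulated study does not state its value, so $d$ is a free
parameter). Emission weight equals excitation weight — the simplest
model that reproduces the key physics: molecules at the bottom of the
cell are bright and bleach fast, molecules elsewhere are dim and
protected. Epifluorescence mode sets $w \equiv 1$, which removes every
diffusion dependence from bleaching — a useful internal control.

Bleaching precedes emission within each frame, and the dark interval
between frames does not bleach (continuous-illumination approximation
at frame resolution). Per-pixel photon counts are sampled as
independent Poisson draws of the PSF-weighted means (exactly equivalent
to multinomial thinning of a per-fluorophore Poisson total); means
above 1000 use a rounded Gaussian approximation. An
`expected_photons` mode replaces every stochastic element — photon
shot noise, binary bleach fates, read noise, quantization — with its
expectation, giving deterministic images for closed-form oracle tests.

## Line-scan statistics

`extract_perimeter_scans()` samples the two lateral membrane traces of
each labelled cell at 1-px spacing with bilinear interpolation, along a
midline placed at the mask's lateral half-extent minus half the
expected membrane width (1 px by default) — the source experiments
trace "along the membrane" without defining the line, so the membrane
midline is an explicit, documented choice. A side is dropped when
another cell lies within `adjacency_gap` (default 3 px; the exclusion
rule is stated in the emulated analysis, the distance is not). Cells
touching the image border are skipped.

Per scan, `scan_stats()` reports the mean and the $n-1$ sample variance
(scan lengths are short and variable). `field_summary()` aggregates a
field with lower-convention medians. Variance is computed on raw
intensities by default — it is invariant under the background offset,
whereas the mean is only comparable across fields after background
subtraction (`background = "auto"`); whether the original analysis
subtracted background before computing variance is unstated, and the
offset-invariance makes the choice immaterial for variance.

The focus signature is a field whose median per-scan variance is
several-fold higher with substrate sites than without, at unchanged
median mean intensity — clustering redistributes, but does not create,
fluorescence.

## Kymograms and persistence

`build_kymogram()` scans each frame along a principal axis of the mask
(second-moment eigenvectors; no manual line placement) through the
centroid, averaging across a 3-px band, and stacks scans in time. By
default 3 px at each end of the scan are trimmed: the outermost columns
carry the static PSF roll-off of the cell edge, a geometric feature
that otherwise dominates row-to-row correlation regardless of protein
dynamics.

`persistence_score()` quantifies the fixed-versus-live contrast as the
mean Pearson correlation between rows separated by a chosen lag.
Formaldehyde-fixed cells (the `fixed` preset: all dynamics frozen)
score near 1; live cells decorrelate. Two honest caveats, both visible
in the simulator: (i) long-wavelength density fluctuations relax slowly
($\tau = 1/(Dq^2)$ exceeds the 3 s acquisition for the longest axial
modes), so individual live cells occasionally score up to ~0.6, and the
live-cell persistence is therefore reported as a mean over several
cells; (ii) the live-cell checks use clustering-free simulations,
because simulator substrate sites are immobile by design — a
site-bearing "live" cell carries artificially persistent structure that
real cells, whose transcript population turns over, do not.
`ridge_slope()` (column-argmax regression) checks for directed
transport; the default simulator has none, and recovered slopes are
zero within error.

## Continuous-photobleaching diffusion estimation

Under TIRF, only a thin stripe of the membrane is excited. A molecule
that diffuses quickly leaves the stripe before bleaching, so the
bleachable pool drains slowly; a slow molecule sits in the stripe until
bleached. The field-summed decay rate therefore falls as diffusion gets
faster — the core mechanism linking photobleaching to mobility.

`cell_trace()` produces per-cell traces (footprint mean minus
background mean, normalized to 100 at frame 0; the default background
region is everything ≥ 5 px outside any dilated mask).
`fit_photobleach_global()` fits each condition's field-mean curve with
the constrained two-phase exponential

$$I_c(t) = A_c e^{-k_{fast} t} + (100 - A_c) e^{-K_c t},$$

no offset (decay to 0), one fast rate $k_{fast}$ shared across all
conditions (intrinsic fluorophore bleaching), and a per-condition slow
diffusion-limited rate $K_c$. Identifiability of "fast" is enforced by
parameterization ($K_c = k_{fast}\cdot\mathrm{logistic}(q_c)$ keeps
$0 \le K_c \le k_{fast}$; amplitudes are logistic-bounded in $[0,100]$),
with $\ge 5$ log-spaced multi-starts for $k_{fast}$ and a polish pass.
Standard errors come from the Jacobian covariance
$\sigma^2 (J^\top J)^{-1}$ at the optimum in natural parameters, and
$R^2$ is computed per condition on its mean curve; the source figures
name SEM and $R^2$ without defining them, so these standard
definitions are used. Fitting the mean curve (not pooled per-cell
points) matches plots of averaged normalized intensities with error
bars; per-cell traces can be fitted individually by passing them as
separate conditions.

`compare_conditions()` reports $K \pm$ SEM, ratios to a reference, and
the induced ordering — smaller $K$ means faster diffusion.

### The acquisition window matters

The diffusion-to-$K$ mapping is monotone only while the acquisition
ends before the fastest-diffusing pool is fully depleted. At long times
the ordering inverts: fast diffusion ultimately bleaches the *entire*
pool, while slow diffusion strands an unbleached reservoir at the top
of the cell whose weak excitation produces a shallow tail. The default
bleach acquisition is therefore 40 frames of 100 ms (4 s) at a bleach
coefficient of 1/s — in-zone bleaching outpaces azimuthal exchange for
every probed diffusion coefficient, and the window closes before
crossover. This is the same regime choice a bench experiment makes
implicitly by selecting laser power and acquisition length.

## What the synthetic data does and does not establish

The generator emulates: rod-shaped cells with membrane-confined
diffusing fluorophores, substrate-site clustering, evanescent versus
uniform excitation, photobleaching, PSF blur, Poisson and read noise,
and per-cell label masks. It does not emulate: cell-to-cell expression
variability, autofluorescence, focus drift, transcript turnover (sites
are immobile and permanent), the hemispherical poles, or segmentation
error (masks are ground truth). A green test therefore establishes that
the analysis code correctly recovers the stated physics from data
generated under these assumptions — not that the biological
interpretation of any real experiment is correct, and not absolute
diffusion coefficients (only relative rates are ever reported).

## The helix module

The membrane-targeting sequence (MTS) of RNase E is a short amphipathic
α-helix. `classify_residues()` projects a peptide on an ideal helical
wheel (100°/residue, 3.6 residues/turn) and partitions all 20 residues
into hydrophobic (F L I V M W Y A), basic (K R H), small hydrophilic
(G S T N Q) and other (C P D E). Alanine is classed hydrophobic per
standard usage even though wheel displays of the MTS highlight only
bulky residues; this is a documented divergence. The exact class
boundaries in the source display are graphical only, so the standard
partition is used. `hydrophobic_moment()` computes the per-residue
mean-vector amphipathicity

$$\mu_H = \frac{1}{n}\left|\sum_i h_i
  \big(\cos 100^\circ i,\ \sin 100^\circ i\big)\right|$$

under a named hydrophobicity scale (Eisenberg consensus by default;
scales are plain data tables). The wild-type MTS peptide outscores its
F→A double substitution, matching the loss of membrane binding of that
variant; an 18-residue homopolymer scores exactly 0 (five full turns of
cancelling phasors).

## Numerical and format choices

* Stacks and masks travel as plain-text TSV containers with a JSON
  metadata header (pixel size, frame interval) because no TIFF codec is
  available in the supported dependency set; the metadata schema is
  unchanged.
* Configuration sidecars are JSON.
* Medians use the lower-median convention for even counts.
* Degenerate inputs error early with named messages: empty masks,
  border cells, unnormalizable traces, zero-variance kymogram rows,
  non-canonical residues, unknown scales.
* All randomness flows from explicit integer seeds; every pipeline
  output is a pure function of (config, seed).

## Known limitations

* The simulator's substrate sites neither move nor turn over; focus
  positional persistence is therefore overstated relative to real
  cells.
* The shared fast component of the bleach fit is asserted (intrinsic
  fluorophore photophysics), not derived; the simulator generates its
  fast phase from in-zone bleaching instead, which reproduces the
  fit's behaviour but not its photophysical interpretation.
* Absolute $K$ values depend on the chosen bleach coefficient,
  evanescent depth and window; only cross-condition comparisons at
  fixed optics are meaningful.
* The flat-metric surface approximation breaks down for
  $\sqrt{4D\,\mathrm{d}t} \gtrsim r$; the configuration layer warns
  well before that point.
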