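# tirfdyn

Simulation and analysis of membrane protein diffusion in rod-shaped
bacteria, measured by TIRF continuous photobleaching.

Membrane-anchored enzymes such as RNase E, the hub of the *E. coli* RNA
degradosome, diffuse over the inner membrane and transiently cluster
into short-lived foci. Two live-cell imaging readouts capture this
behaviour: (1) under total internal reflection (TIRF) illumination only
a thin evanescent layer (depth *d* ≈ 100 nm) above the coverslip is
excited, so the decay rate of total fluorescence under continuous
illumination reports on diffusion — molecules that leave the excited
stripe before bleaching protect the pool, making *fast diffusion bleach
slowly*; (2) intensity statistics along the membrane perimeter detect
clustering — foci raise the per-scan variance without changing the mean.

`tirfdyn` provides, for people who build or validate such analyses:

* **membrane simulator** — Brownian dynamics on the wall of a
  spherocylinder with transient binding to immobile substrate sites
  (the focus mechanism; removing sites emulates rifampicin-induced
  substrate depletion), fully reproducible from a seed;
* **optics** — rendering of trajectories into synthetic TIRF or
  epifluorescence stacks: evanescent excitation
  *w*(θ) = exp(−*z*/*d*), stochastic photobleaching, Poisson photons,
  Gaussian PSF, camera offset and read noise, plus ground-truth masks;
* **linescan** — membrane-perimeter scans with the adjacency exclusion
  rule, per-scan mean/variance, field medians;
* **kymo** — kymograms along the principal cell axes and a Pearson
  persistence score separating fixed from live cells;
* **bleachfit** — per-cell normalized bleach traces and the global
  constrained two-phase fit
  *I*(t) = *A*·e^(−k_fast·t) + (100−*A*)·e^(−K·t)
  with a shared fast rate across conditions, yielding the
  diffusion-limited slow rate *K* (± SEM, R²) per condition;
* **helix** — helical-wheel residue classification and hydrophobic
  moment µH of amphipathic membrane-targeting peptides;
* **pipeline** — one-call experiments (`run_experiment()`) with
  canonical presets (`untreated`, `rifampicin`, `fixed`,
  `control_protein`) and a CLI (`inst/cli/tirfdyn`).

## Worked example

```r
library(tirfdyn)
cfg <- experiment_config(
  conditions = list(
    untreated  = condition_preset("untreated",  n_particles = 600),
    rifampicin = condition_preset("rifampicin", n_particles = 600)),
  n_cells = 6L, out_dir = "results/demo", seed = 42L)
res <- run_experiment(cfg)
res$bleach_fit
```

```
Global two-phase bleach fit (shared fast rate)
  k_fast = 1.25 1/s (SEM 0.0755)
   condition      K   SEM_K A_fast k_fast    R2 n K_at_bound
1  untreated 0.2351 0.01729  45.01   1.25 0.998 6      FALSE
2 rifampicin 0.1514 0.01828  51.27   1.25 0.997 6      FALSE
```

The slow rate *K* drops from 0.235 to 0.151 1/s when substrate sites are
removed: without clustering the protein diffuses faster, spends less
time in the evanescent stripe, and bleaches more slowly.
`res$comparison` spells this out (ratio 0.644, "faster diffusion under
rifampicin"). The line-scan medians from the same run show the focus
signature — variance roughly halves with unchanged mean:

```
untreated :  median mean  66.8 counts   median variance 349.4 counts^2
rifampicin:  median mean  65.0 counts   median variance 176.0 counts^2
```

The helix module ranks the wild-type membrane-targeting peptide above
its F→A double substitution (which loses membrane binding):

```r
hydrophobic_moment("PAQPGLLSRFFGALKALFSGGK")   # wild type     0.2676
hydrophobic_moment("PAQPGLLSRAAGALKALFSGGK")   # F574A/F575A   0.2456
```

## File formats

Image stacks and label masks are serialized as plain-text TSV with a
JSON metadata header (pixel size in µm, frame interval in s);
trajectories as long-format TSV with a JSON config sidecar. See
`write_stack()`, `write_trajectory()`, `read_sim_config()`.

## Design notes

The methods vignette (`vignettes/tirfdyn-methods.Rmd`) documents the
physical model, every default parameter with units and rationale, the
acquisition-window regime in which the diffusion-to-K mapping is
monotone, what the synthetic data does and does not emulate, and known
limitations.
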