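# minstedsim

A desk-scale simulator and statistical analysis stack for **MINSTED**
single-fluorophore localization — the super-resolution modality that
encircles one active fluorophore with the central zero of a STED donut
beam, sharpens the effective PSF photon by photon, and nudges the scan
circle toward every detection until the fluorophore is pinned down with
sub-nanometer precision.

The package is aimed at microscopy method developers and analysts who
want to study the statistics of donut-zero tracking localization —
precision versus photon number, background sensitivity, stability
decomposition, downstream structure analysis — without access to the
(one-of-a-kind) instrument.

## What is modeled

**Effective PSF.** The emission probability at radial offset `r` under
pulse energy `E` is

    h(r, E) = [exp(-4 ln2 r²/F_c²) + β E d(r)] · exp(-ln2 (E/E_sat) d(r))

with confocal FWHM `F_c = 250 nm`, vortex donut `d(r) = u e^(1-u)`,
`u = 2r²/w²`, and a direct-excitation pedestal `β` from the blue-shifted
donut. `E_sat` is calibrated so the E-PSF reaches **24 nm FWHM at 1 nJ**.
Background from diffusing imagers scales with the E-PSF area, giving a
\>10-fold SBR gain over confocal, anchored at **SBR = 60 at 1 nJ**.

**Localizer.** Scan radius locked to half the FWHM (floor 12 nm),
geometric FWHM ramp reaching the minimum at `N_c = 80` detected photons,
center update `0.15 R_i` toward each detection azimuth, Poisson photon
timing at 50 kHz, low-rate termination (16 detections / 20 ms).

**Precision stack.** Convergence filter (σ < 4.2 nm per axis), 10-nm
complete-linkage clustering of repeated localizations, cluster spread
`σ_cluster(N)`, blocked standard error `σ_block(M)` of stride-1 moving
means, power-law fit `σ_est(M) = a/(b+M)^c` with `b > 0`,
`c ∈ (0.4, 0.5]`, and the stability decomposition
`σ_cluster² = σ_est² + s²`.

**Samples.** DNA-origami grids (12/6/4-nm pitch, rect/hex), 8×4-site
nuclear-pore models on a 112-nm ring, DNA-PAINT renewal kinetics with
linker disks and slow site jitter (`s = 0.72 nm`), photoactivation
single-shot mode.

**Structure analysis.** Sector occupancy (40–70 nm band), radial-Gaussian
ring fits with conic-fit ellipticity, 20-nm radial outlier rejection,
template-free kernel-correlation particle overlay with symmetry
randomization, reference-site coverage, density clustering with
`4√(σ_x σ_y)` diameters. Plus CNLP Gaussian rendering and TSV/JSON I/O.

## Worked example

Simulate ten long emission traces of a static emitter, estimate the
localization precision, and extrapolate over photon number:

```r
library(minstedsim)

optics <- optics_model()            # calibrated: 24 nm @ 1 nJ, SBR 60
cfg    <- localizer_config()        # alpha = 0.15, R_min = 12 nm, N_c = 80

traces <- simulate_static_traces(n_traces = 10, photons_after_nc = 10000,
                                 cfg = cfg, optics = optics, seed = 7)
ps <- precision_summary(traces, N_eval = c(400, 2000, 10000))
round(apply(ps$est, 2, median), 3)
#> [1] 0.669 0.277 0.122

cb <- sigma_block_curve(traces[[1]])
print(fit_power_law(cb$M, cb$sigma_nm))
#> power-law precision fit: sigma(M) = 10.41 / (10.16 + M)^0.4625  (log-RMS 0.0229)
```

Read: the median estimated precision is **0.67 nm at 400 detections**,
**2.8 Å at 2,000** and **1.2 Å at 10,000** — the simulated instrument at
its stated operating point beats the published bounds (1 nm, 4.7 Å,
2.3 Å), as it should: the experimental numbers include real-world
disturbances the simulator idealizes away, while background is included.

A repeated-binding origami experiment separates localization precision
from site stability:

```r
ex <- simulate_origami_experiment(n_origami = 3, duration_s = 240, seed = 11)
pc <- precision_config()
keep <- vapply(ex$traces, function(tr)
  tr$initiated && isTRUE(convergence_filter(tr, pc)), logical(1))
tr2  <- ex$traces[keep]
locs <- localization_table(tr2, pc)
cl   <- cluster_localizations(locs[, c("x_nm", "y_nm")], pc)
sigma_cluster(tr2[locs$id], cl, N = c(80, 400, 1500), pc)
#>      N sigma_cluster_nm n_clusters
#> 1   80        3.3460821         16
#> 2  400        1.0195877         16
#> 3 1500        0.7187734         16
```

The cluster spread converges to ~0.72 nm at large N — the injected site
jitter — and `fit_stability()` recovers it (`s = 0.714 nm` in this run).

## Command line

A thin CLI wraps the main workflows (launcher in `inst/cli/minsted`):

```sh
minsted epsf --curve fwhm.tsv --sbr sbr.tsv
minsted simulate --traces 39 --photons 10000 --seed 1 --out traces.tsv
minsted precision --traces traces.tsv --out curves.tsv
minsted npc --locs locs.tsv --out report.json
minsted cluster --locs locs.tsv --out clusters.tsv
minsted render --locs locs.tsv --pixel 0.3 --mode unit_area --out img.tsv
```

See `vignettes/minsted-model.Rmd` for the full model description,
parameter rationale and known limitations.
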