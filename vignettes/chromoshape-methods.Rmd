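---
title: "Simulating chromosome shape by condensin loop capture: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating chromosome shape by condensin loop capture: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromoshape)
```

## The scientific question

Mitotic chromosome arms shorten and thicken as cells progress through
mitosis, and longer arms become disproportionately thicker. `chromoshape`
implements the polymer-physics machinery needed to study one candidate
mechanism for this behaviour: **condensin loop capture**, in which a
condensin complex entraps two chromatin segments that meet by diffusion,
holds them together for a while, and releases them. Transient pairwise
bonds of this kind compact a chromatin chain into dynamically
rearranging rosettes, and the package asks what shapes such chains adopt —
at equilibrium without bonds, at steady state with bonds, and on the way
from an artificially elongated (prophase-like) state towards steady
state.

## The chain model

The chromatin fibre is a coarse-grained bead-spring chain. One bead has
radius $a$ = 25 nm and stands for roughly 10 nucleosomes, i.e. about 2 kb
of DNA, so chains of $N$ = 100 to 4000 beads represent 200 kb to 8 Mb
fibres (`beads_to_genome_mb()`). Everything is expressed in reduced
units: $a = 1$ (length), $k_BT = 1$ (energy), friction $\gamma = 1$, so
the free-bead diffusion constant is $D = k_BT/\gamma = 1$ and one reduced
time unit is roughly the time a bead takes to diffuse its own radius.

Three forces act on every bead (plus condensin bonds, below):

* **Chain springs** — Hookean springs of rest length $l_0 = 2a$
  (touching beads) between consecutive beads.
* **Soft steric repulsion** — any two beads closer than $2a$ repel with
  force $k_{rep}(2a - d)$. This "soft overlap" keeps the chain
  self-avoiding without the stiffness cost of hard exclusion; at the
  default $k_{rep} = 25\,k_BT/a^2$ full overlap costs $50\,k_BT$, so
  chain crossings are rare.
* **Thermal noise** — overdamped Langevin (Euler–Maruyama) updates
  $x \leftarrow x + (dt/\gamma)F + \sqrt{2 (k_BT/\gamma)\,dt}\,\xi$.

The geometry ($a$, $l_0$, condensin site spacing) is fixed by the
biology; absolute force constants and the timestep are numerical
choices, and we calibrate them for stability and speed rather than
transcribing them from any particular source. The defaults are
$k_{spr} = k_{rep} = 25\,k_BT/a^2$ and $dt = 3\times 10^{-3}$: bond-length
fluctuations are then $\sqrt{k_BT/k_{spr}} = 0.2\,a$, far below chain
dimensions, while the stability margin $dt \cdot k_{spr}/\gamma = 0.075$
stays below the enforced guard of 0.1 (the Euler discretisation inflates
the stationary bond-length variance by about 4% at this margin, verified
against the exact Boltzmann quadrature in the tests). A stiffer chain
($k = 100\,k_BT/a^2$) would force a four-times smaller timestep for no
measurable change in any shape observable we report, since those depend
on $l_0$ and the excluded volume, not on the spring stiffness, once
fluctuations are small.

Integration cost is kept near-linear in $N$ with a dense cell grid over
the conformation's bounding box (cell edge = interaction cutoff $2a$,
epoch-stamped lazy clearing, half-neighbourhood pair sweep), rebuilt
every step.

## Shape measure

A conformation is reduced to length/width/depth through the eigenvalues
$\lambda_1 \ge \lambda_2 \ge \lambda_3$ of the $3\times 3$ covariance
matrix of bead positions: $L = 2\sqrt{\lambda_1}$, $w = 2\sqrt{\lambda_2}$,
$d = 2\sqrt{\lambda_3}$, and roundness $r = w/L$. The covariance is
normalised by $N$ (population form) because it describes the shape of
one point cloud, not an estimator of a parent distribution. Probability
theory gives a random polymer time-averaged proportions
$L:w:d = 3.44:1.64:1$, hence an expected roundness
$r = 1.64/3.44 = 0.48$ — the benchmark the unconstrained simulated chain
must reproduce.

## Equilibrating the unconstrained chain

Global conformational relaxation of a self-avoiding chain under
Brownian dynamics takes reduced time growing roughly like $N^{2.2}$
(Rouse scaling with excluded volume) — prohibitive at $N = 1000$ on one
CPU. The package therefore equilibrates global structure with a
**Metropolis pivot Monte Carlo** sampler (`init_equilibrated()`), the
standard global-move equilibrator for self-avoiding polymers: a random
interior bead is chosen, the shorter chain arm is rotated about it by a
uniform random rotation, and the move is accepted by the change in the
same soft-overlap energy the dynamics engine integrates,
$U(d) = k_{rep}(2a-d)^2/2$. Pivot moves preserve bond lengths exactly, so
a short Brownian relaxation (5 reduced time units by default) restores
thermal bond-length fluctuations afterwards. Equilibrium ensembles
(`equilibrium_ensemble()`) are built from *independent* pivot draws, each
finished with Brownian dynamics, rather than from one long correlated
trajectory; Brownian dynamics remains the engine for every kinetic
question (loop capture, timecourses).

With this sampler the equilibrium sweep
(`experiment_equilibrium()`) reproduces the expected behaviour at desk
scale: mean size grows as $N^{\nu}$ with $\nu$ close to the Flory value
0.588 over $N \in \{100, 250, 500, 1000\}$, and mean roundness is
$\approx 0.48$, independent of $N$.

## Condensin loop capture

Every 10th bead is a condensin binding site (`condensin_sites()`),
matching the measured mean spacing of condensin sites in fission yeast
(about 23 kb at 2 kb per bead). Bonds obey four rules
(`update_bonds()`):

1. a site holds at most one bond (condensin entraps exactly two
   segments), so the bond set is always a matching;
2. every existing bond is released with probability `p_release` per
   update;
3. all currently free site pairs within `d_cutoff` are collected, the
   list is shuffled uniformly (no index-order bias inside crowded
   rosettes), and each pair whose sites are still free bonds with
   probability `p_capture`;
4. a bonded pair is pulled together by a Hookean spring toward a rest
   separation of one bead diameter; the bond is deliberately *softer*
   than the chain backbone ($k_{bond} = 5$ vs $25\,k_BT/a^2$), because a
   condensin bridge is a flexible protein linkage, not a chromatin
   segment.

Bond updates run every 10 dynamics steps. Because bonds keep forming
and breaking at steady state, the compact state is actively maintained
(a steady state in the thermodynamic sense), unlike the passive
equilibrium of the unconstrained chain.

### Choosing the capture parameters

No measured values exist for `d_cutoff`, `p_capture` and `p_release` at
this level of coarse-graining, so they are calibrated — once — against
the phenomenology the model must show: genuine compaction from coil
starts, steady-state roundness above the unconstrained 0.48, SAW-like
size scaling maintained, and robustness to doubling/halving
`p_capture`. The calibration scans exposed three failure regimes worth
recording:

* **No compaction.** Small capture radius with short bond lifetimes
  (e.g. $2.5a$, lifetime $10^3$ steps): isolated bonds die before
  further sites can diffuse into reach, nucleation never cascades and
  the chain stays an open coil.
* **Bottlebrush collapse of the loop spectrum.** Large capture radius
  or very fast turnover: sites bond almost exclusively with their
  genomic neighbours (which are always the closest in space), producing
  a chain of short tight loops — an elongated bottlebrush with
  *decreased* roundness (0.2–0.35). This is the shape regime the
  loop-capture model is meant to contrast with, not reproduce.
* **Arrested pearl necklaces.** Very long lifetimes: deeply bound
  rosette clusters coarsen so slowly that replicates freeze in
  different cluster counts, with enormous scatter in shape.

The defaults sit between these failures (`capture_params()`: capture
radius $3a$, `p_capture` 0.5, `p_release` 0.025 per update, bond
stiffness $5\,k_BT/a^2$). The capture radius lies comfortably below the
typical spatial distance of *adjacent* sites
($\approx 2 \cdot 10^{0.59} \approx 7.7a$), so bonds record genuine 3D
encounters; the capture/release ratio of 20 sets a sticker strength deep
enough to compact but shallow enough that the ensemble keeps mixing; and
the soft bond turned out to be the decisive lever for roundness — stiff
bonds ($k_{bond} = k_{spr}$) pin captured pairs into dense cores and the
chain responds by either staying elongated or collapsing outright,
whereas the flexible bridge yields compact structures whose mean
roundness sits close to the published benchmark of 0.51 with the smallest
replicate scatter of any regime scanned. Within a factor of two in
`p_capture` the steady-state dimensions are statistically
indistinguishable, as required. Steady-state shape fluctuations remain
intrinsically broad: individual runs wander between open and
near-globular states on slow timescales, and per-run mean roundness
spans roughly 0.3–0.8 at $N = 250$. Rosette clusters merge and split
slowly, so this run-to-run spread is physical, not numerical noise;
desk-scale replicate means of roundness consequently carry standard
errors of several hundredths, and any single small-replicate estimate
can land outside the $0.51 \pm 0.03$ band in either direction.

## Elongated initial condition and timecourses

The elongated (prophase-like) start (`init_elongated()`) draws bead $z$
coordinates from a Gaussian of standard deviation $L_0/2$, sorts them,
and adds transverse $x, y$ coordinates from Gaussians of standard
deviation $w_0/2$; width and depth start equal because experimental
images cannot distinguish them. $L_0$ and $w_0$ are set to 4x the
loop-capture steady-state length and 1x the steady-state width for each
$N$; these anchors come from pilot runs cached in
`steady_state_lookup()` (regenerable with `pilot_steady_state()`). Bond
lengths are not enforced at placement — the first dynamics steps relax
them — but any bond exceeding $10\,l_0$ is resampled so the engine's
instability guard cannot trip at $t = 0$.

`experiment_timecourse()` releases such chains into loop-capture
dynamics and summarises replicate means (with standard errors of the
mean, the error model used for all replicate-averaged fits), per-$N$
exponential relaxation fits, and the power-law exponent series
$\alpha(t)$.

## Fitting procedures

* **Power laws** (`fit_power_law()`): ordinary least squares of
  $\log w$ on $\log L$, as is standard for length-to-width data;
  $\alpha$ is the slope, $c$ the exponentiated intercept, CIs from
  linear-regression theory. Over the one-decade ranges available here a
  power law is a convenient descriptive form, not a tested asymptotic
  law.
* **Exponential relaxation** (`fit_relaxation()`):
  $V(t) = L_{ss} + \Delta L\, e^{-t/\tau}$, first minimised with the
  derivative-free Nelder–Mead simplex, whose optimum seeds a
  Levenberg–Marquardt least-squares refinement that supplies standard
  errors. $\tau$ is bounded by $10^3 \times$ the observation window to
  prevent runaway plateaus; a decay amplitude below twice its standard
  error flags the fit unidentifiable; non-convergence is flagged, never
  silently replaced. The *plateau* parameter — not a tail average — is
  the reported steady-state value wherever a relaxation fit is
  available (both are computed).
* **Flory exponent** (`fit_scaling_exponent()`): log-log regression of
  ensemble-mean size on $N$.

## Image measurements and their validation

Since raw microscopy data are external to this package, the two
measurement operators are validated on synthetic images whose ground
truth is known (`make_chromosome_image()`): rods (straight or curved)
with Gaussian cross-section of specified FWHM, with Gaussian or Poisson
noise at a chosen peak SNR.

* **Moving-Gaussian FWHM** (`fwhm_width()`): intensities outside the
  traced mask are zeroed, one-pixel slices are taken perpendicular to
  the centerline (supplied polyline, else the mask's principal axis), a
  Gaussian is fitted per slice, and the mean
  $\mathrm{FWHM} = 2\sqrt{2\ln 2}\,\sigma$ is reported. Failed slices
  (flat profiles) are skipped and counted; more than half skipped flags
  the measurement.
* **Equal-area ellipse** (`equal_area_ellipse()`): orientation and axis
  ratio from the mask's second central moments; both axes rescaled by a
  common factor so the ellipse area *exactly* equals the mask area. The
  exact pixel conventions of interactive tracing tools are not
  published, so this moments-plus-area construction is validated
  against synthetic shapes (disks, rotated ellipses) rather than
  byte-for-byte against any particular tool.

Masks are defined at half of the per-object maximum intensity,
emulating the half-maximum threshold used when tracing real spreads.
Pixel centres sit at integer coordinates (0-based); mask area is pixel
count times pixel area; deciles interpolate linearly between order
statistics (`stats::quantile` type 7).

The synthetic generator emulates the geometry and noise of DAPI-stained
arms but not optical blur along the length axis, out-of-focus light or
touching chromosomes; passing recovery tests therefore validates the
measurement *operators*, not segmentation of real spreads (tracing is
manual in practice).

## Problem sizes, tolerances, degenerate inputs

Desk-scale experiment defaults are chosen so the whole analysis reruns
from scratch in well under an hour on one CPU: 3 replicates per
condition, $N$ up to 1000, 30 independent conformations per equilibrium
replicate, and loop-capture horizons of 1000/1200/800 reduced time
units for $N$ = 250/500/1000 — roughly 10 relaxation times at $N = 250$
($\tau \approx 97$ from the pilot fits), with the larger chains
deliberately left mid-relaxation and their steady-state dimensions
taken from the exponential-fit plateau rather than the drifting tail
(the same convention the analysis uses for its reported steady-state
values). Study-scale runs (10 replicates, $N$ to 4000, horizons from
`default_horizon()`) use the same code paths. Noise defaults for the synthetic generators (peak SNR 10,
multiplicative log-noise 0.1) keep recovery tests sensitive but stable.

Degenerate inputs are handled explicitly rather than propagated:
coincident beads repel along a deterministic $+x$ fallback (never NaN);
an all-coincident cloud reports zero dimensions with flagged roundness;
zero images and underpopulated timepoints return flagged records;
collinear masks report zero width, flagged. Every stochastic function
takes an integer seed and is bit-reproducible from it; derived
per-replicate seeds come from a fixed linear-congruential mix kept
below $2^{31}$.

## Known limitations

* The reduced-time-to-minutes mapping is a single calibration constant
  (anchored to the $N = 250$ relaxation, `reduced_time_to_minutes()`),
  not a measured quantity; only orderings and ratios of relaxation
  times are meaningful across $N$.
* Hydrodynamics, bending stiffness, confinement, topoisomerase strand
  passage, sister-chromatid cohesion and distinct condensin I/II bond
  types are all outside the model.
* Steady-state shape distributions at strong bond coupling are broad;
  replicate-to-replicate scatter of roundness is physical, and
  desk-scale means carry correspondingly wide errors.
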