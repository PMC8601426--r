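---
title: "Restraint-based chromatin reconstruction by dissipative particle dynamics: models, parameters and design choices"
author: "DPDfold authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DPDfold methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A single-cell Hi-C experiment reports, for one nucleus, a sparse set of
locus pairs that were spatially close at fixation. Binned at a resolution of
tens to hundreds of kilobases, a cell typically yields between 0.001 and 1
contacts per genome bin. DPDfold turns such a contact set into an explicit
3D bead-spring model of the chromosome and, just as importantly, quantifies
how much the answer can be trusted at a given contact density.

## The physical model

The chromatin fibre is coarse-grained to one bead per genomic bin.
Everything is expressed in reduced DPD units: the non-bonded cutoff
$r_c = 1$ is the length unit, $k_BT = 1$ the energy unit, bead mass is 1.

Three pairwise forces act between beads closer than $r_c$
(Groot--Warren DPD):

* conservative soft repulsion
  $F^C_{ij} = a_{ij}\,(1 - r_{ij}/r_c)\,\hat e_{ij}$,
* dissipative friction
  $F^D_{ij} = -\gamma\,(1 - r_{ij}/r_c)^2 (\hat e_{ij} \cdot v_{ij})\,\hat e_{ij}$,
* random kicks
  $F^R_{ij} = \sigma\,(1 - r_{ij}/r_c)\,\theta_{ij}\,\hat e_{ij}/\sqrt{\Delta t}$,
  with $\sigma = \sqrt{2\gamma k_BT}$ fixed by fluctuation--dissipation.

The dissipative/random pair is a momentum-conserving thermostat, so
hydrodynamics-scale artefacts of global thermostats are avoided.
Consecutive beads, and every bead pair observed in contact, are joined by
harmonic bonds $U(r) = \tfrac{k}{2}(r - l_0)^2$.

Parameter defaults, their units and origin:

| parameter | default | meaning |
|---|---|---|
| $a_{pp} = a_{ss}$ | 25 | like-species repulsion; soft enough for chain crossing |
| $a_{ps}$ | 55 | polymer–solvent repulsion; with density 3 this is $\chi = 0.286\,\Delta a = 8.58$, deep poor solvent, so the chain collapses to a globule |
| $r_c$ | 1.0 | interaction cutoff, the length unit |
| $k$ | 40 | bond stiffness |
| $l_0$ | 0.5 | unperturbed bond length; under the soft repulsion the realised bond length equilibrates near 0.65 |
| $\gamma$ | 4.5 | friction; the standard DPD value |
| $k_BT$ | 1 | thermostat target |
| $\Delta t$ | 0.04 | integration step; soft potentials allow a step roughly an order of magnitude larger than hard-core MD |
| $\rho$ | 3 | bead number density; chosen because the linear $\chi(\Delta a)$ calibration holds there, making $\chi = 8.58$ exact |
| $\lambda$ | 0.65 | velocity-prediction factor of the modified velocity-Verlet integrator |

$\gamma$, $k_BT$, $\rho$ and the integrator variant are not dictated by the
reconstruction problem itself; they are the standard DPD working point and
are exposed in `DPDParams()` rather than hard-coded.

### Phantom chains

With $a = 25$ and $l_0 = 0.5$ the energy barrier for one chain strand to
pass through another is a few $k_BT$: the chain is effectively *phantom*.
This is essential, not incidental. The reconstruction starts from a random
walk whose restraint bonds are massively over-stretched and topologically
entangled; only because strands can cross can the network relax into the
target fold instead of vitrifying. Shortening $l_0$ to 0.3 or below closes
the gap between consecutive beads and destroys phantomness — the test suite
demonstrates this directly with a pair of Hopf-linked rings that unlink at
$l_0 = 0.5$ but stay linked at $l_0 = 0.2$ under identical driving.
`reconstructionConfig()` therefore refuses $l_0 \le 0.3$ unless explicitly
overridden.

## The reconstruction protocol

1. Bin the contact list (`binPairs()`): one chain per chromosome,
   bin index = `floor(pos / resolution)`. Intra-bin and bin-adjacent
   contacts are dropped — they are always satisfied by the backbone and
   would add no information.
2. Build the start (`buildRestrainedSystem()`): an independent random walk
   per chain with step $l_0$, solvent filled to density $\rho$ in a cubic
   box sized so the polymer occupies the configured volume fraction
   (default 10%, a nucleus-like chromatin concentration), Maxwell
   velocities, and one restraint bond per contact with the *same* $(k, l_0)$
   as the backbone — restraints and backbone bonds are physically
   interchangeable, and after equilibration their length distributions
   should coincide.
3. Equilibrate (`equilibrateReconstruction()`): DPD until the median
   restraint length is stationary — over the trailing 20% of checkpoints
   (taken every 1000 steps) the median of the later half differs from the
   median of the earlier half by less than 1% — or a budget of
   $10^5 \cdot N/512$ steps runs out (the result is then flagged
   unconverged). Solvent is stripped from the output.
4. Score (`conformationAccuracy()`): distance maps normalised by the radius
   of gyration, compared by the Modified Jaccard Index.

### Periodic boundaries and bonded forces

Non-bonded interactions are periodic (cubic box, minimum image, linked-cell
neighbour search rebuilt every step). Bonded forces, however, act on
*true-space* displacements, equivalent to the image-flag convention of
standard MD packages. This is a deliberate design choice: if restraints
were also evaluated under minimum image, a restraint could be "satisfied"
by the partner bead's periodic image, and restrained systems relax into
image-threading tangles that are mechanically stable but not physical
conformations. In controlled comparisons this failure mode cost roughly 50
accuracy points on dense gold-standard maps while every local observable
(temperature, bond-length medians) looked healthy — a reminder that
restraint networks probe global geometry in a way plain polymer simulations
do not.

### Integrator and randomness

The modified velocity-Verlet scheme evaluates forces once per step using
predicted velocities ($\lambda = 0.65$) for the dissipative term. The
per-pair random variate is uniform on $[-\sqrt3, \sqrt3]$ (unit variance;
a Gaussian variant is available via `DPDParams(gaussianTheta = TRUE)`), and
is produced by a counter-based hash of `(seed, step, i, j)` rather than a
sequential generator. Consequences: forces are independent of pair
enumeration order, the cell-list and brute-force paths agree bitwise (a
standing regression test), and trajectories are exactly reproducible from
the seed across runs.

The instability guard aborts a run when any bead moves more than half the
box edge in one step; this triggers only for pathologically over-stiff
restraint networks (e.g. contact radii far above the coordination shell
combined with long rest lengths).

## Gold standards and what the benchmarks mean

`generateGlobule()` collapses a random walk in poor solvent until the
radius of gyration plateaus; this is the model of a chromosome at ~10 kb
resolution and below, where one bead represents fibre plus bound solvent
and the effective concentration approaches 100%. The starting walk is
confined to a ball slightly larger than the final droplet: a box-spanning
start can arrest in a metastable interface-free column percolating through
the periodic boundary, a finite-size artefact, whereas the compact start
collapses locally into the same equilibrium droplet (the generator's
contract is the equilibrium sample, not collapse kinetics). `mooreCurve()` provides an
analytical, perfectly deterministic space-filling closed curve with
$8^{\text{order}}$ beads (built from eight rotated Hilbert blocks arranged
on a Gray-code octant cycle; the construction is verified exhaustively at
orders up to 3). `generateSolution()` equilibrates coils at chosen volume
fractions in athermal solvent; solutions fluctuate, so benchmark points are
averaged over independent replicates.

The dropout benchmark (`runDropoutSweep()`) subsamples a gold-standard
contact map, reconstructs, and scores accuracy against the gold standard.
Accuracy follows an exponential law in contacts per bead $x$,

$$\mathrm{accuracy}(x) = (1 - A e^{-x/\beta})\,A_{\max},$$

with reference constants $A = 0.642$, $\beta = 0.239$, $A_{\max} = 93.7$%
established on 4096-bead globules with full radius/dropout sweeps. The
ceiling $A_{\max}$ is physical: beads on the surface of an equilibrated
structure keep fluctuating, so even a reconstruction seeded from the gold
standard itself scores about 93%, not 100%. `fitAccuracyCurve()` re-fits
these constants from sweep points with bounded Levenberg–Marquardt least
squares.

### Desk-scale choices

The package's own test suite runs everything at $N = 512$ (Moore order 3 or
a 512-bead globule), with reconstruction budgets of 15–30k steps and the
thermostat check on a 648-bead solvent box. These sizes were chosen as the
smallest at which the claims are cleanly measurable: bond statistics are
local and already converged at 512 beads, while the *absolute* accuracy
ceiling and the fitted $(A, \beta)$ constants are defined at $N = 4096$
full sweeps and are *not* re-measured at desk scale — at 512 beads the
curve's shape (monotone recovery, >60% at full contacts) is reproducible,
its constants are not. `experimentSpec(n = 4096, ...)` runs the
publication-scale versions when the compute is available.

## The similarity metric

For conformations $1, 2$ with (Rg-normalised) distance maps $D, D'$:

$$\mathrm{IMJ} = \frac{\lVert (D - D')/2 \rVert}{\lVert (D + D')/2 \rVert},
\qquad
A = \frac{\mathrm{IMJ}_r - \mathrm{IMJ}_{12}}{\mathrm{IMJ}_r}\times 100\%.$$

IMJ is zero for identical structures and invariant to rigid motion and
mirror reflection (chirality is genuinely invisible to any distance-based
score; `mirrorConformation()` exists for visual comparisons). The random
baseline $\mathrm{IMJ}_r = 0.378$ is the mean IMJ of two independent
symmetric matrices with iid uniform $[0,1]$ entries; the uniform choice is
an inference — it reproduces the conventional 0.378 exactly, since
$\sqrt{E[(X-Y)^2]/E[(X+Y)^2]} = \sqrt{1/7} \approx 0.37796$ — and the
estimate is size-stable, so the 2000×2000 Monte Carlo used in the checks
matches larger matrices. Accuracies below the baseline are reported as
negative numbers, never clipped. When maps carry missing-data masks
(oligopaint imports), masks are intersected and excluded from both norms.

## What the synthetic fixtures do and do not emulate

`syntheticContactMap()` produces sparse symmetric maps with a power-law
contact-separation profile $P(s) \sim s^{-1}$ and a tunable density of
0.001–1 contacts per bead — the statistics that drive the accuracy model.
It does not emulate locus-specific structure (compartments, TADs, loops),
restriction-site spacing, or trans-contact patterns of real nuclei. Tests
passing on these fixtures therefore validate the machinery (binning,
sampling, shuffling, metric plumbing) and the density–accuracy
relationship, not biological interpretation of any particular genome.

Ambiguities resolved as package policy: backbone-adjacent bead pairs are
excluded from contact maps (always in contact, no information);
inter-chromosomal contacts are kept as restraints by default
(`binPairs(trans = "keep")`); multiple chromosome copies are modelled as a
single chain per chromosome name; sampled counts use
round-half-away-from-zero so they are platform-reproducible.

## Known limitations

* One bead per bin and a single force-field working point: resolution-
  dependent fibre stiffness or locus-specific chromatin states are not
  modelled.
* Reconstruction from very dense restraint networks (contact radii well
  above the first coordination shell) can be mechanically over-determined;
  the engine detects instability and aborts rather than annealing through
  it (annealing schedules are out of scope).
* The accuracy model's constants transfer to experimental data only in the
  sense of the exponential *form*; per-dataset ceilings depend on noise
  sources the simulation does not represent.
* Distance-based scoring cannot distinguish mirror images; reported
  structures are one of two enantiomers.
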