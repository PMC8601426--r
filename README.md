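# DPDfold

3D chromosome conformations from single-cell Hi-C contact maps by
dissipative particle dynamics (DPD), with the benchmarking apparatus to say
how much such a reconstruction can be trusted.

## The problem

A single-cell Hi-C experiment captures, for one nucleus, a sparse list of
locus pairs that were spatially adjacent — typically between 0.001 and 1
contacts per genome bin once binned at 20–200 kb. Restraint-based modelling
turns that list into an explicit polymer conformation: the chromatin fibre
becomes a bead-spring chain (one bead per bin), every observed contact
becomes an extra harmonic bond, and the system is relaxed by molecular
simulation. DPDfold implements this pipeline with a DPD force field, whose
two properties make it work where hard-core molecular dynamics vitrifies:

* **soft conservative repulsion** `F^C = a_ij (1 − r/r_c) ê` lets chain
  strands cross ("phantom" chain), so the massively over-stretched,
  entangled restraint network of the random-walk start can untangle;
* a **pairwise momentum-conserving thermostat**
  (`F^D = −γ (1 − r/r_c)² (ê·v) ê`, `F^R = σ (1 − r/r_c) θ ê / √Δt`,
  `σ² = 2γk_BT`) keeps the dynamics honest at a time step of 0.04.

Bonds are harmonic, `U = (k/2)(r − l0)²`, with `k = 40` and `l0 = 0.5` for
backbone and restraints alike; the default repulsion (`a_pp = a_ss = 25`,
`a_ps = 55`, giving Flory–Huggins χ = 0.286·Δa = 8.58 at density ρ = 3)
puts the chain in poor solvent, the globular regime appropriate for
chromatin at ~10 kb resolution and below.

Reconstruction quality is scored by the **Modified Jaccard Index** of
Rg-normalised distance maps, `IMJ = ‖(D − D′)/2‖ / ‖(D + D′)/2‖`, rescaled
to an accuracy `A = (IMJ_r − IMJ) / IMJ_r × 100 %` against the
random-matrix baseline `IMJ_r = 0.378 (= √(1/7))`. Accuracy follows an
exponential law in the contacts per bead `x`,

```
accuracy(x) = (1 − A e^(−x/β)) · A_max ,   A = 0.642, β = 0.239, A_max = 93.7 %
```

which the package can both evaluate (`expectedAccuracy()`) and re-fit from
benchmark sweeps (`fitAccuracyCurve()`, `runDropoutSweep()`).

For whom: computational biologists reconstructing single-cell 3D genomes,
and polymer-physics practitioners who need a compact, fully seeded DPD
engine with restraint support.

## Worked example

Reconstruct a 64-bead closed Moore curve (an analytical space-filling gold
standard) from its own contact map and score the result:

```r
library(DPDfold)

gold <- mooreCurve(2, latticeConstant = 0.65)   # 8^2 = 64 beads
cmap <- contactsFromConformation(gold, rContact = 0.68)
cmap
#> ContactMap: 81 unique pairs over 64 beads (1.266 per bead)

cfg <- reconstructionConfig(l0 = 0.5, concentration = 0.1, seed = 11)
res <- reconstruct(cmap, cfg = cfg, nReplicates = 1)
res$results[[1]]
#> ReconstructionResult: 64 beads, converged, restraint satisfaction 0.568

conformationAccuracy(res$results[[1]]@conformation, gold)
#> [1] 81.10185

expectedAccuracy(contactsPerBead(cmap))
#> [1] 93.39838
```

Reading the numbers: the map carries 1.27 contacts per bead, so the
exponential model predicts ~93% accuracy at publication scale (N = 4096);
the 64-bead desk run reaches 81% — small chains fluctuate relatively more,
which lowers the achievable ceiling. Restraint satisfaction of ~0.57 at the
equilibrium bond length 0.65 is expected for a *well-equilibrated* system:
restraint lengths fluctuate around the same distribution as backbone bonds
(medians 0.627 vs 0.652 here), which is the reference signature of a
successful reconstruction, not a defect.

For experimental input, `readPairs()` + `binPairs()` convert a 4-column
pairs TSV and a chrom.sizes file into a bead-level `ContactMap` (one chain
per chromosome), and `estimateAccuracyTable()` reports the expected
per-chromosome accuracy before you spend any simulation time on it.

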