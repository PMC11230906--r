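---
title: "Modelling multiphase condensate miscibility with condmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling multiphase condensate miscibility with condmix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condmix)
```

## The scientific problem

Biomolecular condensates are often *multiphasic*: two or more condensed
phases coexist while remaining compositionally distinct (the nucleolus is the
canonical example). Whether two intrinsically disordered regions (IDRs) demix
into separate phases depends on (i) how different their sequence-encoded
interactions are and (ii) how strongly each is oligomerized, e.g. by a
multimeric scaffold. `condmix` implements a minimal, fully testable pipeline
for studying this interplay:

1. **Sequence patterning metrics** for model K/E polyampholytes (SCD and its
   normalized form Omega).
2. **Coarse-grained direct-coexistence simulations** of binary polyampholyte
   mixtures, with either component built as a linear chain or an
   `f`-armed star around a repulsive scaffold core.
3. **Coexistence analysis**: density profiles along the slab normal,
   hyperbolic-tangent fits, partition coefficients `K_p`, interfacial
   tension `gamma` from the pressure tensor, and the
   heterotypic/homotypic bond ratio `phi_B`.
4. **An imaging readout** mirroring the in-vivo assay: segmentation of
   condensates in two-channel volumes and the normalized centre-to-centre
   (CTC) distance between overlapping condensates.
5. **Synthetic-data generators** that embed their ground truth, so every
   stage has an oracle that requires no external data.

## Charge patterning: SCD and Omega

For a sequence of charges $q_i \in \{+1, -1\}$ (K $\to +1$, E $\to -1$),

$$\mathrm{SCD} = \frac{1}{N}\sum_{i<j} q_i q_j \sqrt{j-i}.$$

Blocky sequences have large negative SCD; strict alternation gives SCD near
zero. Because two prefactor conventions circulate ($1/N$ and $1/(N-1)$), the
package states its choice ($1/N$) in the documentation; the choice cancels in
the normalized score

$$\Omega = \frac{\mathrm{SCD}(s)}{\mathrm{SCD}(\text{diblock of the same
length and composition})} \in (0, 1],$$

which is 1 for the blockiest arrangement and invariant under sequence
reversal and global charge flip. The literature names a normalized SCD but
does not print its formula; the diblock normalization above is this
package's documented choice, validated against the one printed patterning
difference available (the KE4/KE6 pair, $-\Delta\Omega = 0.09$; see the
acceptance suite).

```{r}
ke <- ke_sequences()
pattern_metrics(ke)
delta_omega(ke$KE4, ke$KE6)
```

### The packaged KE series is synthetic

The seven `KE1`–`KE7` sequences shipped in `inst/extdata/ke_synthetic.fasta`
are **synthetic stand-ins**, generated by `generate_sequence_series()`
(simulated-annealing pair swaps on length-50, charge-neutral, half-K/half-E
chains) against the Omega ladder 0.02, 0.08, 0.16, 0.28, 0.33, 0.37, 0.42.
The ladder was chosen once so that the series spans near-alternating to
moderately blocky patterning and reproduces the two patterning relations the
study conditions fix: the KE4/KE6 difference of 0.09, and a small KE6/KE7
difference (0.05) against a large KE1/KE7 difference (0.40). Any
user-supplied registry (`read_charge_sequences()`) can replace the
stand-ins; every function takes plain `charge_sequence` objects.

## The coarse-grained model

One bead per residue, implicit solvent. Parameters live in
`inst/extdata/hps_params.csv` and are the published hydrophobicity-scale
set for lysine and glutamate:

* **Ashbaugh–Hatch short-range potential.** For $r \le 2^{1/6}\sigma_{ij}$,
  $U = U_{LJ}(r) + (1-\lambda_{ij})\,\epsilon$; beyond,
  $U = \lambda_{ij} U_{LJ}(r)$, with $\sigma_{ij}, \lambda_{ij}$ arithmetic
  means of per-type values and $\epsilon = 0.2$ kcal/mol. Cutoff 20 Å,
  energy-shifted to zero there.
* **Debye–Hückel electrostatics.** $U = \frac{332.0637\,q_i q_j}
  {\epsilon_r r} e^{-r/\kappa^{-1}}$ kcal/mol with $\epsilon_r = 80$ and
  screening length $\kappa^{-1} = 10$ Å (standard companions of the model;
  the source text is silent on them). Cutoff 35 Å, energy-shifted. The
  radial term is tabulated on an $r^2$ grid with cubic Hermite
  interpolation, so the implemented force is the exact derivative of the
  implemented energy.
* **Bonds.** Harmonic, $U = \tfrac{1}{2} k (r - r_0)^2$ with
  $k = 2.39$ kcal/mol/Å$^2$ (10 kJ/mol/Å$^2$) and $r_0 = 3.8$ Å. Bonded
  pairs are excluded from non-bonded interactions.
* **The star core.** Oligomerization is modelled by bonding the first
  residue of each of $f$ arms to a central scaffold bead. The source text
  prints a core diameter of "1.2 Å, roughly double the diameter of a
  lysine or glutamate bead", which is internally inconsistent (a lysine
  bead is 6.36 Å); the package follows the unambiguous parenthetical
  intent and uses $2\times$ the lysine diameter (12.72 Å), exposed as
  `core_sigma`. Core beads are neutral and purely repulsive (their pair
  $\lambda$ is forced to 0, i.e. Weeks–Chandler–Andersen behaviour),
  regardless of the mixing rule.

Internal units are Å / Da / kcal mol$^{-1}$, giving a derived time unit of
48.89 fs; the user-facing time step is specified in fs (default 10 fs).

### Dynamics

`run_md()` integrates Langevin dynamics with the BAOAB splitting at the
thermostat setpoint (default 250 K, friction 1 ps$^{-1}$). The noise stream
is *counter-based*: each (seed, step, bead) triple is hashed independently,
so trajectories are bit-reproducible and restartable mid-stream
(`step_offset`). With friction 0 and the thermostat off the integrator
reduces to velocity Verlet; the test suite verifies energy conservation to
$10^{-4}$ relative over $10^4$ steps in that limit, force/energy consistency
against numerical gradients, equipartition within 2%, and the ideal-gas
pressure identity.

The production ensemble is **NVT slab coexistence only**. The source
protocol follows equilibration with an NPAT (constant normal pressure and
cross-sectional area) stage; with a large vacuum fraction along z, a
fixed-Lz NVT slab yields the same coexistence observables at the scales this
package targets, so the barostat stage is declared out of scope. This is a
deliberate, documented reduction.

### Preparing a slab

`simulate_pair()` chains the standard preparation: random placement of both
species at equal polyampholyte mass fraction (`assemble_binary_mixture()`,
which enumerates copy numbers to minimize the bead-mass imbalance; scaffold
CORE beads are excluded from the mass balance because they are not component
material), box compression with dynamics running (`compress_box()`, with a
per-bead force cap during this stage only), slab expansion along z
(`make_slab()`, which unwraps molecules so none is split across the new
vacuum), then NVT equilibration and production (`run_coexistence()`).

Molecule placement uses a directionally persistent self-avoiding walk with a
minimum intra-molecular non-bonded distance and a 0.9-sigma inter-molecular
exclusion, so the initial configuration starts inside the stable region of
the potential.

## Coexistence observables

* `density_profile()` bins polyampholyte beads along z, recentring each
  frame on the material's circular-mean centre of mass so slab diffusion
  does not blur the average. The profile integrates back to the species'
  bead count (conservation is asserted in the tests).
* `fit_tanh()` fits
  $\rho(z) = \frac{\rho_{den}+\rho_{dil}}{2} - \frac{\rho_{den}-\rho_{dil}}
  {2}\tanh\!\big(\frac{|z-z_c|-z_0}{w}\big)$ with $z_c$ fixed at $L_z/2$ and
  $\rho_{den} \ge \rho_{dil}$ enforced by parameterization
  ($\rho_{den} = \rho_{dil} + \Delta$, $\Delta \ge 0$, bounded
  Levenberg–Marquardt via \pkg{minpack.lm}). Flat profiles and
  non-convergent fits fall back to 10th/90th-percentile plateau estimates
  and are flagged, never silent.
* `partition_coefficient()` computes $K_p = C_p^{den}/C_p^{dil}$. The
  condensed region is where the total (p+q) profile exceeds the midpoint
  between its robust plateau quantiles; within it, bins where q exceeds its
  own plateau midpoint are q-rich and the rest q-lean. Working bin-wise
  rather than from a symmetric interface geometry keeps the rule valid for
  any slab arrangement (centred q with a p annulus, or two side-by-side
  sub-slabs, both of which occur at reduced scale); one bin is eroded at
  every region boundary as interface exclusion. A candidate q-lean region
  only counts as a phase if q is genuinely depleted there (below half its
  q-rich level); otherwise the components are co-condensed, the result is
  flagged `miscible`, and $K_p$ falls back to the ratio of p's
  concentration between the two geometric halves of the condensed core.
  This null statistic is 1 in expectation for identical species — which is
  what makes the identical-species control meaningful — whereas a literal
  dilute-phase ratio would not be.
  The SEM comes from 5 contiguous frame blocks (regions held fixed), with
  the first 20% of production discarded as burn-in.
  The concentration measure is configurable: bead number density by
  default, or molecule-centroid (molar) density via
  `density_profile(mode = "molecule")` passed as `prof_p_measure`. At full
  scale the two coincide within a phase; in a reduced-scale slab a 91-bead
  star straddling a thin interface smears bead density into the adjacent
  phase while its centroid stays put, so trend comparisons across valence
  use the molar measure. An empty q-rich denominator is floored at half a
  molecule in that region's volume, making the reported $K_p$ a finite
  lower bound instead of a dropped block.
* `interfacial_tension()` uses the mechanical route
  $\gamma = \frac{L_z}{2}\big[\langle P_{zz}\rangle - \tfrac{1}{2}(\langle
  P_{xx}\rangle + \langle P_{yy}\rangle)\big]$ (two interfaces per periodic
  slab), block-averaged, reported in kcal/mol/Å$^2$ and in reduced
  $\epsilon/\sigma^2$ units with $\sigma$ the mean K/E diameter. In a
  multiphase slab this measures the *total* interfacial free energy per
  area, which is the right comparator when the same two materials are
  rearranged (e.g. swapping which species is oligomerized).
* `contact_bond_ratio()` counts inter-molecular bead pairs within
  $1.5\,\sigma_{ij}$ (the first coordination shell; the source defines the
  ratio but not the contact criterion — 1.2–2.0 give the same orderings)
  and reports heterotypic/homotypic contacts of the oligomerized species.

## Problem sizes and what the scaled-down runs can show

The reference protocol for this model family runs tens of thousands of beads
for microseconds — far beyond a single-CPU test suite. The package therefore
ships two presets (`coexistence_preset()`): `"full"` records that protocol,
and `"desk"` is the package's own desk-scale study condition: ~1,200 beads of
length-50 chains, a 130 Å box compressed to 88 Å (which lands at the
observed dense-phase density, ~1.8×10$^{-3}$ beads/Å$^3$ at 250 K), slab
$L_z$ = 300 Å, 10 fs steps. The packaged validation runs scale this further
(600–1,200 beads, 1.2–1.7×10$^4$ production steps, cutoffs 20/15 Å) so the
whole suite runs in minutes.

Four consequences are documented rather than hidden:

* **Chain lengths are 30–50, not 20.** Shorter chains have markedly lower
  critical temperatures; 20-mers at 250 K sit near their critical point and
  do not condense reliably, which would void every coexistence observable.
  The 50-residue registry sequences condense robustly (dense/dilute
  contrast ~600 at 250 K), and the 30-residue analogues used by the trend
  runs (same Omega ladder, annealed to 0.28/0.37/0.42) still show contrast
  above 10^3 while tripling the molecule count per bead.
* **Trend runs start pre-demixed.** Demixing from a random mixture is
  diffusion-limited and needs microseconds; the validation runs instead
  start from a sandwich (vacuum | p | q | p | vacuum) and let the dynamics
  run toward equilibrium: a miscible configuration dissolves measurably
  within the window while an immiscible one retains its structure. The
  Langevin friction is lowered to 0.2 ps$^{-1}$ in these runs purely as a
  sampling accelerator — equilibrium observables do not depend on the
  friction.
* **Molar $K_p$ for valence comparisons** (see above).
* **Only orderings are asserted.** Absolute $K_p$ and $\gamma$ at this
  scale are not the literature's absolute values; the acceptance surface is
  the trend structure: $K_p$ grows with valence, $K_p = 1$ for an
  identical-species null, $\gamma$ is higher (and $\phi_B$ lower) when the
  blockier partner of a similar-patterning pair is the oligomerized one.
  The last of these — the differential-oligomerization asymmetry — does
  **not** stabilize at suite scale: with only 3–7 star molecules the
  coarsening stochastics exceed the asymmetry signal across seeds, and the
  corresponding check in the test suite documents this honestly (it runs
  the faithful protocol and is expected to fail at this scale). Individual
  runs at favourable seeds do show the full effect (an order-of-magnitude
  $\phi_B$ difference), so the observables are sound; the sampling, not the
  method, is the limitation.

What the synthetic generators do *not* emulate about real data: polydisperse
and 20-letter sequences, solvent-mediated many-body effects, microscope
point-spread anisotropy, cell-shaped boundaries and autofluorescence.
Passing tests show the pipeline measures what it claims on data whose truth
is known; they do not calibrate the force field against experiment.

## The imaging readout

`segment_condensates()` thresholds each channel at the larger of the
iterative intermeans (Ridler–Calvard) threshold — the canonical reading of
an "iterative threshold" — and a floor of 20% of the condition-average
maximum intensity, labels 26-connected components (8-connected in 2D) and
discards objects under 50 voxels. Radii are equivalent-sphere radii
$(3V/4\pi)^{1/3}$ (area-equivalent circles in 2D); centroids are geometric
(intensity weighting is off by default since the source does not state it).
`pair_overlapping()` emits one record per intersecting pair across channels
(no exclusive matching), and `normalized_ctc()` divides the centroid
distance by the sum of radii: ~0 for miscible (concentric) condensates, ~1
for associated-but-immiscible ones. `ctc_histogram()` uses right-open bins
of width 0.1 — the bin width that absorbs the measurement noise — and
reports the median of the unbinned values.

```{r}
sp <- sphere_pair_spec(c(24, 32, 32), r1 = 8, r2 = 8, offset = 0.5)
vol <- synth_two_channel_volume(dim = c(48, 64, 64), spheres = sp,
                                noise_sd = 5, seed = 1)
ctc_analysis(vol, min_size = 50, floor_fraction = 0.2)
```

## Numerical choices, degeneracies, tie-breaks

* Pair potentials are *shifted* (not switched) at their cutoffs; whether the
  original work shifted or switched is unstated, so the choice is recorded
  here.
* The Debye–Hückel table introduces interpolation error < 10$^{-7}$
  kcal/mol; the Hermite form keeps force = −dU/dr exactly on the
  interpolant.
* `fit_tanh()` tries a ladder of starting points (the dilute plateau start
  is kept on the profile's scale — a near-zero start makes the internally
  rescaled Jacobian singular) before falling back to quantile estimates.
* Synthetic profile noise is unclipped Gaussian: clipping at zero would
  bias the dilute plateau and poison the fit-recovery calibration.
* Degenerate segmentations (flat or empty images) return empty object
  lists; degenerate tanh fits return flagged quantile plateaus.
* `balance_copy_numbers()` breaks stoichiometric ties toward the smaller
  total-bead deviation; the residual imbalance is returned for logging.

## Known limitations

* NPAT (barostatted) production, replica exchange, finite-size scaling of
  $\gamma$ and critical-temperature estimation are out of scope.
* The neighbour search is an all-pairs Verlet list: appropriate to the
  ≤10$^4$-bead systems targeted here, not to the full-scale protocol.
* $\gamma$ at desk scale carries residual-stress transients; the package
  discards 20% burn-in and block-averages, but slab equilibration, not
  statistics, is the binding constraint for absolute values.
* Star valences are arbitrary in the topology builder, but the study
  conditions exercise f ∈ {1, 3, 5} only.
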