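---
title: "Viability evolution for symmetric assembly prediction: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Viability evolution for symmetric assembly prediction: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Integrative modeling predicts the architecture of a macromolecular complex
from the atomic structures of its subunits plus sparse, heterogeneous
experimental information: a handful of inter-subunit residue-residue
distances (e.g. from crosslinking mass spectrometry), a low-resolution
cryo-EM density map of the whole complex, or per-residue disulfide
crosslinking fractions. For a cyclic (Cn) homo-oligomer the search space is
tiny — the whole ring is generated from one subunit by four parameters
$[\alpha, \beta, \gamma, x]$: three Euler angles orienting the subunit and
the ring radius $x$ — but the scoring is the hard part. The classical recipe
collapses a steric term and a restraint term into one weighted fitness

$$f = w\,E_{phys} + (1-w)\,E_{data}, \qquad w = 0.2,$$

which forces an arbitrary choice of $w$ and lets a deep clash basin trade
against restraint violations. `viasm` implements the alternative this
package exists for: **viability evolution**. Every restraint interval
$l_i \le o_i \le u_i$ and the steric condition $E_{phys} < 0$ are independent
*viability constraints*. Candidate solutions survive only if they lie within
per-constraint boundaries that start wide (every initial candidate is
admissible) and tighten monotonically to the true bounds; once candidates
are viable, a free objective — population diversity, map cross-correlation,
or a crosslink correlation — is optimised over the feasible region. No
weights, ever. The aggregated $f$ above is kept only as a comparison
baseline (`protocol_aggregated_reference()`).

A note on the constraint notation: the inequality is enforced on the
*observed* distance $o_i$ of restraint $i$ in the candidate model, with
$[l_i, u_i] = [t_i - e, t_i + e]$ around the target $t_i$ and a default
tolerance $e = 2$ Å absorbing experimental noise.

## Scoring terms

* **Steric energy** $E_{phys}$: a coarse 9-6 Lennard-Jones potential over
  all unique inter-subunit Cα pairs,
  $4\varepsilon[(\sigma/r)^9 - (\sigma/r)^6]$ with $\sigma = 4.7$ Å,
  $\varepsilon = 1$ kcal/mol, truncated (not shifted) at 12 Å. All copy
  pairs are summed, not only adjacent ones: in a closed ring, non-adjacent
  copies can clash. The truncation discontinuity
  ($\approx -0.0136$ kcal/mol per pair at the cutoff) is accepted as in
  typical coarse scoring. `E_phys < 0` is enforced with a $10^{-6}$ margin,
  so "no contact at all" ($E_{phys}=0$ beyond the cutoff) never counts as
  viable: viable assemblies are clash-free *and* in contact.
* **Restraint residuals**: restraints are measured between copies 1 and 2 —
  under Cn symmetry all adjacent interfaces are equivalent.
  $E_{data} = \sqrt{\sum_i (o_i - t_i)^2}$ exists for the reference mode
  only.
* **Diversity** of a candidate $x$ against the population of unit means
  $X_i$: $\sqrt{\sum_i \lVert x - X_i\rVert^2}\,/\,n$, computed in the
  normalised unit box (angles/2π, radius/x_max) so radians and Ångström are
  not mixed in one Euclidean norm.
* **Crosslink objective**: Pearson correlation between the fractional
  crosslinking profile and the inter-subunit Cβ distances of the profiled
  residues. The magnitude $|R|$ is maximised and the signed value is
  reported alongside: physically the correlation should be negative (more
  crosslinking at shorter distance), and the generator indeed produces
  negative $R$, but magnitude maximisation keeps the objective agnostic to
  the reported sign convention of any given dataset.
* **Precision audit**: $PPV = TP/(TP+FP)$ over satisfied restraints, where a
  restraint is satisfied iff its observed distance lies in its own
  $[l, u]$ — no extra slack, matching the viability definition.

## The optimizer

`mvie_run()` evolves `n_units = 20` local search units, each a (1+1)-CMA-ES
in the normalised unit box: sample $y = m + \sigma A z$, accept if the
lexicographic comparison favours it (fewer boundary-violated constraints;
then smaller total boundary excess; then, among boundary-viable candidates,
the better objective; ties keep the incumbent), adapt the Cholesky factor by
a rank-one update with learning rate $2/(d^2+6)$ and the step size by the
1/5th-success rule (target success 2/11, damping $1 + d/2$). Every 10 local
generations a DE/rand/1/bin sweep (F = 0.7, CR = 0.9) recombines the unit
means; a replaced unit resets its covariance and step size. Viability
boundaries start at the worst initial violation of each constraint and
shrink as the pointwise minimum of (previous boundary, current worst
personal-best violation, a linear schedule that reaches zero halfway through
the budget). These internals are not prescribed anywhere authoritative at
this level of detail, so each default is frozen here and exposed through the
`control`/`optimizer` lists for reproducibility. Box handling is a
resample-clip hybrid (clip after 10 rejected resamples) so the evaluation
budget accounting stays exact. One master seed drives everything; each unit
owns an RNG stream derived from it by a fixed offset, making runs
bit-reproducible and independent of scheduling details.

Only candidates with zero violation of the *final* bounds (tolerance
$10^{-9}$) enter the archive; `best` is the archive's best by objective, or
the least-violating candidate flagged infeasible when the archive is empty
("no viable solutions" is an explicit, reportable outcome).

## Density maps

Maps are simulated by summing unit-weight isotropic Gaussians at Cα
positions with FWHM equal to the nominal resolution
($\sigma_k = \text{res}/(2\sqrt{2\ln 2})$), truncated spherically at
$3\sigma_k$, on a voxel-lattice-anchored grid padded by $3\sigma_k$ (default
voxel = resolution/3, e.g. 5 Å at 15 Å). The kernel of the original map
simulator behind this convention is not documented precisely; the FWHM
convention is the common one and is frozen here. Cross-correlation is the
Pearson correlation over voxels where either map exceeds $10^{-6}$ of its
maximum, so empty space cannot dominate. Rigid fitting is a deterministic
multistart Nelder-Mead over the 6 rigid dof (12 fixed starting orientations,
translation initialised by centre-of-mass alignment) rather than an
FFT-exhaustive search; self-fit and ground-truth-recovery tests demonstrate
its adequacy at desk scale. I/O covers MRC/CCP4 mode 2 and the SITUS ASCII
dialect.

**Ranking uses Laplacian filtering by default.** Cluster centroids are
scored on 6-neighbour-Laplacian-filtered maps (`rank_mode = "laplace"`).
This is the standard contour-sharpening trick for low-resolution fitting,
and on desk-scale toys it is not optional: at 15 Å a plain ccc is so blobby
that models 8 Å from the truth can outscore sub-Ångström ones by refitting
into the torus of density, while the filtered score separates them cleanly.
The blind-dock *objective* stays a plain ccc (the smoother landscape
searches better); filtering enters at the ranking stage.

## Protocols

* `protocol_diversity()` — restraints + energy as constraints, diversity as
  objective; archive clustered at 1 Å fixed-frame Cα RMSD
  (complete linkage — the only linkage that *guarantees* every cluster's
  pairwise diameter stays below the cut); centroids of the largest clusters
  ccc-ranked against the input map; top 5 returned.
* `protocol_energy_objective()` — minimise $E_{phys}$ subject to restraints.
* `protocol_ccc_objective()` — restraints + energy as constraints, ccc as
  objective; the assembly stays 4-parameter while a 6-dof re-fit every 1000
  evaluations refreshes the frame in which candidates are scored.
* `protocol_blind_dock()` — no restraints: 10 parameters
  ($[\alpha,\beta,\gamma,x]$ + a global pose around the map centre),
  $E_{phys}<0$ the sole constraint, ccc the objective, default budget
  100,000 (desk-scale experiments here use 20,000). Models are already
  posed in the map frame, so ranking scores them without refitting.
* `protocol_crosslink()` — homodimer mode: an anchor interval on the Cβ
  distance of the most crosslinked residue (supplied explicitly in the
  config — no silent default) plus $E_{phys}<0$; $|R|$ maximised.
* `protocol_audit()` — mixtures of labelled true/false restraints are all
  imposed as viability constraints at their stated intervals. Because a
  genuinely wrong restraint can contradict the true set geometrically,
  strict viability may be unreachable; the search units then converge to
  least-violating models — exactly the "satisfy as many restraints as
  possible" behaviour the lexicographic comparison encodes — and the
  selection pool is the final unit personal bests plus any fully viable
  archive. The pool is deduplicated by 1 Å clustering (so PPV averages over
  distinct structures, not over how many units found the same one), the
  models satisfying the most restraints are kept (ties: all kept) and their
  precision is averaged. An earlier interval-relaxation design (widen all
  intervals until viable models appear, then count at zero relaxation) was
  measured to be worse: a relaxed-feasible archive can concentrate in a
  basin that satisfies only the wrong restraints.

Cluster-frame choice: candidates are clustered on *fixed-frame* RMSD
because all assemblies share one canonical symmetry frame (axis z, first
copy on +x); superposition would merge genuinely different radii and
orientations. Comparison to a reference uses optimal superposition minimised
over the n cyclic chain relabelings (`compare_to_reference()`), since a Cn
ring is defined only up to a cyclic relabeling; reflections are not
minimised over by default.

Rotations are intrinsic ZYZ about the subunit's Cα centroid, applied before
the radial translation; internal angles are radians. Any fixed convention
spans SO(3), so this choice affects reproducibility, not correctness.

## The synthetic fixtures

`make_toy_subunit()` provides two geometries: an ideal α-helix (rise 1.5 Å,
100°/residue, radius 2.3 Å — consecutive Cα ≈ 3.8 Å) and a compact
self-avoiding cluster (3.8 Å steps, minimum pairwise separation 3.8 Å), both
with pseudo-Cβ atoms 1.5 Å radially outward. `make_reference_assembly()`
draws a random orientation and line-searches the smallest radius giving
contact without clash ($E_{phys}<0$, minimum inter-copy Cα distance ≥ 3 Å).
True restraints are sampled from cross-interface Cα pairs under 8 Å at their
true distances ± 2 Å; wrong restraints claim a plausible contact (6 ± 2 Å)
for pairs actually ≥ 13 Å apart, so no correct geometry can satisfy them.
Crosslink profiles follow a decreasing logistic of the inter-subunit Cβ
distance (midpoint 12 Å, scale 3 Å) with Gaussian noise (default sd 0.05,
a realistic precision for fractional crosslinking estimates), clamped to
[0, 1].

Fixture geometry is chosen per experiment for an identifiability reason
worth stating: restraint-driven recovery uses the helix (restraints pin the
orientation, and the elongated shape is a good analogue of an interfacial
helix), while density-driven blind docking uses the compact random blob.
A straight helical rod at 15 Å resolution is nearly invariant to rolling
about and flipping along its own axis, so a map alone cannot resolve those
degrees of freedom for it — wrong-orientation rings scores within 0.002 of
the truth. That is a genuine property of featureless shapes at low
resolution, not of the optimizer; an asymmetric blob (like a real protein
domain) does not have the degeneracy. The crosslink experiment profiles the
16 residues nearest the interface, mirroring a disulfide scan of an
interfacial helix.

What the fixtures do *not* emulate: side-chain packing and sequence-specific
interactions (the subunits are Cα/Cβ traces scored by one generic LJ pair
potential), experimental map noise and anisotropy (simulated maps are
noise-free), restraint ambiguity from conformational heterogeneity, and
subunit flexibility (everything is rigid-body, as in the method itself).
Passing the recovery tests therefore demonstrates the search and scoring
machinery, not performance on real heterogeneous data.

## Study conditions used by the test suite

The end-to-end experiments (in `tests/testthat/test-acceptance.R`) run at
the conditions the protocols are built around: 3 restraints ± 2 Å, 15 Å
maps, budget 10,000 for restraint-driven recovery (5 seeds, top-ranked
centroid within 2 Å in ≥ 4); blind docking at budget 20,000 over 5 seeds
(best run within 2.5 Å); audits with mixtures of 3-5 true and 1-4 wrong
restraints (wrong never outnumbering correct) at budget 10,000 over 5
trials; crosslink recovery at budget 5,000 (|R| ≥ 0.9, interface within
2 Å). `scripts/acceptance.R` re-runs the
blind-docking experiment from scratch and reports the best RMSD as JSON.
The optimizer oracle check compares mViE's constrained optima against a
$10^6$-point grid enumeration on 2-D toys.

## Known limitations

* Cyclic symmetry only; no dihedral/helical/icosahedral groups, no
  hetero-oligomers, no flexibility.
* The multistart map fitter is local; for very large maps or far-off
  initial placements an exhaustive FFT search would be more robust.
* The coarse LJ potential rewards dense packing; its minima need not be
  native, which is why it serves as a *constraint* (clash-free contact)
  rather than the primary objective in the viability modes.
* Wrong-restraint discrimination degrades at desk scale. On a 20-residue
  toy, the feasible manifold left by 3-4 true restraints at ±2 Å is wide
  enough that structurally distinct models can satisfy all true restraints
  *plus* one wrong restraint (or trade one true for one wrong at equal
  count), so audit precision averages ~0.83-0.88 rather than approaching 1
  for the thinner mixtures; with 5 true restraints pinning the geometry,
  precision reaches 0.92-0.99. On large complexes, where a wrong surface
  pair is tens of Ångström off and the true restraints leave little slack,
  the discrimination is much sharper — the toy understates it. The
  lexicographic comparison even *prefers* a model violating one true
  restraint slightly over one violating a wrong restraint grossly (both
  violate one constraint; the smaller excess wins), an inherent cost of
  treating all restraints impartially before truth labels are known.
* `protocol_crosslink()` maximises $|R|$; with noisy profiles the $|R|$
  optimum can sit a couple of Ångström from the true interface — the
  correlation objective is informative but shallow near its maximum.
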