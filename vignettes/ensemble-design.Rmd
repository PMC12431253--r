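---
title: "Ensemble-based ranking of enzyme point mutations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble-based ranking of enzyme point mutations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ensdesign)
```

## The design protocol

`ensdesign` implements an ensemble-based computational filter for prioritizing
point mutations in a serine hydrolase. The chain of reasoning is: a reaction's
rate is governed by the energy gap between the enzyme–substrate ground state
(ES, the substrate docked non-covalently) and the tetrahedral intermediate
(ES\*, the serine O&gamma; covalently attached to the substrate's carbonyl
carbon, taken as a transition-state proxy). A mutation that lowers that gap
relative to wild type is predicted to accelerate the reaction. Because a
single minimized structure is a fragile basis for such a prediction, the
protocol evaluates every mutation over a *conformational ensemble* and ranks
by a robust summary statistic.

Concretely, for each variant $v$ and ensemble frame $i$:

$$\Delta E_{v,i} = E_{v,i}(\mathrm{ES}^{*}) - E_{v,i}(\mathrm{ES}),$$

both states energy-minimized from frame $i$. Frames correspond one-to-one
between a mutant ensemble and the wild-type ensemble (the mutant frame is the
wild-type frame with the side chain rebuilt), so the natural normalization is
per-frame:

$$\tilde{\Delta E}_v = \operatorname{median}_i
  \frac{\Delta E_{v,i}}{\Delta E_{\mathrm{WT},i}}.$$

The median, not the mean, is used so that an occasional badly minimized frame
cannot dominate the statistic. $\tilde{\Delta E}_v < 1$ predicts
transition-state stabilization. Candidates are then passed through three
strict filters — $\tilde{\Delta E}_v < 0.985$, PSSM conservation score
$> -4.0$ bits, and minimum heavy-atom distance to the substrate $< 5$ &Aring;
in the seed reactant complex — and survivors are ranked ascending by
$\tilde{\Delta E}_v$ (ties broken lexicographically by name, so ranking is
deterministic).

The normalization formula is not uniquely determined by the protocol
description; `normalize_median()` therefore implements the per-frame-ratio
default above and an alternate `median_of_medians` mode
($\operatorname{median}_i \Delta E_{v,i} / \operatorname{median}_i \Delta
E_{\mathrm{WT},i}$), records the mode in its result, and the stability
analysis can compare both — the choice itself perturbs rankings, which is part
of the phenomenon under study. A floor of $10^{-6}$ kcal/mol on
$|\Delta E_{\mathrm{WT},i}|$ guards the division; if no frame clears it the
statistic is reported as undefined rather than silently extrapolated.

## Conformer generation under distance bounds

Ensembles are generated in the spirit of distance-geometry samplers: from a
seed structure, `derive_bounds()` builds interval bounds on interatomic
distances and `generate_conformer()` samples structures satisfying all of
them. Bound classes and default tolerances (all configurable):

| class        | pairs                                   | tolerance (&Aring;) |
|--------------|-----------------------------------------|------|
| `bond12`     | covalently bonded                       | 0.05 |
| `angle13`    | second neighbours in the bond graph     | 0.10 |
| `dihedral14` | third neighbours                        | 0.30 |
| `contact`    | heavy-atom pairs within 6.0 &Aring;     | 0.50 |
| `anchor`     | all pairs inside the anchored atom set  | 0.05 |

The tight/loose hierarchy mirrors the covalent-versus-contact structure of
established distance-bound samplers; the exact values are a package choice
since the upstream tooling does not publish its internals. Covalent bonds are
detected from the seed geometry (1.25 times the sum of covalent radii).

The *anchor* class is the scientifically load-bearing one: all heavy-atom
pairs among the catalytic-triad side chains plus the bound substrate are held
within &plusmn;0.05 &Aring; of the seed, so every conformer keeps the
transition-state-competent active-site geometry of the seed while the rest of
the protein samples variability. Whether the substrate atoms belong in the
anchored set is an assumption (the protocol description only anchors "the
catalytic triad"); we include them by default and expose the residue list in
the config.

Sampling is a random isotropic Gaussian perturbation (default
$\sigma = 0.8$ &Aring; per axis) followed by sequential pairwise projection
sweeps (each violated bound moves its two atoms symmetrically onto the nearest
bound face; bound order is reshuffled every sweep) until the worst violation
is below half the satisfaction tolerance (default tolerance 0.01 &Aring;) or a
sweep cap (5000) is reached. Projection from a random start occasionally
lands in a locally infeasible basin even though the bound set is satisfiable
by construction; a stuck run is restarted with a fresh perturbation whose
amplitude shrinks geometrically (factor 0.85, up to 8 attempts). All draws
derive deterministically from the caller's seed, so a given
(seed structure, config, seed) triple reproduces the ensemble bitwise.
Chirality and planarity are *not* restrained beyond what the distance bounds
imply — a documented simplification of the distance-only model.

`build_design_ensemble()` assembles the protocol's working object: the
unmodified seed as member 1 plus (by default) 95 generated conformers, 96
members in total.

## Mutations

`apply_mutation()` rebuilds side chains from ideal-geometry internal
coordinate templates with &chi; angles searched on a coarse grid
({&minus;60&deg;, 60&deg;, 180&deg;} per rotatable bond) and the combination
minimizing a steric clash count (heavy-atom pairs closer than 0.8 &times; the
sum of Bondi van der Waals radii against everything outside the residue and
its chain neighbours) selected; ties resolve to the first grid point, so the
result is deterministic. This is a deliberately lower-fidelity stand-in for a
rotamer-library packer: backbone atoms are never touched, rings are placed
with fixed planar internal coordinates, the proline ring is not closed back
to the backbone nitrogen, and no backbone-dependent rotamer statistics are
used. When no rotamer clears the clash threshold the structure is returned
with a warning flag rather than silently.

## The energy model

The published protocol minimizes with a molecular-dynamics force field in
implicit solvent. That is out of reach for a dependency-free desk-scale
package, and — more importantly — the protocol's own conclusion is that
mutation rankings are sensitive to the parameterization. The energy model
here is therefore deliberately *swappable* (an `energy_spec()` value):

* Lennard-Jones (r<sub>min</sub>/&epsilon; per element, Lorentz–Berthelot
  combination) plus Coulomb with a distance-dependent dielectric
  $\varepsilon(r) = 4r$ (Coulomb constant 332.0636 kcal&middot;&Aring;/mol/e²,
  constant-dielectric mode available), over all pairs except 1-2 and 1-3;
* harmonic terms for covalent bonds and for 1-3 distances (a Urey–Bradley
  form was chosen over explicit angle terms so that every bonded interaction
  is a pair term with one gradient kernel); reference distances default to
  the evaluated structure's own build-time geometry, i.e. a
  structure-restrained relaxation;
* partial charges from a small per-atom-name template table (backbone
  amide-carbonyl charges, generic polar side-chain values, substrate charges
  supplied by the template and swappable as a "substrate parameterization");
* in the ES\* state, a harmonic restraint between the serine O&gamma; and the
  substrate carbonyl carbon at 1.9 &Aring; (the ester-addition
  transition-state bond length; 1.93 &Aring; applies to the later steps and
  is configurable), with the restrained pair excluded from the nonbonded list
  because it is a forming covalent bond.

Fidelity target: *ordinal* behaviour of rankings, not reproduction of any
force field's energies. Minimization is steepest descent with step halving on
energy increase (trace monotone non-increasing by construction), default
gradient tolerance 0.01 kcal/mol/&Aring; on the largest per-atom gradient,
cap 2000 iterations. Any atom pair closer than 0.1 &Aring; aborts with an
overlap error — that geometry is corrupt, not minimizable. Frames whose
minimization fails are excluded from the energy table *and recorded*; the
normalization then uses the shared surviving frames of mutant and wild type.

## Conservation and proximity filters

`compute_pssm()` builds a position-specific scoring matrix from an aligned
FASTA alignment: base-2 log-odds of pseudocount-smoothed column frequencies
against a background (uniform by default, pseudocount 1.0 scaled by the
background, gaps excluded from counts, no sequence weighting by default).
All-gap columns score from pseudocounts alone and are flagged. Because the
background, pseudocount and weighting of the original matrix are not
published, the &minus;4.0-bit threshold should be read as an ordinal cutoff;
all knobs are exposed so a user can calibrate against their own alignment.
The proximity filter measures the minimum heavy-atom distance between the
candidate residue and the substrate in the seed reactant complex.

## Rank stability

`rank_stability()` re-derives the full ranking under perturbed conditions —
different `energy_spec()` parameterizations and random frame subsets — and
summarizes agreement as the mean pairwise Spearman &rho; of rank vectors plus
the mean top-k overlap. The default subset size is 12 frames (an eighth of
the 96-frame design ensemble): small enough that subsets are nearly disjoint
and genuinely test frame sensitivity, large enough for a meaningful median.
Subsampling is without replacement and seeded per (condition, subsample), so
reports are reproducible. With planted per-variant effects spaced 1 kcal/mol
apart, frame noise of 0.1 kcal/mol leaves rankings essentially perfectly
stable while noise of 5 kcal/mol collapses the mean &rho; — the package's
synthetic reproduction of the qualitative finding that rankings are unstable
under re-parameterization and frame selection.

## Hydrogen-bond occupancy

`detect_hbond()` applies the standard geometric criteria (donor–acceptor
distance &le; 3.0 &Aring; and donor–hydrogen–acceptor angle &ge; 150&deg;,
both configurable; the protocol also scans 2.5–4.0 &Aring; via
`threshold_scan()`, under which distance-only occupancy is provably monotone).
Four canonical bonds ship as `canonical_hbonds()`: the substrate carbonyl
oxygen to the two oxyanion-hole backbone amines, the catalytic serine
hydroxyl to the histidine imidazole nitrogen, and the histidine pyrrole
nitrogen to the aspartate carboxylate. `hbond_occupancy()` reports per-bond
formation frequencies and the simultaneous all-bonds frequency (the
transition-state-analogue metric), which can never exceed any marginal.

Crystallographic and predicted structures usually lack hydrogens. When the
donor is a backbone nitrogen an idealized amide hydrogen is placed from the
N/C&alpha;/previous-C frame; otherwise detection falls back to distance-only
(both behaviours selectable). `activity_association()` relates occupancy to
measured relative activity: Spearman &rho; with average-rank ties and a
seeded permutation p-value (zero-variance series report &rho; = 0 with a
degeneracy flag rather than NaN), a rank-sum test between active and inactive
variants (inactive defined as activity exactly 0, matching the packaged
activity table's convention), and Benjamini–Hochberg adjusted p-values
alongside the raw ones. Replicate frame sets are pooled by default; feed
replicates separately to average instead.

## What the synthetic generators emulate — and what they do not

Every input the pipeline needs can be generated with known ground truth:

* `make_toy_enzyme()` — an ideal-geometry helix–loop–helix poly-alanine fold
  with a designated Ser/His/Asp triad and a 6-atom ester-like substrate
  docked at the serine hydroxyl (carbonyl carbon at 2.9 &Aring;). It is a
  *scaffold*, not a protein: no packing core, no realistic loop geometry, no
  hydrogens.
* `make_flex_ensemble()` — rigid per-residue isotropic Gaussian displacement
  with set &sigma;, so the expected RMSF is &sigma;&radic;3 exactly; real
  ensembles have correlated, anisotropic motions.
* `plant_variant_effects()` — wild-type per-frame energy gaps from
  Normal(10, 1) kcal/mol (positive, barrier-like, keeping ratio
  normalization well-defined) plus per-variant offsets &delta; and
  Normal(0, &sigma;) frame noise; offsets on the &plusmn;2 kcal/mol scale of
  plausible transition-state stabilization.
* `make_hbond_frames()` — per-frame Bernoulli placement of each bond in
  satisfying (2.8 &Aring;/165&deg;) or violating (4.5 &Aring;) geometry,
  independently or jointly.
* `make_msa()` — per-column consensus probability equal to the stated
  conservation, non-consensus residues uniform over the other 19 (so
  conservation 0.05 reproduces the uniform background exactly).

Passing tests on these generators demonstrates that the *machinery* —
bound satisfaction, RMSF/RMSD algebra, normalization, filters, occupancy
counting, association statistics — is correct and that planted signals of
stated size are recovered. It does not demonstrate predictive validity on
real enzymes; the stability analysis exists precisely because the underlying
ranking is fragile.

## Numerical choices and degenerate inputs

* Coordinates are &Aring;ngstr&ouml;m throughout; residue numbering is
  1-based exactly as in the PDB records, never re-indexed.
* Alternate locations: highest occupancy wins, ties broken by altloc letter;
  duplicate atoms within a model and topology mismatches across models are
  hard errors.
* Superposition is Kabsch via SVD with reflection correction; selections
  with fewer than three pairs or collinear geometry are rejected rather than
  silently fit. RMSF is measured about the per-atom mean position after an
  optional fit of every member to member 1.
* All generator and subsampling randomness flows through one seed with named
  substreams, so independent stages never share or reorder draws.
* Problem sizes used by the shipped tests and the acceptance script — a
  20-residue toy, 96-member ensembles, 1000–2000-frame statistical checks,
  a 0.5&deg; exhaustive rotation grid on 4-point systems — were chosen so the
  whole suite runs in well under an hour on one core while keeping sampling
  errors a factor of several below the asserted tolerances.

## Known limitations

* The energy model is a simplified pairwise form; absolute energies are
  meaningless and only within-model comparisons are used.
* The rotamer stand-in has no library statistics; unusual side-chain
  environments may pack suboptimally (flagged via the clash warning).
* Distance-only conformer generation cannot preserve chirality by
  construction; with the default tight covalent/anchor tolerances inversions
  are not observed in practice, but the guarantee is only on distances.
* PSSM scores depend on alignment depth; shallow synthetic alignments make
  absent-residue scores saturate near the pseudocount floor.
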