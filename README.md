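# ensdesign

Ensemble-based ranking of enzyme point mutations, with the downstream
structural and hydrogen-bond analyses needed to interrogate the ranking.

## The problem

Serine hydrolases catalyze ester hydrolysis through a covalent tetrahedral
intermediate formed at the catalytic Ser–His–Asp triad. A mutation that
stabilizes that intermediate relative to the docked ground state should
accelerate the reaction. `ensdesign` implements a computational filter built
on that idea, for people who want to study the *method* — its machinery, its
statistics, and above all its stability — on fully controlled synthetic
systems:

1. **Ensemble**: from a seed structure, sample conformers under
   structure-derived distance bounds with the catalytic triad and substrate
   anchored to the seed geometry (`derive_bounds()`,
   `build_design_ensemble()`; the protocol default is 95 conformers plus the
   seed, 96 members).
2. **Mutate**: rebuild side chains on every frame from ideal-geometry rotamer
   templates with a deterministic clash-minimizing chi search
   (`apply_variant()`, `enumerate_singles()`, `enumerate_doubles()`).
3. **Score**: build the reactant complex ES and the tetrahedral-intermediate
   complex ES\* (Ser Oγ–carbonyl-C restrained at 1.9 Å) on each frame,
   minimize both with a swappable molecular-mechanics spec, and record the
   per-frame gap ΔE = E(ES\*) − E(ES) (`build_state()`, `minimize_state()`,
   `delta_e_ensemble()`).
4. **Rank**: the statistic is the wild-type-normalized median
   ΔẼ_v = median_i(ΔE_v,i / ΔE_WT,i); variants pass three strict filters —
   ΔẼ < 0.985, PSSM conservation > −4.0 bits, substrate distance < 5 Å — and
   are ranked ascending (`normalize_median()`, `compute_pssm()`,
   `apply_filters()`).
5. **Stress the ranking**: recompute it under different energy
   parameterizations and frame subsets and report Spearman ρ / top-k overlap
   (`rank_stability()`) — the package's reproduction of the finding that such
   rankings can be strongly condition-dependent.
6. **Resolution analyses**: per-residue RMSF, pairwise Cα and active-site
   backbone RMSD matrices, catalytic hydrogen-bond occupancy (the four
   canonical bonds plus the simultaneous "all-four" metric), threshold scans,
   and occupancy–activity association tests with a packaged variant-activity
   table (`rmsf_profile()`, `pairwise_rmsd_matrix()`, `hbond_occupancy()`,
   `activity_association()`).

Every input the pipeline needs can be generated with planted ground truth
(`make_toy_enzyme()`, `make_flex_ensemble()`, `plant_variant_effects()`,
`make_hbond_frames()`, `make_msa()`), so the whole chain is testable without
any external data.

## Worked example

Planted per-variant effects, recovered by the ranking statistic:

```r
library(ensdesign)
pl <- plant_variant_effects(c(WT = 0, V1 = -2, V2 = -1, V3 = 0, V4 = 1, V5 = 2),
                            noise_sigma = 0.1, n_frames = 96, rng_seed = 1)
sort(vapply(pl$variants, function(tb) as.numeric(normalize_median(tb, pl$wt)),
            numeric(1)))
#>     V1     V2     V3     V4     V5
#> 0.8003 0.9031 0.9994 1.1004 1.1985
```

The planted offsets (−2, −1, 0, +1, +2 kcal/mol on a ~10 kcal/mol wild-type
gap) come back in exactly the planted order, with ΔẼ < 1 flagging the
stabilizing variants. The same statistic under 12-frame subsampling is
perfectly stable at low frame noise and collapses at high noise:

```r
st <- function(noise) {
  p <- plant_variant_effects(c(WT = 0, V1 = -2, V2 = -1, V3 = 0, V4 = 1, V5 = 2),
                             noise_sigma = noise, n_frames = 96, rng_seed = 1)
  rank_stability(list(wt = p$wt, variants = p$variants),
                 n_subsamples = 20, subsample_frames = 12, rng_seed = 1)$mean_rho
}
c(low = st(0.1), high = st(5))
#>   low  high
#> 1.000 0.375
```

The full pipeline on a generated toy enzyme (20 residues, Ser/His/Asp triad,
docked ester fragment):

```r
rep <- run_design(list(rng_seed = 5, n_conformers = 8))
rep
#> RunReport (config e4e2e3cb , seed 5 )
#> ranked variants:
#>     name delta_e_norm pssm_score min_substrate_distance passes rank
#> A3G  A3G    0.9885983 -2.2934997               2.839843  FALSE    1
#> A5L  A5L    0.9914889 -1.3112017               4.908855  FALSE    2
#> A4V  A4V    1.0138687 -0.1512058               3.237440  FALSE    3
#> A8S  A8S    1.0568143 -0.3201348               4.849690  FALSE    4
#> rank stability: mean Spearman rho 0.907, mean top-3 overlap 1.000 over 10 instances
```

Here no variant clears the strict ΔẼ < 0.985 cutoff — the toy's alanine
substitutions are nearly wild-type-neutral, which is the expected answer —
and the stability block quantifies how much of the remaining ordering is
parameterization noise. A thin CLI over the same functions ships in
`inst/scripts/ensdesign-cli.R` (subcommands `simulate`, `generate-ensemble`,
`rank`, `hbonds`, `resolve`).

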