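# rdcens

Characterizing correlated inter-domain motions of multi-domain proteins
from backbone residual dipolar couplings (RDCs) measured under steric
alignment.

A protein that exchanges rapidly between inter-domain arrangements shows a
single averaged RDC per amide. Because steric alignment depends only on
molecular shape, each arrangement aligns differently, and the averaged
couplings carry information about the *distribution* of arrangements.
`rdcens` implements the full pipeline that turns that information into
state populations:

1. **Steric tensor prediction** — a planar-barrier excluded-orientation
   model computes the Saupe alignment tensor *S* (3×3, symmetric,
   traceless) of every conformer from its bead-model shape.
2. **RDC back-calculation** — `D = D_max · v̂ᵀ S v̂` per amide, averaged
   over ensemble members with per-conformer tensors, rescaled by the
   least-squares factor, and scored with the quality factor
   `Q = rms(D_calc − D_exp) / rms(D_exp)`.
3. **Ensemble selection** — a genetic algorithm searches a large conformer
   pool for the minimal multiset of conformers whose averaged couplings fit
   the data; ensemble size is chosen by free-RDC cross-validation
   (Q_work / Q_free over random 20% holdouts).
4. **Analysis** — 2-D distributions over the two inter-domain opening
   angles (θ_AMPbd, θ_LID), rectangular-basin populations with
   noise-replica uncertainties, and FRET-style distance projections.
5. **Validation** — RDC scrambling, synthetic box-target reconstruction,
   tensor-magnitude-error robustness, and two-state population-recovery
   sweeps.

The package is tidyverse-native: RDC sets, angle tables, traces and
distributions are tibbles; fitted objects have `tidy()`, `glance()` and
`autoplot()` methods. A built-in three-domain toy protein and a rigid-body
hinge pool generator make the entire pipeline runnable without any
external data; real structures and pools come in through ordinary
(multi-model) PDB files, couplings through plain-text tables
(`resid atom1 atom2 value_Hz sigma_Hz`).

## Worked example

Build the toy system, design a single-basin synthetic target, and ask the
genetic algorithm to reconstruct it from its (1% noise) couplings:

```r
library(rdcens)

toy  <- make_toy_structure()
pool <- generate_hinge_pool(toy$structure, toy$domains, toy$angle_def,
                            targets = default_angle_grid(20), rng_seed = 1)
pool <- precompute_pool_rdcs(pool)
pool
#> <conformer_pool> 400 conformers, 378 atoms each
#>   theta_AMPbd range: 28.7 - 90.9 deg; theta_LID range: 89.3 - 160.4 deg
#>   cached RDCs: 126 keys

target <- basin_set("box", 50, 65, 100, 115, population = 1)
synth  <- make_synthetic_rdcs(pool, target, noise_pct = 1, rng_seed = 1)

ga <- run_ga(pool, synth, 8, ga_config_scaled(rng_seed = 1))
glance(ga)
#>       n n_repeats q_work_best q_work_median
#>       8        20      0.0197        0.0215

basin_populations(build_distribution(ga, pool), target)
#>   label      fraction
#> 1 box           0.388
#> 2 unassigned    0.612
```

The best ensembles fit the synthetic couplings to Q ≈ 0.02 — the 1% noise
floor — and the selected members concentrate in and immediately around the
generating basin. (On the deliberately smooth toy system, near-degenerate
neighbours just outside the rectangle can substitute for in-box members;
see the vignette's *Limits* section for why, and for what does and does
not transfer to real data.) `autoplot(build_distribution(ga, pool))` draws
the recovered (θ_AMPbd, θ_LID) distribution.

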