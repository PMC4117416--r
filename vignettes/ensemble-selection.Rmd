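---
title: "Inter-domain ensembles from steric-alignment RDCs: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inter-domain ensembles from steric-alignment RDCs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdcens)
```

## The problem and the model

A multi-domain protein in fast exchange between inter-domain arrangements
produces a single set of backbone N–H residual dipolar couplings (RDCs)
that is the population-weighted average over the arrangements. Under
*steric* alignment (for example in a stretched polyacrylamide gel) the
degree and direction of alignment depend only on molecular shape, so every
arrangement carries its own alignment tensor, and the averaged couplings
encode the distribution of inter-domain orientations.

For a bonded pair P–Q the coupling is the Saupe contraction

$$D = D_\mathrm{max} \sum_{ij} S_{ij}\cos\varphi_i\cos\varphi_j
    = D_\mathrm{max}\, \hat v^{\,\top} S\, \hat v,$$

where $S$ is the 3×3 symmetric traceless alignment tensor expressed in the
molecular frame, $\hat v$ the inter-nuclear unit vector and $\varphi_i$ its
angle to molecular axis $i$. $D_\mathrm{max}$ is computed from
$\mu_0, h, \gamma_P, \gamma_Q$ and the bond length (1.02 Å for N–H; the
negative gyromagnetic ratio of ¹⁵N makes the N–H prefactor positive). Its
absolute magnitude never matters downstream: the ensemble-averaged
couplings are rescaled against experiment by the least-squares factor
$s^* = \sum D^\mathrm{calc} D^\mathrm{exp} / \sum (D^\mathrm{calc})^2$,
which also absorbs the unknown concentration of the alignment medium.
Agreement is scored with the quality factor
$Q = \mathrm{rms}(D^\mathrm{calc}-D^\mathrm{exp})/\mathrm{rms}(D^\mathrm{exp})$
(the Cornilescu normalization; not the variant normalized by the alignment
magnitude).

The exact printed forms of the coupling equation and of $Q$ vary across the
literature; this package adopts the standard Saupe-contraction and
rms-ratio forms stated above and documents that choice here once.

## Steric tensor prediction

`predict_tensor()` implements a planar-barrier excluded-orientation model:
the molecule, coarse-grained into beads (one 3.8 Å bead per Cα by default;
one 1.7 Å bead per heavy atom for accuracy checks), is placed between two
parallel obstructing planes a distance $L$ apart. For an orientation with
bead-model extent $h$ along the plane normal, the allowed fraction of
translational positions is $\max(0, 1-h/L)$; the Saupe tensor is the
allowed-fraction-weighted orientational average of
$(3\cos\varphi_i\cos\varphi_j-\delta_{ij})/2$. Elongated orientations are
excluded more often, which is exactly why the tensor reports on
inter-domain arrangement.

Numerical choices:

* The orientation average uses Gauss–Legendre nodes in $\cos\theta$ crossed
  with a uniform midpoint rule in $\phi$ (default resolution 10°, valid up
  to 30°). Gauss–Legendre integrates the degree-2 Saupe integrand exactly,
  so an isotropic shape yields a numerically zero tensor and rotation
  equivariance holds to a few percent at the default grid.
* Default barrier spacing is 4× the maximal molecular radius; halving the
  spacing strengthens alignment monotonically. Spacing so small that the
  molecule fits at no orientation is rejected as degenerate. Spacing and
  grid affect mainly the tensor scale, which the downstream rescaling
  absorbs.
* Per-conformer tensors and couplings are cached on the pool
  (`precompute_pool_rdcs()`), keyed by a hash of keys and configuration,
  because the genetic algorithm re-reads them millions of times.

A second, independent shape-based predictor reported to give equivalent
distributions is not published in algorithmic detail; the prediction step
is therefore a single implementation behind a small interface
(`predict_tensor(model, config)`) that an alternative predictor could
replace.

## The conformer pool and the toy system

The selection method needs a broad, evenly covering pool of inter-domain
arrangements, not a Boltzmann sample. `generate_hinge_pool()` therefore
replaces biased all-atom simulation with deterministic rigid-body hinge
rotations: each mobile domain is rotated about the axis through the centers
of mass of its two flanking hinge windows until the measured opening angle
hits its target within 2°, targets being a regular grid over
θ_AMPbd ∈ [30°, 90°] and θ_LID ∈ [90°, 160°] (the ranges sampled for
adenylate kinase) with 0.5° Gaussian jitter. The default 45×45 grid gives a
pool of about 2000 conformers. Conformers with inter-domain Cα–Cα contacts
under 3.0 Å are discarded and logged (pairs within six residues along the
chain are exempt — their proximity is covalent geometry, not a collision),
as are unreachable targets. Real pools from any simulation engine can be
imported as multi-model PDB files instead.

`make_toy_structure()` builds the synthetic study system: a Cα/N/H
three-domain protein (60-residue core split in three segments, a 30-residue
AMPbd-like hairpin, a 36-residue LID-like hairpin) whose two opening angles
are geometrically independent — the AMPbd analogue swings in one plane
about one side of the core, the LID analogue in a perpendicular plane about
the other side. Amide N–H directions follow a Fibonacci-sphere sequence so
that tensors are identifiable from the couplings. The "open" preset sits at
(80°, 150°), "closed" at (40°, 100°); their steric tensors differ by more
than 10% in the leading eigenvalue, which is the mechanism the whole method
exploits.

What the toy does *not* emulate: side chains, internal domain flexibility,
loop dynamics, and sequence-specific coupling patterns. Every conformer
differs from every other only through two rigid hinge angles. The
consequences for what passing tests show are discussed under *Limits*.

## Opening angles

`theta_ampbd()`/`theta_lid()` implement the center-of-mass angle
definitions over Cα windows (equal weights — all atoms are Cα). The
adenylate-kinase preset uses the published windows: θ_AMPbd from vertex
90–100 to hinge 115–125 and AMPbd 35–55; θ_LID from vertex 115–125 to CORE
179–185 and LID 125–153. The hinge window 115–125 and LID window 125–153
share residue 125 in the published definition; it is kept verbatim rather
than "corrected". Windows are fully configurable, which is how the toy maps
its own geometry onto the same operations.

## The genetic algorithm

`run_ga()` follows the published schedule. A population of ensembles
(multisets of pool indices, so repeated members can express unequal state
populations) evolves by, per step: one mutated copy per ensemble (with
probability equal to the mutation rate, one uniformly chosen member is
replaced by a uniform pool draw) and one crossed copy (randomly paired
ensembles swap one uniformly chosen member with probability equal to the
crossing rate), followed by truncation selection of the best third by
optimally-rescaled ensemble-averaged Q. The mutation rate starts at 100%
and is divided by 1.001 each step; the crossing rate starts at 2% and is
multiplied by 1.001; both are clamped to [0.001, 1] as a numerical
safeguard. Whether the published crossing operation exchanges one member or
a segment is not stated; the one-member swap is the simplest operator
consistent with the description and is what this package implements.
Selection keeps parents among the candidates, so the best Q never worsens
(asserted on traces). Ties in Q are resolved by the stable sort order of
candidate construction, making runs byte-reproducible under a seed.

Two presets matter:

* `ga_config()` — the published scale: 1000 ensembles, 1000 steps, 200
  repeats, sizes {1, 2, 4, 8, 16, 32, 64}.
* `ga_config_scaled()` — the desk scale used by this package's tests and
  validation runs: 200 ensembles, 300 steps, 20 repeats, sizes up to 32.
  On toy-scale problems the Q trace plateaus well within the 300 steps
  (change below 1% over the final 100 steps).

Ensemble size is chosen by free-RDC cross-validation
(`select_ensemble_size()`): random 20% holdout sets, a single GA run per
(set, run) on the working couplings, Q_free scored on the withheld ones
with the scale fitted on the working set. The adequate size N\* is the
smallest N whose median Q_free lies within 5% (configurable) of the minimum
median over all sizes. The published protocol uses 10 holdout sets × 20
runs; the desk-scale default here is 5 holdout sets with 8 runs each,
chosen once as this package's scaled preset — enough runs that per-size
Q_free medians are stable against run-to-run GA noise.

Experimental uncertainty is propagated by `propagate_rdc_error()`: repeated
GA runs on couplings perturbed with Gaussian noise of σ = 1.0 Hz — three
times the typical 0.3 Hz measurement error — and the scatter of basin
populations across replicas is the population uncertainty.

## Distributions, basins and projections

Selected ensembles pooled across repeats become a 2° 2-D histogram over
(θ_AMPbd, θ_LID) (`build_distribution()`; each member carries weight
1/(members × repeats)). Basin populations are rectangle sums
(`basin_populations()`), with defaults centred on the reported state
angles: closed-like [45°, 70°] × [95°, 120°] and open [65°, 85°] ×
[135°, 160°] — the published figures do not print the rectangle bounds, so
these are this package's documented choice. `fret_projection()` maps an
ensemble onto a Cα–Cα distance coordinate and reports the fraction beyond a
cutoff; donor/acceptor residues and the cutoff are deliberately
config-only, because the published estimates do not state them.

## Validation procedures

* **Scrambling** (`scramble_rdcs()`): permuting coupling values across
  keys preserves their marginal statistics but destroys the structural
  signal; the GA must fail (best Q > 0.9 at protein scale) — evidence that
  a good fit is encoded in the data, not in pool composition.
* **Synthetic targets** (`make_synthetic_rdcs()`): couplings from designed
  box distributions (uniform within each box — the intra-box weighting is
  not stated in the source and uniform is the neutral choice), with
  Gaussian noise expressed as a percentage of the maximum coupling (the
  reported ladder is 1/3/6%).
* **Tensor-magnitude error** (`tensor_error_scales()`): each conformer's
  couplings are multiplied by `fold^d`, with `d` the normalized Euclidean
  distance from the centre of the pool's angle ranges (0 at the centre, 1
  at the farthest conformer). "Along the reaction coordinate" is
  interpreted as this radial coordinate in normalized angle space; scaling
  couplings is equivalent to scaling tensor magnitudes because the
  coupling is linear in the tensor. The reported fold ladder is
  {2, 3, 10, 20, 50}.
* **Population-recovery sweep** (`population_recovery_sweep()`): two-state
  targets with closed population swept 0–100%, reconstructed at each
  tensor-error fold. Synthetic couplings are noise-free here because the
  control isolates tensor error. The fitted closed population is read out
  as a two-state classification — each selected member is assigned to the
  nearer basin (inside a rectangle wins) — because the rectangles generate
  the data but are not classification boundaries, and in a two-state
  system every member belongs to one state. The desk-scale default is 5%
  steps with 5 pooled runs per point (the published control used 1% steps
  and 100 runs per error level).

## Problem sizes used by tests and the acceptance script

The packaged runs use the toy system with a 45×45-target pool
(≈ 2000 conformers, 126 N–H couplings), the scaled GA preset, 5 × 8
size-selection effort, ensemble sizes up to 32, 5 scramble seeds, and
sweeps at 5% steps. These sizes are the package's desk-scale study
conditions; the `paper` preset retains the published scale for users with
real pools and data.

## Limits: what desk-scale agreement does and does not show

The toy system is *more* degenerate than a real protein pool. Its
conformers differ only through two rigid hinge angles, so couplings vary
smoothly and slowly across angle space, and the coupling variance *within*
a 15° basin is small compared with a real all-atom pool, where side-chain
and backbone heterogeneity make every conformer's tensor and geometry more
individual. Two consequences are visible in the packaged runs and should
be expected by users of the toy:

* **Plateau sizes halve.** Fewer members suffice to reproduce a basin
  average within a 1% noise floor, so free-RDC selection plateaus at
  roughly half the published ensemble sizes (observed N\* of 2–4 for the
  unimodal control and 8 for the four-state control, against published
  values of 8 and 16). The selection *rule* is unchanged; the shift is a
  property of the smoother toy information content.
* **Near-degenerate neighbours leak.** Within the noise floor, members
  just outside a generating rectangle can substitute for members inside
  it, so strict rectangle counting under-reports recovered populations
  (the reason the sweep uses the two-state readout above, and why the
  sweep's zero-error maximum deviation settles near 0.07 rather than
  vanishing).

Neither effect weakens the core demonstrations, which do transfer: exact
analytic behaviour of the coupling/Q machinery, agreement of the steric
predictor with a brute-force Monte-Carlo oracle, GA equivalence to
exhaustive search, failure to fit scrambled data, and degradation of
population recovery with growing tensor error. Conclusions about *how
many* members a real data set needs, or *how sharply* populations are
recovered, must come from a real pool and real couplings via the `paper`
preset and the external-data workflow.

## A minimal worked run

```{r example, eval = FALSE}
toy <- make_toy_structure()
pool <- generate_hinge_pool(toy$structure, toy$domains, toy$angle_def,
                            targets = default_angle_grid(20), rng_seed = 1)
pool <- precompute_pool_rdcs(pool)

target <- basin_set("box", 50, 65, 100, 115, population = 1)
synth <- make_synthetic_rdcs(pool, target, noise_pct = 1, rng_seed = 1)

ga <- run_ga(pool, synth, 8, ga_config_scaled(rng_seed = 1))
glance(ga)
autoplot(build_distribution(ga, pool))
```
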