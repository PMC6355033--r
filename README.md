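# chromsm — Markov state models of chromatin organization from Hi-C maps

Binned Hi-C contact maps describe a chromosome as a weighted network of
locus–locus interactions. `chromsm` analyses that network as an energy
landscape: contact counts `f_ij` define pairwise contact energies
`E_ij = −ln f_ij`, and a probe particle performs a random walk with
Boltzmann flux `π_ij ∝ exp(−β E_ij)`, stationary weights
`μ_i = Σ_j π_ij` and transitions `p_ij = π_ij/μ_i`. Annealing (raising
the inverse temperature β) separates the walk's kinetic time scales, and
that separation is mined for structure:

* **Kinetics** — mean first-passage times `τ_ij`
  (`τ_ij = 1 + Σ_{k≠j} p_ik τ_kj`), recurrence times `τ_i = 1/μ_i`, and
  pairwise committors `Γ_ij = τ_i/(τ_ij + τ_ji)`.
* **Metastability** — a hub set `M` is scored by
  `ρ_M = max_{i∈M} max_{j∈M\{i}} Γ_ij / min_{i∉M} max_{j∈M} Γ_ij`, and
  Monte-Carlo optimization of `ρ_M` over hub sets of every size yields a
  profile whose qualified local minima are the chromosome's hierarchy
  levels.
* **Partitions** — committor probabilities `q_a(i)` around the optimal
  hubs define soft partitions, hard-assigned by `argmax_a q_a(i)`; these
  are the TAD/compartment-scale structural units.
* **Architecture** — effective interactions
  `F_ab = Σ_i q_a(i) π_ib` (exact, intra-chromosomal) or block sums
  `F_AB = Σ_{i∈A,j∈B} π_ij` (mean-field, genome-wide), interaction-layer
  classification, and the observed/expected affinity
  `C_AB = P(A∩B)/(P(A)P(B))`.
* **Epigenomics** — length-weighted signal densities per partition,
  weighted Z-scores, Giemsa-band eu/heterochromatin classes, and
  log–log enrichment-vs-interaction regressions.

It is aimed at computational epigenomics groups who want a
kinetics-based, largely parameter-free alternative to image-segmentation
TAD callers, plus a fully synthetic, ground-truthed toy chromosome for
method validation.

## Worked example: the hierarchical toy chromosome

The built-in generator produces a 500-locus chromosome with 18 nested
energy wells (2 arms × 3 mid-basins × 3 leaf wells; barriers 2, 1.25 and
0.5 energy units) and power-law contacts (`α = 1.5`):

```r
library(chromsm)
profile <- toy_profile(toy_spec())          # deterministic ground truth
model   <- toy_msm(profile, beta = 10)      # annealed MSM
kin     <- kinetics(model)                  # MFPT, MRT, committors
prof    <- rho_profile(model, gamma = kin$gamma, n_max = 50,
                       iters = 500, seed = 1)
levels  <- select_hierarchy(prof, keep_trivial = TRUE)
levels
#> <hierarchy_levels> 3 level(s): {2, 6, 18} (rho < 0.8)
```

The profile's qualified minima sit at hub-set sizes 2, 6 and 18 —
exactly the planted basin counts; the unqualified shallow wiggles are
rejected by the prominence rule (see the methods vignette). Partitions
at the middle level recover the six mid-basins:

```r
soft  <- committor_probabilities(model, levels$hubs[[2]])
parts <- hard_assign(soft)
parts
#> <hard_partition> 500 loci in 6 partitions
effective_flux_soft(soft, model)
#> <effective_interactions> 6 partitions (soft_intra), total F = 0.0409243
```

`partition_intervals(parts)` lists the genomic extents; agreement with
the ground-truth basin labels exceeds 99% of loci at every level (the
test suite asserts ≥ 95%).

For real data the same chain is one call:
`run_chromosome("chr17_50kb.txt", run_config(resolution = 50000))`
reads GEO-style triplet text, smooths (σ = 200 kbp, truncated at 4σ),
masks zero-coverage bins, picks the largest numerically stable integer
β, and writes profile/partition/interaction artifacts with a manifest.
A thin CLI wraps the same functions:
`inst/scripts/chromsm {toy|run|config}`.

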