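---
title: "Metastability analysis of chromatin contact networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metastability analysis of chromatin contact networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromsm)
```

# The model

Hi-C assigns every pair of genomic bins $(i, j)$ a contact count
$f_{ij}$. chromsm treats these counts as a *contact-energy landscape*,
$E_{ij} = -\ln f_{ij}$, and studies the discrete-time random walk of a
probe particle in that landscape. The walk is defined by a symmetric
Boltzmann flux,

$$\pi_{ij}(\beta) = \frac{e^{-\beta E_{ij}}}{Z(\beta)},\qquad
Z(\beta) = \sum_{(i,j),\, i \neq j} e^{-\beta E_{ij}},$$

with stationary weights $\mu_i = \sum_j \pi_{ij}$ and transition
probabilities $p_{ij} = \pi_{ij}/\mu_i$ ($p_{ii} = 0$). The sum in $Z$
runs over ordered off-diagonal pairs, so that $\sum_i \mu_i = 1$ exactly
and the mean recurrence time is exactly $1/\mu_i$ (Kac). Detailed
balance holds by construction because the flux is symmetric. The inverse
temperature $\beta$ is an annealing knob: at $\beta = 1$ all contacts
contribute and the walk mixes quickly; at high $\beta$ only the
strongest contacts carry flux and the walk becomes trapped in kinetic
basins, which is exactly the structure the method extracts.

Kinetics are summarized by three quantities, all in units of discrete
steps or probabilities:

* the mean first-passage time (MFPT) $\tau_{ij}$, solving
  $\tau_{ij} = 1 + \sum_{k \neq j} p_{ik}\tau_{kj}$;
* the mean recurrence time $\tau_i = 1 + \sum_{k \neq i} p_{ik}\tau_{ki}$;
* the pairwise committor $\Gamma_{ij} = \tau_i/(\tau_{ij} + \tau_{ji})$,
  the probability that a probe leaving $i$ hits $j$ before returning to
  $i$.

## Metastability index and hub-set optimization

A hub set $M$ is a small set of loci intended as attractors of the walk.
Its quality is the metastability index

$$\rho_M = \frac{\max_{i \in M}\max_{j \in M\setminus\{i\}} \Gamma_{ij}}
                {\min_{i \notin M}\max_{j \in M} \Gamma_{ij}},$$

small when hubs rarely reach one another before returning home
(numerator) while every other locus quickly reaches some hub
(denominator). Optimal hub sets of each size $n = 2..n_{\max}$ are found
by Metropolis Monte Carlo: the size-2 seed pairs the highest-$\mu$ locus
with the locus minimizing the pair index; each subsequent size grows the
previous optimum by the locus whose addition gives the lowest index,
then re-optimizes with two move types mixed 50/50 — replace a random hub
by its most reachable partner ($\arg\max_i \Gamma_{ai}$), or by a
uniformly random non-hub locus. Duplicate-producing moves are redrawn.
The profile $\rho_M(n)$ then exposes the hierarchy: its qualified local
minima are the natural levels.

Two optimization parameters are not dictated by the construction and are
package choices: the Metropolis temperature `t_mc = 0.05` (the index is
an $O(1)$ quantity, so 0.05 accepts only small uphill moves) and the
50/50 move mixing. Both are configurable; the optimizer's results on
chains small enough for exhaustive enumeration are checked in the test
suite (global optimum recovered in more than 99% of seeded runs).

## Hierarchy-level selection

A local minimum of $\rho_M(n)$ qualifies as a hierarchy level when its
index is below the operational threshold 0.8 *both* in absolute terms
*and* relative to the lower of its two flanking profile maxima
($\rho < 0.8\cdot\min(1, \text{flank})$). On real chromosomes the
profile baseline sits near 1 and the relative condition is vacuous, so
the rule reduces to the plain $\rho < 0.8$ cutoff with which the
per-chromosome hierarchies (e.g. sizes $\{5, 12, 27\}$-type ladders) are
selected. The relative condition matters on strongly idealized
landscapes such as the built-in toy chromosome: there an exhaustive hub
search also discovers *shallow* dips (e.g. $\rho \approx 0.5$ flanked by
$\approx 0.55$) between the true levels. These reflect alternative hub
placements of comparable quality — for example, hubs in the two outer
sub-basins of an arm, whose mutual passage crosses two mid-level
barriers while the worst non-hub locus crosses one, a pure
prefactor ratio of about $1/2$ at any $\beta$ — not a separated time
scale, and they are rejected by the prominence condition without any
additional parameter. Selected minima are then filtered by the doubling
rule $n_i \ge 2\, n_{i-1}$ (ascending, greedy), the trivial size-2 level
is dropped unless explicitly kept (on real chromosomes it only finds the
two arms; on the toy it is the genuine top split), and a per-chromosome
`skip_first` override reproduces the convention used for the largest
chromosomes, where the second-smallest minimum is taken as the first
level.

## Partitions, interactions, affinity

Given a hub set, the committor $q_a(i)$ (probability of reaching hub $a$
before any other hub) defines soft partitions; each locus is hard-assigned
to $\arg\max_a q_a(i)$, with ties to the genomically lower hub. Soft
effective interactions on one chromosome are
$F_{ab} = \sum_i q_a(i)\,\pi_{ib}$ (reported symmetrized; the raw matrix
is retained). Genome-wide, committors are never computed — the mean-field
block sum $F_{AB} = \sum_{i\in A}\sum_{j\in B} \pi_{ij}$ is used, which
conserves total flux exactly. Interaction strengths are ranked and cut
into layers (strongest 2000 pairs = scaffold, then percentile bands);
the affinity $C_{AB} = P(A\cap B)/(P(A)P(B))$ is the observed/expected
contact ratio with marginals defined over ordered distinct partition
pairs, which makes $\sum_A P(A) = 1$ exact. Note that with these
marginals, perfectly independent (product-structured) counts give
$C = K/(K-1)$-type values for $K$ equal partitions — indistinguishable
from 1 at genome granularity, and the two-partition closed form is
exactly $C = 2$.

## Partition-scheme comparison

The mutual information between two partition schemes of the same
chromosome is normalized as $2 I /(H_1 + H_2)$ by default, so identical
schemes score 1; the literal single-factor normalization (identical
schemes score 0.5) is retained as the `"paper"` variant but is
internally inconsistent with replicate similarities above 0.9, which is
why the symmetric form is the default. The random-boundary baseline
draws, per chromosome, uniformly random distinct internal boundaries for
the same partition counts and combines per-chromosome NMIs by a
locus-weighted mean; on the bundled synthetic 539-partition genome
scheme this gives $\approx 0.76$, consistent with the 0.77 baseline used
in the rescaled mutual information
$\mathrm{RMI} = (\mathrm{NMI} - 0.77)/0.23$. A genome-pooled NMI is
deliberately not the default: concatenating chromosomes inflates the
score (to $\approx 0.89$ here) because both schemes trivially agree on
chromosome identity.

# The toy chromosome generator

`toy_spec()`/`toy_profile()` build a deterministic 1D chromosome of
$N = 500$ loci whose intrinsic energies form nested basins: 2 arms split
by a barrier of 2 energy units, each arm into 3 mid-basins (barriers
1.25), each mid-basin into 3 leaf wells (barriers 0.5) — 18 leaf wells,
17 internal barriers. Loci are assigned to leaf wells in contiguous
equal blocks (remainder appended to the last well); well bottoms sit at
energy 0 and the profile interpolates half-cosines up to each barrier
top, so every internal boundary is a strict local maximum of prominence
at least the level's barrier height. The mid-level barrier height (1.25)
is the midpoint of the stated 0.5–2 range; only the basin counts
(2/6/18) and the barrier range are treated as ground truth. Nested-depth
variants (wells deepening toward each basin core) were evaluated and
rejected: they produce additional shallow profile dips and, beyond ~3
energy units of total relief, numerically singular first-passage systems
at $\beta = 10$.

Contacts follow the power-law polymer model: pair energies
$E_{ij} = (E_i + E_j)/2 + \alpha \ln(d_{ij}/d_0)$ with $\alpha = 1.5$
and $d_{ij} = |i - j|$, so the toy feeds the exact same MSM machinery as
real data (and `toy_contacts()` exports it in the sparse triplet format
the readers consume). What the toy emulates is the *hierarchical basin
structure* of a chromosome's energy landscape; what it does not emulate
is Hi-C noise (counts are noiseless), mappability gaps, centromeres,
replicate variability, or genuinely 3D contact geometry. Passing the toy
recovery tests therefore validates the kinetic machinery and the
optimization, not robustness to experimental noise.

The generator takes a `seed` argument only for interface uniformity —
it is fully deterministic; all stochasticity in the pipeline lives in
the Monte-Carlo optimizer, whose per-size streams are derived
deterministically from one seed.

# Numerical choices

* **MFPT**: one dense linear solve per target column over the
  non-target states; a solve is rejected (condition of class
  `chromsm_singular`) when it errors, produces non-finite or
  non-positive times, or leaves a relative residual above $10^{-6}$.
  `select_beta()` scans integer candidates (default 1..12) from the top
  and returns the largest that passes — the annealing schedule is "as
  cold as the numerics allow".
* **Underflow**: fluxes are built in log space with a max-shift before
  exponentiation; pairs with zero counts have infinite energy and carry
  exactly zero flux. A disconnected flux graph is an error on the
  per-chromosome path and allowed on the genome mean-field path.
* **Committors**: the interior system is factored once and shared by all
  hubs (one solve with $|M|$ right-hand sides); rows sum to 1 by
  harmonicity, which the test suite asserts to $10^{-10}$.
* **Smoothing**: separable truncated-Gaussian convolution
  ($\sigma = 200$ kbp, truncated at $4\sigma$), zero padding without
  edge renormalization; $\sigma = 0$ is the identity. Smoothing operates
  on the full matrix including zeros.
* **Coordinates**: 0-based half-open bins; the diagonal of the count
  matrix is stored but excluded from the model and from $f_i$.
* **Ties**: hard assignment breaks committor ties toward the
  genomically lower hub; layer ranking breaks value ties by pair index;
  plateau minima of the profile take the smallest $n$.
* **Degenerate inputs**: all-zero matrices, single-partition schemes
  (zero entropy), zero-variance signal tracks and sub-3-pair regressions
  raise typed errors or flagged `NA` columns rather than silent output.

# Problem sizes used in validation

The bundled validation runs at desk scale: the full toy chromosome
(500 loci, hub sizes 2..50, 500 MC iterations per size, about 10 s),
a 120-locus two-level toy for end-to-end pipeline tests, chains of up to
20 states for oracle comparisons (simulation, exhaustive enumeration),
and 2000 random-boundary samples on the 539-partition synthetic genome
scheme. Full-genome Hi-C analyses (tens of thousands of loci) use the
same code paths; their published reference quantities are recorded in
`stretch_benchmarks()` and require the original contact-map downloads.

# Known limitations

* The MC optimizer guarantees no global optimality at genome scale; only
  the paper-scale scheme (greedy growth + 500 Metropolis iterations) is
  implemented, with no parallel tempering.
* The hierarchical-label nesting uses majority overlap and can be
  ambiguous when partitions are strongly non-contiguous.
* Matrix balancing (KR/ICE), `.hic`/`.cool` binary parsing, read
  mapping, spectral MSM analysis and 3D reconstruction are out of scope;
  inputs are plain-text triplet or dense matrices at a fixed resolution.
* The affinity marginals exclude intra-partition counts by definition,
  so intra-chromosomal affinities are systematically large and the
  measure is most informative between chromosomes.
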