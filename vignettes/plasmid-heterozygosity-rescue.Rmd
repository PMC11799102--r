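---
title: "Evolutionary rescue through heterozygosity on multicopy plasmids: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolutionary rescue through heterozygosity on multicopy plasmids: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmidrescue)
```

## The scenario

A bacterial population carries a plasmid at a fixed copy number $n$ per
cell. An environmental change (say, simultaneous exposure to two related
antibiotics) makes the resident plasmid allele insufficient: cells whose
plasmids all carry the same allele decline, while cells carrying *both*
alleles on different plasmid copies — plasmid-mediated heterozygotes —
can grow. A mutation converting one plasmid copy to the second allele can
rescue the population, but only if the two alleles are maintained
together in the same cell line against the randomizing force of plasmid
segregation at every division. This package computes, exactly where
possible and by simulation everywhere, the probability that such a rescue
succeeds, and the critical combinations of copy number and heterozygote
fitness below which it cannot.

## Cell types and fitness

A cell is classified by the number $i \in \{0, \dots, n\}$ of mutant
plasmid copies it carries. Cells die at rate $\mu_i = 1$ — this fixes the
unit of time to the mean cell lifespan, and `rescale_rates()` converts
times for any other death rate — and divide at rate
$\lambda_i = 1 + s(n, i)$, where $s(n, i)$ is the net growth rate
(Malthusian fitness). Two built-in fitness functions cover the cases of
interest:

* **dominant** (`dominant_fitness()`): every heterozygote
  ($0 < i < n$) has fitness $s_{\max} > 0$; both homozygotes have
  $s_{\min} < 0$. One copy of either allele confers its full effect.
* **peaked** (`peaked_fitness()`):
  $s(n,i) = s_{\max} - \tfrac{2(s_{\max}-s_{\min})}{n}\,|i - n/2|$,
  linear between a maximum at the balanced mixture and $s_{\min}$ at the
  homozygote endpoints. For odd $n$ the balanced point is a half-integer
  and no cell attains $s_{\max}$; the formula is evaluated exactly, with
  no rounding.

Arbitrary fitness tables are accepted (`fitness_model(kind = "custom")`)
subject to two validity rules that the rescue theory requires: both
homozygote fitnesses must be negative (otherwise the wild-type population
does not decline and the improper time integral behind the rescue
probability diverges), and every $s(n,i)$ must exceed $-1$ so that birth
rates are nonnegative. The second rule resolves a genuinely open corner:
nothing in the model bounds how negative a custom fitness may be, and we
chose to reject $s \le -1$ outright rather than silently truncate birth
rates at zero. `n = 1` is accepted as a well-defined model, but it has no
heterozygote class, so every establishment probability downstream is
defined as zero.

## Replication and segregation kernels

Before division the cell replicates its plasmids to $2n$ copies and
segregates $n$ into each daughter. `pair_kernel(n, mode)` computes the
distribution $P(i \to \{j, k\})$ over unordered daughter pairs under two
classical modes of copy-number control:

* **regular**: every copy is replicated exactly once, so the $2n$-pool
  holds $2i$ mutant copies and the daughter's count is hypergeometric;
  the pair is supported on $j + k = 2i$.
* **random**: templates are drawn uniformly with replacement-and-growth
  (a Pólya urn) until $2n$ copies exist, then segregated as above. The
  urn's rich-get-richer property makes unbalanced outcomes more likely,
  which is why this mode loses heterozygosity faster.

The urn pmf uses the binomial conventions $\binom{-1}{0} = 1$ and
$\binom{a}{b} = 0$ for $b < 0$ or $b > a \ge 0$; coefficients are
evaluated through `lchoose()` in log space, which keeps every kernel
probability accurate to well below $10^{-12}$ over the copy numbers of
practical interest — the test suite pins all kernels against exhaustive
labelled-copy enumeration and an independent urn dynamic program at this
tolerance. Kernels are cached per `(n, mode)`.

Under random replication a mutation arising *during* replication can
itself be re-replicated within the same cell cycle, so the mutant lineage
may start from several plasmids, possibly split across both daughters.
`conditional_single_mutation_pmf()` gives the law of the mutant copy
number after replication given exactly one mutation, and
`single_mutation_pair_pmf()` composes it with the segregation split to
give the lineage's launch state.

## Establishment: the branching-process fixed point

The fate of a rare mutant lineage is a continuous-time multitype
branching process; only the final outcome matters, so extinction
probabilities are computed in discrete generations. A type-$i$ cell
leaves no offspring with probability $1 - \rho_i$ and two offspring drawn
from the division kernel with probability
$\rho_i = \lambda_i / (\lambda_i + 1)$. The extinction probabilities
$Q_0, \dots, Q_n$ are the least fixed point of
$$f_i(z) = (1 - \rho_i) + \rho_i \sum_{\{j,k\}} P(i \to \{j,k\})\, z_j z_k ,$$
and the establishment probability is $1 - Q_1$ under regular replication
or $1 - \sum w(j,k)\, Q_j Q_k$ under random replication, with $w$ the
launch-state law above.

`extinction_probabilities()` reaches the least fixed point by iterating
from the zero vector, which is monotone and convergent but slows down
severely near criticality. The default solver therefore switches to
Newton's method on $z - f(z)$ after a warm-up: for monotone convex
systems of this form, Newton iterates started below the least fixed point
converge to it monotonically, and quadratically away from the critical
manifold. Numerical policies, all chosen once:

* sup-norm residual tolerance $10^{-12}$, iteration cap $10^5$
  (non-convergence is an error, with the residual reported);
* after the residual converges, Newton steps continue until the step
  itself falls below $10^{-13}$ — near criticality the fixed point is
  (almost) a double root and a residual criterion alone leaves an
  $O(\sqrt{\text{tol}})$ gap;
* the solver first applies the classical extinction criterion: with no
  final classes the process dies out almost surely if and only if the
  leading eigenvalue of the expected-progeny matrix $M$ is $\le 1$, in
  which case $Q = \mathbf 1$ exactly. This makes the threshold theorems
  exact statements rather than iteration-limited ones, including on the
  boundary itself, which is classified as non-establishment;
* reported probabilities are snapped: $Q_i > 1 - 10^{-9}$ to 1 and
  $P_{\text{est}} < 10^{-9}$ to 0, so threshold comparisons are stable.

`monte_carlo_establishment()` is the independent stochastic oracle: it
simulates lineages cell by cell and declares establishment when living
mutant-carrying cells reach 500 (the default), at which point the
heterozygote core is so supercritical that later extinction is
negligible; replicates that hit the event cap are flagged, never silently
counted.

## Rescue: the inhomogeneous Poisson closure

The declining wild-type population is treated deterministically,
$N(t) = N_0 e^{s(n,0)t}$. Each wild-type division carries a successful
mutation with probability $u n P_{\text{est}}$ (at most one mutation per
division), so successful mutations form an inhomogeneous Poisson process
with intensity $u n P_{\text{est}} \lambda_0 N(t)$ and
$$P_{\text{rescue}} = 1 - \exp\!\Big({-u n N_0 \tfrac{1 + s(n,0)}{|s(n,0)|} P_{\text{est}}}\Big).$$
The analytics depend on $u$ and $N_0$ only through their product, so
`rescue_setting()` accepts the product `uN0` directly; the rescue-time
distribution, its median (by root bracketing) and its mean (by adaptive
quadrature of the survival function) follow from the closed-form time
integral.

## Spectral structure and critical thresholds

In regular mode the expected-progeny matrix factors as $M = 2RP$ with $R$
the diagonal matrix of reproduction probabilities and $P$ the
hypergeometric segregation marginal, whose eigenvalues are
$\chi_i = 2^i \binom{n}{i} / \binom{2n}{i}$. The establishment threshold
(dominant fitness) is the point where the largest heterozygote eigenvalue
of $M$ crosses 1:

* regular replication: $s_{\max} > 2 / (2n - 3)$;
* random replication: $s_{\max} > 4n / (2n^2 - 3n - 1)$;

equivalently thresholds on $n$ (`critical_n()`), with the boundary itself
excluded. The rescued population's long-run growth rate is
$(1 + s_{\max})(2\chi - 1) - 1$ with $\chi = 2(n-1)/(2n-1)$ (regular) or
$(n-1)(2n+1)/((n+1)(2n-1))$ (random); this closed form is derived for the
dominant fitness function, and for peaked fitness only the numerical
eigenvalues are offered. `half_and_half_threshold()` exposes the weaker
threshold of the simplified comparison model in which every heterozygote
is treated as a balanced mixture.

`stationary_type_distribution()` returns the leading left eigenvector of
$M$, normalized — the long-run distribution of cell types among progeny,
defined only for supercritical models. One distinction matters when
validating against simulation: a *snapshot* of a continuous-time
population stabilizes at the leading left eigenvector of the rate matrix
$\Lambda(2P - I) - D$, which differs from $M$'s eigenvector by about a
percentage point at typical parameters (slow-dividing homozygotes
accumulate slightly more in continuous time). The simulation tests
therefore compare type frequencies against the rate-matrix eigenvector
and separately check that the two theoretical compositions agree closely.

## Cointegration

Plasmid fusion changes the segregation calculus: a multimer carries its
alleles as one molecule that can no longer be separated, but an $m$-mer
also counts $m$-fold against the copy-number control total. The
extension (`cointegration_config()` and friends) is deliberately minimal:
regular replication, dominant fitness, fusion only (no resolution), at
most one fusion per cell cycle, and the mutation arising in an
all-monomer cell.

Cell types are multisets of molecules, each molecule a multiset of
allele-bearing units summing to $n$ (`enumerate_cell_types()`; canonical
`(AA)(AB)(B)` notation via `format_cell_type()`). Fusion picks a uniform
unordered pair of molecules. Division duplicates every molecule and
splits the $2L$ labelled copies uniformly over all assortments giving
each daughter a unit total of exactly $n$. The uniform-over-labelled-
splits measure is a design choice — the model statement fixes only
"enumeration of the possible daughter pairs and the number of ways to
produce each" — and it is the choice under which all-monomer cells
reproduce the regular segregation kernel exactly, which the tests assert
as the decisive consistency check. The two copies of a duplicated
molecule assort freely; alternative measures (e.g. uniform over unordered
daughter multiset pairs) would change probabilities for mixed multimer
sizes. Fusion is composed before division within a cycle, which is
immaterial for selection since fitness depends only on the alleles
present.

The extinction system over the full type space reuses the same least-
fixed-point solver; with fusion probability $\kappa = 0$ it reduces to
the base model (asserted to $10^{-10}$), for any $\kappa > 0$ the
establishment threshold disappears, and $\kappa = \infty$ (immediate
fusion of all plasmids into one multimer) gives the ceiling
$s_{\max}/(1 + s_{\max})$. The state space grows combinatorially, so
enumeration is capped at $n \le 8$ by default; larger systems require an
explicit override.

## The Gillespie simulator

`simulate_trajectory()` is an exact direct-method implementation of the
continuous-time model — no tau-leaping — with per-type aggregated rates;
the inner loop is compiled. Wild-type cells form a pool; each mutation
founds a labelled lineage, so the first mutation whose descendants are
alive at the horizon is identifiable, enabling the comparison with the
conditional rescue-time law. Mutant-lineage daughters that segregate to
fully wild-type rejoin the pool (and may later mutate — consistent with
mutation arising only in fully wild-type cells; recurrent mutation inside
mutant-carrying cells is ignored, as in the analytics).

Defaults, chosen once as the package's study conditions: when only the
product $uN_0$ is given it is split as $N_0 = 1000$, $u = uN_0/1000$
(both overridable); horizon `t_max = 25` mean lifespans with a recording
grid of 0.5; event cap $2 \times 10^7$ per replicate, with capped
trajectories flagged as truncated. At these settings a rescued population
has typically grown to $10^4$–$10^6$ cells by the horizon, large enough
for survival classification and growth-rate estimation and comfortably
inside the cap. Validation experiments in the test suite use 120–200
replicates at $n = 4$, dominant fitness, $s_{\max} = 1$,
$s_{\min} = -0.1$, $uN_0 = 0.1$, and $10^5$ lineages per parameter point
for the establishment oracle; growth rates are fitted per replicate on
the last 40% of the grid, restricted to populations that are already
large ($\ge 1000$ cells) at the window start, where the asymptotic
growth law applies.

## What the simulations do and do not show

The simulator implements the same stochastic model the analytics
approximate, so agreement validates the derivations (the branching
factorization, the Poisson closure, the spectral growth rate) — it cannot
validate the model against real bacterial populations. Biological
features deliberately outside both: resource competition and carrying
capacity (the branching approximation assumes rarity), recurrent mutation
inside mutant lineages, standing variation present before the decline,
horizontal transfer and conjugation, gene-dosage dependence of
$s_{\max}$ on $n$ (representable implicitly through custom fitness
tables), cointegrate resolution, and fluctuating selection. Within the
model, all quantities are exact up to the stated numerical tolerances.

## A worked example

```{r example}
model <- fitness_model(4, "dominant", s_min = -0.1, s_max = 1.0)
establishment_regular(model)
establishment_random(model)
setting <- rescue_setting(model, "regular", uN0 = 0.1)
rescue_probability(setting)
mean_rescue_time(setting)
critical_s_max(4, "regular")
rescued_growth_rate(4, 1.0, "regular")
```
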