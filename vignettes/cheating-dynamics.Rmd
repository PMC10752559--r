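---
title: "Conservative and innovative cheating in mutualistic network dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conservative and innovative cheating in mutualistic network dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cheatnet)
```

## The model

`cheatnet` simulates bipartite plant–pollinator communities in which some
pollinators *cheat*: they extract nectar without pollinating. Two kinds of
cheating are distinguished. **Conservative** cheating happens between
partners that already interact mutualistically — it replaces a mutualistic
interaction with an exploitative one without changing who interacts with
whom. **Innovative** cheating happens with plants outside the cheater's
mutualistic niche (for instance a corolla too long for the bill, pierced at
its base), so it adds links the mutualistic network does not have.

A community starts from a binary backbone $IM$ ($n_P$ plants ×
$n_A$ pollinators). Four parameters control cheating: the proportion of
pollinator species cheating $\bar\Delta$, their cheating frequency
$\Omega$, the innovative proportion $\Psi$, and the per-interaction cost of
mutualism $\Lambda$. Given a binary cheater vector $\Delta$ the strength
matrices are

$$M_{ij} = IM_{ij}\,(1 - \Delta_j \Omega), \qquad
  C_{ij} = \Delta_j \Omega\,\big[(1-\Psi)\,IM_{ij} + \Psi\,(1 - IM_{ij})\big].$$

Abundances follow a generalized Lotka–Volterra system with saturating
functional responses. For plants,

$$\frac{dP_i}{dt} = P_i\left(r_{P_i}
 + \frac{(\alpha - \Lambda)\sum_j M_{ij}A_j}{1 + \beta\sum_j M_{ij}A_j + c\sum_k \Pi_{ik}P_k}
 - \frac{\Lambda \sum_j C_{ij}A_j}{1 + \beta\sum_j C_{ij}A_j + c\sum_k \Upsilon_{ik}P_k}
 - \sum_k cP_{ik} P_k\right),$$

and pollinators gain the benefit $\alpha$ from every interaction but pay
the mutualism cost only on legitimate ones:

$$\frac{dA_j}{dt} = A_j\left(r_{A_j}
 + \frac{\sum_i [\alpha(M_{ij}+C_{ij}) - \Lambda M_{ij}]\,P_i}
        {1 + \beta\sum_i (M_{ij}+C_{ij})P_i + c\sum_k \Theta_{jk}A_k}
 - \sum_k cA_{jk} A_k\right).$$

Both guilds are obligate mutualists: all basal growth rates are negative,
so any species without enough interaction benefit declines to extinction.
Cheating is therefore a double-edged sword — it drains service from plants
but can keep otherwise-doomed specialist pollinators in the community,
which feeds back as pollination for their host plants.

### Default parameters

| symbol | meaning | default |
|---|---|---|
| $\alpha$ | per-interaction benefit | 1.5 |
| $\beta$ | handling time (saturation) | 1 |
| $c$ | within-guild interference strength | 1 |
| $\Lambda$ | per-interaction mutualism cost | 0 / 0.15 / 0.3 |
| $r_{P}, r_{A}$ | basal growth rates (time⁻¹) | Beta-drawn in $[-0.5, -0.001]$ |
| $cP, cA$ | competition for space | intraspecific 1, interspecific 0 |
| initial abundance | all species | 1 |
| $\varphi$ | backbone connectance | 0.2 / 0.3 / 0.4 |
| $n_P + n_A$ | community size | 20 + 20 (10 + 10 variant) |

$\Lambda = 0.15$ and $0.3$ correspond to a cost of 10% and 20% of the
benefit ($\Lambda/\alpha$). The mutualism condition $\alpha > \Lambda$ is
enforced whenever a cheating configuration meets dynamics parameters.

## Design choices in under-specified corners

Several ingredients of the study design admit more than one reasonable
construction; the package makes these choices explicitly and treats them as
documented stand-ins.

**Backbone construction.** Each species gets one standard-normal
morphological trait; a link exists where plant and pollinator traits lie
within a distance $d$, with $d$ bisected so realized connectance is closest
to the target $\varphi$. Isolated species are reattached to their
nearest-trait partner, and traits are redrawn (≤ 50 times) if the realized
connectance misses $\varphi$ by more than 0.05. Trait-threshold rules of
this kind are the standard way to obtain nested networks from
one-dimensional niches.

**Growth rates.** Each community draws beta-distribution shape parameters
$a, b \sim U[0.5, 5]$ and maps Beta($a$, $b$) draws affinely onto
$[-0.5, -0.001]$. Re-drawing the shapes per community gives a wide variety
of growth-rate vectors — some communities harsh, some mild — rather than a
single fixed distribution.

**Similarity matrices.** Interference among plants uses the cosine
similarity of their legitimate strength rows ($\Pi$), the dilution of
cheating costs uses the cosine of the cheating rows ($\Upsilon$), and
interference among pollinators uses the cosine of their full interaction
columns ($\Theta$, from $M + C$). Cosine similarity is symmetric, lives in
$[0, 1]$, equals 1 for identical niches and 0 for disjoint ones — every
property the interference terms require. Using $M + C$ for $\Theta$
encodes the niche expansion of innovative cheaters: a specialist that
robs many new plants interferes with many more pollinators.

**Integration and stopping.** The system is integrated with a
stiff-capable adaptive solver (`deSolve::lsoda`, relative tolerance 1e-8)
and sampled at unit time steps; one "iteration" is one unit-time sample.
Integration stops when the variance of every species' trailing 10 samples
falls below 1e-14, or at 8,000 samples. Solver restarts happen on
geometrically growing chunks so long runs cost about one continuous solve
while the stopping rule is still evaluated at every sample. Abundances
dipping below 1e-9 are clamped to zero: extinction is absorbing in a
multiplicative model, and the clamp prevents resurrection by floating-point
noise.

**Stability and persistence.** At the stopping state the Jacobian of the
surviving-species subsystem (central differences, step
$10^{-6}\max(1,|x|)$) must have all eigenvalue real parts below 1e-8 for
the state to count as stable; total extinction under negative growth rates
is stable by inspection. Persistence is the percentage of species strictly
above 1e-5.

**Tie-breaking.** Cheater selection ranks pollinators by backbone degree
(fewest links first under the specialist scenario, most links first under
the generalist one) with ties broken by a seeded permutation, and the
number of cheaters is `round(delta_bar * n_A)` rounded half away from zero
so results do not depend on platform rounding.

## The sweep and its analyses

The full design crosses $\bar\Delta \in \{0.1,\dots,1\}$,
$\Omega, \Psi \in \{0,\dots,1\}$ (step 0.1) and
$\Lambda \in \{0, 0.15, 0.3\}$ — 3,630 combinations — with two cheater
scenarios, three connectance values and 500 community seeds: 10,890,000
simulations. `enumerate_grid()` reproduces these counts exactly;
`run_sweep()` executes any sub-grid. The *effect of cheating* is the
persistence difference against the matched no-cheating baseline: one
$\Omega = 0$ run per (seed, scenario, $\varphi$, $\Lambda$), shared across
all $(\bar\Delta, \Psi)$ because cheating parameters are inert at
$\Omega = 0$, and sharing the community seed so the difference isolates
cheating.

`variance_explained()` computes $1 - V_g/V$: the share of effect variance
captured by a grouping (typically parameter × scenario combination).
`residual_structure_model()` regresses the group-centered residual effects
on mean growth rates and backbone structure (connectance, NODF nestedness,
Barber modularity), centering nestedness and modularity within each
connectance class to break their correlation with connectance.

Structural metrics are implemented in the package: binary NODF (paired
overlap with strictly decreasing fill, averaged over row and column pairs)
and Barber bipartite modularity optimized by label propagation plus module
agglomeration, best-of-`restarts` with a fixed seed; an exhaustive
partition search is available for networks of up to 12 species and backs
the unit tests.

## Problem sizes used in the shipped experiments

The full 10.89-million-run sweep is a cluster-scale computation; the
package's own experiments are scaled-down designs chosen to keep every
result reproducible on a single workstation core:

- stability of the stopping rule: 1,000 simulations sampled uniformly from
  the full grid (20 + 20 species);
- favorable-window ceiling: specialist cheaters, $\Lambda = 0$,
  $\varphi = 0.4$, $\Psi \in \{0.8, 1\}$, $\Omega \in \{0.2,\dots,0.6\}$,
  $\bar\Delta \in \{0.1, 0.3, 0.5\}$, 50 shared community seeds;
- sign-pattern experiments (conservative windows, scenario contrast, cost
  gradient, 10 + 10 size variant, no-interference variant): 25–30 seeds on
  2–6 combination windows each.

At these sizes the Monte-Carlo error of a per-combination mean effect is
roughly half a percentage point, which is why the favorable-window ceiling
is compared with a tolerance of a couple of percentage points rather than
exactly. Because the backbone recipe, growth-rate hyperparameters and
similarity formulas above are stand-ins, the *magnitude* of the ceiling is
more uncertain than its sign and location: the scaled-down experiments
reproduce the qualitative geometry of the effect (where it is positive,
how it shrinks with cost, size and generalism) more faithfully than any
single headline number.

## The synthetic field dataset

`generate_field_dataset()` emulates a two-country camera-trap campaign:
17 sites along a 700–3,500 m elevation gradient, each sampling a regional
pool of plants (log-normal corolla lengths, mm; a curvature index) and
birds (log-normal bill lengths, mm). Traits and pairwise mutualistic
abilities are species(-pair) properties fixed at the pool level — sites
differ in which species are present and in sampling noise — so a bird's
pooled mutualistic niche is consistent across sites. A legitimate link is
feasible where the corolla is not longer than the bill can handle, thinned
to a target sparsity. Visit counts are negative-binomial (camera-trap
counts are overdispersed) around per-pair daily rates times sampling
hours, and converted to frequencies as `counts / hours * 24`
(interactions·day⁻¹).

Cheating in the generator follows the patterns the dynamic model predicts
to be stabilizing, so that the estimators have a known truth to recover:

- a share `psi_true` (default 0.9) of each cheater's illegitimate mass
  goes to plants *outside* the convex hull of its legitimate partners in
  (corolla length, curvature) space, weighted by squared distance from the
  hull — nectar robbing targets strongly mismatched flowers;
- cheating frequency follows a logit-linear model with negative slope on
  log partner diversity (specialists cheat more) and negative slope on
  standardized elevation (cheating declines uphill), as does the
  probability of being a cheater at all.

What the generator does **not** emulate: temporal (monthly) structure,
phylogenetic signal, observer error, plant abundance variation along the
gradient, or any feedback of cheating on abundances. Passing recovery
tests therefore show that the estimators are consistent for data shaped
like these mechanisms — not that real camera-trap data satisfy them.

## The estimators

Per site, the proportion of cheaters is the share of bird species with at
least one illegitimate record; the overall level of cheating (the
empirical analogue of $\bar\Delta \times \Omega$) is total illegitimate
frequency over total frequency. Per bird and site, the cheating frequency
is the same ratio restricted to the focal bird, and partner diversity
counts plants with at least one legitimate record.

The innovative proportion compares two weighted 2-D kernel densities over
(corolla length, curvature): the mutualistic niche (legitimate-frequency
weights) and the cheating space (illegitimate-frequency weights), pooled
over sites. Gaussian product kernels are evaluated on a shared 100 × 100
grid spanning the union of the points padded 10% per side; each density is
normalized to sum to one; the overlap (sum of cell-wise minima) is the
conservative proportion and one minus it the innovative proportion. Each
density gets its own per-dimension Silverman bandwidth
($0.9\,\sigma_w\,n_\mathrm{eff}^{-1/5}$, weighted SD and Kish effective
sample size): smoothing each niche at its own scale keeps well-separated
niches from being blurred into each other, which a pooled bandwidth would
do. The estimate is invariant to rescaling a bird's frequencies, and
plants with missing traits are dropped with a count attribute.

Trends are fitted by `glm_trend()`, an IRLS logit GLM with binomial totals
as weights and, under the quasibinomial family, a Pearson-dispersion-scaled
covariance; each term gets a Wald χ² test. The package deliberately fits
the *fixed-effects* analogue of the mixed model used for bird-level
trends: random site and bird intercepts are routine external statistics
(`lme4::glmer` fits them directly on the same table) and not part of the
bespoke computation here; the fixed-effects slope is what the recovery
tests check. `glm_trend` is implemented in the package precisely so that
`stats::glm` can serve as an independent cross-check in the test suite.

## Parameterizing the dynamics with field networks

`empirical_backbone()` converts a site network into the model's inputs:
$I_{ij}$ flags pairs that interacted mutualistically at least once,
$C_{ij}$ is the illegitimate share of each pair's frequency, and
$M_{ij} = I_{ij}(1 - C_{ij})$ is the legitimate ability. Pairs with only
illegitimate records keep $I = 0$ and feed the cheating matrix only (a
documented toggle excludes them). Frequencies enter only through these
proportions — abundance is a state variable of the model, not an input.

`effect_of_cheating()` runs the dynamics with and without the observed
cheating ($C = 0$, $M = I$) over a grid of 6 benefits × 5 costs × 2
interference strengths (60 combinations), sharing growth-rate vectors
between the paired runs. `randomize_cheating()` redraws cheater identities
and the conservative/innovative split while preserving the total cheating
mass exactly, and `zscore_pipeline()` compares observed persistence to the
null distribution on the logit scale (0 and 1 adjusted to 0.01 and 0.99),
clamping sign-definite infinite scores to ±5; the degenerate case of an
observation equal to every null value is defined as 0 rather than ±5,
since it carries no directional evidence.

## Known limitations

- The backbone, growth-rate and similarity recipes are explicit stand-ins
  (above); headline magnitudes inherit their uncertainty.
- The modularity optimizer is a heuristic; only networks ≤ 12 species can
  be verified exhaustively, and the reported $Q$ is a lower bound on the
  optimum in general.
- No evolutionary dynamics: $\bar\Delta, \Omega, \Psi$ are imposed, not
  evolved.
- Only pollinators cheat; plants never do.
- The field-data generator's elevational trend enters through the logit
  intercepts only; it does not reshape the species pool with elevation.
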