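---
title: "Modelling trioecy via cytoplasmic male sterility in androdioecious populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling trioecy via cytoplasmic male sterility in androdioecious populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triocms)
```

## The biological question

Trioecy — the stable coexistence of males, females and hermaphrodites — is
strikingly rare in plants, yet it occurs, for instance in Iberian
populations of the androdioecious annual *Mercurialis annua*, where male
sterility appears to be cytoplasmic. `triocms` implements a deterministic
population-genetic model asking when a cytoplasmic male sterility (CMS)
mutation can invade a population that already contains males, and when the
resulting three-phenotype polymorphism persists rather than collapsing to
gynodioecy, dioecy or extinction.

The model couples two polymorphisms:

* an **XY sex-determination locus** with disomic inheritance: `XY`
  individuals express a dominant female-sterility allele and are males;
  `XX` individuals are hermaphrodites;
* a **maternally transmitted cytotype**: normal (`n`) or CMS (`c`). CMS
  abolishes pollen production in `XX` carriers, turning them into females.
  The Y chromosome carries a (partial) fertility restorer, so `XY,c` males
  lose only a fraction `e_m` of their pollen.

Four genotypes therefore segregate — `XX,n` hermaphrodites, `XY,n` males,
`XX,c` females and `XY,c` CMS males — and the package tracks their
frequencies across non-overlapping generations.

## Parameters and phenotypes

All fecundities are expressed relative to a hermaphrodite, which produces
`G_h` ovules and `P_h` pollen grains (both 1 by default; see *Numerical
conventions*).

| parameter | meaning | range | default used in examples |
|-----------|---------|-------|--------------------------|
| `g`   | seed production of a female relative to a hermaphrodite | `>= 0` | 1.1 |
| `alpha` | pollen production of a male relative to a hermaphrodite | `>= 1` | 5 |
| `s`   | prior selfing rate of hermaphrodites | `[0, 1]` | 0.4 |
| `d`   | inbreeding depression of selfed zygotes | `[0, 1]` | 0.1 |
| `e_m` | fraction of a CMS male's pollen aborted | `[0, 1]` | 0.8 |

`g > 1` and `alpha > 1` reflect sex-allocation trade-offs: an individual
relieved of one sexual function reallocates to the other. `e_m = 0` means
the Y restores male fertility completely; `e_m = 1` means restoration works
in hermaphrodites only, so CMS males are sterile.

Three mating-system variants differ in how outcross fertilization responds
to the amount of pollen in the population (mean per-capita production
`P`, in units of `P_h`):

1. **Model 1** — no pollen limitation: every non-prior-selfed ovule is
   outcrossed.
2. **Model 2** — the probability of outcrossing is `min(1, P / P_h)`;
   unfertilized ovules abort, in females and hermaphrodites alike.
3. **Model 3** — as model 2, but hermaphrodites fertilize their
   unoutcrossed ovules by delayed selfing. Females cannot self, so their
   unfertilized ovules still abort.

Prior selfing (a fraction `s` of hermaphrodite ovules) happens regardless
of pollen availability and, like delayed selfing, incurs inbreeding
depression `d`.

## The one-generation map

Each generation, [gamete_pools()] aggregates pollen by genotype
(hermaphrodites `P_h`, males `alpha * P_h`, CMS males
`(1 - e_m) * alpha * P_h`, females 0), splits it into X- and Y-bearing
fractions `P_X` and `P_Y` (all hermaphrodite pollen plus half of male
pollen carries X), and sorts ovules into outcrossed (`O`), prior-selfed
(`S1`) and delayed-selfed (`S2`) classes. [step_generation()] then forms the
next generation in proportion to

```
f'_XXn : O_XXn * P_X + (S1 + S2)(1 - d)      f'_XXc : O_XXc * P_X
f'_XYn : O_XXn * P_Y                          f'_XYc : O_XXc * P_Y
```

normalized by the viable zygote total
`N_S = O_XXn + O_XXc + (S1 + S2)(1 - d)`. Two features of this map drive
everything else: the cytotype is strictly maternal (a `c` mother's sons
carry CMS but cannot transmit it — males are a *CMS sink*), and selfed seed
is always `XX,n` (selfing protects the normal cytotype).

```{r}
p <- cms_params(g = 1.1, alpha = 5, s = 0.4, d = 0.1, e_m = 0.8)
step_generation(population_state(0.8, 0.2), p)
```

## Closed-form thresholds

Invasion analysis of the map yields four thresholds, exported as plain
functions:

* males invade hermaphrodites iff `alpha > 2(1 - s d) / (1 - s)`
  ([male_invasion_alpha()]) — at `s = 0`, twice the siring success;
* CMS invades pure hermaphrodites iff `g > 1 - s d`
  ([cms_invasion_g_herm()]) — barely more seed than a hermaphrodite;
* CMS invades an *androdioecious* population iff
  `g > 1 - s + s(1 - d) / P_X0` ([cms_invasion_g_andro()]), where `P_X0`
  is the fraction of X-bearing pollen at the male/hermaphrodite equilibrium
  ([androdioecy_equilibrium()]). Since `0.5 <= P_X0 <= 1`, males make CMS
  invasion harder — the CMS-sink effect;
* with males present (model 1), CMS fixes iff `g >= 1 + s - 2 s d`
  ([cms_fixation_g()]), the invasion criterion at the dioecious limit
  `P_X0 = 0.5`.

The band between the last two thresholds is where trioecy is maintained by
negative frequency-dependent selection: more females beget more males
(females' sons are always male-sired), and more males throttle the spread
of CMS. The band exists only when hermaphrodites self (`s > 0`) and
closes as `d` approaches 1/2; `e_m` affects the equilibrium frequencies but
not the thresholds (except that `e_m = 1` removes the dioecious refuge
entirely and invasion implies extinction).

Under pollen limitation, fixation is additionally blocked below a bound
that grows as the dioecious end state gets more pollen-starved
([trioecy_upper_g()]): `g < 1 - s + 4 s (1 - d) / (alpha (1 - e_m))` in
model 2, and the wider `g < (1 - s)(2 d - 1) + 4 (1 - d) / (alpha (1 - e_m))`
in model 3, applicable whenever a dioecious population would be
pollen-limited (`alpha (1 - e_m) / 2 < 1`). The package treats
pollen-limited fixation as requiring the model-1 criterion *and* the
failure of this bound, and cross-checks that conjunction against direct
simulation (the exact combined expressions add nothing qualitative).

```{r}
threshold_report(cms_params(alpha = 5, s = 0.4, d = 0.1, e_m = 0.8, model = 2))
```

## Simulation protocol

[run_scenario()] reproduces the invasion protocols. In the `males_first`
order, `XY,n` males enter a pure hermaphroditic population at frequency
1e-6 and evolve to equilibrium; `XX,c` females then enter at 1e-6 and the
system is iterated again. The `females_first` order reverses this; when CMS
is destined to fix (which without males or pollen limitation means
population extinction), males are introduced as a rescue the moment the CMS
frequency reaches 0.99. Convergence is declared when no genotype frequency
changes by more than 1e-10 over 20 generations; [classify()] then labels
the outcome by which phenotypes exceed a presence threshold.

```{r}
run_scenario(p, "males_first")
```

Because the equilibrium is maintained by negative frequency-dependent
selection, both orders reach the same polymorphic state whenever no
phenotype has been irreversibly excluded.

[bisect_threshold()] turns this machinery into a numerical oracle: it
bisects any one parameter against a qualitative outcome predicate, which is
how the closed-form thresholds above are validated (agreement to 1e-4) in
the test suite. [invasion_verdict()] offers a third, independent route: a
central-difference Jacobian of the map at a boundary equilibrium
([jacobian_at()]), with the spectral radius of the invading genotypes'
block deciding invasion. Because the recursion is a discrete-time map, the
criterion is leading modulus greater versus less than 1 (not the sign of
real parts, which applies to continuous-time flows).

## Numerical conventions

These choices are deliberate and tested; changing them changes only
numerics, not biology.

* **Ratio scale.** `G_h = P_h = 1` by default. The map is invariant under
  joint rescaling of both (a property test asserts this), so only the
  ratios `g`, `alpha`, `e_m`, `s`, `d` matter.
* **Zero-pollen convention.** A population with no pollen producers
  outcrosses nothing in all three models; with no selfing seed either,
  `N_S = 0` and a `population_extinct` condition carrying the pre-step
  state is signalled. Model 1's "no pollen limitation" cannot conjure
  pollen that does not exist.
* **Prior selfing does not deplete the pollen pool.** A hermaphrodite's
  contribution to the outcross pool is independent of `s`; pollen is not a
  consumable budget.
* **Clamping.** Frequencies below 1e-15 after a step are set to 0 and the
  state renormalized, so equilibria are reproducible and denormal tails do
  not linger. A consequence worth knowing: a run whose true endpoint is the
  all-female boundary may satisfy the convergence criterion (changes
  < 1e-10 over 20 generations) with a hermaphrodite remnant around 1e-11,
  i.e. just before the hard `N_S = 0` signal would fire. [classify()]
  labels such states `extinction` regardless, because no seed parent
  remains above the presence threshold.
* **Presence threshold `eps = 1e-4`** for classification: two orders of
  magnitude above the 1e-6 introduction frequency and six above the
  convergence tolerance. A test verifies the trioecious classification is
  unchanged for `eps` anywhere in `[1e-6, 1e-3]`.
* **Generation cap.** `max_gen` defaults to 2e6; hitting it yields
  `converged = FALSE` (and a label marked provisional) rather than an
  error, since sweeps must record near-threshold cells, not crash on them.
  The inner loop is compiled (Rcpp), so even cap-length runs take well
  under a second.
* **Rescue mechanics.** The 0.99-rescue introduces males exactly like any
  other introduction: the invader is set to 1e-6 and residents are rescaled
  proportionally, keeping the state on the simplex. If males still cannot
  establish, iteration simply continues and the run ends in extinction.
* **Jacobian probes** use central differences with `h = 1e-7` on the
  analytic (unclamped) form of the map, renormalizing each probe onto the
  simplex; boundary coordinates may go slightly negative during probing,
  which the rational map tolerates. Verdicts within 1e-3 of modulus 1 are
  reported `marginal` rather than forced to a side.
* **Boundary-vs-simulation conventions.** Threshold functions return the
  boundary value itself; on-the-boundary parameter sets are resolved by
  simulation, and strictness follows the inequalities above (fixation is
  weak, the others strict).
* The fraction of X-bearing pollen at the androdioecious equilibrium is
  always computed from its pollen-weighted definition,
  `(f_XXn + 0.5 alpha f_XYn) / (f_XXn + alpha f_XYn)`; algebraic
  "simplifications" of this ratio are easy to get wrong and are avoided.

## What the deterministic model does and does not show

All runs are fully deterministic — no seeds, bit-reproducible trajectories.
The model omits finite-population drift (an invasion that succeeds
deterministically can still be lost by chance when one mutant arrives),
overlapping generations, spatial pollen dispersal and metapopulation
colonization dynamics, paternal leakage of the cytoplasm, and systems with
multiple CMS cytotypes or unlinked nuclear restorers. Passing the test
suite therefore demonstrates the internal consistency of this
infinite-population recursion and its analytical thresholds, not the fate
of CMS in any finite or spatially structured population.

## Problem sizes used by the tests

The suite validates each closed form against bisection on full simulations
(14 random parameter draws per threshold, bisection tolerance 2e-5,
predicate runs of up to 3e5–5e5 generations) and against Jacobian verdicts
offset 0.02 either side of each boundary; the equilibrium-structure sweep
covers 2,700 parameter combinations. These sizes give threshold estimates
well inside the 1e-4 comparison tolerance while keeping the whole suite in
the tens of seconds on one core.

## Command-line use

A thin CLI over these functions ships with the package:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "triocms.R", package = "triocms"))') \
  threshold --s 0.4 --d 0.1 --alpha 5
```

Subcommands `simulate`, `scenario`, `threshold`, `stability` and `phase`
emit CSV (trajectories, stage summaries, phase tables) or labelled text;
`--config` reads the same YAML accepted by [load_config()].
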