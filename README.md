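# triocms

Deterministic population-genetic modelling of **trioecy via cytoplasmic
male sterility (CMS)**: when can a maternally transmitted male-sterility
mutation invade a plant population that already contains males, and when do
males, females and hermaphrodites then coexist?

The package is aimed at evolutionary biologists studying plant sexual
systems (androdioecy, gynodioecy, trioecy, dioecy) and the role of
cytonuclear conflict in transitions between combined and separate sexes —
the situation documented, for example, in androdioecious *Mercurialis
annua*, where females appear to be caused by CMS.

## The model

Four genotypes segregate, combining an XY sex-determination locus with a
maternally inherited cytotype (n = normal, c = CMS): hermaphrodites
(XX,n; `G_h` ovules, `P_h` pollen), males (XY,n; `αP_h` pollen), females
(XX,c; `gG_h` ovules, no pollen) and CMS males (XY,c; `(1−e_m)αP_h`
pollen — the Y carries a partial fertility restorer). Hermaphrodites
prior-self a fraction `s` of their ovules; selfed zygotes die with
probability `d`. Writing `O`, `S1`, `S2` for outcrossed, prior-selfed and
delayed-selfed fertilized ovules and `P_X`, `P_Y` for the X/Y pollen
shares, genotype frequencies follow the exact recursion

    f′_XXn ∝ O_XXn·P_X + (S1+S2)(1−d)     f′_XXc ∝ O_XXc·P_X
    f′_XYn ∝ O_XXn·P_Y                    f′_XYc ∝ O_XXc·P_Y

normalized by the viable zygote total `N_S`. Three mating-system variants
cover no pollen limitation (model 1), pollen-limited outcrossing
(probability `min(1, P/P_h)`) with abortion of unfertilized ovules
(model 2), and recovery of hermaphrodites' unfertilized ovules by delayed
selfing (model 3).

On top of the recursion the package provides:

* closed-form invasion/fixation thresholds — males invade iff
  `α > 2(1−sd)/(1−s)`; CMS invades hermaphrodites iff `g > 1−sd`, an
  androdioecious population iff `g > 1−s+s(1−d)/P⁰_X`, and fixes iff
  `g ≥ 1+s−2sd`; pollen-limited bounds on fixation for models 2–3;
* forward simulation to equilibrium (compiled inner loop), invasion-order
  scenarios with the 0.99-CMS male-rescue protocol, and sexual-system
  classification;
* numerical Jacobians and leading-eigenvalue invasion verdicts at boundary
  equilibria;
* bisection threshold-finding on full simulations, `(g, α)` phase sweeps
  with threshold-curve overlays, CSV/YAML I/O and a small CLI
  (`inst/cli/triocms.R`).

## Worked example

Moderate selfing (`s = 0.4`, `d = 0.1`), strong males (`α = 5`) whose CMS
copies lose 80% of pollen (`e_m = 0.8`), and females with 10% more seed
than hermaphrodites (`g = 1.1`), without pollen limitation:

```r
library(triocms)
p <- cms_params(g = 1.1, alpha = 5, s = 0.4, d = 0.1, e_m = 0.8, model = 1)
male_invasion_alpha(0.4, 0.1)    # 3.2    -- males invade since alpha = 5 > 3.2
cms_invasion_g_andro(0.4, 0.1, 5)# 1.064516 -- CMS invades since g = 1.1
cms_fixation_g(0.4, 0.1)         # 1.32   -- ...but cannot fix: trioecy band
run_scenario(p, "males_first")
```

```
Invasion scenario (males_first), 2 stage(s) -> trioecy
  androdioecy          94 generations, androdioecy
  cms_invasion       1106 generations, trioecy
Population state (genotype frequencies):
     XXn      XYn      XXc      XYc 
0.507692 0.107692 0.276923 0.107692 
  hermaphrodites 0.5077 | males 0.2154 | females 0.2769 | CMS 0.3846
```

Males first establish androdioecy at frequency 0.141; invading CMS then
settles at 0.385 rather than fixing, leaving all three phenotypes —
trioecy maintained by negative frequency-dependent selection: females
boost male fitness (their sons are always male-sired), while males, which
carry but never transmit CMS, act as a sink that halts its spread. Raising
`g` above 1.32 instead drives hermaphrodites out, yielding dioecy with
males exactly at frequency 0.5.

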