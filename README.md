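# farm

Constraint-based analysis of genome-scale metabolic models in R, built
around three optimization algorithms for model construction and
validation:

- **limed-FBA** — flux balance analysis with **li**near **me**tabolite
  **d**ilution. Classical FBA maximises the biomass flux subject to
  steady state, `max cᵀv s.t. Sv = 0, lb ≤ v ≤ ub`, but ignores the
  growth-associated dilution of metabolites in active reactions, so
  metabolic cycles can run without any input flux and the enzymes feeding
  them look dispensable. limed-FBA replaces the steady-state constraint
  with `(S − ε S̄)v = 0` on the irreversible model, where `S̄` is the 0/1
  pattern of `S` and `ε` is a per-metabolite diagonal chosen as
  `ε_ii = d_max/(k_i·v_max)` so that no metabolite's dilution rate can
  exceed `d_max = 0.1`. Biomass metabolites and simple transport
  reactions (no chemical change) are exempt.
- **OnePrune** — classifies every reaction as blocked or flux-carrying
  with a **single** goal-programming LP
  (`max Σtᵢ s.t. S_limed v = 0, δtᵢ ≤ vᵢ, 0 ≤ tᵢ ≤ 1`) under unlimited
  nutrients, and prunes the blocked ones. The blocked set matches
  per-reaction flux-variability analysis, at a fraction of the solves.
- **CROP** — reconciles in-silico and experimental growth/no-growth
  phenotypes by suggesting evidence-weighted reaction additions (LP
  relaxation with indicator rounding and verification) or removals
  (exact minimum-weight search with an embedded growth check). Evidence
  is combined as `w = −log(p_biochem · p_thermo · p_pathway)`; curated
  reactions are free to keep and impossible to remove.

Around these sit the validation screens used for model quality control —
gene essentiality with sensitivity/specificity scoring, nutrient rescue
of auxotrophs (supplements capped at 3 mmol/gDW/h), and genome-wide
synthetic-lethal screening with mechanistic classification (isozyme /
same pathway / interacting pathways) — plus COBRA-dialect SBML import
and export with a reversible identifier codec, media handling, GPR
logic, and a generator of small synthetic networks so that every
algorithm is testable with no external data.

## A worked example

The classic failure mode of plain FBA, on a five-metabolite fixture: a
catalytic carrier cycle converts substrate `S` to the biomass precursor
`P` while regenerating its carriers, and an input enzyme (gene `g_in`)
synthesises the carrier de novo.

```r
library(farm)
fx <- makeFixture("input_cycle", n = 3)

limedFBA(fx$model, fx$media)
#> FluxSolution (limed): status optimal, objective 1.49948
#>   max realized dilution: 0.00015

limedFBA(fx$model, fx$truth$mediaNoInput)   # no carrier input
#> FluxSolution (limed): status optimal, objective 0

fba(fx$model, fx$truth$mediaNoInput)        # FBA runs the cycle for free
#> FluxSolution (fba): status optimal, objective 1.5
```

With dilution, growth requires the input flux (objective 1.49948, just
under the 1.5 mmol/gDW/h substrate cap because a small fraction feeds
carrier dilution, every metabolite's dilution staying ≤ 0.1); without it
the cycle starves (objective 0), while plain FBA happily reports full
growth. Accordingly the input gene is essential under limed-FBA only:

```r
limed <- predictEssentiality(fx$model, fx$media)
plain <- predictEssentiality(fx$model, fx$media, method = "fba")
setdiff(limed$gene[limed$essential], plain$gene[plain$essential])
#> [1] "g_in" "g_tx"
```

Only the dilution-aware method recognises that the carrier-input enzyme
(`g_in`) and the transporter feeding it (`g_tx`) are essential.

Screens, pruning and reconciliation follow the same pattern; see the
methods vignette (`vignettes/farm-methods.Rmd`) for the model, the
parameter choices and the numerical design, and `inst/scripts/farm.R`
for a command-line front end (`convert`, `validate`, `limedfba`,
`prune`, `essentiality`, `synlethal`, `fixture`).

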