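---
title: "Constraint-based modeling with metabolite dilution: methods and design"
author: "farm package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-based modeling with metabolite dilution: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(farm)
```

# The modeling framework

A genome-scale metabolic model is a stoichiometric matrix $S$ (metabolites
$\times$ reactions), flux bounds $lb \le v \le ub$ in mmol/gDW/h, a biomass
objective $c^T v$ whose flux is the growth rate, and gene–protein–reaction
(GPR) rules linking genes to reactions (`and` = enzyme complex, every
subunit required; `or` = isozymes, any one suffices). Classical flux
balance analysis (FBA) predicts growth capability by solving

$$\max_v\; c^T v \quad \text{s.t.}\quad S v = 0,\; lb \le v \le ub .$$

A knockout is simulated by closing (bounds $[0,0]$) every reaction whose
GPR evaluates false with the knocked-out genes absent; a strain is called
viable when the optimal biomass flux exceeds 0.02, the conventional
threshold this package adopts as its default. Media enter as bounds on
exchange reactions: a minimal medium caps the carbon source at
1.5 mmol/gDW/h and supplemental nutrients at 3 mmol/gDW/h; non-limiting
salts get the global flux cap $v_{max} = 1000$.

## limed-FBA: linear metabolite dilution

FBA ignores the growth-associated dilution of metabolites in active
reactions, so it lets a metabolic cycle regenerate its intermediates
for free — a conserved carrier pool can run forever without any input
flux, which makes the enzymes that synthesise the carriers appear
dispensable. limed-FBA closes this gap linearly. Work on the
irreversible form of the model (every reversible reaction split into
`__fwd`/`__rev` children, all fluxes non-negative) and define the binary
pattern matrix $S^{binary}$, with a 1 wherever $S \ne 0$. Row $i$ of
$S^{binary} v$ is then the summed absolute flux through the reactions
metabolite $i$ participates in (twice its turnover). Forcing each active
metabolite to be net-produced at the rate

$$b = \varepsilon\, S^{binary} v , \qquad
  S v = b \iff (S - \varepsilon S^{binary})\, v = 0$$

with a small diagonal $\varepsilon$ makes every active metabolite dilute:
cycles now need a counteracting input flux, and cycle-feeding enzymes
become essential, while supplement rescue still works because the diluted
compound can be imported.

**Choosing $\varepsilon$.** We require that no metabolite's dilution rate
can exceed a preset cap $d_{max} = 0.1$ (flux units) for any flux in the
box $0 \le v \le v_{max}$. Since metabolite $i$ appears in $k_i$
(non-exempt) reactions, each contributing at most $v_{max}$, the unique
simple assignment making the guarantee tight is

$$\varepsilon_{ii} = \frac{d_{max}}{k_i\, v_{max}} ,$$

zero for metabolites in no reactions. A `scale` knob multiplies the whole
diagonal should a different normalisation be wanted; `scale = 0` recovers
plain FBA exactly, a property the test suite asserts.

**Exemptions.** Two sets opt out of dilution. (1) Metabolites already
drained by the biomass reaction (its substrates, by default) would be
double-diluted, so they get $\varepsilon_{ii} = 0$. (2) *Simple transport*
reactions — those that move metabolites between compartments with no
chemical change, including antiporters of unchanged species but not
cofactor-coupled pumps — have their $S^{binary}$ columns zeroed. Without
this, a high-flux shuttle loop through such a transporter would
manufacture dilution capacity and let an exporter-less by-product
disappear; the `transport_cheat` fixture reproduces the leak when the
exemption is disabled and its closure when enabled.

The dilution cap is applied on the irreversible model (the formulation is
stated in irreversible terms), so both directions of a reversible
reaction count toward a metabolite's turnover.

## OnePrune: blocked reactions from one LP

Reactions that cannot carry flux under any nutrient condition (blocked
reactions) are removed by functional pruning. Instead of one
flux-variability LP pair per reaction, a single goal program classifies
all of them at once:

$$\max \sum_i t_i \quad \text{s.t.}\quad S_{limed}\, v = 0,\;
  0 \le v \le v_{max},\; 0 \le t_i \le 1,\; \delta\, t_i \le v_i$$

with every nutrient uptake open to $v_{max}$. Once a reaction carries
$\delta$ units of flux its goal variable saturates, freeing the optimizer
to pursue the others, so at the optimum $t$ is binary and $t_i = 1$
exactly marks reactions that can carry flux. Using the dilution-corrected
$S_{limed}$ kills the two-cycles created by splitting a disconnected
reversible reaction; cycles with an input flux, and exempt-transport
self-cycles, legitimately survive — the latter are caught by the
documented fallback, net-flux flux-variability on the parent model
(`fluxVariability()`, `pruneModel(fvaCheck = TRUE)`).

**The saturation scale $\delta$.** With dilution active a legitimate flux
can be capped far below one unit: the feeder of a dead-end metabolite may
carry only the small dilution leak of its product. A saturation scale of
1 would misclassify such reactions as blocked. The default
$\delta = 10^{-3}$ sits below every dilution-capped flux that arises at
the package's problem sizes and well above solver tolerance
($10^{-6}$). Because dilution leaks put tiny nonzero flux maxima on a
continuum, "blocked" needs an operational threshold, and the package uses
one shared definition everywhere: a reaction is flux-capable iff it can
carry $\delta$ units. With it the goal program's blocked set is identical
to the flux-variability oracle (per-reaction maxima compared against
$\delta$) on all 100 random networks the acceptance suite generates, at
exactly one LP solve per call (both asserted). The binariness of the goal
variables is asserted at $tol/\delta = 10^{-3}$: flux noise below the
solver tolerance enters $t$ scaled by $1/\delta$.

Pruning removes reactions all of whose directions are blocked, tightens
reversible reactions with one blocked direction to the surviving one,
drops orphaned metabolites, and refuses to delete the biomass reaction —
a model that cannot grow on any nutrients is surfaced as an error, not
silently emptied.

## CROP: evidence-weighted growth reconciliation

When predictions contradict curated growth phenotypes, CROP proposes
minimal model edits, weighting each reaction by its evidence on a
probabilistic scale:

$$w_r = -\log\!\big(p_{biochem}\; p_{thermo}\; p_{pathway}\big)$$

so that minimising a sum of weights maximises the joint probability of
the edited set (the maximum-a-posteriori view); evidence contributions
are additive in log space, and halving any one probability adds exactly
$\ln 2$. Manually curated reactions cost 0 as additions and are
immutable for removal ($w = \infty$). Where no pathway prediction
exists, $p_{pathway}$ defaults to the uninformative 0.5 (configurable).

*Restoring growth* (observed viable, predicted inviable): candidate
reactions from a database are merged into the model with indicator
variables $y_r \in [0,1]$ and coupling $v_r \le v_{max} y_r$; the LP
relaxation of $\min \sum_r w_r y_r$ subject to biomass $\ge$ threshold
under the limed constraints is solved, indicators above 0.5 are taken,
the set is verified by re-simulation, greedily extended by descending
$y$ if verification fails, and stripped of redundant members heaviest
first. On every fixture battery the result matches exhaustive
minimum-weight subset enumeration (up to two additions).

*Suppressing growth* (observed inviable, predicted viable): the
indicator program over removals is solved exactly within a size cap
(default 3 changes, the small-edit scale of comparable reconciliation
tools): subsets are enumerated in order of increasing total weight with
lexicographic tie-breaks, each candidate verified by an embedded
limed-FBA solve, and pruned by the necessary condition that a
suppressing set must intersect the support of the current optimal flux
(reversible reactions stay in the support superset because they can
carry gross flux at zero net flux). This enumeration is a deliberate
design choice: it is exact, deterministic, and at the package's problem
sizes faster than a general branch-and-bound would be.

Suggestions are returned ranked with their weights and are never
auto-applied; the `accepted` slot of a `Reconciliation` is a hook for
manual literature review.

## Phenotype screens

`predictEssentiality()` performs one limed-FBA solve per distinct
disabled-reaction set (knockouts sharing a set share a solve) and, given
a truth table, reports sensitivity (experimentally viable mutants
predicted viable) and specificity (experimentally inviable predicted
inviable). `predictRescue()` requires the mutant to be inviable on the
base medium, simulates each supplement at the 3 mmol/gDW/h cap, and
marks multi-nutrient combinations implied by a rescuing single without
re-simulation. `syntheticLethalScreen()` tests all unordered pairs of
individually viable genes; the GPRs are evaluated under the *joint*
knockout (an isozyme pair disables reactions neither single touches),
and a pair whose joint disabled set equals one single's is skipped as
its LP would be identical — an exact shortcut that `exhaustive = TRUE`
disables. Synthetic-lethal pairs are classified mechanistically:
`isozyme` when some reaction survives either single knockout but not the
double; `same_pathway` when the reactions unique to each gene share a
pathway annotation; `interacting_pathways` otherwise.

An accumulation allowance (`addSink()`) reproduces the relaxation needed
for mutants that demonstrably accumulate an intermediate that
steady-state analysis would force to be consumed.

# The synthetic-network generator

`makeFixture()` builds the pedagogical motifs the algorithms are tested
on, each with machine-readable ground truth: `input_cycle` (a catalytic
carrier cycle whose input enzyme is essential only under dilution),
`linear_chain` (upstream/downstream supplement rescue), `branch_rescue`
(a branch point whose lesions are rescued only by their own product),
`dual_route_sl` (a planted synthetic-lethal pair in any of the three
mechanistic classes, with its rescuing supplement), `transport_cheat`
(the shuttle-loop dilution leak), and `dead_end` (a planted blocked set).
`randomModel()` adds connected random networks with coefficients in
$\{\pm1, \pm2\}$ — small integers keep the brute-force oracles exact —
a guaranteed uptake/biomass backbone, and per-seed determinism that
leaves the caller's RNG stream untouched.

What the fixtures emulate is topology: cycles, redundancy, dead ends,
compartment shuttles. What they do not emulate is the scale, the biomass
composition, or the evidence landscape of a genome-scale reconstruction,
so green tests certify the algorithms' contracts, not any biological
claim about a particular organism; genome-scale work should go through
`readCobraSbml()` on a curated model.

# Numerical design

No linear-programming package is available in this environment's R
installation, and the general-purpose fallbacks proved unreliable on
exactly this package's problem class (all-zero right-hand sides with
redundant stoichiometric rows, heavily degenerate goal programs). The
optimization layer is therefore a package-authored bounded-variable
two-phase primal simplex with Bland's anti-cycling rule, a pivot
tolerance of $10^{-7}$ that refuses near-singular pivots (redundant rows
leave phase-1 artificials basic at zero), an entering threshold equal to
the pivot tolerance (reduced costs below it are $\varepsilon$-matrix
arithmetic noise and admitting them causes degenerate two-cycles), a
rotation of the entering choice under prolonged degenerate stalling, and
an exact recomputation of the basic values at optimality. Every solution
is verified against the original constraints at $10^{-6}$ before being
accepted; on failure the same program is re-solved with an alternate LP
method (`pracma::linprog`'s Big-M simplex — the classic remedy for the
conditioning issues that small dilution coefficients can cause) before
an error is raised. The test suite cross-checks the solver against that
independent implementation and against exhaustive vertex enumeration on
tiny instances. The OnePrune goal-coupling row is written as
$\delta t_i - v_i \le 0$ rather than $t_i - v_i/\delta \le 0$ so that
feasibility checks are not amplified by $1/\delta$.

Problem sizes used by the default test and acceptance runs — motifs of
4–20 reactions and 100 random networks of at most ~15 reactions
(≈30 irreversible children) — keep every oracle exact and the whole
acceptance computation in a few minutes on one core.

# Identifier codec and SBML dialect

SBML identifiers admit only letters, digits and underscore and may not
start with a digit. Database identifiers such as `CPD[c]` or `1diacyl`
are encoded by substituting each disallowed character with its ASCII
decimal value demarcated by double underscores (`[` → `__91__`) and
prefixing digit-initial identifiers with one underscore. The bare scheme
is not injective on strings that already contain `__<digits>__` or start
with `_<digit>`; to make decode∘encode the identity on all printable
ASCII, the encoder first escapes the underscores of such substrings as
`__95__`, and the decoder scans left-to-right, treating all-digit tokens
as substitutions, digit-free `__x__` runs as literal text, and
mixed-content tokens as errors. Round-trip identity over random strings
and the adversarial corner cases is asserted in the suite.

Models are written as SBML Level 2 with COBRA-style Notes
(`GENE_ASSOCIATION`, `PATHWAYS`, formula/charge, and the evidence fields
`CURATED`, `P_BIOCHEM`, `P_THERMO`, `PATHWAY_SUPPORT`) and kinetic-law
bound parameters; the reader also recognises SBML-3 `fbc` bound and
objective attributes. Writing a single dialect keeps the write→read→write
cycle a byte-level fixed point, which the suite asserts; emitting a
second, parallel encoding of the same facts (fbc alongside Notes) was
considered and rejected as a redundancy that cannot be round-trip
tested against itself.

# A worked example

```{r example}
fx <- makeFixture("input_cycle", n = 3)
limedFBA(fx$model, fx$media)                      # grows with the input
limedFBA(fx$model, fx$truth$mediaNoInput)         # cycle alone: no growth
fba(fx$model, fx$truth$mediaNoInput)              # FBA misses the dilution
ess <- predictEssentiality(fx$model, fx$media)
ess[ess$essential, c("gene", "biomass")]
```

# Known limitations

Kinetics, enzyme capacity and regulation are outside the framework:
condition-dependent enzyme induction and subunit rearrangements cannot
be captured, and transporters with different affinities are treated
equally. The dense simplex is sized for curated models and fixtures, not
for screening million-variable communities. The suppression search is
exact only within its size cap. GPRs with unknown gene leaves treat the
unknown gene as present. The full genome-scale reproduction path
(`readCobraSbml()` on a published model plus curated truth tables) is
implemented and tested at the interface level, but the published model
and tables must be supplied by the user; they are not shipped.
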