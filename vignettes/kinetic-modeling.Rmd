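---
title: "Condition-specific kinetic models of metabolism from expression and flux data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Condition-specific kinetic models of metabolism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmakin)
```

# The modeling idea

Gene expression alone does not predict metabolic phenotypes: the same
transcriptional change can raise, lower or leave a flux untouched
depending on where the enzyme sits in the network. `gmakin` builds a
mechanistic bridge between the two by translating a metabolic network
reconstruction into a kinetic model whose parameters come almost
entirely from data routinely measured at a *reference condition*:

1. a **reference flux distribution** `v` (from 13C-labeling
   experiments, or estimated from exchange rates alone),
2. **gene-expression ratios** between a condition of interest and the
   reference, aggregated per reaction into a vector `g`,
3. a handful of global fitting parameters `p`.

The trick is a reduced generalized mass-action (GMA) form in which all
rate constants collapse into the reference flux. Concentrations are
normalized to the reference condition, so `c = 1`, `g = 1` is a steady
state by construction, and simulating another condition amounts to
replacing `g`.

## Rate laws

For an irreversible reaction $\sum_i a_i A_i \to \sum_j b_j B_j$:

$$ r = v\, g\, \left( \frac{\prod_i [A_i]^{m_i}}{\prod_j [B_j]^{m_j}}
   \right)^{1/\gamma} $$

Products appear in the denominator: without saturable kinetics, product
inhibition is what lets reactions downstream of an irreversible step
influence the flux through a pathway. The kinetic orders $m$ default to
2 exactly where the stoichiometric coefficient is 2.0 and to 1
otherwise (non-integer biomass-style coefficients get order 1; the
choice is deliberately crude and the sensitivity sweeps exist to check
it does not matter). $\gamma$ counts the irreversible steps lumped into
the reaction (1 for individual reactions): the $1/\gamma$ exponent
applies to the whole substrate/product ratio, the only grouping under
which $\gamma = 1$ reduces to a plain ratio law and $\gamma \to \infty$
yields the flux-carrying lumped limit $r = v\,g$. A lumped reaction
containing an irreversible step is itself irreversible, so reversible
reactions always carry $\gamma = 1$.

For a reversible reaction the net flux is split into nonnegative
forward and backward parts,

$$ r = g \left( v^f \prod_i [A_i]^{m_i} - v^b \prod_j [B_j]^{m_j}
  \right), \qquad v^f - v^b = v, $$

with $v^f = \beta v$, $v^b = (\beta - 1) v$ for $v > 0$. For $v < 0$ we
apply the same assignment to $|v|$ with the larger part backward
($v^f = (\beta-1)|v|$, $v^b = \beta|v|$): this is the only sign
convention under which both parts stay nonnegative *and* the reference
identity $r = v$ holds, which we treat as the defining requirement.
$\beta \ge 1$ plays the role of a pooled equilibrium parameter; a
single global value (default 30) is used for all reversible reactions,
except members of reversible parallel routes (below). $\beta = 1$
degenerates gracefully to an irreversible law.

Biomass formation is not one reaction but a set of precursor **drain
fluxes**. Amino-acid drains follow

$$ r = v\, g\, \prod_i [A_i]^{\alpha} \; \bigl(\min_j [A_j]\bigr)^{\alpha}, $$

where $i$ runs over the drain's consumed species (the amino acid and
ATP) and $j$ over *all* amino acids: a shortage of any amino acid slows
protein synthesis and with it every other amino-acid drain. Generic
drains (carbohydrate, lipid, RNA, one-carbon) drop the min term. The
drain order $\alpha$ is small (default 0.1) because drains are
empirically insensitive to precursor concentrations. The growth rate is

$$ \mu = \frac{\lambda}{X_{MW}} \sum_i \phi_i\, r_i $$

over the drains only, with $\phi_i$ the moles of carbon per mole of
precursor and $\lambda$ a correction factor; in normalized units
$X_{MW}$ defaults to 1 and $\lambda$ is calibrated so that the
reference growth rate equals the chemostat dilution rate
(`calibrateChemostat()`). Growth can stay positive when individual
drains vanish, which is intended.

The assembled model is the mass balance $C\,\dot c = S\,r(v, g, c, p)$
over internal metabolites; boundary species (extracellular pools,
biomass sinks) are open and excluded from `S`'s rows. At steady state
the normalization matrix `C` drops out — the package only uses it in
the dynamic-relaxation oracle, and a test asserts the steady state is
independent of it.

Cofactor pairs (ATP/ADP, NADH/NAD, and in the fixture also a pooled
NADPH) are modeled as single pooled species, matching how the rate
laws treat them as ordinary substrates/products.

## Tunable parameters

| parameter | meaning | default | units |
|---|---|---|---|
| `alpha` | kinetic order of drain fluxes | 0.1 | – |
| `beta` | forward/backward split of reversible reactions | 30 | – |
| `lambda` | growth correction (calibrated to the dilution rate) | 1 | – |
| `xMW` | biomass molecular weight | 1 | normalized |
| `phi` | carbon per mole of each precursor | per drain | mol C/mol |
| `inhibition` | per-reaction multiplicative factor, 1 = none, 0 = complete | – | – |
| `woaUptake` | weak-organic-acid uptake rate | 0 | flux units |
| `atpPerWoa` | ATP cost per WOA taken up | 2 | mol/mol |

The WOA stress model is a fixed ATP drain `atpPerWoa * woaUptake` added
to the ATP balance: one ATP for proton export (Pma1-like) plus one for
anion export (Pdr12-like) per acid molecule entering by diffusion. The
stoichiometry is configurable because it is a biological convention,
not a model output.

# Data-derived parameterization

**Expression aggregation.** Per-gene ratios are mapped to reactions
through GPR (gene-protein-reaction) rules: `AND` nodes take the minimum
of their children (an enzyme complex is limited by its scarcest
subunit), `OR` nodes take the mean weighted by reference intensities
when available (isoenzyme capacities add), and the per-step rules of
lumped reactions (separated by `;`) combine by geometric mean,
respecting the multiplicative role of `g` in a lumped flux. These are
this package's conventions; they are isolated behind
`aggregateExpression()` so they can be swapped. Genes missing from the
data default to ratio 1 with a warning, keeping `g` total over
reactions.

**Microarray preprocessing.** `preprocessMicroarray()` scales each
array to mean intensity 150.0, takes the per-gene median across
replicates, and removes the intensity-dependent trend of the log-ratios
by Lowess smoothing in MA coordinates (span 0.3 by default; the span is
a free choice, set where the smoother is stable on a few hundred genes
and mild enough not to absorb real signal).

**Reference fluxes from exchange rates.** When no labeled flux
distribution exists, `estimateReferenceFluxes()` solves the
minimum-$\ell_2$-norm program: minimize $\sum_j v_j^2$ subject to
$S v = 0$, measured exchange rates fixed (hard constraints, absolute
tolerance $10^{-6}$), and nonnegativity of irreversible reactions. The
implementation is an equality-constrained KKT solve (SVD-based, so
redundant conservation rows are harmless) with active-set clamping of
violated irreversibility constraints, followed by a null-space polish
that pushes $\|S v\|_\infty$ to machine precision. Minimum norm is a
neutral prior: it splits parallel routes symmetrically and keeps
futile cycles at zero. Inconsistent measurements (e.g. uptake 5,
production 7 on a linear chain) are reported with per-constraint
residuals rather than silently projected away.

**Betas on parallel routes.** Two disjoint reversible paths joining the
same metabolite pair form a cycle on the undirected reaction graph; a
thermodynamically consistent split must make the product of
$v^f/v^b$ ratios around the cycle equal 1 (a Wegscheider-type
condition). `assignBetas()` finds fundamental cycles from a spanning
forest of the graph (one edge per reversible reaction, between its
first substrate and first product), and rescales the member betas by
the minimal adjustment in $x = \log(\beta/(\beta-1))$ coordinates — an
orthogonal projection onto the cycle constraint, verified in the tests
against a brute-force grid search. Cycles whose reference fluxes make
consistency impossible with $\beta \ge 1$ (or that contain a zero
flux) fall back to the global beta with a warning naming the cycle.

# Solving the steady state

`solveSteadyState()` runs a damped Newton iteration on
$F(x) = S\,r(e^x)$ in log-concentration coordinates: positivity is
automatic, and the reference condition is the starting point $x = 0$
(conditions are perturbations of the reference, so this start is
usually inside the Newton basin). Details that matter:

* finite-difference Jacobian (the networks of interest have at most a
  few hundred metabolites; the balance map is vectorized through two
  sparse exponent matrices, so a Jacobian costs $n+1$ cheap
  evaluations);
* backtracking line search on $\|F\|_\infty$ with a step cap of 2 log
  units per iteration, and Levenberg regularization when the Jacobian
  is near-singular;
* convergence at $\|F\|_\infty \le 10^{-9} \max(1, \|v\|_\infty)$
  (configurable); a stalled search falls back to dynamic relaxation
  and re-polishes;
* nonconvergence raises a structured condition carrying the best
  iterate and residual.

`relaxToSteadyState()` integrates $\dot x = f(e^x)/(C e^x)$ with a
stiff integrator (`deSolve::lsoda`) in geometrically growing stages
until $\|\dot c\|_\infty$ falls below threshold. It is deliberately an
independent path to the same fixed point and serves as the cross-check
oracle: the tests require agreement with the Newton solver within
$10^{-6}$ relative on twenty seeded toy networks. Where the two solvers
disagree (multiple steady states are not excluded by the model class),
the package reports rather than resolves the discrepancy — we have not
observed it on the fixtures.

## Chemostat layer

`simulateChemostat()` couples the intracellular model to a continuous
culture: intracellular balances vanish given extracellular glucose
$s$; the growth rate must match the dilution rate, $\mu(c(s)) = D$; and
the glucose balance closes, $D(feed - s) = q_{glc}(s, c)\,X$. Only
glucose is environment-coupled; other exchange products are free
sinks. The solver tracks the solution branch outward from the
calibrated reference point $s = 1$ with warm starts (jumping straight
to trace or feed-level glucose puts the inner Newton solve far outside
its basin), brackets the root of $\mu(c(s)) - D$ geometrically, and
declares **washout** when no $s \le feed$ sustains $\mu = D$ with
biomass above the floor (default $10^{-3}$ of reference). A failed
inner solve during bracketing counts as "unable to grow", which makes
washout detection fast and, in our tests, agrees with the slow path.

Calibration fixes $\lambda = D/\mu_{raw}$ and
$feed = 1 + q_{glc,ref}/D$, after which the unstressed culture sits at
exactly $X = 1$, $s = 1$; calibration is idempotent.

# Model-based analyses

**Mechanism-of-action ranking** (`rankTargets()`): each intracellular
reaction is perturbed one at a time — forward and backward rates of
reversible reactions individually — by a factor in $[0.1, 10]$ chosen
to minimize the SSE of predicted vs observed log concentration
changes. The 1-D optimization is a golden-section search on the log
factor (tolerance $10^{-3}$ in log units), warm-started from the
baseline steady state; factor 1 is always admissible and preferred on
ties, so the no-change answer is recovered exactly when the data equal
the baseline prediction. Results are ranked by SSE normalized to the
unperturbed SSE, ties broken by reaction id; nonconverging
perturbations are flagged and ranked last.

**Tolerance contributions (NTC/NUC)**: the tolerance measure is either
the maximum tolerated inhibition depth $1 - k^*$ (bisection of the
washout boundary over the inhibition factor, width $10^{-3}$) or the
WOA uptake rate that reduces biomass to 5% of reference. For a subset
$i$ of reactions, the normalized contribution is the average of the
add-one-in and leave-one-out tolerance changes, normalized by the
total expression-driven change:

$$ \mathrm{NTC}_i = \tfrac12\,
  \frac{[tol(\mathrm{NoGED}+g_i) - tol(\mathrm{NoGED})] +
        [tol(\mathrm{GED}) - tol(\mathrm{GED}-g_i)]}
       {tol(\mathrm{GED}) - tol(\mathrm{NoGED})}. $$

Using the tolerated *depth* rather than $k^*$ itself only flips a sign
that the normalization absorbs. Scenario evaluations are memoized, so
a subset with no expression change scores exactly 0 and the subset of
all changed reactions exactly 1, as identities rather than numerical
accidents. Subsets of size 2-3 probe coordinated regulation that
single-reaction scores miss.

**Dose-response curves** (`doseResponse()`) sweep the WOA uptake over
a grid for three expression scenarios — measured (GED), none (NoGED),
and log-scale extrapolated ($g \mapsto g^2$, `extrapolateExpression()`)
— encoding washout as biomass 0. **Sensitivity sweeps**
(`sensitivitySweep()`) re-evaluate any SSE metric over grids of
$\alpha$, $\beta$, $\lambda$ or kinetic orders, and
`shuffleExpression()` provides the shuffled-expression null.

# Synthetic fixtures and what they do (not) show

All tests run against generated data with known ground truth:

* `makeToyNetwork()` builds chains, diamonds and branched pathways
  (3-15 internal metabolites) with seeded uptake fluxes routed through
  the topology and polished onto the null space of S, optional
  reversible steps, and optional ATP-coupled biomass drains.
* `makeYeastLikeFixture()` is a deterministic central-carbon +
  amino-acid network at the published scale — 75 internal metabolites,
  125 reactions, 309 genes across 96 gene-associated reactions, lumped
  reactions up to $\gamma = 4$, both drain classes, glucose uptake
  6.09 — with a minimum-norm reference state. It is an *emulation*: it
  matches those counts and the pathway-class composition, but its
  exact stoichiometry is this package's own construction, not a
  curated reconstruction.
* `makeCondition()` plants known perturbations, solves, and emits
  observations with multiplicative log-normal noise on concentrations
  (sd of the log equals the CV) and additive noise on fluxes (sd
  $= cv\,|v|$, since fluxes may be negative).

Passing tests therefore demonstrate internal correctness —
reference-identity, conservation, solver agreement, recovery of
planted mechanisms (20/20 noise-free, at least 17/20 at 10% noise) —
not agreement with any particular organism's measured data. Published
yeast results that depend on the original experimental datasets and
the exact curated network are outside what the fixtures can
reproduce, and the package makes no claim about them. Problem sizes in
the test suite (toys of 3-15 metabolites, the 75-metabolite fixture,
400-draw noise panels) are chosen so the full suite runs in about a
minute while still exercising every code path at the published model
scale.

# Known limitations

* No saturable (Michaelis-Menten) kinetics, no allosteric regulation,
  no elementary-step decomposition: the rate laws are deliberately the
  reduced GMA form, and systems dominated by saturation effects will
  be misdescribed.
* Gene-expression ratios stand in for protein-activity ratios;
  post-translational regulation is ignored.
* The transient behavior of the model is only used internally (the
  relaxation oracle); absolute concentrations `C` would be required to
  give trajectories physical time units.
* Steady-state multiplicity is possible in principle; the package
  detects disagreement between its two solvers but does not enumerate
  branches.
* The SBML layer covers L3V1 core with the package's own annotations
  and MathML export of the rate laws; it is not a general-purpose SBML
  toolkit.
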