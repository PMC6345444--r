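---
title: "Structurally constrained metabolite concentrations: model, assumptions, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structurally constrained metabolite concentrations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sccnet)
```

## The model

A metabolic network with $m$ metabolites and $n$ reactions is described by
the split stoichiometric matrices $N^+$ (products) and $N^-$ (substrates),
$N = N^+ - N^-$. Concentrations evolve as $\dot x = N v(x)$ and every
reaction follows mass action kinetics,
$$ v_i \;=\; \theta_i \prod_j x_j^{N^-_{ji}}, \qquad \theta_i > 0 . $$
Reactions with an empty substrate column are zero-order imports across the
system boundary ($v_i = \theta_i$); this is the package's reading of
exchange pseudo-reactions, which stoichiometric models leave kinetically
unspecified. All analyses run on the *split* network (reversible reactions
replaced by forward/backward halves, so $v \ge 0$) after removal of blocked
reactions — both steps are prerequisites for a strictly positive steady
state, which the whole theory presumes.

Units follow the conventions of constraint-based modeling: fluxes in
mmol/gDW/hr, concentrations in mmol/gDW. Rate-constant units are
order-dependent but never needed: $\theta$ enters all downstream formulas
only through ratios.

## Couplings

Two reactions are *fully coupled* when their flux ratio is one constant
$\lambda > 0$ across all admissible states.

* **Structural couplings** hold for every steady-state flux in
  $F = \{v : Nv = 0,\; lb \le v \le ub\}$. They are detected by the
  Charnes–Cooper transformation of the fractional program
  $\mathrm{opt}\ v_i / v_j$: optimize $v_i$ subject to $Nv = 0$, $v_j = 1$,
  $t\,lb \le v \le t\,ub$, $t \ge 0$. Coinciding minimum and maximum
  (relative tolerance $10^{-6}$, absolute floor $10^{-9}$) certify coupling,
  with $\lambda$ the common ratio. Only pairs inside one connected
  component of the substrate/product adjacency are tested; cross-component
  pairs cannot be coupled.
* **Kinetic couplings** hold at *any* state: identical columns of $N^-$
  give $v_l / v_k = \theta_l / \theta_k$ by cancellation in the mass-action
  product. Zero-order imports all share the empty column and are therefore
  mutually coupled — a consequence the test suite checks explicitly.

Both relations merge by transitivity (union–find with coefficient
composition). Coefficients are stored as a numeric factor times a product
of symbolic $\theta$-ratios, so they stay exact when rate constants are
unknown; composed coefficients are reduced through their exponent vector,
which cancels the ratios introduced by routing a path through a class
representative. An inconsistent coefficient cycle (product $\ne 1$ at
relative $10^{-6}$) raises an error rather than silently averaging.

## Certificates

For a target metabolite $X_i$, a witness metabolite $X_j$ adjacent to the
reactions consuming $X_i$ certifies SCC when, on one side of $X_j$'s ODE,
every reaction has a non-empty set of reactions *lacking one substrate
molecule of $X_i$* relative to it ($N^-$ columns equal except one fewer in
row $i$), a selection of those lack partners is mutually fully coupled, and
the opposite side of the ODE is mutually fully coupled. Case I places the
lack sets on the producing side $P_j$, Case II on the consuming side $S_j$
(which always offers $X_j = X_i$ itself as a witness candidate). The
implementation scans witnesses over the products and substrates of the
consumers of $X_i$; this is lossless, because a lack relation in row $i$
forces the lacking side's reactions to consume $X_i$.

Each certificate stores both sides, the per-reaction lack sets restricted
to one qualifying coupling class, and all combinations of lack-set
representatives ($Q$ choices) up to a cap of 64 (a warning reports
truncation). It pins the closed form
$$ x_i \;=\; \frac{\sigma_{\mathrm{num}}}{\sigma_{\mathrm{den}}}\cdot
   \frac{v_{\mathrm{anchor}}}{v_{\mathrm{rep}}} $$
with the anchor the alphabetically first reaction of the intact side (any
choice gives the same value — changing the anchor rescales $\sigma$ and the
flux ratio inversely) and the representative the first member of the chosen
lack set. The $\sigma$ sums run over the witness ODE's sides with flux
ratios replaced by coupling coefficients; their $\theta$-content defines
the certificate's *relevant rate constants*, and the anchor/representative
fluxes its *relevant flux ratio*. The package's central correctness
property — enforced in the test suite over dozens of random networks and
initial conditions — is that this closed form equals the integrated
steady-state concentration to $10^{-6}$ relative, for every certificate and
every representative choice.

## Ranges, missing information, calibration, knockouts

*Ranges.* Over a flux set (simulated ensemble or LP-derived ratio
interval), each certificate yields $[L_{ij}, U_{ij}]$ as the min/max of
$\sigma$-ratio $\times$ flux-ratio jointly over the set and the $Q$
choices; per metabolite the witness intervals intersect as
$[\max_j L_{ij},\, \min_j U_{ij}]$. The surrounding narrative of that
intersection rule can be read two ways (max of minima vs. min of maxima);
the package follows the formula as printed, which is the only reading under
which the intersection is an intersection. An empty result is retained and
flagged infeasible — it indicates the absence of a positive steady state —
rather than dropped.

*Missing rate constants.* Missing $\theta$-ratios are substituted by one,
the mean, or the median of the ratios known *within the same certificate*
(falling back to one when none are known). Removal experiments operate at
the rate-constant level — a constant shared by several certificates
disappears from all of them — and only relevant constants are candidates,
avoiding dilution by parameters that cannot affect the predictions.

*Flux ratios from optimization.* When no kinetic ensemble is available the
relevant ratio is bounded at the optimum of
$\max\, w_{\mathrm{atp}} v_{\mathrm{atp}} - w_{\mathrm{flux}} \sum_{i \ne \mathrm{atp}} v_i$
subject to condition constraints (fixed or boxed exchange fluxes) and a
minimum-flux floor $\varepsilon = 10^{-7}$ on all reactions. The second
program fixes the objective at its optimum inside the Charnes–Cooper
change of variables. Two modes exist: `scaled` (default) pins
$w_{\mathrm{atp}} v_{\mathrm{atp}} - w_{\mathrm{flux}}\sum v = t\,z^*$,
the form consistent with the substitution $v \to v/v_s$, $t = 1/v_s$;
`literal` keeps the unscaled constraint $\ldots = z^*$ for replication
purposes (the two agree whenever the optimum is attained at $t = 1$ or
$z^* = 0$). The optimum is pinned with slack
$10^{-6}\max(1, |z^*|)$ to absorb solver round-off on degenerate faces.
Weight presets of interest: $(1, 0.01)$ for kinetic-ensemble experiments,
$(0.1, 1)$ and $(0.001, 1000)$ for chemostat-style datasets where growth is
fixed from measurements.

*Calibration.* Since $\sigma_p/\sigma_s$ is condition-invariant, a measured
concentration $x$ and a reference-condition ratio range $[r_-, r_+]$ give
$\sigma_p/\sigma_s \in [x/r_+,\, x/r_-]$; per-replicate estimates (each
replicate uses its own exchange constraints, hence its own ratio range) are
combined by envelope — the display convention of per-replicate bars plus an
all-replicates bar — with intersection available behind a flag. Predictions
for a new condition multiply the $\sigma$ interval by the new ratio range;
the round trip provably contains the reference measurement, a property the
suite fuzz-tests. Volumetric measurements convert to per-dry-weight units
with a configurable aqueous-volume-to-dry-weight factor, default
0.0023 L/g.

*Knockouts.* Mutant fluxes are the MOMA projection: the unique minimizer of
$\|v - v_{\mathrm{ref}}\|^2$ over $F \cap \{v_{\mathrm{ko}} = 0\}$ (both
halves of a split reversible reaction are zeroed together). Certificate
concentrations are evaluated at the projected flux; a metabolite whose
certificates all have a vanished relevant flux is reported undefined, the
signature of a mutant without a positive steady state for it. When a
metabolite has several certificates their point values are averaged — they
coincide at genuine mass-action steady states, but a MOMA projection is not
one, so the average is a deliberate smoothing choice. Fold changes against
the reference are binned into 12 symmetric half-open bins on the
$\log_2$ axis, $(-\infty,-2.5], (-2.5,-2], \ldots, (2.5,\infty)$; the bin
count is fixed by convention, the edges are configurable because no
canonical edge set exists.

## The synthetic generator

`generate_network()` plants motifs whose SCC status is provable by hand:
linear chains fed by a zero-order import (every chain metabolite SCC),
dimerization motifs ($\varnothing \to A$, $2A \to B$, $B \to \varnothing$;
only $B$ SCC), and the seven-reaction fan of the worked example ($B$ SCC
from two witness ODEs). Background reactions extend randomly chosen exports
into fresh conversion chains, which preserves every planted certificate.
Rate constants are drawn log-uniformly over two decades centred on one, and
initial concentrations log-uniformly in $[0.1, 10]$ — ranges chosen so that
steady states exist, vary across the ensemble, and stay away from the
integrator's guard rails. Initial-condition ensembles perturb each
metabolite independently by $\pm\{1, 5, 10, 20\}\%$ with symmetric random
signs (a single-metabolite mode exists as a flag).

What the generator does *not* emulate: conserved moieties, bimolecular
couplings between distinct metabolites, thermodynamic reversibility,
measurement noise, or the heavy-tailed rate-constant distributions of real
enzyme data. Passing tests on these ensembles therefore demonstrate the
correctness of the structural machinery — detection, coupling algebra,
$\sigma$ evaluation, the certificate identity — not predictive accuracy on
organisms; accuracy on a real network inherits the quality of its model
and parameters.

## Numerical choices

* Linear programs run on the GLPK primal simplex through a small C binding;
  blocked-reaction detection uses an absolute flux tolerance of $10^{-9}$,
  ratio-constancy a relative $10^{-6}$. Unbounded flux ratios are detected
  by a large cap on the Charnes–Cooper scaling variable and reported as
  open intervals.
* The quadratic MOMA projection uses the Goldfarb–Idnani active-set solver.
* Steady states come from `lsoda` with the analytic Jacobian
  $J = N\,\mathrm{diag}(v)\,(N^-)^\top \mathrm{diag}(1/x)$, relative/absolute
  tolerances $10^{-10}/10^{-14}$, integrated in geometrically growing time
  chunks until $\max_j |\dot x_j| \le 10^{-10} \max(1, x_j)$ — a relative
  criterion, because concentrations span orders of magnitude, and strict
  enough that residual slow-mode error stays well below the $10^{-6}$ at
  which the certificate identity is asserted. Divergence
  (any $x_j > 10^{12}$) returns a non-converged state instead of an error.
* Predicted concentrations whose relevant fluxes differ by more than six
  orders of magnitude are flagged `unstable` and retained; such flux-ratio
  extremes are where the closed form loses numerical meaning.
* Stoichiometric comparisons (lack relations, identical columns) use exact
  arithmetic on the stored coefficients with a $10^{-9}$ rounding guard.

## Problem sizes used by the tests

The suite validates the certificate identity on 50 generated networks
$\times$ 10 perturbed initial conditions, and the substitution-robustness
trend on 20 networks with 5 random removals each per fraction and scheme
(100 removals per condition) over 8-member ensembles; the acceptance script
uses 20 networks $\times$ 5 initial conditions for the identity and 8
networks $\times$ 4 removals for robustness. These sizes keep the whole
suite in the minutes range on a single core while exercising every code
path; all of them scale up by changing the corresponding arguments.

## Known limitations

* Only order differences of exactly one are handled; a lack of two or more
  molecules leads to a polynomial in $x_i$ that the method does not solve.
* Enzyme-mechanism kinetics (Michaelis–Menten and relatives) are out of
  scope unless the network is rewritten in elementary mass-action steps.
* Only *full* coupling is used; partial or directional couplings carry no
  information for the closed form.
* The LP-based ratio ranges inherit the biological plausibility of the
  chosen objective and constraints; with a poorly chosen objective the
  predicted ranges can be tight but wrong.
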