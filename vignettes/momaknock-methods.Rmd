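---
title: "Bi-level knockout design under the MOMA phenotype: model and algorithm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bi-level knockout design under the MOMA phenotype}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The phenotype models

A constraint-based metabolic model consists of the stoichiometric matrix
$S \in \mathbb{R}^{N \times M}$ ($N$ metabolites, $M$ reactions), flux
bounds $v^{\min} \le v \le v^{\max}$, and a steady-state assumption
$Sv = 0$. All fluxes are in mmol/gDW/hr. Three reactions are designated:
the substrate (glucose) uptake, whose flux is fixed to the culture
uptake rate; the biomass drain, whose flux is the growth rate; and the
target secretion whose flux we want to maximize.

Two phenotype predictors appear in the package:

* **FBA** — the wild type is assumed growth-optimal:
  $w = \arg\max v_{biom}$ subject to the constraints above. Because the
  optimal vertex is usually degenerate, `fba()` adds a deterministic
  second stage that picks the minimum-$\|v\|_2$ point among
  biomass-optimal solutions, so the reference $w$ is unique and
  reproducible across solvers (disable with `lexicographic = FALSE`).
* **MOMA** — a knockout mutant is assumed to minimize its squared flux
  adjustment from the wild type:
  $\min_v \sum_{j \ne \text{target}} (v_j - w_j)^2$ subject to
  steady state, bounds with deleted reactions pinned to zero, fixed
  uptake, and a minimum-biomass viability floor. The target reaction is
  excluded from the adjustment sum in design mode, since the design
  question is precisely how much target flux can move.

Because the MOMA objective is strictly convex in every non-target flux,
the optimal non-target flux vector is unique, and the target flux is
then pinned by whatever stoichiometric rows it appears in. The
"optimistic" inner tie-break implicit in duality-based bi-level
reformulations (choose, among inner optima, the one best for the outer
objective) therefore only has bite when the target column of $S$ is
entirely zero; `moma()` then sets the target to its upper bound. With
`exclude_target = FALSE` the plain QP is solved, and an empty knockout
set returns $v = w$ exactly — a useful identity test.

## The bi-level design problem

With binaries $y_j \in \{0,1\}$ ($y_j = 0$: reaction $j$ deleted, at
most $K$ deletions among the candidate set), the design problem is

$$\max_y v_{target} \quad \text{s.t.} \quad v \in
\arg\min_v \Big\{ \textstyle\sum_{j \ne target} (v_j - w_j)^2 :
S v = 0,\; v_{glc} \text{ fixed},\; v_{biom} \ge b_{\min},\;
v^{\min}_j y_j \le v_j \le v^{\max}_j y_j \Big\}.$$

The inner problem is a QP, so the classical LP-duality reduction does
not apply directly; a mixed-integer *quadratically constrained* program
would result. Instead the quadratic cost is replaced by a
convex-combination (lambda-form) piecewise-linear overestimate: per
reaction, grid endpoints $v_j^1 < \dots < v_j^{T_j}$ with
$v_j = \sum_t \beta_{jt} v_j^t$, $\sum_t \beta_{jt} = 1$,
$\beta \ge 0$, and cost $\sum_t (v_j^t{}^2 - 2 w_j v_j^t)\beta_{jt}$
(the constant $w_j^2$ is dropped). Because the cost is convex, the
chordal estimate is an overestimate, exact exactly at the endpoints, so
no SOS2 machinery is needed.

The linearized inner LP is collapsed by strong duality. The dual is
derived mechanically from the primal block: $a_j$ for the convexity
rows, $b_i$ for stoichiometry, $\mu_{glc}$ (free) and
$\mu_{biom} \ge 0$ for the uptake and biomass rows, and $c_j, d_j \ge 0$
for the $y$-gated upper/lower bound rows, giving dual rows
$a_j + \sum_i S_{ij} v_j^t b_i \,[+\, v_j^t \mu] - v_j^t c_j + v_j^t
d_j \le v_j^t{}^2 - 2 w_j v_j^t$ (right-hand side zero for the target)
and dual objective
$\sum_j a_j + v_{glc}\mu_{glc} + b_{\min}\mu_{biom} -
\sum_j v_j^{\max} c_j y_j + \sum_j v_j^{\min} d_j y_j$. Note the
pairing: $c_j$ (upper-bound dual) multiplies $v^{\max}_j$ and $d_j$
multiplies $v^{\min}_j$; the derivation is gated in the test suite by a
numerical strong-duality check (fixed-$y$ primal LP vs dual LP agree to
1e-6 relative), which passes — this is the package's authority for the
sign conventions. The bilinear products $c_j y_j$, $d_j y_j$ become
auxiliary variables $e_j, f_j$ via the standard four-inequality big-M
gadget; the single-level MILP then maximizes
$\sum_t v_{target}^t \beta_{target,t}$ subject to the primal block, the
dual block, the strong-duality equality, the big-M rows and the budget.

**Big-M choice.** $M$ defaults to
$10\,(1 + \max(4 V_{\max},\, q_{\max}/V_{\max}))$ where $V_{\max}$ is
the largest absolute flux bound and $q_{\max}$ the largest linearized
cost magnitude. Every solve is audited: if any $e_j, f_j, c_j, d_j$
lands within $10^{-4} M$ of $\pm M$, the model is rebuilt with
$10 M$ and re-solved (twice at most). The audit also checks the
strong-duality residual, $|e_j - c_j y_j|$, convexity-row residuals and
mass balance of the reconstructed fluxes.

## The adaptive refinement loop

Starting from `k_init = 4` uniform segments per reaction — with $0$
(the knocked-out state) and $w_j$ (the wild type) always inserted as
endpoints, so both are representable with zero linearization error —
the driver iterates:

1. solve the MILP, with a valid lower-bound cut
   $\sum_t v_{target}^t\beta_{target,t} \ge \text{objL}$, where objL is
   the best exact MOMA value of any design seen so far (the exact value
   of a feasible design is always a valid bound on the bi-level
   optimum); if a coarse grid prices that bound as unattainable the cut
   is dropped for that iteration and the event logged;
2. evaluate the returned design with the exact MOMA QP;
3. compute per-reaction gaps
   $\Delta_j = \sum_t (v_j^t - w_j)^2 \beta_{jt} - (\hat v_j - w_j)^2$
   (the generalized form, which reduces to the two-adjacent-endpoint
   expression at nondegenerate LP optima and also covers degenerate
   bases with more than two nonzeros);
4. stop when every non-target $\Delta_j < \varepsilon$, every
   $\max_t \beta_{jt} > \theta$, **and** the MILP objective matches the
   exact QP value of its own design to $10^{-6}$ relative — otherwise
   insert the reconstructed fluxes $\hat v_j$ of failing reactions and
   the exact response fluxes of the incumbent design as new endpoints
   and repeat.

The target reaction is excluded from the gap test and from refinement:
its cost coefficients are identically zero, so its $\beta$ may spread
without affecting anything and its "gap" is not meaningful.

Two safeguards address genuine failure modes of refine-at-incumbent
schemes that we observed and characterized during development:

* **Exact-response insertion (step 4).** A design whose linearized
  solution lies entirely on existing endpoints has all gaps zero and
  would never be refined, even when its *claimed* value is wrong
  because its true response lies between grid points where the chord
  overestimates. Inserting the exact QP response makes the true
  response representable; a design with a representable response can
  never be under-priced (the chord is exact there, so the true response
  stays linearized-inner-optimal), and its claim collapses to the
  truth on the next solve.
* **Verification splits.** Conversely, a *competing* design that never
  becomes the incumbent can stay under-priced indefinitely. On apparent
  convergence the driver halves every segment (quartering every chord
  error) and re-solves; convergence is accepted only when a round of
  global splitting leaves the objective unchanged. Up to
  `verify_rounds = 6` such rounds are allowed; as the grid densifies,
  the linearized value of every design approaches its exact value, so
  the certified optimum is the true bi-level optimum.

In addition, the initial grid is seeded with the exact MOMA responses
of all single-candidate deletions (`seed_grid = TRUE`, one small QP
per candidate). This prices every single-knockout design at no less
than its true value from the first MILP solve, which in particular
makes the $K = 1$ problem exact by construction and anchors the search
for larger budgets.

Among designs tied on the target flux (within $10^{-9}$ relative), the
driver prefers the smaller adjustment $\|v - w\|_2$, seeded with the
empty design — consistent with the minimal-adjustment philosophy and
with how a practitioner would break such ties.

## Parameters and defaults

| parameter | default | units / meaning |
|---|---|---|
| `uptake` | — | fixed substrate uptake, mmol/gDW/hr |
| `min_biomass` | — | viability floor, mmol/gDW/hr |
| `K` | — | knockout budget |
| `k_init` | 4 | initial uniform segments per reaction |
| `eps` | $10^{-6}(1 + \|w\|_2^2)$ | gap threshold, flux² units |
| `theta` | 0.999 | concentration threshold |
| `M_val` | automatic | big-M, audited with ×10 retry |
| `max_iter` | 50 | refinement iterations |
| `verify_rounds` | 6 | global splits for certification |
| `tol_balance` | $10^{-6}$ | mass-balance residual tolerance |

The scale-aware `eps` default makes the stopping rule invariant to the
magnitude of the wild-type flux vector. Fixed reactions
(`lb == ub`) get a single-endpoint grid (the convexity row then pins
the flux exactly) and are excluded from refinement. The glucose
reaction keeps its piecewise representation even though its flux is
fixed by an equality row — its grid simply never needs refinement.

## The synthetic study system

`toy_network(n_internal, seed)` generates the study conditions for all
desk-scale validation. The topology emulates the canonical
overproduction motif (succinate dehydrogenase in *E. coli* being the
textbook case): a substrate exchange feeds a hub metabolite; the
efficient wild-type biomass route runs through the *target precursor*
chain and back into biomass via an amplifying salvage reaction; a
lower-yield, capacity-limited direct route runs in parallel (its
capacity is drawn uniformly from 40–90% of the uptake rate, like a real
enzymatic bottleneck); remaining reactions are random cross-links, some
reversible. Growth-optimal FBA therefore secretes nothing, while
deleting the salvage reaction forces precursor to spill into secretion
with biomass surviving on the bypass — so generated instances have
genuinely competitive, sometimes multi-knockout, optima rather than
trivial empty ones. Default conditions: uptake 10 mmol/gDW/hr, minimum
biomass 1 mmol/gDW/hr, internal capacity 100 mmol/gDW/hr — a scaled-
down version of the classical core-model protocol (uptake 100, minimum
biomass 5), keeping enumeration oracles and repeated MILP solves fast.
Every generated instance carries an LP feasibility certificate (FBA
biomass at least the floor), redrawn from a derived sub-seed on the
rare failure.

What the generator does *not* emulate: genome-scale redundancy
(isozymes, parallel pathways at scale), gene–protein–reaction mapping
(deletions act on reactions, as in the method itself), cofactor
balancing, and realistic biomass compositions. Passing the desk-scale
suites therefore certifies the *optimization machinery* — not that any
particular biological prediction is correct for a real organism.

## Numerical choices

* LP/MILP solves run on HiGHS via `scipy.optimize` in the system
  `python` (no LP/MILP solver ships with this R stack); problems cross
  the bridge as JSON in sparse triplet form, batched to amortize
  start-up. HiGHS is deterministic, so runs are reproducible; the MIP
  relative gap is set to $10^{-9}$, effectively exact at desk scale.
* QPs (MOMA, the FBA second stage) use `quadprog` after a pivoted-QR
  reduction of the equality system — stoichiometric matrices routinely
  carry dependent rows (conserved moieties) that `solve.QP` would
  reject; dropped rows are verified on the returned solution so a
  genuinely inconsistent system is still reported infeasible.
* The design-mode MOMA Hessian is only positive semidefinite (the
  target carries no cost); a centred ridge of $10^{-9}$ on the target
  keeps the factorization positive definite, and the reported objective
  is re-evaluated without the ridge.
* Lethal designs (MOMA-infeasible after deletion) are reported with
  `status = "infeasible"` rather than as errors, so enumeration tables
  and comparisons keep running.
* The brute-force oracle prunes supersets of sets already proven
  lethal; deleting more reactions only shrinks the feasible set, so
  pruning cannot change any label.

## Known limitations

* The MILP grows with the total endpoint count; verification splitting
  doubles it per round. Desk-scale instances (tens of reactions) solve
  in seconds; genome-scale use would want `verify_rounds = 0`,
  `seed_grid = FALSE` and a commercial MILP backend, and then inherits
  the original scheme's heuristic character.
* Alternate optimal knockout sets are not enumerated; one optimum is
  returned (ties broken toward smaller adjustment).
* ROOM-style $L_0/L_1$ inner objectives, gene-level (GPR) deletions,
  and thermodynamic/loopless constraints are out of scope.
* Problem sizes used by the validation suites — 6–12 internal reactions
  for oracle-certified panels, 23 reactions for the bundled worked
  example — were chosen so that exhaustive enumeration remains a
  practical ground truth; the machinery itself has no such limit.
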