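# momaknock

Bi-level strain design for targeted chemical overproduction under the
MOMA phenotype, in R.

## The problem

Metabolic engineers delete reactions from a genome-scale metabolic model
to force a microbe to secrete a chemical of interest. The classical
OptKnock formulation assumes the mutant grows at its maximal rate, but
freshly engineered knockouts have not been selected for growth: their
fluxes stay as close as possible to the wild-type state — the
*minimization of metabolic adjustment* (MOMA) hypothesis. A knockout set
chosen under the wrong phenotype model can look excellent on paper and
produce almost nothing in a MOMA-predicted (or real) mutant.

`momaknock` finds knockout sets that are optimal **under the MOMA
phenotype**. With stoichiometric matrix `S`, wild-type reference `w`
(from FBA), flux bounds `v_min <= v <= v_max`, fixed substrate uptake
`v_glc`, minimum biomass `v_biom >= b_min`, and binary knockout
decisions `y_j` (0 = deleted, at most `K` deletions), it solves the
bi-level program

```
max_y   v_chemical
s.t.    v  solves   min_v  sum_{j != chemical} (v_j - w_j)^2
                    s.t.   S v = 0,  v_glc fixed,  v_biom >= b_min,
                           v_min_j y_j <= v_j <= v_max_j y_j
        sum_j (1 - y_j) <= K ,   y_j in {0, 1}
```

The inner problem is a convex QP, so the LP-duality trick that makes
OptKnock a single MILP does not apply directly. Instead the quadratic
cost is replaced by an adaptively refined piecewise-linear
(convex-combination) overestimate: each flux is written as
`v_j = sum_t beta_jt v_jt` over grid endpoints with `sum_t beta_jt = 1`,
`beta >= 0`, and cost coefficients `v_jt^2 - 2 w_j v_jt`. The linearized
inner LP is collapsed by strong duality into a single-level MILP
(big-M linearization for the products of duals and binaries), the MILP
is solved, the linearization gap
`Delta_j = sum_t (v_jt - w_j)^2 beta_jt - (v_hat_j - w_j)^2` is
measured at the incumbent, and new endpoints are inserted until the
approximation is exact at the solution (`Delta_j < eps`, each `beta_j`
concentrated on one endpoint) and the claimed objective matches the
exact QP value of the returned design. Every run is re-validated with
the exact MOMA QP, and an exhaustive-enumeration oracle is included for
desk-scale certification.

All fluxes are in mmol/gDW/hr.

## Worked example

```r
library(momaknock)

net  <- read_model(system.file("extdata", "core_model_synthetic.tsv",
                               package = "momaknock"))
spec <- design_spec(uptake = 10, min_biomass = 1, K = 2)

wt <- fba(net, spec)                       # wild-type reference
#> FBA wild-type: biomass 100 mmol/gDW/hr, target 3.68388e-15 mmol/gDW/hr

flux_max(net, net$target, spec)            # theoretical maximum secretion
#> [1] 100

fit <- momaknock(net, spec = spec)         # adaptive bi-level design
fit
#> MOMA bi-level knockout design (K = 2)
#>   knockouts: R18, R7
#>   target flux (MILP outer): 12.089 mmol/gDW/hr
#>   exact MOMA re-evaluation: target 12.089, biomass 88.6358, ||v-w||_2 = 58.604
#>   3 iteration(s), status: converged

optknock(net, spec = spec, w = wt)         # biomass-maximal baseline
#> OptKnock baseline design (K = 2)
#>   knockouts: R6
#>   design phase (max-biomass inner): target 100, biomass 100 mmol/gDW/hr
#>   MOMA re-evaluation: target -4.75566e-17, biomass 99.8112, ||v-w||_2 = 7.42062
```

The wild type secretes nothing (its FBA optimum routes all substrate to
biomass). The MOMA-aware design deletes two reactions and the mutant,
predicted by MOMA, secretes 12.1 mmol/gDW/hr while keeping 89% of the
wild-type growth. The baseline design *claims* secretion at the
theoretical maximum (100) under its max-growth assumption, but its
MOMA-predicted mutant secretes essentially zero — the failure mode the
MOMA-aware formulation exists to avoid.

`summary(fit)` prints the iteration trace (MILP objective, largest
linearization gap, endpoint counts, warm-start bound), `coef(fit)` the
0/1 knockout decisions, `fitted(fit)` the mutant flux vector,
`residuals(fit)` the flux adjustment `v - w`, and `plot(fit)` the
convergence trace.

A thin command-line front end with subcommands `synth`, `fba`, `moma`,
`fluxmax`, `momaknock`, `optknock`, `compare` and `oracle` is installed
at `system.file("cli", "momaknock.R", package = "momaknock")`; models
are exchanged in a one-reaction-per-row TSV dialect
(`write_model_tsv()`) or SBML Level 3 with fbc bounds (`read_sbml()`).

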