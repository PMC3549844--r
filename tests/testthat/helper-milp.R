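# Build (without solving) the fixed-y linearized inner primal LP and its
# dual, so that many strong-duality checks can be batched into two
# backend calls.
build_inner_primal_problem <- function(net, w, grid, spec, y = NULL) {
  lay <- momaknock:::milp_layout(net, w, grid, spec)
  yfull <- stats::setNames(rep(1, lay$M), lay$rxns)
  if (!is.null(y)) yfull[names(y)] <- y
  rows <- momaknock:::new_rows()
  momaknock:::primal_rows(lay, rows, y_fixed = yfull)
  trip <- momaknock:::rows_triplet(rows)
  obj <- numeric(lay$n)
  for (j in lay$rxns) {
    if (j != net$target) {
      obj[momaknock:::beta_cols(lay, j) + 1L] <- lay$qs[[j]]
    }
  }
  lb <- rep(0, lay$n); ub <- rep(Inf, lay$n)
  ub[seq_len(lay$sumT)] <- 1
  momaknock:::lp_problem("min", obj, trip[c("i", "j", "x", "m")],
                         trip$cl, trip$cu, lb, ub)
}

build_inner_dual_problem <- function(net, w, grid, spec, y = NULL) {
  lay <- momaknock:::milp_layout(net, w, grid, spec)
  yfull <- stats::setNames(rep(1, lay$M), lay$rxns)
  if (!is.null(y)) yfull[names(y)] <- y
  rows <- momaknock:::new_rows()
  momaknock:::dual_rows(lay, rows)
  trip <- momaknock:::rows_triplet(rows)
  dob <- momaknock:::dual_obj_cols(lay, y_fixed = yfull)
  obj <- numeric(lay$n)
  obj[dob$cols + 1L] <- dob$vals
  lb <- rep(-Inf, lay$n); ub <- rep(Inf, lay$n)
  lb[c(lay$c_col, lay$d_col, lay$mu_biom) + 1L] <- 0
  used <- sort(unique(c(lay$a_col, lay$b_col, lay$c_col, lay$d_col,
                        lay$mu_glc, lay$mu_biom))) + 1L
  fixzero <- setdiff(seq_len(lay$n), used)
  lb[fixzero] <- 0; ub[fixzero] <- 0
  momaknock:::lp_problem("max", obj, trip[c("i", "j", "x", "m")],
                         trip$cl, trip$cu, lb, ub)
}

# random fixed-y strong-duality cases over fixtures; returns a data frame
# of primal and dual LP optima solved in two batched backend calls
batched_duality_cases <- function(n_cases, seed = 99) {
  set.seed(seed)
  primals <- list(); duals <- list()
  k <- 0L
  while (k < n_cases) {
    k <- k + 1L
    s <- sample(1:8, 1)
    fx <- toy_fixture(6 + (s %% 5), seed = s)
    grid <- initial_grid(fx$net, fx$w, k_init = sample(2:5, 1))
    y <- stats::setNames(rep(1, length(fx$net$candidates)),
                         fx$net$candidates)
    nko <- sample(0:2, 1)
    if (nko > 0) y[sample(names(y), nko)] <- 0
    primals[[k]] <- build_inner_primal_problem(fx$net, fx$w$fluxes, grid,
                                               fx$spec, y)
    duals[[k]] <- build_inner_dual_problem(fx$net, fx$w$fluxes, grid,
                                           fx$spec, y)
  }
  pres <- momaknock:::highs_solve(primals)
  dres <- momaknock:::highs_solve(duals)
  data.frame(
    primal_status = vapply(pres, `[[`, "", "status"),
    dual_status = vapply(dres, `[[`, "", "status"),
    primal = vapply(pres, function(r) r$objective %||% NA_real_, 0),
    dual = vapply(dres, function(r) r$objective %||% NA_real_, 0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
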