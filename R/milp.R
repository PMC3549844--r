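# Single-level MILP reduction of the bi-level knockout problem.
#
# Outer: choose binaries y_j (0 = knocked out, at most K zeros among the
# candidate reactions) maximizing the target flux. Inner: the piecewise-
# linearized MOMA LP over convex-combination coefficients beta. The inner
# LP is collapsed by strong duality: its primal constraints, its dual
# constraints, and the equality of both objectives are imposed jointly.
# Products of duals with binaries (c_j*y_j, d_j*y_j) are linearized by the
# big-M method into auxiliary variables e_j, f_j.
#
# The dual block is derived mechanically from the primal block (c_j is the
# multiplier of the upper-bound row, d_j of the lower-bound row), and is
# validated numerically by the fixed-y primal-vs-dual strong-duality test
# in the test suite.

milp_layout <- function(net, w, grid, spec) {
  w <- as_flux(w, net)
  rxns <- net$reactions
  M <- length(rxns); N <- length(net$metabolites)
  T_j <- vapply(grid$points, length, integer(1))[rxns]
  cand <- net$candidates
  nc <- length(cand)
  beta_off <- cumsum(c(0L, T_j[-M]))          # 0-based start of beta_j
  names(beta_off) <- rxns
  sumT <- sum(T_j)
  off <- sumT
  y_col <- stats::setNames(off + seq_len(nc) - 1L, cand); off <- off + nc
  a_col <- stats::setNames(off + seq_len(M) - 1L, rxns); off <- off + M
  b_col <- off + seq_len(N) - 1L; off <- off + N
  c_col <- stats::setNames(off + seq_len(M) - 1L, rxns); off <- off + M
  d_col <- stats::setNames(off + seq_len(M) - 1L, rxns); off <- off + M
  mu_glc <- off; mu_biom <- off + 1L; off <- off + 2L
  e_col <- stats::setNames(off + seq_len(nc) - 1L, cand); off <- off + nc
  f_col <- stats::setNames(off + seq_len(nc) - 1L, cand); off <- off + nc
  qs <- lapply(rxns, function(j) {
    if (j == net$target) rep(0, length(grid$points[[j]]))
    else pwl_cost(grid$points[[j]], w[[j]])
  })
  names(qs) <- rxns
  list(net = net, grid = grid, spec = spec, w = w, rxns = rxns,
       M = M, N = N, T_j = T_j, sumT = sumT, cand = cand, nc = nc,
       beta_off = beta_off, y_col = y_col, a_col = a_col, b_col = b_col,
       c_col = c_col, d_col = d_col, mu_glc = mu_glc, mu_biom = mu_biom,
       e_col = e_col, f_col = f_col, n = off, qs = qs)
}

# row accumulator for sparse triplets
new_rows <- function() {
  env <- new.env(parent = emptyenv())
  env$i <- list(); env$j <- list(); env$x <- list()
  env$cl <- list(); env$cu <- list(); env$m <- 0L
  env
}
add_row <- function(rows, cols, vals, cl, cu) {
  k <- rows$m
  rows$i[[k + 1L]] <- rep.int(k, length(cols))
  rows$j[[k + 1L]] <- as.integer(cols)
  rows$x[[k + 1L]] <- as.numeric(vals)
  rows$cl[[k + 1L]] <- cl; rows$cu[[k + 1L]] <- cu
  rows$m <- k + 1L
  invisible(rows)
}
rows_triplet <- function(rows) {
  list(i = unlist(rows$i), j = unlist(rows$j), x = unlist(rows$x),
       m = rows$m, cl = unlist(rows$cl), cu = unlist(rows$cu))
}

beta_cols <- function(lay, j) lay$beta_off[[j]] + seq_len(lay$T_j[[j]]) - 1L

# Linearized inner primal constraints over beta (and y when y_fixed NULL):
# convexity, stoichiometry in beta-space, glucose equality, biomass floor,
# y-gated flux bound rows.
primal_rows <- function(lay, rows, y_fixed = NULL) {
  net <- lay$net; grid <- lay$grid; spec <- lay$spec
  for (j in lay$rxns) {
    add_row(rows, beta_cols(lay, j), rep(1, lay$T_j[[j]]), 1, 1)
  }
  for (i in seq_len(lay$N)) {
    cols <- integer(0); vals <- numeric(0)
    for (j in lay$rxns) {
      s <- net$S[i, j]
      if (s != 0) {
        cols <- c(cols, beta_cols(lay, j))
        vals <- c(vals, s * grid$points[[j]])
      }
    }
    add_row(rows, cols, vals, 0, 0)
  }
  add_row(rows, beta_cols(lay, net$glucose), grid$points[[net$glucose]],
          spec$uptake, spec$uptake)
  add_row(rows, beta_cols(lay, net$biomass), grid$points[[net$biomass]],
          spec$min_biomass, Inf)
  for (j in lay$rxns) {
    pts <- grid$points[[j]]
    yj <- if (!is.null(y_fixed)) y_fixed[[j]]
          else if (j %in% lay$cand) NA else 1
    if (is.na(yj)) {  # y is a variable column
      add_row(rows, c(beta_cols(lay, j), lay$y_col[[j]]),
              c(-pts, net$ub[[j]]), 0, Inf)
      add_row(rows, c(beta_cols(lay, j), lay$y_col[[j]]),
              c(pts, -net$lb[[j]]), 0, Inf)
    } else {
      add_row(rows, beta_cols(lay, j), -pts, -net$ub[[j]] * yj, Inf)
      add_row(rows, beta_cols(lay, j), pts, net$lb[[j]] * yj, Inf)
    }
  }
  rows
}

# Dual feasibility rows: one per (reaction, endpoint):
# a_j + sum_i S_ij v_jt b_i + [glc] v_jt mu_glc + [biom] v_jt mu_biom
#   - v_jt c_j + v_jt d_j <= q_jt  (q = 0 for the target reaction)
dual_rows <- function(lay, rows) {
  net <- lay$net
  for (j in lay$rxns) {
    pts <- lay$grid$points[[j]]
    Scol <- net$S[, j]
    nzi <- which(Scol != 0)
    for (t in seq_along(pts)) {
      v <- pts[t]
      cols <- c(lay$a_col[[j]], lay$b_col[nzi],
                lay$c_col[[j]], lay$d_col[[j]])
      vals <- c(1, v * Scol[nzi], -v, v)
      if (j == net$glucose) { cols <- c(cols, lay$mu_glc); vals <- c(vals, v) }
      if (j == net$biomass) { cols <- c(cols, lay$mu_biom); vals <- c(vals, v) }
      add_row(rows, cols, vals, -Inf, lay$qs[[j]][t])
    }
  }
  rows
}

# dual objective coefficients (for the fixed-y dual LP and the duality row):
# sum_j a_j + uptake*mu_glc + min_biomass*mu_biom
#   - sum_j ub_j * (c_j y_j) + sum_j lb_j * (d_j y_j)
dual_obj_cols <- function(lay, y_fixed = NULL) {
  net <- lay$net
  cols <- c(lay$a_col, lay$mu_glc, lay$mu_biom)
  vals <- c(rep(1, lay$M), lay$spec$uptake, lay$spec$min_biomass)
  for (j in lay$rxns) {
    if (is.null(y_fixed) && j %in% lay$cand) {
      cols <- c(cols, lay$e_col[[j]], lay$f_col[[j]])
      vals <- c(vals, -net$ub[[j]], net$lb[[j]])
    } else {
      yj <- if (is.null(y_fixed)) 1 else y_fixed[[j]]
      cols <- c(cols, lay$c_col[[j]], lay$d_col[[j]])
      vals <- c(vals, -net$ub[[j]] * yj, net$lb[[j]] * yj)
    }
  }
  list(cols = cols, vals = vals)
}

# big-M linearization of e_j = c_j y_j and f_j = d_j y_j (candidates only)
bigM_rows <- function(lay, rows, M_val) {
  for (j in lay$cand) {
    for (pair in list(c(lay$e_col[[j]], lay$c_col[[j]]),
                      c(lay$f_col[[j]], lay$d_col[[j]]))) {
      ec <- pair[1]; cc <- pair[2]; yc <- lay$y_col[[j]]
      add_row(rows, c(ec, yc), c(1, -M_val), -Inf, 0)    # e <=  M y
      add_row(rows, c(ec, yc), c(1, M_val), 0, Inf)      # e >= -M y
      add_row(rows, c(ec, cc, yc), c(1, -1, M_val), -Inf, M_val)
      add_row(rows, c(ec, cc, yc), c(1, -1, -M_val), -M_val, Inf)
    }
  }
  rows
}

# strong-duality equality: linearized inner cost (over j != target) equals
# the dual objective
duality_row <- function(lay, rows) {
  cols <- integer(0); vals <- numeric(0)
  for (j in lay$rxns) {
    if (j == lay$net$target) next
    cols <- c(cols, beta_cols(lay, j))
    vals <- c(vals, lay$qs[[j]])
  }
  dob <- dual_obj_cols(lay)
  add_row(rows, c(cols, dob$cols), c(vals, -dob$vals), 0, 0)
  rows
}

default_bigM <- function(lay) {
  qmax <- max(abs(unlist(lay$qs)))
  vmax <- max(abs(c(lay$net$lb, lay$net$ub)))
  10 * (1 + max(4 * vmax, qmax / max(1, vmax)))
}

#' Assemble the single-level MILP for the bi-level knockout problem
#'
#' @param net a `metabolic_network`
#' @param w wild-type reference flux
#' @param grid a `pwl_grid`
#' @param spec a [design_spec()] (knockout budget `K` is taken from it)
#' @param M_val big-M constant; default scales with flux bounds and the
#'   linearized cost magnitudes
#' @param objL optional valid lower bound on the outer objective (target
#'   flux), added as a cut
#' @return an unsolved model object (class `bilevel_milp`) for
#'   [solve_bilevel_milp()]
#' @export
assemble_milp <- function(net, w, grid, spec, M_val = NULL, objL = NULL) {
  lay <- milp_layout(net, w, grid, spec)
  if (is.null(M_val)) M_val <- default_bigM(lay)
  rows <- new_rows()
  primal_rows(lay, rows)
  dual_rows(lay, rows)
  duality_row(lay, rows)
  bigM_rows(lay, rows, M_val)
  if (lay$nc > 0) {  # budget: sum(1 - y) <= K
    add_row(rows, lay$y_col, rep(1, lay$nc), lay$nc - spec$K, Inf)
  }
  tgt_cols <- beta_cols(lay, net$target)
  tgt_vals <- grid$points[[net$target]]
  if (!is.null(objL) && is.finite(objL)) {
    add_row(rows, tgt_cols, tgt_vals, objL, Inf)
  }
  trip <- rows_triplet(rows)
  n <- lay$n
  obj <- numeric(n); obj[tgt_cols + 1L] <- tgt_vals
  lb <- rep(-Inf, n); ub <- rep(Inf, n)
  integrality <- integer(n)
  bseq <- seq_len(lay$sumT)
  lb[bseq] <- 0; ub[bseq] <- 1
  if (lay$nc > 0) {
    yi <- lay$y_col + 1L
    lb[yi] <- 0; ub[yi] <- 1; integrality[yi] <- 1L
  }
  lb[lay$c_col + 1L] <- 0
  lb[lay$d_col + 1L] <- 0
  lb[lay$mu_biom + 1L] <- 0
  structure(list(layout = lay, M_val = M_val, objL = objL,
                 problem = lp_problem("max", obj,
                                      trip[c("i", "j", "x", "m")],
                                      trip$cl, trip$cu, lb, ub, integrality)),
            class = "bilevel_milp")
}

#' Dimensions of an assembled bi-level MILP
#'
#' Closed-form audit of the model size: with `M` reactions, `N`
#' metabolites, `sumT` grid endpoints and `nc` candidates, the model has
#' `sumT + 3M + N + 3nc + 2` variables and
#' `M + N + 2 + 2M + sumT + 1 + 8nc + [nc > 0] (+1 for an objL cut)` rows.
#' @param model a `bilevel_milp`
#' @return list with `n_var`, `n_row`
#' @export
milp_dims <- function(model) {
  list(n_var = model$problem$n, n_row = model$problem$A$m)
}

#' Solve an assembled bi-level MILP
#'
#' Runs the HiGHS backend, extracts the knockout decisions, the
#' convex-combination coefficients and the dual block, and audits the
#' solution: primal residuals, the strong-duality residual, the big-M
#' products (`|e - c y|`, `|f - d y|`), and whether any linearized product
#' variable sits suspiciously close to `+-M` (a too-small big-M). On a
#' big-M audit failure the model is rebuilt with `M * 10` and re-solved,
#' up to `retries` times.
#'
#' @param model a `bilevel_milp` from [assemble_milp()]
#' @param mip_gap relative MIP optimality gap (default 1e-9: effectively
#'   exact at desk scale)
#' @param retries big-M escalation retries
#' @param seed unused by the deterministic HiGHS backend; accepted so
#'   callers can thread a seed through uniformly
#' @return list: `status`, `objective` (target flux), `y` (named 0/1 over
#'   candidates), `knockouts`, `beta` (named list), `duals`, `audit`
#' @export
solve_bilevel_milp <- function(model, mip_gap = 1e-9, retries = 2L,
                               seed = NULL) {
  res <- highs_solve1(model$problem, mip_gap = mip_gap)
  if (res$status != "optimal") {
    return(list(status = res$status, objective = NA_real_,
                y = NULL, knockouts = character(), beta = NULL,
                duals = NULL, audit = NULL))
  }
  out <- extract_milp_solution(model, res)
  if (!out$audit$bigM_ok && retries > 0L) {
    lay <- model$layout
    model2 <- assemble_milp(lay$net, lay$w, lay$grid, lay$spec,
                            M_val = model$M_val * 10, objL = model$objL)
    return(solve_bilevel_milp(model2, mip_gap = mip_gap,
                              retries = retries - 1L, seed = seed))
  }
  out
}

extract_milp_solution <- function(model, res) {
  lay <- model$layout
  x <- res$x
  beta <- stats::setNames(lapply(lay$rxns, function(j) {
    x[beta_cols(lay, j) + 1L]
  }), lay$rxns)
  y <- if (lay$nc > 0) {
    stats::setNames(round(x[lay$y_col + 1L]), lay$cand)
  } else stats::setNames(numeric(0), character(0))
  knockouts <- names(y)[y == 0]
  duals <- list(
    a = stats::setNames(x[lay$a_col + 1L], lay$rxns),
    b = x[lay$b_col + 1L],
    c = stats::setNames(x[lay$c_col + 1L], lay$rxns),
    d = stats::setNames(x[lay$d_col + 1L], lay$rxns),
    mu_glc = x[lay$mu_glc + 1L],
    mu_biom = x[lay$mu_biom + 1L],
    e = stats::setNames(x[lay$e_col + 1L], lay$cand),
    f = stats::setNames(x[lay$f_col + 1L], lay$cand))
  audit <- audit_milp(lay, model$M_val, beta, y, duals)
  list(status = "optimal", objective = res$objective, y = y,
       knockouts = knockouts, beta = beta, duals = duals, audit = audit)
}

audit_milp <- function(lay, M_val, beta, y, duals, tol = 1e-5) {
  primal_cost <- 0
  for (j in lay$rxns) {
    if (j != lay$net$target) {
      primal_cost <- primal_cost + sum(lay$qs[[j]] * beta[[j]])
    }
  }
  yfull <- stats::setNames(rep(1, lay$M), lay$rxns)
  yfull[names(y)] <- y
  dual_obj <- sum(duals$a) + lay$spec$uptake * duals$mu_glc +
    lay$spec$min_biomass * duals$mu_biom -
    sum(lay$net$ub * duals$c * yfull) + sum(lay$net$lb * duals$d * yfull)
  sd_resid <- abs(primal_cost - dual_obj)
  prod_err <- 0; near_M <- FALSE
  if (lay$nc > 0) {
    prod_err <- max(abs(duals$e - duals$c[lay$cand] * y),
                    abs(duals$f - duals$d[lay$cand] * y))
    vals <- c(duals$e, duals$f, duals$c[lay$cand], duals$d[lay$cand])
    near_M <- any(abs(vals) > M_val * (1 - 1e-4))
  }
  conv_resid <- max(abs(vapply(beta, sum, numeric(1)) - 1))
  v <- pwl_reconstruct(lay$grid, beta)
  balance <- max(abs(lay$net$S %*% v[lay$rxns]))
  list(strong_duality_residual = sd_resid,
       duality_ok = sd_resid <= 1e-5 * (1 + abs(primal_cost)),
       product_residual = prod_err,
       bigM_ok = !near_M,
       convexity_residual = conv_resid,
       balance_residual = balance,
       M_val = M_val)
}

# ---- fixed-y LPs used by the duality validation ------------------------

#' Linearized inner MOMA LP for a fixed knockout decision
#'
#' Minimizes the piecewise-linearized adjustment cost over the
#' convex-combination coefficients with binaries frozen at `y`.
#' @param net,w,grid,spec as in [assemble_milp()]
#' @param y named 0/1 vector over candidate reactions (defaults to all 1)
#' @return list: `status`, `objective`, `beta`, `fluxes`
#' @export
linearized_inner_lp <- function(net, w, grid, spec, y = NULL) {
  lay <- milp_layout(net, w, grid, spec)
  yfull <- stats::setNames(rep(1, lay$M), lay$rxns)
  if (!is.null(y)) yfull[names(y)] <- y
  rows <- new_rows()
  primal_rows(lay, rows, y_fixed = yfull)
  trip <- rows_triplet(rows)
  obj <- numeric(lay$n)
  for (j in lay$rxns) {
    if (j != net$target) obj[beta_cols(lay, j) + 1L] <- lay$qs[[j]]
  }
  lb <- rep(0, lay$n); ub <- rep(Inf, lay$n)
  ub[seq_len(lay$sumT)] <- 1
  p <- lp_problem("min", obj, trip[c("i", "j", "x", "m")],
                  trip$cl, trip$cu, lb, ub)
  res <- highs_solve1(p)
  if (res$status != "optimal") return(list(status = res$status))
  beta <- stats::setNames(lapply(lay$rxns, function(j) {
    res$x[beta_cols(lay, j) + 1L]
  }), lay$rxns)
  list(status = "optimal", objective = res$objective, beta = beta,
       fluxes = pwl_reconstruct(grid, beta))
}

#' Dual LP of the linearized inner problem for a fixed knockout decision
#'
#' @inheritParams linearized_inner_lp
#' @return list: `status`, `objective`
#' @export
linearized_inner_dual <- function(net, w, grid, spec, y = NULL) {
  lay <- milp_layout(net, w, grid, spec)
  yfull <- stats::setNames(rep(1, lay$M), lay$rxns)
  if (!is.null(y)) yfull[names(y)] <- y
  rows <- new_rows()
  dual_rows(lay, rows)
  trip <- rows_triplet(rows)
  dob <- dual_obj_cols(lay, y_fixed = yfull)
  obj <- numeric(lay$n)
  obj[dob$cols + 1L] <- dob$vals
  lb <- rep(-Inf, lay$n); ub <- rep(Inf, lay$n)
  lb[c(lay$c_col, lay$d_col, lay$mu_biom) + 1L] <- 0
  used <- sort(unique(c(lay$a_col, lay$b_col, lay$c_col, lay$d_col,
                        lay$mu_glc, lay$mu_biom))) + 1L
  fixzero <- setdiff(seq_len(lay$n), used)   # beta/e/f columns unused here
  lb[fixzero] <- 0; ub[fixzero] <- 0
  p <- lp_problem("max", obj, trip[c("i", "j", "x", "m")],
                  trip$cl, trip$cu, lb, ub)
  res <- highs_solve1(p)
  list(status = res$status, objective = res$objective)
}
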