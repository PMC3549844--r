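# OptKnock-style baseline: same outer problem (max target flux over up to
# K knockouts) but the inner phenotype is biomass *maximization* (an LP),
# collapsed to a single-level MILP by LP duality exactly as in the
# original method. Used as the comparator whose designs are then
# re-evaluated under the MOMA objective.

optknock_layout <- function(net, spec) {
  rxns <- net$reactions
  M <- length(rxns); N <- length(net$metabolites)
  cand <- net$candidates; nc <- length(cand)
  off <- 0L
  v_col <- stats::setNames(off + seq_len(M) - 1L, rxns); off <- off + M
  y_col <- stats::setNames(off + seq_len(nc) - 1L, cand); off <- off + nc
  l_col <- off + seq_len(N) - 1L; off <- off + N        # stoich duals
  mu <- off; nu <- off + 1L; off <- off + 2L            # glc (free), biom (>=0)
  p_col <- stats::setNames(off + seq_len(M) - 1L, rxns); off <- off + M
  q_col <- stats::setNames(off + seq_len(M) - 1L, rxns); off <- off + M
  e_col <- stats::setNames(off + seq_len(nc) - 1L, cand); off <- off + nc
  f_col <- stats::setNames(off + seq_len(nc) - 1L, cand); off <- off + nc
  list(net = net, spec = spec, rxns = rxns, M = M, N = N, cand = cand,
       nc = nc, v_col = v_col, y_col = y_col, l_col = l_col, mu = mu,
       nu = nu, p_col = p_col, q_col = q_col, e_col = e_col,
       f_col = f_col, n = off)
}

assemble_optknock <- function(net, spec, M_val = NULL) {
  lay <- optknock_layout(net, spec)
  if (is.null(M_val)) M_val <- 100 * (1 + max(abs(c(net$lb, net$ub))) /
                                        max(1, max(abs(net$S))))
  rows <- new_rows()
  # inner primal: S v = 0, glucose fixed, biomass floor, gated bounds
  for (i in seq_len(lay$N)) {
    nz <- which(net$S[i, ] != 0)
    add_row(rows, lay$v_col[nz], net$S[i, nz], 0, 0)
  }
  add_row(rows, lay$v_col[[net$glucose]], 1, spec$uptake, spec$uptake)
  add_row(rows, lay$v_col[[net$biomass]], 1, spec$min_biomass, Inf)
  for (j in lay$rxns) {
    if (j %in% lay$cand) {
      add_row(rows, c(lay$v_col[[j]], lay$y_col[[j]]),
              c(1, -net$ub[[j]]), -Inf, 0)              # v <= ub y
      add_row(rows, c(lay$v_col[[j]], lay$y_col[[j]]),
              c(1, -net$lb[[j]]), 0, Inf)               # v >= lb y
    }  # non-candidates: plain variable bounds suffice
  }
  # inner dual feasibility: S' lambda + [glc] mu - [biom] nu + p - q = c
  for (j in lay$rxns) {
    nz <- which(net$S[, j] != 0)
    cols <- c(lay$l_col[nz], lay$p_col[[j]], lay$q_col[[j]])
    vals <- c(net$S[nz, j], 1, -1)
    if (j == net$glucose) { cols <- c(cols, lay$mu); vals <- c(vals, 1) }
    if (j == net$biomass) { cols <- c(cols, lay$nu); vals <- c(vals, -1) }
    rhs <- as.numeric(j == net$biomass)
    add_row(rows, cols, vals, rhs, rhs)
  }
  # strong duality: v_biom = u*mu - bmin*nu + sum ub e - sum lb f
  cols <- c(lay$v_col[[net$biomass]], lay$mu, lay$nu)
  vals <- c(1, -spec$uptake, spec$min_biomass)
  for (j in lay$rxns) {
    if (j %in% lay$cand) {
      cols <- c(cols, lay$e_col[[j]], lay$f_col[[j]])
    } else {
      cols <- c(cols, lay$p_col[[j]], lay$q_col[[j]])
    }
    vals <- c(vals, -net$ub[[j]], net$lb[[j]])
  }
  add_row(rows, cols, vals, 0, 0)
  bigM_rows_generic(lay, rows, M_val)
  if (lay$nc > 0) add_row(rows, lay$y_col, rep(1, lay$nc),
                          lay$nc - spec$K, Inf)
  trip <- rows_triplet(rows)
  obj <- numeric(lay$n); obj[lay$v_col[[net$target]] + 1L] <- 1
  lb <- rep(-Inf, lay$n); ub <- rep(Inf, lay$n)
  lb[lay$v_col + 1L] <- net$lb; ub[lay$v_col + 1L] <- net$ub
  integrality <- integer(lay$n)
  if (lay$nc > 0) {
    yi <- lay$y_col + 1L
    lb[yi] <- 0; ub[yi] <- 1; integrality[yi] <- 1L
  }
  lb[c(lay$p_col, lay$q_col, lay$nu) + 1L] <- 0
  structure(list(layout = lay, M_val = M_val,
                 problem = lp_problem("max", obj,
                                      trip[c("i", "j", "x", "m")],
                                      trip$cl, trip$cu, lb, ub,
                                      integrality)),
            class = "optknock_milp")
}

bigM_rows_generic <- function(lay, rows, M_val) {
  for (j in lay$cand) {
    for (pair in list(c(lay$e_col[[j]], lay$p_col[[j]]),
                      c(lay$f_col[[j]], lay$q_col[[j]]))) {
      ec <- pair[1]; cc <- pair[2]; yc <- lay$y_col[[j]]
      add_row(rows, c(ec, yc), c(1, -M_val), -Inf, 0)
      add_row(rows, c(ec, yc), c(1, M_val), 0, Inf)
      add_row(rows, c(ec, cc, yc), c(1, -1, M_val), -Inf, M_val)
      add_row(rows, c(ec, cc, yc), c(1, -1, -M_val), -M_val, Inf)
    }
  }
  rows
}

#' OptKnock-style baseline design
#'
#' Solves the classical bi-level strain-design problem — outer: maximize
#' the target flux over up to `K` knockouts; inner: biomass-maximizing LP
#' — as a single-level MILP via LP duality, then re-evaluates the
#' returned knockout set under the MOMA objective for comparison with
#' [momaknock()]. Inner degeneracy is resolved optimistically (the target
#' flux is maximized among biomass-optimal fluxes), which is the
#' behaviour the duality reformulation implies.
#'
#' @inheritParams momaknock
#' @param w wild-type reference used only for the MOMA re-evaluation
#' @return an object of class `optknock`: `knockouts`, `design_target`,
#'   `design_biomass` (inner = max-biomass phenotype), `moma` (a
#'   `moma_fit`, possibly with status "infeasible" for lethal designs),
#'   `status`
#' @export
optknock <- function(net, K = NULL, spec = attr(net, "spec"), w = NULL,
                     M_val = NULL, mip_gap = 1e-9, seed = NULL) {
  if (is.null(spec)) stop("no design_spec: pass `spec` or use a network ",
                          "with an attached one")
  if (!is.null(K)) spec$K <- as.integer(K)
  check_spec(net, spec)
  if (is.null(w)) w <- fba(net, spec)
  w <- as_flux(w, net)
  model <- assemble_optknock(net, spec, M_val = M_val)
  for (try in 1:3) {
    res <- highs_solve1(model$problem, mip_gap = mip_gap)
    if (res$status != "optimal") {
      stop("OptKnock MILP not solved (status: ", res$status, ")")
    }
    lay <- model$layout
    prods <- abs(res$x[c(lay$e_col, lay$f_col, lay$p_col[lay$cand],
                         lay$q_col[lay$cand]) + 1L])
    if (lay$nc == 0L || all(prods < model$M_val * (1 - 1e-4))) break
    model <- assemble_optknock(net, spec, M_val = model$M_val * 10)
  }
  lay <- model$layout
  v <- stats::setNames(res$x[lay$v_col + 1L], lay$rxns)
  y <- if (lay$nc > 0) stats::setNames(round(res$x[lay$y_col + 1L]),
                                       lay$cand)
       else stats::setNames(numeric(0), character(0))
  knockouts <- sort(names(y)[y == 0])
  evaluation <- moma(net, w, knockouts, spec, exclude_target = TRUE)
  structure(list(knockouts = knockouts,
                 design_target = unname(v[net$target]),
                 design_biomass = unname(v[net$biomass]),
                 design_fluxes = v,
                 moma = evaluation,
                 spec = spec, status = "optimal"),
            class = "optknock")
}

#' @export
print.optknock <- function(x, ...) {
  cat("OptKnock baseline design (K = ", x$spec$K, ")\n", sep = "")
  cat("  knockouts: ",
      if (length(x$knockouts)) paste(x$knockouts, collapse = ", ")
      else "(none)", "\n", sep = "")
  cat("  design phase (max-biomass inner): target ",
      format(x$design_target, digits = 6), ", biomass ",
      format(x$design_biomass, digits = 6), " mmol/gDW/hr\n", sep = "")
  if (x$moma$status == "optimal") {
    cat("  MOMA re-evaluation: target ",
        format(x$moma$target_flux, digits = 6), ", biomass ",
        format(x$moma$biomass_flux, digits = 6), ", ||v-w||_2 = ",
        format(x$moma$l2_distance, digits = 6), "\n", sep = "")
  } else {
    cat("  MOMA re-evaluation: ", x$moma$status, " design\n", sep = "")
  }
  invisible(x)
}

#' Side-by-side comparison of MOMA-aware and biomass-maximal designs
#'
#' Runs [momaknock()] and [optknock()] for each budget in `K_range` and
#' tabulates the design-phase fluxes, the MOMA re-evaluated fluxes and
#' the flux adjustment `||v - w||_2` of both strategies.
#'
#' @param net a `metabolic_network`
#' @param spec a [design_spec()]
#' @param K_range integer vector of knockout budgets
#' @param ... passed on to [momaknock()]
#' @return data frame with one row per (K, method)
#' @export
compare_strategies <- function(net, spec = attr(net, "spec"),
                               K_range = 1:2, ...) {
  if (length(K_range) == 0L) {
    return(data.frame(K = integer(0), method = character(0),
                      knockouts = character(0), design_target = numeric(0),
                      design_biomass = numeric(0), moma_target = numeric(0),
                      moma_biomass = numeric(0), l2_distance = numeric(0),
                      moma_status = character(0),
                      stringsAsFactors = FALSE))
  }
  w <- fba(net, spec)
  rows <- lapply(K_range, function(K) {
    mk <- momaknock(net, K = K, spec = spec, w = w, ...)
    ok <- optknock(net, K = K, spec = spec, w = w)
    rbind(
      data.frame(K = K, method = "momaknock",
                 knockouts = paste(mk$knockouts, collapse = ","),
                 design_target = mk$objective,
                 design_biomass = if (mk$moma$status == "optimal")
                   mk$moma$biomass_flux else NA_real_,
                 moma_target = mk$moma$target_flux,
                 moma_biomass = mk$moma$biomass_flux,
                 l2_distance = mk$moma$l2_distance,
                 moma_status = mk$moma$status, stringsAsFactors = FALSE),
      data.frame(K = K, method = "optknock",
                 knockouts = paste(ok$knockouts, collapse = ","),
                 design_target = ok$design_target,
                 design_biomass = ok$design_biomass,
                 moma_target = ok$moma$target_flux,
                 moma_biomass = ok$moma$biomass_flux,
                 l2_distance = ok$moma$l2_distance,
                 moma_status = ok$moma$status, stringsAsFactors = FALSE))
  })
  do.call(rbind, rows)
}
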