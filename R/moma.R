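#' MOMA: predicted flux response of a knockout strain
#'
#' Solves the minimization-of-metabolic-adjustment quadratic program: the
#' mutant flux vector `v` minimizing the squared Euclidean distance to the
#' wild-type reference `w`, subject to mass balance, flux bounds with
#' knocked-out reactions pinned to zero, the fixed substrate uptake, and
#' the minimum-biomass constraint.
#'
#' With `exclude_target = TRUE` (the convention of the bi-level
#' optimizer), the target reaction does not contribute to the adjustment
#' objective. The objective is then strictly convex in every non-target
#' flux, so the optimal non-target flux vector is unique and the target
#' flux is pinned by the stoichiometric rows it appears in; the
#' "optimistic" tie-break implicit in the duality-based single-level
#' reformulation (maximize the target among inner optima) therefore only
#' has bite when the target column of `S` is entirely zero, in which case
#' the target flux is set to its upper bound. With
#' `exclude_target = FALSE` the plain QP optimum is returned, so an empty
#' knockout set reproduces `w` exactly.
#'
#' @param net a `metabolic_network`
#' @param w wild-type reference: an [fba()] fit or named flux vector
#' @param knockouts character vector of reaction ids forced to zero
#' @param spec a [design_spec()]
#' @param exclude_target drop the target reaction from the QP objective
#'   and apply the optimistic tie-break (default TRUE)
#' @param tol_balance mass-balance residual tolerance for the returned flux
#' @return an object of class `moma_fit`: `fluxes`, `moma_objective`
#'   (squared-flux units, over the objective reactions), `target_flux`,
#'   `biomass_flux`, `l2_distance` (`||v - w||_2` over all reactions),
#'   `status` ("optimal" or "infeasible"), `knockouts`. Infeasible
#'   (lethal) designs are reported via `status`, not an error.
#' @export
moma <- function(net, w, knockouts = character(), spec,
                 exclude_target = TRUE, tol_balance = 1e-6) {
  check_spec(net, spec)
  w <- as_flux(w, net)
  unknown <- setdiff(knockouts, net$reactions)
  if (length(unknown)) stop("unknown knockout reaction(s): ",
                            paste(unknown, collapse = ", "))
  M <- length(net$reactions)
  lb <- net$lb; ub <- net$ub
  lb[knockouts] <- 0; ub[knockouts] <- 0
  tgt <- match(net$target, net$reactions)

  obj_mask <- rep(TRUE, M)
  if (exclude_target) obj_mask[tgt] <- FALSE
  ridge <- 1e-9
  Dd <- ifelse(obj_mask, 2, 2 * ridge)
  D <- diag(Dd, M)
  d <- Dd * w

  blocks <- flux_qp_blocks(net, spec, lb, ub)
  stage1 <- solve_qp(D, d, blocks$E, blocks$e, blocks$G, blocks$h)
  if (stage1$status != "optimal") {
    return(moma_result(net, w, NULL, knockouts, obj_mask, "infeasible"))
  }
  v <- stage1$x
  if (exclude_target && all(net$S[, tgt] == 0)) {
    # target decoupled from mass balance: any value in its bounds is
    # inner-optimal, take the outer-optimal one
    v[tgt] <- ub[[net$target]]
  }
  fit <- moma_result(net, w, v, knockouts, obj_mask, "optimal")
  if (fit$balance_residual > tol_balance * max(1, max(abs(v)))) {
    fit$status <- "unbalanced"
  }
  fit
}

moma_result <- function(net, w, v, knockouts, obj_mask, status) {
  if (is.null(v)) {
    return(structure(list(fluxes = NULL, moma_objective = NA_real_,
                          target_flux = NA_real_, biomass_flux = NA_real_,
                          l2_distance = NA_real_, balance_residual = NA_real_,
                          knockouts = knockouts, status = status),
                     class = "moma_fit"))
  }
  v <- stats::setNames(v, net$reactions)
  structure(list(
    fluxes = v,
    moma_objective = sum((v[obj_mask] - w[obj_mask])^2),
    target_flux = unname(v[net$target]),
    biomass_flux = unname(v[net$biomass]),
    l2_distance = sqrt(sum((v - w)^2)),
    balance_residual = max(abs(net$S %*% v)),
    knockouts = knockouts,
    status = status), class = "moma_fit")
}

#' @export
print.moma_fit <- function(x, ...) {
  if (x$status != "optimal") {
    cat("MOMA: ", x$status, " design (knockouts: ",
        paste(x$knockouts, collapse = ", "), ")\n", sep = "")
    return(invisible(x))
  }
  cat("MOMA flux response",
      if (length(x$knockouts)) paste0(" (knockouts: ",
                                      paste(x$knockouts, collapse = ", "), ")"),
      "\n  target ", format(x$target_flux, digits = 6),
      ", biomass ", format(x$biomass_flux, digits = 6),
      " mmol/gDW/hr; ||v-w||_2 = ", format(x$l2_distance, digits = 6),
      "\n", sep = "")
  invisible(x)
}
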