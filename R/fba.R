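#' Flux balance analysis: the wild-type reference flux distribution
#'
#' Maximizes the biomass flux subject to steady-state mass balance
#' `S v = 0`, flux bounds, and the fixed substrate uptake. Because the
#' biomass-optimal vertex is typically degenerate (many alternate optima),
#' a second, deterministic stage picks the unique minimum-Euclidean-norm
#' flux vector among biomass-optimal solutions, so the wild-type reference
#' `w` is reproducible across solvers and runs; disable with
#' `lexicographic = FALSE` to keep the raw LP vertex.
#'
#' @param net a `metabolic_network`
#' @param spec a [design_spec()] (only `uptake` is used here)
#' @param lexicographic resolve degeneracy by a min `||v||_2` second stage
#' @return an object of class `fba_fit`: `fluxes` (named, mmol/gDW/hr),
#'   `biomass_flux`, `target_flux`
#' @export
fba <- function(net, spec, lexicographic = TRUE) {
  check_spec(net, spec)
  M <- length(net$reactions)
  obj <- as.numeric(net$reactions == net$biomass)
  glc_row <- as.numeric(net$reactions == net$glucose)
  A <- rbind(net$S, glc_row)
  cl <- c(rep(0, nrow(net$S)), spec$uptake)
  res <- highs_solve1(lp_problem("max", obj, A, cl, cl, net$lb, net$ub))
  if (res$status == "infeasible") {
    stop("FBA infeasible: no steady-state flux supports the fixed uptake")
  }
  if (res$status == "unbounded") stop("FBA unbounded: biomass has no finite maximum")
  if (res$status != "optimal") stop("FBA solve failed: ", res$status)
  bmax <- res$objective
  if (bmax <= 1e-9) stop("FBA infeasible/zero growth: maximum biomass is ", bmax)
  v <- res$x
  if (lexicographic) {
    blocks <- flux_qp_blocks(net, spec, net$lb, net$ub,
                             fix = stats::setNames(bmax, net$biomass))
    qp <- solve_qp(D = diag(2, M), d = rep(0, M),
                   E = blocks$E, e = blocks$e, G = blocks$G, h = blocks$h)
    if (qp$status == "optimal") v <- qp$x
  }
  v <- stats::setNames(v, net$reactions)
  structure(list(fluxes = v,
                 biomass_flux = unname(v[net$biomass]),
                 target_flux = unname(v[net$target]),
                 status = "optimal"),
            class = "fba_fit")
}

#' @export
print.fba_fit <- function(x, ...) {
  cat("FBA wild-type: biomass", format(x$biomass_flux, digits = 6),
      "mmol/gDW/hr, target", format(x$target_flux, digits = 6),
      "mmol/gDW/hr\n")
  invisible(x)
}

#' Theoretical maximum flux of a reaction
#'
#' LP maximum of `v[rxn]` subject to mass balance, flux bounds, the fixed
#' substrate uptake, and the minimum-biomass constraint of `spec`.
#'
#' @param net a `metabolic_network`
#' @param rxn reaction id
#' @param spec a [design_spec()]
#' @return maximum flux (mmol/gDW/hr)
#' @export
flux_max <- function(net, rxn, spec) {
  check_spec(net, spec)
  if (!rxn %in% net$reactions) stop("unknown reaction: ", rxn)
  obj <- as.numeric(net$reactions == rxn)
  glc_row <- as.numeric(net$reactions == net$glucose)
  bio_row <- as.numeric(net$reactions == net$biomass)
  A <- rbind(net$S, glc_row, bio_row)
  cl <- c(rep(0, nrow(net$S)), spec$uptake, spec$min_biomass)
  cu <- c(rep(0, nrow(net$S)), spec$uptake, Inf)
  res <- highs_solve1(lp_problem("max", obj, A, cl, cu, net$lb, net$ub))
  if (res$status == "infeasible") {
    stop("flux_max infeasible: the minimum-biomass constraint cannot be met")
  }
  if (res$status != "optimal") stop("flux_max solve failed: ", res$status)
  res$objective
}

# coerce a wild-type reference (fba_fit or named vector) to a flux vector
as_flux <- function(w, net) {
  if (inherits(w, "fba_fit")) w <- w$fluxes
  if (is.null(names(w))) {
    stopifnot(length(w) == length(net$reactions))
    names(w) <- net$reactions
  }
  w[net$reactions]
}
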