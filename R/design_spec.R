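#' Culture / design conditions for a strain-design run
#'
#' Bundles the scalar parameters shared by FBA, MOMA and the bi-level
#' optimizer: the fixed substrate (glucose) uptake rate, the minimum
#' biomass flux that keeps the mutant viable, and the knockout budget.
#'
#' @param uptake fixed glucose uptake rate (mmol/gDW/hr)
#' @param min_biomass minimum biomass flux (mmol/gDW/hr), >= 0
#' @param K maximum number of knockouts, integer >= 0
#' @return an object of class `design_spec`
#' @export
design_spec <- function(uptake, min_biomass, K = 0L) {
  stopifnot(is.numeric(uptake), length(uptake) == 1L,
            is.numeric(min_biomass), min_biomass >= 0,
            is.numeric(K), K >= 0, K == round(K))
  structure(list(uptake = as.numeric(uptake),
                 min_biomass = as.numeric(min_biomass),
                 K = as.integer(K)),
            class = "design_spec")
}

#' @export
print.design_spec <- function(x, ...) {
  cat("Design conditions: uptake =", x$uptake,
      "mmol/gDW/hr, min biomass =", x$min_biomass,
      "mmol/gDW/hr, K =", x$K, "\n")
  invisible(x)
}

check_spec <- function(net, spec) {
  stopifnot(inherits(net, "metabolic_network"), inherits(spec, "design_spec"))
  g <- net$glucose
  if (spec$uptake < net$lb[[g]] - 1e-9 || spec$uptake > net$ub[[g]] + 1e-9) {
    stop("uptake rate ", spec$uptake, " outside the bounds of the glucose ",
         "reaction ", g, " [", net$lb[[g]], ", ", net$ub[[g]], "]")
  }
  invisible(TRUE)
}
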