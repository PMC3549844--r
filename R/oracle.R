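#' Brute-force bi-level reference by exhaustive enumeration
#'
#' Enumerates every candidate knockout subset of size at most `K`,
#' evaluates each with the exact optimistic MOMA QP, and returns the best.
#' This is the ground-truth oracle the adaptive MILP path is validated
#' against; it is a test instrument, not a scalable solver.
#'
#' Supersets of sets already proven lethal (MOMA-infeasible) are marked
#' infeasible without re-solving — knocking out more reactions only
#' shrinks the feasible flux set, so this pruning never changes results.
#'
#' @param net a `metabolic_network`
#' @param spec a [design_spec()]
#' @param candidates candidate reaction ids (default `net$candidates`)
#' @param K maximum subset size (default `spec$K`)
#' @param w wild-type reference (default: [fba()])
#' @param cap maximum number of subsets to enumerate
#' @return an object of class `bilevel_oracle`: `best_knockouts`,
#'   `best_value` (optimistic MOMA target flux), `table` (one row per
#'   subset: ids, status, target, biomass, adjustment)
#' @export
brute_force_bilevel <- function(net, spec = attr(net, "spec"),
                                candidates = net$candidates, K = spec$K,
                                w = NULL, cap = 20000L) {
  stopifnot(!is.null(spec))
  if (is.null(w)) w <- fba(net, spec)
  w <- as_flux(w, net)
  candidates <- sort(candidates)
  subsets <- list(character(0))
  for (k in seq_len(K)) {
    if (length(candidates) >= k) {
      cmb <- utils::combn(candidates, k, simplify = FALSE)
      subsets <- c(subsets, cmb)
    }
  }
  if (length(subsets) > cap) {
    stop("enumeration of ", length(subsets), " subsets exceeds the cap (",
         cap, "); shrink the instance or lower K")
  }
  lethal <- list()
  rows <- vector("list", length(subsets))
  for (s in seq_along(subsets)) {
    ko <- subsets[[s]]
    pruned <- any(vapply(lethal, function(l) all(l %in% ko), logical(1)))
    if (pruned) {
      rows[[s]] <- data.frame(knockouts = paste(ko, collapse = ","),
                              size = length(ko), status = "infeasible",
                              target = NA_real_, biomass = NA_real_,
                              moma_objective = NA_real_,
                              l2_distance = NA_real_,
                              stringsAsFactors = FALSE)
      next
    }
    fit <- moma(net, w, ko, spec, exclude_target = TRUE)
    if (fit$status != "optimal") lethal[[length(lethal) + 1L]] <- ko
    rows[[s]] <- data.frame(knockouts = paste(ko, collapse = ","),
                            size = length(ko), status = fit$status,
                            target = fit$target_flux,
                            biomass = fit$biomass_flux,
                            moma_objective = fit$moma_objective,
                            l2_distance = fit$l2_distance,
                            stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  feas <- which(tab$status == "optimal")
  if (!length(feas)) stop("no feasible knockout subset (wild type lethal?)")
  best <- feas[which.max(tab$target[feas])]
  best_ko <- subsets[[best]]
  structure(list(best_knockouts = sort(best_ko),
                 best_value = tab$target[best],
                 table = tab, K = K, candidates = candidates),
            class = "bilevel_oracle")
}

#' @export
print.bilevel_oracle <- function(x, ...) {
  cat("Brute-force bi-level oracle: ", nrow(x$table), " subsets (K <= ",
      x$K, ")\n  best: {",
      paste(x$best_knockouts, collapse = ", "), "} -> target ",
      format(x$best_value, digits = 8), " mmol/gDW/hr\n", sep = "")
  invisible(x)
}

# Enumeration reference for the OptKnock baseline: for every subset, the
# inner phenotype is the biomass-maximizing LP with the optimistic
# (max-target among biomass-optimal) tie-break. All LPs are batched into
# two backend calls. Test instrument only.
enumerate_optknock <- function(net, spec, candidates = net$candidates,
                               K = spec$K) {
  candidates <- sort(candidates)
  subsets <- list(character(0))
  for (k in seq_len(K)) {
    if (length(candidates) >= k) {
      subsets <- c(subsets, utils::combn(candidates, k, simplify = FALSE))
    }
  }
  glc_row <- as.numeric(net$reactions == net$glucose)
  bio_row <- as.numeric(net$reactions == net$biomass)
  A <- rbind(net$S, glc_row, bio_row)
  cl <- c(rep(0, nrow(net$S)), spec$uptake, spec$min_biomass)
  cu <- c(rep(0, nrow(net$S)), spec$uptake, Inf)
  bounds_for <- function(ko) {
    lb <- net$lb; ub <- net$ub
    lb[ko] <- 0; ub[ko] <- 0
    list(lb = lb, ub = ub)
  }
  bio_obj <- bio_row
  probs <- lapply(subsets, function(ko) {
    b <- bounds_for(ko)
    lp_problem("max", bio_obj, A, cl, cu, b$lb, b$ub)
  })
  stage1 <- highs_solve(probs)
  tgt_obj <- as.numeric(net$reactions == net$target)
  idx_ok <- which(vapply(stage1, function(r) r$status == "optimal",
                         logical(1)))
  probs2 <- lapply(idx_ok, function(s) {
    b <- bounds_for(subsets[[s]])
    A2 <- rbind(A, bio_row)
    bmax <- stage1[[s]]$objective
    lp_problem("max", tgt_obj, A2, c(cl, bmax), c(cu, bmax), b$lb, b$ub)
  })
  stage2 <- if (length(idx_ok)) highs_solve(probs2) else list()
  tab <- data.frame(knockouts = vapply(subsets, paste, "", collapse = ","),
                    size = lengths(subsets), status = "infeasible",
                    design_biomass = NA_real_, design_target = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_along(idx_ok)) {
    s <- idx_ok[k]
    if (stage2[[k]]$status == "optimal") {
      tab$status[s] <- "optimal"
      tab$design_biomass[s] <- stage1[[s]]$objective
      tab$design_target[s] <- stage2[[k]]$objective
    }
  }
  feas <- which(tab$status == "optimal")
  best <- feas[which.max(tab$design_target[feas])]
  list(best_knockouts = sort(subsets[[best]]),
       best_value = tab$design_target[best], table = tab)
}
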