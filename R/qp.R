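# Dense convex-QP wrapper around quadprog with rank-reduced equality
# handling. Stoichiometric matrices routinely carry linearly dependent rows
# (conserved moieties); quadprog rejects those, so the equality system is
# reduced to an independent subset by pivoted QR and the dropped rows are
# verified on the returned solution.

#' Solve min 1/2 x'Dx - d'x  s.t.  E x = e,  G x >= h
#'
#' @param D positive-definite quadratic term
#' @param d linear term
#' @param E,e equality system (may be rank deficient or NULL)
#' @param G,h inequality system (may be NULL)
#' @param tol feasibility tolerance for post-checking dropped equality rows
#' @return list with `status` ("optimal"/"infeasible") and `x`
#' @keywords internal
solve_qp <- function(D, d, E = NULL, e = NULL, G = NULL, h = NULL,
                     tol = 1e-7) {
  n <- length(d)
  if (!is.null(E) && nrow(E) > 0L) {
    qrE <- qr(t(E))
    r <- qrE$rank
    keep <- qrE$pivot[seq_len(r)]
  } else {
    E <- matrix(0, 0L, n); e <- numeric(0); keep <- integer(0)
  }
  Ek <- E[keep, , drop = FALSE]; ek <- e[keep]
  if (is.null(G)) { G <- matrix(0, 0L, n); h <- numeric(0) }
  Amat <- t(rbind(Ek, G))
  bvec <- c(ek, h)
  sol <- tryCatch(
    quadprog::solve.QP(D, d, Amat, bvec, meq = length(ek)),
    error = function(err) NULL)
  if (is.null(sol)) return(list(status = "infeasible", x = NULL))
  x <- sol$solution
  if (nrow(E) > length(keep)) {
    resid <- E %*% x - e
    scale <- max(1, max(abs(x)))
    if (max(abs(resid)) > tol * scale) {
      return(list(status = "infeasible", x = NULL))
    }
  }
  list(status = "optimal", x = x)
}

# Equality/inequality blocks shared by all flux QPs:
# S v = 0, v_glc = uptake, pinned variables; biomass floor and finite bounds.
flux_qp_blocks <- function(net, spec, lb, ub, fix = NULL) {
  M <- length(net$reactions)
  glc_row <- as.numeric(net$reactions == net$glucose)
  fixed <- which(ub - lb <= 0)
  E <- rbind(net$S, glc_row)
  e <- c(rep(0, nrow(net$S)), spec$uptake)
  if (length(fixed)) {
    Ef <- matrix(0, length(fixed), M)
    Ef[cbind(seq_along(fixed), fixed)] <- 1
    E <- rbind(E, Ef); e <- c(e, lb[fixed])
  }
  if (!is.null(fix) && length(fix)) {
    idx <- match(names(fix), net$reactions)
    Ef <- matrix(0, length(fix), M)
    Ef[cbind(seq_along(fix), idx)] <- 1
    E <- rbind(E, Ef); e <- c(e, as.numeric(fix))
  }
  bio_row <- as.numeric(net$reactions == net$biomass)
  free_idx <- setdiff(seq_len(M), fixed)
  G <- rbind(bio_row)
  h <- spec$min_biomass
  lo <- free_idx[is.finite(lb[free_idx])]
  if (length(lo)) {
    Gl <- matrix(0, length(lo), M); Gl[cbind(seq_along(lo), lo)] <- 1
    G <- rbind(G, Gl); h <- c(h, lb[lo])
  }
  hi <- free_idx[is.finite(ub[free_idx])]
  if (length(hi)) {
    Gh <- matrix(0, length(hi), M); Gh[cbind(seq_along(hi), hi)] <- -1
    G <- rbind(G, Gh); h <- c(h, -ub[hi])
  }
  list(E = E, e = e, G = G, h = h)
}
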