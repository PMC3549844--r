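# Piecewise linearization of the quadratic MOMA objective: each reaction
# flux is written as a convex combination of grid endpoints,
# v_j = sum_t beta_jt * v_jt with sum_t beta_jt = 1, beta >= 0, and the
# quadratic cost (v_j - w_j)^2 is replaced by its chordal overestimate
# sum_t (v_jt - w_j)^2 beta_jt (constant w^2 dropped:
# cost coefficient q_jt = v_jt^2 - 2 w_j v_jt).

#' Initial piecewise grid
#'
#' Lays `k_init` uniform segments over `[lb_j, ub_j]` for every reaction,
#' then forces `0` (the knocked-out state) and `w_j` (the wild-type flux)
#' in as endpoints so both states are exactly representable with zero
#' linearization error. Endpoints closer than `tol_merge` are merged.
#' Fixed reactions (`lb == ub`) get a single-endpoint grid and are never
#' refined.
#'
#' @param net a `metabolic_network`
#' @param w wild-type reference ([fba()] fit or named vector)
#' @param k_init number of initial uniform segments (>= 1)
#' @param tol_merge merge tolerance, as a fraction of the flux range
#' @return an object of class `pwl_grid`: named list `points` of strictly
#'   increasing endpoint vectors
#' @export
initial_grid <- function(net, w, k_init = 4L, tol_merge = 1e-9) {
  stopifnot(k_init >= 1L)
  w <- as_flux(w, net)
  points <- stats::setNames(vector("list", length(net$reactions)),
                            net$reactions)
  for (j in seq_along(net$reactions)) {
    lo <- net$lb[[j]]; hi <- net$ub[[j]]
    if (hi - lo <= 0) {
      points[[j]] <- lo
      next
    }
    pts <- seq(lo, hi, length.out = k_init + 1L)
    tol <- tol_merge * (hi - lo)
    for (extra in c(0, w[[j]])) {
      if (extra >= lo - tol && extra <= hi + tol) {
        pts <- insert_endpoint(pts, min(max(extra, lo), hi), tol)
      }
    }
    points[[j]] <- pts
  }
  structure(list(points = points), class = "pwl_grid")
}

# insert x into a sorted endpoint vector unless within tol of an existing one
insert_endpoint <- function(pts, x, tol) {
  if (min(abs(pts - x)) <= tol) return(pts)
  sort(c(pts, x))
}

#' Linearized cost coefficients for one reaction
#'
#' The chordal cost of endpoint `v` relative to wild-type flux `w` is
#' `(v - w)^2`; dropping the constant `w^2` gives `v^2 - 2 w v`, the
#' coefficient multiplying `beta` in the linearized inner problem.
#' @param v endpoint value(s)
#' @param w wild-type flux of the reaction
#' @return numeric coefficient(s), squared-flux units
#' @export
pwl_cost <- function(v, w) v^2 - 2 * w * v

#' Reconstruct fluxes from convex-combination coefficients
#'
#' @param grid a `pwl_grid`
#' @param beta named list of coefficient vectors (one per reaction,
#'   matching the grid endpoints; each sums to 1, nonnegative)
#' @return named flux vector `v_j = sum_t beta_jt v_jt`
#' @export
pwl_reconstruct <- function(grid, beta) {
  vapply(names(grid$points), function(j) {
    sum(beta[[j]] * grid$points[[j]])
  }, numeric(1))
}

#' Linearization gap per reaction
#'
#' The gap is the chordal overestimate minus the true quadratic at the
#' reconstructed flux:
#' `Delta_j = sum_t (v_jt - w_j)^2 beta_jt - (v_hat_j - w_j)^2`.
#' When `beta_j` has exactly two adjacent nonzero entries this reduces to
#' the textbook two-endpoint expression; the generalized form also covers
#' degenerate LP bases with more than two nonzeros. `Delta_j = 0` whenever
#' `beta_j` is concentrated on a single endpoint.
#'
#' @inheritParams pwl_reconstruct
#' @param w wild-type reference (named vector or [fba()] fit)
#' @return data frame with one row per reaction: `reaction`, `gap`
#'   (squared-flux units), `max_beta`, `recon` (reconstructed flux)
#' @export
pwl_gap <- function(grid, beta, w) {
  rxns <- names(grid$points)
  w <- w[rxns]
  gap <- max_beta <- recon <- numeric(length(rxns))
  for (j in seq_along(rxns)) {
    b <- beta[[rxns[j]]]
    pts <- grid$points[[rxns[j]]]
    v <- sum(b * pts)
    gap[j] <- sum((pts - w[j])^2 * b) - (v - w[j])^2
    max_beta[j] <- max(b)
    recon[j] <- v
  }
  data.frame(reaction = rxns, gap = gap, max_beta = max_beta,
             recon = recon, stringsAsFactors = FALSE)
}

#' Convergence test of the adaptive linearization
#'
#' TRUE iff every reaction's gap is below `eps` and every reaction's
#' largest convex-combination coefficient exceeds `theta` (the solution
#' sits essentially on grid endpoints, where the linearization is exact).
#' @param record a gap record from [pwl_gap()]
#' @param eps absolute gap threshold (squared-flux units)
#' @param theta concentration threshold in (0, 1)
#' @return logical
#' @export
pwl_converged <- function(record, eps, theta) {
  all(record$gap < eps & record$max_beta > theta)
}

#' Refine a grid at the reconstructed fluxes
#'
#' For every reaction failing the per-reaction convergence test
#' (`gap >= eps` or `max_beta <= theta`), the reconstructed flux is
#' inserted as a new endpoint (skipped when within `tol_merge` of an
#' existing endpoint). Bounds endpoints and single-endpoint (fixed)
#' reactions are never touched.
#'
#' @inheritParams pwl_converged
#' @param grid a `pwl_grid`
#' @param tol_merge merge tolerance, as a fraction of the flux range
#' @return list: `grid` (new `pwl_grid`), `inserted` (number of endpoints
#'   added)
#' @export
pwl_refine <- function(grid, record, eps, theta, tol_merge = 1e-9) {
  inserted <- 0L
  for (j in seq_len(nrow(record))) {
    rxn <- record$reaction[j]
    pts <- grid$points[[rxn]]
    if (length(pts) < 2L) next
    if (record$gap[j] < eps && record$max_beta[j] > theta) next
    tol <- tol_merge * (pts[length(pts)] - pts[1])
    new_pts <- insert_endpoint(pts, record$recon[j], tol)
    if (length(new_pts) > length(pts)) {
      grid$points[[rxn]] <- new_pts
      inserted <- inserted + 1L
    }
  }
  list(grid = grid, inserted = inserted)
}

#' Insert a flux vector's values as grid endpoints
#'
#' Used by the adaptive solver to make the exact inner response of the
#' incumbent design representable with zero linearization error: without
#' this, a design whose linearized solution sits entirely on existing
#' endpoints is never refined, and its chord-overestimated true response
#' can leave the claimed objective inflated.
#'
#' @param grid a `pwl_grid`
#' @param v named flux vector
#' @param skip reaction ids to leave untouched
#' @param tol_merge merge tolerance, as a fraction of the flux range
#' @return list: `grid`, `inserted`
#' @export
pwl_insert_fluxes <- function(grid, v, skip = character(), tol_merge = 1e-9) {
  inserted <- 0L
  for (rxn in names(grid$points)) {
    if (rxn %in% skip) next
    pts <- grid$points[[rxn]]
    if (length(pts) < 2L) next
    x <- v[[rxn]]
    if (is.na(x) || x < pts[1] || x > pts[length(pts)]) next
    tol <- tol_merge * (pts[length(pts)] - pts[1])
    new_pts <- insert_endpoint(pts, x, tol)
    if (length(new_pts) > length(pts)) {
      grid$points[[rxn]] <- new_pts
      inserted <- inserted + 1L
    }
  }
  list(grid = grid, inserted = inserted)
}

#' Halve every segment of a grid
#'
#' Inserts the midpoint of each segment of each (non-fixed) reaction.
#' Used by the adaptive solver to certify convergence: refining only at
#' the incumbent cannot correct a competing design whose true response is
#' overpriced by the chord approximation, while a global split shrinks
#' every chord error by a factor of four.
#' @param grid a `pwl_grid`
#' @param skip reaction ids left untouched
#' @return a refined `pwl_grid`
#' @export
split_all_segments <- function(grid, skip = character()) {
  for (rxn in names(grid$points)) {
    if (rxn %in% skip) next
    pts <- grid$points[[rxn]]
    if (length(pts) < 2L) next
    mids <- (pts[-1] + pts[-length(pts)]) / 2
    grid$points[[rxn]] <- sort(c(pts, mids))
  }
  grid
}

#' Serialize / restore a piecewise grid as TSV
#'
#' One row per reaction: the reaction id and its comma-separated endpoint
#' list. Intended for debugging and for restarting a refinement run.
#' @param grid a `pwl_grid`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_grid_tsv <- function(grid, path) {
  lines <- c("reaction\tendpoints",
             vapply(names(grid$points), function(j) {
               paste0(j, "\t", paste(format(grid$points[[j]], digits = 17),
                                     collapse = ","))
             }, ""))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_grid_tsv
#' @export
read_grid_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  points <- stats::setNames(lapply(tab$endpoints, function(s) {
    as.numeric(strsplit(s, ",")[[1]])
  }), tab$reaction)
  structure(list(points = points), class = "pwl_grid")
}

#' @export
print.pwl_grid <- function(x, ...) {
  T <- vapply(x$points, length, integer(1))
  cat("Piecewise grid: ", length(T), " reactions, ", sum(T),
      " endpoints (", min(T), "-", max(T), " per reaction)\n", sep = "")
  invisible(x)
}
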