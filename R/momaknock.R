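#' Warm-start lower bound from a previous knockout set
#'
#' The exact (QP-evaluated, optimistic) MOMA target flux of any feasible
#' knockout set is a valid lower bound on the bi-level optimum, since that
#' set is itself a feasible outer decision. Returns `-Inf` when there is
#' no previous iterate or the previous set is lethal.
#'
#' @param net a `metabolic_network`
#' @param w wild-type reference
#' @param prev_knockouts reaction ids from the previous iteration (or NULL)
#' @param spec a [design_spec()]
#' @return scalar lower bound on the target flux (mmol/gDW/hr), or `-Inf`
#' @export
warm_bound <- function(net, w, prev_knockouts, spec) {
  if (is.null(prev_knockouts)) return(-Inf)
  fit <- moma(net, w, prev_knockouts, spec, exclude_target = TRUE)
  if (fit$status != "optimal") return(-Inf)
  fit$target_flux
}

#' Bi-level knockout design under the MOMA phenotype
#'
#' Finds up to `K` reaction knockouts maximizing the target flux when the
#' mutant flux distribution is the MOMA response (the feasible flux vector
#' closest, in squared Euclidean distance, to the wild-type reference).
#' The inner quadratic program is linearized piecewise, the resulting
#' linear bi-level program is collapsed to a single-level MILP via LP
#' strong duality, and the linearization is refined adaptively at the
#' incumbent fluxes until it is exact at the solution: every linearization
#' gap below `eps` and every convex-combination vector concentrated on a
#' single endpoint (`max beta > theta`). Each iteration warm-starts the
#' MILP with the exact MOMA value of the previous knockout set as a valid
#' lower-bound cut.
#'
#' @param net a `metabolic_network`
#' @param K knockout budget (overrides `spec$K`)
#' @param spec a [design_spec()]; defaults to the conditions attached to a
#'   [toy_network()]
#' @param w wild-type reference; defaults to [fba()] under `spec`
#' @param k_init initial uniform segments per reaction
#' @param eps gap threshold (squared-flux units); default
#'   `1e-6 * (1 + ||w||_2^2)`
#' @param theta concentration threshold, close to 1
#' @param M_val big-M constant (default: automatic, with post-solve audit)
#' @param max_iter refinement iteration cap
#' @param tol_obj objective-stall tolerance; default
#'   `1e-6 * (1 + |objective|)`
#' @param seed_grid seed the initial grid with the exact MOMA response
#'   of every single-candidate deletion (one QP each); a design whose
#'   response is representable is never under-priced by the chord
#'   overestimate, so this anchors the search (default TRUE)
#' @param verify_rounds maximum global grid splits used to certify
#'   convergence: refining only at the incumbent can leave a competing
#'   design undervalued by the chord overestimate, so on apparent
#'   convergence every segment is halved and the problem re-solved until
#'   no design claims a higher value (0 disables verification)
#' @param mip_gap relative MIP gap passed to the solver
#' @param seed accepted for interface uniformity; the backend is
#'   deterministic
#' @return an object of class `momaknock`: `knockouts`, `objective` (MILP
#'   outer target flux), `moma` (exact-QP re-evaluation, a `moma_fit`),
#'   `wild_type` (`fba_fit`), `trace` (per-iteration data frame),
#'   `converged`, `status`, `spec`
#' @export
momaknock <- function(net, K = NULL, spec = attr(net, "spec"), w = NULL,
                      k_init = 4L, eps = NULL, theta = 0.999,
                      M_val = NULL, max_iter = 50L, tol_obj = NULL,
                      verify_rounds = 6L, seed_grid = TRUE,
                      mip_gap = 1e-9, seed = NULL) {
  if (is.null(spec)) stop("no design_spec: pass `spec` or use a network ",
                          "with an attached one")
  if (!is.null(K)) spec$K <- as.integer(K)
  check_spec(net, spec)
  if (is.null(w)) w <- fba(net, spec)
  wt <- if (inherits(w, "fba_fit")) w else NULL
  w <- as_flux(w, net)
  if (is.null(eps)) eps <- 1e-6 * (1 + sum(w^2))

  grid <- initial_grid(net, w, k_init)
  if (seed_grid) {
    # response seeding: the exact MOMA response of each single deletion is
    # made representable up front. A design whose response is on the grid
    # can never be under-valued by the chord overestimate, so every
    # single-knockout design is priced at least at its true value from
    # the first MILP solve.
    for (j in net$candidates) {
      fit_j <- moma(net, w, j, spec, exclude_target = TRUE)
      if (fit_j$status == "optimal") {
        grid <- pwl_insert_fluxes(grid, fit_j$fluxes)$grid
      }
    }
  }
  prev_knockouts <- NULL
  prev_obj <- NA_real_
  objL <- -Inf
  best <- NULL
  evaluation <- NULL
  # the empty design is always feasible when the wild type is: it seeds
  # the incumbent (ties later resolve toward the smaller adjustment) and
  # its exact value is a valid first warm-start bound
  ev0 <- moma(net, w, character(), spec, exclude_target = TRUE)
  if (ev0$status == "optimal") {
    best <- list(knockouts = character(), value = ev0$target_flux,
                 fit = ev0)
    objL <- ev0$target_flux
  }
  stall_count <- 0L
  stall_patience <- 5L
  pending_verify <- FALSE
  verify_obj <- NA_real_
  verify_used <- 0L
  sol <- NULL
  record <- NULL
  trace <- list()
  status <- "max_iter"

  for (iter in seq_len(max_iter)) {
    model <- assemble_milp(net, w, grid, spec, M_val = M_val,
                           objL = if (is.finite(objL)) objL else NULL)
    sol <- solve_bilevel_milp(model, mip_gap = mip_gap, seed = seed)
    cut_dropped <- FALSE
    if (sol$status != "optimal" && is.finite(objL)) {
      # a coarse linearization can price the true lower bound as
      # unattainable; retry without the cut rather than aborting
      model <- assemble_milp(net, w, grid, spec, M_val = M_val)
      sol <- solve_bilevel_milp(model, mip_gap = mip_gap, seed = seed)
      cut_dropped <- TRUE
    }
    if (sol$status != "optimal") {
      stop("bi-level MILP not solved (status: ", sol$status,
           "); big-M audit: ",
           if (is.null(sol$audit)) "unavailable" else
             paste0("M = ", sol$audit$M_val))
    }
    # exact inner response of the incumbent design: supplies the
    # warm-start bound, the convergence certificate, and extra
    # refinement points
    evaluation <- moma(net, w, sol$knockouts, spec, exclude_target = TRUE)
    tol_tie <- 1e-9 * (1 + abs(evaluation$target_flux))
    if (evaluation$status == "optimal" &&
        (is.null(best) ||
         evaluation$target_flux > best$value + tol_tie ||
         (abs(evaluation$target_flux - best$value) <= tol_tie &&
          evaluation$l2_distance < best$fit$l2_distance - 1e-12))) {
      best <- list(knockouts = sol$knockouts,
                   value = evaluation$target_flux, fit = evaluation)
    }
    record <- pwl_gap(grid, sol$beta, w)
    inner <- record[record$reaction != net$target, ]
    obj_match <- evaluation$status == "optimal" &&
      abs(sol$objective - evaluation$target_flux) <=
        1e-6 * (1 + abs(sol$objective))
    conv <- pwl_converged(inner, eps, theta) && obj_match
    trace[[iter]] <- data.frame(
      iter = iter, milp_objective = sol$objective,
      exact_value = evaluation$target_flux,
      max_gap = max(inner$gap), min_max_beta = min(inner$max_beta),
      endpoints = sum(vapply(grid$points, length, integer(1))),
      objL = objL, cut_dropped = cut_dropped,
      knockouts = paste(sort(sol$knockouts), collapse = ","),
      stringsAsFactors = FALSE)
    if (conv) {
      if (pending_verify &&
          abs(sol$objective - verify_obj) <=
            1e-6 * (1 + abs(sol$objective))) {
        status <- "converged"; break
      }
      if (verify_used >= verify_rounds) {
        status <- if (verify_rounds > 0L) "verify_limit" else "converged"
        break
      }
      # certification: halve every segment so no competing design stays
      # undervalued by the chord overestimate, then re-solve
      grid <- split_all_segments(grid, skip = net$target)
      pending_verify <- TRUE
      verify_obj <- sol$objective
      verify_used <- verify_used + 1L
      objL <- max(objL, evaluation$target_flux, na.rm = TRUE)
      prev_knockouts <- sol$knockouts
      prev_obj <- sol$objective
      next
    }
    pending_verify <- FALSE
    # stall safeguard: refinement no longer moves the objective or the
    # incumbent design for several consecutive iterations
    stalled <- !is.na(prev_obj) &&
      abs(sol$objective - prev_obj) <
        (tol_obj %||% (1e-6 * (1 + abs(sol$objective)))) &&
      identical(sort(sol$knockouts), sort(prev_knockouts %||% character()))
    stall_count <- if (stalled) stall_count + 1L else 0L
    if (stall_count >= stall_patience) { status <- "objective_stalled"; break }
    # refine both at the linearized solution (textbook rule) and at the
    # exact inner response of the incumbent design
    ref <- pwl_refine(grid, inner, eps, theta)
    grid <- ref$grid
    inserted <- ref$inserted
    if (evaluation$status == "optimal") {
      ref2 <- pwl_insert_fluxes(grid, evaluation$fluxes)
      grid <- ref2$grid
      inserted <- inserted + ref2$inserted
    }
    if (inserted == 0L) { status <- "no_refinement"; break }
    objL <- max(objL, evaluation$target_flux, na.rm = TRUE)
    prev_knockouts <- sol$knockouts
    prev_obj <- sol$objective
  }

  # report the incumbent with the best exact MOMA value seen; ties go to
  # the smaller flux adjustment (the MOMA philosophy)
  if (!is.null(best) &&
      (evaluation$status != "optimal" ||
       best$value > evaluation$target_flux + 1e-12 ||
       (abs(best$value - evaluation$target_flux) <=
          1e-9 * (1 + abs(best$value)) &&
        best$fit$l2_distance < evaluation$l2_distance - 1e-12))) {
    sol$knockouts <- best$knockouts
    sol$objective <- best$value
    evaluation <- best$fit
  }
  structure(list(
    knockouts = sort(sol$knockouts),
    objective = sol$objective,
    moma = evaluation,
    wild_type = wt %||% structure(
      list(fluxes = w, biomass_flux = unname(w[net$biomass]),
           target_flux = unname(w[net$target]), status = "supplied"),
      class = "fba_fit"),
    gap_record = record,
    trace = do.call(rbind, trace),
    converged = status == "converged",
    status = status,
    eps = eps, theta = theta,
    spec = spec, net = net),
    class = "momaknock")
}

#' @export
print.momaknock <- function(x, ...) {
  cat("MOMA bi-level knockout design (K = ", x$spec$K, ")\n", sep = "")
  cat("  knockouts: ",
      if (length(x$knockouts)) paste(x$knockouts, collapse = ", ")
      else "(none)", "\n", sep = "")
  cat("  target flux (MILP outer): ", format(x$objective, digits = 6),
      " mmol/gDW/hr\n", sep = "")
  if (x$moma$status == "optimal") {
    cat("  exact MOMA re-evaluation: target ",
        format(x$moma$target_flux, digits = 6), ", biomass ",
        format(x$moma$biomass_flux, digits = 6), ", ||v-w||_2 = ",
        format(x$moma$l2_distance, digits = 6), "\n", sep = "")
  }
  cat("  ", nrow(x$trace), " iteration(s), status: ", x$status, "\n", sep = "")
  invisible(x)
}

#' @export
summary.momaknock <- function(object, ...) {
  structure(list(fit = object), class = "summary.momaknock")
}

#' @export
print.summary.momaknock <- function(x, ...) {
  print(x$fit)
  cat("\nIteration trace:\n")
  print(x$fit$trace[, c("iter", "milp_objective", "max_gap",
                        "endpoints", "objL", "knockouts")],
        row.names = FALSE)
  wt <- x$fit$wild_type
  cat("\nWild type: biomass ", format(wt$biomass_flux, digits = 6),
      ", target ", format(wt$target_flux, digits = 6), " mmol/gDW/hr\n",
      sep = "")
  invisible(x)
}

#' Knockout decisions of a fitted design
#'
#' @param object a `momaknock` fit
#' @param ... unused
#' @return named 0/1 vector over candidate reactions (0 = knocked out)
#' @export
coef.momaknock <- function(object, ...) {
  y <- stats::setNames(rep(1, length(object$net$candidates)),
                       object$net$candidates)
  y[object$knockouts] <- 0
  y
}

#' Predicted mutant fluxes of a fitted design
#'
#' @param object a `momaknock` fit
#' @param ... unused
#' @return named MOMA flux vector of the designed strain (mmol/gDW/hr)
#' @export
fitted.momaknock <- function(object, ...) object$moma$fluxes

#' Flux adjustment of the designed strain
#'
#' @param object a `momaknock` fit
#' @param ... unused
#' @return `v - w`: per-reaction deviation of the mutant MOMA fluxes from
#'   the wild-type reference
#' @export
residuals.momaknock <- function(object, ...) {
  object$moma$fluxes - object$wild_type$fluxes
}

#' Convergence trace of the adaptive linearization
#'
#' Plots the MILP outer objective and the worst per-reaction
#' linearization gap against the refinement iteration.
#' @param x a `momaknock` fit
#' @param ... passed to [graphics::plot()]
#' @export
plot.momaknock <- function(x, ...) {
  tr <- x$trace
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(tr$iter, tr$milp_objective, type = "b", pch = 19,
                 xlab = "iteration", ylab = "target flux (mmol/gDW/hr)",
                 main = "MILP outer objective", ...)
  graphics::plot(tr$iter, pmax(tr$max_gap, .Machine$double.xmin),
                 type = "b", pch = 19, log = "y",
                 xlab = "iteration", ylab = "max linearization gap",
                 main = "Adaptive refinement", ...)
  invisible(x)
}
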