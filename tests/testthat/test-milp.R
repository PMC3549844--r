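test_that("wild-type representation satisfies the primal block", {
  fx <- toy_fixture(6, 1)
  grid <- initial_grid(fx$net, fx$w, k_init = 3)
  lp <- linearized_inner_lp(fx$net, fx$w$fluxes, grid, fx$spec)
  expect_identical(lp$status, "optimal")
  # with w on the grid the linearized minimum is exactly -||w||^2
  # restricted to the inner-objective reactions (cost + w^2 = 0 at w)
  w <- fx$w$fluxes
  mask <- fx$net$reactions != fx$net$target
  expect_equal(lp$objective, -sum(w[mask]^2), tolerance = 1e-6)
  expect_lt(max(abs(fx$net$S %*% lp$fluxes)), 1e-6)
})

test_that("a zeroed knockout decision forces zero flux in beta space", {
  fx <- toy_fixture(6, 1)
  grid <- initial_grid(fx$net, fx$w, k_init = 3)
  ko <- fx$net$candidates[1]
  y <- stats::setNames(rep(1, length(fx$net$candidates)),
                       fx$net$candidates)
  y[ko] <- 0
  lp <- linearized_inner_lp(fx$net, fx$w$fluxes, grid, fx$spec, y)
  if (lp$status == "optimal") {
    expect_equal(unname(lp$fluxes[ko]), 0, tolerance = 1e-8)
  } else {
    expect_identical(lp$status, "infeasible")
  }
})

test_that("fixed-y primal and dual LP optima coincide (strong duality)", {
  cases <- batched_duality_cases(12, seed = 5)
  solved <- cases$primal_status == "optimal"
  expect_gt(sum(solved), 6)
  for (i in which(solved)) {
    expect_identical(cases$dual_status[i], "optimal")
    expect_equal(cases$primal[i], cases$dual[i],
                 tolerance = 1e-6 * (1 + abs(cases$primal[i])))
  }
  # an infeasible primal (lethal y) must not have a bounded dual optimum
  # equal to anything -- just check statuses are consistent
  for (i in which(!solved)) {
    expect_true(cases$dual_status[i] %in% c("unbounded", "optimal",
                                            "infeasible"))
  }
})

test_that("target dual rows carry zero cost and symmetric duals exist", {
  fx <- toy_fixture(6, 2)
  grid <- initial_grid(fx$net, fx$w, k_init = 2)
  lay <- momaknock:::milp_layout(fx$net, fx$w$fluxes, grid, fx$spec)
  expect_true(all(lay$qs[[fx$net$target]] == 0))
  # every non-target reaction pays v^2 - 2wv at its endpoints
  j <- setdiff(lay$rxns, fx$net$target)[1]
  expect_equal(lay$qs[[j]],
               pwl_cost(grid$points[[j]], fx$w$fluxes[[j]]))
})

test_that("model dimensions match the closed-form audit", {
  fx <- toy_fixture(7, 3)
  grid <- initial_grid(fx$net, fx$w, k_init = 4)
  model <- assemble_milp(fx$net, fx$w$fluxes, grid, fx$spec)
  lay <- model$layout
  sumT <- sum(vapply(grid$points, length, integer(1)))
  nc <- length(fx$net$candidates)
  M <- length(fx$net$reactions); N <- length(fx$net$metabolites)
  dims <- milp_dims(model)
  expect_equal(dims$n_var, sumT + 3 * M + N + 3 * nc + 2)
  expect_equal(dims$n_row,
               M + N + 2 + 2 * M + sumT + 1 + 8 * nc + (nc > 0))
  # an objL cut adds exactly one row
  model2 <- assemble_milp(fx$net, fx$w$fluxes, grid, fx$spec, objL = 0)
  expect_equal(milp_dims(model2)$n_row, dims$n_row + 1)
})

test_that("big-M rows force e = c*y at both binary values", {
  # scalar check of the four-row gadget
  M_val <- 50
  gadget <- function(y, c_val, e_val) {
    all(e_val <= M_val * y + 1e-12, e_val >= -M_val * y - 1e-12,
        e_val <= c_val + M_val * (1 - y) + 1e-12,
        e_val >= c_val - M_val * (1 - y) - 1e-12)
  }
  expect_true(gadget(1, 7, 7))
  expect_false(gadget(1, 7, 0))
  expect_true(gadget(0, 7, 0))
  expect_false(gadget(0, 7, 7))
})

test_that("solved MILP passes duality, product and balance audits", {
  fx <- toy_fixture(6, 1)
  spec <- fx$spec; spec$K <- 1L
  grid <- initial_grid(fx$net, fx$w, k_init = 3)
  model <- assemble_milp(fx$net, fx$w$fluxes, grid, spec)
  sol <- solve_bilevel_milp(model)
  expect_identical(sol$status, "optimal")
  expect_true(sol$audit$duality_ok)
  expect_true(sol$audit$bigM_ok)
  expect_lt(sol$audit$product_residual, 1e-5)
  expect_lt(sol$audit$convexity_residual, 1e-6)
  expect_lt(sol$audit$balance_residual, 1e-5)
  expect_lte(sum(sol$y == 0), spec$K)
})

test_that("K = 0 restriction equals the wild-type optimistic evaluation", {
  fx <- toy_fixture(6, 2)
  spec <- fx$spec; spec$K <- 0L
  grid <- initial_grid(fx$net, fx$w, k_init = 3)
  model <- assemble_milp(fx$net, fx$w$fluxes, grid, spec)
  sol <- solve_bilevel_milp(model)
  expect_identical(sol$status, "optimal")
  expect_length(sol$knockouts, 0)
  ref <- moma(fx$net, fx$w, character(), spec, exclude_target = TRUE)
  expect_equal(sol$objective, ref$target_flux,
               tolerance = 1e-5 * (1 + abs(ref$target_flux)))
})

test_that("a lower-bound cut above the optimum makes the MILP infeasible", {
  fx <- toy_fixture(6, 1)
  spec <- fx$spec; spec$K <- 1L
  grid <- initial_grid(fx$net, fx$w, k_init = 3)
  base <- solve_bilevel_milp(assemble_milp(fx$net, fx$w$fluxes, grid, spec))
  cut <- assemble_milp(fx$net, fx$w$fluxes, grid, spec,
                       objL = base$objective + 10)
  res <- solve_bilevel_milp(cut)
  expect_identical(res$status, "infeasible")
})

test_that("repeated solves of one instance are identical", {
  fx <- toy_fixture(6, 3)
  spec <- fx$spec; spec$K <- 1L
  grid <- initial_grid(fx$net, fx$w, k_init = 3)
  model <- assemble_milp(fx$net, fx$w$fluxes, grid, spec)
  s1 <- solve_bilevel_milp(model, seed = 1)
  s2 <- solve_bilevel_milp(model, seed = 1)
  expect_equal(s1$objective, s2$objective)
  expect_identical(s1$knockouts, s2$knockouts)
})
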