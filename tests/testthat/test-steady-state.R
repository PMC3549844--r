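# boot::simplex works on x >= 0, so flux LPs are shifted by their finite
# lower bounds: x = v - lb. Used as the independent LP oracle.
simplex_flux_lp <- function(net, spec, objective_rxn, extra_floor = TRUE) {
  S <- net$S
  lb <- net$lb; ub <- net$ub
  shift <- as.numeric(S %*% lb)
  obj <- as.numeric(net$reactions == objective_rxn)
  glc <- as.numeric(net$reactions == net$glucose)
  bio <- as.numeric(net$reactions == net$biomass)
  A3 <- rbind(S, glc)
  b3 <- c(-shift, spec$uptake - lb[net$glucose])
  A1 <- diag(length(lb))           # x <= ub - lb
  b1 <- ub - lb
  if (extra_floor) {
    A2 <- rbind(bio); b2 <- spec$min_biomass - lb[net$biomass]
    fit <- boot::simplex(obj, A1 = A1, b1 = b1, A2 = A2, b2 = b2,
                         A3 = A3, b3 = b3, maxi = TRUE)
  } else {
    fit <- boot::simplex(obj, A1 = A1, b1 = b1, A3 = A3, b3 = b3,
                         maxi = TRUE)
  }
  stopifnot(fit$solved == 1)
  unname(fit$value) + lb[[objective_rxn]]
}

test_that("FBA biomass equals an independent simplex solve", {
  skip_if_not_installed("boot")
  for (s in 1:3) {
    fx <- toy_fixture(6 + s, seed = s)
    ref <- simplex_flux_lp(fx$net, fx$spec, fx$net$biomass,
                           extra_floor = FALSE)
    expect_equal(fx$w$biomass_flux, ref, tolerance = 1e-7)
  }
})

test_that("FBA degeneracy resolution returns the minimum-norm optimum", {
  fx <- toy_fixture(8, 2)
  raw <- fba(fx$net, fx$spec, lexicographic = FALSE)
  lex <- fba(fx$net, fx$spec, lexicographic = TRUE)
  expect_equal(lex$biomass_flux, raw$biomass_flux, tolerance = 1e-7)
  expect_lte(sum(lex$fluxes^2), sum(raw$fluxes^2) + 1e-6)
})

test_that("blocked biomass pathway raises an informative error", {
  net <- hand_network()
  net$ub["Rb"] <- 0
  expect_error(fba(net, hand_spec()), "zero growth|infeasible")
})

test_that("theoretical flux maximum matches the independent LP oracle", {
  skip_if_not_installed("boot")
  for (s in 1:3) {
    fx <- toy_fixture(6 + s, seed = s)
    got <- flux_max(fx$net, fx$net$target, fx$spec)
    ref <- simplex_flux_lp(fx$net, fx$spec, fx$net$target)
    expect_equal(got, ref, tolerance = 1e-7)
  }
})

test_that("MOMA with no knockouts reproduces the wild type exactly", {
  fx <- toy_fixture(6, 1)
  fit <- moma(fx$net, fx$w, character(), fx$spec, exclude_target = FALSE)
  expect_equal(fit$moma_objective, 0, tolerance = 1e-8)
  expect_equal(max(abs(fit$fluxes - fx$w$fluxes)), 0, tolerance = 1e-8)
})

test_that("MOMA QP optimum matches an independent SLSQP solve", {
  fx <- toy_fixture(6, 1)
  # use the first candidate whose deletion is viable
  for (ko in fx$net$candidates) {
    fit <- moma(fx$net, fx$w, ko, fx$spec, exclude_target = FALSE)
    if (fit$status == "optimal") break
  }
  expect_identical(fit$status, "optimal")

  payload <- list(S = unname(fx$net$S), lb = unname(fx$net$lb),
                  ub = unname(fx$net$ub), w = unname(fx$w$fluxes),
                  glc = match(fx$net$glucose, fx$net$reactions),
                  bio = match(fx$net$biomass, fx$net$reactions),
                  ko = match(ko, fx$net$reactions),
                  uptake = fx$spec$uptake, bmin = fx$spec$min_biomass)
  fin <- withr::local_tempfile(fileext = ".json")
  fout <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(payload, fin, auto_unbox = TRUE, digits = NA)
  script <- "
import json, sys
import numpy as np
from scipy.optimize import minimize
p = json.load(open(sys.argv[1]))
S = np.array(p['S']); w = np.array(p['w'])
lb = np.array(p['lb'], float); ub = np.array(p['ub'], float)
ko = p['ko'] - 1; lb[ko] = 0.0; ub[ko] = 0.0
glc = p['glc'] - 1; bio = p['bio'] - 1
cons = [
  {'type': 'eq', 'fun': lambda v: S @ v},
  {'type': 'eq', 'fun': lambda v: v[glc] - p['uptake']},
  {'type': 'ineq', 'fun': lambda v: v[bio] - p['bmin']},
]
x0 = np.clip(w, lb, ub)
res = minimize(lambda v: np.sum((v - w)**2), x0, method='SLSQP',
               bounds=list(zip(lb, ub)), constraints=cons,
               options={'maxiter': 500, 'ftol': 1e-12})
json.dump({'obj': float(res.fun)}, open(sys.argv[2], 'w'))
"
  sf <- withr::local_tempfile(fileext = ".py")
  writeLines(script, sf)
  out <- system2(Sys.which("python"), c(sf, fin, fout),
                 stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(fout))
  ref <- jsonlite::read_json(fout)$obj
  expect_equal(fit$moma_objective, ref,
               tolerance = 1e-6 * (1 + abs(ref)))
})

test_that("MOMA optimum is no worse than random feasible points", {
  fx <- toy_fixture(7, 2)
  for (ko in fx$net$candidates) {
    fit <- moma(fx$net, fx$w, ko, fx$spec, exclude_target = FALSE)
    if (fit$status == "optimal") break
  }
  expect_identical(fit$status, "optimal")
  # vertices of the knockout polytope from random LP objectives, plus
  # their convex combinations, are feasible comparison points
  lb <- fx$net$lb; ub <- fx$net$ub
  lb[ko] <- 0; ub[ko] <- 0
  glc <- as.numeric(fx$net$reactions == fx$net$glucose)
  bio <- as.numeric(fx$net$reactions == fx$net$biomass)
  A <- rbind(fx$net$S, glc, bio)
  cl <- c(rep(0, nrow(fx$net$S)), fx$spec$uptake, fx$spec$min_biomass)
  cu <- c(rep(0, nrow(fx$net$S)), fx$spec$uptake, Inf)
  set.seed(7)
  probs <- lapply(1:6, function(i) {
    momaknock:::lp_problem("max", rnorm(length(lb)), A, cl, cu, lb, ub)
  })
  res <- momaknock:::highs_solve(probs)
  pts <- lapply(Filter(function(r) r$status == "optimal", res),
                function(r) r$x)
  expect_gt(length(pts), 0)
  for (v in pts) {
    expect_lte(fit$moma_objective, sum((v - fx$w$fluxes)^2) + 1e-7)
  }
  mix <- Reduce(`+`, pts) / length(pts)
  expect_lte(fit$moma_objective, sum((mix - fx$w$fluxes)^2) + 1e-7)
})

test_that("lethal designs report infeasible status instead of erroring", {
  net <- hand_network()
  spec <- hand_spec()
  w <- fba(net, spec)
  fit <- moma(net, w, "R1", spec)      # sole route from substrate
  expect_identical(fit$status, "infeasible")
  expect_true(is.na(fit$target_flux))
})

test_that("returned fluxes satisfy mass balance and knockout bounds", {
  fx <- toy_fixture(8, 4)
  for (ko in list(character(), fx$net$candidates[1])) {
    fit <- moma(fx$net, fx$w, ko, fx$spec)
    if (fit$status != "optimal") next
    v <- fit$fluxes
    expect_lt(max(abs(fx$net$S %*% v)), 1e-6 * max(1, max(abs(v))))
    if (length(ko)) expect_equal(unname(v[ko]), 0, tolerance = 1e-8)
  }
})
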