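test_that("warm bound is the exact value of the previous design", {
  fx <- toy_fixture(6, 1)
  spec <- fx$spec; spec$K <- 1L
  expect_identical(warm_bound(fx$net, fx$w, NULL, spec), -Inf)
  wtval <- moma(fx$net, fx$w, character(), spec)$target_flux
  expect_equal(warm_bound(fx$net, fx$w, character(), spec), wtval)
  # lethal previous set falls back to the sentinel
  net <- hand_network()
  w <- fba(net, hand_spec())
  expect_identical(warm_bound(net, w, "R1", hand_spec(1L)), -Inf)
})

test_that("K = 0 returns the empty design at the wild-type value", {
  fx <- toy_fixture(6, 2)
  fit <- momaknock(fx$net, K = 0, spec = fx$spec, w = fx$w)
  expect_length(fit$knockouts, 0)
  ref <- moma(fx$net, fx$w, character(), fx$spec)
  expect_equal(fit$objective, ref$target_flux,
               tolerance = 1e-5 * (1 + abs(ref$target_flux)))
})

test_that("adaptive MILP path equals brute-force enumeration", {
  for (s in c(1, 8, 10)) {
    n <- 6 + (s %% 5)
    fx <- toy_fixture(n, s)
    K <- 1 + (s %% 2)
    orc <- brute_force_bilevel(fx$net, fx$spec, K = K, w = fx$w)
    fit <- momaknock(fx$net, K = K, spec = fx$spec, w = fx$w)
    expect_equal(fit$moma$target_flux, orc$best_value,
                 tolerance = 1e-5 * max(1, abs(orc$best_value)))
    expect_lte(length(fit$knockouts), K)
  }
})

test_that("trace records monotone endpoint growth and the warm bound", {
  fx <- toy_fixture(7, 1)
  fit <- momaknock(fx$net, K = 2, spec = fx$spec, w = fx$w)
  tr <- fit$trace
  expect_true(all(diff(tr$endpoints) >= 0))
  expect_true(all(is.finite(tr$milp_objective)))
  if (nrow(tr) > 1) {
    # once finite, the warm bound never regresses
    ob <- tr$objL[is.finite(tr$objL)]
    if (length(ob) > 1) expect_true(all(diff(ob) >= -1e-9))
  }
  # the final exact value is at least the last finite warm bound
  last_bound <- tr$objL[nrow(tr)]
  if (is.finite(last_bound)) {
    expect_gte(fit$moma$target_flux, last_bound - 1e-6)
  }
})

test_that("convergence certificate holds at termination", {
  fx <- toy_fixture(8, 4)
  fit <- momaknock(fx$net, K = 1, spec = fx$spec, w = fx$w)
  expect_identical(fit$status, "converged")
  inner <- fit$gap_record[fit$gap_record$reaction != fx$net$target, ]
  expect_true(all(inner$gap < fit$eps))
  expect_true(all(inner$max_beta > fit$theta))
  expect_equal(fit$moma$target_flux, fit$objective,
               tolerance = 1e-5 * (1 + abs(fit$objective)))
})

test_that("runs are reproducible", {
  fx <- toy_fixture(6, 3)
  f1 <- momaknock(fx$net, K = 1, spec = fx$spec, w = fx$w, seed = 7)
  f2 <- momaknock(fx$net, K = 1, spec = fx$spec, w = fx$w, seed = 7)
  expect_identical(f1$knockouts, f2$knockouts)
  expect_equal(f1$objective, f2$objective)
})

test_that("fit methods expose decisions, fluxes and adjustments", {
  fx <- toy_fixture(6, 1)
  fit <- momaknock(fx$net, K = 1, spec = fx$spec, w = fx$w)
  y <- coef(fit)
  expect_setequal(names(y), fx$net$candidates)
  expect_equal(sum(y == 0), length(fit$knockouts))
  expect_equal(unname(y[fit$knockouts]), rep(0, length(fit$knockouts)))
  v <- fitted(fit)
  expect_equal(unname(v[fit$knockouts]), rep(0, length(fit$knockouts)),
               tolerance = 1e-8)
  r <- residuals(fit)
  expect_equal(r, fitted(fit) - fx$w$fluxes)
  expect_output(print(fit), "knockouts")
  expect_output(print(summary(fit)), "Iteration trace")
})
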