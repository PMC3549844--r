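test_that("initial grid construction forces bounds, zero and wild type", {
  net <- hand_network()
  w <- stats::setNames(rep(0, 6), net$reactions)
  w["R1"] <- 3
  net$lb["R1"] <- -10; net$ub["R1"] <- 10
  grid <- initial_grid(net, w, k_init = 2)
  expect_equal(grid$points[["R1"]], c(-10, 0, 3, 10))

  # lb = 0, w = 0, one segment: endpoints collapse to {0, ub}
  net2 <- hand_network()
  w2 <- stats::setNames(rep(0, 6), net2$reactions)
  g2 <- initial_grid(net2, w2, k_init = 1)
  expect_equal(g2$points[["R1"]], c(0, 100))

  # first/last endpoints are always the bounds
  fx <- toy_fixture(7, 3)
  g3 <- initial_grid(fx$net, fx$w, k_init = 4)
  for (j in fx$net$reactions) {
    pts <- g3$points[[j]]
    expect_equal(pts[1], unname(fx$net$lb[j]))
    expect_equal(pts[length(pts)], unname(fx$net$ub[j]))
    expect_true(all(diff(pts) > 0))
  }
})

test_that("linearized cost coefficients follow v^2 - 2wv", {
  expect_equal(pwl_cost(3, 3), -9)     # exact at the wild-type point
  expect_equal(pwl_cost(0, 5), 0)      # zero endpoint always costs zero
  expect_equal(pwl_cost(2, 0), 4)
  v <- seq(-5, 5, by = 0.5); w <- 1.3
  expect_equal(pwl_cost(v, w) + w^2, (v - w)^2)
})

test_that("reconstruction is the convex combination of endpoints", {
  net <- hand_network()
  w <- stats::setNames(rep(0, 6), net$reactions)
  grid <- initial_grid(net, w, k_init = 2)
  beta <- lapply(grid$points, function(pts) {
    b <- numeric(length(pts)); b[1] <- 1; b
  })
  v <- pwl_reconstruct(grid, beta)
  expect_equal(unname(v), unname(vapply(grid$points, `[[`, 0, 1)))

  beta2 <- lapply(grid$points, function(pts) rep(1 / length(pts), length(pts)))
  v2 <- pwl_reconstruct(grid, beta2)
  expect_true(all(v2 >= net$lb[names(v2)] - 1e-12))
  expect_true(all(v2 <= net$ub[names(v2)] + 1e-12))

  g1 <- list(points = list(r = c(0, 2)))
  class(g1) <- "pwl_grid"
  expect_equal(unname(pwl_reconstruct(g1, list(r = c(0.5, 0.5)))), 1)
})

test_that("gap formula: two-endpoint arithmetic and degenerate cases", {
  g <- structure(list(points = list(r = c(0, 2))), class = "pwl_grid")
  w <- c(r = 0)
  # chord at midpoint: (0*0.5 + 4*0.5) - 1^2 = 1
  rec <- pwl_gap(g, list(r = c(0.5, 0.5)), w)
  expect_equal(rec$gap, 1)
  # concentrated beta has zero gap
  rec0 <- pwl_gap(g, list(r = c(1, 0)), w)
  expect_equal(rec0$gap, 0)
})

test_that("gap equals linearized-minus-quadratic at the reconstruction", {
  set.seed(11)
  fx <- toy_fixture(6, 2)
  grid <- initial_grid(fx$net, fx$w, k_init = 3)
  w <- fx$w$fluxes
  for (rep in 1:20) {
    beta <- adjacent_beta(grid)
    rec <- pwl_gap(grid, beta, w)
    for (j in seq_along(grid$points)) {
      rxn <- names(grid$points)[j]
      pts <- grid$points[[rxn]]
      wj <- w[[rxn]]
      lin <- sum((pts - wj)^2 * beta[[rxn]])
      vhat <- sum(pts * beta[[rxn]])
      expect_equal(rec$gap[rec$reaction == rxn],
                   lin - (vhat - wj)^2, tolerance = 1e-10)
    }
  }
})

test_that("chord overestimate property on random grids and coefficients", {
  set.seed(23)
  for (rep in 1:40) {
    pts <- sort(stats::runif(sample(2:6, 1), -10, 10))
    if (length(unique(pts)) < length(pts)) next
    w <- stats::runif(1, -10, 10)
    b <- stats::rexp(length(pts)); b <- b / sum(b)
    lin <- sum((pts - w)^2 * b)
    vhat <- sum(pts * b)
    expect_gte(lin, (vhat - w)^2 - 1e-10)
  }
  # equality when beta is concentrated at one endpoint
  pts <- c(-1, 0.5, 2); b <- c(0, 1, 0); w <- 0.2
  expect_equal(sum((pts - w)^2 * b), (sum(pts * b) - w)^2)
})

test_that("refinement inserts the reconstruction and preserves bounds", {
  g <- structure(list(points = list(r = c(0, 2))), class = "pwl_grid")
  rec <- pwl_gap(g, list(r = c(0.5, 0.5)), c(r = 0))
  out <- pwl_refine(g, rec, eps = 1e-9, theta = 0.999)
  expect_equal(out$grid$points[["r"]], c(0, 1, 2))
  expect_equal(out$inserted, 1L)

  # converged reaction untouched
  rec0 <- pwl_gap(g, list(r = c(1, 0)), c(r = 0))
  out0 <- pwl_refine(g, rec0, eps = 1e-9, theta = 0.999)
  expect_equal(out0$grid$points[["r"]], c(0, 2))
  expect_equal(out0$inserted, 0L)
})

test_that("inserting the reconstruction makes the cost exact there", {
  pts <- c(0, 2); w <- 0.3; lam <- 0.37
  vhat <- (1 - lam) * pts[1] + lam * pts[2]
  new_pts <- sort(c(pts, vhat))
  t0 <- match(vhat, new_pts)
  b <- numeric(3); b[t0] <- 1
  lin <- sum((new_pts - w)^2 * b)
  expect_equal(lin, (vhat - w)^2)
})

test_that("repeated refinement drives the gap monotonically to zero", {
  w <- c(r = 0.7)
  g <- structure(list(points = list(r = c(-4, 6))), class = "pwl_grid")
  v_fix <- 1.9                       # fixed flux to represent
  gaps <- numeric(8)
  for (i in 1:8) {
    pts <- g$points[["r"]]
    # adjacent-pair beta representing v_fix on the current grid
    t0 <- max(which(pts <= v_fix + 1e-12)); t0 <- min(t0, length(pts) - 1L)
    lam <- (v_fix - pts[t0]) / (pts[t0 + 1] - pts[t0])
    b <- numeric(length(pts)); b[t0] <- 1 - lam; b[t0 + 1] <- lam
    rec <- pwl_gap(g, list(r = b), w)
    gaps[i] <- rec$gap
    g <- pwl_refine(g, rec, eps = 1e-14, theta = 1 - 1e-12)$grid
  }
  expect_true(all(diff(gaps) <= 1e-12))
  expect_lt(gaps[8], 1e-10)
})

test_that("convergence test requires both small gaps and concentration", {
  rec <- data.frame(reaction = c("a", "b"), gap = c(0, 0),
                    max_beta = c(1, 1), recon = c(0, 0))
  expect_true(pwl_converged(rec, eps = 1e-8, theta = 0.999))
  rec$gap[2] <- 2e-8
  expect_false(pwl_converged(rec, eps = 1e-8, theta = 0.999))
  rec$gap[2] <- 0; rec$max_beta[1] <- 0.5
  expect_false(pwl_converged(rec, eps = 1e-8, theta = 0.999))
})

test_that("grid TSV serialization round-trips endpoints", {
  fx <- toy_fixture(6, 2)
  g <- initial_grid(fx$net, fx$w, k_init = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_grid_tsv(g, path)
  back <- read_grid_tsv(path)
  expect_identical(names(back$points), names(g$points))
  for (j in names(g$points)) expect_equal(back$points[[j]], g$points[[j]])
})

test_that("fixed reactions get a single-endpoint grid and are never refined", {
  net <- hand_network()
  net$lb["EX_A"] <- 10; net$ub["EX_A"] <- 10
  w <- stats::setNames(rep(0, 6), net$reactions); w["EX_A"] <- 10
  g <- initial_grid(net, w, k_init = 4)
  expect_equal(g$points[["EX_A"]], 10)
  rec <- pwl_gap(g, lapply(g$points, function(p) rep(1 / length(p),
                                                     length(p))), w)
  out <- pwl_refine(g, rec, eps = 1e-12, theta = 1 - 1e-9)
  expect_equal(out$grid$points[["EX_A"]], 10)
})
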