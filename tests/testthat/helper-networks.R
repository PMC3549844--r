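# Shared fixtures: generated in code, never stored.

# tiny hand-built linear network: A -> B -> (biomass | target)
# EX_A (uptake), R1: A -> B, Rb: B -> BIO, Rt: B -> TGT,
# BIOMASS drain, EX_tgt secretion
hand_network <- function() {
  mets <- c("A", "B", "BIO", "TGT")
  rxns <- c("EX_A", "R1", "Rb", "Rt", "BIOMASS", "EX_tgt")
  S <- matrix(0, 4, 6, dimnames = list(mets, rxns))
  S["A", "EX_A"] <- 1
  S["A", "R1"] <- -1; S["B", "R1"] <- 1
  S["B", "Rb"] <- -1; S["BIO", "Rb"] <- 1
  S["B", "Rt"] <- -1; S["TGT", "Rt"] <- 1
  S["BIO", "BIOMASS"] <- -1
  S["TGT", "EX_tgt"] <- -1
  metabolic_network(S, lb = rep(0, 6), ub = c(20, 100, 100, 100, 100, 100),
                    biomass = "BIOMASS", glucose = "EX_A",
                    target = "EX_tgt")
}

hand_spec <- function(K = 0L) design_spec(uptake = 10, min_biomass = 1, K = K)

# cached toy fixtures so repeated tests don't re-run the FBA certificate
.fixture_cache <- new.env(parent = emptyenv())
toy_fixture <- function(n = 6, seed = 1) {
  key <- paste0("n", n, "s", seed)
  if (is.null(.fixture_cache[[key]])) {
    net <- toy_network(n, seed = seed)
    w <- fba(net, attr(net, "spec"))
    .fixture_cache[[key]] <- list(net = net, spec = attr(net, "spec"), w = w)
  }
  .fixture_cache[[key]]
}

# random valid convex-combination coefficients for a grid
random_beta <- function(grid) {
  lapply(grid$points, function(pts) {
    b <- stats::rexp(length(pts))
    b / sum(b)
  })
}

# beta supported on one random adjacent endpoint pair per reaction
adjacent_beta <- function(grid) {
  lapply(grid$points, function(pts) {
    b <- numeric(length(pts))
    if (length(pts) == 1L) { b[1] <- 1; return(b) }
    t0 <- sample.int(length(pts) - 1L, 1L)
    lam <- stats::runif(1)
    b[t0] <- lam; b[t0 + 1L] <- 1 - lam
    b
  })
}
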