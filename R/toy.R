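#' Generate a small synthetic metabolic network
#'
#' Builds a random, mass-balanced toy network with one substrate uptake
#' exchange, one biomass drain, one target secretion, and `n_internal`
#' internal conversion reactions forming branched pathways between them.
#' Every internal metabolite is reachable from the substrate by
#' construction, and both the biomass precursor and the target precursor
#' drain to their sinks, so flux balance analysis is feasible; a feasibility
#' certificate (FBA biomass >= `min_biomass`) is still checked and the
#' topology is re-drawn from a derived sub-seed on the rare failure.
#'
#' The generated instance is deterministic in `(n_internal, seed)` and the
#' caller's RNG state is left untouched.
#'
#' @param n_internal number of internal reactions (>= 4)
#' @param seed integer seed
#' @param uptake substrate uptake rate the network is designed for
#'   (mmol/gDW/hr); the glucose exchange bounds are `[0, 2 * uptake]`
#' @param min_biomass biomass flux the feasibility certificate requires
#' @param internal_ub flux capacity of internal reactions (mmol/gDW/hr)
#' @param max_tries topology redraws before giving up
#' @return a validated `metabolic_network`; the matching conditions are
#'   attached as attribute `"spec"` (a [design_spec()] with `K = 0`)
#' @export
toy_network <- function(n_internal = 6L, seed = 1L, uptake = 10,
                        min_biomass = 1, internal_ub = 100,
                        max_tries = 50L) {
  stopifnot(n_internal >= 4L)
  for (try in seq_len(max_tries)) {
    sub_seed <- as.integer((as.numeric(seed) * 1000 + try - 1) %% 2147483647)
    net <- with_seed(sub_seed, {
      build_toy(n_internal, uptake, internal_ub)
    })
    spec <- design_spec(uptake, min_biomass, K = 0L)
    ok <- tryCatch({
      w <- fba(net, spec)
      w$biomass_flux >= min_biomass - 1e-9
    }, error = function(e) FALSE)
    if (ok) {
      attr(net, "spec") <- spec
      return(net)
    }
  }
  stop("could not generate a feasible toy network after ", max_tries,
       " tries (n_internal = ", n_internal, ", seed = ", seed, ")")
}

# run code under a fixed RNG seed, restoring the caller's state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Topology: the substrate A feeds a hub metabolite H; the efficient
# wild-type biomass route runs H -> target-precursor chain -> (salvage,
# with an amplifying yield) -> biomass chain, while a less efficient
# direct route H -> biomass chain exists in parallel. FBA therefore pulls
# flux through the target precursor and secretes none of it; knocking the
# salvage reaction forces the precursor to spill into secretion while
# biomass survives on the direct route -- the competition motif (cf.
# succinate dehydrogenase in E. coli) the optimizer is meant to exploit.
# Remaining reactions are random cross-links. Every metabolite drains to
# a sink, so steady state is feasible by construction.
build_toy <- function(n_internal, uptake, internal_ub) {
  L <- n_internal - 2L            # internal conversions besides Rtgt/Rbio
  if (L >= 4L) {
    budget <- L - 3L              # beyond A->H, first chain step, salvage,
    nt <- 1L                      # and the direct route
    nb <- if (budget > 1L) sample.int(budget, 1L) - 1L else 0L
    rem <- budget - 1L - nb
    if (rem > 0L && stats::runif(1) < 0.5) { nt <- nt + 1L; rem <- rem - 1L }
    ncx <- rem
  } else {                        # minimal split topologies
    nt <- 1L; nb <- 0L; ncx <- 0L
  }
  tgt_chain <- paste0("T", seq_len(nt))
  bio_chain <- paste0("B", seq_len(nb + 1L))   # B1 fed by salvage/direct
  has_salvage <- L >= 3L
  has_direct <- L >= 4L
  mets <- c("A", "H", tgt_chain, if (has_salvage) bio_chain)

  src <- prod_met <- character(L)
  coef_out <- numeric(L)
  src[1] <- "A"; prod_met[1] <- "H"; coef_out[1] <- 1
  k <- 1L
  for (tt in seq_len(nt)) {        # target-precursor chain H -> T1 -> ...
    k <- k + 1L
    src[k] <- if (tt == 1L) "H" else tgt_chain[tt - 1L]
    prod_met[k] <- tgt_chain[tt]
    coef_out[k] <- 1
  }
  if (has_salvage) {               # salvage: precursor to biomass, 1:2 yield
    k <- k + 1L
    src[k] <- tgt_chain[nt]; prod_met[k] <- "B1"; coef_out[k] <- 2
  }
  direct <- NA_integer_
  if (has_direct) {                # direct route: lower yield (1:1) and
    k <- k + 1L                    # capacity-limited, like a real bypass
    src[k] <- "H"; prod_met[k] <- "B1"; coef_out[k] <- 1
    direct <- k
  }
  for (b in seq_len(nb)) {         # biomass chain B1 -> B2 -> ...
    k <- k + 1L
    src[k] <- bio_chain[b]
    prod_met[k] <- bio_chain[b + 1L]
    coef_out[k] <- sample(c(1, 1, 2), 1L)
  }
  for (cx in seq_len(ncx)) {       # random cross-links
    k <- k + 1L
    pair <- sample(setdiff(mets, "A"), 2L)
    src[k] <- pair[1]; prod_met[k] <- pair[2]
    coef_out[k] <- sample(c(1, 1, 2), 1L)
  }
  stopifnot(k == L)
  bio_src <- if (has_salvage) bio_chain[nb + 1L] else "H"
  tgt_src <- tgt_chain[nt]
  mets_all <- c(mets, "TGT", "BIO")

  rxns <- c(paste0("R", seq_len(L)), "Rtgt", "Rbio",
            "EX_glc", "EX_tgt", "BIOMASS")
  S <- matrix(0, nrow = length(mets_all), ncol = length(rxns),
              dimnames = list(mets_all, rxns))
  for (k in seq_len(L)) {
    rj <- paste0("R", k)
    S[src[k], rj] <- S[src[k], rj] - 1
    S[prod_met[k], rj] <- S[prod_met[k], rj] + coef_out[k]
  }
  S[tgt_src, "Rtgt"] <- -1; S["TGT", "Rtgt"] <- 1
  S[bio_src, "Rbio"] <- -1; S["BIO", "Rbio"] <- 1
  S["A", "EX_glc"] <- 1                       # substrate enters the system
  S["TGT", "EX_tgt"] <- -1                    # target secretion
  S["BIO", "BIOMASS"] <- -1                   # biomass drain
  S["A", "BIOMASS"] <- -0.1                   # growth consumes substrate too

  lb <- stats::setNames(rep(0, length(rxns)), rxns)
  ub <- stats::setNames(rep(internal_ub, length(rxns)), rxns)
  reversible <- paste0("R", which(stats::runif(L) < 0.25))
  lb[intersect(reversible, rxns)] <- -internal_ub
  if (!is.na(direct)) {            # bypass cannot carry the full uptake
    ub[paste0("R", direct)] <- round(uptake * stats::runif(1, 0.4, 0.9), 1)
    lb[paste0("R", direct)] <- 0
  }
  lb["EX_glc"] <- 0; ub["EX_glc"] <- 2 * uptake
  ub["EX_tgt"] <- 10 * internal_ub
  ub["BIOMASS"] <- 10 * internal_ub

  metabolic_network(S, lb = lb, ub = ub, biomass = "BIOMASS",
                    glucose = "EX_glc", target = "EX_tgt")
}
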