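#' Construct a constraint-based metabolic network model
#'
#' A network holds the stoichiometric matrix `S` (metabolites x reactions),
#' per-reaction flux bounds, and the three designated reactions every strain
#' design run needs: the biomass drain, the substrate (glucose) uptake, and
#' the target secretion reaction. Fluxes are in mmol/gDW/hr throughout.
#'
#' @param S numeric matrix, metabolites in rows, reactions in columns;
#'   dimnames are used as metabolite/reaction identifiers when
#'   `metabolites`/`reactions` are not given.
#' @param lb,ub per-reaction flux bounds; reversible reactions simply have
#'   `lb < 0` (no forward/backward splitting).
#' @param biomass,glucose,target identifiers of the designated reactions;
#'   must exist and be pairwise distinct.
#' @param metabolites,reactions identifier vectors (default: dimnames of `S`).
#' @param candidates knockout-candidate reaction ids; defaults to
#'   [candidate_knockouts()] with the standard policy (internal reactions
#'   minus the designated three).
#' @return an object of class `metabolic_network`
#' @export
metabolic_network <- function(S, lb, ub, biomass, glucose, target,
                              metabolites = rownames(S),
                              reactions = colnames(S),
                              candidates = NULL) {
  S <- as.matrix(S)
  if (is.null(metabolites)) metabolites <- paste0("m", seq_len(nrow(S)))
  if (is.null(reactions)) reactions <- paste0("r", seq_len(ncol(S)))
  dimnames(S) <- list(metabolites, reactions)
  lb <- stats::setNames(as.numeric(lb), reactions)
  ub <- stats::setNames(as.numeric(ub), reactions)
  net <- structure(
    list(S = S, lb = lb, ub = ub,
         metabolites = metabolites, reactions = reactions,
         biomass = biomass, glucose = glucose, target = target,
         candidates = candidates),
    class = "metabolic_network")
  if (is.null(candidates)) {
    net$candidates <- candidate_knockouts(net)
  }
  validate_network(net)
}

#' Validate a metabolic network
#'
#' Checks dimensions, bound ordering, existence and distinctness of the
#' designated reactions, and that none of biomass/glucose/target is a
#' knockout candidate.
#' @param net a `metabolic_network`
#' @return `net`, invisibly-validated (errors describe the offending entry)
#' @export
validate_network <- function(net) {
  stopifnot(inherits(net, "metabolic_network"))
  M <- length(net$reactions); N <- length(net$metabolites)
  if (!all(dim(net$S) == c(N, M))) {
    stop("S is ", nrow(net$S), "x", ncol(net$S), " but the model declares ",
         N, " metabolites and ", M, " reactions")
  }
  if (anyDuplicated(net$reactions)) stop("duplicated reaction ids")
  if (anyDuplicated(net$metabolites)) stop("duplicated metabolite ids")
  bad <- which(net$lb > net$ub)
  if (length(bad)) {
    stop("lb > ub for reaction(s): ", paste(net$reactions[bad], collapse = ", "))
  }
  des <- c(biomass = net$biomass, glucose = net$glucose, target = net$target)
  missing <- des[!des %in% net$reactions]
  if (length(missing)) {
    stop("designated reaction(s) not in model: ",
         paste(names(missing), "=", missing, collapse = ", "))
  }
  if (anyDuplicated(des)) stop("biomass/glucose/target must be distinct")
  if (any(des %in% net$candidates)) {
    stop("designated reactions may not be knockout candidates: ",
         paste(intersect(des, net$candidates), collapse = ", "))
  }
  if (!all(net$candidates %in% net$reactions)) {
    stop("unknown candidate reaction id(s): ",
         paste(setdiff(net$candidates, net$reactions), collapse = ", "))
  }
  net
}

#' Exchange reactions of a network
#'
#' An exchange (boundary) reaction has a single nonzero stoichiometric
#' entry: it moves one metabolite across the system boundary.
#' @param net a `metabolic_network`
#' @return character vector of reaction ids
#' @export
exchange_reactions <- function(net) {
  net$reactions[colSums(net$S != 0) == 1L]
}

#' Knockout-candidate policy
#'
#' The biomass, glucose and target reactions are never candidates. By
#' default exchange reactions are excluded as well (deletions act on
#' internal metabolism). An allow-list restricts candidates to exactly the
#' eligible ids given; a deny-list removes ids.
#'
#' @param net a `metabolic_network`
#' @param exclude_exchanges drop exchange reactions (default TRUE)
#' @param allow optional allow-list of reaction ids
#' @param deny optional deny-list of reaction ids
#' @return character vector of candidate reaction ids
#' @export
candidate_knockouts <- function(net, exclude_exchanges = TRUE,
                                allow = NULL, deny = NULL) {
  unknown <- setdiff(c(allow, deny), net$reactions)
  if (length(unknown)) {
    stop("candidate policy references unknown reaction id(s): ",
         paste(unknown, collapse = ", "))
  }
  cand <- net$reactions
  if (exclude_exchanges) cand <- setdiff(cand, exchange_reactions(net))
  cand <- setdiff(cand, c(net$biomass, net$glucose, net$target))
  if (!is.null(allow)) cand <- intersect(cand, allow)
  if (!is.null(deny)) cand <- setdiff(cand, deny)
  cand
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat("Metabolic network: ", length(x$metabolites), " metabolites, ",
      length(x$reactions), " reactions\n", sep = "")
  cat("  biomass: ", x$biomass, "   glucose: ", x$glucose,
      "   target: ", x$target, "\n", sep = "")
  cat("  knockout candidates: ", length(x$candidates), "\n", sep = "")
  invisible(x)
}

# ---- plain-text model dialect -------------------------------------------

#' Read a metabolic model file
#'
#' Two formats are supported: the package's plain-text TSV dialect (see
#' [write_model_tsv()]) and SBML Level 3 with the fbc extension. With
#' `format = "auto"` the choice is made on the file extension
#' (`.xml`/`.sbml` vs anything else).
#'
#' @param path model file
#' @param format "auto", "tsv" or "sbml"
#' @param biomass,glucose,target designated reaction ids, overriding any
#'   designation stored in the file (required for SBML files that do not
#'   annotate them).
#' @return a validated `metabolic_network`
#' @export
read_model <- function(path, format = c("auto", "tsv", "sbml"),
                       biomass = NULL, glucose = NULL, target = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("model file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "tsv"
  }
  if (format == "sbml") {
    read_sbml(path, biomass = biomass, glucose = glucose, target = target)
  } else {
    read_model_tsv(path, biomass = biomass, glucose = glucose, target = target)
  }
}

#' Read the plain-text TSV model dialect
#'
#' One reaction per row with columns `reaction`, `stoichiometry` (a
#' comma-separated `metabolite:coefficient` list), `lb`, `ub`. Header
#' comment lines `#! key value` carry the designated reactions
#' (`biomass`, `glucose`, `target`) and an optional comma-separated
#' `candidates` list.
#' @inheritParams read_model
#' @return a validated `metabolic_network`
#' @export
read_model_tsv <- function(path, biomass = NULL, glucose = NULL,
                           target = NULL) {
  lines <- readLines(path)
  meta_lines <- grep("^#!", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    parts <- strsplit(sub("^#!\\s*", "", ln), "\\s+")[[1]]
    if (length(parts) >= 2) meta[[parts[1]]] <- paste(parts[-1], collapse = " ")
  }
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  tab <- utils::read.delim(text = body, header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("reaction", "stoichiometry", "lb", "ub")
  if (!all(need %in% names(tab))) {
    stop("model table must have columns: ", paste(need, collapse = ", "))
  }
  rxns <- as.character(tab$reaction)
  stoich <- lapply(tab$stoichiometry, function(s) {
    if (is.na(s) || !nzchar(s)) return(numeric(0))
    pieces <- strsplit(strsplit(s, ",")[[1]], ":")
    coefs <- vapply(pieces, function(p) as.numeric(p[2]), numeric(1))
    stats::setNames(coefs, vapply(pieces, `[[`, "", 1))
  })
  mets <- unique(unlist(lapply(stoich, names)))
  S <- matrix(0, nrow = length(mets), ncol = length(rxns),
              dimnames = list(mets, rxns))
  for (j in seq_along(stoich)) S[names(stoich[[j]]), j] <- stoich[[j]]
  cand <- NULL
  if (!is.null(meta$candidates)) {
    cand <- strsplit(meta$candidates, ",")[[1]]
  }
  metabolic_network(
    S, lb = tab$lb, ub = tab$ub,
    biomass = biomass %||% meta$biomass,
    glucose = glucose %||% meta$glucose,
    target = target %||% meta$target,
    candidates = cand)
}

#' Write a network in the plain-text TSV dialect
#'
#' @param net a `metabolic_network`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_model_tsv <- function(net, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# momaknock model, TSV dialect",
    paste("#! biomass", net$biomass),
    paste("#! glucose", net$glucose),
    paste("#! target", net$target),
    paste("#! candidates", paste(net$candidates, collapse = ",")),
    "reaction\tstoichiometry\tlb\tub"), con)
  for (j in seq_along(net$reactions)) {
    nz <- which(net$S[, j] != 0)
    st <- paste(net$metabolites[nz], net$S[nz, j], sep = ":", collapse = ",")
    writeLines(paste(net$reactions[j], st,
                     format(net$lb[j], digits = 17),
                     format(net$ub[j], digits = 17), sep = "\t"), con)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
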