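# Bridge to the HiGHS LP/MILP solver (scipy.optimize) through the system
# `python`. Problems are serialized to JSON in sparse triplet form, solved in
# one batch per call to amortize interpreter start-up, and read back.

INF <- 1e30

#' Locate the python interpreter used for LP/MILP solves
#'
#' The solver backend runs `scipy.optimize.milp` (HiGHS) in the `python`
#' found on the PATH. Override with `options(momaknock.python = "...")`.
#' @return path to the interpreter
#' @keywords internal
find_python <- function() {
  py <- getOption("momaknock.python", "")
  if (!nzchar(py)) py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py)) {
    stop("no `python` interpreter found on PATH; the LP/MILP backend needs ",
         "python with scipy >= 1.9 (HiGHS)", call. = FALSE)
  }
  py
}

backend_script <- function() {
  path <- system.file("python", "milp_backend.py", package = "momaknock")
  if (!nzchar(path)) stop("milp_backend.py not found in installed package")
  path
}

# triplet representation of a dense or pre-built triplet constraint matrix
as_triplet <- function(A, n) {
  if (is.list(A) && !is.null(A$i)) return(A)
  if (is.null(A) || length(A) == 0L || NROW(A) == 0L) {
    return(list(i = integer(0), j = integer(0), x = numeric(0), m = 0L))
  }
  A <- as.matrix(A)
  nz <- which(A != 0, arr.ind = TRUE)
  list(i = as.integer(nz[, 1] - 1L), j = as.integer(nz[, 2] - 1L),
       x = as.numeric(A[nz]), m = nrow(A))
}

#' Build an LP/MILP problem description
#'
#' @param sense "min" or "max"
#' @param obj objective coefficients
#' @param A constraint matrix (dense, or triplet list `i`,`j`,`x`,`m` 0-based)
#' @param cl,cu row bounds (use -Inf/Inf for one-sided rows)
#' @param lb,ub variable bounds
#' @param integrality 0/1 vector, 1 marks integer variables
#' @keywords internal
lp_problem <- function(sense, obj, A, cl, cu, lb, ub, integrality = NULL) {
  n <- length(obj)
  trip <- as_triplet(A, n)
  clamp <- function(v) {
    v[v == -Inf] <- -INF
    v[v == Inf] <- INF
    v
  }
  p <- list(sense = sense, n = n, c = as.numeric(obj), A = trip,
            cl = clamp(as.numeric(cl)), cu = clamp(as.numeric(cu)),
            lb = clamp(as.numeric(lb)), ub = clamp(as.numeric(ub)))
  if (!is.null(integrality) && any(integrality != 0)) {
    p$integrality <- as.integer(integrality)
  }
  p
}

#' Solve a batch of LP/MILP problems with the HiGHS backend
#'
#' @param problems list of problems from [lp_problem()]
#' @param mip_gap optional relative MIP gap applied to every problem
#' @param time_limit optional per-problem time limit (seconds)
#' @return list of results: `status` ("optimal", "infeasible", ...),
#'   `objective`, `x`
#' @keywords internal
highs_solve <- function(problems, mip_gap = NULL, time_limit = NULL) {
  stopifnot(is.list(problems), length(problems) >= 1L)
  if (!is.null(mip_gap) || !is.null(time_limit)) {
    problems <- lapply(problems, function(p) {
      if (!is.null(mip_gap)) p$mip_gap <- mip_gap
      if (!is.null(time_limit)) p$time_limit <- time_limit
      p
    })
  }
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  jsonlite::write_json(list(problems = problems), fin,
                       auto_unbox = TRUE, digits = NA)
  status <- system2(find_python(), c(backend_script(), fin, fout),
                    stdout = TRUE, stderr = TRUE)
  code <- attr(status, "status")
  if (!is.null(code) && code != 0) {
    stop("LP/MILP backend failed:\n", paste(status, collapse = "\n"),
         call. = FALSE)
  }
  res <- jsonlite::read_json(fout, simplifyVector = TRUE,
                             simplifyMatrix = FALSE)
  out <- res$results
  if (is.data.frame(out)) {  # jsonlite may simplify homogeneous results
    out <- lapply(seq_len(nrow(out)), function(k) {
      r <- list(status = out$status[k])
      if (!is.null(out$objective)) r$objective <- out$objective[k]
      if (!is.null(out$x)) r$x <- unlist(out$x[k])
      r
    })
  }
  lapply(out, function(r) {
    r$x <- as.numeric(unlist(r$x))
    r
  })
}

highs_solve1 <- function(problem, ...) highs_solve(list(problem), ...)[[1]]
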