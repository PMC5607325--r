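# Deterministic treatment of a compiled system: feasibility, the
# minimum-norm (parsimonious) solution, and per-flow attainable ranges.

SOLVE_TOL <- 1e-8   # constraint-satisfaction tolerance; flows are O(0.01-10)

check_system <- function(system) {
  n <- length(system$flow_labels)
  if (ncol(system$E) != n || ncol(system$G) != n ||
      nrow(system$E) != length(system$f) ||
      nrow(system$G) != length(system$h)) {
    stop("dimension mismatch in lim_system")
  }
  invisible(system)
}

# min ||x||^2 subject to Ex = f, Gx >= h via quadprog; NULL if infeasible
qp_min_norm <- function(E, f, G, h) {
  n <- ncol(G)
  Amat <- t(rbind(E, G))
  bvec <- c(f, h)
  sol <- tryCatch(
    quadprog::solve.QP(Dmat = diag(n), dvec = rep(0, n), Amat = Amat,
                       bvec = bvec, meq = nrow(E)),
    error = function(e) e
  )
  if (inherits(sol, "error")) {
    if (grepl("inconsistent|no solution", conditionMessage(sol))) {
      return(NULL)
    }
    stop(sol)
  }
  sol$solution
}

residuals_ok <- function(system, x, tol = SOLVE_TOL) {
  eq_ok <- nrow(system$E) == 0 ||
    max(abs(system$E %*% x - system$f)) <= tol
  in_ok <- nrow(system$G) == 0 ||
    min(system$G %*% x - system$h) >= -tol
  eq_ok && in_ok
}

#' Feasibility check with infeasibility certificate
#'
#' Decides whether the polytope `{x : Ex = f, Gx >= h}` is non-empty. On
#' infeasibility, a small (deletion-filter) set of row provenances that
#' is jointly unsatisfiable is reported, naming the biological
#' constraints in conflict.
#'
#' @param system A `lim_system` from [compile_lim()].
#' @return A list with `feasible` (logical), `x` (a feasible point or
#'   `NULL`) and `certificate` (character vector of row provenances,
#'   empty when feasible).
#' @export
check_feasibility <- function(system) {
  check_system(system)
  x <- qp_min_norm(system$E, system$f, system$G, system$h)
  if (!is.null(x)) {
    return(list(feasible = TRUE, x = x, certificate = character(0)))
  }
  list(feasible = FALSE, x = NULL,
       certificate = infeasibility_certificate(system))
}

# deletion filter over provenance groups: drop groups whose removal
# keeps the system infeasible; what remains is an irreducible core
infeasibility_certificate <- function(system) {
  eq_groups <- unique(system$eq_provenance)
  ineq_groups <- setdiff(unique(system$ineq_provenance),
                         grep("^nonnegativity", system$ineq_provenance,
                              value = TRUE))
  groups <- c(eq_groups, ineq_groups)
  active <- rep(TRUE, length(groups))
  infeasible_without <- function(active_groups) {
    keep_eq <- system$eq_provenance %in% active_groups
    keep_in <- system$ineq_provenance %in% active_groups |
      grepl("^nonnegativity", system$ineq_provenance)
    is.null(qp_min_norm(system$E[keep_eq, , drop = FALSE],
                        system$f[keep_eq],
                        system$G[keep_in, , drop = FALSE],
                        system$h[keep_in]))
  }
  if (!infeasible_without(groups)) {
    # infeasibility involves nonnegativity itself; report everything
    return(groups)
  }
  for (i in seq_along(groups)) {
    trial <- groups[active & seq_along(groups) != i]
    if (infeasible_without(trial)) active[i] <- FALSE
  }
  groups[active]
}

#' Parsimonious (minimum-norm) solution
#'
#' The unique flow vector of least Euclidean norm satisfying all
#' constraints. It is reported as a convenient start point for the
#' sampler and for diagnostics only, never as "the" solution: the
#' analysis characterises the whole solution polytope by sampling.
#'
#' @param system A feasible `lim_system`.
#' @return Named numeric flow vector (mmol C m-2 d-1).
#' @export
parsimonious_solution <- function(system) {
  check_system(system)
  x <- qp_min_norm(system$E, system$f, system$G, system$h)
  if (is.null(x)) {
    cert <- infeasibility_certificate(system)
    stop("system is infeasible; conflicting constraints: ",
         paste(cert, collapse = ", "))
  }
  if (!residuals_ok(system, x, tol = 1e-6)) {
    stop("quadratic program returned an inaccurate solution")
  }
  stats::setNames(x, system$flow_labels)
}

#' Attainable range of every flow
#'
#' Minimum and maximum of each flow coordinate over the feasible
#' polytope (two linear programs per flow, solved by the package's
#' two-phase simplex with a shared warm start). Coordinates that are not
#' finitely constrained in a direction are flagged unbounded rather than
#' raising an error: the shipped site models are bounded by their
#' oxygen-consumption and deposition rows, but user models need not be.
#'
#' @param system A feasible `lim_system`.
#' @return A `data.frame` with columns `flow`, `min`, `max`, `unbounded`.
#' @export
flow_ranges <- function(system) {
  check_system(system)
  ph1 <- simplex_phase1(system$E, system$f, system$G, system$h)
  if (is.null(ph1)) {
    cert <- infeasibility_certificate(system)
    stop("system is infeasible; conflicting constraints: ",
         paste(cert, collapse = ", "))
  }
  n <- length(system$flow_labels)
  lo <- hi <- rep(NA_real_, n)
  unbounded <- rep(FALSE, n)
  for (j in seq_len(n)) {
    rlo <- simplex_coordinate(ph1, j, maximize = FALSE)
    rhi <- simplex_coordinate(ph1, j, maximize = TRUE)
    if (rlo$status == "optimal") {
      lo[j] <- if (abs(rlo$value) < SOLVE_TOL) max(rlo$value, 0)
               else rlo$value
    } else {
      unbounded[j] <- TRUE
    }
    if (rhi$status == "optimal") hi[j] <- rhi$value
    else unbounded[j] <- TRUE
  }
  data.frame(flow = system$flow_labels, min = lo, max = hi,
             unbounded = unbounded, stringsAsFactors = FALSE)
}

#' Single-call solve report
#'
#' Convenience wrapper combining [check_feasibility()],
#' [parsimonious_solution()] and [flow_ranges()].
#'
#' @param system A `lim_system`.
#' @return A list of class `solve_report` with `feasible`,
#'   `parsimonious_x`, `flow_ranges` and `diagnostics`.
#' @export
solve_report <- function(system) {
  feas <- check_feasibility(system)
  if (!feas$feasible) {
    return(structure(list(feasible = FALSE, parsimonious_x = NULL,
                          flow_ranges = NULL,
                          diagnostics = feas$certificate),
                     class = "solve_report"))
  }
  structure(list(feasible = TRUE,
                 parsimonious_x = parsimonious_solution(system),
                 flow_ranges = flow_ranges(system),
                 diagnostics = character(0)),
            class = "solve_report")
}
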