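# Uniform sampling of the feasible flow polytope.

# orthonormal basis of the null space of E (k = n when E has no rows)
null_space_basis <- function(E, n) {
  if (is.null(E) || nrow(E) == 0) return(diag(n))
  sv <- svd(E, nu = 0, nv = n)
  d <- sv$d
  tol <- max(dim(E)) * max(d, 0) * .Machine$double.eps
  rank <- sum(d > tol)
  if (rank == n) return(matrix(0, n, 0))
  sv$v[, seq(rank + 1, n), drop = FALSE]
}

#' Sample valid flow vectors uniformly from the feasible polytope
#'
#' Runs a reflective (mirror) random walk in the null-space
#' parameterisation of the equality constraints: each proposal is an
#' isotropic Gaussian step that is folded across any inequality
#' hyperplane it meets, which leaves the uniform distribution over the
#' polytope invariant. Every equality holds to machine precision by
#' construction; every retained row is checked against the inequalities
#' at tolerance 1e-8.
#'
#' @param system A feasible, bounded `lim_system`.
#' @param n_iterations Number of retained solutions (one per step).
#' @param seed Integer seed; identical inputs give bit-identical
#'   ensembles.
#' @param jump_length Step standard deviation in flow units. Default is
#'   0.3 times the mean width of the per-flow attainable ranges, so that
#'   mixing is scaled to flows spanning orders of magnitude.
#' @param start Optional start vector (defaults to the parsimonious
#'   solution).
#' @param burn_in Steps discarded before retention (default 1000; use 0
#'   to retain from the start point onwards).
#' @param ranges Optional precomputed [flow_ranges()] table, to avoid
#'   recomputing it for the default jump length and boundedness check.
#' @return An object of class `flow_ensemble`: `samples`
#'   (`n_iterations` x `n_flows` matrix with flow-label columns),
#'   `flow_labels`, `seed`, `n_burn_in`, `jump_length`,
#'   `n_iterations_requested`.
#' @export
sample_polytope <- function(system, n_iterations, seed,
                            jump_length = NULL, start = NULL,
                            burn_in = 1000, ranges = NULL) {
  check_system(system)
  stopifnot(n_iterations >= 1, burn_in >= 0)
  feas <- check_feasibility(system)
  if (!feas$feasible) {
    stop("cannot sample an infeasible system; conflicting constraints: ",
         paste(feas$certificate, collapse = ", "))
  }
  if (is.null(jump_length) || is.null(ranges)) {
    ranges <- if (is.null(ranges)) flow_ranges(system) else ranges
  }
  if (!is.null(ranges) && any(ranges$unbounded)) {
    stop("polytope is unbounded in flow(s): ",
         paste(ranges$flow[ranges$unbounded], collapse = ", "))
  }
  if (is.null(jump_length)) {
    width <- ranges$max - ranges$min
    jump_length <- 0.3 * mean(width[is.finite(width)])
    if (!is.finite(jump_length) || jump_length <= 0) jump_length <- 0.1
  }
  n <- length(system$flow_labels)
  x0 <- if (is.null(start)) feas$x else {
    stopifnot(length(start) == n)
    as.numeric(start)
  }
  if (!residuals_ok(system, x0, tol = 1e-6)) {
    stop("start point does not satisfy the constraint system")
  }
  # width-scaled parameterisation: x = x0 + diag(w) Z q with Z an
  # orthonormal null-space basis of E diag(w). The map is linear with
  # constant Jacobian, so uniformity in q is uniformity over the
  # polytope, while steps move each flow in proportion to its
  # attainable range (without this, flows spanning orders of magnitude
  # force thousands of mirror reflections per step).
  w <- rep(1, n)
  if (!is.null(ranges)) {
    width <- ranges$max - ranges$min
    ok <- is.finite(width) & width > 0
    if (any(ok)) {
      w <- ifelse(ok, width, min(width[ok]))
      w <- w / mean(w)
    }
  }
  Z <- null_space_basis(system$E %*% diag(w, n), n)
  M <- diag(w, n) %*% Z
  k <- ncol(Z)
  if (k == 0) {
    # fully determined by the equalities: the polytope is a single point
    samples <- matrix(rep(x0, each = n_iterations), nrow = n_iterations,
                      dimnames = list(NULL, system$flow_labels))
  } else {
    A <- system$G %*% M
    b <- as.numeric(system$h - system$G %*% x0)
    # rows with a zero null-space component constrain no direction
    keep <- rowSums(abs(A)) > 1e-12
    A <- A[keep, , drop = FALSE]
    b <- b[keep]
    old_seed <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv()))
    set.seed(as.integer(seed))
    Q <- mirror_walk_cpp(A, b, rep(0, k), jump_length,
                         as.integer(n_iterations), as.integer(burn_in))
    samples <- Q %*% t(M) + matrix(x0, nrow(Q), n, byrow = TRUE)
    colnames(samples) <- system$flow_labels
  }
  viol <- ensemble_violation(system, samples)
  if (viol > SOLVE_TOL) {
    stop("sampler produced an invalid solution (max violation ",
         signif(viol, 3), ")")
  }
  structure(
    list(samples = samples, flow_labels = system$flow_labels,
         seed = as.integer(seed), n_burn_in = as.integer(burn_in),
         jump_length = jump_length,
         n_iterations_requested = as.integer(n_iterations)),
    class = "flow_ensemble"
  )
}

# worst constraint violation over all rows of an ensemble matrix
ensemble_violation <- function(system, samples) {
  v <- 0
  if (nrow(system$E) > 0) {
    v <- max(v, max(abs(system$E %*% t(samples) - system$f)))
  }
  if (nrow(system$G) > 0) {
    v <- max(v, max(pmax(0, system$h - system$G %*% t(samples))))
  }
  v
}

#' @export
print.flow_ensemble <- function(x, ...) {
  cat("<flow_ensemble>", nrow(x$samples), "solutions x",
      ncol(x$samples), "flows | seed", x$seed, "| burn-in", x$n_burn_in,
      "| jump", signif(x$jump_length, 4), "\n")
  invisible(x)
}

#' Convergence diagnostic over a ladder of run lengths
#'
#' Re-runs the sampler at increasing numbers of iterations, all begun
#' from the same start point, and reports for a tracked subset of flows
#' the relative deviation of each run's mean and standard deviation from
#' the longest run. The minimum number of iterations to converge is the
#' smallest run length at which every tracked deviation is within
#' `tolerance` (default 2 percent).
#'
#' @param system A feasible, bounded `lim_system`.
#' @param tracked_flows Flow labels to track; default picks five flows
#'   spanning the range of parsimonious flow magnitudes.
#' @param run_lengths Strictly increasing run lengths; the default
#'   ladder is 300, 3000, 30000, 200000 iterations.
#' @param seed Integer seed; run `i` uses `seed + i - 1`.
#' @param tolerance Relative deviation threshold.
#' @param jump_length,burn_in Passed to [sample_polytope()].
#' @return An object of class `convergence_report`: `tracked_flows`,
#'   `run_lengths`, `mean_deviation` and `sd_deviation` (run x flow
#'   matrices), `min_iterations_to_converge`.
#' @export
convergence_diagnostic <- function(system, tracked_flows = NULL,
                                   run_lengths = c(300, 3000, 30000,
                                                   200000),
                                   seed = 1, tolerance = 0.02,
                                   jump_length = NULL, burn_in = 0) {
  check_system(system)
  if (length(run_lengths) < 2 || any(diff(run_lengths) <= 0)) {
    stop("run_lengths must be at least two strictly increasing values")
  }
  start <- parsimonious_solution(system)
  ranges <- flow_ranges(system)
  if (is.null(tracked_flows)) {
    ord <- order(abs(start))
    pick <- unique(round(seq(1, length(ord), length.out = min(5, length(ord)))))
    tracked_flows <- system$flow_labels[ord[pick]]
  }
  bad <- setdiff(tracked_flows, system$flow_labels)
  if (length(bad) > 0) {
    stop("tracked flow(s) not in system: ", paste(bad, collapse = ", "))
  }
  nr <- length(run_lengths); nf <- length(tracked_flows)
  means <- sds <- matrix(NA_real_, nr, nf,
                         dimnames = list(NULL, tracked_flows))
  for (i in seq_len(nr)) {
    ens <- sample_polytope(system, run_lengths[i], seed = seed + i - 1,
                           jump_length = jump_length, start = start,
                           burn_in = burn_in, ranges = ranges)
    s <- ens$samples[, tracked_flows, drop = FALSE]
    means[i, ] <- colMeans(s)
    sds[i, ] <- apply(s, 2, stats::sd)
  }
  rel_dev <- function(m, final) {
    d <- abs(sweep(m, 2, final))
    denom <- matrix(abs(final), nrow(m), ncol(m), byrow = TRUE)
    out <- d / denom
    out[denom < 1e-12] <- 0   # flows fixed by the equalities
    out
  }
  mean_dev <- rel_dev(means, means[nr, ])
  sd_dev <- rel_dev(sds, sds[nr, ])
  # a flow whose spread is essentially zero at the final run is treated
  # as converged everywhere (constant coordinate)
  sd_dev[, sds[nr, ] < 1e-12] <- 0
  ok <- apply(mean_dev <= tolerance & sd_dev <= tolerance, 1, all)
  structure(
    list(tracked_flows = tracked_flows, run_lengths = run_lengths,
         means = means, sds = sds,
         mean_deviation = mean_dev, sd_deviation = sd_dev,
         tolerance = tolerance,
         min_iterations_to_converge = run_lengths[which(ok)[1]]),
    class = "convergence_report"
  )
}

#' @export
print.convergence_report <- function(x, ...) {
  cat("<convergence_report>", length(x$tracked_flows), "tracked flows |",
      "run lengths:", paste(x$run_lengths, collapse = ", "), "\n",
      "min iterations to converge (tolerance", x$tolerance, "):",
      x$min_iterations_to_converge, "\n")
  invisible(x)
}
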