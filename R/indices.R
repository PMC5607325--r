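# Ecological network indices computed from a flow solution: total system
# throughflow, Finn cycling index, average mutual information and a
# pairwise-neighbourhood compartmentalisation index.

#' Construct a flow matrix
#'
#' Container for the between-compartment flow matrix `T` (entry `[i, j]`
#' is the flow from compartment `i` to `j`), extended with import,
#' export and respiration vectors. Imports are flows entering from
#' outside (deposition, suspension capture, DIC fixation); exports are
#' flows leaving to external pools other than DIC (burial, DOC efflux,
#' external predation); respiration flows to DIC are kept as a separate
#' vector so that throughflows stay balanced.
#'
#' @param T Square non-negative matrix with zero diagonal; dimnames give
#'   compartment labels.
#' @param imports,exports,respiration Non-negative vectors, one entry
#'   per compartment (default zero).
#' @return An object of class `flow_matrix`.
#' @export
flow_matrix <- function(T, imports = NULL, exports = NULL,
                        respiration = NULL) {
  T <- as.matrix(T)
  n <- nrow(T)
  stopifnot(n == ncol(T))
  if (is.null(rownames(T))) {
    dimnames(T) <- list(paste0("C", seq_len(n)), paste0("C", seq_len(n)))
  }
  zero <- stats::setNames(rep(0, n), rownames(T))
  fill <- function(v) {
    if (is.null(v)) return(zero)
    stopifnot(length(v) == n)
    stats::setNames(as.numeric(v), rownames(T))
  }
  imports <- fill(imports); exports <- fill(exports)
  respiration <- fill(respiration)
  if (any(T < 0) || any(imports < 0) || any(exports < 0) ||
      any(respiration < 0)) {
    stop("flow matrix entries must be non-negative")
  }
  if (any(abs(diag(T)) > 0)) stop("flow matrix must have a zero diagonal")
  structure(list(T = T, imports = imports, exports = exports,
                 respiration = respiration, labels = rownames(T)),
            class = "flow_matrix")
}

#' Build the flow matrix of a model solution
#'
#' Maps a flow vector onto the internal-compartment flow matrix plus
#' import/export/respiration vectors, following the model topology.
#'
#' @param model A [build_topology()] model.
#' @param flow_vector Numeric vector in the model's flow order.
#' @return A [flow_matrix()].
#' @export
to_flow_matrix <- function(model, flow_vector) {
  if (length(flow_vector) != nrow(model$flows)) {
    stop("flow vector length ", length(flow_vector),
         " does not match the model's ", nrow(model$flows), " flows")
  }
  if (any(flow_vector < -1e-9)) {
    stop("flow vector has negative entries")
  }
  flow_vector <- pmax(flow_vector, 0)
  internals <- internal_ids(model)
  n <- length(internals)
  T <- matrix(0, n, n, dimnames = list(internals, internals))
  imports <- exports <- respiration <- stats::setNames(rep(0, n),
                                                       internals)
  for (r in seq_len(nrow(model$flows))) {
    src <- model$flows$source[r]; snk <- model$flows$sink[r]
    v <- flow_vector[model$flows$index[r]]
    if (src %in% internals && snk %in% internals) {
      T[src, snk] <- T[src, snk] + v
    } else if (snk %in% internals) {
      imports[snk] <- imports[snk] + v
    } else if (snk == "DIC") {
      respiration[src] <- respiration[src] + v
    } else {
      exports[src] <- exports[src] + v
    }
  }
  flow_matrix(T, imports, exports, respiration)
}

throughflow <- function(fm) {
  colSums(fm$T) + fm$imports
}

#' Total system throughflow
#'
#' Sum over compartments of their throughflow (total inputs, which equal
#' total outputs for a mass-balanced solution), in mmol C m-2 d-1.
#'
#' @param fm A [flow_matrix()].
#' @return Scalar TST.
#' @export
total_system_throughflow <- function(fm) {
  sum(throughflow(fm))
}

#' Finn cycling index
#'
#' Fraction of total system throughflow that is recycled. With
#' output-fraction matrix `g[i, j] = T[i, j] / Ti` (`Ti` the throughflow
#' of `i`) and `N = (I - g)^-1`, the cycled throughflow is
#' `Tc = sum_i ((n_ii - 1)/n_ii) * Ti` and `FCI = Tc / TST`. The
#' corrected variant (`corrected = TRUE`) relates the cycled fraction to
#' the non-cycled ("straight-through") throughflow instead:
#' `cFCI = Tc / (TST - Tc)`.
#'
#' @param fm A balanced [flow_matrix()] with positive TST.
#' @param corrected Return the corrected index.
#' @return Dimensionless index; plain FCI lies in [0, 1].
#' @export
finn_cycling_index <- function(fm, corrected = FALSE) {
  Ti <- throughflow(fm)
  tst <- sum(Ti)
  if (tst <= 0) stop("total system throughflow must be positive")
  n <- length(Ti)
  g <- fm$T / ifelse(Ti > 0, Ti, 1)
  g[Ti == 0, ] <- 0
  IG <- diag(n) - g
  N <- tryCatch(solve(IG), error = function(e) {
    stop("(I - g) is singular: the network contains a fully cyclic ",
         "component with no dissipation")
  })
  nii <- diag(N)
  tc <- sum((nii - 1) / nii * Ti)
  if (corrected) tc / (tst - tc) else tc / tst
}

#' Average mutual information of the flow network
#'
#' The constraint, in bits, that the network places on where a unit of
#' carbon flows next:
#' `AMI = sum_ij (t_ij / t..) log2(t_ij t.. / (t_i. t_.j))` over the
#' extended matrix in which imports enter from an external source row
#' and exports plus respiration leave to external sink columns. Zero
#' flows contribute zero.
#'
#' @param fm A [flow_matrix()] with positive total flow.
#' @return AMI in bits (non-negative).
#' @export
average_mutual_information <- function(fm) {
  n <- length(fm$labels)
  # extended matrix: +1 source row (imports), +2 sink columns
  # (exports, respiration)
  M <- matrix(0, n + 1, n + 2)
  M[seq_len(n), seq_len(n)] <- fm$T
  M[n + 1, seq_len(n)] <- fm$imports
  M[seq_len(n), n + 1] <- fm$exports
  M[seq_len(n), n + 2] <- fm$respiration
  tot <- sum(M)
  if (tot <= 0) stop("total flow must be positive")
  p <- M / tot
  ri <- rowSums(p); cj <- colSums(p)
  nz <- which(p > 0, arr.ind = TRUE)
  sum(p[nz] * log2(p[nz] / (ri[nz[, 1]] * cj[nz[, 2]])))
}

#' Compartmentalisation index
#'
#' Mean Jaccard overlap, over unordered compartment pairs, of the
#' undirected interaction neighbourhoods (each neighbourhood includes
#' the focal compartment itself when it interacts at all): 1 for a
#' completely connected web, 0 for an edgeless one; high values indicate
#' subsystem structure shared across the web.
#'
#' @param fm A [flow_matrix()] with at least two compartments, or a
#'   square adjacency/flow matrix.
#' @return Index in [0, 1].
#' @export
compartmentalisation <- function(fm) {
  T <- if (inherits(fm, "flow_matrix")) fm$T else as.matrix(fm)
  n <- nrow(T)
  if (n < 2) stop("need at least two compartments")
  adj <- (T + t(T)) > 0
  nb <- lapply(seq_len(n), function(i) {
    ni <- which(adj[i, ])
    if (length(ni) > 0) unique(c(i, ni)) else integer(0)
  })
  tot <- 0; np <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      u <- length(union(nb[[i]], nb[[j]]))
      tot <- tot + if (u == 0) 0 else
        length(intersect(nb[[i]], nb[[j]])) / u
      np <- np + 1
    }
  }
  tot / np
}

#' All network indices of one solution
#'
#' @param fm A [flow_matrix()].
#' @return Named vector: `tst`, `n_links`, `fci`, `cfci`, `ami`,
#'   `compartmentalisation`.
#' @export
network_indices <- function(fm) {
  c(tst = total_system_throughflow(fm),
    n_links = sum(fm$T > 0) + sum(fm$imports > 0) + sum(fm$exports > 0) +
      sum(fm$respiration > 0),
    fci = finn_cycling_index(fm),
    cfci = finn_cycling_index(fm, corrected = TRUE),
    ami = average_mutual_information(fm),
    compartmentalisation = compartmentalisation(fm))
}

#' Ensemble network indices
#'
#' Computes every index per sampled solution and reports the ensemble
#' mean and sample standard deviation, matching the convention of
#' reporting indices as mean +/- SD over the solution set. Set
#' `per_solution = FALSE` to evaluate the indices once on the ensemble
#' mean flow network instead.
#'
#' @param model The model the ensemble was sampled from.
#' @param ensemble A [sample_polytope()] ensemble (or a plain sample
#'   matrix).
#' @param per_solution Compute per solution then average (default).
#' @return A `data.frame` with columns `index`, `mean`, `sd` (the `sd`
#'   column is `NA` when `per_solution = FALSE`).
#' @export
ensemble_indices <- function(model, ensemble, per_solution = TRUE) {
  samples <- if (inherits(ensemble, "flow_ensemble")) ensemble$samples
             else as.matrix(ensemble)
  if (nrow(samples) == 0) stop("ensemble is empty")
  if (!per_solution) {
    v <- network_indices(to_flow_matrix(model, colMeans(samples)))
    return(data.frame(index = names(v), mean = unname(v), sd = NA_real_,
                      stringsAsFactors = FALSE))
  }
  vals <- t(apply(samples, 1, function(x)
    network_indices(to_flow_matrix(model, x))))
  data.frame(index = colnames(vals),
             mean = unname(colMeans(vals)),
             sd = unname(apply(vals, 2, stats::sd)),
             stringsAsFactors = FALSE)
}
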