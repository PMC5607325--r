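# Dense two-phase simplex for the small linear programs behind
# flow_ranges(): min/max of single flow coordinates over the feasible
# polytope. Problems are tiny (tens of variables, ~100 rows) but often
# degenerate, so pricing is Dantzig with a Bland fallback for
# anti-cycling, and phase 1 is solved once per polytope and reused for
# every objective.
#
# Standard form: variables z >= 0 with x = u - v and one slack per
# inequality:  [E  -E   0] z = f ,  [G  -G  -I] z = h  (rows sign-flipped
# to a non-negative right-hand side), artificials appended for phase 1.

simplex_pivot <- function(T, basis, pr, pc) {
  piv <- T[pr, pc]
  T[pr, ] <- T[pr, ] / piv
  other <- setdiff(seq_len(nrow(T)), pr)
  T[other, ] <- T[other, ] - outer(T[other, pc], T[pr, ])
  basis[pr] <- pc
  list(T = T, basis = basis)
}

# minimise c'z from a basic feasible tableau; returns status in
# {"optimal", "unbounded"}. piv_tol guards against pivoting on rounding
# noise (rows are equilibrated to unit scale by the caller, so genuine
# entries are well above it); among minimum-ratio ties the largest
# pivot element is taken for stability, except under the Bland
# anti-cycling fallback.
simplex_run <- function(T, basis, cvec, allowed, tol = 1e-9,
                        piv_tol = 1e-7, max_iter = 20000) {
  m <- nrow(T); N <- ncol(T) - 1L
  bland_after <- 40L * (m + N)
  it <- 0L
  repeat {
    it <- it + 1L
    if (it > max_iter) stop("simplex iteration limit reached")
    cb <- cvec[basis]
    # reduced costs over allowed (non-artificial) columns
    red <- cvec[allowed] - as.numeric(crossprod(T[, allowed, drop = FALSE],
                                                cb))
    # basic columns must not re-enter on rounding noise: a duplicated
    # basis column silently corrupts the tableau
    red[allowed %in% basis] <- 0
    neg <- which(red < -tol)
    if (length(neg) == 0) {
      return(list(T = T, basis = basis,
                  obj = sum(cb * T[, N + 1L]), status = "optimal"))
    }
    bland <- it > bland_after
    pc <- if (bland) {
      allowed[min(neg)]                      # Bland: smallest index
    } else {
      allowed[neg[which.min(red[neg])]]      # Dantzig: most negative
    }
    col <- T[, pc]
    pos <- which(col > piv_tol)
    if (length(pos) == 0) {
      return(list(T = T, basis = basis, obj = -Inf, status = "unbounded",
                  entering = pc))
    }
    ratio <- T[pos, N + 1L] / col[pos]
    rmin <- min(ratio)
    cand <- pos[ratio <= rmin + tol]
    pr <- if (length(cand) > 1) {
      if (bland) cand[which.min(basis[cand])]
      else cand[which.max(col[cand])]
    } else {
      cand
    }
    up <- simplex_pivot(T, basis, pr, pc)
    T <- up$T; basis <- up$basis
  }
}

# phase 1 for {Ex = f, Gx >= h}; returns a feasible tableau over
# [u, v, s] columns or NULL when infeasible
simplex_phase1 <- function(E, f, G, h, tol = 1e-7) {
  n <- ncol(G)
  mE <- nrow(E); mG <- nrow(G)
  A <- rbind(
    if (mE > 0) cbind(E, -E, matrix(0, mE, mG)) else NULL,
    cbind(G, -G, -diag(mG))
  )
  b <- c(f, h)
  # equilibrate: unit max-abs per row, so pivot tolerances are absolute
  scale <- pmax(apply(abs(A), 1, max), abs(b), 1e-12)
  A <- A / scale
  b <- b / scale
  flip <- b < 0
  A[flip, ] <- -A[flip, , drop = FALSE]
  b[flip] <- -b[flip]
  m <- nrow(A); N <- ncol(A)
  T <- cbind(A, diag(m), b)
  basis <- N + seq_len(m)
  cvec <- c(rep(0, N), rep(1, m))
  res <- simplex_run(T, basis, cvec, allowed = seq_len(N + m))
  if (res$obj > tol) return(NULL)
  T <- res$T; basis <- res$basis
  # drive any residual artificials out of the basis
  drop_rows <- integer(0)
  for (r in which(basis > N)) {
    entry <- which(abs(T[r, seq_len(N)]) > 1e-9)
    if (length(entry) == 0) {
      drop_rows <- c(drop_rows, r)           # redundant row
    } else {
      up <- simplex_pivot(T, basis, r, entry[1])
      T <- up$T; basis <- up$basis
    }
  }
  if (length(drop_rows) > 0) {
    T <- T[-drop_rows, , drop = FALSE]
    basis <- basis[-drop_rows]
  }
  T <- T[, c(seq_len(N), N + nrow(T) + length(drop_rows) + 1L), drop = FALSE]
  # (keep only structural columns + rhs)
  list(T = T, basis = basis, n = n, N = N)
}

# minimise or maximise coordinate j of x over the polytope, warm-started
# from a shared phase-1 tableau; status "unbounded" when the coordinate
# is not finitely constrained in that direction
simplex_coordinate <- function(ph1, j, maximize = FALSE) {
  N <- ph1$N
  cvec <- rep(0, N)
  sgn <- if (maximize) -1 else 1
  cvec[j] <- sgn           # u_j
  cvec[ph1$n + j] <- -sgn  # v_j
  res <- simplex_run(ph1$T, ph1$basis, cvec, allowed = seq_len(N))
  if (res$status == "unbounded") {
    return(list(status = "unbounded", value = NA_real_))
  }
  list(status = "optimal", value = if (maximize) -res$obj else res$obj)
}
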