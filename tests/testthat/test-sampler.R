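simplex3 <- function() {
  toy_system(E = matrix(c(1, 1, 1), 1), f = 1, G = diag(3),
             h = rep(0, 3), labels = c("a", "b", "c"))
}

corner3 <- function() {
  toy_system(G = rbind(diag(3), c(-1, -1, -1)), h = c(0, 0, 0, -1),
             labels = c("a", "b", "c"))
}

test_that("sampler reproduces flat-Dirichlet moments on the simplex", {
  e <- sample_polytope(simplex3(), 50000, seed = 42)
  expect_equal(unname(colMeans(e$samples)), rep(1 / 3, 3),
               tolerance = 0.02)
  expect_equal(unname(apply(e$samples, 2, stats::var)), rep(1 / 18, 3),
               tolerance = 0.05)
})

test_that("sampler matches uniform moments on a 1-D box", {
  s <- toy_system(G = rbind(1, -1), h = c(0, -1), labels = "x")
  e <- sample_polytope(s, 50000, seed = 3)
  expect_equal(mean(e$samples), 0.5, tolerance = 0.02)
  expect_equal(stats::var(as.numeric(e$samples)), 1 / 12,
               tolerance = 0.05)
})

test_that("sampler agrees with a rejection oracle on the corner simplex", {
  e <- sample_polytope(corner3(), 50000, seed = 7)
  expect_equal(unname(colMeans(e$samples)), rep(0.25, 3),
               tolerance = 0.02)
  oracle <- rejection_oracle(corner3()$G, corner3()$h,
                             lower = rep(0, 3), upper = rep(1, 3),
                             n_keep = 50000, seed = 123)
  expect_equal(unname(colMeans(e$samples)), unname(colMeans(oracle)),
               tolerance = 0.02)
  # marginal distributions: two-sample Kolmogorov-Smirnov distance
  for (j in 1:3) {
    d <- suppressWarnings(
      stats::ks.test(e$samples[, j], oracle[, j])$statistic)
    expect_lt(d, 0.02)
  }
})

test_that("marginals match the oracle on a lopsided 4-D polytope", {
  G <- rbind(diag(4),
             c(-2, -1, 0, 0),
             c(0, 0, -1, -3),
             c(-1, -1, -1, -1))
  h <- c(0, 0, 0, 0, -2, -1.5, -2.5)
  s <- toy_system(G = G, h = h, labels = paste0("x", 1:4))
  e <- sample_polytope(s, 50000, seed = 11)
  oracle <- rejection_oracle(G, h, lower = rep(0, 4),
                             upper = c(1, 2, 1.5, 0.5),
                             n_keep = 50000, seed = 99)
  for (j in 1:4) {
    d <- suppressWarnings(
      stats::ks.test(e$samples[, j], oracle[, j])$statistic)
    expect_lt(d, 0.02)
  }
})

test_that("identical seeds give bit-identical ensembles", {
  e1 <- sample_polytope(corner3(), 2000, seed = 5)
  e2 <- sample_polytope(corner3(), 2000, seed = 5)
  expect_identical(e1$samples, e2$samples)
  e3 <- sample_polytope(corner3(), 2000, seed = 6)
  expect_false(identical(e1$samples, e3$samples))
})

test_that("every retained sample satisfies the constraint system", {
  for (m in bransfield_fixtures()[c("BOV", "HR2")]) {
    sys <- compile_lim(m)
    e <- sample_polytope(sys, 5000, seed = 1)
    expect_lt(max(abs(sys$E %*% t(e$samples) - sys$f)), 1e-8)
    expect_gt(min(sys$G %*% t(e$samples) - sys$h), -1e-8)
    # and the LP ranges bracket 100% of sampled points
    r <- flow_ranges(sys)
    expect_true(all(t(e$samples) >= r$min - 1e-7))
    expect_true(all(t(e$samples) <= r$max + 1e-7))
  }
})

test_that("linear-functional means are insensitive to jump length", {
  s <- corner3()
  means <- vapply(c(0.05, 0.15, 0.5), function(j) {
    e <- sample_polytope(s, 40000, seed = 17, jump_length = j)
    mean(e$samples %*% c(1, 2, 3))
  }, numeric(1))
  expect_lt(max(means) - min(means), 0.05 * mean(means))
})

test_that("doubling iterations keeps errors within Monte-Carlo scaling", {
  s <- simplex3()
  err <- function(n) {
    e <- sample_polytope(s, n, seed = 31)
    max(abs(colMeans(e$samples) - 1 / 3))
  }
  e1 <- err(12500); e2 <- err(25000); e4 <- err(50000)
  # regression guard: longer runs must not be grossly worse
  expect_lt(e4, max(2.5 * e1, 0.01))
  expect_lt(e2, max(2.5 * e1, 0.01))
})

test_that("infeasible or unbounded systems are refused with names", {
  s_bad <- toy_system(E = matrix(c(1, 1), 1), f = -1, G = diag(2),
                      h = c(0, 0), labels = c("x1", "x2"))
  expect_error(sample_polytope(s_bad, 100, seed = 1), "infeasible")
  s_unb <- toy_system(E = matrix(c(1, -1), 1), f = 0, G = diag(2),
                      h = c(0, 0), labels = c("x1", "x2"))
  expect_error(sample_polytope(s_unb, 100, seed = 1), "unbounded")
})

test_that("a degenerate polytope collapses to the single solution", {
  s <- toy_system(E = rbind(c(1, 1), c(1, -1)), f = c(1, 0),
                  G = diag(2), h = c(0, 0), labels = c("x1", "x2"))
  e <- sample_polytope(s, 50, seed = 2)
  expect_true(all(abs(e$samples - 0.5) < 1e-9))
})

test_that("convergence ladder defaults follow the documented protocol", {
  expect_equal(formals(convergence_diagnostic)$run_lengths,
               quote(c(300, 3000, 30000, 200000)))
  expect_error(
    convergence_diagnostic(simplex3(), run_lengths = c(500, 100),
                           seed = 1),
    "strictly increasing")
})

test_that("tracked means on the simplex converge within the 2% rule", {
  cv <- convergence_diagnostic(simplex3(),
                               tracked_flows = c("a", "b", "c"),
                               run_lengths = c(300, 3000, 30000),
                               seed = 8)
  expect_lte(cv$min_iterations_to_converge, 30000)
  expect_true(all(cv$mean_deviation[nrow(cv$mean_deviation), ] == 0))
})

test_that("flows fixed by equalities converge at the smallest run length", {
  s <- toy_system(E = rbind(c(1, 0, 0), c(0, 1, 1)), f = c(0.4, 1),
                  G = diag(3), h = rep(0, 3), labels = c("a", "b", "c"))
  cv <- convergence_diagnostic(s, tracked_flows = "a",
                               run_lengths = c(300, 3000), seed = 2)
  expect_equal(cv$min_iterations_to_converge, 300)
  expect_true(all(cv$mean_deviation[, "a"] == 0))
})
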