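test_that("ensemble summary gives sample statistics and CoV bins", {
  s <- cbind(a = c(1, 3), b = c(2, 2), c = c(1, -1))
  es <- ensemble_summary(s)
  expect_equal(es$table$mean, c(2, 2, 0))
  expect_equal(es$table$sd[1], sqrt(2), tolerance = 1e-12)
  expect_equal(es$table$cov[1], sqrt(2) / 2, tolerance = 1e-12)
  expect_equal(es$table$cov[2], 0)
  expect_true(is.na(es$table$cov[3]))      # zero-mean flow flagged
  expect_equal(es$n_cov_undefined, 1)
  expect_equal(es$n_cov_lt_0.2, 1)         # the constant flow
  expect_equal(es$n_cov_ge_1, 0)
  expect_error(ensemble_summary(s[1, , drop = FALSE]), "two solutions")
})

test_that("summary is invariant to duplicating the ensemble", {
  set.seed(1)
  s <- matrix(stats::runif(60), 20, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  es1 <- ensemble_summary(s)
  es2 <- ensemble_summary(rbind(s, s))
  expect_equal(es1$table$mean, es2$table$mean)
  expect_equal(es1$table$cov, es2$table$cov, tolerance = 0.03)
})

test_that("fraction_greater matches exhaustive enumeration", {
  res <- fraction_greater(c(2, 3), c(1, 2))
  expect_equal(res$fraction_greater, 0.75)   # pairs: 2>1, 3>1, 3>2
  expect_equal(res$verdict, "none")

  expect_equal(fraction_greater(c(5, 5), c(5, 5))$fraction_greater, 0)

  res2 <- fraction_greater(c(10, 11), c(1, 2))
  expect_equal(res2$fraction_greater, 1)
  expect_equal(res2$verdict, "highly_significant")

  # property: random instances with ties vs brute force
  set.seed(42)
  for (rep in 1:25) {
    a <- sample(0:5, sample(1:100, 1), replace = TRUE) / 2
    b <- sample(0:5, sample(1:100, 1), replace = TRUE) / 2
    brute <- mean(outer(a, b, ">"))
    expect_equal(fraction_greater(a, b)$fraction_greater, brute)
    # complementarity with equality iff no ties
    fab <- fraction_greater(a, b)$fraction_greater
    fba <- fraction_greater(b, a)$fraction_greater
    expect_lte(fab + fba, 1 + 1e-12)
  }
})

test_that("verdict thresholds trigger strictly above 0.95 and 0.98", {
  a96 <- c(rep(1, 96), rep(-1, 4)); b <- rep(0, 100)
  expect_equal(fraction_greater(a96, b)$verdict, "significant")
  a95 <- c(rep(1, 95), rep(-1, 5))
  expect_equal(fraction_greater(a95, b)$verdict, "none")
  a99 <- c(rep(1, 99), rep(-1, 1))
  expect_equal(fraction_greater(a99, b)$verdict, "highly_significant")
  a98 <- c(rep(1, 98), rep(-1, 2))
  expect_equal(fraction_greater(a98, b)$verdict, "significant")
})

test_that("diet composition averages feeding-inflow proportions", {
  m <- bransfield_fixtures()$HR1
  sys <- compile_lim(m)
  x <- parsimonious_solution(sys)
  # single hand-built solution: proportions follow directly
  d <- diet_composition(m, rbind(x), "MacDF")
  i_food <- m$flows$label[m$flows$sink == "MacDF"]
  expect_equal(sum(d$table$percent), 100, tolerance = 1e-8)
  expect_equal(nrow(d$table), length(i_food))
  manual <- 100 * x[i_food] / sum(x[i_food])
  expect_equal(d$table$percent, unname(manual))

  # single food source -> 100%
  dsf <- diet_composition(m, rbind(x), "MacSF")
  expect_equal(dsf$table$percent, 100)

  # symbiont-bearing fauna have no diet
  expect_error(diet_composition(m, rbind(x), "MacES"),
               "symbiont")
})

test_that("diet percentages sum to 100 on sampled ensembles", {
  m <- bransfield_fixtures()$HR2
  e <- sample_polytope(compile_lim(m), 500, seed = 12)
  for (consumer in c("MacDF", "MacPS", "MegDF")) {
    d <- diet_composition(m, e, consumer)
    expect_equal(sum(d$table$percent), 100, tolerance = 1e-4)
  }
})

test_that("the OM budget reproduces a hand ledger on a single solution", {
  m <- bransfield_fixtures()$HR1
  sys <- compile_lim(m)
  x <- parsimonious_solution(sys)
  b <- om_budget(m, rbind(x, x))
  g <- function(v) b$table$mean[b$table$variable == v]
  expect_equal(g("POC deposition"), unname(x["Det_w->Det"]))
  expect_equal(g("Net Suspension Feeding"),
               unname(x["Det_w->MacSF"] + x["Det_w->MegSF"] -
                        x["MacSF->DIC"] - x["MegSF->DIC"]))
  expect_equal(g("Net Chemosynthesis"),
               unname(x["DIC->ChBac"] + x["DIC->MacES"] -
                        x["ChBac->DIC"] - x["MacES->DIC"]))
  expect_equal(g("Gross Total OM Input"),
               unname(x["Det_w->Det"] + x["Det_w->MacSF"] +
                        x["Det_w->MegSF"] + x["DIC->ChBac"] +
                        x["DIC->MacES"]))
  expect_equal(g("Burial of Organic C"), unname(x["Det->Det_s"]))
  expect_equal(g("DOC Efflux"), unname(x["DOC->DOC_w"]))
  resp <- sum(x[m$flows$label[m$flows$sink == "DIC"]])
  expect_equal(g("Total C Respiration"), resp)
  expect_equal(sum(b$shares), 100, tolerance = 1e-8)
  # net never exceeds gross per route
  expect_lte(g("Net Suspension Feeding"),
             unname(x["Det_w->MacSF"] + x["Det_w->MegSF"]) + 1e-12)
  expect_lte(g("Net Chemosynthesis"),
             unname(x["DIC->ChBac"] + x["DIC->MacES"]) + 1e-12)
})

test_that("whole-system carbon conservation holds for every sampled solution", {
  for (m in bransfield_fixtures()) {
    e <- sample_polytope(compile_lim(m), 2000, seed = 5)
    b <- om_budget(m, e)
    expect_lt(b$conservation_residual, 1e-6)
  }
})

test_that("an all-zero solution yields an all-zero budget", {
  m <- bransfield_fixtures()$BOV
  z <- matrix(0, 2, nrow(m$flows),
              dimnames = list(NULL, m$flows$label))
  b <- om_budget(m, z)
  expect_true(all(b$table$mean == 0))
  expect_equal(b$conservation_residual, 0)
})

test_that("a toy net-chemosynthesis line subtracts mediator respiration", {
  m <- bransfield_fixtures()$HR2          # has ChBac, no MacES
  x <- stats::setNames(rep(0, nrow(m$flows)), m$flows$label)
  x["DIC->ChBac"] <- 1.0
  x["ChBac->DIC"] <- 0.3
  b <- om_budget(m, rbind(x, x))
  expect_equal(b$table$mean[b$table$variable == "Net Chemosynthesis"],
               0.7)
})
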