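test_that("flow matrices are built and balanced from model solutions", {
  m <- tiny_model()
  x <- c(1, 1, 1)     # In->A, A->B, B->Out
  fm <- to_flow_matrix(m, x)
  expect_equal(unname(fm$T["A", "B"]), 1)
  expect_equal(unname(fm$imports["A"]), 1)
  expect_equal(unname(fm$exports["B"]), 1)
  # balance: inputs equal outputs per compartment
  inputs <- colSums(fm$T) + fm$imports
  outputs <- rowSums(fm$T) + fm$exports + fm$respiration
  expect_equal(inputs, outputs)
  expect_error(to_flow_matrix(m, c(1, 1)), "does not match")
  expect_error(to_flow_matrix(m, c(1, -1, 1)), "negative")
})

test_that("total system throughflow sums compartment throughflows", {
  fm1 <- flow_matrix(matrix(c(0, 1, 0, 0), 2, byrow = TRUE,
                            dimnames = list(c("A", "B"), c("A", "B"))),
                     imports = c(1, 0), exports = c(0, 1))
  expect_equal(total_system_throughflow(fm1), 2)
  # worked loop: import 1 -> A, A->B 1, B->A 0.5, B->export 0.5
  fm2 <- flow_matrix(matrix(c(0, 1, 0.5, 0), 2, byrow = TRUE,
                            dimnames = list(c("A", "B"), c("A", "B"))),
                     imports = c(1, 0), exports = c(0, 0.5))
  expect_equal(total_system_throughflow(fm2), 2.5)
  fm0 <- flow_matrix(matrix(0, 2, 2), imports = c(0, 0))
  expect_equal(total_system_throughflow(fm0), 0)
})

test_that("Finn cycling index matches the hand-inverted worked example", {
  # N = [[1.5, 1.0], [0.75, 1.5]] and FCI = 1/3
  fm <- flow_matrix(matrix(c(0, 1, 0.5, 0), 2, byrow = TRUE,
                           dimnames = list(c("A", "B"), c("A", "B"))),
                    imports = c(1, 0), exports = c(0, 0.5))
  expect_equal(finn_cycling_index(fm), 1 / 3, tolerance = 1e-12)
  # corrected variant relates cycled to straight-through throughflow
  expect_equal(finn_cycling_index(fm, corrected = TRUE), 0.5,
               tolerance = 1e-12)

  chain <- flow_matrix(matrix(c(0, 1, 0, 0), 2, byrow = TRUE,
                              dimnames = list(c("A", "B"),
                                              c("A", "B"))),
                       imports = c(1, 0), exports = c(0, 1))
  expect_equal(finn_cycling_index(chain), 0, tolerance = 1e-12)
})

test_that("average mutual information has its closed-form values", {
  # k parallel deterministic transfers -> log2(k)
  for (k in c(2, 4, 8)) {
    T <- matrix(0, 2 * k, 2 * k)
    for (i in seq_len(k)) T[i, k + i] <- 1 / k
    fm <- flow_matrix(T)
    expect_equal(average_mutual_information(fm), log2(k),
                 tolerance = 1e-12)
  }
  # single flow -> 0
  fm1 <- flow_matrix(matrix(c(0, 1, 0, 0), 2, byrow = TRUE))
  expect_equal(average_mutual_information(fm1), 0, tolerance = 1e-12)
  # fully mixed 2x2 (independent margins) -> 0
  T <- matrix(0, 4, 4)
  T[1, 3] <- T[1, 4] <- T[2, 3] <- T[2, 4] <- 0.25
  expect_equal(average_mutual_information(flow_matrix(T)), 0,
               tolerance = 1e-12)
})

test_that("adding a parallel duplicate path does not increase AMI", {
  # one source splitting over two identical sinks is less constrained
  # than a single deterministic transfer
  T1 <- matrix(0, 3, 3); T1[1, 2] <- 1
  T2 <- matrix(0, 3, 3); T2[1, 2] <- 0.5; T2[1, 3] <- 0.5
  expect_lte(average_mutual_information(flow_matrix(T2)),
             average_mutual_information(flow_matrix(T1)) + 1e-12)
})

test_that("compartmentalisation matches pairwise-overlap enumeration", {
  full <- matrix(1, 3, 3) - diag(3)
  expect_equal(compartmentalisation(flow_matrix(full * 0.1)), 1)
  # two disjoint dyads: AB and CD perfect overlap, cross pairs zero
  T <- matrix(0, 4, 4)
  T[1, 2] <- 1; T[3, 4] <- 1
  expect_equal(compartmentalisation(flow_matrix(T)), 1 / 3,
               tolerance = 1e-12)
  expect_equal(compartmentalisation(flow_matrix(matrix(0, 3, 3))), 0)
})

test_that("indices are scale-free except TST which is linear", {
  m <- bransfield_fixtures()$HR1
  sys <- compile_lim(m)
  x <- parsimonious_solution(sys)
  fm1 <- to_flow_matrix(m, x)
  fm2 <- to_flow_matrix(m, 3.7 * x)
  expect_equal(total_system_throughflow(fm2),
               3.7 * total_system_throughflow(fm1))
  expect_equal(finn_cycling_index(fm2), finn_cycling_index(fm1))
  expect_equal(average_mutual_information(fm2),
               average_mutual_information(fm1))
  expect_equal(compartmentalisation(fm2), compartmentalisation(fm1))
  # capacity bound: AMI cannot exceed log2 of the extended network size
  expect_lte(average_mutual_information(fm1),
             log2(length(fm1$labels) + 3))
})

test_that("ensemble indices average per-solution values", {
  m <- tiny_model()
  rows <- rbind(c(1, 1, 1), c(2, 2, 2))
  ix <- ensemble_indices(m, rows)
  tst <- ix[ix$index == "tst", ]
  expect_equal(tst$mean, mean(c(2, 4)))   # per-row TSTs are 2 and 4
  expect_equal(tst$sd, stats::sd(c(2, 4)))
  # identical rows -> zero SD everywhere
  ix0 <- ensemble_indices(m, rbind(c(1, 1, 1), c(1, 1, 1)))
  expect_true(all(ix0$sd == 0))
  # FCI convexity: ensemble mean stays in [0, 1]
  fx <- bransfield_fixtures()$BOV
  sys <- compile_lim(fx)
  e <- sample_polytope(sys, 200, seed = 3)
  ixf <- ensemble_indices(fx, e)
  fci <- ixf[ixf$index == "fci", "mean"]
  expect_gte(fci, 0); expect_lte(fci, 1)
})
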