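test_that("mass balance yields one zero-sum row per internal compartment", {
  m <- tiny_model()
  sys <- compile_lim(m, include = c("mass_balance", "nonnegativity"))
  expect_equal(nrow(sys$E), 2)
  expect_equal(sys$f, c(0, 0))
  # pool A: +In->A -A->B
  rA <- which(sys$eq_provenance == "mass_balance:A")
  expect_equal(unname(sys$E[rA, ]), c(1, -1, 0))
  rB <- which(sys$eq_provenance == "mass_balance:B")
  expect_equal(unname(sys$E[rB, ]), c(0, 1, -1))
})

test_that("fixture models compile to 9/10/9 mass-balance rows", {
  fx <- bransfield_fixtures()
  counts <- vapply(fx, function(m) nrow(compile_lim(m)$E), numeric(1))
  expect_equal(unname(counts), c(9, 10, 9))
})

test_that("every flow gets a nonnegativity row and dimensions agree", {
  fx <- bransfield_fixtures()
  for (m in fx) {
    sys <- compile_lim(m)
    n <- nrow(m$flows)
    expect_equal(ncol(sys$E), n)
    expect_equal(ncol(sys$G), n)
    expect_equal(length(sys$h), nrow(sys$G))
    expect_equal(length(sys$f), nrow(sys$E))
    nn <- grepl("^nonnegativity:", sys$ineq_provenance)
    expect_equal(sum(nn), n)
    expect_true(all(rowSums(abs(sys$G)) > 0))
    expect_true(all(rowSums(abs(sys$E)) > 0))
  }
})

test_that("compilation is deterministic", {
  m <- bransfield_fixtures()$HR2
  expect_identical(compile_lim(m), compile_lim(m))
})

test_that("temperature changes touch only temperature-limited rows", {
  fx <- bransfield_fixtures()
  m1 <- fx$HR1
  m2 <- m1
  m2$environment$temperature <- 30
  s1 <- compile_lim(m1); s2 <- compile_lim(m2)
  expect_identical(s1$G, s2$G)      # coefficients unchanged
  expect_identical(s1$E, s2$E)
  differs <- which(s1$h != s2$h)
  tags <- unique(s1$ineq_provenance[differs])
  expect_true(all(grepl("physiology:(growth|maintenance|respiration_band)",
                        tags)))
  expect_true(length(differs) > 0)
})

test_that("removing a compartment removes exactly its rows and columns", {
  comp <- default_compartments()
  stocks <- ventlim:::synthetic_stocks("HR1")
  comp <- ventlim:::apply_stocks(comp, stocks)
  env <- site_environment("t", temperature = 24,
                          scoc_range = c(1.62, 2.86),
                          poc_range = c(0.7, 27.17))
  m_full <- build_topology(comp, environment = env)
  m_red <- build_topology(comp, site_absences = "ChBac",
                          environment = env)
  s_full <- compile_lim(m_full)
  s_red <- compile_lim(m_red)
  gone_flows <- setdiff(s_full$flow_labels, s_red$flow_labels)
  expect_true(all(grepl("ChBac", gone_flows)))
  gone_eq <- setdiff(s_full$eq_provenance, s_red$eq_provenance)
  expect_equal(gone_eq, "mass_balance:ChBac")
  gone_ineq <- setdiff(unique(s_full$ineq_provenance),
                       unique(s_red$ineq_provenance))
  expect_true(all(grepl("ChBac", gone_ineq)))
})

test_that("isotope rows implement two-sided linear mixing", {
  # two sources at -20 and -30 with discrimination 1: equal flows give a
  # consumer tissue value of -24; a consumer at -24 +/- 1 is satisfied
  comp <- data.frame(
    id = c("S1", "S2", "C", "In", "Out"),
    name = c("s1", "s2", "consumer", "in", "out"),
    locality = c("internal", "internal", "internal", "external",
                 "external"),
    taxon_class = c("detritus", "detritus", "macrofauna", "detritus",
                    "external"),
    biomass = c(NA, NA, 5, NA, NA),
    d13c_mean = c(-20, -30, -24, NA, NA),
    d13c_sd = c(1, 1, 1, NA, NA),
    feeding_modes = c("", "", "deposit", "", ""),
    stringsAsFactors = FALSE)
  flows <- data.frame(source = c("In", "In", "S1", "S2", "C"),
                      sink = c("S1", "S2", "C", "C", "Out"))
  m <- build_topology(comp, flow_list = flows,
                      environment = site_environment("iso",
                                                     temperature = 20))
  rows <- compile_isotope_constraints(m, delta = 1, k = 2)
  expect_equal(length(rows$rhs), 2)
  sys <- ventlim:::assemble_system(rows, m)
  # equal flows (1, 1): mixture -24 equals the consumer -> satisfied
  x <- c(0, 0, 1, 1, 0)
  expect_true(all(sys$G %*% x >= sys$h - 1e-12))
  # all S1 (mixture -19, outside -24 +/- 2) -> violated
  x2 <- c(0, 0, 1, 0, 0)
  expect_false(all(sys$G %*% x2 >= sys$h - 1e-12))
})

test_that("single mismatched source makes the system infeasible with an isotope certificate", {
  # lone source at -30 + 1 discrimination vs consumer -25 +/- 2*1:
  # any positive intake violates the mixing rows, and mass balance
  # forces positive intake
  comp <- data.frame(
    id = c("S1", "C", "Out"),
    name = c("s1", "consumer", "out"),
    locality = c("internal", "internal", "external"),
    taxon_class = c("detritus", "macrofauna", "external"),
    biomass = c(NA, 5, NA),
    d13c_mean = c(-30, -25, NA),
    d13c_sd = c(1, 1, NA),
    feeding_modes = c("", "deposit", ""),
    stringsAsFactors = FALSE)
  flows <- data.frame(source = c("Out", "S1", "C"),
                      sink = c("S1", "C", "Out"))
  m <- build_topology(comp, flow_list = flows,
                      environment = site_environment("iso2",
                                                     temperature = 20))
  sys <- compile_lim(m, include = c("mass_balance", "isotope",
                                    "nonnegativity"))
  # add a floor forcing the consumer to actually feed
  floor <- matrix(0, 1, ncol(sys$G))
  floor[1, which(sys$flow_labels == "S1->C")] <- 1
  sys <- ventlim:::augment_system(sys, floor, 0.1, "floor")
  feas <- check_feasibility(sys)
  expect_false(feas$feasible)
  expect_true(any(grepl("^isotope:", feas$certificate)))
})

test_that("consumers without isotope data contribute no rows", {
  m <- tiny_model()   # no d13c anywhere, no feeding modes
  rows <- compile_isotope_constraints(m)
  expect_equal(length(rows$rhs), 0)
  # fixtures: symbiont/chemoautotroph compartments emit no isotope rows
  sys <- compile_lim(bransfield_fixtures()$HR1)
  expect_false(any(grepl("^isotope:(MacES|ChBac)$", sys$ineq_provenance)))
})

test_that("site rows carry the environment bounds", {
  fx <- bransfield_fixtures()
  s_hr1 <- compile_lim(fx$HR1)
  s_bov <- compile_lim(fx$BOV)
  scoc_rhs <- function(s) sort(s$h[s$ineq_provenance == "scoc"])
  expect_equal(scoc_rhs(s_hr1), c(-2.86, 1.62))
  expect_equal(scoc_rhs(s_bov), c(-2.86, 0.81))
  poc_rhs <- sort(s_hr1$h[s_hr1$ineq_provenance == "poc"])
  expect_equal(poc_rhs, c(-27.17, 0.70))
  # missing ranges -> error
  m <- fx$HR1
  m$environment$scoc_range <- NULL
  expect_error(compile_site_constraints(m), "scoc_range")
})
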