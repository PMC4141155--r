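make_table <- function(n_ligand, n_counterion, area) {
  tab <- data.frame(n_ligand = n_ligand, n_counterion = n_counterion,
                    area = area)
  attr(tab, "unassigned_area") <- 0
  class(tab) <- c("abundance_table", "data.frame")
  tab
}

test_that("fraction bound follows the area-ratio definition and policy", {
  expect_equal(fraction_bound(make_table(0L, 0L, 10)), 0)
  expect_equal(fraction_bound(make_table(c(0L, 1L), c(0L, 0L), c(5, 5))), 0.5)
  # equilibrium class abundances at the tetrachloride-DNA constants
  tab <- make_table(c(0L, 1L, 2L), c(0L, 0L, 0L), c(2.7725, 5.5470, 1.6805))
  expect_equal(fraction_bound(tab), 0.7228, tolerance = 1e-4)
  # invariant under uniform area scaling
  tab2 <- tab; tab2$area <- tab2$area * 1e6
  expect_equal(fraction_bound(tab2), fraction_bound(tab), tolerance = 1e-12)
  # counter-ion-only adducts of free Q count as bound only under the policy
  tab3 <- make_table(c(0L, 0L, 1L), c(0L, 1L, 0L), c(4, 2, 4))
  expect_equal(fraction_bound(tab3), 0.4)
  expect_equal(fraction_bound(tab3, counterion_only_is_bound = TRUE), 0.6)
  expect_error(fraction_bound(make_table(0L, 0L, 0)), "zero total")
})

test_that("areas convert to concentrations with ligand closed by difference", {
  st <- concentrations_from_areas(
    make_table(c(0L, 1L, 2L), c(0L, 0L, 0L), c(50, 50, 0)), 1e-5, 1e-5)
  expect_equal(st$free_Q, 5e-6); expect_equal(st$c11, 5e-6)
  expect_equal(st$c12, 0);       expect_equal(st$free_L, 5e-6)

  # saturation boundary: areas imply all ligand consumed
  expect_error(concentrations_from_areas(
    make_table(c(0L, 1L, 2L), c(0L, 0L, 0L), c(25, 50, 25)), 1e-5, 1e-5),
    "mass balance")

  # arithmetic case: free_L = 10 - 5.5470 - 2*1.6805 uM
  st <- concentrations_from_areas(
    make_table(c(0L, 1L, 2L), c(0L, 0L, 0L), c(27.725, 55.470, 16.805)),
    1e-5, 1e-5)
  expect_equal(st$free_L, 1.0920e-6, tolerance = 1e-4)

  # counter-ion dimension is collapsed before the conversion
  st2 <- concentrations_from_areas(
    make_table(c(0L, 0L, 1L, 1L), c(0L, 1L, 0L, 2L), c(30, 20, 25, 25)),
    1e-5, 1e-5)
  expect_equal(st2$free_Q, 5e-6)
  expect_equal(st2$c11, 5e-6)
})

test_that("K1/K2 estimation applies the sequential definitions exactly", {
  st <- equilibrium_state(free_Q = 2.5e-6, c11 = 2.5e-6, c12 = 0,
                          free_L = 7.5e-6)
  K <- estimate_constants(st)
  expect_equal(K$K1, 1 / 7.5e-6, tolerance = 1e-12)
  expect_equal(K$K2, 0)
  expect_false(attr(K, "k2_estimable"))
  expect_error(estimate_constants(
    equilibrium_state(0, 1e-6, 0, 1e-6)), "free quadruplex")
  expect_error(estimate_constants(
    equilibrium_state(1e-6, 1e-6, 0, 0)), "free ligand")
})

test_that("forward solver closes both mass balances and honors limits", {
  expect_equal(solve_equilibrium(1e-5, 1e-5, binding_constants(0, 0)),
               equilibrium_state(1e-5, 0, 0, 1e-5))
  set.seed(21)
  for (i in 1:30) {
    K <- binding_constants(10^runif(1, 4, 9), 10^runif(1, 3, 8))
    CQ <- runif(1, 1e-6, 5e-5); CL <- runif(1, 1e-6, 5e-5)
    st <- solve_equilibrium(CQ, CL, K)
    expect_lt(abs(st$free_Q + st$c11 + st$c12 - CQ) / CQ, 1e-12)
    expect_lt(abs(st$free_L + st$c11 + 2 * st$c12 - CL) / CL, 1e-12)
  }
  # fraction bound is monotone in K1 at equimolar concentrations, and in
  # K2 under ligand excess (at equimolar it is not: each 1:2 complex
  # sequesters two ligands, so raising K2 can starve complex formation)
  fb <- function(K1, K2, CL) {
    st <- solve_equilibrium(1e-5, CL, binding_constants(K1, K2))
    (st$c11 + st$c12) / 1e-5
  }
  expect_true(all(diff(vapply(10^(4:8), fb, 0, K2 = 1e5, CL = 1e-5)) > 0))
  expect_true(all(diff(vapply(10^(3:7), fb, 0, K1 = 1e6, CL = 1e-3)) > 0))
})

test_that("forward solve at the tetrachloride-DNA constants matches the
           reported bound fraction", {
  st <- solve_equilibrium(1e-5, 1e-5, dna_constants())
  expect_equal(100 * (st$c11 + st$c12) / 1e-5, 72.28, tolerance = 0.1 / 72.28)
})

test_that("estimate(solve(K)) is the identity across the constants' range", {
  for (K_true in list(dna_constants(), rna_constants())) {
    st <- solve_equilibrium(1e-5, 1e-5, K_true)
    K <- estimate_constants(st)
    expect_equal(K$K1, K_true$K1, tolerance = 1e-6)
    expect_equal(K$K2, K_true$K2, tolerance = 1e-6)
  }
  set.seed(33)
  ok <- 0
  for (i in 1:100) {
    K_true <- binding_constants(10^runif(1, 4, 9), 10^runif(1, 3, 8))
    CQ <- runif(1, 1e-6, 5e-5); CL <- runif(1, 1e-6, 5e-5)
    st <- solve_equilibrium(CQ, CL, K_true)
    if (st$free_L < 1e-12) next       # saturation excluded
    # through the area representation and back
    tab <- make_table(c(0L, 1L, 2L), c(0L, 0L, 0L),
                      c(st$free_Q, st$c11, st$c12))
    K <- estimate_constants(concentrations_from_areas(tab, CQ, CL))
    expect_equal(K$K1, K_true$K1, tolerance = 1e-6)
    expect_equal(K$K2, K_true$K2, tolerance = 1e-6)
    ok <- ok + 1
  }
  expect_gt(ok, 80)
})

test_that("replicate statistics use the sample (n-1) convention", {
  s <- replicate_summary(c(1.68e6, 1.87e6, 2.06e6))
  expect_equal(s$mean, 1.87e6)
  expect_equal(s$sd, 1.9e5, tolerance = 1e-12)
  expect_equal(s$n, 3)
  s1 <- replicate_summary(5)
  expect_true(is.na(s1$sd))
  expect_equal(replicate_summary(rep(2, 4))$sd, 0)
  expect_error(replicate_summary(numeric(0)), "no replicate")
})

test_that("affinity ratios quantify the RNA-over-DNA preference", {
  r <- affinity_ratio(rna_constants(), dna_constants())
  expect_gte(r$K1_ratio, 10)
  expect_equal(r$K1_ratio, 5.62e7 / 1.87e6, tolerance = 1e-12)
  expect_equal(r$K2_ratio, 2.62e6 / 2.83e5, tolerance = 1e-12)
  same <- affinity_ratio(dna_constants(), dna_constants())
  expect_equal(unlist(same), c(K1_ratio = 1, K2_ratio = 1))
  expect_error(affinity_ratio(dna_constants(), binding_constants(0, 1)),
               "positive")
})
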