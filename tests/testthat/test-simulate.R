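test_that("noise-free tetrachloride simulation reproduces its own truth
           through the full pipeline", {
  cfg <- chloride_config(seed = 101)
  sim <- simulate_binding_spectrum(cfg, dna_27mer)
  fit <- infer_binding(sim$spectrum, dna_27mer)

  truth_fb <- (sim$truth$state$c11 + sim$truth$state$c12) / cfg$C_Q
  expect_equal(fit$fraction_bound, truth_fb, tolerance = 1e-9)
  # and the truth itself sits at the reported bound fraction
  expect_equal(100 * truth_fb, 72.28, tolerance = 0.2 / 72.28)

  expect_equal(fit$constants$K1, 1.87e6, tolerance = 1e-6)
  expect_equal(fit$constants$K2, 2.83e5, tolerance = 1e-6)
})

test_that("simulated area mass is the C_Q-normalized equilibrium", {
  cfg <- chloride_config(seed = 7)
  sim <- simulate_binding_spectrum(cfg, dna_27mer)
  expect_equal(sum(sim$truth$species$area_true), 1, tolerance = 1e-9)
  # per-class totals match the equilibrium proportions
  st <- sim$truth$state
  for (k in 0:2) {
    cls <- sim$truth$species$n_ligand == k
    expect_equal(sum(sim$truth$species$area_true[cls]),
                 c(st$free_Q, st$c11, st$c12)[k + 1] / cfg$C_Q,
                 tolerance = 1e-9)
  }
})

test_that("simulation is deterministic in the seed", {
  mk <- function(seed) simulate_binding_spectrum(
    chloride_config(seed = seed, mz_jitter_sd = 0.05, area_noise_sd = 0.05,
                    n_decoys = 5L), dna_27mer)$spectrum
  expect_equal(mk(42), mk(42))
  expect_false(isTRUE(all.equal(mk(42)$mz, mk(43)$mz)))
  # the caller's RNG stream is not disturbed
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(mk(42)); after <- runif(1)
  expect_identical(before, after)
})

test_that("decoys and tosylate adducts flow through annotation correctly", {
  cfg <- spectrum_sim_config(truth = dna_constants(), seed = 5,
                             counterion_probs = c(0.55, 0.25, 0.15, 0.05),
                             n_decoys = 3L)
  sim <- simulate_binding_spectrum(cfg, dna_27mer)
  ann <- annotate_spectrum(sim$spectrum, dna_27mer)
  # area conservation through match + aggregate
  expect_equal(sum(ann$abundances$area) +
                 attr(ann$abundances, "unassigned_area"),
               sum(sim$spectrum$area), tolerance = 1e-12)
  # tosylate classes appear, and the policy flag moves free-Q+Ts classes
  tab <- ann$abundances
  expect_true(any(tab$n_counterion > 0))
  expect_gt(fraction_bound(tab, counterion_only_is_bound = TRUE),
            fraction_bound(tab, counterion_only_is_bound = FALSE))
})

test_that("K1 recovery under replicate noise stays within tolerance", {
  # noisy recovery: 3 replicates, 5 % multiplicative area noise
  fits <- lapply(1:3, function(i) {
    cfg <- chloride_config(seed = 200 + i, area_noise_sd = 0.05)
    sim <- simulate_binding_spectrum(cfg, dna_27mer)
    infer_binding(sim$spectrum, dna_27mer)
  })
  K1s <- vapply(fits, function(f) f$constants$K1, 0)
  s <- replicate_summary(K1s)
  expect_lt(abs(s$mean - 1.87e6), 3 * s$sd)

  # 20 seeds: median relative K1 error below 10 %
  rel_err <- vapply(1:20, function(i) {
    cfg <- chloride_config(seed = 1000 + i, area_noise_sd = 0.05)
    sim <- simulate_binding_spectrum(cfg, dna_27mer)
    fit <- infer_binding(sim$spectrum, dna_27mer)
    abs(fit$constants$K1 - 1.87e6) / 1.87e6
  }, 0)
  expect_lt(median(rel_err), 0.10)
})

test_that("two-state melting simulator satisfies its closed form", {
  cv <- simulate_melting_curve(Tm = 65, dH_vH = 45)
  # theta(Tm) = 0.5 exactly: absorbance at Tm is the baseline midpoint
  i <- which.min(abs(cv$temperature - 65))
  A_f <- 1.00 - 0.0005 * 65; A_u <- 0.62 - 0.0002 * 65
  expect_equal(cv$absorbance[i], (A_f + A_u) / 2, tolerance = 1e-6)
  expect_lt(abs(extract_tm(cv)$Tm - 65), 0.2)
  # determinism of the noisy generator
  n1 <- simulate_melting_curve(Tm = 65, noise_sd = 0.01, seed = 3)
  n2 <- simulate_melting_curve(Tm = 65, noise_sd = 0.01, seed = 3)
  expect_equal(n1, n2)
})
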