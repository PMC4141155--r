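#!/usr/bin/env Rscript
# Parameter recovery from synthetic spectra.
#
# Simulates triplicate 10 uM equimolar tetrachloride-mode spectra at the
# reported DNA constants with 5 % multiplicative area noise and 0.05 Da/z
# jitter, runs the full pipeline (enumerate -> match -> aggregate ->
# mass-balance closure -> K1/K2), and summarizes the replicate recovery.
# A second block contrasts the tetratosylate mode, where tosyl-adduct
# classes appear and the counterion_only_is_bound policy changes the
# apparent bound fraction.

suppressMessages(library(gquadms))
dir.create("results", showWarnings = FALSE)
seed0 <- 20260901

dna <- "d[(TTAGGG)4TTA]"
truth <- binding_constants(1.87e6, 2.83e5)

cat("== triplicate recovery, tetrachloride mode (5 % area noise) ==\n")
fits <- lapply(1:3, function(i) {
  cfg <- spectrum_sim_config(truth = truth, seed = seed0 + i,
                             mz_jitter_sd = 0.05, area_noise_sd = 0.05)
  sim <- simulate_binding_spectrum(cfg, dna)
  write_peaklist(sim$spectrum,
                 sprintf("results/sim_spectrum_rep%d.tsv", i))
  infer_binding(sim$spectrum, dna)
})
K1 <- replicate_summary(vapply(fits, function(f) f$constants$K1, 0))
K2 <- replicate_summary(vapply(fits, function(f) f$constants$K2, 0))
fb <- replicate_summary(vapply(fits, function(f) 100 * f$fraction_bound, 0))
cat(sprintf("  K1: %s   (truth %s)\n", K1$label, format_constant(truth$K1)))
cat(sprintf("  K2: %s   (truth %s)\n", K2$label, format_constant(truth$K2)))
cat(sprintf("  bound fraction: %.2f +/- %.2f %%\n\n", fb$mean, fb$sd))

summary_df <- data.frame(
  quantity = c("K1", "K2", "fraction_bound_pct"),
  mean = c(K1$mean, K2$mean, fb$mean),
  sd = c(K1$sd, K2$sd, fb$sd), n = 3,
  truth = c(truth$K1, truth$K2, NA))
utils::write.table(summary_df, "results/recovery_summary.tsv",
                   sep = "\t", row.names = FALSE, quote = FALSE)

cat("== salt-form contrast: tosylate adducts and the bound policy ==\n")
tos_cfg <- spectrum_sim_config(truth = truth, seed = seed0,
                               counterion_probs = c(0.55, 0.25, 0.15, 0.05))
tos <- simulate_binding_spectrum(tos_cfg, dna)
tab <- annotate_spectrum(tos$spectrum, dna)$abundances
cat(sprintf("  tosylate mode, counter-ion-only adducts as free:  RBA %.2f %%\n",
            100 * fraction_bound(tab)))
cat(sprintf("  tosylate mode, counter-ion-only adducts as bound: RBA %.2f %%\n",
            100 * fraction_bound(tab, counterion_only_is_bound = TRUE)))
cat("Counting tosyl-only adducts of the free quadruplex as bound raises\n")
cat("the apparent RBA, the direction the tetratosylate salt showed.\n")
cat("wrote results/recovery_summary.tsv and results/sim_spectrum_rep*.tsv\n")
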