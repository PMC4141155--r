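#!/usr/bin/env Rscript
# UV-melting: Tm extraction and ligand-induced stabilization.
#
# Simulates triplicate 295-nm hypochromic melting curves for the free
# quadruplex (Tm 60.00 C) and for the two TMPyP4 salt forms at the
# reported shifts (+6.45 C tetratosylate, +4.18 C tetrachloride), with
# realistic absorbance noise, and recovers delta-Tm for each arm.

suppressMessages(library(gquadms))
dir.create("results", showWarnings = FALSE)
seed0 <- 4100

arms <- list(free = 60.00, tetratosylate = 66.45, tetrachloride = 64.18)
curves <- lapply(names(arms), function(nm) {
  lapply(1:3, function(i)
    simulate_melting_curve(Tm = arms[[nm]], dH_vH = 45, noise_sd = 0.002,
                           seed = seed0 + match(nm, names(arms)) * 10 + i))
})
names(curves) <- names(arms)

cat("== per-arm Tm (midpoint method, n = 3) ==\n")
rows <- list()
for (nm in names(arms)) {
  tms <- vapply(curves[[nm]], function(cv) extract_tm(cv)$Tm, 0)
  s <- replicate_summary(tms)
  cat(sprintf("  %-14s Tm %.2f +/- %.2f C (true %.2f)\n",
              nm, s$mean, s$sd, arms[[nm]]))
  rows[[nm]] <- data.frame(arm = nm, Tm_mean = s$mean, Tm_sd = s$sd, n = s$n,
                           Tm_true = arms[[nm]])
}

cat("\n== ligand-induced shifts ==\n")
for (nm in c("tetratosylate", "tetrachloride")) {
  d <- delta_tm(curves[[nm]], curves$free)
  cat(sprintf("  delta-Tm %-14s %.2f +/- %.2f C (true %.2f)\n",
              nm, d$delta_Tm, d$sd, arms[[nm]] - arms$free))
}
d_extra <- delta_tm(curves$tetratosylate, curves$tetrachloride)
cat(sprintf("  extra stabilization by the tosylate salt: %.2f C (true 2.27)\n",
            d_extra$delta_Tm))

utils::write.table(do.call(rbind, rows), "results/melting_summary.tsv",
                   sep = "\t", row.names = FALSE, quote = FALSE)
cat("wrote results/melting_summary.tsv\n")
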