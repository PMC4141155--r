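# shared fixtures: Table-style constants and simulation configs

dna_27mer <- "d[(TTAGGG)4TTA]"
rna_27mer <- "r[(UUAGGG)4UUA]"

dna_constants <- function() binding_constants(1.87e6, 2.83e5)
rna_constants <- function() binding_constants(5.62e7, 2.62e6)

# tetrachloride-mode simulation (no counter-ion adducts)
chloride_config <- function(seed, truth = dna_constants(), ...) {
  spectrum_sim_config(truth = truth, seed = seed, ...)
}

# independent atom-count oracle: counts atoms from plain formula strings,
# one per residue, by regex token parsing (separate code path from elem_comp)
count_atoms_oracle <- function(formulas) {
  tot <- c(C = 0, H = 0, N = 0, O = 0, P = 0, S = 0)
  for (f in formulas) {
    toks <- regmatches(f, gregexpr("[A-Z][a-z]?[0-9]*", f))[[1]]
    for (tk in toks) {
      el <- gsub("[0-9]", "", tk)
      n <- suppressWarnings(as.integer(gsub("[A-Z][a-z]?", "", tk)))
      if (is.na(n)) n <- 1L
      tot[el] <- tot[el] + n
    }
  }
  tot[tot > 0]
}

random_composition <- function() {
  els <- sample(c("C", "H", "N", "O", "P", "S"), sample(2:6, 1))
  do.call(elem_comp, as.list(stats::setNames(sample(1:50, length(els)), els)))
}
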