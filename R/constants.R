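#' Atomic mass constants
#'
#' Standard average atomic weights (IUPAC conventional values) and
#' principal-isotope monoisotopic masses for the elements needed by
#' nucleic-acid and small-molecule mass arithmetic. Frozen here so that
#' every mass in the package derives from one table.
#'
#' @format A data.frame with columns `element`, `average` (Da) and
#'   `monoisotopic` (Da).
#' @export
atomic_masses <- data.frame(
  element      = c("H", "C", "N", "O", "P", "S"),
  average      = c(1.008, 12.011, 14.007, 15.999, 30.974, 32.06),
  monoisotopic = c(1.0078250319, 12.0, 14.0030740052,
                   15.9949146221, 30.97376151, 31.97207069),
  stringsAsFactors = FALSE
)

# mass of the proton, used for deprotonation arithmetic in both mass modes
PROTON_MASS <- 1.007276

# nucleotide residue compositions: 5'-monophosphate nucleoside minus water,
# i.e. the internal-chain residue of the phosphodiester backbone
NUCLEOTIDE_RESIDUES <- list(
  DNA = list(
    A = c(C = 10, H = 12, N = 5, O = 5, P = 1),
    C = c(C = 9,  H = 12, N = 3, O = 6, P = 1),
    G = c(C = 10, H = 12, N = 5, O = 6, P = 1),
    T = c(C = 10, H = 13, N = 2, O = 7, P = 1)
  ),
  RNA = list(
    A = c(C = 10, H = 12, N = 5, O = 6, P = 1),
    C = c(C = 9,  H = 12, N = 3, O = 7, P = 1),
    G = c(C = 10, H = 12, N = 5, O = 7, P = 1),
    U = c(C = 9,  H = 11, N = 2, O = 8, P = 1)
  )
)

WATER <- c(H = 2, O = 1)
HPO3  <- c(H = 1, P = 1, O = 3)
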