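#' Annotate a spectrum against the theoretical species inventory
#'
#' Runs enumerate -> theoretical m/z -> greedy matching -> per-class
#' aggregation for one spectrum.
#'
#' @param spectrum a `spectrum`
#' @param oligo an `oligo_seq` or notation string
#' @param molecules molecule list
#' @param tolerance matching tolerance, Da/charge
#' @param mass_mode "average" or "monoisotopic"
#' @param ... enumeration bounds passed to [enumerate_species()]
#' @return list with `ions`, `matched` (assignments + unassigned) and
#'   `abundances` (the `abundance_table`)
#' @export
annotate_spectrum <- function(spectrum, oligo,
                              molecules = builtin_molecules(),
                              tolerance = 1.0, mass_mode = "average", ...) {
  if (is.character(oligo)) oligo <- parse_oligo(oligo)
  M_Q <- if (mass_mode == "average") average_mass(oligo)
         else monoisotopic_mass(oligo)
  ions <- theoretical_ions(enumerate_species(...), M_Q, molecules, mass_mode)
  matched <- match_peaks(spectrum, ions, tolerance)
  list(ions = ions, matched = matched,
       abundances = aggregate_abundances(matched))
}

#' Full binding inference for one spectrum
#'
#' Annotates the spectrum, computes the fraction of bound quadruplex and
#' estimates K1/K2 from the mass-balance-closed species concentrations.
#' Concentrations are taken from the spectrum metadata (`C_Q`, `C_L`,
#' mol/L) unless given explicitly.
#'
#' @inheritParams annotate_spectrum
#' @param C_Q,C_L total concentrations, mol/L; default from metadata
#' @param counterion_only_is_bound policy for the fraction-bound statistic
#' @return list with `annotation`, `fraction_bound`, `state`, `constants`
#' @export
infer_binding <- function(spectrum, oligo, C_Q = NULL, C_L = NULL,
                          molecules = builtin_molecules(), tolerance = 1.0,
                          counterion_only_is_bound = FALSE, ...) {
  md <- spectrum_metadata(spectrum)
  if (is.null(C_Q)) C_Q <- md$C_Q
  if (is.null(C_L)) C_L <- md$C_L
  if (is.null(C_Q) || is.null(C_L))
    stop("C_Q and C_L must be supplied or present in spectrum metadata")
  ann <- annotate_spectrum(spectrum, oligo, molecules, tolerance, ...)
  fb <- fraction_bound(ann$abundances, counterion_only_is_bound)
  state <- concentrations_from_areas(ann$abundances, C_Q, C_L)
  K <- estimate_constants(state)
  list(annotation = ann, fraction_bound = fb, state = state, constants = K)
}

#' Binding inference pooled over replicates
#'
#' @param spectra list of `spectrum` objects (or a `replicate_set`)
#' @inheritParams infer_binding
#' @return list with per-replicate results and pooled
#'   [replicate_summary()] statistics for K1, K2 and fraction bound
#' @export
infer_binding_replicates <- function(spectra, oligo, ...) {
  if (inherits(spectra, "replicate_set")) spectra <- spectra$spectra
  if (length(spectra) == 0L) stop("no spectra supplied")
  fits <- lapply(spectra, infer_binding, oligo = oligo, ...)
  list(
    replicates = fits,
    K1 = replicate_summary(vapply(fits, function(f) f$constants$K1, 0)),
    K2 = replicate_summary(vapply(fits, function(f) f$constants$K2, 0)),
    fraction_bound = replicate_summary(
      vapply(fits, function(f) f$fraction_bound, 0))
  )
}
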