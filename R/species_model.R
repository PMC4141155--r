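#' Complex-ion species
#'
#' An `ion_species` records the stoichiometry of one gas-phase ion:
#' quadruplex : ligand : counter-ion : ammonium counts plus the (negative)
#' charge state. The label convention follows native-MS usage:
#' `[1:1]^5-` is one quadruplex with one ligand cation at z = -5;
#' tosylate and ammonium adducts are rendered as `+cTs +dNH4` suffixes.
#'
#' @param n_quadruplex,n_ligand,n_counterion,n_ammonium non-negative counts
#'   (`n_quadruplex >= 1`)
#' @param charge negative integer charge state
#' @export
ion_species <- function(n_quadruplex = 1L, n_ligand = 0L, n_counterion = 0L,
                        n_ammonium = 0L, charge = -5L) {
  stopifnot(n_quadruplex >= 1, n_ligand >= 0, n_counterion >= 0,
            n_ammonium >= 0, charge <= -1, charge == round(charge))
  structure(
    list(n_quadruplex = as.integer(n_quadruplex),
         n_ligand = as.integer(n_ligand),
         n_counterion = as.integer(n_counterion),
         n_ammonium = as.integer(n_ammonium),
         charge = as.integer(charge)),
    class = "ion_species"
  )
}

#' @export
format.ion_species <- function(x, ...) {
  core <- if (x$n_ligand == 0) {
    if (x$n_quadruplex == 1) "[Q]" else sprintf("[%dQ]", x$n_quadruplex)
  } else {
    sprintf("[%d:%d]", x$n_quadruplex, x$n_ligand)
  }
  lab <- sprintf("%s^%d-", core, abs(x$charge))
  if (x$n_counterion > 0) lab <- sprintf("%s +%dTs", lab, x$n_counterion)
  if (x$n_ammonium > 0) lab <- sprintf("%s +%dNH4", lab, x$n_ammonium)
  lab
}

#' @export
print.ion_species <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' Theoretical m/z of a complex ion
#'
#' Charge bookkeeping treats the ligand as an intrinsic tetracation and
#' ammonium / counter-ion adducts as charged attachments; the observed
#' negative charge is reached by removing protons from the backbone. With
#' intrinsic charge `q = 4*n_ligand + n_ammonium - n_counterion`, the
#' number of protons removed is `n_H = q - z`, and
#' `m/z = (masses - n_H * m_proton) / |z|`.
#'
#' @param species an `ion_species`
#' @param quadruplex_mass neutral strand mass, Da
#' @param molecules molecule list as from [builtin_molecules()]; must
#'   contain `ligand` mass via element `TMPyP4` (or a `ligand` entry),
#'   `tosylate` (counter-ion) and `ammonium`
#' @param mass_mode "average" or "monoisotopic"
#' @return m/z in Da per unit charge
#' @export
ion_mz <- function(species, quadruplex_mass, molecules = builtin_molecules(),
                   mass_mode = c("average", "monoisotopic")) {
  mass_mode <- match.arg(mass_mode)
  stopifnot(inherits(species, "ion_species"), quadruplex_mass > 0)
  key <- paste0(mass_mode, "_mass")
  lig <- if (!is.null(molecules$ligand)) molecules$ligand else molecules$TMPyP4
  ci  <- if (!is.null(molecules$counterion)) molecules$counterion else molecules$tosylate
  m_L <- lig[[key]]; m_CI <- ci[[key]]; m_NH4 <- molecules$ammonium[[key]]
  q_intrinsic <- 4L * species$n_ligand + species$n_ammonium - species$n_counterion
  n_H <- q_intrinsic - species$charge
  if (n_H < 0)
    stop("species ", format(species),
         " cannot reach charge ", species$charge,
         " by deprotonation (intrinsic charge ", q_intrinsic, ")")
  m <- species$n_quadruplex * quadruplex_mass +
    species$n_ligand * m_L +
    species$n_counterion * m_CI +
    species$n_ammonium * m_NH4 -
    n_H * PROTON_MASS
  m / abs(species$charge)
}

#' Enumerate candidate ion species
#'
#' Cartesian product of the configured stoichiometry ranges, in a
#' deterministic order (sorted by ligand count, counter-ion count,
#' ammonium count, then decreasing |z|). Defaults mirror the species
#' inventory seen for TMPyP4-quadruplex mixtures in negative mode:
#' ligand 0-2, counter-ion 0-3, ammonium 0-2, charge -4 to -6.
#'
#' @param n_ligand,n_counterion,n_ammonium integer vectors of counts
#' @param charge integer vector of negative charge states
#' @return list of `ion_species`
#' @export
enumerate_species <- function(n_ligand = 0:2, n_counterion = 0:3,
                              n_ammonium = 0:2, charge = -(4:6)) {
  stopifnot(length(n_ligand) > 0, length(n_counterion) > 0,
            length(n_ammonium) > 0, length(charge) > 0, all(charge <= -1))
  grid <- expand.grid(n_ligand = unique(sort(n_ligand)),
                      n_counterion = unique(sort(n_counterion)),
                      n_ammonium = unique(sort(n_ammonium)),
                      charge = unique(charge))
  grid <- grid[order(grid$n_ligand, grid$n_counterion, grid$n_ammonium,
                     -grid$charge), ]
  lapply(seq_len(nrow(grid)), function(i)
    ion_species(1L, grid$n_ligand[i], grid$n_counterion[i],
                grid$n_ammonium[i], grid$charge[i]))
}

#' Theoretical ion table
#'
#' Computes m/z for every species in a list, dropping species that cannot
#' reach their charge state by deprotonation.
#'
#' @inheritParams ion_mz
#' @param species_list list of `ion_species`
#' @return data.frame with columns `label`, `n_ligand`, `n_counterion`,
#'   `n_ammonium`, `charge`, `mz`, plus a `species` list-column
#' @export
theoretical_ions <- function(species_list, quadruplex_mass,
                             molecules = builtin_molecules(),
                             mass_mode = c("average", "monoisotopic")) {
  mass_mode <- match.arg(mass_mode)
  rows <- lapply(species_list, function(sp) {
    mz <- tryCatch(ion_mz(sp, quadruplex_mass, molecules, mass_mode),
                   error = function(e) NA_real_)
    if (is.na(mz)) return(NULL)
    data.frame(label = format(sp), n_ligand = sp$n_ligand,
               n_counterion = sp$n_counterion, n_ammonium = sp$n_ammonium,
               charge = sp$charge, mz = mz, stringsAsFactors = FALSE)
  })
  keep <- !vapply(rows, is.null, logical(1))
  out <- do.call(rbind, rows[keep])
  out$species <- species_list[keep]
  # deduplicate on identical stoichiometry
  key <- with(out, paste(n_ligand, n_counterion, n_ammonium, charge))
  out <- out[!duplicated(key), ]
  rownames(out) <- NULL
  out
}
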