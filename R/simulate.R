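# run expr with a local RNG stream: the caller's .Random.seed is untouched
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Configuration for a synthetic binding spectrum
#'
#' Defaults emulate an equimolar 10 uM quadruplex/ligand mixture in
#' ammonium acetate whose species abundances follow the 1:1/1:2
#' sequential equilibrium. The ammonium-adduct distribution puts most
#' weight on the 2-adduct ion, the predominant form of the intact
#' quadruplex (two ammoniums sandwiched between the tetrads); charge is
#' spread over -4/-5/-6 with -5 predominant. `counterion_probs` defaults
#' to the tetrachloride case (no counter-ion adducts); pass e.g.
#' `c(0.55, 0.25, 0.15, 0.05)` over 0-3 tosylates for the tetratosylate
#' salt.
#'
#' @param truth `binding_constants` used as ground truth
#' @param C_Q,C_L total concentrations, mol/L
#' @param ammonium_probs probabilities over 0, 1, 2 ammonium adducts
#' @param charge_probs probabilities over charge -4, -5, -6
#' @param counterion_probs probabilities over 0-3 counter-ion adducts
#' @param response_factors per-class (free, 1:1, 1:2) detector response
#' @param mz_jitter_sd Gaussian m/z jitter sd, Da/charge
#' @param area_noise_sd sd of log-normal multiplicative area noise
#' @param n_decoys number of uniform random decoy peaks
#' @param decoy_scale decoy area scale as a fraction of the max true area
#' @param seed integer seed (mandatory)
#' @export
spectrum_sim_config <- function(truth, C_Q = 1e-5, C_L = 1e-5,
                                ammonium_probs = c(0.1, 0.3, 0.6),
                                charge_probs = c(0.2, 0.6, 0.2),
                                counterion_probs = c(1, 0, 0, 0),
                                response_factors = c(1, 1, 1),
                                mz_jitter_sd = 0, area_noise_sd = 0,
                                n_decoys = 0L, decoy_scale = 0.01,
                                seed) {
  stopifnot(inherits(truth, "binding_constants"), C_Q > 0, C_L > 0,
            length(ammonium_probs) == 3, length(charge_probs) == 3,
            length(counterion_probs) == 4, length(response_factors) == 3,
            mz_jitter_sd >= 0, area_noise_sd >= 0, n_decoys >= 0)
  if (missing(seed)) stop("seed is mandatory")
  norm1 <- function(p) {
    if (any(p < 0) || sum(p) <= 0) stop("invalid probability vector")
    p / sum(p)
  }
  structure(list(
    truth = truth, C_Q = C_Q, C_L = C_L,
    ammonium_probs = norm1(ammonium_probs),
    charge_probs = norm1(charge_probs),
    counterion_probs = norm1(counterion_probs),
    response_factors = response_factors,
    mz_jitter_sd = mz_jitter_sd, area_noise_sd = area_noise_sd,
    n_decoys = as.integer(n_decoys), decoy_scale = decoy_scale,
    seed = as.integer(seed)), class = "spectrum_sim_config")
}

#' Simulate a native-MS binding spectrum
#'
#' Forward-solves the equilibrium at the configured truth, normalizes the
#' class concentrations by C_Q into areas (times per-class response
#' factors), distributes each class over the ammonium/charge/counter-ion
#' states by the configured probabilities, applies Gaussian m/z jitter
#' and log-normal area noise, and appends decoy peaks at uniform random
#' m/z. Deterministic for a fixed seed.
#'
#' @param config a `spectrum_sim_config`
#' @param oligo an `oligo_seq` (or notation string)
#' @param molecules molecule list, as [builtin_molecules()]
#' @param mass_mode "average" or "monoisotopic"
#' @return list with `spectrum` (a `spectrum`) and `truth` (the
#'   `equilibrium_state` plus the per-species table actually emitted)
#' @export
simulate_binding_spectrum <- function(config, oligo,
                                      molecules = builtin_molecules(),
                                      mass_mode = "average") {
  stopifnot(inherits(config, "spectrum_sim_config"))
  if (is.character(oligo)) oligo <- parse_oligo(oligo)
  M_Q <- if (mass_mode == "average") average_mass(oligo)
         else monoisotopic_mass(oligo)
  state <- solve_equilibrium(config$C_Q, config$C_L, config$truth)
  class_conc <- c(state$free_Q, state$c11, state$c12)
  class_area <- class_conc / config$C_Q * config$response_factors

  with_local_seed(config$seed, {
    rows <- list()
    for (k in 0:2) {                       # ligand stoichiometry class
      if (class_area[k + 1] <= 0) next
      for (ci in 0:3) {
        p_ci <- config$counterion_probs[ci + 1]
        if (p_ci <= 0) next
        for (nh in 0:2) {
          p_nh <- config$ammonium_probs[nh + 1]
          if (p_nh <= 0) next
          for (zi in 1:3) {
            z <- -(3L + zi)                # -4, -5, -6
            p_z <- config$charge_probs[zi]
            if (p_z <= 0) next
            sp <- ion_species(1L, k, ci, nh, z)
            mz <- tryCatch(ion_mz(sp, M_Q, molecules, mass_mode),
                           error = function(e) NA_real_)
            if (is.na(mz)) next
            rows[[length(rows) + 1L]] <- data.frame(
              label = format(sp), n_ligand = k, n_counterion = ci,
              n_ammonium = nh, charge = z, mz_true = mz,
              area_true = class_area[k + 1] * p_ci * p_nh * p_z,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    truth_tab <- do.call(rbind, rows)
    mz_obs <- truth_tab$mz_true +
      stats::rnorm(nrow(truth_tab), 0, config$mz_jitter_sd)
    area_obs <- truth_tab$area_true *
      exp(stats::rnorm(nrow(truth_tab), 0, config$area_noise_sd))
    if (config$n_decoys > 0L) {
      win <- range(truth_tab$mz_true) + c(-50, 50)
      mz_obs <- c(mz_obs, stats::runif(config$n_decoys, win[1], win[2]))
      area_obs <- c(area_obs,
                    stats::runif(config$n_decoys) * config$decoy_scale *
                      max(truth_tab$area_true))
    }
    meta <- list(polarity = "negative", C_Q = config$C_Q, C_L = config$C_L,
                 ligand = "TMPyP4", seed = config$seed)
    list(spectrum = new_spectrum(mz_obs, area_obs, meta),
         truth = list(state = state, species = truth_tab,
                      quadruplex_mass = M_Q))
  })
}

#' Simulate a two-state UV melting curve
#'
#' Folded fraction from the van 't Hoff two-state model,
#' `theta(T) = 1 / (1 + exp[(dH/R) (1/Tm - 1/T)])` in Kelvin, so that
#' `theta(Tm) = 0.5` exactly; absorbance is the theta-weighted mix of the
#' two linear baselines plus Gaussian noise. The default hypochromic
#' baselines (folded above unfolded) match quadruplex melting at 295 nm.
#'
#' @param Tm melting temperature, degrees C, inside the grid
#' @param dH_vH van 't Hoff enthalpy, kcal/mol (> 0)
#' @param grid temperature grid, degrees C (default 20-95 in 0.5 steps)
#' @param baseline_folded,baseline_unfolded c(intercept, slope) of each
#'   baseline in absorbance units
#' @param noise_sd Gaussian absorbance noise sd
#' @param seed integer seed
#' @return a `melting_curve`
#' @export
simulate_melting_curve <- function(Tm, dH_vH = 45,
                                   grid = seq(20, 95, by = 0.5),
                                   baseline_folded = c(1.00, -0.0005),
                                   baseline_unfolded = c(0.62, -0.0002),
                                   noise_sd = 0, seed = 1L) {
  stopifnot(dH_vH > 0)
  if (Tm < min(grid) || Tm > max(grid))
    stop("Tm must lie inside the temperature grid")
  R <- 1.98720425e-3                      # kcal / (mol K)
  TK <- grid + 273.15; TmK <- Tm + 273.15
  theta <- 1 / (1 + exp((dH_vH / R) * (1 / TmK - 1 / TK)))
  A_f <- baseline_folded[1] + baseline_folded[2] * grid
  A_u <- baseline_unfolded[1] + baseline_unfolded[2] * grid
  A <- theta * A_f + (1 - theta) * A_u
  if (noise_sd > 0)
    A <- with_local_seed(seed, A + stats::rnorm(length(A), 0, noise_sd))
  melting_curve(grid, A)
}
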