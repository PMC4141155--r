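#' Match observed peaks to theoretical ions
#'
#' Greedy one-to-one matching in order of increasing |observed -
#' theoretical| m/z. Each peak is assigned to at most one species and each
#' theoretical ion claims at most one peak. Ties (equal |delta| within
#' 1e-9) are broken in favour of the species with fewer total adducts,
#' then lexicographic label order. The default tolerance of 1.0 Da/charge
#' tolerates a per-spectrum calibration offset while staying well below
#' the smallest inter-species spacing in the default enumeration.
#'
#' @param spectrum a `spectrum`
#' @param ions theoretical ion table from [theoretical_ions()]
#' @param tolerance maximum |delta m/z| in Da per unit charge
#' @return list with `assignments` (data.frame: mz, area, label, n_ligand,
#'   n_counterion, n_ammonium, charge, theoretical_mz, delta_mz) and
#'   `unassigned` (data.frame of unmatched peaks)
#' @export
match_peaks <- function(spectrum, ions, tolerance = 1.0) {
  stopifnot(inherits(spectrum, "spectrum"), tolerance > 0)
  np <- nrow(spectrum); ni <- nrow(ions)
  if (np == 0L)
    return(list(assignments = empty_assignments(), unassigned = spectrum))
  # candidate pairs within tolerance
  cand <- do.call(rbind, lapply(seq_len(ni), function(j) {
    d <- spectrum$mz - ions$mz[j]
    ok <- which(abs(d) <= tolerance)
    if (!length(ok)) return(NULL)
    data.frame(peak = ok, ion = j, delta = d[ok],
               adducts = ions$n_counterion[j] + ions$n_ammonium[j],
               label = ions$label[j], stringsAsFactors = FALSE)
  }))
  assigned_peak <- rep(FALSE, np); assigned_ion <- rep(FALSE, ni)
  rows <- list()
  if (!is.null(cand) && nrow(cand)) {
    # round |delta| so that numerically-equal distances tie deterministically
    cand <- cand[order(round(abs(cand$delta), 9), cand$adducts, cand$label), ]
    for (r in seq_len(nrow(cand))) {
      p <- cand$peak[r]; j <- cand$ion[r]
      if (assigned_peak[p] || assigned_ion[j]) next
      assigned_peak[p] <- TRUE; assigned_ion[j] <- TRUE
      rows[[length(rows) + 1L]] <- data.frame(
        mz = spectrum$mz[p], area = spectrum$area[p],
        label = ions$label[j], n_ligand = ions$n_ligand[j],
        n_counterion = ions$n_counterion[j],
        n_ammonium = ions$n_ammonium[j], charge = ions$charge[j],
        theoretical_mz = ions$mz[j], delta_mz = cand$delta[r],
        stringsAsFactors = FALSE)
    }
  }
  assignments <- if (length(rows)) do.call(rbind, rows) else empty_assignments()
  assignments <- assignments[order(assignments$mz), , drop = FALSE]
  rownames(assignments) <- NULL
  unassigned <- as.data.frame(spectrum)[!assigned_peak, , drop = FALSE]
  rownames(unassigned) <- NULL
  list(assignments = assignments, unassigned = unassigned)
}

empty_assignments <- function() {
  data.frame(mz = numeric(0), area = numeric(0), label = character(0),
             n_ligand = integer(0), n_counterion = integer(0),
             n_ammonium = integer(0), charge = integer(0),
             theoretical_mz = numeric(0), delta_mz = numeric(0),
             stringsAsFactors = FALSE)
}

#' Aggregate assigned areas into stoichiometry classes
#'
#' Sums peak areas per (n_ligand, n_counterion) class, collapsing charge
#' states and ammonium adduct counts within a class. Total area is
#' conserved: class sums plus the unassigned total equal the input total.
#'
#' @param matched result of [match_peaks()], or a bare assignment
#'   data.frame plus `unassigned_area`
#' @param unassigned_area total area of unmatched peaks (ignored when
#'   `matched` comes from [match_peaks()])
#' @return an `abundance_table`: data.frame with columns `n_ligand`,
#'   `n_counterion`, `area`; attribute `unassigned_area`
#' @export
aggregate_abundances <- function(matched, unassigned_area = 0) {
  if (is.list(matched) && !is.data.frame(matched) &&
      all(c("assignments", "unassigned") %in% names(matched))) {
    unassigned_area <- sum(matched$unassigned$area)
    matched <- matched$assignments
  }
  stopifnot(is.data.frame(matched))
  if (nrow(matched) == 0L) {
    tab <- data.frame(n_ligand = integer(0), n_counterion = integer(0),
                      area = numeric(0))
  } else {
    agg <- stats::aggregate(area ~ n_ligand + n_counterion, data = matched,
                            FUN = sum)
    tab <- agg[order(agg$n_ligand, agg$n_counterion), , drop = FALSE]
  }
  rownames(tab) <- NULL
  attr(tab, "unassigned_area") <- unassigned_area
  class(tab) <- c("abundance_table", "data.frame")
  tab
}

#' @export
print.abundance_table <- function(x, ...) {
  cat("stoichiometry-class abundances (unassigned area:",
      format(attr(x, "unassigned_area")), ")\n")
  NextMethod()
}
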