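#' Melting curve container
#'
#' @param temperature degrees C, strictly increasing, >= 10 points
#' @param absorbance arbitrary units
#' @param wavelength label, e.g. "295 nm" (quadruplex unfolding is
#'   hypochromic at 295 nm)
#' @return a `melting_curve` data.frame
#' @export
melting_curve <- function(temperature, absorbance, wavelength = "295 nm") {
  stopifnot(length(temperature) == length(absorbance),
            length(temperature) >= 10)
  if (any(diff(temperature) <= 0))
    stop("temperature must be strictly increasing")
  df <- data.frame(temperature = temperature, absorbance = absorbance)
  attr(df, "wavelength") <- wavelength
  class(df) <- c("melting_curve", "data.frame")
  df
}

#' Read a melting curve from delimited text
#'
#' Columns `temperature_C, absorbance` (CSV with header, or two bare
#' whitespace-delimited numeric columns); `#` comments allowed.
#'
#' @param path file path
#' @param wavelength wavelength label
#' @return a `melting_curve`
#' @export
read_melting_curve <- function(path, wavelength = "295 nm") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0L) stop("empty melting-curve file: ", path)
  has_header <- grepl("[A-Za-z]", lines[1])
  df <- utils::read.table(text = lines, header = has_header,
                          sep = if (grepl(",", lines[1])) "," else "")
  melting_curve(df[[1]], df[[2]], wavelength)
}

#' Extract the melting temperature from a curve
#'
#' Midpoint method (default): straight lines are fitted to the folded and
#' unfolded baseline windows (defaults: first and last 10 percent of
#' points); the folded fraction is
#' `theta(T) = (A(T) - A_u(T)) / (A_f(T) - A_u(T))` and Tm is the linear
#' interpolation of the theta = 0.5 crossing. Both hypochromic and
#' hyperchromic transitions work, since the baseline ordering carries the
#' sign. Derivative method: a smoothing spline of A(T) is differentiated
#' and Tm is the argmax of |dA/dT| on a fine grid.
#'
#' @param curve a `melting_curve`
#' @param method "midpoint" or "derivative"
#' @param baseline_frac fraction of points in each initial baseline window
#'   (midpoint method)
#' @param refine after the window-based estimate, refit baselines and
#'   transition jointly (two-state model with linear baselines, Levenberg-
#'   Marquardt); removes the bias the transition tails put on the edge
#'   windows when a broad transition never fully reaches its unfolded
#'   baseline inside the scanned range. Default `TRUE`; on fit failure the
#'   window-based estimate is returned.
#' @return list with `Tm` (degrees C), `method`, and for the midpoint
#'   method the fitted baseline coefficients
#' @export
extract_tm <- function(curve, method = c("midpoint", "derivative"),
                       baseline_frac = 0.10, refine = TRUE) {
  method <- match.arg(method)
  stopifnot(inherits(curve, "melting_curve"))
  Tc <- curve$temperature; A <- curve$absorbance
  n <- length(Tc)
  if (method == "midpoint") {
    k <- max(3L, ceiling(baseline_frac * n))
    lo <- seq_len(k); hi <- seq(n - k + 1L, n)
    fit_f <- stats::lm(A[lo] ~ Tc[lo])   # folded (low-T) baseline
    fit_u <- stats::lm(A[hi] ~ Tc[hi])   # unfolded (high-T) baseline
    A_f <- stats::coef(fit_f)[1] + stats::coef(fit_f)[2] * Tc
    A_u <- stats::coef(fit_u)[1] + stats::coef(fit_u)[2] * Tc
    sep <- A_f - A_u
    if (max(abs(sep)) < 1e-12 * max(abs(A), 1))
      stop("degenerate baselines: no transition amplitude")
    theta <- (A - A_u) / sep
    cross <- which(diff(sign(theta - 0.5)) != 0)
    # restrict to the transition region between the baseline windows
    cross <- cross[cross >= k & cross <= n - k]
    if (length(cross) == 0L)
      stop("folded fraction never crosses 0.5: no melting transition found")
    i <- cross[which.min(abs(Tc[cross] - stats::median(Tc)))]
    t0 <- theta[i] - 0.5; t1 <- theta[i + 1L] - 0.5
    Tm <- Tc[i] + (Tc[i + 1L] - Tc[i]) * t0 / (t0 - t1)
    bf <- stats::coef(fit_f); bu <- stats::coef(fit_u)
    if (refine) {
      ref <- refine_two_state(Tc, A, Tm, theta, bf, bu)
      if (!is.null(ref)) { Tm <- ref$Tm; bf <- ref$bf; bu <- ref$bu }
    }
    list(Tm = as.numeric(Tm), method = "midpoint",
         baseline_folded = bf, baseline_unfolded = bu)
  } else {
    # differentiate against 1/T(K): the two-state transition is symmetric
    # in inverse temperature, so the |dA/d(1/T)| extremum sits at Tm
    # without the O(R Tm^2 / dH) skew a dA/dT argmax has on broad
    # transitions
    invT <- 1 / (Tc + 273.15)
    sp <- stats::smooth.spline(invT, A, spar = 0.3)
    grid <- seq(min(Tc) + 2, max(Tc) - 2, length.out = 2000L)
    dA <- stats::predict(sp, 1 / (grid + 273.15), deriv = 1)$y
    Tm <- grid[which.max(abs(dA))]
    list(Tm = as.numeric(Tm), method = "derivative")
  }
}

two_state_absorbance <- function(Tc, Tm, dH, f0, f1, u0, u1) {
  R <- 1.98720425e-3
  th <- 1 / (1 + exp((dH / R) * (1 / (Tm + 273.15) - 1 / (Tc + 273.15))))
  th * (f0 + f1 * Tc) + (1 - th) * (u0 + u1 * Tc)
}

# joint two-state refit: A(T) = theta(Tm,dH)*(bf0+bf1*T) + (1-theta)*(bu0+bu1*T)
# theta is the van 't Hoff sigmoid; returns NULL when the fit fails or the
# refined Tm leaves the scanned range
refine_two_state <- function(Tc, A, Tm0, theta0, bf, bu) {
  R <- 1.98720425e-3
  # initial enthalpy from the folded-fraction slope at the midpoint:
  # |d theta/dT| at Tm = dH / (4 R Tm_K^2)
  i <- which.min(abs(Tc - Tm0))
  ii <- max(2L, min(length(Tc) - 1L, i))
  slope <- abs((theta0[ii + 1L] - theta0[ii - 1L]) / (Tc[ii + 1L] - Tc[ii - 1L]))
  dH0 <- max(10, min(200, 4 * R * (Tm0 + 273.15)^2 * slope))
  df <- data.frame(Tc = Tc, A = A)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      A ~ two_state_absorbance(Tc, Tm, dH, f0, f1, u0, u1),
      data = df,
      start = list(Tm = Tm0, dH = dH0, f0 = bf[[1]], f1 = bf[[2]],
                   u0 = bu[[1]], u1 = bu[[2]]),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  p <- stats::coef(fit)
  if (!is.finite(p[["Tm"]]) || p[["Tm"]] < min(Tc) || p[["Tm"]] > max(Tc))
    return(NULL)
  list(Tm = p[["Tm"]],
       bf = c(p[["f0"]], p[["f1"]]), bu = c(p[["u0"]], p[["u1"]]))
}

#' Ligand-induced melting-temperature shift
#'
#' `delta Tm = mean Tm(with ligand) - mean Tm(without)`, with sd
#' propagated as `sqrt(sd1^2/n1 + sd2^2/n2)` (NA when either arm has a
#' single replicate).
#'
#' @param with_ligand,without lists of `melting_curve` objects (or
#'   `replicate_set`s of them)
#' @param ... passed to [extract_tm()]
#' @return list with `delta_Tm`, `sd`, and the per-arm Tm summaries
#' @export
delta_tm <- function(with_ligand, without, ...) {
  arm <- function(x) {
    if (inherits(x, "replicate_set")) x <- x$spectra
    if (inherits(x, "melting_curve")) x <- list(x)
    if (length(x) == 0L) stop("empty replicate arm")
    vapply(x, function(cv) extract_tm(cv, ...)$Tm, 0)
  }
  tw <- arm(with_ligand); to <- arm(without)
  sw <- replicate_summary(tw); so <- replicate_summary(to)
  sd_prop <- if (is.na(sw$sd) || is.na(so$sd)) NA_real_ else
    sqrt(sw$sd^2 / sw$n + so$sd^2 / so$n)
  list(delta_Tm = sw$mean - so$mean, sd = sd_prop,
       with_ligand = sw, without = so)
}
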