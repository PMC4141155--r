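#' Fraction of bound quadruplex
#'
#' The relative-binding-affinity statistic: the peak-area share of
#' ligand-containing complexes among all quadruplex-containing species.
#' Counter-ion-only adducts of the free quadruplex (n_ligand = 0,
#' n_counterion >= 1) count as bound only when
#' `counterion_only_is_bound = TRUE`.
#'
#' @param table an `abundance_table`
#' @param counterion_only_is_bound policy flag, default `FALSE`
#' @return fraction in [0, 1]
#' @export
fraction_bound <- function(table, counterion_only_is_bound = FALSE) {
  stopifnot(is.data.frame(table), nrow(table) >= 1)
  total <- sum(table$area)
  if (total <= 0) stop("zero total quadruplex-containing area")
  bound <- table$n_ligand >= 1
  if (counterion_only_is_bound)
    bound <- bound | (table$n_ligand == 0 & table$n_counterion >= 1)
  sum(table$area[bound]) / total
}

#' Equilibrium species concentrations from relative peak areas
#'
#' Assumes peak areas are proportional to solution abundances. After
#' collapsing the counter-ion dimension, each ligand-stoichiometry class i
#' gets concentration `C_Q * A_i / sum(A)`; free ligand follows by
#' difference from the ligand mass balance.
#'
#' @param table an `abundance_table` (classes with n_ligand 0, 1, 2)
#' @param C_Q,C_L total quadruplex and ligand concentrations, mol/L
#' @return an `equilibrium_state`: list with `free_Q`, `c11`, `c12`,
#'   `free_L` (mol/L)
#' @export
concentrations_from_areas <- function(table, C_Q, C_L) {
  stopifnot(is.data.frame(table), C_Q > 0, C_L > 0)
  if (any(table$n_ligand > 2))
    stop("classes with n_ligand > 2 are outside the 1:1/1:2 sequential model")
  a <- vapply(0:2, function(k) sum(table$area[table$n_ligand == k]), 0)
  total <- sum(a)
  if (total <= 0) stop("zero total area")
  conc <- C_Q * a / total
  free_L <- C_L - conc[2] - 2 * conc[3]
  if (free_L <= 0)
    stop(sprintf(paste0(
      "ligand mass balance violated: c11 + 2*c12 = %.4g M >= C_L = %.4g M ",
      "(areas imply more ligand sequestered than supplied)"),
      conc[2] + 2 * conc[3], C_L))
  equilibrium_state(free_Q = conc[1], c11 = conc[2], c12 = conc[3],
                    free_L = free_L)
}

#' Equilibrium state constructor
#'
#' Species concentrations (mol/L) of the sequential binding equilibrium:
#' free quadruplex, 1:1 complex, 1:2 complex and free ligand.
#'
#' @param free_Q,c11,c12,free_L concentrations, mol/L, all >= 0
#' @export
equilibrium_state <- function(free_Q, c11, c12, free_L) {
  stopifnot(free_Q >= 0, c11 >= 0, c12 >= 0, free_L >= 0)
  structure(list(free_Q = free_Q, c11 = c11, c12 = c12, free_L = free_L),
            class = "equilibrium_state")
}

#' @export
print.equilibrium_state <- function(x, ...) {
  cat(sprintf(
    "equilibrium (uM): free Q %.4g | 1:1 %.4g | 1:2 %.4g | free L %.4g\n",
    1e6 * x$free_Q, 1e6 * x$c11, 1e6 * x$c12, 1e6 * x$free_L))
  invisible(x)
}

#' Sequential association constants from an equilibrium state
#'
#' K1 = [1:1] / ([free Q] [free L]); K2 = [1:2] / ([1:1] [free L]).
#' When the 1:2 complex is absent, K2 is reported as 0 with attribute
#' `k2_estimable = FALSE` rather than an error.
#'
#' @param state an `equilibrium_state` with positive free_Q, free_L, c11
#' @return a `binding_constants` list with `K1`, `K2` (1/M)
#' @export
estimate_constants <- function(state) {
  stopifnot(inherits(state, "equilibrium_state"))
  if (state$free_Q <= 0)
    stop("free quadruplex concentration is zero; K1 undefined")
  if (state$free_L <= 0)
    stop("free ligand concentration is zero; K1, K2 undefined")
  if (state$c11 <= 0)
    stop("1:1 complex concentration is zero; K1 = 0 boundary, K2 undefined")
  K1 <- state$c11 / (state$free_Q * state$free_L)
  K2 <- state$c12 / (state$c11 * state$free_L)
  binding_constants(K1, K2, k2_estimable = state$c12 > 0)
}

#' @param K1,K2 association constants, 1/M
#' @param k2_estimable logical flag carried for K2 = 0 boundary cases
#' @rdname estimate_constants
#' @export
binding_constants <- function(K1, K2, k2_estimable = TRUE) {
  stopifnot(K1 >= 0, K2 >= 0)
  structure(list(K1 = K1, K2 = K2),
            k2_estimable = k2_estimable, class = "binding_constants")
}

#' @export
print.binding_constants <- function(x, ...) {
  cat("K1 =", format_constant(x$K1), "  K2 =",
      if (isFALSE(attr(x, "k2_estimable"))) "not estimable (c12 = 0)"
      else format_constant(x$K2), "\n")
  invisible(x)
}

#' Render a constant in scientific report style
#'
#' @param x value in 1/M
#' @return string like "1.87 x 10^6 M-1"
#' @export
format_constant <- function(x) {
  if (x == 0) return("0 M-1")
  e <- floor(log10(abs(x)))
  sprintf("%.2f x 10^%d M-1", x / 10^e, e)
}

#' Forward-solve the sequential binding equilibrium
#'
#' Given total concentrations and K1/K2, finds the unique free-ligand
#' concentration l in (0, C_L) solving the ligand mass balance
#' `l + (K1 l + 2 K1 K2 l^2) C_Q / (1 + K1 l + K1 K2 l^2) = C_L`
#' (continuous and strictly increasing in l), by bracketed root finding
#' followed by Newton polishing; then recovers all species from the
#' binding polynomial. Both mass balances close to 1e-12 relative.
#'
#' @param C_Q,C_L total quadruplex / ligand concentrations, mol/L
#' @param K a `binding_constants` (K1, K2 in 1/M; either may be 0)
#' @return an `equilibrium_state`
#' @export
solve_equilibrium <- function(C_Q, C_L, K) {
  stopifnot(is.finite(C_Q), is.finite(C_L), C_Q > 0, C_L > 0)
  K1 <- K$K1; K2 <- K$K2
  stopifnot(is.finite(K1), is.finite(K2), K1 >= 0, K2 >= 0)
  if (K1 == 0)
    return(equilibrium_state(C_Q, 0, 0, C_L))
  g <- function(l) {
    denom <- 1 + K1 * l + K1 * K2 * l^2
    l + (K1 * l + 2 * K1 * K2 * l^2) * C_Q / denom - C_L
  }
  gp <- function(l) {
    denom <- 1 + K1 * l + K1 * K2 * l^2
    num <- K1 * l + 2 * K1 * K2 * l^2
    dnum <- K1 + 4 * K1 * K2 * l
    ddenom <- K1 + 2 * K1 * K2 * l
    1 + C_Q * (dnum * denom - num * ddenom) / denom^2
  }
  l <- stats::uniroot(g, c(0, C_L), tol = .Machine$double.eps * C_L)$root
  for (i in 1:8) {                 # Newton polish to machine precision
    step <- g(l) / gp(l)
    l_new <- min(max(l - step, 0), C_L)
    if (!is.finite(l_new) || abs(l_new - l) <= .Machine$double.eps * l) {
      l <- l_new; break
    }
    l <- l_new
  }
  denom <- 1 + K1 * l + K1 * K2 * l^2
  free_Q <- C_Q / denom
  c11 <- K1 * free_Q * l
  c12 <- K1 * K2 * free_Q * l^2
  equilibrium_state(free_Q, c11, c12, l)
}

#' Replicate summary statistics
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator);
#' the sd is reported as `NA` for a single replicate.
#'
#' @param values numeric vector, one value per replicate
#' @return list with `mean`, `sd`, `n` and a formatted `label`
#' @export
replicate_summary <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0L) stop("no replicate values supplied")
  m <- mean(values)
  s <- if (n >= 2L) stats::sd(values) else NA_real_
  list(mean = m, sd = s, n = n,
       label = if (is.na(s)) sprintf("%.4g (n = 1)", m)
               else sprintf("%.4g +/- %.2g (n = %d)", m, s, n))
}

#' Ratio of binding affinities between two targets
#'
#' @param K_a,K_b `binding_constants` for the numerator and denominator
#'   targets
#' @return list with `K1_ratio`, `K2_ratio`
#' @export
affinity_ratio <- function(K_a, K_b) {
  if (K_b$K1 <= 0 || K_b$K2 <= 0)
    stop("denominator constants must be positive")
  list(K1_ratio = K_a$K1 / K_b$K1, K2_ratio = K_a$K2 / K_b$K2)
}
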