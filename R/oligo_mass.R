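#' Elemental compositions
#'
#' An `elem_comp` is a named integer vector of element counts (C, H, N, O,
#' P, S, ...). Addition and subtraction are element-wise; subtraction that
#' would produce a negative count is an error.
#'
#' @param ... named element counts, e.g. `elem_comp(C = 10, H = 14, N = 2, O = 5)`
#' @return an object of class `elem_comp`
#' @export
elem_comp <- function(...) {
  x <- c(...)
  if (length(x) == 0L)
    return(structure(stats::setNames(numeric(0), character(0)),
                     class = "elem_comp"))
  if (is.null(names(x)) || any(names(x) == ""))
    stop("elem_comp: all counts must be named by element symbol")
  if (any(x < 0)) stop("elem_comp: negative element count")
  if (any(x != round(x))) stop("elem_comp: non-integer element count")
  x <- tapply(x, names(x), sum)       # merge duplicated symbols
  x <- x[x > 0, drop = FALSE]
  out <- as.numeric(x)
  names(out) <- names(x)
  out <- out[order(names(out))]
  structure(out, class = "elem_comp")
}

as_elem_comp <- function(x) {
  if (inherits(x, "elem_comp")) return(x)
  do.call(elem_comp, as.list(x))
}

#' @export
Ops.elem_comp <- function(e1, e2) {
  if (!.Generic %in% c("+", "-"))
    stop("operation '", .Generic, "' not defined for elem_comp")
  a <- as_elem_comp(e1); b <- as_elem_comp(e2)
  els <- union(names(a), names(b))
  av <- stats::setNames(rep(0, length(els)), els); av[names(a)] <- a
  bv <- stats::setNames(rep(0, length(els)), els); bv[names(b)] <- b
  r <- if (.Generic == "+") av + bv else av - bv
  if (any(r < 0)) stop("elem_comp subtraction produced a negative count")
  do.call(elem_comp, as.list(r))
}

#' @export
format.elem_comp <- function(x, ...) {
  # Hill order: C, H, then alphabetical
  els <- names(x)
  ord <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  paste0(ord, ifelse(unclass(x)[ord] == 1, "", unclass(x)[ord]), collapse = "")
}

#' @export
print.elem_comp <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Parse oligonucleotide sequence notation
#'
#' Accepts the compact bracket notation used for synthetic oligos, e.g.
#' `d[(TTAGGG)4TTA]` for DNA or `r[(UUAGGG)4UUA]` for RNA, with
#' parenthesized repeat groups (both `(TTAGGG)4` and the underscored
#' `(TTAGGG)_4_` dialect), or a bare base string (assumed DNA unless it
#' contains U).
#'
#' @param text sequence notation string
#' @param five_prime_phosphate logical; `TRUE` if the strand carries a
#'   5'-terminal phosphate. Default `FALSE`, matching vendor desalted
#'   oligos with free 5'-OH.
#' @return an `oligo_seq` object with fields `alphabet` ("DNA"/"RNA"),
#'   `residues` (character vector of bases) and `five_prime_phosphate`
#' @examples
#' parse_oligo("d[(TTAGGG)4TTA]")
#' @export
parse_oligo <- function(text, five_prime_phosphate = FALSE) {
  stopifnot(is.character(text), length(text) == 1L)
  txt <- gsub("\\s", "", text)
  alphabet <- NULL
  body <- txt
  m <- regmatches(txt, regexec("^([dr])\\[(.*)\\]$", txt))[[1]]
  if (length(m) == 3L) {
    alphabet <- if (m[2] == "d") "DNA" else "RNA"
    body <- m[3]
  } else if (grepl("^[dr]\\[", txt) || grepl("\\]$", txt)) {
    stop("unbalanced brackets in oligo notation: ", text)
  }
  # normalize the underscored repeat dialect (TTAGGG)_4_ -> (TTAGGG)4
  body <- gsub("\\)_([0-9]+)_", ")\\1", body)
  if (body == "") stop("empty oligo sequence: ", text)

  residues <- character(0)
  i <- 1L
  chars <- strsplit(body, "")[[1]]
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "(") {
      close <- NULL
      for (j in seq(i + 1L, n)) if (chars[j] == ")") { close <- j; break }
      if (is.null(close)) stop("unbalanced parenthesis in: ", text)
      grp <- chars[seq(i + 1L, close - 1L)]
      if (length(grp) == 0L) stop("empty repeat group in: ", text)
      k <- close + 1L
      digs <- character(0)
      while (k <= n && grepl("[0-9]", chars[k])) { digs <- c(digs, chars[k]); k <- k + 1L }
      if (length(digs) == 0L) stop("repeat group without count in: ", text)
      rep_count <- as.integer(paste(digs, collapse = ""))
      if (rep_count <= 0L) stop("zero or negative repeat count in: ", text)
      residues <- c(residues, rep(grp, rep_count))
      i <- k
    } else if (ch == ")") {
      stop("unbalanced parenthesis in: ", text)
    } else {
      residues <- c(residues, ch)
      i <- i + 1L
    }
  }
  if (is.null(alphabet))
    alphabet <- if ("U" %in% residues) "RNA" else "DNA"
  legal <- names(NUCLEOTIDE_RESIDUES[[alphabet]])
  bad <- setdiff(unique(residues), legal)
  if (length(bad))
    stop("illegal base(s) for ", alphabet, ": ", paste(bad, collapse = ", "))
  structure(
    list(alphabet = alphabet, residues = residues,
         five_prime_phosphate = isTRUE(five_prime_phosphate)),
    class = "oligo_seq"
  )
}

#' @export
format.oligo_seq <- function(x, ...) {
  paste0(if (x$alphabet == "DNA") "d[" else "r[",
         paste(x$residues, collapse = ""), "]")
}

#' @export
print.oligo_seq <- function(x, ...) {
  cat(format(x), sprintf("(%s, %d nt%s)\n", x$alphabet, length(x$residues),
      if (x$five_prime_phosphate) ", 5'-p" else ""))
  invisible(x)
}

#' Elemental composition of an oligonucleotide strand
#'
#' Sums the internal-residue compositions (nucleoside-5'-monophosphate
#' minus water) and adds one water for the chain termini. For the default
#' free 5'-OH strand one HPO3 is removed, leaving the neutral free-acid
#' phosphodiester with 5'-OH and 3'-OH ends.
#'
#' @param seq an `oligo_seq` (or notation string, parsed on the fly)
#' @return an `elem_comp`
#' @export
oligo_composition <- function(seq) {
  if (is.character(seq)) seq <- parse_oligo(seq)
  stopifnot(inherits(seq, "oligo_seq"))
  tab <- NUCLEOTIDE_RESIDUES[[seq$alphabet]]
  counts <- table(factor(seq$residues, levels = names(tab)))
  total <- stats::setNames(rep(0, 6), c("C", "H", "N", "O", "P", "S"))
  for (b in names(tab)) {
    if (counts[[b]] == 0) next
    r <- tab[[b]]
    total[names(r)] <- total[names(r)] + counts[[b]] * r
  }
  comp <- do.call(elem_comp, as.list(total[total > 0]))
  comp <- comp + as_elem_comp(WATER)
  if (!seq$five_prime_phosphate) comp <- comp - as_elem_comp(HPO3)
  comp
}

mass_from_comp <- function(comp, mode = c("average", "monoisotopic")) {
  mode <- match.arg(mode)
  comp <- as_elem_comp(comp)
  idx <- match(names(comp), atomic_masses$element)
  if (anyNA(idx))
    stop("unknown element symbol(s): ",
         paste(names(comp)[is.na(idx)], collapse = ", "))
  sum(unclass(comp) * atomic_masses[[mode]][idx])
}

#' Average molecular mass of a composition
#'
#' @param comp an `elem_comp`, an `oligo_seq`, or a notation string
#' @return mass in Da, from standard average atomic weights
#' @examples
#' average_mass("d[(TTAGGG)4TTA]")  # 8496.6 Da
#' @export
average_mass <- function(comp) {
  if (is.character(comp) || inherits(comp, "oligo_seq"))
    comp <- oligo_composition(comp)
  mass_from_comp(comp, "average")
}

#' Monoisotopic mass of a composition
#'
#' @inheritParams average_mass
#' @return mass in Da, from principal-isotope masses
#' @export
monoisotopic_mass <- function(comp) {
  if (is.character(comp) || inherits(comp, "oligo_seq"))
    comp <- oligo_composition(comp)
  mass_from_comp(comp, "monoisotopic")
}

#' Built-in small-molecule species
#'
#' The molecules needed for TMPyP4-salt binding studies: the TMPyP4
#' tetracation (C44H38N8, +4), the tosylate counter-anion (C7H7O3S, -1)
#' and the ammonium adduct cation (NH4, +1). Masses are computed from the
#' compositions; `intrinsic_charge` is the formal charge the species
#' carries into an ion.
#'
#' @return a named list of molecule specs, each with fields `name`,
#'   `composition`, `intrinsic_charge`, `average_mass`, `monoisotopic_mass`
#' @export
builtin_molecules <- function() {
  mk <- function(name, comp, q) {
    list(name = name, composition = comp, intrinsic_charge = q,
         average_mass = mass_from_comp(comp, "average"),
         monoisotopic_mass = mass_from_comp(comp, "monoisotopic"))
  }
  list(
    TMPyP4   = mk("TMPyP4",   elem_comp(C = 44, H = 38, N = 8), +4L),
    tosylate = mk("tosylate", elem_comp(C = 7, H = 7, O = 3, S = 1), -1L),
    ammonium = mk("ammonium", elem_comp(N = 1, H = 4), +1L)
  )
}
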