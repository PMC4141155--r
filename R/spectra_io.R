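#' Spectrum container
#'
#' A `spectrum` is a data.frame with numeric columns `mz` (strictly
#' ascending) and `area` (>= 0), carrying experiment metadata as an
#' attribute: strand/ligand concentrations (`C_Q`, `C_L`, mol/L), ligand
#' and counter-ion names, replicate id, polarity and buffer descriptor.
#'
#' @param mz,area numeric vectors of equal length
#' @param metadata named list of metadata fields
#' @export
new_spectrum <- function(mz, area, metadata = list()) {
  stopifnot(length(mz) == length(area), all(mz > 0), all(area >= 0))
  o <- order(mz)
  mz <- mz[o]; area <- area[o]
  # merge exact-duplicate m/z rows by summing areas
  if (anyDuplicated(mz)) {
    area <- as.numeric(tapply(area, factor(mz, levels = unique(mz)), sum))
    mz <- unique(mz)
  }
  df <- data.frame(mz = mz, area = area)
  attr(df, "metadata") <- metadata
  class(df) <- c("spectrum", "data.frame")
  df
}

#' @export
print.spectrum <- function(x, ...) {
  md <- attr(x, "metadata")
  cat(sprintf("spectrum: %d peaks, total area %.4g\n", nrow(x), sum(x$area)))
  if (length(md)) {
    flat <- vapply(md, function(v) paste(format(v), collapse = ","), "")
    cat("  ", paste(names(flat), flat, sep = "=", collapse = "  "), "\n")
  }
  NextMethod()
}

#' Metadata attached to a spectrum
#'
#' @param s a `spectrum`
#' @return the named metadata list
#' @export
spectrum_metadata <- function(s) attr(s, "metadata")

#' Read a peak list from delimited text
#'
#' Two numeric columns (m/z, area), whitespace- or tab-delimited; lines
#' starting with `#` are comments. `#@ key value` comment lines written by
#' [write_peaklist()] are parsed back into metadata.
#'
#' @param path file path
#' @param metadata named list merged over any metadata found in the header
#' @return a `spectrum`
#' @export
read_peaklist <- function(path, metadata = list()) {
  lines <- readLines(path, warn = FALSE)
  meta <- list()
  for (ln in grep("^#@", lines, value = TRUE)) {
    kv <- strsplit(sub("^#@\\s*", "", ln), "\\s+")[[1]]
    if (length(kv) >= 2) {
      val <- paste(kv[-1], collapse = " ")
      num <- suppressWarnings(as.numeric(val))
      meta[[kv[1]]] <- if (!is.na(num)) num else val
    }
  }
  data_lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(data_lines) == 0L) stop("empty peak list: ", path)
  fields <- strsplit(trimws(data_lines), "[\\s,;]+", perl = TRUE)
  bad <- which(vapply(fields, length, 0L) < 2L)
  if (length(bad)) stop("malformed row ", bad[1], " in ", path)
  mz <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 1L)))
  area <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  if (anyNA(mz) || anyNA(area))
    stop("non-numeric value in peak list: ", path)
  meta[names(metadata)] <- metadata
  new_spectrum(mz, area, meta)
}

#' Write a peak list as delimited text
#'
#' Metadata fields are echoed as `#@ key value` header comments so that a
#' read/write round trip preserves both peaks and metadata.
#'
#' @param spectrum a `spectrum` with at least one peak
#' @param path output path
#' @return `path`, invisibly
#' @export
write_peaklist <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "spectrum"))
  if (nrow(spectrum) == 0L) stop("refusing to write a spectrum with 0 peaks")
  md <- spectrum_metadata(spectrum)
  hdr <- c("# peak list: mz<TAB>area",
           vapply(names(md), function(k)
             sprintf("#@ %s %s", k, paste(format(md[[k]], digits = 15),
                                          collapse = " ")), ""))
  body <- sprintf("%.10g\t%.10g", spectrum$mz, spectrum$area)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Centroid a profile-mode trace
#'
#' Contiguous runs of intensity above `noise_threshold` become peaks: the
#' centroid is the intensity-weighted mean m/z of the run and the area is
#' the trapezoidal integral of the run.
#'
#' @param mz strictly increasing m/z grid
#' @param intensity intensities on the grid
#' @param noise_threshold intensities at or below this are baseline
#' @param metadata metadata for the returned spectrum
#' @return a `spectrum` (possibly 0 peaks)
#' @export
centroid_profile <- function(mz, intensity, noise_threshold = 0,
                             metadata = list()) {
  stopifnot(length(mz) == length(intensity), length(mz) >= 2)
  if (any(diff(mz) <= 0)) stop("m/z grid must be strictly increasing")
  above <- intensity > noise_threshold
  if (!any(above)) {
    df <- data.frame(mz = numeric(0), area = numeric(0))
    attr(df, "metadata") <- metadata
    class(df) <- c("spectrum", "data.frame")
    return(df)
  }
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values)
  cent <- numeric(0); ar <- numeric(0)
  for (k in keep) {
    idx <- starts[k]:ends[k]
    w <- intensity[idx]
    cent <- c(cent, sum(mz[idx] * w) / sum(w))
    if (length(idx) == 1L) {
      # lone point: approximate area over its local grid spacing
      dx <- mean(diff(mz))
      ar <- c(ar, w * dx)
    } else {
      x <- mz[idx]
      ar <- c(ar, sum(diff(x) * (head(w, -1) + tail(w, -1)) / 2))
    }
  }
  new_spectrum(cent, ar, metadata)
}

#' Build a replicate set
#'
#' @param spectra list of `spectrum` objects sharing target/ligand/
#'   concentration metadata
#' @return object of class `replicate_set`
#' @export
replicate_set <- function(spectra) {
  stopifnot(length(spectra) >= 1,
            all(vapply(spectra, inherits, TRUE, "spectrum")))
  structure(list(spectra = spectra), class = "replicate_set")
}
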