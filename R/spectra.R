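# Centroided spectrum container and the peak-level operations the decision
# procedure relies on: base-peak normalisation with the 0.01 relative
# threshold, nominal (unit-resolution) binning, cosine similarity and the
# weighted subtraction used for the mixed-spectrum crosscheck.

#' Construct a centroided spectrum
#'
#' @param mz numeric peak m/z values
#' @param intensity nonnegative intensities (relative or raw)
#' @param precursor_path integer vector of nominal precursor m/z values,
#'   outermost first (e.g. `c(527, 509, 365)` for the MS4 path 527>509>365)
#' @param metadata free-form named list
#' @return object of class `ms_spectrum`
#' @export
ms_spectrum <- function(mz, intensity, precursor_path = integer(),
                        metadata = list()) {
  stopifnot(length(mz) == length(intensity))
  if (length(intensity) && any(intensity < 0))
    stop("intensities must be nonnegative")
  o <- order(mz)
  structure(list(mz = as.numeric(mz)[o],
                 intensity = as.numeric(intensity)[o],
                 precursor_path = as.integer(precursor_path),
                 metadata = metadata),
            class = "ms_spectrum")
}

#' @export
print.ms_spectrum <- function(x, ...) {
  cat("<ms_spectrum> ", length(x$mz), " peaks",
      if (length(x$precursor_path))
        paste0("  path ", paste(x$precursor_path, collapse = ">")),
      "\n", sep = "")
  if (length(x$mz)) {
    top <- order(x$intensity, decreasing = TRUE)[seq_len(min(6, length(x$mz)))]
    for (i in sort(top))
      cat(sprintf("  %9.3f  %.4f\n", x$mz[i], x$intensity[i]))
  }
  invisible(x)
}

#' Normalise a spectrum to its base peak and apply the intensity threshold
#'
#' The base peak is scaled to 1 and peaks below `threshold` (relative;
#' default 0.01, the acquisition threshold used throughout) are removed.
#' Idempotent.
#'
#' @param s an [ms_spectrum()]
#' @param threshold relative intensity cutoff
#' @return normalised [ms_spectrum()]
#' @export
normalise_spectrum <- function(s, threshold = 0.01) {
  stopifnot(inherits(s, "ms_spectrum"))
  if (!length(s$mz) || max(s$intensity) <= 0)
    stop("cannot normalise an empty or all-zero spectrum")
  int <- s$intensity / max(s$intensity)
  keep <- int >= threshold
  ms_spectrum(s$mz[keep], int[keep], s$precursor_path, s$metadata)
}

#' Bin a spectrum onto the nominal m/z grid
#'
#' Peaks within `tolerance` of the same integer are summed. Returns a named
#' numeric vector indexed by nominal m/z (only nonzero bins).
#'
#' @param s an [ms_spectrum()]
#' @param tolerance half-width in u (default 0.5: unit resolution)
#' @return named numeric vector
#' @export
bin_nominal <- function(s, tolerance = 0.5) {
  stopifnot(inherits(s, "ms_spectrum"))
  if (!length(s$mz)) return(stats::setNames(numeric(), character()))
  bins <- round(s$mz)
  keep <- abs(s$mz - bins) <= tolerance
  v <- tapply(s$intensity[keep], bins[keep], sum)
  stats::setNames(as.numeric(v), names(v))
}

#' Presence call for a diagnostic ion
#'
#' An ion counts as present when its nominal bin reaches `threshold`
#' (default 0.01) in the normalised spectrum.
#' @param s an [ms_spectrum()] (normalised)
#' @param mz nominal m/z (vectorised)
#' @param threshold presence cutoff
#' @return logical vector
#' @export
ion_present <- function(s, mz, threshold = 0.01) {
  b <- bin_nominal(s)
  as.vector(!is.na(b[as.character(as.integer(round(mz)))]) &
            b[as.character(as.integer(round(mz)))] >= threshold)
}

#' Cosine similarity between two spectra on nominal bins
#'
#' Symmetric, bounded in `[0, 1]`; exactly 1 for identical spectra and 0 for
#' disjoint peak sets. The ranking of database candidates, not the absolute
#' score, drives structural decisions.
#'
#' @param a,b normalised [ms_spectrum()] objects
#' @return list with `value` and `matched_peaks`
#' @export
spectrum_similarity <- function(a, b) {
  va <- bin_nominal(a); vb <- bin_nominal(b)
  if (!length(va) || !length(vb)) stop("cannot score an empty spectrum")
  keys <- union(names(va), names(vb))
  xa <- stats::setNames(numeric(length(keys)), keys)
  xb <- xa
  xa[names(va)] <- va; xb[names(vb)] <- vb
  val <- sum(xa * xb) / (sqrt(sum(xa^2)) * sqrt(sum(xb^2)))
  list(value = as.numeric(val),
       matched_peaks = sum(xa > 0 & xb > 0))
}

#' Weighted spectral subtraction
#'
#' Computes `mixed - w * ref` with the weight chosen so that `zero_ion` has
#' zero intensity in the result, mirroring the mixed-spectrum crosscheck
#' where the identified component's fingerprint is nulled at an ion unique
#' to it. Negative residual intensities are clipped to zero (physical
#' intensities) and the result is renormalised. The pre-normalisation
#' residual maximum is kept as attribute `residual_max`, and the weight as
#' `weight`; a residual whose `residual_max` falls below the near-zero
#' cutoff indicates no second component.
#'
#' @param mixed,ref normalised [ms_spectrum()] objects
#' @param zero_ion nominal m/z to null; must be present in `ref`
#' @param w_max sanity bound on the weight (warning tag above it)
#' @return residual [ms_spectrum()] (possibly with zero peaks); attributes
#'   `residual_max`, `weight`, `warning`
#' @export
subtract_spectrum <- function(mixed, ref, zero_ion, w_max = 10) {
  vm <- bin_nominal(mixed); vr <- bin_nominal(ref)
  key <- as.character(as.integer(round(zero_ion)))
  if (is.na(vr[key]) || vr[key] <= 0)
    stop("zero_ion ", zero_ion, " absent from the reference spectrum")
  w <- if (!is.na(vm[key])) as.numeric(vm[key] / vr[key]) else 0
  warn <- NULL
  if (w > w_max) warn <- sprintf("subtraction weight %.3g exceeds bound %g", w, w_max)
  keys <- union(names(vm), names(vr))
  xm <- stats::setNames(numeric(length(keys)), keys)
  xr <- xm
  xm[names(vm)] <- vm; xr[names(vr)] <- vr
  resid <- pmax(xm - w * xr, 0)
  resid[key] <- 0
  rmax <- if (length(resid)) max(resid) else 0
  keep <- resid > 0
  out <- ms_spectrum(as.numeric(names(resid)[keep]), resid[keep],
                     mixed$precursor_path,
                     c(mixed$metadata, list(subtracted = TRUE)))
  if (rmax > 0) out <- normalise_spectrum(out)
  attr(out, "residual_max") <- rmax
  attr(out, "weight") <- w
  attr(out, "warning") <- warn
  out
}

# ---- MGF I/O ------------------------------------------------------------

#' Write spectra to an MGF file
#'
#' The precursor path is carried in the TITLE as `p527>509>365`.
#' @param spectra a list of [ms_spectrum()] objects
#' @param path output file
#' @return invisibly, the path
#' @export
write_mgf <- function(spectra, path) {
  if (inherits(spectra, "ms_spectrum")) spectra <- list(spectra)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (s in spectra) {
    writeLines("BEGIN IONS", con)
    title <- if (length(s$precursor_path))
      paste0("p", paste(s$precursor_path, collapse = ">")) else "p"
    writeLines(paste0("TITLE=", title), con)
    if (length(s$precursor_path))
      writeLines(sprintf("PEPMASS=%d",
                         s$precursor_path[length(s$precursor_path)]), con)
    writeLines("CHARGE=1+", con)
    if (length(s$mz))
      writeLines(sprintf("%.4f %.6g", s$mz, s$intensity), con)
    writeLines("END IONS", con)
  }
  invisible(path)
}

#' Read spectra from an MGF file
#'
#' @param path MGF file written by [write_mgf()] (or any centroid MGF whose
#'   TITLE encodes the precursor path as `p527>509>365`)
#' @return list of [ms_spectrum()] objects
#' @export
read_mgf <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (trimws(lines[i]) == "BEGIN IONS") {
      path_vec <- integer(); mzs <- numeric(); ints <- numeric()
      i <- i + 1L
      while (i <= length(lines) && trimws(lines[i]) != "END IONS") {
        ln <- trimws(lines[i])
        if (startsWith(ln, "TITLE=")) {
          t <- sub("^TITLE=p?", "", ln)
          if (nzchar(t))
            path_vec <- as.integer(strsplit(t, ">", fixed = TRUE)[[1]])
        } else if (grepl("^[0-9]", ln)) {
          parts <- strsplit(ln, "[ \t]+")[[1]]
          mzs <- c(mzs, as.numeric(parts[1]))
          ints <- c(ints, as.numeric(parts[2]))
        }
        i <- i + 1L
      }
      out[[length(out) + 1L]] <- ms_spectrum(mzs, ints, path_vec)
    }
    i <- i + 1L
  }
  out
}
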