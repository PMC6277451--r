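# Shared domain containers: Spectrum, DIARun, LibraryEntry, PeptideLibrary.
# Plain-list S3 objects in the style of limma's list-based classes.

#' Construct a mass spectrum
#'
#' @param scan_id scan identifier (text)
#' @param ms_level 1 or 2
#' @param rt retention time in minutes (>= 0)
#' @param mzs strictly increasing numeric vector of m/z values
#' @param intensities non-negative vector aligned to \code{mzs}
#' @param isolation_center precursor isolation-window center (MS2 only)
#' @param isolation_width precursor isolation-window width (MS2 only)
#' @return object of class \code{Spectrum}
#' @export
new_spectrum <- function(scan_id, ms_level, rt, mzs, intensities,
                         isolation_center = NA_real_,
                         isolation_width = NA_real_) {
  ord <- order(mzs)
  mzs <- as.numeric(mzs[ord]); intensities <- as.numeric(intensities[ord])
  s <- structure(list(
    scan_id = as.character(scan_id), ms_level = as.integer(ms_level),
    rt = as.numeric(rt), isolation_center = as.numeric(isolation_center),
    isolation_width = as.numeric(isolation_width),
    mzs = mzs, intensities = intensities
  ), class = "Spectrum")
  validate_spectrum(s)
  s
}

validate_spectrum <- function(s) {
  stopifnot(inherits(s, "Spectrum"))
  if (length(s$mzs) != length(s$intensities))
    stop("spectrum ", s$scan_id, ": mzs and intensities differ in length")
  if (length(s$mzs) > 1L && any(diff(s$mzs) <= 0))
    stop("spectrum ", s$scan_id, ": m/z values not strictly increasing")
  if (any(s$intensities < 0))
    stop("spectrum ", s$scan_id, ": negative intensity")
  if (is.na(s$rt) || s$rt < 0)
    stop("spectrum ", s$scan_id, ": retention time must be >= 0")
  if (s$ms_level == 2L && (is.na(s$isolation_center) || is.na(s$isolation_width)))
    stop("MS2 spectrum ", s$scan_id, " lacks isolation window metadata")
  invisible(s)
}

#' @export
print.Spectrum <- function(x, ...) {
  cat(sprintf("Spectrum %s MS%d rt=%.3f min, %d peaks", x$scan_id,
              x$ms_level, x$rt, length(x$mzs)))
  if (x$ms_level == 2L)
    cat(sprintf(", window %.2f +/- %.2f m/z", x$isolation_center,
                x$isolation_width / 2))
  cat("\n")
  invisible(x)
}

#' Construct a DIA run from time-ordered spectra
#'
#' Infers the isolation-window scheme from the observed (center, width)
#' pairs and assigns each MS2 spectrum a window index and a half-cycle
#' number. A new half cycle starts whenever the window sequence wraps
#' around (the isolation center stops increasing).
#'
#' @param spectra list of \code{Spectrum}, time ordered
#' @param run_id run identifier
#' @return object of class \code{DIARun} with fields \code{run_id},
#'   \code{spectra}, \code{window_scheme} (data.frame low/high) and
#'   \code{cycle_index} (data.frame spectrum/ms_level/rt/window/half_cycle)
#' @export
new_dia_run <- function(spectra, run_id = "run") {
  stopifnot(is.list(spectra))
  rts <- vapply(spectra, `[[`, numeric(1), "rt")
  spectra <- spectra[order(rts)]
  lev <- vapply(spectra, `[[`, integer(1), "ms_level")
  rts <- vapply(spectra, `[[`, numeric(1), "rt")
  ctr <- vapply(spectra, `[[`, numeric(1), "isolation_center")
  wid <- vapply(spectra, `[[`, numeric(1), "isolation_width")

  is2 <- lev == 2L
  scheme <- unique(data.frame(low = ctr[is2] - wid[is2] / 2,
                              high = ctr[is2] + wid[is2] / 2))
  scheme <- scheme[order(scheme$low), , drop = FALSE]
  rownames(scheme) <- NULL

  window <- rep(NA_integer_, length(spectra))
  if (any(is2)) {
    key <- paste(signif(ctr[is2], 10), signif(wid[is2], 10))
    skey <- paste(signif((scheme$low + scheme$high) / 2, 10),
                  signif(scheme$high - scheme$low, 10))
    window[is2] <- match(key, skey)
    if (anyNA(window[is2])) stop("MS2 spectrum maps to no window-scheme entry")
  }

  # half-cycle boundaries: window index not increasing among MS2 scans
  half <- integer(length(spectra))
  h <- 1L; last_w <- -Inf
  for (k in seq_along(spectra)) {
    if (is2[k]) {
      if (window[k] <= last_w) { h <- h + 1L; last_w <- window[k] }
      else last_w <- window[k]
    }
    half[k] <- h
  }

  run <- structure(list(
    run_id = as.character(run_id), spectra = spectra,
    window_scheme = scheme,
    cycle_index = data.frame(spectrum = seq_along(spectra), ms_level = lev,
                             rt = rts, window = window, half_cycle = half)
  ), class = "DIARun")
  validate_dia_run(run)
  run
}

validate_dia_run <- function(run) {
  stopifnot(inherits(run, "DIARun"))
  ci <- run$cycle_index
  ms2 <- ci[ci$ms_level == 2L, ]
  if (nrow(ms2)) {
    dup <- stats::aggregate(spectrum ~ window + half_cycle, ms2, length)
    if (any(dup$spectrum > 1L))
      stop("run ", run$run_id, ": a window index repeats within a half cycle")
  }
  invisible(run)
}

#' @export
print.DIARun <- function(x, ...) {
  ci <- x$cycle_index
  cat(sprintf("DIARun '%s': %d spectra (%d MS1, %d MS2), %d windows, %d half cycles\n",
              x$run_id, nrow(ci), sum(ci$ms_level == 1L), sum(ci$ms_level == 2L),
              nrow(x$window_scheme), max(ci$half_cycle)))
  invisible(x)
}

#' Indices of MS2 spectra whose isolation window contains an m/z
#'
#' Window membership uses half-open intervals [low, high) so boundary
#' m/z values are never double-assigned.
#' @param run a \code{DIARun}
#' @param mz precursor m/z
#' @return integer vector of spectrum indices, time ordered
#' @export
ms2_column <- function(run, mz) {
  ws <- run$window_scheme
  wi <- which(ws$low <= mz & mz < ws$high)
  if (!length(wi)) return(integer(0))
  ci <- run$cycle_index
  ci$spectrum[ci$ms_level == 2L & ci$window %in% wi]
}

#' Median time between consecutive half cycles of a run, in minutes
#' @param run a \code{DIARun}
#' @return numeric scalar (minutes); NA for runs with < 2 half cycles
#' @export
cycle_time <- function(run) {
  ci <- run$cycle_index
  t0 <- tapply(ci$rt, ci$half_cycle, min)
  if (length(t0) < 2L) return(NA_real_)
  stats::median(diff(as.numeric(t0)))
}

#' Construct a library entry
#'
#' @param peptide_modseq modified peptide sequence (bracketed delta masses)
#' @param charge precursor charge
#' @param library_rt library retention time coordinate (minutes, or
#'   normalized units for foreign libraries)
#' @param fragment_mzs fragment m/z values
#' @param fragment_intensities relative intensities aligned to
#'   \code{fragment_mzs}
#' @param fragment_correlations correlation weights in [-1, 1]; default 1
#' @param fragment_annotations optional data.frame (type, index, charge)
#'   aligned to \code{fragment_mzs}; NA rows mark unannotated peaks
#' @param is_decoy decoy flag
#' @param source "spectrum_library" or "chromatogram_library"
#' @param precursor_mz override for the precursor m/z (default computed
#'   from the sequence and charge)
#' @return object of class \code{LibraryEntry}
#' @export
new_library_entry <- function(peptide_modseq, charge, library_rt,
                              fragment_mzs, fragment_intensities,
                              fragment_correlations = NULL,
                              fragment_annotations = NULL,
                              is_decoy = FALSE,
                              source = "spectrum_library",
                              precursor_mz = NULL) {
  k <- length(fragment_mzs)
  if (is.null(fragment_correlations)) fragment_correlations <- rep(1, k)
  if (is.null(fragment_annotations))
    fragment_annotations <- data.frame(type = rep(NA_character_, k),
                                       index = rep(NA_integer_, k),
                                       charge = rep(NA_integer_, k))
  if (is.null(precursor_mz)) precursor_mz <- precursor_mz(peptide_modseq, charge)
  ord <- order(fragment_mzs)
  e <- structure(list(
    peptide_modseq = peptide_modseq, charge = as.integer(charge),
    precursor_mz = as.numeric(precursor_mz),
    library_rt = as.numeric(library_rt),
    fragment_mzs = as.numeric(fragment_mzs[ord]),
    fragment_intensities = as.numeric(fragment_intensities[ord]),
    fragment_correlations = as.numeric(fragment_correlations[ord]),
    fragment_annotations = fragment_annotations[ord, , drop = FALSE],
    is_decoy = isTRUE(is_decoy), source = source
  ), class = "LibraryEntry")
  rownames(e$fragment_annotations) <- NULL
  validate_library_entry(e)
  e
}

validate_library_entry <- function(e) {
  stopifnot(inherits(e, "LibraryEntry"))
  k <- length(e$fragment_mzs)
  if (length(e$fragment_intensities) != k ||
      length(e$fragment_correlations) != k ||
      nrow(e$fragment_annotations) != k)
    stop("entry ", e$peptide_modseq, ": fragment arrays differ in length")
  if (any(e$fragment_correlations < -1 | e$fragment_correlations > 1))
    stop("entry ", e$peptide_modseq, ": correlation outside [-1, 1]")
  if (e$charge < 1L) stop("entry ", e$peptide_modseq, ": charge < 1")
  invisible(e)
}

entry_key <- function(modseq, charge, is_decoy) {
  paste0(modseq, "/", charge, if (is_decoy) "/decoy" else "")
}

#' Construct a peptide library
#'
#' @param entries list of \code{LibraryEntry}
#' @param protein_map data.frame with columns \code{modseq},
#'   \code{accession} (bare-sequence to protein mapping)
#' @return object of class \code{PeptideLibrary} with entries keyed by
#'   \code{modseq/charge[/decoy]}
#' @export
new_library <- function(entries = list(), protein_map = NULL) {
  if (is.null(protein_map))
    protein_map <- data.frame(modseq = character(0), accession = character(0))
  keys <- vapply(entries, function(e)
    entry_key(e$peptide_modseq, e$charge, e$is_decoy), character(1))
  if (anyDuplicated(keys)) stop("duplicate library entry keys")
  names(entries) <- keys
  structure(list(entries = entries, protein_map = protein_map),
            class = "PeptideLibrary")
}

#' @export
print.PeptideLibrary <- function(x, ...) {
  dec <- sum(vapply(x$entries, `[[`, logical(1), "is_decoy"))
  cat(sprintf("PeptideLibrary: %d entries (%d targets, %d decoys), %d peptide-protein links\n",
              length(x$entries), length(x$entries) - dec, dec,
              nrow(x$protein_map)))
  invisible(x)
}

#' Subset a library to targets or decoys
#' @param lib a \code{PeptideLibrary}
#' @param decoys if TRUE return decoy entries, else targets
#' @return list of \code{LibraryEntry}
#' @export
library_entries <- function(lib, decoys = FALSE) {
  Filter(function(e) e$is_decoy == decoys, lib$entries)
}
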