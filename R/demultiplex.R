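# Deconvolution of 50%-overlapped DIA isolation windows into half-width
# pseudo-spectra, using the previous and next half cycles as evidence.

# Unique nearest-match: each neighbor peak is usable by one query peak only
# (ties resolved in favor of the smaller m/z error).
match_unique_ppm <- function(query_mz, peak_mz, tol_ppm) {
  idx <- match_nearest_ppm(query_mz, peak_mz, tol_ppm)
  ok <- which(!is.na(idx))
  if (length(ok) > 1L) {
    err <- abs(peak_mz[idx[ok]] - query_mz[ok]) / query_mz[ok]
    o <- ok[order(err)]
    seen <- logical(length(peak_mz))
    for (q in o) {
      if (seen[idx[q]]) idx[q] <- NA_integer_ else seen[idx[q]] <- TRUE
    }
  }
  idx
}

# Summed intensity of matches for each query peak across a list of
# neighbor spectra (absent neighbors contribute nothing).
neighbor_evidence <- function(query_mz, neighbors, tol_ppm) {
  total <- numeric(length(query_mz))
  any_side <- FALSE
  for (nb in neighbors) {
    if (is.null(nb)) next
    any_side <- TRUE
    idx <- match_unique_ppm(query_mz, nb$mzs, tol_ppm)
    hit <- !is.na(idx)
    total[hit] <- total[hit] + nb$intensities[idx[hit]]
  }
  list(total = total, available = any_side)
}

#' Demultiplex one 50%-overlapped MS2 spectrum
#'
#' Splits the fragment peaks of \code{current} into a lower and an upper
#' half-width pseudo-spectrum. A peak matched only in the lower
#' previous/next neighbors goes entirely to the lower bin, only in the
#' upper neighbors to the upper bin; a peak matched on both sides is
#' split proportionally to the summed neighbor intensities L/(L+U); a
#' peak matched on neither side is treated as noise and dropped. When one
#' side has no neighbor spectra at all (scheme edge), unmatched peaks are
#' kept and assigned to that unobservable side; with no neighbors on
#' either side the spectrum is passed through unsplit with a warning.
#'
#' @param ctx list with fields \code{current}, \code{lower_prev},
#'   \code{lower_next}, \code{upper_prev}, \code{upper_next} (Spectrum or
#'   NULL) and \code{match_tolerance} (ppm)
#' @return list of two \code{Spectrum} objects (\code{lower},
#'   \code{upper}) carrying half-width isolation windows, or the
#'   unmodified input under \code{passthrough = TRUE}
#' @export
demultiplex_spectrum <- function(ctx) {
  cur <- ctx$current
  tol <- ctx$match_tolerance
  low_ev <- neighbor_evidence(cur$mzs, ctx[c("lower_prev", "lower_next")], tol)
  up_ev <- neighbor_evidence(cur$mzs, ctx[c("upper_prev", "upper_next")], tol)

  if (!low_ev$available && !up_ev$available) {
    warning("spectrum ", cur$scan_id,
            ": no overlapping neighbors on either side; passed through unsplit")
    return(list(lower = NULL, upper = NULL, passthrough = cur))
  }

  L <- low_ev$total; U <- up_ev$total
  frac_lower <- numeric(length(cur$mzs)) # fraction of intensity to lower bin
  keep <- rep(TRUE, length(cur$mzs))
  both <- L > 0 & U > 0
  only_l <- L > 0 & U == 0
  only_u <- U > 0 & L == 0
  none <- L == 0 & U == 0
  frac_lower[only_l] <- 1
  frac_lower[only_u] <- 0
  frac_lower[both] <- L[both] / (L[both] + U[both])
  if (low_ev$available && up_ev$available) {
    keep[none] <- FALSE # unmatched on both observed sides: noise
  } else if (low_ev$available) {
    frac_lower[none] <- 0 # upper side unobservable: keep peak there
  } else {
    frac_lower[none] <- 1
  }

  half <- cur$isolation_width / 2
  quarter <- half / 2
  # upper = input - lower, so matched peaks conserve intensity exactly
  lower_int <- cur$intensities * frac_lower
  upper_int <- cur$intensities - lower_int
  mk <- function(side, ints) {
    sel <- keep & ints > 0
    new_spectrum(
      paste0(cur$scan_id, if (side == "lower") ".L" else ".U"),
      2L, cur$rt, cur$mzs[sel], ints[sel],
      isolation_center = cur$isolation_center +
        if (side == "lower") -quarter else quarter,
      isolation_width = half)
  }
  list(lower = mk("lower", lower_int), upper = mk("upper", upper_int),
       passthrough = NULL)
}

# TRUE when consecutive sorted windows overlap by half their width.
is_overlapped_scheme <- function(scheme, rel_tol = 0.05) {
  if (nrow(scheme) < 2L) return(FALSE)
  w <- scheme$high - scheme$low
  step <- diff(scheme$low)
  all(abs(step - w[-length(w)] / 2) < rel_tol * w[-length(w)])
}

#' Demultiplex every MS2 spectrum of a 50%-overlapped DIA run
#'
#' Each MS2 spectrum is replaced by its two half-width pseudo-spectra
#' using evidence from the previous and next half cycles; MS1 spectra are
#' carried through unchanged. The resulting window scheme has twice the
#' windows at half the width. Only three half cycles are held at a time.
#'
#' @param run a \code{DIARun} acquired with a 50%-overlapped scheme
#' @param tol_ppm fragment-matching tolerance between neighboring spectra
#' @return a demultiplexed \code{DIARun}
#' @export
demultiplex_run <- function(run, tol_ppm = 10) {
  scheme <- run$window_scheme
  if (!is_overlapped_scheme(scheme)) {
    warning("run ", run$run_id,
            ": window scheme is not 50%-overlapped; returning run unchanged")
    return(run)
  }
  ci <- run$cycle_index
  key <- paste(ci$half_cycle, ci$window)
  lookup <- seq_len(nrow(ci))
  names(lookup) <- key
  get_spec <- function(h, w) {
    if (w < 1L || w > nrow(scheme)) return(NULL)
    i <- lookup[paste(h, w)]
    if (is.na(i)) NULL else run$spectra[[i]]
  }

  out <- list()
  for (k in seq_len(nrow(ci))) {
    if (ci$ms_level[k] == 1L) {
      out[[length(out) + 1L]] <- run$spectra[[k]]
      next
    }
    h <- ci$half_cycle[k]; w <- ci$window[k]
    ctx <- list(current = run$spectra[[k]],
                lower_prev = get_spec(h - 1L, w - 1L),
                lower_next = get_spec(h + 1L, w - 1L),
                upper_prev = get_spec(h - 1L, w + 1L),
                upper_next = get_spec(h + 1L, w + 1L),
                match_tolerance = tol_ppm)
    dm <- demultiplex_spectrum(ctx)
    if (!is.null(dm$passthrough)) {
      out[[length(out) + 1L]] <- dm$passthrough
    } else {
      out[[length(out) + 1L]] <- dm$lower
      out[[length(out) + 1L]] <- dm$upper
    }
  }
  new_dia_run(out, run$run_id)
}
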