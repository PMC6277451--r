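# Peptide-centric scoring of library entries against a DIA run: fragment
# matching, the factorial-boosted weighted dot-product primary score, the
# best-retention-time search, and the 15 auxiliary match features.

FEATURE_NAMES <- c(
  "deltaCN", "eValue", "logDotProduct", "logWeightedDotProduct",
  "xCorrLib", "xCorrModel", "sumOfSquaredErrors",
  "weightedSumOfSquaredErrors", "numberOfMatchingPeaks",
  "averageAbsFragDeltaMass", "averageFragmentDeltaMass",
  "isotopeDotProduct", "averageAbsPPM", "averagePPM", "deltaRT")

#' Match library fragments against an acquired spectrum
#'
#' Each library fragment is matched to at most one acquired peak (the
#' nearest within tolerance); unmatched fragments are dropped.
#' @param spec acquired \code{Spectrum}
#' @param entry \code{LibraryEntry} whose precursor falls in the
#'   spectrum's isolation window
#' @param tol_ppm fragment tolerance in ppm
#' @return data.frame with columns \code{I} (acquired intensity), \code{P}
#'   (library intensity), \code{C} (correlation weight), \code{ppm}
#'   (signed error), \code{lib_mz}, \code{obs_mz}, \code{frag} (index into
#'   the entry's fragment arrays); attributes \code{i_max}/\code{p_max}
#'   hold the normalization maxima (spectrum/entry base peaks)
#' @export
match_fragments <- function(spec, entry, tol_ppm = 10) {
  idx <- match_nearest_ppm(entry$fragment_mzs, spec$mzs, tol_ppm)
  hit <- which(!is.na(idx))
  out <- data.frame(
    I = spec$intensities[idx[hit]],
    P = entry$fragment_intensities[hit],
    C = entry$fragment_correlations[hit],
    ppm = ppm_error(spec$mzs[idx[hit]], entry$fragment_mzs[hit]),
    lib_mz = entry$fragment_mzs[hit],
    obs_mz = spec$mzs[idx[hit]],
    frag = hit)
  attr(out, "i_max") <- if (length(spec$intensities)) max(spec$intensities) else 1
  attr(out, "p_max") <- if (length(entry$fragment_intensities))
    max(entry$fragment_intensities) else 1
  out
}

#' Primary match score
#'
#' log10 of the correlation-weighted dot product of the (transformed)
#' acquired intensities and the base-peak-normalized library
#' intensities, multiplied by the factorial of the number of matching
#' fragments. Acquired intensities are deliberately not normalized per
#' spectrum, so the score tracks signal height across the elution
#' profile and peaks at the chromatographic apex. An empty match set or
#' an all-zero dot product yields \code{-Inf}.
#' @param matches output of \code{\link{match_fragments}}
#' @param transform "sqrt" (default; square-root intensities, robust to
#'   dynamic range) or "linear"
#' @return numeric score, possibly \code{-Inf}
#' @export
primary_score <- function(matches, transform = c("sqrt", "linear")) {
  transform <- match.arg(transform)
  n <- nrow(matches)
  if (n == 0L) return(-Inf)
  f <- if (transform == "sqrt") sqrt else identity
  p_max <- attr(matches, "p_max") %||% 1
  ihat <- f(matches$I)
  phat <- f(matches$P) / f(max(p_max, .Machine$double.xmin))
  s <- sum(ihat * phat * matches$C)
  if (s <= 0) return(-Inf)
  log10(s) + lgamma(n + 1) / log(10)
}

# Lean scoring used inside the per-spectrum search loop (no data.frame).
score_spectrum <- function(spec, entry, tol_ppm, sqrt_transform = TRUE) {
  idx <- match_nearest_ppm(entry$fragment_mzs, spec$mzs, tol_ppm)
  hit <- !is.na(idx)
  n <- sum(hit)
  if (n == 0L) return(-Inf)
  I <- spec$intensities[idx[hit]]
  P <- entry$fragment_intensities[hit]
  C <- entry$fragment_correlations[hit]
  pm <- max(entry$fragment_intensities)
  s <- if (sqrt_transform) sum(sqrt(I) * sqrt(P / pm) * C)
    else sum(I * (P / pm) * C)
  if (s <= 0) return(-Inf)
  log10(s) + lgamma(n + 1) / log(10)
}

#' Find the highest-scoring retention-time point of an entry in a run
#'
#' Evaluates the primary score at every MS2 spectrum in the entry's
#' isolation-window column, excluding spectra within one cycle time of a
#' masked retention time. Ties break to the earlier retention time.
#' @param run a (demultiplexed) \code{DIARun}
#' @param entry \code{LibraryEntry}
#' @param masked retention times (minutes) to exclude, with a +/- one
#'   cycle-time radius
#' @param tol_ppm fragment tolerance
#' @param transform intensity transform for \code{\link{primary_score}}
#' @return a \code{ScoredMatch}: entry reference, \code{apex_rt},
#'   \code{primary_score}, \code{n_matching}, apex match table, the full
#'   candidate score profile, and \code{out_of_range} flag
#' @export
find_best_rt <- function(run, entry, masked = numeric(0), tol_ppm = 10,
                         transform = "sqrt") {
  col <- ms2_column(run, entry$precursor_mz)
  res <- structure(list(
    modseq = entry$peptide_modseq, charge = entry$charge,
    is_decoy = entry$is_decoy, run_id = run$run_id,
    apex_rt = NA_real_, spectrum_index = NA_integer_,
    n_matching = 0L, primary_score = -Inf,
    matches = NULL, candidate_rts = numeric(0),
    candidate_scores = numeric(0), masked_rts = masked,
    out_of_range = FALSE), class = "ScoredMatch")
  if (!length(col)) {
    res$out_of_range <- TRUE
    return(res)
  }
  rts <- vapply(run$spectra[col], `[[`, numeric(1), "rt")
  ct <- cycle_time(run)
  if (length(masked) && !is.na(ct)) {
    ok <- !vapply(rts, function(r) any(abs(r - masked) <= ct), logical(1))
    col <- col[ok]; rts <- rts[ok]
  }
  if (!length(col)) {
    res$out_of_range <- TRUE
    return(res)
  }
  sqrt_t <- identical(transform, "sqrt")
  scores <- numeric(length(col))
  for (k in seq_along(col)) {
    scores[k] <- score_spectrum(run$spectra[[col[k]]], entry, tol_ppm, sqrt_t)
  }
  best <- which(scores == max(scores))[1L] # ties: earliest RT (time order)
  res$candidate_rts <- rts
  res$candidate_scores <- scores
  if (is.finite(scores[best])) {
    res$apex_rt <- rts[best]
    res$spectrum_index <- col[best]
    res$matches <- match_fragments(run$spectra[[col[best]]], entry, tol_ppm)
    res$n_matching <- nrow(res$matches)
    res$primary_score <- scores[best]
  } else {
    res$out_of_range <- TRUE
  }
  res
}

#' @export
print.ScoredMatch <- function(x, ...) {
  cat(sprintf("ScoredMatch %s/%d%s in %s: score %.3f (n=%d) at rt %.3f min\n",
              x$modseq, x$charge, if (x$is_decoy) " [decoy]" else "",
              x$run_id, x$primary_score, x$n_matching, x$apex_rt))
  invisible(x)
}

# Sequest-style cross-correlation between two 1-Da-binned sparse spectra,
# with the mean over +/- 75-bin offsets subtracted.
xcorr_binned <- function(obs_bins, obs_vals, lib_bins, lib_vals,
                         max_shift = 75L) {
  if (!length(obs_bins) || !length(lib_bins)) return(0)
  obs <- numeric(4000L)
  keep <- obs_bins >= 1L & obs_bins <= 4000L
  obs[obs_bins[keep]] <- obs[obs_bins[keep]] + obs_vals[keep]
  dot_at <- function(tau) {
    b <- lib_bins + tau
    ok <- b >= 1L & b <= 4000L
    sum(lib_vals[ok] * obs[b[ok]])
  }
  shifts <- setdiff(-max_shift:max_shift, 0L)
  d0 <- dot_at(0L)
  bg <- mean(vapply(shifts, dot_at, numeric(1)))
  d0 - bg
}

#' Auxiliary feature scores for a match
#'
#' Computes the 15 named features at the apex of a \code{ScoredMatch}:
#' overall scoring (deltaCN, eValue, logDotProduct, logWeightedDotProduct,
#' xCorrLib, xCorrModel), fragment accuracy (sumOfSquaredErrors,
#' weightedSumOfSquaredErrors, numberOfMatchingPeaks,
#' averageAbsFragDeltaMass, averageFragmentDeltaMass), precursor accuracy
#' (isotopeDotProduct, averageAbsPPM, averagePPM) and retention-time
#' accuracy (deltaRT, 0 unless an RT model is supplied).
#'
#' @param run the searched \code{DIARun}
#' @param entry the matched \code{LibraryEntry}
#' @param match \code{ScoredMatch} with a finite primary score
#' @param bg optional \code{BackgroundDistribution} for the entry's
#'   precursor window; without it the weighted features fall back to
#'   their unweighted values
#' @param rt_model optional \code{RTModel}; enables deltaRT
#' @param decoy_scores optional vector of decoy primary scores from the
#'   same run, used for the eValue survival feature; without it the
#'   entry's own candidate-score profile is the null sample
#' @param tol_ppm precursor tolerance for MS1 isotope lookup
#' @return named numeric vector over \code{FEATURE_NAMES}
#' @export
feature_scores <- function(run, entry, match, bg = NULL, rt_model = NULL,
                           decoy_scores = NULL, tol_ppm = 10) {
  stopifnot(inherits(match, "ScoredMatch"), is.finite(match$primary_score))
  m <- match$matches
  n <- nrow(m)
  out <- stats::setNames(numeric(length(FEATURE_NAMES)), FEATURE_NAMES)

  # deltaCN: relative gap to the best candidate outside +/- 1 cycle
  ct <- cycle_time(run)
  far <- if (is.na(ct)) rep(TRUE, length(match$candidate_rts)) else
    abs(match$candidate_rts - match$apex_rt) > ct
  s2 <- suppressWarnings(max(match$candidate_scores[far &
    is.finite(match$candidate_scores)]))
  s1 <- match$primary_score
  out["deltaCN"] <- if (is.finite(s2) && s1 > 0) (s1 - s2) / s1 else 0

  null_scores <- if (!is.null(decoy_scores))
    decoy_scores[is.finite(decoy_scores)]
  else match$candidate_scores[is.finite(match$candidate_scores)]
  out["eValue"] <- -log10((1 + sum(null_scores >= s1)) /
                            (1 + length(null_scores)))

  f <- sqrt
  ihat <- f(m$I) / f(max(attr(m, "i_max"), .Machine$double.xmin))
  phat <- f(m$P) / f(max(attr(m, "p_max"), .Machine$double.xmin))
  out["logDotProduct"] <- log10(max(sum(ihat * phat), 1e-6))

  w <- rep(1, n)
  if (!is.null(bg)) {
    bins <- pmin(pmax(trunc(m$lib_mz), 0L), 4000L)
    w <- -log10(bg$freq[as.character(bins)])
    w[is.na(w)] <- -log10(bg$pseudo_floor)
  }
  out["logWeightedDotProduct"] <- log10(max(sum(ihat * phat * w), 1e-6))

  spec <- run$spectra[[match$spectrum_index]]
  obs_bins <- trunc(spec$mzs)
  obs_vals <- sqrt(spec$intensities)
  if (length(obs_vals) && max(obs_vals) > 0) obs_vals <- obs_vals / max(obs_vals)
  lib_bins <- trunc(entry$fragment_mzs)
  lib_vals <- sqrt(entry$fragment_intensities)
  if (length(lib_vals) && max(lib_vals) > 0) lib_vals <- lib_vals / max(lib_vals)
  out["xCorrLib"] <- xcorr_binned(obs_bins, obs_vals, lib_bins, lib_vals)
  th <- fragment_ions(entry$peptide_modseq,
                      if (entry$charge > 2L) 1:2 else 1L)
  out["xCorrModel"] <- xcorr_binned(obs_bins, obs_vals, trunc(th$mz),
                                    rep(1, nrow(th)))

  iu <- m$I / max(sqrt(sum(m$I^2)), .Machine$double.xmin)
  pu <- m$P / max(sqrt(sum(m$P^2)), .Machine$double.xmin)
  out["sumOfSquaredErrors"] <- sum((iu - pu)^2)
  out["weightedSumOfSquaredErrors"] <- sum(w * (iu - pu)^2)
  out["numberOfMatchingPeaks"] <- n
  dm_da <- (m$obs_mz - m$lib_mz)
  out["averageFragmentDeltaMass"] <- mean(dm_da)
  out["averageAbsFragDeltaMass"] <- mean(abs(dm_da))

  iso <- precursor_isotopes(run, entry, match$apex_rt, tol_ppm)
  if (length(iso$obs) && sum(iso$obs) > 0) {
    expd <- iso$expected
    out["isotopeDotProduct"] <- sum(iso$obs * expd) /
      (sqrt(sum(iso$obs^2)) * sqrt(sum(expd^2)))
    found <- iso$obs > 0
    out["averagePPM"] <- mean(iso$ppm[found])
    out["averageAbsPPM"] <- mean(abs(iso$ppm[found]))
  }

  if (!is.null(rt_model))
    out["deltaRT"] <- abs(match$apex_rt - predict_rt(rt_model,
                                                     entry$library_rt))
  out
}

# Observed 4-peak precursor isotope envelope from the MS1 spectrum
# nearest in retention time.
precursor_isotopes <- function(run, entry, rt, tol_ppm = 10, n_iso = 4L) {
  ci <- run$cycle_index
  ms1 <- ci[ci$ms_level == 1L, ]
  expected <- isotope_envelope(peptide_mass(entry$peptide_modseq), n_iso)
  if (!nrow(ms1))
    return(list(obs = numeric(0), ppm = numeric(0), expected = expected))
  k <- ms1$spectrum[which.min(abs(ms1$rt - rt))]
  spec <- run$spectra[[k]]
  mzs <- entry$precursor_mz + (0:(n_iso - 1L)) * NEUTRON_SPACING / entry$charge
  idx <- match_nearest_ppm(mzs, spec$mzs, tol_ppm)
  obs <- ifelse(is.na(idx), 0, spec$intensities[idx])
  ppm <- ifelse(is.na(idx), 0, ppm_error(spec$mzs[idx], mzs))
  list(obs = obs, ppm = ppm, expected = expected)
}

#' Gate detections of modified peptides sharing a window with their
#' unmodified form
#'
#' When any of the first four isotope peaks of the modified and
#' unmodified precursors fall in one isolation window, the match is
#' accepted only if fragments exclusive to the modified form carry at
#' least 25\% of the score contribution (sum of I.P.C).
#' @param match \code{ScoredMatch} for the modified entry
#' @param unmod_entry \code{LibraryEntry} of the unmodified form
#' @param run the searched \code{DIARun} (for the window scheme)
#' @param tol_ppm tolerance for deciding fragment exclusivity
#' @param min_fraction required exclusive score fraction
#' @return TRUE if accepted (or the gate does not apply), FALSE otherwise
#' @export
modified_form_gate <- function(match, unmod_entry, run, tol_ppm = 10,
                               min_fraction = 0.25) {
  mod_mz <- precursor_mz(match$modseq, match$charge)
  iso <- function(mz, z) mz + (0:3) * NEUTRON_SPACING / z
  ws <- run$window_scheme
  win_of <- function(mzs) which(vapply(seq_len(nrow(ws)), function(i)
    any(ws$low[i] <= mzs & mzs < ws$high[i]), logical(1)))
  shared_window <- length(intersect(win_of(iso(mod_mz, match$charge)),
                                    win_of(iso(unmod_entry$precursor_mz,
                                               unmod_entry$charge)))) > 0
  if (!shared_window) return(TRUE)
  m <- match$matches
  if (is.null(m) || nrow(m) == 0L) return(FALSE)
  excl <- vapply(m$lib_mz, function(mz)
    all(abs(ppm_error(mz, unmod_entry$fragment_mzs)) > tol_ppm), logical(1))
  contrib <- m$I * m$P * m$C
  total <- sum(contrib)
  if (!any(excl)) {
    message("modified form ", match$modseq,
            ": no modification-exclusive fragments; rejected")
    return(FALSE)
  }
  total > 0 && sum(contrib[excl]) >= min_fraction * total
}

#' Score every entry of a library against a run
#'
#' Runs \code{\link{find_best_rt}} for all target and decoy entries, then
#' computes the 15 auxiliary features using the run's decoy primary-score
#' distribution and per-window background ion frequencies.
#' @param run a (demultiplexed) \code{DIARun}
#' @param lib a \code{PeptideLibrary} containing targets and decoys
#' @param tol_ppm fragment/precursor tolerance
#' @param rt_model optional \code{RTModel} enabling deltaRT
#' @param masked named list: entry key -> masked retention times
#' @param transform intensity transform
#' @return list with \code{matches} (named list of \code{ScoredMatch})
#'   and \code{features} (data.frame: entry reference, apex, primary
#'   score and the 15 features, one row per entry with a finite score)
#' @export
search_run <- function(run, lib, tol_ppm = 10, rt_model = NULL,
                       masked = list(), transform = "sqrt") {
  entries <- lib$entries
  matches <- vector("list", length(entries))
  names(matches) <- names(entries)
  for (key in names(entries)) {
    mk <- masked[[key]] %||% numeric(0)
    matches[[key]] <- find_best_rt(run, entries[[key]], masked = mk,
                                   tol_ppm = tol_ppm, transform = transform)
  }
  features <- features_from_matches(run, lib, matches, rt_model = rt_model,
                                    tol_ppm = tol_ppm)
  list(matches = matches, features = features)
}

#' Feature table from a set of scored matches
#'
#' Computes the 15-feature rows for every match with a finite primary
#' score, using per-window background distributions (cached) and the
#' run's decoy primary-score distribution.
#' @param run the searched \code{DIARun}
#' @param lib the \code{PeptideLibrary}
#' @param matches named list of \code{ScoredMatch} (keys as in
#'   \code{lib$entries})
#' @param rt_model optional \code{RTModel} enabling deltaRT
#' @param tol_ppm tolerance
#' @return data.frame (one row per finite-scored entry) or NULL
#' @export
features_from_matches <- function(run, lib, matches, rt_model = NULL,
                                  tol_ppm = 10) {
  entries <- lib$entries
  decoy_keys <- names(entries)[vapply(entries, `[[`, logical(1), "is_decoy")]
  decoy_scores <- vapply(matches[decoy_keys], `[[`, numeric(1),
                         "primary_score")
  bgs <- list()
  rows <- list()
  for (key in names(entries)) {
    sm <- matches[[key]]
    if (is.null(sm) || !is.finite(sm$primary_score)) next
    e <- entries[[key]]
    wi <- which(run$window_scheme$low <= e$precursor_mz &
                  e$precursor_mz < run$window_scheme$high)[1L]
    wkey <- as.character(wi)
    if (!is.na(wi) && is.null(bgs[[wkey]]))
      bgs[[wkey]] <- build_background(lib, c(run$window_scheme$low[wi],
                                             run$window_scheme$high[wi]))
    fs <- feature_scores(run, e, sm, bg = bgs[[wkey]], rt_model = rt_model,
                         decoy_scores = decoy_scores, tol_ppm = tol_ppm)
    rows[[length(rows) + 1L]] <- data.frame(
      modseq = sm$modseq, charge = sm$charge, is_decoy = sm$is_decoy,
      run_id = sm$run_id, apex_rt = sm$apex_rt,
      primary_score = sm$primary_score, t(fs))
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}
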