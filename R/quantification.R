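# Fragment-ion chromatogram extraction, transition refinement against
# the median peak shape, trapezoidal integration with background
# subtraction, and study-level transition selection and aggregation.

#' Savitzky-Golay smoothing
#'
#' Least-squares polynomial smoothing with symmetric windows; near the
#' ends the window shrinks to the available points (fitting a polynomial
#' of reduced order when necessary). Sampling is assumed uniform within
#' the window.
#' @param y numeric vector
#' @param window odd window length in points (default 7)
#' @param order polynomial order (default 2)
#' @return smoothed vector of the same length
#' @export
savgol <- function(y, window = 7L, order = 2L) {
  n <- length(y)
  if (n == 0L) return(y)
  m <- window %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - m); hi <- min(n, i + m)
    t <- (lo:hi) - i
    k <- min(order, length(t) - 1L)
    A <- outer(t, 0:k, "^")
    cf <- qr.solve(A, y[lo:hi])
    out[i] <- cf[1L]
  }
  out
}

trapezoid <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum((y[-1L] + y[-length(y)]) / 2 * diff(x))
}

#' Extract per-fragment chromatograms around a detection apex
#'
#' For every library fragment, the nearest-peak intensity (within
#' tolerance) in each MS2 spectrum of the entry's window column within
#' \code{apex_rt +/- rt_halfwidth}; missing peaks contribute 0.
#' @param run a (demultiplexed) \code{DIARun}
#' @param match \code{ScoredMatch} with an apex
#' @param entry the matched \code{LibraryEntry}
#' @param rt_halfwidth extraction half-window in minutes (default 0.5)
#' @param tol_ppm fragment tolerance
#' @return list of \code{TransitionTrace}: \code{fragment_id},
#'   \code{mz}, \code{rts}, \code{raw}
#' @export
extract_traces <- function(run, match, entry, rt_halfwidth = 0.5,
                           tol_ppm = 10) {
  col <- ms2_column(run, entry$precursor_mz)
  if (!length(col)) return(list())
  rts <- vapply(run$spectra[col], `[[`, numeric(1), "rt")
  keep <- abs(rts - match$apex_rt) <= rt_halfwidth
  col <- col[keep]; rts <- rts[keep]
  if (!length(col)) return(list())
  ann <- entry$fragment_annotations
  traces <- vector("list", length(entry$fragment_mzs))
  raw <- matrix(0, nrow = length(col), ncol = length(entry$fragment_mzs))
  for (k in seq_along(col)) {
    spec <- run$spectra[[col[k]]]
    idx <- match_nearest_ppm(entry$fragment_mzs, spec$mzs, tol_ppm)
    hit <- !is.na(idx)
    raw[k, hit] <- spec$intensities[idx[hit]]
  }
  for (j in seq_along(traces)) {
    fid <- if (!is.na(ann$type[j]))
      sprintf("%s%d^%d", ann$type[j], ann$index[j], ann$charge[j])
    else sprintf("mz%.4f", entry$fragment_mzs[j])
    traces[[j]] <- structure(list(
      fragment_id = fid, mz = entry$fragment_mzs[j],
      rts = rts, raw = raw[, j],
      smoothed = NULL, unit_norm = NULL,
      correlation = NA_real_, status = NA_character_),
      class = "TransitionTrace")
  }
  traces
}

# Walk downhill from the apex of the median shape; stop at the minimum
# before the trace rises for more than `rise_max` consecutive spectra, or
# where it drops below `floor_frac` of the maximum.
trace_boundary <- function(shape, apex, direction, rise_max = 2L,
                           floor_frac = 0.01) {
  n <- length(shape)
  peak <- shape[apex]
  i <- apex
  min_i <- apex
  rises <- 0L
  repeat {
    j <- i + direction
    if (j < 1L || j > n) return(min_i)
    if (shape[j] < floor_frac * peak) return(j)
    if (shape[j] > shape[i]) {
      rises <- rises + 1L
      if (rises > rise_max) return(min_i)
    } else {
      rises <- 0L
      if (shape[j] <= shape[min_i]) min_i <- j
    }
    i <- j
  }
}

#' Refine transitions against the median peak shape
#'
#' Smooths each trace (Savitzky-Golay), normalizes to unit integrated
#' intensity, computes the pointwise median shape, traces the peak
#' boundaries downhill from the shape maximum (stopping at a sustained
#' rise of more than 2 spectra or below 1\% of the maximum), and scores
#' each trace by Pearson correlation to the median shape inside the
#' boundaries. Status: quantitative (r >= 0.9), detection
#' (0.75 <= r < 0.9), interfered otherwise (including traces with 3 or
#' fewer in-boundary points, where r is undefined).
#' @param traces list of \code{TransitionTrace} from
#'   \code{\link{extract_traces}}
#' @param sg_window,sg_order smoothing parameters
#' @param r_quant,r_detect status thresholds
#' @return list with \code{boundaries} (\code{PeakBoundaries}: left_rt,
#'   right_rt, indices, median_shape) and \code{traces} (refined)
#' @export
refine_transitions <- function(traces, sg_window = 7L, sg_order = 2L,
                               r_quant = 0.9, r_detect = 0.75) {
  nz <- vapply(traces, function(tr) sum(tr$raw) > 0, logical(1))
  if (sum(nz) < 2L)
    stop("fewer than 2 transitions with signal: peptide not quantifiable")
  rts <- traces[[which(nz)[1L]]]$rts
  U <- matrix(NA_real_, nrow = length(rts), ncol = length(traces))
  for (j in seq_along(traces)) {
    sm <- pmax(savgol(traces[[j]]$raw, sg_window, sg_order), 0)
    traces[[j]]$smoothed <- sm
    tot <- trapezoid(rts, sm)
    traces[[j]]$unit_norm <- if (tot > 0) sm / tot else sm
    if (nz[j]) U[, j] <- traces[[j]]$unit_norm
  }
  med <- apply(U[, nz, drop = FALSE], 1L, stats::median)
  apex <- which.max(med)
  li <- trace_boundary(med, apex, -1L)
  ri <- trace_boundary(med, apex, +1L)
  inb <- li:ri
  for (j in seq_along(traces)) {
    r <- NA_real_
    if (nz[j] && length(inb) > 3L &&
        stats::sd(traces[[j]]$unit_norm[inb]) > 0 && stats::sd(med[inb]) > 0)
      r <- stats::cor(traces[[j]]$unit_norm[inb], med[inb])
    traces[[j]]$correlation <- r
    traces[[j]]$status <- if (!is.na(r) && r >= r_quant) "quantitative"
      else if (!is.na(r) && r >= r_detect) "detection" else "interfered"
  }
  boundaries <- structure(list(
    left_rt = rts[li], right_rt = rts[ri], left_idx = li, right_idx = ri,
    rts = rts, median_shape = med, apex_idx = apex), class = "PeakBoundaries")
  list(boundaries = boundaries, traces = traces)
}

#' Background-subtracted trapezoidal peak area
#'
#' Trapezoid over the values between the boundaries, minus a background
#' rectangle of the boundary width times the larger of the two edge
#' values; a rectangle larger than the trapezoid yields 0.
#' @param rts retention times
#' @param values (smoothed) intensities aligned to \code{rts}
#' @param left_idx,right_idx boundary indices into \code{rts}
#' @return non-negative area
#' @export
integrate_area <- function(rts, values, left_idx, right_idx) {
  stopifnot(left_idx >= 1L, right_idx <= length(rts), left_idx <= right_idx)
  sel <- left_idx:right_idx
  tz <- trapezoid(rts[sel], values[sel])
  rect <- (rts[right_idx] - rts[left_idx]) *
    max(values[left_idx], values[right_idx])
  max(tz - rect, 0)
}

#' Integrate a refined transition trace between peak boundaries
#' @param trace refined \code{TransitionTrace} (smoothed)
#' @param boundaries \code{PeakBoundaries} from
#'   \code{\link{refine_transitions}}
#' @return non-negative area
#' @export
integrate_trace <- function(trace, boundaries) {
  integrate_area(trace$rts, trace$smoothed, boundaries$left_idx,
                 boundaries$right_idx)
}

#' Quantify one peptide match in one run
#'
#' Extraction, refinement and integration in one step.
#' @param run,match,entry as in \code{\link{extract_traces}}
#' @param ... passed to \code{\link{extract_traces}}
#' @return data.frame (one row per transition): \code{modseq},
#'   \code{charge}, \code{run_id}, \code{transition}, \code{area},
#'   \code{correlation}, \code{status}; NULL when not quantifiable
#' @export
quantify_match <- function(run, match, entry, ...) {
  traces <- extract_traces(run, match, entry, ...)
  ref <- tryCatch(refine_transitions(traces), error = function(e) NULL)
  if (is.null(ref)) return(NULL)
  do.call(rbind, lapply(ref$traces, function(tr) data.frame(
    modseq = match$modseq, charge = match$charge, run_id = run$run_id,
    transition = tr$fragment_id,
    area = integrate_trace(tr, ref$boundaries),
    correlation = tr$correlation, status = tr$status)))
}

#' Interference score of a transition across a study
#'
#' Sum of the transition's intensities in runs where it shows
#' interference (correlation < 0.9) over the sum in runs where it does
#' not.
#' @param areas per-run areas of the transition
#' @param correlations per-run correlations
#' @param r_quant quantitative-correlation threshold
#' @return non-negative score (Inf when never quantitative)
#' @export
interference_score <- function(areas, correlations, r_quant = 0.9) {
  correlations[is.na(correlations)] <- -1
  clean <- sum(areas[correlations >= r_quant])
  bad <- sum(areas[correlations < r_quant])
  if (clean <= 0) return(Inf)
  bad / clean
}

#' Study-wide transition selection and peptide quantities
#'
#' Transitions are ranked by the sum of their quantitative correlations
#' across runs, transitions with interference score > 0.2 are dropped
#' study-wide, and the peptide quantity in each run is the sum of the
#' top five surviving transitions (fixed across the study). Peptides
#' with fewer than \code{min_transitions} surviving quantitative
#' transitions are dropped.
#' @param records data.frame of per-run transition rows from
#'   \code{\link{quantify_match}}
#' @param max_interference interference-score cutoff (default 0.2)
#' @param top_n transitions summed per peptide (default 5)
#' @param min_transitions minimum surviving transitions (default 3)
#' @param r_quant quantitative-correlation threshold
#' @return data.frame \code{modseq}, \code{run_id}, \code{area},
#'   \code{n_transitions}
#' @export
select_transitions_study <- function(records, max_interference = 0.2,
                                     top_n = 5L, min_transitions = 3L,
                                     r_quant = 0.9) {
  out <- list()
  for (pep in unique(records$modseq)) {
    rp <- records[records$modseq == pep, ]
    stats_t <- lapply(split(rp, rp$transition), function(d) {
      cors <- ifelse(is.na(d$correlation), -1, d$correlation)
      list(rank_score = sum(cors[cors >= r_quant]),
           interference = interference_score(d$area, d$correlation, r_quant))
    })
    keep <- names(stats_t)[vapply(stats_t, function(s)
      s$rank_score > 0 && s$interference <= max_interference, logical(1))]
    if (length(keep) < min_transitions) next
    rank_scores <- vapply(stats_t[keep], `[[`, numeric(1), "rank_score")
    sel <- keep[order(-rank_scores)][seq_len(min(top_n, length(keep)))]
    rsel <- rp[rp$transition %in% sel, ]
    agg <- stats::aggregate(area ~ run_id, rsel, sum)
    agg$modseq <- pep
    agg$n_transitions <- length(sel)
    out[[pep]] <- agg[, c("modseq", "run_id", "area", "n_transitions")]
  }
  if (!length(out)) return(NULL)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Study-level peptide filters
#'
#' Keeps a peptide iff (a) it is quantified (area > 0) in every
#' replicate of at least one condition and (b) its study-wide CV after
#' per-condition median-centering is below \code{cv_max}. Optional
#' back-filled quantities (e.g. from cross-run retention-time alignment)
#' are merged in before filtering.
#' @param quant data.frame \code{modseq}, \code{run_id}, \code{area}
#' @param design data.frame \code{run_id}, \code{condition},
#'   \code{replicate}
#' @param cv_max CV threshold (default 0.20)
#' @param backfill optional data.frame \code{modseq}, \code{run_id},
#'   \code{area} used where \code{quant} has no row
#' @return filtered data.frame with a \code{cv} column attached per
#'   peptide
#' @export
study_filters <- function(quant, design, cv_max = 0.20, backfill = NULL) {
  if (!is.null(backfill)) {
    have <- paste(quant$modseq, quant$run_id)
    add <- backfill[!(paste(backfill$modseq, backfill$run_id) %in% have), ,
                    drop = FALSE]
    if (nrow(add)) {
      add <- add[, c("modseq", "run_id", "area")]
      add$n_transitions <- NA_integer_
      common <- intersect(names(quant), names(add))
      quant <- rbind(quant[, common], add[, common])
    }
  }
  keep <- list()
  for (pep in unique(quant$modseq)) {
    qp <- merge(design, quant[quant$modseq == pep, ], by = "run_id",
                all.x = TRUE)
    qp$area[is.na(qp$area)] <- 0
    complete_cond <- vapply(split(qp, qp$condition),
                            function(d) all(d$area > 0), logical(1))
    if (!any(complete_cond)) next
    meas <- qp[qp$area > 0, ]
    med <- tapply(meas$area, meas$condition, stats::median)
    corrected <- meas$area / as.numeric(med[as.character(meas$condition)])
    cv <- stats::sd(corrected) / mean(corrected)
    if (is.na(cv) || cv >= cv_max) next
    rows <- quant[quant$modseq == pep & quant$area > 0, , drop = FALSE]
    rows$cv <- cv
    keep[[pep]] <- rows
  }
  if (!length(keep)) return(NULL)
  res <- do.call(rbind, keep)
  rownames(res) <- NULL
  res
}

#' Protein quantities from sequence-unique peptides
#'
#' Per protein group and run, the sum of quantities of peptides whose
#' accession sets fall entirely inside that group (shared peptides
#' contribute to no group).
#' @param quant filtered peptide quantities (\code{modseq},
#'   \code{run_id}, \code{area})
#' @param groups passing protein groups from
#'   \code{\link{parsimonious_proteins}} (data.frame with
#'   \code{accessions}, ";"-separated)
#' @param protein_map \code{modseq} (bare) / \code{accession} map
#' @return data.frame \code{accessions}, \code{run_id}, \code{area}
#' @export
protein_quant <- function(quant, groups, protein_map) {
  if (is.null(groups) || nrow(groups) == 0L || is.null(quant)) return(NULL)
  out <- list()
  for (gi in seq_len(nrow(groups))) {
    acc <- strsplit(groups$accessions[gi], ";", fixed = TRUE)[[1L]]
    rows <- list()
    for (pep in unique(quant$modseq)) {
      pacc <- unique(protein_map$accession[protein_map$modseq ==
                                             strip_mods(pep)])
      if (length(pacc) && all(pacc %in% acc))
        rows[[pep]] <- quant[quant$modseq == pep, c("run_id", "area")]
    }
    if (!length(rows)) {
      message("protein group ", groups$accessions[gi],
              " has no sequence-unique peptides; omitted")
      next
    }
    d <- do.call(rbind, rows)
    agg <- stats::aggregate(area ~ run_id, d, sum)
    agg$accessions <- groups$accessions[gi]
    out[[gi]] <- agg[, c("accessions", "run_id", "area")]
  }
  if (!length(out)) return(NULL)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
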