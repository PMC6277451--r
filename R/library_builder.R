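# Decoy generation, per-window background ion frequencies, and
# construction of DIA-derived chromatogram libraries.

# Annotate an entry's fragments as B/Y ions by matching against the
# theoretical ion series (nearest within tol); leaves NA where no ion fits.
annotate_fragments <- function(entry, tol_ppm = 10) {
  ann <- entry$fragment_annotations
  if (!anyNA(ann$type)) return(entry)
  th <- fragment_ions(entry$peptide_modseq,
                      if (entry$charge > 2L) 1:2 else 1L)
  idx <- match_nearest_ppm(entry$fragment_mzs, sort(th$mz), tol_ppm)
  th_sorted <- th[order(th$mz), ]
  hit <- !is.na(idx)
  ann$type[hit] <- th_sorted$type[idx[hit]]
  ann$index[hit] <- th_sorted$index[idx[hit]]
  ann$charge[hit] <- th_sorted$charge[idx[hit]]
  entry$fragment_annotations <- ann
  entry
}

#' Generate the reversed-sequence decoy of a target entry
#'
#' The sequence is reversed keeping the C-terminal (enzyme-specific)
#' residue fixed, so the decoy still looks tryptic. Only fragments
#' annotatable as B/Y ions on the target are transferred, to the decoy
#' m/z of the same ion type/index/charge; the per-fragment delta-mass
#' error of the library peak relative to theory is preserved. +2H
#' fragments are transferred only for precursors above charge 2;
#' unannotated peaks are omitted; A ions and water/ammonia losses are
#' never generated. A palindromic target yields a \code{degenerate_decoy}
#' flag (such pairs are excluded from FDR estimation).
#' @param entry target \code{LibraryEntry}
#' @param tol_ppm annotation tolerance for unannotated libraries
#' @return decoy \code{LibraryEntry} (field \code{degenerate_decoy}
#'   TRUE/FALSE)
#' @export
make_decoy <- function(entry, tol_ppm = 10) {
  stopifnot(!entry$is_decoy)
  p <- parse_modseq(entry$peptide_modseq)
  n <- length(p$residues)
  ord <- c(rev(seq_len(n - 1L)), n) # reverse, C-terminal residue fixed
  dres <- p$residues[ord]; dmods <- p$mods[ord]
  decoy_modseq <- paste0(vapply(seq_len(n), function(i)
    if (dmods[i] != 0)
      sprintf("%s[%+.6f]", dres[i], dmods[i]) else dres[i],
    character(1)), collapse = "")
  degenerate <- identical(strip_mods(decoy_modseq), strip_mods(entry$peptide_modseq))

  entry <- annotate_fragments(entry, tol_ppm)
  ann <- entry$fragment_annotations
  zmax <- if (entry$charge > 2L) 2L else 1L
  keep <- which(!is.na(ann$type) & ann$type %in% c("B", "Y") &
                  ann$charge <= zmax)
  th_target <- fragment_ions(entry$peptide_modseq, 1:2)
  th_decoy <- fragment_ions(decoy_modseq, 1:2)
  frag_mz <- numeric(0); frag_int <- numeric(0); frag_cor <- numeric(0)
  frag_ann <- ann[integer(0), , drop = FALSE]
  for (k in keep) {
    sel <- th_target$type == ann$type[k] & th_target$index == ann$index[k] &
      th_target$charge == ann$charge[k]
    dsel <- th_decoy$type == ann$type[k] & th_decoy$index == ann$index[k] &
      th_decoy$charge == ann$charge[k]
    if (!any(sel) || !any(dsel)) next
    delta_rel <- entry$fragment_mzs[k] / th_target$mz[sel][1L] # keeps ppm error
    frag_mz <- c(frag_mz, th_decoy$mz[dsel][1L] * delta_rel)
    frag_int <- c(frag_int, entry$fragment_intensities[k])
    frag_cor <- c(frag_cor, entry$fragment_correlations[k])
    frag_ann <- rbind(frag_ann, ann[k, , drop = FALSE])
  }
  d <- new_library_entry(decoy_modseq, entry$charge, entry$library_rt,
                         frag_mz, frag_int, frag_cor,
                         fragment_annotations = frag_ann,
                         is_decoy = TRUE, source = entry$source,
                         precursor_mz = entry$precursor_mz)
  d$degenerate_decoy <- degenerate
  d
}

#' Add one decoy per target entry to a library
#' @param lib \code{PeptideLibrary} of targets
#' @param tol_ppm annotation tolerance
#' @return library containing targets plus their decoys
#' @export
add_decoys <- function(lib, tol_ppm = 10) {
  targets <- library_entries(lib, decoys = FALSE)
  decoys <- lapply(targets, make_decoy, tol_ppm = tol_ppm)
  new_library(c(unname(targets), unname(decoys)), lib$protein_map)
}

#' Background fragment-ion frequency distribution for one window
#'
#' The frequency of each nominal m/z bin (rounded by truncation,
#' calculated out to 4000) among target entries whose precursor falls in
#' the window. Duplicate bins within one entry count once; a pseudocount
#' of 1 keeps every bin's frequency positive.
#' @param lib \code{PeptideLibrary}
#' @param window numeric length-2 (low, high) precursor window, half-open
#' @param pseudocount added to every bin count
#' @return \code{BackgroundDistribution}: named \code{freq} vector over
#'   bins "0".."4000", \code{n_entries}, \code{pseudo_floor}
#' @export
build_background <- function(lib, window, pseudocount = 1) {
  targets <- library_entries(lib, decoys = FALSE)
  inwin <- Filter(function(e)
    e$precursor_mz >= window[1L] && e$precursor_mz < window[2L], targets)
  counts <- stats::setNames(numeric(4001L), as.character(0:4000))
  if (!length(inwin)) {
    warning("no library entries in window [", window[1L], ", ", window[2L],
            "); background is pseudocount-only")
  }
  for (e in inwin) {
    bins <- unique(pmin(pmax(trunc(e$fragment_mzs), 0), 4000))
    counts[as.character(bins)] <- counts[as.character(bins)] + 1
  }
  n <- length(inwin)
  freq <- (counts + pseudocount) / (n + pseudocount)
  structure(list(window = window, freq = freq, n_entries = n,
                 pseudocount = pseudocount,
                 pseudo_floor = pseudocount / (n + pseudocount)),
            class = "BackgroundDistribution")
}

#' Build a chromatogram library from narrow-window search results
#'
#' For each peptide passing the global FDR filter, stores the
#' run-measured apex retention time, the apex fragment intensities, and
#' per-fragment correlations to the median peak shape (the C vector,
#' from transition refinement on the narrow-window data). Only +1H/+2H
#' B/Y ions are retained, fragments with correlation below 0.75 are
#' dropped, and of multiple charge states only the highest scoring is
#' kept. Peptides left with fewer than \code{min_fragments} fragments
#' are excluded.
#'
#' @param passing data.frame of FDR-passing observations with columns
#'   \code{modseq}, \code{charge}, \code{run_id}, \code{score} (higher is
#'   better; the best row per peptide decides the charge state)
#' @param matches nested list \code{run_id -> entry key -> ScoredMatch}
#'   from the narrow-window searches
#' @param runs named list of demultiplexed \code{DIARun}
#' @param source_lib the searched \code{PeptideLibrary}
#' @param min_fragments minimum retained fragments (default 3)
#' @param min_correlation fragments below this correlation are dropped
#' @param rt_halfwidth extraction half-window in minutes
#' @return chromatogram \code{PeptideLibrary} (one entry per peptide)
#' @export
build_chromatogram_library <- function(passing, matches, runs, source_lib,
                                       min_fragments = 3L,
                                       min_correlation = 0.75,
                                       rt_halfwidth = 0.5) {
  if (is.null(passing) || nrow(passing) == 0L) return(new_library())
  passing <- passing[order(-passing$score), ]
  best <- passing[!duplicated(passing$modseq), , drop = FALSE] # best charge
  entries <- list()
  for (i in seq_len(nrow(best))) {
    modseq <- best$modseq[i]; charge <- best$charge[i]
    run_id <- best$run_id[i]
    key <- entry_key(modseq, charge, FALSE)
    sm <- matches[[run_id]][[key]]
    entry <- source_lib$entries[[key]]
    if (is.null(sm) || is.null(entry) || !is.finite(sm$primary_score)) next
    run <- runs[[run_id]]
    entry <- annotate_fragments(entry)
    ann <- entry$fragment_annotations
    keepable <- !is.na(ann$type) & ann$type %in% c("B", "Y") &
      ann$charge %in% 1:2
    traces <- extract_traces(run, sm, entry, rt_halfwidth = rt_halfwidth)
    ref <- tryCatch(refine_transitions(traces), error = function(e) NULL)
    if (is.null(ref)) next
    cors <- vapply(ref$traces, function(tr) tr$correlation, numeric(1))
    apex_int <- vapply(ref$traces, function(tr) max(tr$smoothed), numeric(1))
    sel <- which(keepable & !is.na(cors) & cors >= min_correlation)
    if (length(sel) < min_fragments) {
      message("peptide ", modseq, "/", charge,
              " excluded from chromatogram library: ",
              length(sel), " fragments after ion filtering")
      next
    }
    entries[[length(entries) + 1L]] <- new_library_entry(
      modseq, charge, sm$apex_rt,
      entry$fragment_mzs[sel], apex_int[sel], pmin(cors[sel], 1),
      fragment_annotations = ann[sel, , drop = FALSE],
      source = "chromatogram_library")
  }
  new_library(entries, source_lib$protein_map)
}
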