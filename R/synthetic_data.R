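# Ground-truth-labeled synthetic libraries, DIA runs and multi-run
# studies. The generator is first-class, deterministic under a seed, and
# is the oracle for most of the test suite. No analysis module reads the
# ground truth.

SIM_ALPHABET <- c("A", "D", "E", "F", "G", "H", "L", "M", "N", "P", "Q",
                  "S", "T", "V", "W", "Y") # no C/K/R internal, no I (I/L dup)

#' Simulate a spectrum library with ground truth
#'
#' Random tryptic-like peptides (length 7-14, C-terminal K/R, no internal
#' K/R, isoleucine excluded so reversal decoys stay non-degenerate), B/Y
#' +1H (and +2H for 3+ precursors) fragment ions with log-normal relative
#' intensities, retention times uniform over the gradient, and peptides
#' grouped into proteins of ~3 peptides.
#'
#' @param n_peptides number of target peptides
#' @param seed integer RNG seed (fully determines the output)
#' @param gradient_min gradient length in minutes
#' @param n_fragments fragments sampled per peptide (range)
#' @param prop_charge3 proportion of 3+ precursors
#' @param peptides_per_protein protein group size
#' @return list with \code{library} (a \code{PeptideLibrary} of targets)
#'   and \code{truth} (a \code{GroundTruth} list: peptide table, fragment
#'   tables, seed)
#' @export
simulate_library <- function(n_peptides, seed = 1L, gradient_min = 90,
                             n_fragments = c(6L, 10L), prop_charge3 = 0.2,
                             peptides_per_protein = 3L) {
  set.seed(seed)
  if (n_peptides == 0L)
    return(list(library = new_library(),
                truth = list(peptides = NULL, fragments = list(), seed = seed)))
  seqs <- character(0)
  while (length(seqs) < n_peptides) {
    need <- n_peptides - length(seqs)
    len <- sample(7:14, need, replace = TRUE)
    new <- vapply(len, function(l)
      paste0(paste(sample(SIM_ALPHABET, l - 1L, replace = TRUE), collapse = ""),
             sample(c("K", "R"), 1L)), character(1))
    seqs <- unique(c(seqs, new))
  }
  seqs <- seqs[seq_len(n_peptides)]
  charge <- ifelse(stats::runif(n_peptides) < prop_charge3, 3L, 2L)
  rt <- stats::runif(n_peptides, 0.05, 0.95) * gradient_min
  abundance <- stats::rlnorm(n_peptides, meanlog = log(1e5), sdlog = 0.8)
  prot <- paste0("PROT", sprintf("%04d",
    ((seq_len(n_peptides) - 1L) %/% peptides_per_protein) + 1L))

  entries <- vector("list", n_peptides)
  frags <- vector("list", n_peptides)
  for (i in seq_len(n_peptides)) {
    zf <- if (charge[i] > 2L) 1:2 else 1L
    th <- fragment_ions(seqs[i], zf)
    th <- th[th$index >= 2L & th$mz > 200 & th$mz < 1800, , drop = FALSE]
    k <- min(sample(n_fragments[1L]:n_fragments[2L], 1L), nrow(th))
    pick <- th[sample(nrow(th), k), , drop = FALSE]
    rel <- stats::rlnorm(k, 0, 0.6)
    rel <- rel / max(rel)
    frags[[i]] <- data.frame(type = pick$type, index = pick$index,
                             charge = pick$charge, mz = pick$mz,
                             rel_intensity = rel)
    entries[[i]] <- new_library_entry(
      seqs[i], charge[i], rt[i], pick$mz, rel,
      fragment_annotations = pick[, c("type", "index", "charge")])
  }
  pm <- data.frame(modseq = seqs, accession = prot)
  truth <- list(
    peptides = data.frame(modseq = seqs, charge = charge,
                          precursor_mz = vapply(entries, `[[`, numeric(1),
                                                "precursor_mz"),
                          rt = rt, abundance = abundance,
                          accession = prot),
    fragments = frags, gradient_min = gradient_min, seed = seed)
  class(truth) <- "GroundTruth"
  list(library = new_library(entries, pm), truth = truth)
}

#' Isolation-window grid for a simulated acquisition scheme
#'
#' For overlapped schemes two half-offset window grids are interleaved in
#' time, one per half cycle.
#' @param scheme "overlapped_narrow" (4 m/z), "overlapped_wide" (24 m/z)
#'   or "fixed" (no overlap)
#' @param mz_min,mz_max precursor range
#' @param window_width window width override (m/z)
#' @return list with \code{grids} (list of data.frames low/high, one per
#'   alternating half cycle) and \code{width}
#' @export
scheme_windows <- function(scheme = c("overlapped_wide", "overlapped_narrow",
                                      "fixed"),
                           mz_min = 400, mz_max = 1000,
                           window_width = NULL) {
  scheme <- match.arg(scheme)
  w <- if (!is.null(window_width)) window_width
       else switch(scheme, overlapped_wide = 24, overlapped_narrow = 4,
                   fixed = 24)
  lows_a <- seq(mz_min, mz_max - w, by = w)
  grid_a <- data.frame(low = lows_a, high = lows_a + w)
  if (scheme == "fixed") return(list(grids = list(grid_a), width = w))
  lows_b <- lows_a + w / 2
  grid_b <- data.frame(low = lows_b, high = lows_b + w)
  list(grids = list(grid_a, grid_b), width = w)
}

merge_peaks <- function(mz, intensity, min_sep = 1e-4) {
  keep <- intensity > 0
  mz <- mz[keep]; intensity <- intensity[keep]
  if (length(mz) < 2L) return(list(mz = mz, intensity = intensity))
  ord <- order(mz)
  mz <- mz[ord]; intensity <- intensity[ord]
  grp <- cumsum(c(TRUE, diff(mz) > min_sep))
  tot <- as.numeric(tapply(intensity, grp, sum))
  list(mz = as.numeric(tapply(mz * intensity, grp, sum)) / tot,
       intensity = tot)
}

#' Simulate one DIA run from ground truth
#'
#' Peptides elute as Gaussian peaks (default sd 0.1 min, i.e. ~6 s);
#' fragments appear in every MS2 spectrum whose isolation window contains
#' the (possibly warped) precursor, at their library-consistent relative
#' intensities. Overlapped schemes alternate two half-offset window grids
#' between consecutive half cycles. Optional multiplicative shot noise,
#' m/z jitter, uniform chemical noise, and injected coeluting
#' interference events. MS1 spectra with 4-peak isotope envelopes are
#' interleaved once per half cycle.
#'
#' @param truth \code{GroundTruth} from \code{\link{simulate_library}}
#' @param scheme acquisition scheme (see \code{\link{scheme_windows}})
#' @param warp monotone retention-time warp function (minutes to minutes)
#' @param noise list with \code{shot_cv}, \code{mz_jitter_ppm},
#'   \code{chem_peaks_per_spectrum}, \code{chem_mean}; NULL for noise-free
#' @param seed integer RNG seed
#' @param run_id run identifier
#' @param mz_min,mz_max,window_width acquisition range and window width
#' @param dwell_s time per MS2 spectrum in seconds
#' @param peak_sd_min chromatographic peak standard deviation (minutes)
#' @param gradient_min override of the simulated gradient length
#' @param abundance_scale per-peptide multiplier on the truth abundances
#' @param interference data.frame with columns \code{peptide} (index),
#'   \code{fragment} (index into that peptide's fragment table),
#'   \code{rt_offset} (minutes), \code{magnitude} (relative to the
#'   fragment's apex intensity) and optionally \code{sd} (elution sd of
#'   the interferer, default \code{peak_sd_min}); NULL for none
#' @return a \code{DIARun}
#' @export
simulate_run <- function(truth, scheme = "overlapped_wide",
                         warp = identity, noise = NULL, seed = 1L,
                         run_id = "sim_run", mz_min = 400, mz_max = 1000,
                         window_width = NULL, dwell_s = 0.25,
                         peak_sd_min = 0.1, gradient_min = NULL,
                         abundance_scale = NULL, interference = NULL) {
  set.seed(seed)
  pep <- truth$peptides
  if (is.null(gradient_min)) gradient_min <- truth$gradient_min
  if (is.null(abundance_scale)) abundance_scale <- rep(1, nrow(pep))
  sw <- scheme_windows(scheme, mz_min, mz_max, window_width)
  grids <- sw$grids
  rt_true <- vapply(pep$rt, warp, numeric(1))
  amp <- pep$abundance * abundance_scale

  n_win <- nrow(grids[[1L]])
  half_cycle_s <- (n_win + 1L) * dwell_s
  n_half <- floor(gradient_min * 60 / half_cycle_s)
  spectra <- vector("list", n_half * (n_win + 1L))
  si <- 0L
  noise_on <- !is.null(noise)
  shot_cv <- if (noise_on) noise$shot_cv %||% 0 else 0
  jit_ppm <- if (noise_on) noise$mz_jitter_ppm %||% 0 else 0
  chem_n <- if (noise_on) noise$chem_peaks_per_spectrum %||% 0L else 0L
  chem_mean <- if (noise_on) noise$chem_mean %||% 100 else 100

  for (h in seq_len(n_half)) {
    grid <- grids[[(h - 1L) %% length(grids) + 1L]]
    t0 <- (h - 1L) * half_cycle_s / 60

    # MS1 with isotope envelopes of all eluting peptides
    t_ms1 <- t0
    act <- which(abs(t_ms1 - rt_true) < 4 * peak_sd_min)
    mz1 <- numeric(0); it1 <- numeric(0)
    for (i in act) {
      env <- isotope_envelope(peptide_mass(pep$modseq[i]), 4L)
      g <- amp[i] * exp(-(t_ms1 - rt_true[i])^2 / (2 * peak_sd_min^2))
      mzs <- pep$precursor_mz[i] +
        (0:3) * NEUTRON_SPACING / pep$charge[i]
      mz1 <- c(mz1, mzs); it1 <- c(it1, 5 * g * env)
    }
    if (jit_ppm > 0 && length(mz1))
      mz1 <- mz1 * (1 + stats::rnorm(length(mz1), 0, jit_ppm * 1e-6))
    mp <- merge_peaks(mz1, it1)
    si <- si + 1L
    spectra[[si]] <- new_spectrum(sprintf("scan=%d", si), 1L, t_ms1,
                                  mp$mz, mp$intensity)

    for (wi in seq_len(n_win)) {
      t <- t0 + wi * dwell_s / 60
      lo <- grid$low[wi]; hi <- grid$high[wi]
      act <- which(pep$precursor_mz >= lo & pep$precursor_mz < hi &
                     abs(t - rt_true) < 4 * peak_sd_min)
      mzv <- numeric(0); itv <- numeric(0)
      for (i in act) {
        fr <- truth$fragments[[i]]
        g <- amp[i] * exp(-(t - rt_true[i])^2 / (2 * peak_sd_min^2))
        mzv <- c(mzv, fr$mz); itv <- c(itv, fr$rel_intensity * g)
      }
      if (!is.null(interference)) {
        for (e in seq_len(nrow(interference))) {
          i <- interference$peptide[e]
          if (!(pep$precursor_mz[i] >= lo && pep$precursor_mz[i] < hi)) next
          fr <- truth$fragments[[i]]
          fi <- interference$fragment[e]
          rt_e <- rt_true[i] + interference$rt_offset[e]
          sd_e <- interference$sd[e] %||% peak_sd_min
          if (is.na(sd_e)) sd_e <- peak_sd_min
          if (abs(t - rt_e) >= 4 * sd_e) next
          g <- interference$magnitude[e] * amp[i] * fr$rel_intensity[fi] *
            exp(-(t - rt_e)^2 / (2 * sd_e^2))
          mzv <- c(mzv, fr$mz[fi]); itv <- c(itv, g)
        }
      }
      if (shot_cv > 0 && length(itv))
        itv <- pmax(itv * (1 + stats::rnorm(length(itv), 0, shot_cv)), 0)
      if (jit_ppm > 0 && length(mzv))
        mzv <- mzv * (1 + stats::rnorm(length(mzv), 0, jit_ppm * 1e-6))
      if (chem_n > 0L) {
        mzv <- c(mzv, stats::runif(chem_n, 200, 1800))
        itv <- c(itv, stats::rexp(chem_n, 1 / chem_mean))
      }
      keep <- itv > 0
      mp <- merge_peaks(mzv[keep], itv[keep])
      si <- si + 1L
      spectra[[si]] <- new_spectrum(sprintf("scan=%d", si), 2L, t,
                                    mp$mz, mp$intensity,
                                    isolation_center = (lo + hi) / 2,
                                    isolation_width = hi - lo)
    }
  }
  new_dia_run(spectra[seq_len(si)], run_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a multi-run study with known fold changes
#'
#' Per-run abundances are the truth abundances scaled by the condition
#' fold change (per peptide), each run gets its own monotone retention
#' time warp, and the acquisition/noise settings are shared.
#'
#' @param truth \code{GroundTruth} from \code{\link{simulate_library}}
#' @param n_conditions,n_replicates study design
#' @param fold_changes matrix (peptides x conditions) of abundance
#'   multipliers, or a vector of per-condition scalars applied to all
#'   peptides
#' @param seed integer seed; per-run seeds are derived from it
#' @param warp_amplitude_min amplitude of the random smooth monotone warp
#' @param ... passed to \code{\link{simulate_run}}
#' @return list with \code{runs} (list of \code{DIARun}), \code{design}
#'   (data.frame run_id/condition/replicate), \code{warps} (list of warp
#'   functions) and \code{fold_changes} (expanded matrix)
#' @export
simulate_study <- function(truth, n_conditions = 2L, n_replicates = 3L,
                           fold_changes = NULL, seed = 1L,
                           warp_amplitude_min = 0.5, ...) {
  n_pep <- nrow(truth$peptides)
  if (is.null(fold_changes)) fold_changes <- rep(1, n_conditions)
  if (is.vector(fold_changes))
    fold_changes <- matrix(rep(fold_changes, each = n_pep), nrow = n_pep)
  stopifnot(nrow(fold_changes) == n_pep, ncol(fold_changes) == n_conditions)
  runs <- list(); design <- NULL; warps <- list()
  k <- 0L
  grad <- truth$gradient_min
  for (cond in seq_len(n_conditions)) {
    for (rep_i in seq_len(n_replicates)) {
      k <- k + 1L
      run_seed <- (seed * 1000L + k) %% .Machine$integer.max
      set.seed(run_seed)
      shift <- stats::runif(1, -warp_amplitude_min, warp_amplitude_min)
      amp <- stats::runif(1, 0, warp_amplitude_min)
      phase <- stats::runif(1, 0, pi)
      warp <- local({
        shift <- shift; amp <- amp; phase <- phase; grad <- grad
        function(x) x + shift + amp * sin(pi * x / grad + phase)
      })
      run_id <- sprintf("cond%d_rep%d", cond, rep_i)
      runs[[run_id]] <- simulate_run(
        truth, warp = warp, seed = run_seed, run_id = run_id,
        abundance_scale = fold_changes[, cond], ...)
      warps[[run_id]] <- warp
      design <- rbind(design, data.frame(run_id = run_id,
                                         condition = cond,
                                         replicate = rep_i))
    }
  }
  list(runs = runs, design = design, warps = warps,
       fold_changes = fold_changes)
}
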