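# Shared fixtures: everything is generated in code at test time.

# A tiny deterministic spectrum.
tiny_spectrum <- function(mzs, intensities, rt = 1, ms_level = 2L,
                          center = 450, width = 4, id = "scan=1") {
  new_spectrum(id, ms_level, rt, mzs, intensities,
               isolation_center = if (ms_level == 2L) center else NA,
               isolation_width = if (ms_level == 2L) width else NA)
}

# A manually specified library entry (no simulation).
tiny_entry <- function(modseq = "PEPTIDEK", charge = 2L, rt = 10,
                       mzs = NULL, ints = NULL, cors = NULL, ann = NULL) {
  if (is.null(mzs)) {
    th <- fragment_ions(modseq, 1L)
    th <- th[th$index %in% 3:6 & th$type == "Y", ]
    mzs <- th$mz
    ints <- seq(1, 0.4, length.out = length(mzs))
    ann <- th[, c("type", "index", "charge")]
  }
  new_library_entry(modseq, charge, rt, mzs, ints, cors,
                    fragment_annotations = ann)
}

# Memoized medium simulation shared across test files (built once).
.sim_cache <- new.env(parent = emptyenv())

shared_sim <- function() {
  if (is.null(.sim_cache$sim)) {
    sim <- simulate_library(40, seed = 11, gradient_min = 8)
    run <- simulate_run(sim$truth, scheme = "overlapped_wide", seed = 12,
                        mz_min = 400, mz_max = 1000, window_width = 100,
                        dwell_s = 0.4, gradient_min = 8)
    .sim_cache$sim <- list(sim = sim, run = run,
                           demuxed = demultiplex_run(run),
                           lib = add_decoys(sim$library))
  }
  .sim_cache$sim
}

shared_search <- function() {
  if (is.null(.sim_cache$search)) {
    s <- shared_sim()
    .sim_cache$search <- search_run(s$demuxed, s$lib)
  }
  .sim_cache$search
}

# Digit-free synthetic peptide identifiers (valid residue strings).
pepname <- function(i, prefix = "PEP") {
  paste0(prefix, chartr("0123456789", "ACDEFGHLMN", sprintf("%05d", i)), "K")
}

# Synthetic feature tables with known presence labels, for validation
# tests: present targets score high, absent targets behave like decoys.
simulate_features <- function(n_targets = 400L, frac_present = 0.7,
                              n_decoys = n_targets, separation = 2.5,
                              seed = 1L) {
  set.seed(seed)
  present <- stats::runif(n_targets) < frac_present
  n <- n_targets + n_decoys
  X <- matrix(stats::rnorm(n * 15), nrow = n, ncol = 15)
  X[which(present), 1:6] <- X[which(present), 1:6] + separation
  colnames(X) <- chromalib:::FEATURE_NAMES
  ps <- stats::rnorm(n)
  ps[which(present)] <- ps[which(present)] + separation
  df <- data.frame(
    modseq = pepname(seq_len(n)),
    charge = 2L,
    is_decoy = rep(c(FALSE, TRUE), c(n_targets, n_decoys)),
    run_id = "simfeat",
    apex_rt = stats::runif(n, 0, 60),
    primary_score = ps)
  out <- cbind(df, X)
  attr(out, "present") <- c(present, rep(FALSE, n_decoys))
  out
}

# A Gaussian transition trace sampled on a uniform RT grid.
gauss_trace <- function(rts, apex, sd, height, mz = 500, id = "Y3^1") {
  structure(list(fragment_id = id, mz = mz, rts = rts,
                 raw = height * exp(-(rts - apex)^2 / (2 * sd^2)),
                 smoothed = NULL, unit_norm = NULL,
                 correlation = NA_real_, status = NA_character_),
            class = "TransitionTrace")
}

study_noise <- list(shot_cv = 0.05, mz_jitter_ppm = 2,
                    chem_peaks_per_spectrum = 30, chem_mean = 200)

# One wide-window run of 170 peptides, 40 of them absent (abundance 0),
# built once and reused below.
.pipe_cache <- new.env(parent = emptyenv())
pipe_fixture <- function() {
  if (is.null(.pipe_cache$fx)) {
    sim <- simulate_library(170, seed = 51, gradient_min = 8)
    truth <- sim$truth
    truth$peptides$abundance[131:170] <- 0
    run <- simulate_run(truth, scheme = "overlapped_wide", seed = 52,
                        mz_min = 400, mz_max = 1000, window_width = 100,
                        dwell_s = 0.4, gradient_min = 8,
                        noise = study_noise)
    dm <- demultiplex_run(run)
    lib <- add_decoys(sim$library)
    res <- suppressMessages(run_search(dm, lib))
    .pipe_cache$fx <- list(sim = sim, truth = truth, run = dm, lib = lib,
                           res = res)
  }
  .pipe_cache$fx
}
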