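# Fragment matching, primary score, apex finding, features.

test_that("primary score closed forms", {
  mk <- function(I, P, C) {
    m <- data.frame(I = I, P = P, C = C, ppm = 0, lib_mz = 500,
                    obs_mz = 500, frag = seq_along(I))
    attr(m, "i_max") <- 1; attr(m, "p_max") <- 1
    m
  }
  # one match, I = P = C = 1 -> log10(1 * 1!) = 0
  expect_equal(primary_score(mk(1, 1, 1), "linear"), 0)
  # two matches each I*P*C = 5 -> log10(10 * 2!) = log10(20)
  expect_equal(primary_score(mk(c(5, 5), c(1, 1), c(1, 1)), "linear"),
               log10(20), tolerance = 1e-12)
  # zero C vector -> -Inf sentinel, never a finite score
  expect_identical(primary_score(mk(c(1, 1), c(1, 1), c(0, 0)), "linear"),
                   -Inf)
  empty <- data.frame(I = numeric(0), P = numeric(0), C = numeric(0),
                      ppm = numeric(0), lib_mz = numeric(0),
                      obs_mz = numeric(0), frag = integer(0))
  expect_identical(primary_score(empty), -Inf)
})

test_that("fragment matching honors the ppm boundary and nearest-wins", {
  e <- tiny_entry("PEPTIDEK")
  mz0 <- e$fragment_mzs[1]
  sp <- tiny_spectrum(mz0 * (1 + 9e-6), 100, center = e$precursor_mz)
  expect_identical(nrow(match_fragments(sp, e, 10)), 1L)
  sp <- tiny_spectrum(mz0 * (1 + 11e-6), 100, center = e$precursor_mz)
  expect_identical(nrow(match_fragments(sp, e, 10)), 0L)
  # two acquired peaks within tolerance: nearest wins
  sp <- tiny_spectrum(c(mz0 * (1 - 8e-6), mz0 * (1 + 3e-6)), c(100, 7),
                      center = e$precursor_mz)
  m <- match_fragments(sp, e, 10)
  expect_equal(m$I[m$frag == 1], 7)
  # all k fragments present -> k pairs
  sp <- tiny_spectrum(e$fragment_mzs, e$fragment_intensities,
                      center = e$precursor_mz)
  expect_identical(nrow(match_fragments(sp, e, 10)), length(e$fragment_mzs))
})

test_that("primary score is monotone in n for positive contributions", {
  set.seed(7)
  for (rep in 1:25) {
    k <- sample(2:8, 1)
    I <- runif(k, 1, 100); P <- runif(k); C <- runif(k, 0.2, 1)
    mk <- function(n) {
      m <- data.frame(I = I[1:n], P = P[1:n], C = C[1:n], ppm = 0,
                      lib_mz = 1, obs_mz = 1, frag = 1:n)
      attr(m, "p_max") <- max(P)
      m
    }
    s <- vapply(1:k, function(n) primary_score(mk(n)), numeric(1))
    expect_true(all(diff(s) >= -1e-12))
  }
})

test_that("find_best_rt equals an exhaustive direct scorer on small runs", {
  s <- shared_sim()
  run <- s$demuxed
  # brute-force oracle: raw Eq.-1 scoring over every spectrum in the
  # window column, reimplemented directly
  oracle <- function(entry) {
    ws <- run$window_scheme
    wi <- which(ws$low <= entry$precursor_mz & entry$precursor_mz < ws$high)
    ci <- run$cycle_index
    cols <- ci$spectrum[ci$ms_level == 2L & ci$window %in% wi]
    best <- c(score = -Inf, rt = NA)
    for (k in cols) {
      sp <- run$spectra[[k]]
      tot <- 0; n <- 0
      for (j in seq_along(entry$fragment_mzs)) {
        d <- abs(sp$mzs - entry$fragment_mzs[j]) / entry$fragment_mzs[j] * 1e6
        if (any(d <= 10)) {
          i <- which.min(d)
          tot <- tot + sqrt(sp$intensities[i]) *
            sqrt(entry$fragment_intensities[j] /
                   max(entry$fragment_intensities)) *
            entry$fragment_correlations[j]
          n <- n + 1
        }
      }
      sc <- if (n > 0 && tot > 0) log10(tot) + log10(factorial(n)) else -Inf
      if (sc > best["score"]) best <- c(score = sc, rt = sp$rt)
    }
    best
  }
  for (key in names(s$lib$entries)[c(1, 5, 17, 44, 60)]) {
    entry <- s$lib$entries[[key]]
    sm <- find_best_rt(run, entry)
    ref <- oracle(entry)
    if (is.finite(ref["score"])) {
      expect_equal(sm$primary_score, unname(ref["score"]), tolerance = 1e-9)
      expect_equal(sm$apex_rt, unname(ref["rt"]))
    } else {
      expect_false(is.finite(sm$primary_score))
    }
  }
})

test_that("apex lands within one cycle of the generator truth", {
  s <- shared_sim()
  truth <- s$sim$truth$peptides
  ws <- s$demuxed$window_scheme
  eligible <- truth$precursor_mz >= min(ws$low) &
    truth$precursor_mz < max(ws$high)
  ct <- cycle_time(s$demuxed)
  hits <- 0
  for (i in which(eligible)) {
    key <- chromalib:::entry_key(truth$modseq[i], truth$charge[i], FALSE)
    sm <- shared_search()$matches[[key]]
    if (!is.finite(sm$primary_score)) next
    hits <- hits + 1
    expect_lt(abs(sm$apex_rt - truth$rt[i]), ct + 1e-9)
  }
  expect_gte(hits, 0.9 * sum(eligible))
})

test_that("masking removes candidates; fully masked goes out of range", {
  s <- shared_sim()
  truth <- s$sim$truth$peptides
  key <- chromalib:::entry_key(truth$modseq[1], truth$charge[1], FALSE)
  entry <- s$lib$entries[[key]]
  sm <- find_best_rt(s$demuxed, entry)
  sm2 <- find_best_rt(s$demuxed, entry, masked = sm$apex_rt)
  expect_true(is.na(sm2$apex_rt) ||
                abs(sm2$apex_rt - sm$apex_rt) > cycle_time(s$demuxed))
  all_rts <- vapply(s$demuxed$spectra, `[[`, numeric(1), "rt")
  sm3 <- find_best_rt(s$demuxed, entry,
                      masked = seq(0, max(all_rts) + 1,
                                   by = cycle_time(s$demuxed)))
  expect_true(sm3$out_of_range)
})

test_that("feature vector has the 15 named features with sane closed forms", {
  e <- tiny_entry("LGEYGFQNALLVR", 2L, rt = 5)
  sp2 <- tiny_spectrum(e$fragment_mzs, e$fragment_intensities * 1000,
                       rt = 5, center = e$precursor_mz, width = 4,
                       id = "apex")
  iso <- isotope_envelope(peptide_mass(e$peptide_modseq), 4)
  ms1 <- tiny_spectrum(e$precursor_mz + (0:3) * 1.00335483507 / 2,
                       iso * 500, rt = 5, ms_level = 1L, id = "ms1")
  run <- new_dia_run(list(ms1, sp2), "f")
  sm <- find_best_rt(run, e)
  fs <- feature_scores(run, e, sm)
  expect_setequal(names(fs), chromalib:::FEATURE_NAMES)
  # identical library/acquired relative intensities
  expect_equal(unname(fs["sumOfSquaredErrors"]), 0, tolerance = 1e-12)
  expect_equal(unname(fs["averagePPM"]), 0, tolerance = 1e-9)
  expect_equal(unname(fs["averageAbsFragDeltaMass"]), 0, tolerance = 1e-12)
  expect_equal(unname(fs["numberOfMatchingPeaks"]),
               length(e$fragment_mzs))
  expect_equal(unname(fs["isotopeDotProduct"]), 1, tolerance = 1e-9)
  expect_equal(unname(fs["deltaRT"]), 0) # no model supplied
})

test_that("deltaCN matches a brute-force second-best computation", {
  s <- shared_sim()
  sr <- shared_search()
  f <- sr$features
  row <- f[which.max(f$primary_score), ]
  key <- chromalib:::entry_key(row$modseq, row$charge, row$is_decoy)
  sm <- sr$matches[[key]]
  ct <- cycle_time(s$demuxed)
  far <- abs(sm$candidate_rts - sm$apex_rt) > ct
  s2 <- max(sm$candidate_scores[far & is.finite(sm$candidate_scores)])
  expect_equal(row$deltaCN, (sm$primary_score - s2) / sm$primary_score,
               tolerance = 1e-9)
})

test_that("modified-form gate requires 25% exclusive contribution", {
  # unmodified entry and a modified form sharing most fragments
  th <- fragment_ions("PEPTMIDEK", 1L)
  y <- th[th$type == "Y" & th$index %in% 3:6, ]
  unmod <- new_library_entry("PEPTMIDEK", 2L, 10, y$mz, rep(1, 4),
                             fragment_annotations =
                               y[, c("type", "index", "charge")])
  thm <- fragment_ions("PEPTM[+15.994915]IDEK", 1L)
  ym <- thm[thm$type == "Y" & thm$index %in% 3:6, ]
  modent <- new_library_entry("PEPTM[+15.994915]IDEK", 2L, 10, ym$mz,
                              rep(1, 4),
                              fragment_annotations =
                                ym[, c("type", "index", "charge")])
  # y3/y4 below the M are shared; y5/y6 carry the +16
  mkmatch <- function(I_excl) {
    m <- data.frame(I = c(100, 100, I_excl, I_excl), P = 1, C = 1, ppm = 0,
                    lib_mz = ym$mz, obs_mz = ym$mz, frag = 1:4)
    structure(list(modseq = modent$peptide_modseq, charge = 2L,
                   is_decoy = FALSE, run_id = "r", apex_rt = 1,
                   matches = m), class = "ScoredMatch")
  }
  run <- new_dia_run(list(tiny_spectrum(500, 1, center = unmod$precursor_mz,
                                        width = 20)), "g")
  # exclusive ions carry 50% of the dot product -> accepted
  expect_true(modified_form_gate(mkmatch(100), unmod, run))
  # exclusive ions carry ~9% -> rejected
  expect_false(modified_form_gate(mkmatch(10), unmod, run))
  # different windows -> gate not applied
  run2 <- new_dia_run(list(tiny_spectrum(500, 1,
                                         center = unmod$precursor_mz,
                                         width = 1.0)), "g2")
  expect_true(modified_form_gate(mkmatch(1e-6), unmod, run2))
})

test_that("target and decoy scores are exchangeable on pure noise", {
  set.seed(99)
  sim <- simulate_library(60, seed = 21, gradient_min = 4)
  lib <- add_decoys(sim$library)
  # pure-noise run (fixed windows so random peaks are not stripped by
  # demultiplexing): chemical noise only, no peptide signal
  truth0 <- sim$truth
  truth0$peptides$abundance[] <- 0
  dm <- simulate_run(truth0, scheme = "fixed", seed = 22,
                     mz_min = 400, mz_max = 1000, window_width = 150,
                     dwell_s = 0.5, gradient_min = 4,
                     noise = list(shot_cv = 0, mz_jitter_ppm = 0,
                                  chem_peaks_per_spectrum = 400,
                                  chem_mean = 100))
  ts <- ds <- numeric(0)
  for (key in names(lib$entries)) {
    sm <- find_best_rt(dm, lib$entries[[key]])
    if (lib$entries[[key]]$is_decoy) ds <- c(ds, sm$primary_score)
    else ts <- c(ts, sm$primary_score)
  }
  ts <- ts[is.finite(ts)]; ds <- ds[is.finite(ds)]
  expect_gt(length(ts), 10); expect_gt(length(ds), 10)
  expect_gt(suppressWarnings(stats::ks.test(ts, ds)$p.value), 0.01)
})
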