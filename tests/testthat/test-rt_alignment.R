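# KDE ridge, mixture model, reconsideration, cross-run alignment.

test_that("bandwidth and kernel sd closed forms", {
  set.seed(1)
  # N = 64 anchors with stdev(x) = stdev(y) = 2 -> bandwidth 1.0
  x <- rnorm(64); x <- (x - mean(x)) / sd(x) * 2 + 30
  y <- rnorm(64); y <- (y - mean(y)) / sd(y) * 2 + 30
  m <- fit_kde_ridge(data.frame(x = x, y = y))
  expect_equal(m$bandwidth, 64^(-1 / 6) * 2, tolerance = 1e-12)
  expect_equal(64^(-1 / 6) * 2, 1.0, tolerance = 1e-12)
  expect_equal(m$kernel_sd, 1 / 2.35482, tolerance = 1e-5)
})

test_that("ridge follows y = x on clean diagonal anchors", {
  set.seed(2)
  x <- runif(300, 5, 55)
  m <- fit_kde_ridge(data.frame(x = x, y = x))
  xs <- seq(6, 54, length.out = 200)
  cell <- unname(m$cell["dy"])
  err <- abs(predict_rt(m, xs) - xs)
  expect_lt(stats::quantile(err, 0.95), 2 * cell)
  # monotone at every column
  expect_true(all(diff(m$ridge) >= 0))
})

test_that("KDE mass is conserved (boundary reflection)", {
  set.seed(3)
  x <- runif(200, 0, 40); y <- x + rnorm(200, 0, 1)
  m <- fit_kde_ridge(data.frame(x = x, y = y), keep_grid = TRUE)
  expect_equal(sum(m$grid), 200 * m$kernel_mass, tolerance = 0.01)
})

test_that("few anchors fall back to a robust linear fit", {
  x <- 1:10
  y <- 2 * x + 1; y[4] <- 50 # outlier
  expect_warning(m <- fit_kde_ridge(data.frame(x = x, y = y)), "linear")
  expect_identical(m$type, "linear")
  expect_equal(predict_rt(m, 20), 41, tolerance = 0.2)
})

test_that("mixture model closed forms and degenerate input", {
  set.seed(4)
  # IQR of 1.35 min -> gaussian sd of 1.0 min
  d <- stats::qnorm(seq(0.01, 0.99, length.out = 500), 0, 1.35 / 1.349)
  m <- fit_mixture(d)
  expect_equal(m$gauss_sd, stats::IQR(d) / 1.35, tolerance = 1e-12)
  # all deltas identical: floored sd, zero outliers
  expect_warning(m0 <- fit_mixture(rep(0.2, 50)), "flooring")
  expect_identical(sum(m0$outlier), 0L)
  expect_identical(length(m0$posteriors), 50L)
  expect_equal(sum(m0$priors), 1)
})

test_that("mixture recovers an 80/20 gaussian/uniform composition", {
  set.seed(5)
  n <- 1000
  lab <- runif(n) < 0.8
  d <- ifelse(lab, rnorm(n, 0, 0.1), runif(n, -10, 10))
  m <- fit_mixture(d)
  truly_out <- !lab & abs(d) > 0.5
  sens <- sum(m$outlier & truly_out) / sum(truly_out)
  spec <- sum(!m$outlier & lab) / sum(lab)
  expect_gte(sens, 0.9)
  expect_gte(spec, 0.9)
  expect_lt(abs(unname(m$priors["correct"]) - 0.8), 0.06)
})

test_that("reconsideration fixes interference-displaced apexes and leaves
           absent peptides unmatched", {
  sim <- simulate_library(25, seed = 31, gradient_min = 6)
  # pick a peptide inside the acquired precursor range
  i0 <- which(sim$truth$peptides$precursor_mz >= 410 &
                sim$truth$peptides$precursor_mz < 990 &
                sim$truth$peptides$rt < 4.5)[1]
  # strong coeluting interference 1 min after the true peak on every
  # fragment of that peptide, so its best score lands on the wrong apex
  inter <- data.frame(
    peptide = i0,
    fragment = seq_len(nrow(sim$truth$fragments[[i0]])),
    rt_offset = 1.0,
    magnitude = 25,
    sd = 0.03) # a sharp coeluting interferer

  run <- simulate_run(sim$truth, scheme = "overlapped_wide", seed = 32,
                      mz_min = 400, mz_max = 1000, window_width = 100,
                      dwell_s = 0.4, gradient_min = 6,
                      interference = inter)
  dm <- demultiplex_run(run)
  lib <- add_decoys(sim$library)
  truth <- sim$truth$peptides
  # identity-warp study: the RT model is y = x fitted from clean anchors
  anchors <- data.frame(x = truth$rt[-i0], y = truth$rt[-i0])
  model <- fit_kde_ridge(anchors)
  mixture <- fit_mixture(rnorm(500, 0, 0.05))

  key <- chromalib:::entry_key(truth$modseq[i0], truth$charge[i0], FALSE)
  sm <- find_best_rt(dm, lib$entries[[key]])
  expect_gt(abs(sm$apex_rt - truth$rt[i0]), 0.5) # interference wins pass 1
  fixed <- reconsider_outliers(dm, lib$entries[key],
                               stats::setNames(list(sm), key),
                               model, mixture)
  expect_lt(abs(fixed[[key]]$apex_rt - truth$rt[i0]),
            2 * cycle_time(dm) + 1e-9)

  # a peptide absent from the run stays unmatched through 5 rounds
  ghost <- new_library_entry("WWWWWWNK", 2L, 3, c(500.123, 600.456,
                                                  700.789), c(1, 1, 1))
  smg <- find_best_rt(dm, ghost)
  if (is.finite(smg$primary_score)) {
    outg <- reconsider_outliers(dm, list(g = ghost), list(g = smg),
                                model, mixture)
    expect_identical(length(outg), 1L)
  } else {
    expect_true(smg$out_of_range || !is.finite(smg$primary_score))
  }
})

test_that("cross-run alignment picks the anchor run and infers RTs", {
  set.seed(6)
  n <- 300
  base_rt <- runif(n, 2, 58)
  warps <- list(a = function(x) x + 0.5 + 0.3 * sin(x / 8),
                b = function(x) x,
                c = function(x) 1.02 * x - 0.4)
  obs <- do.call(rbind, lapply(names(warps), function(r) {
    # run b observes every peptide (most canonicals + best scores there)
    keep <- if (r == "b") seq_len(n) else sample(n, 250)
    data.frame(modseq = sprintf("P%04dK", keep), run_id = r,
               score = rnorm(length(keep), if (r == "b") 10 else 5),
               apex_rt = vapply(base_rt[keep], warps[[r]], numeric(1)))
  }))
  al <- align_across_experiments(obs)
  expect_identical(al$anchor_run, "b")
  expect_identical(al$canonical$run_id[1], "b")
  # anchor aligned to itself: inferred == canonical rt
  inf_b <- al$inferred[al$inferred$run_id == "b", ]
  m <- match(al$canonical$modseq, inf_b$modseq)
  expect_equal(inf_b$rt[m], al$canonical$rt_anchor, tolerance = 1e-9)
  # inferred RTs in warped runs track the true warp
  for (r in c("a", "c")) {
    inf_r <- al$inferred[al$inferred$run_id == r, ]
    idx <- as.integer(sub("P", "", sub("K", "", inf_r$modseq)))
    true_rt <- vapply(base_rt[idx], warps[[r]], numeric(1))
    frac_ok <- mean(abs(inf_r$rt - true_rt) < 0.25)
    expect_gte(frac_ok, 0.95)
  }
  # single run: identity
  one <- align_across_experiments(obs[obs$run_id == "a", ])
  expect_identical(one$anchor_run, "a")
})
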