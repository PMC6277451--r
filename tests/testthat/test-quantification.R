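# Trace extraction, refinement, integration, study-level selection.

test_that("Savitzky-Golay reproduces polynomials up to its order exactly", {
  x <- seq_len(31)
  quad <- 2 + 0.5 * x - 0.03 * x^2
  expect_equal(savgol(quad, 7, 2), quad, tolerance = 1e-9)
  # and smooths noise: variance shrinks
  set.seed(1)
  noisy <- quad + rnorm(31, 0, 1)
  expect_lt(stats::var(savgol(noisy, 7, 2) - quad),
            stats::var(noisy - quad))
})

test_that("integration closed forms with background subtraction", {
  # [0,1,2,1,0] at unit spacing, zero edges -> 4.0 exactly
  expect_equal(integrate_area(0:4, c(0, 1, 2, 1, 0), 1, 5), 4)
  # same peak on a pedestal of 1: trapezoid 8, rectangle 4 -> 4.0
  expect_equal(integrate_area(0:4, c(1, 2, 3, 2, 1), 1, 5), 4)
  # flat trace: rectangle >= trapezoid -> 0
  expect_equal(integrate_area(0:4, rep(3, 5), 1, 5), 0)
  # linearity: scaling the trace scales the area exactly
  y <- c(0.2, 1, 5, 2, 0.1)
  expect_equal(integrate_area(0:4, 7 * y, 1, 5),
               7 * integrate_area(0:4, y, 1, 5), tolerance = 1e-12)
})

test_that("identical traces refine to r = 1 with symmetric boundaries", {
  rts <- seq(9.5, 10.5, by = 0.05)
  traces <- lapply(1:5, function(i)
    gauss_trace(rts, 10, 0.08, 100 * i, id = sprintf("Y%d^1", i + 2)))
  ref <- refine_transitions(traces)
  for (tr in ref$traces) {
    expect_equal(tr$correlation, 1, tolerance = 1e-9)
    expect_identical(tr$status, "quantitative")
  }
  b <- ref$boundaries
  expect_lt(b$left_rt, 10); expect_gt(b$right_rt, 10)
  expect_equal((10 - b$left_rt), (b$right_rt - 10), tolerance = 0.11)
  # refinement is invariant to trace order
  ref2 <- refine_transitions(rev(traces))
  expect_equal(ref2$boundaries$left_rt, b$left_rt)
  expect_equal(sort(vapply(ref2$traces, `[[`, numeric(1), "correlation")),
               sort(vapply(ref$traces, `[[`, numeric(1), "correlation")))
})

test_that("an interfering shifted peak is flagged non-quantitative", {
  rts <- seq(9.4, 10.6, by = 0.04)
  clean <- lapply(1:4, function(i)
    gauss_trace(rts, 10, 0.08, 80 + 10 * i, id = sprintf("Y%d^1", i + 2)))
  bad <- gauss_trace(rts, 10, 0.08, 100, id = "B4^1")
  bad$raw <- bad$raw + 100 * exp(-(rts - 10.25)^2 / (2 * 0.08^2))
  ref <- refine_transitions(c(clean, list(bad)))
  stat <- vapply(ref$traces, `[[`, character(1), "status")
  expect_identical(stat[5], "interfered")
  expect_true(all(vapply(ref$traces[1:4], `[[`, numeric(1),
                         "correlation") >= 0.9))

  # fewer than 2 nonzero traces: not quantifiable
  zero <- gauss_trace(rts, 10, 0.08, 0)
  expect_error(refine_transitions(list(zero, zero)), "not quantifiable")
})

test_that("boundaries stop below 1% of the maximum", {
  rts <- seq(0, 20, by = 1)
  # shape falls to 0.5% at the edges of a wide grid
  tr1 <- gauss_trace(rts, 10, 2.0, 100)
  tr2 <- gauss_trace(rts, 10, 2.0, 80)
  ref <- refine_transitions(list(tr1, tr2), sg_window = 5)
  med <- ref$boundaries$median_shape
  peak <- max(med)
  expect_lt(med[ref$boundaries$left_idx], 0.011 * peak)
  expect_lt(med[ref$boundaries$right_idx], 0.011 * peak)
})

test_that("interference score thresholds follow the study-wide rule", {
  # interfered runs hold 10 intensity vs clean 100 -> 0.1 -> kept
  expect_equal(interference_score(c(100, 10), c(0.95, 0.5)), 0.1)
  # 30 vs 100 -> 0.3 -> dropped at the 0.2 threshold
  expect_equal(interference_score(c(100, 30), c(0.95, 0.5)), 0.3)

  mk_records <- function(int_bad) {
    runs <- sprintf("r%d", 1:4)
    do.call(rbind, lapply(seq_along(runs), function(s) {
      bad_here <- s == 1
      data.frame(
        modseq = "PEPTIDEK", charge = 2L, run_id = runs[s],
        transition = sprintf("Y%d^1", 3:6),
        area = c(100, 90, 80, if (bad_here) int_bad else 70),
        correlation = c(0.99, 0.98, 0.97, if (bad_here) 0.5 else 0.96),
        status = "quantitative")
    }))
  }
  q_kept <- select_transitions_study(mk_records(21)) # 21/210 = 0.1
  expect_identical(unique(q_kept$n_transitions), 4L)
  q_drop <- select_transitions_study(mk_records(63)) # 63/210 = 0.3
  expect_identical(unique(q_drop$n_transitions), 3L)

  # a peptide with only 2 clean transitions is excluded
  two <- mk_records(21)
  two <- two[two$transition %in% c("Y3^1", "Y4^1"), ]
  expect_null(select_transitions_study(two))
})

test_that("study filters enforce CV and replicate completeness", {
  design <- data.frame(run_id = sprintf("r%d", 1:6),
                       condition = rep(1:2, each = 3),
                       replicate = rep(1:3, 2))
  mkq <- function(modseq, areas) data.frame(modseq = modseq,
                                            run_id = sprintf("r%d", 1:6),
                                            area = areas,
                                            n_transitions = 4L)
  # tight peptide passes; high-CV peptide fails
  good <- mkq("AAAAGK", c(100, 102, 98, 205, 200, 195))
  bad <- mkq("CCCCGK", c(100, 180, 60, 210, 90, 330))
  out <- study_filters(rbind(good, bad), design)
  expect_setequal(unique(out$modseq), "AAAAGK")
  expect_lt(out$cv[1], 0.20)
  # missing one replicate in every condition -> dropped
  holey <- mkq("DDDDGK", c(100, 101, 0, 200, 202, 0))
  expect_null(study_filters(holey, design))
  # back-filled value completes a condition -> kept
  bf <- data.frame(modseq = "DDDDGK", run_id = "r3", area = 99)
  out2 <- study_filters(holey[holey$area > 0, ], design, backfill = bf)
  expect_true("DDDDGK" %in% out2$modseq)
})

test_that("protein quantities sum sequence-unique peptides only", {
  quant <- data.frame(
    modseq = rep(c("AAAAGK", "CCCCGK", "DDDDGK", "SHAREDK"), each = 2),
    run_id = rep(c("r1", "r2"), 4),
    area = c(100, 110, 200, 210, 300, 290, 500, 500))
  pm <- data.frame(modseq = c("AAAAGK", "CCCCGK", "DDDDGK",
                              "SHAREDK", "SHAREDK"),
                   accession = c("P1", "P1", "P1", "P1", "P2"))
  groups <- data.frame(accessions = c("P1", "P2"), n_peptides = c(3, 1),
                       score = c(3, 1), best_pep = c(0.001, 0.01),
                       is_decoy = FALSE, q_value = 0.001)
  out <- protein_quant(quant, groups, pm)
  expect_equal(out$area[out$accessions == "P1" & out$run_id == "r1"], 600)
  # shared peptide contributes to neither protein
  expect_false(any(out$accessions == "P2"))
})

test_that("extracted traces recover the generator peak", {
  s <- shared_sim()
  truth <- s$sim$truth
  f <- shared_search()$features
  best <- f[!f$is_decoy, ][which.max(f$primary_score[!f$is_decoy]), ]
  i <- which(truth$peptides$modseq == best$modseq)
  key <- chromalib:::entry_key(truth$peptides$modseq[i],
                               truth$peptides$charge[i], FALSE)
  sm <- shared_search()$matches[[key]]
  entry <- s$lib$entries[[key]]
  traces <- extract_traces(s$demuxed, sm, entry)
  expect_identical(length(traces), length(entry$fragment_mzs))
  apexes <- vapply(traces, function(tr) tr$rts[which.max(tr$raw)],
                   numeric(1))
  expect_true(all(abs(apexes - truth$peptides$rt[i]) <
                    2 * cycle_time(s$demuxed)))
  # a fragment absent from the run gives an all-zero trace
  ghost <- entry
  ghost$fragment_mzs[1] <- 1234.5678
  tr0 <- extract_traces(s$demuxed, sm, ghost)
  expect_equal(sum(tr0[[1]]$raw), 0)
})
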