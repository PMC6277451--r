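# Target/decoy re-scoring, q-values, PEPs, protein parsimony.

test_that("q-values match a direct enumeration oracle", {
  scores <- c(10, 9, 8, 7, 6, 5, 4)
  dec <- c(FALSE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE)
  # oracle: for each threshold enumerate counts then take the minimum
  # FDR over all equal-or-larger sets
  fdr <- vapply(scores, function(s)
    (sum(dec & scores >= s) + 1) / max(1, sum(!dec & scores >= s)),
    numeric(1))
  qo <- vapply(seq_along(scores), function(i)
    min(fdr[scores <= scores[i]]), numeric(1))
  expect_equal(chromalib:::compute_qvalues(scores, dec), pmin(qo, 1))
  # q is monotone non-increasing in score
  q <- chromalib:::compute_qvalues(scores, dec)
  expect_true(all(diff(q[order(-scores)]) >= 0))
})

test_that("rescore separates a synthetic study and controls FDR", {
  f <- simulate_features(n_targets = 400, frac_present = 0.6, seed = 10)
  out <- rescore(f)
  present <- attr(f, "present")
  hit <- !out$is_decoy & out$q_value <= 0.01
  # most present peptides recovered
  expect_gt(sum(hit & present) / sum(present & !f$is_decoy), 0.8)
  # few false targets sneak in
  emp_fdr <- sum(hit & !present) / max(1, sum(hit))
  expect_lte(emp_fdr, 0.05)
  # q/pep invariants
  expect_true(all(out$pep >= 0 & out$pep <= 1))
  ord <- order(-out$svm_score)
  expect_true(all(diff(out$q_value[ord]) >= -1e-12))
})

test_that("degenerate inputs: all decoys, tiny sets, perfect separation", {
  f <- simulate_features(n_targets = 60, seed = 11)
  f$is_decoy[] <- TRUE
  out <- rescore(f)
  expect_true(all(out$q_value >= 1 - 1e-12))

  expect_warning(out2 <- rescore(simulate_features(n_targets = 20,
                                                   n_decoys = 20,
                                                   seed = 12)),
                 "fewer than 50 decoys")
  expect_true(all(c("svm_score", "q_value", "pep") %in% names(out2)))

  # perfectly separable: top q = 1/#targets and monotone
  f3 <- simulate_features(n_targets = 100, frac_present = 1,
                          separation = 50, seed = 13)
  out3 <- rescore(f3)
  expect_equal(min(out3$q_value[!out3$is_decoy]), 1 / 100, tolerance = 1e-9)
})

test_that("label exchangeability under the null gives uniform q-values", {
  f <- simulate_features(n_targets = 500, frac_present = 0, seed = 14)
  out <- rescore(f)
  qt <- out$q_value[!out$is_decoy]
  # under the null, target q-values should not concentrate near 0
  expect_identical(sum(qt <= 0.01), 0L)
  expect_gt(suppressWarnings(
    stats::ks.test(out$svm_score[out$is_decoy],
                   out$svm_score[!out$is_decoy])$p.value), 0.01)
})

test_that("global peptide FDR collapses to the best observation", {
  f1 <- simulate_features(n_targets = 200, seed = 15)
  f2 <- f1
  f2$run_id <- "run2"
  f2$primary_score <- f2$primary_score - 0.5
  gl <- global_peptide_fdr(list(f1, f2))
  expect_identical(nrow(gl$peptides),
                   length(unique(paste(f1$modseq, f1$is_decoy))))
  # single run reduces to plain rescore ordering
  gl1 <- global_peptide_fdr(f1)
  r1 <- rescore(f1)
  expect_equal(order(-gl1$observations$svm_score), order(-r1$svm_score))
})

test_that("greedy parsimony follows the protein score and Eq.-3 closed form", {
  peptides <- data.frame(modseq = c("AAAAAK", "CCCCCK"),
                         is_decoy = FALSE, pep = c(0.01, 0.01))
  pm <- data.frame(modseq = c("AAAAAK", "CCCCCK", "CCCCCK"),
                   accession = c("A", "A", "B"))
  out <- parsimonious_proteins(peptides, pm)
  expect_identical(nrow(out$groups), 1L) # B has no unique evidence
  expect_identical(out$groups$accessions, "A")
  expect_equal(out$groups$score, 1.98)
  expect_setequal(out$assignment[["A"]], c("AAAAAK", "CCCCCK"))

  # Eq. 3: N = 3 peptides with PEPs .01/.02/.03 -> 2.94
  p3 <- data.frame(modseq = c("DDDDDK", "EEEEEK", "FFFFFK"),
                   is_decoy = FALSE, pep = c(0.01, 0.02, 0.03))
  pm3 <- data.frame(modseq = p3$modseq, accession = "X")
  out3 <- parsimonious_proteins(p3, pm3)
  expect_equal(out3$groups$score, 2.94)
  expect_equal(out3$groups$best_pep, 0.01)
})

test_that("parsimony conservation and unmapped bucket", {
  set.seed(16)
  n <- 60
  peptides <- data.frame(modseq = pepname(1:n, "PE"),
                         is_decoy = FALSE,
                         pep = runif(n, 0, 0.05))
  pm <- data.frame(modseq = rep(peptides$modseq[1:50], times = 2),
                   accession = c(sprintf("PR%02d", rep(1:10, each = 5)),
                                 sprintf("PR%02d", rep(6:15, each = 5))))
  out <- parsimonious_proteins(peptides, pm)
  assigned <- unname(unlist(out$assignment))
  expect_identical(sort(c(assigned, out$unmapped)),
                   sort(peptides$modseq))
  expect_false(anyDuplicated(assigned) > 0)
  expect_setequal(out$unmapped, peptides$modseq[51:60])
})

test_that("decoy protein groups estimate protein FDR", {
  set.seed(17)
  nt <- 150; nd <- 150
  target_pep <- data.frame(modseq = pepname(1:nt, "TG"),
                           is_decoy = FALSE, pep = rbeta(nt, 1, 40))
  decoy_pep <- data.frame(modseq = pepname(1:nd, "DC"),
                          is_decoy = TRUE, pep = rbeta(nd, 2, 3))
  pm <- rbind(
    data.frame(modseq = target_pep$modseq,
               accession = sprintf("TP%03d", rep(1:50, each = 3))),
    # decoy peptides map via their reversed sequence: register the
    # forward form of each decoy
    data.frame(modseq = vapply(decoy_pep$modseq, function(s) {
      n <- nchar(s)
      paste0(paste(rev(strsplit(substr(s, 1, n - 1), "")[[1]]),
                   collapse = ""), substr(s, n, n))
    }, character(1)),
    accession = sprintf("DP%03d", rep(1:50, each = 3))))
  out <- parsimonious_proteins(rbind(target_pep, decoy_pep), pm)
  g <- out$groups
  expect_true(any(g$is_decoy))
  expect_true(all(g$q_value >= 0 & g$q_value <= 1))
  # decoy-heavy groups rank worse than target groups on average
  expect_lt(mean(g$q_value[!g$is_decoy]), mean(g$q_value[g$is_decoy]))
})
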