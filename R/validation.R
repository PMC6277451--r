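# Target/decoy validation: semi-supervised linear re-scoring (an
# in-package stand-in for an external SVM re-scorer), q-values and
# posterior error probabilities, and greedy parsimonious protein
# grouping with protein-level FDR.

# Target-decoy q-values: q(s) = (#decoys >= s + 1) / max(1, #targets >= s),
# monotonized so q never decreases as the score drops.
compute_qvalues <- function(scores, is_decoy) {
  ord <- order(-scores)
  nd <- cumsum(is_decoy[ord])
  nt <- cumsum(!is_decoy[ord])
  fdr <- pmin((nd + 1) / pmax(1, nt), 1)
  q <- rev(cummin(rev(fdr)))
  out <- numeric(length(scores))
  out[ord] <- q
  out
}

# Posterior error probabilities via an isotonic fit of the local
# decoy/target odds along the score ranking.
compute_pep <- function(scores, is_decoy) {
  ord <- order(-scores)
  y <- as.numeric(is_decoy[ord])
  iso <- stats::isoreg(seq_along(y), y) # decoy fraction, nondecreasing
  frac <- pmin(pmax(iso$yf, 0), 1 - 1e-9)
  pep <- pmin(frac / (1 - frac), 1)
  out <- numeric(length(scores))
  out[ord] <- pep
  out
}

#' Semi-supervised re-scoring of target/decoy feature vectors
#'
#' A cross-validated linear re-scorer in the spirit of semi-supervised
#' SVM re-scoring tools: within each training split, targets passing a
#' provisional 1\% FDR on the current score are positives and decoys are
#' negatives; a regularized logistic direction is fit on the
#' standardized features and the score updated, for
#' \code{iterations} rounds; held-out rows are scored by the final
#' direction of their fold. With fewer than 50 decoys the primary score
#' alone is used (with a warning).
#'
#' @param features data.frame from \code{\link{search_run}}: columns
#'   \code{modseq}, \code{charge}, \code{is_decoy}, \code{run_id},
#'   \code{apex_rt}, \code{primary_score} and the 15 feature columns
#' @param folds cross-validation folds (default 3)
#' @param iterations semi-supervised iterations per fold (default 3)
#' @param train_fdr provisional FDR defining positives (default 0.01)
#' @return the input data.frame plus \code{svm_score}, \code{q_value}
#'   and \code{pep} columns
#' @export
rescore <- function(features, folds = 3L, iterations = 3L,
                    train_fdr = 0.01) {
  stopifnot(is.data.frame(features), nrow(features) > 0L)
  feat_cols <- intersect(c("primary_score", FEATURE_NAMES), names(features))
  X <- as.matrix(features[, feat_cols, drop = FALSE])
  X[!is.finite(X)] <- 0
  dec <- features$is_decoy
  n <- nrow(X)

  if (sum(dec) < 50L) {
    warning("fewer than 50 decoys; ranking by primary score only")
    sc <- features$primary_score
  } else {
    # deterministic fold assignment from the row's peptide identity
    fold <- (match(features$modseq, sort(unique(features$modseq))) %% folds) + 1L
    sc <- numeric(n)
    for (f in seq_len(folds)) {
      tr <- fold != f
      mu <- colMeans(X[tr, , drop = FALSE])
      sdv <- apply(X[tr, , drop = FALSE], 2L, stats::sd)
      keep <- sdv > 0
      Z <- sweep(sweep(X[, keep, drop = FALSE], 2L, mu[keep]), 2L,
                 sdv[keep], "/")
      s_tr <- Z[, "primary_score"]
      beta <- NULL
      for (it in seq_len(iterations)) {
        q <- compute_qvalues(s_tr[tr], dec[tr])
        pos <- tr & !dec & replace(rep(NA, n), tr, q <= train_fdr)
        pos[is.na(pos)] <- FALSE
        neg <- tr & dec
        if (sum(pos) < 50L && sum(tr & !dec) > 0L) {
          # cold start: too few provisional positives at the training
          # FDR; seed with the top-decile targets instead
          thr <- stats::quantile(s_tr[tr & !dec], 0.9, names = FALSE)
          pos <- tr & !dec & s_tr >= thr
        }
        if (sum(pos) < 5L) break
        # ridge least-squares discriminant: stable under perfect
        # separation, unlike an unregularized logistic fit
        yv <- c(rep(1, sum(pos)), rep(0, sum(neg)))
        M <- cbind(1, rbind(Z[pos, , drop = FALSE], Z[neg, , drop = FALSE]))
        lambda <- 1
        A <- crossprod(M) + lambda * diag(ncol(M))
        beta <- drop(solve(A, crossprod(M, yv)))
        beta[!is.finite(beta)] <- 0
        s_tr <- drop(cbind(1, Z) %*% beta)
      }
      idx <- fold == f
      s_f <- if (is.null(beta)) Z[idx, "primary_score"]
        else drop(cbind(1, Z[idx, , drop = FALSE]) %*% beta)
      # normalize per fold on the held-out decoys so folds share a scale
      d <- s_f[dec[idx]]
      if (length(d) >= 2L && stats::sd(d) > 0)
        s_f <- (s_f - mean(d)) / stats::sd(d)
      sc[idx] <- s_f
    }
  }
  features$svm_score <- sc
  features$q_value <- compute_qvalues(sc, dec)
  features$pep <- compute_pep(sc, dec)
  features
}

#' Study-wide peptide FDR across runs
#'
#' Concatenates per-run feature tables, re-scores them jointly, and
#' collapses to the best observation per peptide, on which the
#' study-level q-values and PEPs are computed.
#' @param feature_list list of per-run feature data.frames (or a single
#'   data.frame)
#' @param ... passed to \code{\link{rescore}}
#' @return list with \code{observations} (all re-scored rows) and
#'   \code{peptides} (one row per peptide and decoy status: the best
#'   observation with study-level \code{q_value} and \code{pep})
#' @export
global_peptide_fdr <- function(feature_list, ...) {
  if (is.data.frame(feature_list)) feature_list <- list(feature_list)
  all_rows <- do.call(rbind, feature_list)
  scored <- rescore(all_rows, ...)
  ord <- order(-scored$svm_score)
  collapsed <- scored[ord, ][!duplicated(paste(scored$modseq[ord],
                                               scored$is_decoy[ord])), ]
  collapsed$q_value <- compute_qvalues(collapsed$svm_score,
                                       collapsed$is_decoy)
  collapsed$pep <- compute_pep(collapsed$svm_score, collapsed$is_decoy)
  list(observations = scored, peptides = collapsed)
}

# Map peptide modseqs (targets and reversed-sequence decoys) to protein
# accession sets; decoys map to DECOY_-prefixed accessions.
map_peptides_to_proteins <- function(peptides, protein_map) {
  lapply(seq_len(nrow(peptides)), function(i) {
    seq_i <- strip_mods(peptides$modseq[i])
    if (!peptides$is_decoy[i]) {
      protein_map$accession[protein_map$modseq == seq_i]
    } else {
      n <- nchar(seq_i)
      fwd <- paste0(paste(rev(strsplit(substr(seq_i, 1L, n - 1L), "",
                                       fixed = TRUE)[[1L]]), collapse = ""),
                    substr(seq_i, n, n))
      acc <- protein_map$accession[protein_map$modseq == fwd]
      if (length(acc)) paste0("DECOY_", acc) else character(0)
    }
  })
}

#' Greedy parsimonious protein grouping with protein-level FDR
#'
#' Accessions with identical peptide sets are merged into one group.
#' Peptides are assigned iteratively to the remaining candidate group
#' with the highest protein score N - sum(PEP_p); assigned peptides are
#' removed and the process repeats, so every peptide belongs to exactly
#' one group (or the unmapped bucket). Groups are ranked by their lowest
#' member PEP; groups made purely of decoy peptides estimate the protein
#' q-values.
#'
#' @param peptides data.frame of FDR-passing peptides with columns
#'   \code{modseq}, \code{is_decoy}, \code{pep}
#' @param protein_map data.frame \code{modseq} (bare sequence) /
#'   \code{accession}
#' @param fdr protein-level q-value threshold for the \code{passing}
#'   subset (default 0.01)
#' @return list with \code{groups} (data.frame: accessions, n_peptides,
#'   score, best_pep, is_decoy, q_value), \code{assignment} (peptide ->
#'   group), \code{unmapped} (modseqs), and \code{passing} (target groups
#'   at the threshold)
#' @export
parsimonious_proteins <- function(peptides, protein_map, fdr = 0.01) {
  if (is.null(peptides) || nrow(peptides) == 0L)
    return(list(groups = NULL, assignment = list(),
                unmapped = character(0), passing = NULL))
  acc_sets <- map_peptides_to_proteins(peptides, protein_map)
  unmapped <- peptides$modseq[lengths(acc_sets) == 0L]
  mapped <- which(lengths(acc_sets) > 0L)

  # candidate accession -> peptide rows
  acc_pep <- list()
  for (i in mapped) {
    for (a in acc_sets[[i]]) acc_pep[[a]] <- c(acc_pep[[a]], i)
  }
  # merge indistinguishable accessions (identical peptide sets)
  sig <- vapply(acc_pep, function(v) paste(sort(unique(v)), collapse = ","),
                character(1))
  groups <- split(names(acc_pep), sig)
  group_peps <- lapply(names(groups), function(s)
    as.integer(strsplit(s, ",", fixed = TRUE)[[1L]]))
  names(group_peps) <- vapply(groups, paste, character(1), collapse = ";")

  remaining <- rep(TRUE, nrow(peptides))
  rows <- list(); assignment <- list()
  repeat {
    scores <- vapply(group_peps, function(v) {
      v <- v[remaining[v]]
      if (!length(v)) return(-Inf)
      length(v) - sum(peptides$pep[v])
    }, numeric(1))
    if (!length(scores) || all(!is.finite(scores))) break
    best <- names(scores)[which.max(scores)]
    v <- group_peps[[best]]
    v <- v[remaining[v]]
    remaining[v] <- FALSE
    rows[[length(rows) + 1L]] <- data.frame(
      accessions = best, n_peptides = length(v),
      score = length(v) - sum(peptides$pep[v]),
      best_pep = min(peptides$pep[v]),
      is_decoy = all(peptides$is_decoy[v]))
    assignment[[best]] <- peptides$modseq[v]
    group_peps[[best]] <- NULL
    if (!any(remaining[unlist(group_peps)])) break
  }
  if (!length(rows))
    return(list(groups = NULL, assignment = list(), unmapped = unmapped,
                passing = NULL))
  g <- do.call(rbind, rows)
  g <- g[order(g$best_pep), ]
  g$q_value <- compute_qvalues(-g$best_pep, g$is_decoy)
  rownames(g) <- NULL
  list(groups = g, assignment = assignment, unmapped = unmapped,
       passing = g[!g$is_decoy & g$q_value <= fdr, , drop = FALSE])
}
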