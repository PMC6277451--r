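# Orchestration of the three workflows: chromatogram-library building,
# two-pass search with retention-time reconsideration, and study-level
# quantification. Stages log structured counts and can cache
# intermediates keyed by an input hash.

#' Study configuration with package defaults
#'
#' @param tol_ppm precursor/fragment/library tolerance (ppm)
#' @param fdr_peptide,fdr_protein FDR thresholds
#' @param r_quant,r_detect transition correlation thresholds
#' @param max_interference interference-score cutoff
#' @param cv_max study-wide CV threshold
#' @param min_transitions,max_transitions transition count bounds
#' @param rt_outlier_p mixture posterior below which an apex is an
#'   outlier
#' @param transform intensity transform for the primary score
#' @param seed RNG seed recorded with the config
#' @return a \code{StudyConfig} list
#' @export
study_config <- function(tol_ppm = 10, fdr_peptide = 0.01,
                         fdr_protein = 0.01, r_quant = 0.9,
                         r_detect = 0.75, max_interference = 0.2,
                         cv_max = 0.20, min_transitions = 3L,
                         max_transitions = 5L, rt_outlier_p = 0.05,
                         transform = "sqrt", seed = 1L) {
  cfg <- list(tol_ppm = tol_ppm, fdr_peptide = fdr_peptide,
              fdr_protein = fdr_protein, r_quant = r_quant,
              r_detect = r_detect, max_interference = max_interference,
              cv_max = cv_max, min_transitions = min_transitions,
              max_transitions = max_transitions,
              rt_outlier_p = rt_outlier_p, transform = transform,
              seed = seed)
  stopifnot(cfg$fdr_peptide > 0, cfg$fdr_peptide <= 1,
            cfg$fdr_protein > 0, cfg$fdr_protein <= 1,
            cfg$cv_max > 0, cfg$cv_max <= 1)
  structure(cfg, class = "StudyConfig")
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

input_hash <- function(...) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(list(...), f)
  unname(tools::md5sum(f))
}

cache_get <- function(cache_dir, key) {
  if (is.null(cache_dir)) return(NULL)
  f <- file.path(cache_dir, paste0(key, ".rds"))
  if (file.exists(f)) readRDS(f) else NULL
}

cache_put <- function(cache_dir, key, value) {
  if (is.null(cache_dir)) return(invisible(NULL))
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(value, file.path(cache_dir, paste0(key, ".rds")))
  invisible(NULL)
}

#' Two-pass search of a library against one DIA run
#'
#' Pass 1 scores every target/decoy entry and re-scores the feature
#' table; the 1\%-FDR targets anchor the kernel-density retention-time
#' model and its mixture model; apexes that are retention-time outliers
#' (targets and decoys alike) are reconsidered up to five times with
#' their prior apexes masked; features (now including deltaRT) are
#' rebuilt and re-scored for the final pass.
#'
#' @param run a demultiplexed \code{DIARun}
#' @param lib \code{PeptideLibrary} with decoys (decoys are added when
#'   absent)
#' @param cfg a \code{StudyConfig}
#' @param cache_dir optional directory for resumable intermediates
#' @return list with \code{features} (final feature table),
#'   \code{validated} (re-scored), \code{matches}, \code{rt_model},
#'   \code{mixture} and \code{counts}
#' @export
run_search <- function(run, lib, cfg = study_config(), cache_dir = NULL) {
  if (!any(vapply(lib$entries, `[[`, logical(1), "is_decoy")))
    lib <- add_decoys(lib, cfg$tol_ppm)
  key <- input_hash("search", run$run_id, names(lib$entries), cfg)
  cached <- cache_get(cache_dir, key)
  if (!is.null(cached)) {
    stage_log("search", "run %s: cached result reused", run$run_id)
    return(cached)
  }
  res1 <- search_run(run, lib, tol_ppm = cfg$tol_ppm,
                     transform = cfg$transform)
  if (is.null(res1$features)) stop("search stage: no entry scored in run ",
                                   run$run_id)
  stage_log("search", "run %s: %d/%d entries scored", run$run_id,
            nrow(res1$features), length(lib$entries))
  pass1 <- rescore(res1$features, train_fdr = cfg$fdr_peptide)

  anchors_df <- pass1[!pass1$is_decoy & pass1$q_value <= cfg$fdr_peptide, ]
  matches <- res1$matches
  rt_model <- NULL; mixture <- NULL; n_outliers <- 0L
  if (nrow(anchors_df) >= 5L) {
    lib_rts <- vapply(seq_len(nrow(anchors_df)), function(i)
      lib$entries[[entry_key(anchors_df$modseq[i], anchors_df$charge[i],
                             FALSE)]]$library_rt, numeric(1))
    rt_model <- fit_kde_ridge(data.frame(x = lib_rts,
                                         y = anchors_df$apex_rt))
    deltas <- anchors_df$apex_rt - predict_rt(rt_model, lib_rts)
    cell <- if (rt_model$type == "kde") unname(rt_model$cell["dy"]) else NULL
    mixture <- fit_mixture(deltas, outlier_p = cfg$rt_outlier_p,
                           sd_floor = cell)
    stage_log("rt", "run %s: %d anchors, bandwidth %.3f, prior(correct) %.2f",
              run$run_id, nrow(anchors_df),
              if (rt_model$type == "kde") rt_model$bandwidth else NA,
              mixture$priors["correct"])

    # flag outliers among all finite matches (targets and decoys)
    flagged <- list()
    for (k in names(matches)) {
      sm <- matches[[k]]
      if (!is.finite(sm$primary_score)) next
      d <- sm$apex_rt - predict_rt(rt_model, lib$entries[[k]]$library_rt)
      if (mixture_posterior(mixture, d) < cfg$rt_outlier_p)
        flagged[[k]] <- sm
    }
    n_outliers <- length(flagged)
    stage_log("rt", "run %s: %d apexes reconsidered", run$run_id, n_outliers)
    if (n_outliers > 0L) {
      redone <- reconsider_outliers(run, lib$entries[names(flagged)],
                                    flagged, rt_model, mixture,
                                    accept_p = cfg$rt_outlier_p,
                                    tol_ppm = cfg$tol_ppm,
                                    transform = cfg$transform)
      matches[names(redone)] <- redone
    }
  } else {
    stage_log("rt", "run %s: too few anchors (%d); RT stage skipped",
              run$run_id, nrow(anchors_df))
  }

  feats2 <- features_from_matches(run, lib, matches, rt_model = rt_model,
                                  tol_ppm = cfg$tol_ppm)
  validated <- rescore(feats2, train_fdr = cfg$fdr_peptide)
  n_pass <- sum(!validated$is_decoy & validated$q_value <= cfg$fdr_peptide)
  stage_log("validate", "run %s: %d peptides at %.0f%% FDR", run$run_id,
            n_pass, 100 * cfg$fdr_peptide)
  out <- list(features = feats2, validated = validated, matches = matches,
              rt_model = rt_model, mixture = mixture,
              counts = c(scored = nrow(res1$features),
                         anchors = nrow(anchors_df),
                         outliers_reconsidered = n_outliers,
                         passing = n_pass))
  cache_put(cache_dir, key, out)
  out
}

#' Build a chromatogram library from narrow-window runs
#'
#' Searches each (demultiplexed) narrow run against the seed library,
#' applies study-wide peptide FDR, and stores the passing peptides'
#' run-measured coordinates as a chromatogram library.
#' @param narrow_runs list of \code{DIARun} (gas-phase fractions)
#' @param seed_lib seed \code{PeptideLibrary} (DDA spectrum library or
#'   equivalent)
#' @param cfg a \code{StudyConfig}
#' @param cache_dir optional cache directory
#' @return list with \code{library} (chromatogram
#'   \code{PeptideLibrary}), \code{searches}, \code{peptides}
#' @export
run_build_library <- function(narrow_runs, seed_lib, cfg = study_config(),
                              cache_dir = NULL) {
  if (!length(narrow_runs)) stop("library stage: no narrow runs supplied")
  if (!any(vapply(seed_lib$entries, `[[`, logical(1), "is_decoy")))
    seed_lib <- add_decoys(seed_lib, cfg$tol_ppm)
  searches <- list()
  for (run in narrow_runs) {
    searches[[run$run_id]] <- run_search(run, seed_lib, cfg, cache_dir)
  }
  gl <- global_peptide_fdr(lapply(searches, `[[`, "validated"),
                           train_fdr = cfg$fdr_peptide)
  pass <- gl$peptides[!gl$peptides$is_decoy &
                        gl$peptides$q_value <= cfg$fdr_peptide, ]
  stage_log("library", "%d peptides at %.0f%% global FDR", nrow(pass),
            100 * cfg$fdr_peptide)
  passing <- data.frame(modseq = pass$modseq, charge = pass$charge,
                        run_id = pass$run_id, score = pass$svm_score)
  runs_by_id <- stats::setNames(narrow_runs,
                                vapply(narrow_runs, `[[`, character(1),
                                       "run_id"))
  chrom <- build_chromatogram_library(
    passing, lapply(searches, `[[`, "matches"), runs_by_id, seed_lib,
    min_fragments = cfg$min_transitions, min_correlation = cfg$r_detect)
  stage_log("library", "chromatogram library: %d entries",
            length(chrom$entries))
  list(library = chrom, searches = searches, peptides = pass)
}

#' Quantify a study from per-run search results
#'
#' Applies study-wide peptide FDR and parsimonious protein FDR, extracts
#' and refines fragment chromatograms at each passing apex, selects
#' transitions study-wide, applies the replicate-completeness and CV
#' filters, and aggregates to protein quantities. When
#' \code{backfill = TRUE}, peptides missing in individual runs are
#' quantified at retention times inferred by cross-run alignment before
#' filtering.
#'
#' @param searches named list (by run id) of \code{\link{run_search}}
#'   results
#' @param runs named list of the corresponding \code{DIARun}
#' @param lib the searched \code{PeptideLibrary} (with decoys)
#' @param design data.frame \code{run_id}, \code{condition},
#'   \code{replicate}
#' @param cfg a \code{StudyConfig}
#' @param backfill infer and quantify missing peptide/run pairs
#' @return list with \code{peptides} (filtered long table),
#'   \code{proteins} (long table), \code{peptide_matrix},
#'   \code{protein_matrix}, \code{groups}, \code{global}
#' @export
run_quantify <- function(searches, runs, lib, design,
                         cfg = study_config(), backfill = TRUE) {
  gl <- global_peptide_fdr(lapply(searches, `[[`, "validated"),
                           train_fdr = cfg$fdr_peptide)
  peps <- gl$peptides[gl$peptides$q_value <= cfg$fdr_peptide, ]
  targets <- peps[!peps$is_decoy, ]
  stage_log("quantify", "%d peptides at %.0f%% global FDR",
            nrow(targets), 100 * cfg$fdr_peptide)
  prot <- parsimonious_proteins(peps, lib$protein_map,
                                fdr = cfg$fdr_protein)
  stage_log("quantify", "%d protein groups at %.0f%% FDR",
            if (is.null(prot$passing)) 0L else nrow(prot$passing),
            100 * cfg$fdr_protein)

  # per-run observations of study-passing peptides
  obs <- gl$observations
  obs_pass <- obs[!obs$is_decoy & obs$modseq %in% targets$modseq &
                    obs$q_value <= 0.1, ] # run-local evidence gate
  records <- list()
  for (i in seq_len(nrow(obs_pass))) {
    rid <- obs_pass$run_id[i]
    key <- entry_key(obs_pass$modseq[i], obs_pass$charge[i], FALSE)
    sm <- searches[[rid]]$matches[[key]]
    entry <- lib$entries[[key]]
    if (is.null(sm) || is.null(entry)) next
    qm <- quantify_match(runs[[rid]], sm, entry, tol_ppm = cfg$tol_ppm)
    if (!is.null(qm)) records[[length(records) + 1L]] <- qm
  }
  records <- if (length(records)) do.call(rbind, records) else NULL
  if (is.null(records)) stop("quantify stage: no quantifiable peptides")

  quant <- select_transitions_study(records,
                                    max_interference = cfg$max_interference,
                                    top_n = cfg$max_transitions,
                                    min_transitions = cfg$min_transitions,
                                    r_quant = cfg$r_quant)
  if (is.null(quant)) stop("quantify stage: no peptide survived transition selection")
  stage_log("quantify", "%d peptides with >= %d clean transitions",
            length(unique(quant$modseq)), cfg$min_transitions)

  bf <- NULL
  if (backfill && length(runs) > 1L) {
    aligned <- align_across_experiments(
      data.frame(modseq = obs_pass$modseq, run_id = obs_pass$run_id,
                 score = obs_pass$svm_score, apex_rt = obs_pass$apex_rt))
    have <- paste(quant$modseq, quant$run_id)
    need <- aligned$inferred[
      aligned$inferred$modseq %in% unique(quant$modseq) &
        !(paste(aligned$inferred$modseq, aligned$inferred$run_id) %in% have), ]
    rows <- list()
    for (i in seq_len(nrow(need))) {
      modseq <- need$modseq[i]; rid <- need$run_id[i]
      ch <- targets$charge[match(modseq, targets$modseq)]
      key <- entry_key(modseq, ch, FALSE)
      entry <- lib$entries[[key]]
      if (is.null(entry) || is.null(runs[[rid]])) next
      pseudo <- structure(list(modseq = modseq, charge = ch,
                               is_decoy = FALSE, run_id = rid,
                               apex_rt = need$rt[i]), class = "ScoredMatch")
      qm <- quantify_match(runs[[rid]], pseudo, entry, tol_ppm = cfg$tol_ppm)
      if (is.null(qm)) next
      agg <- stats::aggregate(area ~ run_id, qm[qm$correlation >= cfg$r_quant &
                                                  !is.na(qm$correlation), ,
                                                drop = FALSE], sum)
      if (nrow(agg))
        rows[[length(rows) + 1L]] <- data.frame(modseq = modseq,
                                                run_id = rid,
                                                area = agg$area)
    }
    bf <- if (length(rows)) do.call(rbind, rows) else NULL
    stage_log("quantify", "%d peptide/run pairs back-filled",
              if (is.null(bf)) 0L else nrow(bf))
  }

  filtered <- study_filters(quant, design, cv_max = cfg$cv_max,
                            backfill = bf)
  stage_log("quantify", "%d peptides pass replicate/CV filters",
            if (is.null(filtered)) 0L else length(unique(filtered$modseq)))
  proteins <- protein_quant(filtered, prot$passing, lib$protein_map)
  list(peptides = filtered, proteins = proteins,
       peptide_matrix = quant_matrix(filtered, "modseq"),
       protein_matrix = quant_matrix(proteins, "accessions"),
       groups = prot, global = gl)
}

#' Long-to-wide quantity matrix
#' @param long data.frame with \code{run_id}, \code{area} and an entity
#'   column
#' @param id entity column name
#' @return matrix entities x runs (NA where unmeasured)
#' @export
quant_matrix <- function(long, id = "modseq") {
  if (is.null(long) || nrow(long) == 0L) return(NULL)
  tapply(long$area, list(long[[id]], long$run_id), sum)
}
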