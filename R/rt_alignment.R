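# Non-parametric retention-time calibration: 2-D kernel density ridge
# walking, a Gaussian/uniform EM mixture model for outlier calling,
# apex reconsideration, and cross-experiment alignment.

#' Fit the library-to-run retention-time mapping
#'
#' Stamps a separable cosine-approximated Gaussian kernel at every
#' (library RT, run RT) anchor on a 1000x1000 grid and walks the density
#' ridge from the global maximum: uphill moving north/east/northeast
#' (northeast when north and east tie) and downhill south/west/southwest
#' (ties southwest), which forces a monotone mapping. The bandwidth
#' follows Silverman-style scaling \code{N^(-1/6) * (sd(x)+sd(y))/2} and
#' the kernel sd is bandwidth / (2 sqrt(2 ln 2)). Kernel mass falling
#' outside the grid is reflected back at the boundary so total density
#' mass is conserved. Below \code{floor} anchors a robust linear fit is
#' used instead (with a warning).
#'
#' @param anchors data.frame with columns \code{x} (library RT) and
#'   \code{y} (run RT)
#' @param grid_n grid resolution per axis
#' @param floor minimum anchor count for the KDE fit
#' @param keep_grid retain the full density grid in the model (8 MB;
#'   useful for diagnostics and tests)
#' @return an \code{RTModel}
#' @export
fit_kde_ridge <- function(anchors, grid_n = 1000L, floor = 20L,
                          keep_grid = FALSE) {
  x <- anchors$x; y <- anchors$y
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < floor) {
    warning("only ", n, " anchors (< ", floor,
            "); falling back to a robust linear fit")
    fit <- stats::lm(y ~ x)
    r <- stats::residuals(fit)
    keep <- abs(r) <= 3 * stats::mad(r) + .Machine$double.eps
    if (sum(keep) >= 2L) fit <- stats::lm(y ~ x, subset = keep)
    return(structure(list(type = "linear", coef = stats::coef(fit),
                          n_anchors = n), class = "RTModel"))
  }
  bandwidth <- n^(-1 / 6) * (stats::sd(x) + stats::sd(y)) / 2
  kernel_sd <- bandwidth / (2 * sqrt(2 * log(2)))

  dx <- (max(x) - min(x)) / (grid_n - 3L) # 1-cell padding each side
  dy <- (max(y) - min(y)) / (grid_n - 3L)
  if (dx <= 0) dx <- max(bandwidth, 1e-6) / 10
  if (dy <= 0) dy <- max(bandwidth, 1e-6) / 10
  xs <- min(x) - dx + (seq_len(grid_n) - 1L) * dx
  ys <- min(y) - dy + (seq_len(grid_n) - 1L) * dy

  # cosine kernel k(r) = (1 + cos(pi r / R)) / 2, truncated at R chosen so
  # its FWHM equals the Gaussian FWHM (= bandwidth): half max at R/2.
  R <- bandwidth
  kvec <- function(cell) {
    r <- ceiling(R / cell)
    d <- abs((-r:r) * cell)
    k <- ifelse(d < R, (1 + cos(pi * d / R)) / 2, 0)
    k
  }
  kx <- kvec(dx); ky <- kvec(dy)
  rx <- (length(kx) - 1L) %/% 2L; ry <- (length(ky) - 1L) %/% 2L
  kern <- outer(ky, kx)

  grid <- matrix(0, grid_n, grid_n) # rows = y, cols = x
  ix <- pmin(pmax(round((x - xs[1L]) / dx) + 1L, 1L), grid_n)
  iy <- pmin(pmax(round((y - ys[1L]) / dy) + 1L, 1L), grid_n)
  kmass <- sum(kern)
  for (a in seq_len(n)) {
    cols <- (ix[a] - rx):(ix[a] + rx)
    rows <- (iy[a] - ry):(iy[a] + ry)
    cok <- cols >= 1L & cols <= grid_n
    rok <- rows >= 1L & rows <= grid_n
    if (all(cok) && all(rok)) {
      grid[rows, cols] <- grid[rows, cols] + kern
    } else {
      # boundary: cut-and-normalize (truncate the kernel, then rescale
      # to full mass) - conserves total mass without moving the crest
      # the way reflection folding would
      k <- kern[rok, cok, drop = FALSE]
      grid[rows[rok], cols[cok]] <- grid[rows[rok], cols[cok]] +
        k * (kmass / sum(k))
    }
  }

  ridge_y <- walk_ridge(grid)
  # fill uncovered terminal columns by continuing the slope of the
  # terminal 5% of the fitted ridge
  ridge_y <- extrapolate_ridge(ridge_y)
  ridge_y <- cummax(ridge_y) # enforce monotonicity exactly
  structure(list(
    type = "kde", bandwidth = bandwidth, kernel_sd = kernel_sd,
    n_anchors = n, xs = xs, ys = ys,
    ridge = ys[ridge_y], ridge_rows = ridge_y,
    cell = c(dx = dx, dy = dy),
    kernel_mass = sum(kern),
    grid = if (keep_grid) grid else NULL), class = "RTModel")
}

# Walk the ridge of a density grid (rows = y, cols = x). Returns the row
# index of the ridge for each column (NA where unvisited).
walk_ridge <- function(grid) {
  gn <- nrow(grid)
  start <- which(grid == max(grid), arr.ind = TRUE)[1L, ]
  path_row <- rep(NA_integer_, gn)
  note <- function(r, c) path_row[c] <<- max(path_row[c], r, na.rm = TRUE)
  r <- start[1L]; c <- start[2L]
  note(r, c)
  while (r < gn && c < gn) { # uphill: N, E, NE; N==E tie -> NE
    vn <- grid[r + 1L, c]; ve <- grid[r, c + 1L]; vne <- grid[r + 1L, c + 1L]
    m <- max(vn, ve, vne)
    if ((vn == m && ve == m) || vne == m) { r <- r + 1L; c <- c + 1L }
    else if (vn == m) r <- r + 1L
    else c <- c + 1L
    note(r, c)
  }
  r <- start[1L]; c <- start[2L]
  while (r > 1L && c > 1L) { # downhill: S, W, SW; ties -> SW
    vs <- grid[r - 1L, c]; vw <- grid[r, c - 1L]; vsw <- grid[r - 1L, c - 1L]
    m <- max(vs, vw, vsw)
    if ((vs == m && vw == m) || vsw == m) { r <- r - 1L; c <- c - 1L }
    else if (vs == m) r <- r - 1L
    else c <- c - 1L
    # downhill: record the smallest row seen per column
    if (is.na(path_row[c])) path_row[c] <- r else path_row[c] <- min(path_row[c], r)
  }
  path_row
}

extrapolate_ridge <- function(ridge_row) {
  n <- length(ridge_row)
  covered <- which(!is.na(ridge_row))
  if (!length(covered)) return(rep(1L, n))
  lo <- covered[1L]; hi <- covered[length(covered)]
  seg <- max(2L, round(0.05 * (hi - lo + 1L)))
  if (lo > 1L) {
    i <- covered[seq_len(min(seg, length(covered)))]
    slope <- if (length(i) > 1L)
      (ridge_row[i[length(i)]] - ridge_row[i[1L]]) / (i[length(i)] - i[1L]) else 0
    ridge_row[1:(lo - 1L)] <- round(ridge_row[lo] - slope * (lo - (1:(lo - 1L))))
  }
  if (hi < n) {
    i <- covered[(length(covered) - min(seg, length(covered)) + 1L):length(covered)]
    slope <- if (length(i) > 1L)
      (ridge_row[i[length(i)]] - ridge_row[i[1L]]) / (i[length(i)] - i[1L]) else 0
    ridge_row[(hi + 1L):n] <- round(ridge_row[hi] + slope * ((hi + 1L):n - hi))
  }
  pmin(pmax(as.integer(round(ridge_row)), 1L), n)
}

#' Predict run retention time from library retention time
#' @param model an \code{RTModel}
#' @param x library retention times
#' @return mapped run retention times
#' @export
predict_rt <- function(model, x) {
  stopifnot(inherits(model, "RTModel"))
  if (model$type == "linear")
    return(unname(model$coef[1L] + model$coef[2L] * x))
  xs <- model$xs; ry <- model$ridge
  y <- stats::approx(xs, ry, xout = x, rule = 2)$y
  # continue with terminal slope beyond the grid
  n <- length(xs)
  slope_lo <- (ry[min(50L, n)] - ry[1L]) / (xs[min(50L, n)] - xs[1L])
  slope_hi <- (ry[n] - ry[max(1L, n - 50L)]) / (xs[n] - xs[max(1L, n - 50L)])
  below <- x < xs[1L]; above <- x > xs[n]
  y[below] <- ry[1L] + slope_lo * (x[below] - xs[1L])
  y[above] <- ry[n] + slope_hi * (x[above] - xs[n])
  y
}

#' @export
print.RTModel <- function(x, ...) {
  if (x$type == "linear")
    cat(sprintf("RTModel (robust linear fallback, %d anchors): y = %.4f + %.4f x\n",
                x$n_anchors, x$coef[1L], x$coef[2L]))
  else
    cat(sprintf("RTModel (KDE ridge, %d anchors): bandwidth %.4f min, kernel sd %.4f min\n",
                x$n_anchors, x$bandwidth, x$kernel_sd))
  invisible(x)
}

#' Fit the Gaussian/uniform mixture model of retention-time residuals
#'
#' The correct-match component is a Gaussian with mean = median(delta)
#' and sd = IQR/1.35; the incorrect-match component is uniform over the
#' observed delta range. Component shapes stay fixed while exactly 10 EM
#' iterations update the priors (initialized 0.5/0.5) and posteriors.
#' Pairs whose posterior probability of being correct is below
#' \code{outlier_p} are flagged outliers.
#'
#' @param deltas retention-time residuals (run RT - ridge(library RT))
#' @param outlier_p posterior threshold for outlier calls
#' @param sd_floor lower bound on the Gaussian sd (one grid cell; applied
#'   with a warning when IQR is 0)
#' @return an \code{RTMixtureModel} with fields \code{gauss_mean},
#'   \code{gauss_sd}, \code{uniform_range}, \code{priors},
#'   \code{posteriors}, \code{outlier}
#' @export
fit_mixture <- function(deltas, outlier_p = 0.05, sd_floor = NULL) {
  stopifnot(length(deltas) >= 2L)
  mu <- stats::median(deltas)
  sdv <- stats::IQR(deltas) / 1.35
  rng <- range(deltas)
  if (is.null(sd_floor)) sd_floor <- max(diff(rng) / 1000, 1e-9)
  if (sdv <= 0)
    warning("IQR of retention-time residuals is 0; flooring Gaussian sd")
  sdv <- max(sdv, sd_floor)
  du <- if (diff(rng) > 0) 1 / diff(rng) else 1
  fg <- stats::dnorm(deltas, mu, sdv)
  fu <- rep(du, length(deltas))
  pi_g <- 0.5
  post <- rep(0.5, length(deltas))
  for (it in 1:10) {
    num <- pi_g * fg
    den <- num + (1 - pi_g) * fu
    post <- ifelse(den > 0, num / den, 0)
    pi_g <- mean(post)
  }
  structure(list(gauss_mean = mu, gauss_sd = sdv, uniform_range = rng,
                 priors = c(correct = pi_g, incorrect = 1 - pi_g),
                 posteriors = post, outlier = post < outlier_p,
                 outlier_p = outlier_p),
            class = "RTMixtureModel")
}

#' Posterior probability that residuals come from the correct component
#' @param model an \code{RTMixtureModel}
#' @param deltas residuals to evaluate
#' @return posterior probabilities in [0, 1]
#' @export
mixture_posterior <- function(model, deltas) {
  fg <- stats::dnorm(deltas, model$gauss_mean, model$gauss_sd)
  rng <- model$uniform_range
  du <- if (diff(rng) > 0) 1 / diff(rng) else 1
  fu <- rep(du, length(deltas))
  num <- model$priors["correct"] * fg
  den <- num + model$priors["incorrect"] * fu
  unname(ifelse(den > 0, num / den, 0))
}

#' Re-search retention-time outliers with their prior apexes masked
#'
#' For each flagged match (targets and decoys are treated identically)
#' the prior apex is masked and the best remaining retention-time point
#' searched again, up to \code{max_rounds} times, until the new apex
#' satisfies the mixture model at posterior >= \code{accept_p}. If no
#' round succeeds the original match is kept (its deltaRT feature then
#' reflects the violation).
#' @param run the searched \code{DIARun}
#' @param entries named list of \code{LibraryEntry} (keys as in the
#'   library) for the flagged matches
#' @param flagged named list of \code{ScoredMatch} to reconsider
#' @param rt_model fitted \code{RTModel}
#' @param mixture fitted \code{RTMixtureModel}
#' @param max_rounds maximum reconsideration rounds (default 5)
#' @param accept_p posterior acceptance threshold
#' @param tol_ppm fragment tolerance
#' @param transform intensity transform
#' @return named list of \code{ScoredMatch} (same keys as \code{flagged})
#' @export
reconsider_outliers <- function(run, entries, flagged, rt_model, mixture,
                                max_rounds = 5L, accept_p = 0.05,
                                tol_ppm = 10, transform = "sqrt") {
  out <- flagged
  for (key in names(flagged)) {
    orig <- flagged[[key]]
    entry <- entries[[key]]
    if (is.null(entry) || !is.finite(orig$primary_score)) next
    masked <- orig$apex_rt
    accepted <- NULL
    for (round in seq_len(max_rounds)) {
      cand <- find_best_rt(run, entry, masked = masked, tol_ppm = tol_ppm,
                           transform = transform)
      if (!is.finite(cand$primary_score)) break
      delta <- cand$apex_rt - predict_rt(rt_model, entry$library_rt)
      if (mixture_posterior(mixture, delta) >= accept_p) {
        accepted <- cand
        break
      }
      masked <- c(masked, cand$apex_rt)
    }
    if (!is.null(accepted)) {
      accepted$masked_rts <- masked
      out[[key]] <- accepted
    }
  }
  out
}

#' Align retention times across the runs of an experiment
#'
#' The best-scoring observation of each peptide is its canonical
#' representation; the run with the most canonical peptides anchors the
#' experiment (ties to the lexicographically first run id). Every run is
#' ridge-aligned to the anchor in both directions, pairs that are less
#' than \code{outlier_p} likely under the cross-run mixture model are
#' removed, and each peptide receives an inferred retention time in every
#' run via the anchor mapping.
#'
#' @param observations data.frame with columns \code{modseq},
#'   \code{run_id}, \code{score}, \code{apex_rt} (one row per passing
#'   peptide observation)
#' @param outlier_p cross-run mixture outlier threshold (default 0.001)
#' @param floor minimum anchors for the KDE fit (passed through)
#' @return list with \code{anchor_run}, \code{canonical} (data.frame),
#'   \code{models_to_anchor}, \code{models_from_anchor} (named lists of
#'   \code{RTModel}) and \code{inferred} (data.frame modseq/run_id/rt)
#' @export
align_across_experiments <- function(observations, outlier_p = 0.001,
                                     floor = 20L) {
  obs <- observations[order(-observations$score), ]
  canonical <- obs[!duplicated(obs$modseq), c("modseq", "run_id", "apex_rt")]
  runs <- sort(unique(observations$run_id))
  if (length(runs) == 1L) {
    inferred <- canonical
    names(inferred)[3L] <- "rt"
    return(list(anchor_run = runs, canonical = canonical,
                models_to_anchor = NULL, models_from_anchor = NULL,
                inferred = inferred))
  }
  counts <- table(factor(canonical$run_id, levels = runs))
  anchor <- names(counts)[which(counts == max(counts))][1L] # lexicographic tie
  anchor_obs <- observations[observations$run_id == anchor, ]

  models_to <- list(); models_from <- list()
  for (r in runs) {
    if (r == anchor) next
    ro <- observations[observations$run_id == r, ]
    shared <- merge(ro[, c("modseq", "apex_rt")],
                    anchor_obs[, c("modseq", "apex_rt")],
                    by = "modseq", suffixes = c("_run", "_anchor"))
    m_to <- fit_kde_ridge(data.frame(x = shared$apex_rt_run,
                                     y = shared$apex_rt_anchor), floor = floor)
    resid <- shared$apex_rt_anchor - predict_rt(m_to, shared$apex_rt_run)
    # ridge predictions are quantized to the grid: floor the Gaussian sd
    # at one grid cell so quantized residuals are not all outliers
    cell <- if (m_to$type == "kde") unname(m_to$cell["dy"]) else NULL
    mix <- fit_mixture(resid, outlier_p = outlier_p, sd_floor = cell)
    keep <- !mix$outlier
    if (sum(keep) < floor) keep <- rep(TRUE, nrow(shared))
    if (sum(keep) >= floor && any(!keep)) {
      m_to <- fit_kde_ridge(data.frame(x = shared$apex_rt_run[keep],
                                       y = shared$apex_rt_anchor[keep]),
                            floor = floor)
    }
    m_from <- fit_kde_ridge(data.frame(x = shared$apex_rt_anchor[keep],
                                       y = shared$apex_rt_run[keep]),
                            floor = floor)
    models_to[[r]] <- m_to; models_from[[r]] <- m_from
  }

  # canonical retention times expressed in the anchor frame
  rt_anchor <- numeric(nrow(canonical))
  for (i in seq_len(nrow(canonical))) {
    r <- canonical$run_id[i]
    rt_anchor[i] <- if (r == anchor) canonical$apex_rt[i]
      else predict_rt(models_to[[r]], canonical$apex_rt[i])
  }
  canonical$rt_anchor <- rt_anchor

  inferred <- do.call(rbind, lapply(runs, function(r) {
    rt <- if (r == anchor) canonical$rt_anchor
      else predict_rt(models_from[[r]], canonical$rt_anchor)
    data.frame(modseq = canonical$modseq, run_id = r, rt = rt)
  }))
  list(anchor_run = anchor, canonical = canonical,
       models_to_anchor = models_to, models_from_anchor = models_from,
       inferred = inferred)
}
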