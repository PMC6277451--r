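# Monoisotopic masses and peptide fragment chemistry.

PROTON_MASS <- 1.007276466879
WATER_MASS <- 18.0105646863
NEUTRON_SPACING <- 1.00335483507 # average C13-C12 spacing used for isotopes
CARBAMIDOMETHYL <- 57.02146372376

#' Monoisotopic residue masses
#'
#' Residue (not free amino acid) monoisotopic masses in Da.
#' Cysteine is reported carbamidomethylated: the alkylation is treated as a
#' fixed modification throughout the package.
#' @return named numeric vector over the 20 standard one-letter codes
#' @export
residue_masses <- function() {
  m <- c(
    G = 57.02146372, A = 71.03711379, S = 87.03202841, P = 97.05276385,
    V = 99.06841391, T = 101.04767847, C = 103.00918448 + CARBAMIDOMETHYL,
    L = 113.08406398, I = 113.08406398, N = 114.04292744, D = 115.02694302,
    Q = 128.05857751, K = 128.09496302, E = 129.04259309, M = 131.04048461,
    H = 137.05891186, F = 147.06841391, R = 156.10111102, Y = 163.06332853,
    W = 186.07931295
  )
  m
}

#' Parse a modified peptide sequence
#'
#' Modifications are encoded as bracketed delta masses after the residue,
#' e.g. \code{"M[+15.994915]"}. Returns the bare residues and a per-residue
#' modification mass vector.
#' @param modseq modified sequence string
#' @return list with \code{residues} (character vector) and \code{mods}
#'   (numeric vector of delta masses, 0 where unmodified)
#' @export
parse_modseq <- function(modseq) {
  stopifnot(is.character(modseq), length(modseq) == 1L, nzchar(modseq))
  chars <- strsplit(modseq, "", fixed = TRUE)[[1L]]
  residues <- character(0)
  mods <- numeric(0)
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unbalanced '[' in modseq: ", modseq)
      delta <- as.numeric(paste(chars[(i + 1L):(j - 1L)], collapse = ""))
      if (is.na(delta)) stop("unparseable modification in modseq: ", modseq)
      if (length(residues) == 0L) stop("modification before first residue: ", modseq)
      mods[length(mods)] <- mods[length(mods)] + delta
      i <- j + 1L
    } else {
      if (!ch %in% names(residue_masses()))
        stop("unknown residue '", ch, "' in modseq: ", modseq)
      residues <- c(residues, ch)
      mods <- c(mods, 0)
      i <- i + 1L
    }
  }
  list(residues = residues, mods = mods)
}

#' Bare (unmodified-notation) sequence of a modseq
#' @param modseq modified sequence string
#' @return plain sequence string
#' @export
strip_mods <- function(modseq) {
  paste(parse_modseq(modseq)$residues, collapse = "")
}

#' Monoisotopic peptide mass
#' @param modseq modified sequence string
#' @return neutral monoisotopic mass in Da
#' @export
peptide_mass <- function(modseq) {
  p <- parse_modseq(modseq)
  sum(residue_masses()[p$residues]) + sum(p$mods) + WATER_MASS
}

#' Precursor m/z for a peptide at a charge
#' @param modseq modified sequence string
#' @param charge precursor charge (>= 1)
#' @return m/z
#' @export
precursor_mz <- function(modseq, charge) {
  (peptide_mass(modseq) + charge * PROTON_MASS) / charge
}

#' Theoretical B/Y fragment ions of a peptide
#'
#' Enumerates B and Y ions at the requested fragment charges. Only B/Y are
#' produced; A-type ions and water/ammonia losses are deliberately never
#' generated.
#' @param modseq modified sequence string
#' @param frag_charges fragment charge states, e.g. \code{1:2}
#' @return data.frame with columns \code{type} ("B"/"Y"), \code{index},
#'   \code{charge}, \code{mz}
#' @export
fragment_ions <- function(modseq, frag_charges = 1:2) {
  p <- parse_modseq(modseq)
  rm <- residue_masses()[p$residues] + p$mods
  n <- length(rm)
  if (n < 2L) return(data.frame(type = character(0), index = integer(0),
                                charge = integer(0), mz = numeric(0)))
  bsum <- cumsum(rm)[-n]       # b_i = first i residues, i = 1..n-1
  ysum <- cumsum(rev(rm))[-n]  # y_i = last i residues, i = 1..n-1
  out <- list()
  for (z in frag_charges) {
    out[[length(out) + 1L]] <- data.frame(
      type = "B", index = seq_len(n - 1L), charge = z,
      mz = (bsum + z * PROTON_MASS) / z
    )
    out[[length(out) + 1L]] <- data.frame(
      type = "Y", index = seq_len(n - 1L), charge = z,
      mz = (ysum + WATER_MASS + z * PROTON_MASS) / z
    )
  }
  do.call(rbind, out)
}

#' Approximate isotope envelope (averagine-style)
#'
#' Poisson approximation to the first \code{n} isotope peak heights of a
#' peptide of given neutral mass, normalized so the base peak is 1.
#' @param mass neutral monoisotopic mass in Da
#' @param n number of isotope peaks
#' @return numeric vector of length \code{n}
#' @export
isotope_envelope <- function(mass, n = 4L) {
  lambda <- 0.000594 * mass # heavy-isotope rate per Da, averagine-like
  p <- stats::dpois(0:(n - 1L), lambda)
  p / max(p)
}

#' Parts-per-million difference
#' @param observed observed m/z
#' @param expected expected m/z
#' @return signed ppm error
#' @export
ppm_error <- function(observed, expected) {
  (observed - expected) / expected * 1e6
}

# Nearest-match of query m/z values against a sorted peak list.
# Returns the index of the nearest peak within tol_ppm, or NA.
match_nearest_ppm <- function(query_mz, peak_mz, tol_ppm) {
  if (length(peak_mz) == 0L || length(query_mz) == 0L)
    return(rep(NA_integer_, length(query_mz)))
  idx <- findInterval(query_mz, peak_mz)
  lo <- pmax(idx, 1L)
  hi <- pmin(idx + 1L, length(peak_mz))
  d_lo <- abs(peak_mz[lo] - query_mz)
  d_hi <- abs(peak_mz[hi] - query_mz)
  best <- ifelse(d_lo <= d_hi, lo, hi)
  err <- abs(peak_mz[best] - query_mz) / query_mz * 1e6
  best[err > tol_ppm] <- NA_integer_
  best
}
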