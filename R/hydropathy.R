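# Roseman (1988) side-chain hydrophobicity scale, kcal/mol-derived
# dimensionless values as distributed in ProtScale ("Hphob. Roseman").
roseman_scale_values <- c(
  A = 0.39, R = -3.95, N = -1.91, D = -3.81, C = 0.25,
  Q = -1.30, E = -2.91, G = 0.00, H = -0.64, I = 1.82,
  L = 1.82, K = -2.77, M = 0.96, F = 2.27, P = 0.99,
  S = -1.24, T = -1.00, W = 2.13, Y = 1.47, V = 1.30)

#' Residue hydropathy scale
#'
#' @param scale `"roseman"` (the bundled Roseman 1988 scale) or a named
#'   numeric vector mapping one-letter residue codes to hydropathy values.
#'   A custom scale need not cover all 20 residues but must cover every
#'   letter of the sequences it is applied to.
#' @return Object of class `"hydropathy_scale"` (named numeric vector).
#' @export
hydropathy_scale <- function(scale = "roseman") {
  if (is.character(scale)) {
    scale <- match.arg(scale, "roseman")
    v <- roseman_scale_values
    name <- "roseman"
  } else {
    stopifnot(is.numeric(scale), !is.null(names(scale)))
    v <- scale
    name <- "custom"
  }
  structure(v, class = "hydropathy_scale", scale_name = name)
}

#' Sliding-window hydropathy profile of a protein sequence
#'
#' The score at a window center is the unweighted mean of the per-residue
#' scale values over the window; termini shorter than half a window carry
#' no score (no padding). The transmembrane helices of a sequence appear
#' as maxima of the profile.
#'
#' @param seq Amino-acid string (one-letter codes) or character vector of
#'   single letters.
#' @param scale See [hydropathy_scale].
#' @param window Odd window length; the profile analyses here use 9-25
#'   residues (window 1 is allowed as an explicit per-residue override).
#' @return Object of class `"hydropathy_profile"`: `positions` (1-based
#'   window centers), `score`, `window`, `scale_name`.
#' @export
hydropathy_profile <- function(seq, scale = "roseman", window = 19) {
  sc <- hydropathy_scale(scale)
  if (length(seq) == 1L) seq <- strsplit(seq, "")[[1]]
  seq <- toupper(seq)
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("window must be odd, got ", window)
  if (length(seq) < window)
    stop("sequence length ", length(seq), " < window ", window)
  bad <- which(!seq %in% names(sc))
  if (length(bad))
    stop("residue letter '", seq[bad[1]], "' at position ", bad[1],
         " is not in the scale")
  v <- unname(sc[seq])
  cs <- cumsum(c(0, v))
  n <- length(seq)
  score <- (cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]) / window
  half <- (window - 1L) %/% 2L
  structure(list(positions = (half + 1L):(n - half), score = score,
                 window = window, scale_name = attr(sc, "scale_name")),
            class = "hydropathy_profile")
}

#' @export
print.hydropathy_profile <- function(x, ...) {
  cat(sprintf("<hydropathy_profile> %s scale, window %d: %d positions, score %.2f..%.2f\n",
              x$scale_name, x$window, length(x$score),
              min(x$score), max(x$score)))
  invisible(x)
}

#' Difference between two hydropathy profiles (mutant minus wild type)
#'
#' @param profile_mut,profile_wt [hydropathy_profile] objects of equal
#'   length and window (i.e. from equal-length sequences).
#' @param summary_range Optional residue range `c(lo, hi)`; when given, the
#'   mean delta over window centers inside the range is reported as
#'   `summary`.
#' @return List of class `"hydropathy_delta"`: `positions`, `delta`,
#'   optional `summary`.
#' @export
profile_delta <- function(profile_mut, profile_wt, summary_range = NULL) {
  if (profile_mut$window != profile_wt$window)
    stop("window mismatch: ", profile_mut$window, " vs ", profile_wt$window)
  if (length(profile_mut$score) != length(profile_wt$score))
    stop("profile length mismatch")
  delta <- profile_mut$score - profile_wt$score
  out <- list(positions = profile_wt$positions, delta = delta,
              window = profile_wt$window)
  if (!is.null(summary_range)) {
    keep <- out$positions >= summary_range[1] &
            out$positions <= summary_range[2]
    if (!any(keep)) stop("summary range contains no window centers")
    out$summary <- mean(delta[keep])
    out$summary_range <- summary_range
  }
  structure(out, class = "hydropathy_delta")
}

#' Read protein sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta_sequences <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readAAStringSet(path)
  setNames(as.character(ss), names(ss))
}
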