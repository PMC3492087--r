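# PWM scanning of regulatory sites.  Raw scores are log2 odds against a
# uniform background with an additive pseudocount; z-scores calibrate raw
# scores against the distribution of per-region maxima over a background
# region set, making downstream results invariant to affine changes of the
# raw-score convention.

pwmLogOdds <- function(x) {
  log2((x@matrix + x@pseudocount * 0.25) / (0.25 * (1 + x@pseudocount)))
}

#' Raw log-odds score of a window under a PWM
#'
#' score = sum over columns of log2((f[b_i, i] + pc * 0.25) /
#' (0.25 (1 + pc))); an ambiguous base contributes the background score 0.
#'
#' @param window Sequence of length equal to the motif width.
#' @param x A [PWM-class].
#' @return Numeric score.
#' @examples
#' u <- pwm("uniform", matrix(0.25, 4, 6,
#'   dimnames = list(c("A", "C", "G", "T"), NULL)))
#' pwmScore("ACGTAC", u) # 0
#' @export
pwmScore <- function(window, x) {
  if (nchar(window) != pwmWidth(x)) {
    stop("window length must equal motif width")
  }
  lo <- pwmLogOdds(x)
  b <- match(strsplit(toupper(window), "")[[1L]], c("A", "C", "G", "T"))
  sum(lo[cbind(b[!is.na(b)], which(!is.na(b)))])
}

# vectorized per-window scores over one strand of a sequence
scanScores <- function(sequence, x) {
  lo <- pwmLogOdds(x)
  w <- pwmWidth(x)
  b <- match(strsplit(toupper(sequence), "")[[1L]], c("A", "C", "G", "T"))
  n <- length(b) - w + 1L
  if (n < 1L) return(numeric(0L))
  s <- numeric(n)
  for (j in seq_len(w)) {
    bi <- b[j:(j + n - 1L)]
    contrib <- ifelse(is.na(bi), 0, lo[cbind(bi, j)])
    s <- s + contrib
  }
  s
}

#' Calibrate a PWM against background regions
#'
#' Takes, per region, the maximum raw score over both strands, then the mean
#' and standard deviation over regions; a scanned score s then maps to
#' z = (s - mean) / sd, the number of standard deviations above the
#' background mean.
#'
#' @param x A [PWM-class].
#' @param regions Character vector of background region sequences (>= 30,
#'   each at least the motif width).
#' @return A [PWMCalibration-class]; an all-identical region set (sd 0) is
#'   rejected.
#' @export
calibratePwm <- function(x, regions) {
  if (length(regions) < 30L) stop("calibration requires >= 30 regions")
  w <- pwmWidth(x)
  if (any(nchar(regions) < w)) stop("every region must be >= motif width")
  maxima <- vapply(regions, function(r) {
    max(scanScores(r, x), scanScores(revcomp(r), x))
  }, numeric(1L), USE.NAMES = FALSE)
  s <- sd(maxima)
  if (!is.finite(s) || s == 0) {
    stop("calibration rejected: zero variance across background regions")
  }
  new("PWMCalibration",
    pwm_name = x@name, mean = mean(maxima), sd = s,
    n_regions = length(regions)
  )
}

#' Reverse complement a sequence
#' @param x Character vector of sequences.
#' @return Reverse-complemented sequences.
#' @export
revcomp <- function(x) as.character(cpp_revcomp(x))

#' Scan a sequence with a calibrated PWM
#'
#' Scores every window on both strands; hits with z >= `z_min` are returned
#' sorted by position.  Positions are 1-based window starts on the forward
#' strand for both orientations.
#'
#' @param sequence Sequence to scan (length >= motif width).
#' @param x A [PWM-class].
#' @param calibration The matching [PWMCalibration-class].
#' @param z_min Minimum z to report (default 1.64, one-sided 5%).
#' @return Data frame: pwm, pos, strand, score, z, p (one-sided upper
#'   normal tail).
#' @export
scanPwm <- function(sequence, x, calibration, z_min = 1.64) {
  if (missing(calibration) || is.null(calibration)) {
    stop("calibration is required")
  }
  if (calibration@pwm_name != x@name) {
    stop("calibration does not match this PWM")
  }
  w <- pwmWidth(x)
  L <- nchar(sequence)
  if (L < w) stop("sequence shorter than motif width")
  fwd <- scanScores(sequence, x)
  rvs <- scanScores(revcomp(sequence), x)
  # the i-th window of the reverse complement is the forward window
  # starting at L - w + 2 - i, so reversing aligns the two score vectors
  pos <- seq_len(L - w + 1L)
  hits <- rbind(
    data.frame(pos = pos, strand = "+", score = fwd),
    data.frame(pos = pos, strand = "-", score = rev(rvs))
  )
  hits$z <- (hits$score - calibration@mean) / calibration@sd
  hits <- hits[hits$z >= z_min, , drop = FALSE]
  hits$p <- pNormUpper(hits$z)
  hits <- hits[order(hits$pos, hits$strand), , drop = FALSE]
  data.frame(
    pwm = rep(x@name, nrow(hits)), hits,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' One-sided upper-tail normal probability
#'
#' @param z Finite z-score(s).
#' @return P(Z >= z) under the standard normal.
#' @examples
#' pNormUpper(0) # 0.5
#' pNormUpper(2.86) # < 0.003
#' @export
pNormUpper <- function(z) {
  if (any(!is.finite(z))) stop("z must be finite")
  pnorm(z, lower.tail = FALSE)
}

#' Effect of an SNV on a PWM hit score
#'
#' Rescores the hit window with the alternate base substituted; direction is
#' the sign of alt - ref score with a 1e-9 neutrality tolerance.  Indels
#' overlapping a hit are reported unsupported.
#'
#' @param hit One row of a [scanPwm()] result.
#' @param pos,ref,alt The variant (1-based; SNV only).
#' @param x The [PWM-class] of the hit.
#' @param reference Target sequence.
#' @return List with `delta`, `direction` in
#'   increase/decrease/neutral/unsupported, and the two window scores.
#' @export
variantDelta <- function(hit, pos, ref, alt, x, reference) {
  w <- pwmWidth(x)
  if (pos < hit$pos || pos > hit$pos + w - 1L) {
    stop("variant does not intersect the hit span")
  }
  if (nchar(ref) != 1L || nchar(alt) != 1L) {
    return(list(delta = NA_real_, direction = "unsupported"))
  }
  win_ref <- substr(reference, hit$pos, hit$pos + w - 1L)
  win_alt <- win_ref
  substr(win_alt, pos - hit$pos + 1L, pos - hit$pos + 1L) <- alt
  if (hit$strand == "-") {
    score_ref <- pwmScore(revcomp(win_ref), x)
    score_alt <- pwmScore(revcomp(win_alt), x)
  } else {
    score_ref <- pwmScore(win_ref, x)
    score_alt <- pwmScore(win_alt, x)
  }
  delta <- score_alt - score_ref
  direction <- if (abs(delta) <= 1e-9) {
    "neutral"
  } else if (delta > 0) {
    "increase"
  } else {
    "decrease"
  }
  list(
    delta = delta, direction = direction, score_ref = score_ref,
    score_alt = score_alt
  )
}
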