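# Population-genetic summaries for a haploid cohort: Watterson's theta per
# site, pairwise nucleotide diversity from allele counts, and Tajima's D.

#' Tajima's D normalization constants
#'
#' The a1, a2, b1, b2, c1, c2, e1, e2 constants of the D statistic, functions
#' of the chromosome count n only.
#'
#' @param n Number of sampled chromosomes (>= 2).
#' @return Named list of the eight constants.
#' @export
tajimaConstants <- function(n) {
  if (n < 2) stop("n must be >= 2")
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2, e1 = e1,
       e2 = e2)
}

#' Watterson's estimator of the population mutation rate per site
#'
#' theta_w = S / (a1 * L) with a1 the (n-1)-th harmonic number.
#'
#' @param S Number of segregating sites.
#' @param n Number of sampled chromosomes (>= 2).
#' @param L Surveyed length in bases (>= 1).
#' @return Theta per site.
#' @examples
#' wattersonTheta(S = 3, n = 4, L = 100) # 3 / ((11/6) * 100)
#' @export
wattersonTheta <- function(S, n, L) {
  if (n < 2) stop("n must be >= 2")
  if (L < 1) stop("L must be >= 1")
  if (S < 0) stop("S must be >= 0")
  S / (tajimaConstants(n)$a1 * L)
}

#' Total pairwise nucleotide diversity from per-site allele counts
#'
#' For biallelic sites with minor counts k, pi = sum over sites of
#' 2 (k/n)(1 - k/n) n/(n-1), which equals the average pairwise Hamming
#' distance over all n(n-1)/2 haplotype pairs.
#'
#' @param k Vector of per-site minor (or derived) allele counts, each in
#'   1..n-1.
#' @param n Number of sampled chromosomes.
#' @return Total pi (summed over sites).
#' @examples
#' pairwisePi(c(1, 1, 1, 2, 1), n = 4) # 16/6
#' @export
pairwisePi <- function(k, n) {
  if (any(k <= 0 | k >= n)) stop("allele counts must be in 1..n-1")
  sum(2 * (k / n) * (1 - k / n) * n / (n - 1))
}

#' Tajima's D
#'
#' D = (pi - S/a1) / sqrt(e1 S + e2 S (S - 1)); negative under an excess of
#' rare alleles.
#'
#' @param S Number of segregating sites (> 0).
#' @param pi_total Total pairwise diversity over the same sites.
#' @param n Number of sampled chromosomes (>= 4 for a stable variance).
#' @return The D statistic, or NA when the variance term is zero.
#' @examples
#' tajimasD(S = 5, pi_total = 16 / 6, n = 4)
#' @export
tajimasD <- function(S, pi_total, n) {
  if (S <= 0) stop("S must be > 0")
  if (n < 4) stop("n must be >= 4")
  cst <- tajimaConstants(n)
  v <- cst$e1 * S + cst$e2 * S * (S - 1)
  if (v <= 0) return(NA_real_)
  (pi_total - S / cst$a1) / sqrt(v)
}

#' Population-genetic summary of a cohort table
#'
#' @param cohort Cohort table with `type` and `carrier_count` columns.
#' @param n Number of sampled chromosomes.
#' @param L Surveyed length in bases (callable bases).
#' @param include_indels Include indel sites in S and pi (default FALSE:
#'   SNVs only).
#' @return Data frame with S, n, L, a1, theta_w_per_site, pi_total, and D.
#' @export
popgenSummary <- function(cohort, n, L, include_indels = FALSE) {
  sub <- if (include_indels) {
    cohort
  } else {
    cohort[cohort$type == "SNV", , drop = FALSE]
  }
  S <- nrow(sub)
  pi_total <- if (S > 0L) pairwisePi(sub$carrier_count, n) else 0
  data.frame(
    S = S, n = n, L = L, a1 = tajimaConstants(n)$a1,
    theta_w_per_site = wattersonTheta(S, n, L),
    pi_total = pi_total,
    D = if (S > 0L && n >= 4L) tajimasD(S, pi_total, n) else NA_real_
  )
}
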