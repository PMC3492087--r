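# Closing statistics: Poisson upper bound on an unobserved mutation
# frequency, Welch's t-test on normalized reporter ratios, and family
# segregation classification for X-linked variants in males.

#' Upper confidence bound on a mutation frequency from k observations in n
#' trials
#'
#' Under a Poisson model for the number of carriers, the bound is the
#' largest per-trial frequency p consistent with observing at most k
#' carriers: for k = 0, p = -ln(1 - confidence) / n; for k > 0 the
#' gamma-quantile generalization applies.  A binomial alternative
#' (1 - (1 - confidence)^(1/n) for k = 0) is available for comparison; both
#' round to the same percent at the study configuration.
#'
#' @param observed Number of observed carriers (default 0).
#' @param n Number of trials (individuals sequenced).
#' @param confidence Confidence level in (0, 1).
#' @param model "poisson" (default) or "binomial" (k = 0 only).
#' @return Frequency upper bound in \[0, 1\].
#' @examples
#' poissonUpperBound(0, 144, 0.99) # ~0.032, i.e. 3% to the nearest percent
#' @export
poissonUpperBound <- function(observed = 0, n, confidence = 0.99,
                              model = c("poisson", "binomial")) {
  model <- match.arg(model)
  if (n < 1) stop("n must be >= 1")
  if (confidence <= 0 || confidence >= 1) {
    stop("confidence must be inside (0, 1)")
  }
  if (observed < 0) stop("observed must be >= 0")
  if (model == "binomial") {
    if (observed != 0) stop("binomial bound implemented for 0 observations")
    return(1 - (1 - confidence)^(1 / n))
  }
  # Poisson rate lambda with P(X <= k) = 1 - confidence at the bound:
  # lambda = qgamma(confidence, k + 1); frequency = lambda / n
  qgamma(confidence, shape = observed + 1) / n
}

#' Normalize luciferase replicates to the co-transfected Renilla signal
#'
#' @param firefly,renilla Paired replicate measurements.
#' @return Numeric ratios firefly / renilla; replicates with non-positive
#'   Renilla signal are dropped with a warning.
#' @examples
#' normalizeLuciferase(c(100, 120), c(50, 60))
#' @export
normalizeLuciferase <- function(firefly, renilla) {
  stopifnot(length(firefly) == length(renilla))
  bad <- !(renilla > 0)
  if (any(bad)) {
    warning(sum(bad), " replicate(s) with non-positive Renilla signal dropped")
  }
  firefly[!bad] / renilla[!bad]
}

#' Welch's two-sample t-test (unequal variances, two-sided)
#'
#' The Welch statistic with Satterthwaite degrees of freedom.  Degenerate
#' zero-variance inputs are resolved before testing: equal constant groups
#' give p = 1, unequal constant groups give p = 0 flagged degenerate.
#'
#' @param x,y Numeric vectors, each with at least 2 values.
#' @return List with `t`, `df`, `p`, and `degenerate`.
#' @examples
#' welchTTest(c(1, 2, 3), c(2, 3, 4))
#' @export
welchTTest <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) {
    stop("each group needs at least 2 values")
  }
  if (var(x) == 0 && var(y) == 0) {
    if (mean(x) == mean(y)) {
      return(list(t = 0, df = NA_real_, p = 1, degenerate = TRUE))
    }
    return(list(
      t = sign(mean(x) - mean(y)) * Inf, df = NA_real_, p = 0,
      degenerate = TRUE
    ))
  }
  fit <- t.test(x, y, var.equal = FALSE, alternative = "two.sided")
  list(
    t = unname(fit$statistic), df = unname(fit$parameter),
    p = fit$p.value, degenerate = FALSE
  )
}

#' Classify the family segregation pattern of an X-linked variant
#'
#' The proband is a carrier by ascertainment.  The variant is de novo iff
#' the mother is typed non-carrier.  It segregates iff every affected
#' sibling is a carrier and every unaffected male sibling is a non-carrier;
#' an unknown genotype among the informative relatives makes the family
#' uninformative, as do untyped relatives or unaffected female siblings
#' (possible heterozygous carriers).
#'
#' @param pedigree Data frame with columns `member` (`proband`, `mother`,
#'   `sibling`), `carrier` (`carrier`, `non_carrier`, `unknown`),
#'   `affected` (logical), and `sex` (`M`/`F`; used for siblings).
#' @return One of `"segregates"`, `"does_not_segregate"`, `"de_novo"`,
#'   `"uninformative"`.
#' @examples
#' ped <- data.frame(
#'   member = c("proband", "mother", "sibling", "sibling"),
#'   carrier = c("carrier", "carrier", "carrier", "non_carrier"),
#'   affected = c(TRUE, FALSE, TRUE, FALSE),
#'   sex = c("M", "F", "M", "M")
#' )
#' classifySegregation(ped)
#' @export
classifySegregation <- function(pedigree) {
  pro <- pedigree[pedigree$member == "proband", , drop = FALSE]
  if (nrow(pro) == 0L || pro$carrier[1L] != "carrier") {
    stop("proband must be present and a carrier")
  }
  mother <- pedigree[pedigree$member == "mother", , drop = FALSE]
  sibs <- pedigree[pedigree$member == "sibling", , drop = FALSE]
  if (nrow(mother) == 0L && nrow(sibs) == 0L) {
    return("uninformative")
  }
  if (nrow(mother) > 0L && mother$carrier[1L] == "non_carrier") {
    return("de_novo")
  }
  informative <- sibs[sibs$affected | sibs$sex == "M", , drop = FALSE]
  # unaffected female siblings can be silent heterozygous carriers
  informative <- informative[informative$affected |
    (!informative$affected & informative$sex == "M"), , drop = FALSE]
  if (nrow(informative) == 0L) {
    return("uninformative")
  }
  if (any(informative$carrier == "unknown")) {
    return("uninformative")
  }
  aff_ok <- all(informative$carrier[informative$affected] == "carrier")
  unaff_ok <- all(informative$carrier[!informative$affected] ==
    "non_carrier")
  if (aff_ok && unaff_ok) "segregates" else "does_not_segregate"
}
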