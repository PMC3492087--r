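#' Simulation configuration for a synthetic hemizygous cohort
#'
#' Holds every tunable of the synthetic-data generator: target geometry,
#' cohort size, sequencing depth and error model, and the composition of the
#' planted variant set.  Defaults describe the study design the package
#' emulates: a ~65 kb X-linked target tiled by long-PCR amplicons, 144
#' hemizygous males, very deep coverage (median 452x), an excess of rare
#' (singleton) variants, and a variant catalog that contains most common but
#' none of the rare alleles.
#'
#' @slot target_length Target length in bases.
#' @slot n_amplicons Number of amplicons tiling the target.
#' @slot n_samples Number of haploid (hemizygous male) samples.
#' @slot mean_depth Expected per-base fold coverage per sample.
#' @slot read_length Read length in bases.
#' @slot fragment_mean,fragment_sd Fragment-size distribution in bases.
#' @slot error_rate Per-base substitution error probability.
#' @slot n_variants Number of variants planted across the cohort.
#' @slot rare_fraction Fraction of variants that are singletons (1 carrier).
#' @slot catalog_fraction Probability that a common variant is present in the
#'   known-variant catalog (rare variants are never in the catalog).
#' @slot conserved_fraction Fraction of rare variants planted at perfectly
#'   conserved sites (PhastCons 1.0).
#' @slot indel_fraction Fraction of variants that are small indels.
#' @slot edge_margin Bases at each target end excluded from variant placement
#'   (primer-proximal sequence is not reliably callable).
#' @slot allow_overlap Permit fragment_mean < 2 * read_length (overlapping
#'   mates).
#' @slot seed Integer seed controlling all randomness of the generator.
#' @export
setClass("SimulationConfig",
  representation(
    target_length = "integer", n_amplicons = "integer",
    n_samples = "integer", mean_depth = "numeric", read_length = "integer",
    fragment_mean = "numeric", fragment_sd = "numeric", error_rate = "numeric",
    n_variants = "integer", rare_fraction = "numeric",
    catalog_fraction = "numeric", conserved_fraction = "numeric",
    indel_fraction = "numeric", edge_margin = "integer",
    allow_overlap = "logical", seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  counts <- c(
    target_length = object@target_length, n_amplicons = object@n_amplicons,
    n_samples = object@n_samples, read_length = object@read_length,
    n_variants = object@n_variants
  )
  if (any(counts <= 0L)) {
    msg <- c(msg, paste("non-positive count:", paste(
      names(counts)[counts <= 0L],
      collapse = ", "
    )))
  }
  if (object@mean_depth <= 0) msg <- c(msg, "mean_depth must be positive")
  probs <- c(
    error_rate = object@error_rate, rare_fraction = object@rare_fraction,
    catalog_fraction = object@catalog_fraction,
    conserved_fraction = object@conserved_fraction,
    indel_fraction = object@indel_fraction
  )
  if (any(probs < 0 | probs > 1)) {
    msg <- c(msg, paste("probability outside [0,1]:", paste(
      names(probs)[probs < 0 | probs > 1],
      collapse = ", "
    )))
  }
  if (object@target_length < object@n_amplicons * 100L) {
    msg <- c(msg, "target_length must be at least 100 bases per amplicon")
  }
  if (!object@allow_overlap &&
    object@fragment_mean < 2 * object@read_length) {
    msg <- c(msg, "fragment_mean < 2*read_length requires allow_overlap")
  }
  if (object@n_variants >= object@target_length / 10) {
    msg <- c(msg, "n_variants must be < target_length / 10")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a [SimulationConfig-class]
#'
#' @param target_length,n_amplicons,n_samples,mean_depth,read_length
#'   Target/cohort geometry; see the class documentation.
#' @param fragment_mean,fragment_sd Fragment-size distribution (bases).
#' @param error_rate Per-base substitution error probability.
#' @param n_variants,rare_fraction,catalog_fraction,conserved_fraction,indel_fraction
#'   Composition of the planted variant set.
#' @param edge_margin Variant-free margin at the target ends (bases).
#' @param allow_overlap Allow overlapping mates.
#' @param seed Integer seed.
#' @return A validated `SimulationConfig`.
#' @examples
#' simulationConfig(target_length = 10000, n_amplicons = 2, n_samples = 40,
#'                  mean_depth = 50, seed = 1)
#' @export
simulationConfig <- function(target_length = 65000, n_amplicons = 13,
                             n_samples = 144, mean_depth = 452,
                             read_length = 100, fragment_mean = 300,
                             fragment_sd = 30, error_rate = 0.003,
                             n_variants = 208, rare_fraction = 0.65,
                             catalog_fraction = 0.9,
                             conserved_fraction = 0.05,
                             indel_fraction = 32 / 208,
                             edge_margin = read_length,
                             allow_overlap = FALSE, seed = 1) {
  new("SimulationConfig",
    target_length = as.integer(target_length),
    n_amplicons = as.integer(n_amplicons),
    n_samples = as.integer(n_samples),
    mean_depth = as.numeric(mean_depth),
    read_length = as.integer(read_length),
    fragment_mean = as.numeric(fragment_mean),
    fragment_sd = as.numeric(fragment_sd),
    error_rate = as.numeric(error_rate),
    n_variants = as.integer(n_variants),
    rare_fraction = as.numeric(rare_fraction),
    catalog_fraction = as.numeric(catalog_fraction),
    conserved_fraction = as.numeric(conserved_fraction),
    indel_fraction = as.numeric(indel_fraction),
    edge_margin = as.integer(edge_margin),
    allow_overlap = as.logical(allow_overlap),
    seed = as.integer(seed)
  )
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig\n")
  cat(sprintf(
    "  target: %d bp in %d amplicons; %d haploid samples at %.0fx\n",
    object@target_length, object@n_amplicons, object@n_samples,
    object@mean_depth
  ))
  cat(sprintf(
    "  reads: %d bp pairs, fragments %.0f+/-%.0f, error %.4g\n",
    object@read_length, object@fragment_mean, object@fragment_sd,
    object@error_rate
  ))
  cat(sprintf(
    "  variants: %d (rare %.2f, catalog %.2f, conserved %.2f, indel %.2f)\n",
    object@n_variants, object@rare_fraction, object@catalog_fraction,
    object@conserved_fraction, object@indel_fraction
  ))
  cat(sprintf("  seed: %d\n", object@seed))
})

#' Alignment scoring scheme
#'
#' Affine-gap local alignment scores; a gap of length g costs
#' `gap_open + (g - 1) * gap_extend`.
#'
#' @slot match Positive score for a matching base.
#' @slot mismatch Negative penalty for a mismatch.
#' @slot gap_open Negative penalty for the first base of a gap.
#' @slot gap_extend Negative penalty for each further gap base.
#' @export
setClass("ScoringScheme",
  representation(
    match = "integer", mismatch = "integer",
    gap_open = "integer", gap_extend = "integer"
  )
)

setValidity("ScoringScheme", function(object) {
  msg <- character()
  if (object@match <= 0L) msg <- c(msg, "match score must be positive")
  if (object@mismatch >= 0L || object@gap_open >= 0L ||
    object@gap_extend >= 0L) {
    msg <- c(msg, "mismatch and gap penalties must be negative")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a [ScoringScheme-class]
#'
#' @param match,mismatch,gap_open,gap_extend Integer scores (penalties
#'   negative).
#' @return A validated `ScoringScheme`.
#' @examples
#' scoringScheme()
#' @export
scoringScheme <- function(match = 1, mismatch = -3, gap_open = -5,
                          gap_extend = -2) {
  new("ScoringScheme",
    match = as.integer(match), mismatch = as.integer(mismatch),
    gap_open = as.integer(gap_open), gap_extend = as.integer(gap_extend)
  )
}

setMethod("show", "ScoringScheme", function(object) {
  cat(sprintf(
    "ScoringScheme(match %+d, mismatch %+d, gap open %+d, gap extend %+d)\n",
    object@match, object@mismatch, object@gap_open, object@gap_extend
  ))
})

#' Hashed k-mer index of a target sequence
#'
#' Maps every k-mer of the target to the sorted list of its 0-based offsets;
#' windows containing ambiguous (non-ACGT) bases are excluded.
#'
#' @slot k Seed length in bases.
#' @slot reference The target sequence (character).
#' @slot table Named list mapping k-mer strings to integer offset vectors.
#' @slot n_stored Total number of stored offsets.
#' @export
setClass("HashIndex",
  representation(
    k = "integer", reference = "character", table = "list",
    n_stored = "integer"
  )
)

setMethod("show", "HashIndex", function(object) {
  cat(sprintf(
    "HashIndex: k=%d over %d bp target; %d keys, %d stored offsets\n",
    object@k, nchar(object@reference), length(object@table), object@n_stored
  ))
})

#' Gene model on the target
#'
#' A single-gene model with ordered exons and a CDS span; UTR and intron
#' intervals are derived.  All coordinates are 1-based inclusive on the
#' target.
#'
#' @slot gene Gene name.
#' @slot strand "+" or "-".
#' @slot exon_starts,exon_ends Ordered, non-overlapping exon intervals.
#' @slot cds_start,cds_end Genomic CDS span (within the exon union).
#' @export
setClass("GeneModel",
  representation(
    gene = "character", strand = "character",
    exon_starts = "integer", exon_ends = "integer",
    cds_start = "integer", cds_end = "integer"
  )
)

setValidity("GeneModel", function(object) {
  msg <- character()
  ne <- length(object@exon_starts)
  if (ne == 0L || length(object@exon_ends) != ne) {
    msg <- c(msg, "exon_starts/exon_ends must be non-empty and equal length")
  } else {
    if (any(object@exon_ends < object@exon_starts)) {
      msg <- c(msg, "exon end before start")
    }
    if (ne > 1L &&
      any(object@exon_starts[-1L] <= object@exon_ends[-ne])) {
      msg <- c(msg, "exons must be ordered and non-overlapping")
    }
  }
  if (!object@strand %in% c("+", "-")) msg <- c(msg, "strand must be + or -")
  cds <- intersectIntervals(
    object@exon_starts, object@exon_ends,
    object@cds_start, object@cds_end
  )
  if (object@cds_start < min(object@exon_starts) ||
    object@cds_end > max(object@exon_ends)) {
    msg <- c(msg, "CDS outside exon span")
  } else if (sum(cds$end - cds$start + 1L) %% 3L != 0L) {
    msg <- c(msg, "CDS length must be divisible by 3")
  }
  if (length(msg)) msg else TRUE
})

# exonic sub-intervals of [lo, hi]; used by validity and the CDS extractor
intersectIntervals <- function(starts, ends, lo, hi) {
  s <- pmax(starts, lo)
  e <- pmin(ends, hi)
  keep <- s <= e
  list(start = s[keep], end = e[keep])
}

#' Construct a [GeneModel-class]
#'
#' @param gene Gene name.
#' @param strand "+" or "-".
#' @param exon_starts,exon_ends 1-based inclusive exon intervals, ordered.
#' @param cds_start,cds_end Genomic CDS span.
#' @return A validated `GeneModel`.
#' @examples
#' geneModel("toy", "+", exon_starts = c(101, 301), exon_ends = c(200, 400),
#'           cds_start = 151, cds_end = 350)
#' @export
geneModel <- function(gene, strand, exon_starts, exon_ends, cds_start,
                      cds_end) {
  new("GeneModel",
    gene = gene, strand = strand,
    exon_starts = as.integer(exon_starts),
    exon_ends = as.integer(exon_ends),
    cds_start = as.integer(cds_start), cds_end = as.integer(cds_end)
  )
}

setMethod("show", "GeneModel", function(object) {
  cat(sprintf(
    "GeneModel %s (%s): %d exon(s) %d-%d, CDS %d-%d\n", object@gene,
    object@strand, length(object@exon_starts), min(object@exon_starts),
    max(object@exon_ends), object@cds_start, object@cds_end
  ))
})

#' Position weight matrix
#'
#' Column-frequency model of a transcription-factor binding motif; scored by
#' log2 odds against a uniform background with an additive pseudocount.
#'
#' @slot name Motif name.
#' @slot matrix 4 x W numeric matrix, rows A, C, G, T; columns sum to 1.
#' @slot pseudocount Additive pseudocount used when scoring.
#' @export
setClass("PWM",
  representation(name = "character", matrix = "matrix",
                 pseudocount = "numeric")
)

setValidity("PWM", function(object) {
  msg <- character()
  m <- object@matrix
  if (nrow(m) != 4L || is.null(rownames(m)) ||
    !identical(rownames(m), c("A", "C", "G", "T"))) {
    msg <- c(msg, "matrix must have rows A, C, G, T")
  }
  if (ncol(m) < 4L) msg <- c(msg, "motif width must be >= 4")
  if (any(abs(colSums(m) - 1) > 1e-6)) {
    msg <- c(msg, "each column must sum to 1 (tolerance 1e-6)")
  }
  if (object@pseudocount < 0) msg <- c(msg, "pseudocount must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a [PWM-class]
#'
#' @param name Motif name.
#' @param matrix 4 x W frequency matrix with rows A, C, G, T.
#' @param pseudocount Additive pseudocount (default 0.01).
#' @return A validated `PWM`.
#' @examples
#' m <- matrix(c(0.97, 0.01, 0.01, 0.01), nrow = 4, ncol = 5,
#'             dimnames = list(c("A", "C", "G", "T"), NULL))
#' pwm("polyA", m)
#' @export
pwm <- function(name, matrix, pseudocount = 0.01) {
  if (is.null(rownames(matrix))) rownames(matrix) <- c("A", "C", "G", "T")
  new("PWM", name = name, matrix = matrix, pseudocount = pseudocount)
}

#' Motif width of a PWM
#' @param x A [PWM-class].
#' @return Integer width.
#' @export
pwmWidth <- function(x) ncol(x@matrix)

#' Consensus sequence of a PWM (most frequent base per column)
#' @param x A [PWM-class].
#' @return Character consensus string.
#' @export
pwmConsensus <- function(x) {
  paste(rownames(x@matrix)[apply(x@matrix, 2L, which.max)], collapse = "")
}

setMethod("show", "PWM", function(object) {
  cat(sprintf(
    "PWM %s: width %d, consensus %s, pseudocount %g\n", object@name,
    pwmWidth(object), pwmConsensus(object), object@pseudocount
  ))
})

#' Background calibration of PWM raw scores
#'
#' Mean and standard deviation of per-region maximum raw scores across a set
#' of background regions; a scanned score s maps to z = (s - mean) / sd, the
#' number of standard deviations above the background mean.
#'
#' @slot pwm_name Name of the calibrated PWM.
#' @slot mean,sd Background mean and SD of per-region maxima.
#' @slot n_regions Number of background regions used.
#' @export
setClass("PWMCalibration",
  representation(
    pwm_name = "character", mean = "numeric", sd = "numeric",
    n_regions = "integer"
  )
)

setValidity("PWMCalibration", function(object) {
  msg <- character()
  if (!is.finite(object@sd) || object@sd <= 0) {
    msg <- c(msg, "calibration sd must be positive")
  }
  if (object@n_regions < 30L) {
    msg <- c(msg, "calibration requires >= 30 background regions")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "PWMCalibration", function(object) {
  cat(sprintf(
    "PWMCalibration %s: mean %.3f, sd %.3f over %d regions\n",
    object@pwm_name, object@mean, object@sd, object@n_regions
  ))
})
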