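# Synthetic cohort generator.  Emulates the statistical structure of a deep
# targeted-resequencing study of hemizygous males: an amplicon-tiled target,
# a site-frequency spectrum dominated by singletons, a variant catalog that
# holds common but not rare alleles, perfectly conserved sites hosting a
# subset of the rare variants, and planted PWM motif instances.

#' Generate a random reference target tiled by amplicons
#'
#' @param config A [SimulationConfig-class].
#' @return List with `sequence` (character) and `amplicons` (data frame with
#'   1-based inclusive `start`, `end`); amplicon intervals tile the target
#'   without gaps.
#' @examples
#' ref <- makeReference(simulationConfig(target_length = 1000,
#'                                       n_amplicons = 2, n_variants = 20,
#'                                       seed = 7))
#' nchar(ref$sequence)
#' @export
makeReference <- function(config) {
  validObject(config)
  set.seed(config@seed)
  L <- config@target_length
  sequence <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
    collapse = ""
  )
  bounds <- round(seq(0L, L, length.out = config@n_amplicons + 1L))
  amplicons <- data.frame(
    amplicon = paste0("amp", seq_len(config@n_amplicons)),
    start = as.integer(bounds[-length(bounds)] + 1L),
    end = as.integer(bounds[-1L])
  )
  list(sequence = sequence, amplicons = amplicons)
}

#' Left-normalize an indel (or pass an SNV through)
#'
#' Trims shared flanking bases and shifts the event as far left as the
#' reference allows, keeping one shared leading reference base (VCF
#' convention).
#'
#' @param pos 1-based position of the first reference base of `ref`.
#' @param ref,alt Allele strings.
#' @param refseq Reference sequence (character).
#' @return List with normalized `pos`, `ref`, `alt`.
#' @export
leftNormalizeVariant <- function(pos, ref, alt, refseq) {
  baseAt <- function(p) substr(refseq, p, p)
  repeat {
    rn <- nchar(ref)
    an <- nchar(alt)
    if (rn > 0L && an > 0L &&
      substr(ref, rn, rn) == substr(alt, an, an) &&
      !(rn == 1L && an == 1L)) {
      ref <- substr(ref, 1L, rn - 1L)
      alt <- substr(alt, 1L, an - 1L)
      if (nchar(ref) == 0L || nchar(alt) == 0L) {
        if (pos == 1L) { # cannot extend left; re-anchor on the right
          p2 <- pos + max(nchar(ref), 0L)
          ref <- paste0(ref, baseAt(p2))
          alt <- paste0(alt, baseAt(p2))
        } else {
          pos <- pos - 1L
          ref <- paste0(baseAt(pos), ref)
          alt <- paste0(baseAt(pos), alt)
        }
      }
      next
    }
    if (rn > 1L && an > 1L && substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
      ref <- substr(ref, 2L, rn)
      alt <- substr(alt, 2L, an)
      pos <- pos + 1L
      next
    }
    break
  }
  list(pos = as.integer(pos), ref = ref, alt = alt)
}

#' Plant cohort variants with known truth
#'
#' Singleton ("rare") variants get exactly one carrier; common variants get a
#' carrier fraction above 5% and enter the known-variant catalog with
#' probability `catalog_fraction`.  A `conserved_fraction` of the rare
#' variants is placed at sites whose PhastCons track value is 1.0.  Variant
#' positions are drawn with a minimum spacing of 10 bases so that no two
#' events collide (the spec's no-silent-overwrite rule is enforced by
#' construction).
#'
#' @param reference Reference sequence (character).
#' @param config A [SimulationConfig-class].
#' @return List with `truth` (one row per variant: pos, ref, alt, type,
#'   carriers, carrier_count, case_freq, in_catalog, catalog_id, conserved,
#'   phastcons, phylop), `catalog` (pos, id, ref, alt), `track` (per-base
#'   conservation), and `haplotypes` (character vector, one per sample).
#' @export
plantVariants <- function(reference, config) {
  validObject(config)
  set.seed(config@seed + 1L)
  L <- nchar(reference)
  n <- config@n_variants
  ns <- config@n_samples
  margin <- max(config@edge_margin, 5L)
  if (n >= L / 10) stop("n_variants must be < target_length / 10")

  pool <- sample(seq.int(margin + 1L, L - margin))
  pos <- integer(0L)
  for (p in pool) {
    if (length(pos) == n) break
    if (!length(pos) || min(abs(pos - p)) >= 10L) pos <- c(pos, p)
  }
  if (length(pos) < n) stop("target too small to place variants")
  pos <- sort(pos)

  n_rare <- round(config@rare_fraction * n)
  is_rare <- seq_len(n) %in% sample(n, n_rare)
  is_indel <- seq_len(n) %in% sample(n, round(config@indel_fraction * n))

  refA <- altA <- character(n)
  type <- ifelse(is_indel, "indel", "SNV")
  for (i in seq_len(n)) {
    p <- pos[i]
    base <- substr(reference, p, p)
    if (!is_indel[i]) {
      refA[i] <- base
      altA[i] <- sample(setdiff(c("A", "C", "G", "T"), base), 1L)
    } else if (runif(1) < 0.5) { # deletion of 1-3 bases after the anchor
      len <- sample(1:3, 1L)
      refA[i] <- substr(reference, p, p + len)
      altA[i] <- base
    } else { # insertion of 1-3 bases after the anchor
      ins <- paste(sample(c("A", "C", "G", "T"), sample(1:3, 1L),
        replace = TRUE
      ), collapse = "")
      refA[i] <- base
      altA[i] <- paste0(base, ins)
    }
    norm <- leftNormalizeVariant(p, refA[i], altA[i], reference)
    pos[i] <- norm$pos
    refA[i] <- norm$ref
    altA[i] <- norm$alt
  }

  carrier_count <- integer(n)
  carriers <- vector("list", n)
  sample_ids <- paste0("S", seq_len(ns))
  for (i in seq_len(n)) {
    if (is_rare[i]) {
      carrier_count[i] <- 1L
    } else {
      f <- runif(1, 0.06, 0.4)
      carrier_count[i] <- max(floor(0.05 * ns) + 1L, round(f * ns))
      carrier_count[i] <- min(carrier_count[i], ns - 1L)
    }
    carriers[[i]] <- sort(sample(ns, carrier_count[i]))
  }

  in_catalog <- !is_rare & runif(n) < config@catalog_fraction
  catalog_id <- ifelse(in_catalog,
    sprintf("rs%06d", seq_len(n) + 100000L), "."
  )

  conserved <- rep(FALSE, n)
  rare_idx <- which(is_rare)
  n_cons <- round(config@conserved_fraction * length(rare_idx))
  if (n_cons > 0L) conserved[sample(rare_idx, n_cons)] <- TRUE

  track <- data.frame(
    pos = seq_len(L),
    phastcons = round(runif(L, 0, 0.5), 3L),
    phylop = round(rnorm(L), 3L)
  )
  span_cons <- character(n)
  span_phylop <- character(n)
  for (i in seq_len(n)) {
    span <- pos[i]:(pos[i] + nchar(refA[i]) - 1L)
    if (conserved[i]) {
      track$phastcons[span] <- 1.0
      track$phylop[span] <- round(runif(length(span), 1.5, 2.5), 2L)
    }
    span_cons[i] <- paste(track$phastcons[span], collapse = "/")
    span_phylop[i] <- paste(track$phylop[span], collapse = "/")
  }

  truth <- data.frame(
    pos = pos, ref = refA, alt = altA, type = type,
    carriers = vapply(carriers, function(x) {
      paste(sample_ids[x], collapse = ",")
    }, character(1L)),
    carrier_count = carrier_count,
    case_freq = carrier_count / ns,
    in_catalog = in_catalog, catalog_id = catalog_id,
    conserved = conserved, phastcons = span_cons, phylop = span_phylop,
    stringsAsFactors = FALSE
  )

  catalog <- data.frame(
    pos = pos[in_catalog], id = catalog_id[in_catalog],
    ref = refA[in_catalog], alt = altA[in_catalog],
    stringsAsFactors = FALSE
  )

  haplotypes <- vapply(seq_len(ns), function(s) {
    hap <- reference
    mine <- which(vapply(carriers, function(x) s %in% x, logical(1L)))
    for (i in rev(mine)) { # descending position: edits do not shift later ones
      p <- pos[i]
      hap <- paste0(
        substr(hap, 1L, p - 1L), altA[i],
        substr(hap, p + nchar(refA[i]), nchar(hap))
      )
    }
    hap
  }, character(1L))

  list(
    truth = truth, catalog = catalog, track = track,
    haplotypes = setNames(haplotypes, sample_ids)
  )
}

# vectorized uniform substitution errors at `rate` per base
addSubstErrors <- function(reads, rate) {
  if (rate <= 0) return(reads)
  nerr <- rbinom(length(reads), nchar(reads), rate)
  for (i in which(nerr > 0L)) {
    r <- strsplit(reads[i], "")[[1L]]
    at <- sample(length(r), nerr[i])
    for (j in at) r[j] <- sample(setdiff(c("A", "C", "G", "T"), r[j]), 1L)
    reads[i] <- paste(r, collapse = "")
  }
  reads
}

#' Simulate paired-end reads from one haplotype
#'
#' Fragments are placed uniformly along the haplotype (Poisson per-base depth
#' emerges); mates are forward/reverse reads off the fragment ends; errors
#' are uniform substitutions at `error_rate`.  Read names encode the true
#' 0-based origin of each mate (`sample:fragment:start1:start2[:trunc]`), so
#' simulated placements can be checked against truth.
#'
#' @param haplotype Haplotype sequence (character).
#' @param config A [SimulationConfig-class].
#' @param sample_id Sample name embedded in read names.
#' @param seed Seed for this sample's reads (defaults to the config seed).
#' @return List with `read1`, `read2` (character vectors) and `names`.
#' @export
simulateReads <- function(haplotype, config, sample_id = "S1", seed = NULL) {
  validObject(config)
  if (is.null(seed)) seed <- config@seed + 1000L
  set.seed(seed)
  L <- nchar(haplotype)
  rl <- config@read_length
  if (L <= config@fragment_mean + 4 * config@fragment_sd) {
    stop("haplotype shorter than fragment_mean + 4*fragment_sd")
  }
  nfrag <- max(1L, round(config@mean_depth * L / (2 * rl)))
  fl <- round(rnorm(nfrag, config@fragment_mean, config@fragment_sd))
  trunc <- fl < rl
  fl <- pmin(pmax(fl, rl), L)
  start <- 1L + floor(runif(nfrag) * (L - fl + 1))
  frag <- substring(haplotype, start, start + fl - 1L)
  read1 <- substring(frag, 1L, rl)
  read2 <- as.character(cpp_revcomp(substring(frag, fl - rl + 1L, fl)))
  read1 <- addSubstErrors(read1, config@error_rate)
  read2 <- addSubstErrors(read2, config@error_rate)
  names <- sprintf(
    "%s:%d:%d:%d%s", sample_id, seq_len(nfrag), start - 1L,
    start + fl - rl - 1L, ifelse(trunc, ":trunc", "")
  )
  list(read1 = read1, read2 = read2, names = names)
}

#' Generate a PWM set and plant consensus instances in a reference
#'
#' Each motif is a column-frequency matrix with a dominant consensus base per
#' column; one exact consensus instance per motif is written into the
#' reference at a recorded position.
#'
#' @param n_motifs Number of motifs.
#' @param widths Motif widths (recycled); all must be >= 4.
#' @param seed Integer seed.
#' @param reference Optional reference to plant consensus instances into.
#' @param consensus_weight Frequency of the consensus base per column.
#' @return List with `pwms` (named list of [PWM-class]), `reference`
#'   (modified, or NULL), and `planted` (data frame: name, start 1-based,
#'   end).
#' @export
makePwmSet <- function(n_motifs = 3, widths = c(12, 14, 15), seed = 1,
                       reference = NULL, consensus_weight = 0.85) {
  if (any(widths < 4)) stop("motif widths must be >= 4")
  set.seed(seed)
  widths <- rep_len(as.integer(widths), n_motifs)
  bases <- c("A", "C", "G", "T")
  pwms <- list()
  planted <- data.frame(
    name = character(), start = integer(), end = integer(),
    stringsAsFactors = FALSE
  )
  used <- integer(0L)
  for (i in seq_len(n_motifs)) {
    w <- widths[i]
    cons <- sample(bases, w, replace = TRUE)
    m <- matrix((1 - consensus_weight) / 3, nrow = 4L, ncol = w,
      dimnames = list(bases, NULL)
    )
    for (j in seq_len(w)) m[cons[j], j] <- consensus_weight
    name <- sprintf("motif%02d", i)
    pwms[[name]] <- pwm(name, m)
    if (!is.null(reference)) {
      L <- nchar(reference)
      repeat {
        p <- sample.int(L - w + 1L, 1L)
        if (!length(used) || min(abs(used - p)) > 2L * max(widths)) break
      }
      used <- c(used, p)
      reference <- paste0(
        substr(reference, 1L, p - 1L), paste(cons, collapse = ""),
        substr(reference, p + w, L)
      )
      planted <- rbind(planted, data.frame(
        name = name, start = p,
        end = p + w - 1L
      ))
    }
  }
  list(pwms = pwms, reference = reference, planted = planted)
}

#' Generate random background regions for PWM calibration
#'
#' @param n_regions Number of regions.
#' @param width Region width in bases.
#' @param seed Integer seed.
#' @return Named character vector of region sequences.
#' @export
makeBackgroundRegions <- function(n_regions = 200, width = 400, seed = 1) {
  set.seed(seed)
  regions <- vapply(seq_len(n_regions), function(i) {
    paste(sample(c("A", "C", "G", "T"), width, replace = TRUE),
      collapse = ""
    )
  }, character(1L))
  setNames(regions, paste0("bg", seq_len(n_regions)))
}

# synthetic single-gene model on the plus strand with 2 exons, UTRs and a
# frame-complete CDS, scaled to the target length
syntheticGeneModel <- function(target_length) {
  L <- target_length
  a1 <- max(101L, round(0.15 * L))
  b1 <- a1 + max(299L, round(0.008 * L))
  a2 <- b1 + max(501L, round(0.01 * L))
  b2 <- a2 + max(399L, round(0.009 * L))
  cds_start <- a1 + 100L
  cds_end <- a2 + 200L
  len <- (b1 - cds_start + 1L) + (cds_end - a2 + 1L)
  cds_end <- cds_end - (len %% 3L)
  geneModel("GENE1", "+",
    exon_starts = c(a1, a2), exon_ends = c(b1, b2),
    cds_start = cds_start, cds_end = cds_end
  )
}

#' Simulate a complete synthetic cohort and write every pipeline input
#'
#' Produces, under `outdir`: the reference FASTA and amplicon BED, per-sample
#' paired FASTQ files, the truth table, the known-variant catalog VCF, the
#' two-score conservation track, a synthetic gene model, regulatory feature
#' BED tracks, the PWM set with planted-instance truth, background regions
#' for calibration, and a synthetic control-panel genotype table.
#'
#' @param config A [SimulationConfig-class].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with the `config`, generated `reference`,
#'   `truth`, `pwms`, `planted` motif truth, and a named list of `paths`.
#' @export
simulateCohort <- function(config, outdir) {
  validObject(config)
  dir.create(file.path(outdir, "reads"), recursive = TRUE,
    showWarnings = FALSE
  )
  ref <- makeReference(config)
  pw <- makePwmSet(
    n_motifs = 3, widths = c(12, 14, 15), seed = config@seed + 2L,
    reference = ref$sequence
  )
  ref$sequence <- pw$reference
  planted <- plantVariants(ref$sequence, config)

  paths <- list(
    reference = file.path(outdir, "reference.fasta"),
    amplicons = file.path(outdir, "amplicons.bed"),
    truth = file.path(outdir, "truth.tsv"),
    catalog = file.path(outdir, "catalog.vcf"),
    conservation = file.path(outdir, "conservation.tsv"),
    genes = file.path(outdir, "genes.tsv"),
    features = c(
      h3k4me1 = file.path(outdir, "h3k4me1.bed"),
      nas = file.path(outdir, "nas.bed")
    ),
    pwms = file.path(outdir, "pwms.txt"),
    pwm_truth = file.path(outdir, "pwm_truth.tsv"),
    background = file.path(outdir, "background.fasta"),
    controls = file.path(outdir, "controls.tsv"),
    reads = file.path(outdir, "reads")
  )

  writeReference(ref$sequence, paths$reference)
  writeBed(ref$amplicons$start, ref$amplicons$end, paths$amplicons,
    names = ref$amplicons$amplicon
  )
  writeTsv(planted$truth, paths$truth)
  writeVcf(planted$catalog, paths$catalog)
  writeConservationTrack(planted$track, paths$conservation)
  writeGeneModel(syntheticGeneModel(config@target_length), paths$genes)

  # feature tracks: windows around a subset of conserved variants plus noise
  set.seed(config@seed + 3L)
  consPos <- planted$truth$pos[planted$truth$conserved]
  for (tn in names(paths$features)) {
    centers <- c(
      consPos,
      sample.int(config@target_length, max(3L, length(consPos)))
    )
    centers <- sort(sample(centers, max(1L, round(0.7 * length(centers)))))
    starts <- pmax(1L, centers - sample(30:120, length(centers),
      replace = TRUE
    ))
    ends <- pmin(config@target_length, centers + sample(
      30:120,
      length(centers),
      replace = TRUE
    ))
    keep <- !duplicated(starts)
    writeBed(starts[keep], ends[keep], paths$features[[tn]],
      names = paste0(tn, seq_len(sum(keep)))
    )
  }

  writePwms(pw$pwms, paths$pwms)
  writeTsv(pw$planted, paths$pwm_truth)
  bg <- makeBackgroundRegions(
    n_regions = 200, width = 400,
    seed = config@seed + 4L
  )
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(bg),
    paths$background
  )

  # synthetic control panel: catalog variants at comparable frequencies,
  # rare case variants absent
  m <- 1440L
  tr <- planted$truth
  controls <- data.frame(
    pos = tr$pos, ref = tr$ref, alt = tr$alt,
    carrier_count = ifelse(tr$in_catalog,
      pmax(0L, round(tr$case_freq * m * runif(nrow(tr), 0.5, 1.5))), 0L
    ),
    n = m, stringsAsFactors = FALSE
  )
  writeTsv(controls, paths$controls)

  for (s in names(planted$haplotypes)) {
    rd <- simulateReads(planted$haplotypes[[s]], config,
      sample_id = s,
      seed = config@seed + 1000L + match(s, names(planted$haplotypes))
    )
    writeFastqPair(rd$read1, rd$read2, rd$names,
      prefix = file.path(paths$reads, s)
    )
  }

  invisible(list(
    config = config, reference = ref$sequence,
    amplicons = ref$amplicons, truth = planted$truth,
    catalog = planted$catalog, track = planted$track,
    haplotypes = planted$haplotypes, pwms = pw$pwms,
    planted_motifs = pw$planted, paths = paths
  ))
}
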