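# Functional annotation of cohort variants: gene-model class, amino-acid
# change, catalog membership, conservation lookup, and regulatory feature
# overlap.  Gene-model and variant coordinates are 1-based inclusive; BED
# features come in 0-based half-open and are converted at the I/O layer.

# ordered genomic positions of the coding sequence (5'->3' on the genome)
cdsPositions <- function(model) {
  cds <- intersectIntervals(
    model@exon_starts, model@exon_ends,
    model@cds_start, model@cds_end
  )
  unlist(lapply(seq_along(cds$start), function(i) {
    seq.int(cds$start[i], cds$end[i])
  }))
}

#' Classify a position against gene models
#'
#' Precedence: coding > UTR > intron > intergenic; UTR sidedness respects
#' the gene strand (the 5' UTR of a minus-strand gene lies at higher
#' coordinates than its CDS).
#'
#' @param position 1-based position.
#' @param models List of [GeneModel-class] objects.
#' @param target_length Target length, used to reject out-of-range positions.
#' @return One of `"coding"`, `"5'UTR"`, `"3'UTR"`, `"intron"`,
#'   `"intergenic"`, plus attribute `gene` when inside a gene.
#' @export
classifySite <- function(position, models, target_length = NULL) {
  if (position < 1L ||
    (!is.null(target_length) && position > target_length)) {
    stop("position outside target")
  }
  for (model in models) {
    lo <- min(model@exon_starts)
    hi <- max(model@exon_ends)
    if (position < lo || position > hi) next
    in_exon <- any(position >= model@exon_starts &
      position <= model@exon_ends)
    cls <- if (!in_exon) {
      "intron"
    } else if (position >= model@cds_start && position <= model@cds_end) {
      "coding"
    } else if (position < model@cds_start) {
      if (model@strand == "+") "5'UTR" else "3'UTR"
    } else {
      if (model@strand == "+") "3'UTR" else "5'UTR"
    }
    attr(cls, "gene") <- model@gene
    return(cls)
  }
  "intergenic"
}

#' Amino-acid change of a coding SNV
#'
#' Translates the affected codon before and after substitution using the
#' standard genetic code; minus-strand genes are handled by
#' reverse-complementing the coding sequence.  Coding indels are labelled
#' frameshift or in-frame without an amino-acid pair.
#'
#' @param pos 1-based variant position.
#' @param ref,alt Allele strings.
#' @param model A [GeneModel-class] whose CDS contains `pos`.
#' @param reference Target sequence.
#' @return For a synonymous SNV, list with `class = "coding-synonymous"` and
#'   `aa_change = NA`; for missense/nonsense, `class` of
#'   `"coding-missense"`/`"coding-nonsense"` and `aa_change` like `"M1T"`;
#'   for indels, `class` of `"coding-frameshift"`/`"coding-inframe"`.
#' @export
aaChange <- function(pos, ref, alt, model, reference) {
  if (nchar(ref) != 1L || nchar(alt) != 1L) {
    shift <- abs(nchar(ref) - nchar(alt))
    cls <- if (shift %% 3L == 0L) "coding-inframe" else "coding-frameshift"
    return(list(class = cls, aa_change = NA_character_))
  }
  gpos <- cdsPositions(model)
  if (!(pos %in% gpos)) stop("variant is not inside the CDS")
  cds_ref <- paste(strsplit(reference, "")[[1L]][gpos], collapse = "")
  i <- match(pos, gpos)
  cds_alt <- cds_ref
  substr(cds_alt, i, i) <- alt
  if (model@strand == "-") {
    cds_ref <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(cds_ref)
    ))
    cds_alt <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(cds_alt)
    ))
    i <- nchar(cds_ref) - i + 1L
  }
  codon_no <- (i - 1L) %/% 3L + 1L
  cfrom <- substr(cds_ref, (codon_no - 1L) * 3L + 1L, codon_no * 3L)
  cto <- substr(cds_alt, (codon_no - 1L) * 3L + 1L, codon_no * 3L)
  aa_from <- as.character(Biostrings::translate(Biostrings::DNAString(cfrom)))
  aa_to <- as.character(Biostrings::translate(Biostrings::DNAString(cto)))
  if (aa_from == aa_to) {
    list(class = "coding-synonymous", aa_change = NA_character_)
  } else if (aa_to == "*") {
    list(
      class = "coding-nonsense",
      aa_change = paste0(aa_from, codon_no, aa_to)
    )
  } else {
    list(
      class = "coding-missense",
      aa_change = paste0(aa_from, codon_no, aa_to)
    )
  }
}

#' Look up conservation scores over a position span
#'
#' @param start 1-based first position.
#' @param width Span width in bases (1 for an SNV).
#' @param track Conservation data frame (`pos`, `phastcons`, `phylop`).
#' @return List with per-base numeric vectors `phastcons`, `phylop`, and
#'   `missing` (TRUE where the track does not cover the base; scores default
#'   to 0 there).
#' @export
lookupConservation <- function(start, width, track) {
  span <- seq.int(start, start + width - 1L)
  i <- match(span, track$pos)
  missing <- is.na(i)
  phast <- ifelse(missing, 0, track$phastcons[i])
  phylo <- ifelse(missing, 0, track$phylop[i])
  list(phastcons = phast, phylop = phylo, missing = missing)
}

#' Allele-aware catalog membership
#'
#' A variant matches a catalog entry only when position, ref, and alt all
#' agree after left-normalization; catalogs are checked in order and the
#' first hit is reported.  This is stricter than position-only matching and
#' avoids classifying a novel allele at a known position as known.
#'
#' @param pos,ref,alt The variant (already left-normalized).
#' @param catalogs A catalog data frame (`pos`, `id`, `ref`, `alt`) or a
#'   list of them, checked in order.
#' @return List with `known` (logical) and `id` (catalog id or NA).
#' @export
catalogMembership <- function(pos, ref, alt, catalogs) {
  if (is.data.frame(catalogs)) catalogs <- list(catalogs)
  for (cat in catalogs) {
    hit <- which(cat$pos == pos & cat$ref == ref & cat$alt == alt)
    if (length(hit)) {
      return(list(known = TRUE, id = cat$id[hit[1L]]))
    }
  }
  list(known = FALSE, id = NA_character_)
}

#' Feature-track overlap of a variant's reference span
#'
#' @param pos 1-based variant position.
#' @param ref_width Width of the reference span (1 for SNV/insertion).
#' @param feature_tracks Named list of `GRanges` (as from
#'   [readFeatureBed()]).
#' @return Character vector of track names with a nonempty intersection.
#' @export
overlapFeatures <- function(pos, ref_width, feature_tracks) {
  q <- GenomicRanges::GRanges(
    "target",
    IRanges::IRanges(start = pos, width = ref_width)
  )
  hits <- vapply(feature_tracks, function(gr) {
    GenomicRanges::seqnames(q) <- GenomicRanges::seqnames(gr)[1L]
    length(GenomicRanges::findOverlaps(q, gr,
      ignore.strand = TRUE
    )) > 0L
  }, logical(1L))
  names(feature_tracks)[hits]
}

#' Annotate a cohort variant table
#'
#' Attaches, per variant: functional class (with amino-acid change for
#' coding SNVs), allele-aware catalog membership, per-base conservation
#' (PhastCons summarized as the per-base maximum, PhyloP as a `/`-joined
#' per-base list), control-panel frequency when a panel is supplied, and the
#' names of overlapping regulatory feature tracks.
#'
#' @param cohort Cohort table from [mergeCohort()].
#' @param models List of [GeneModel-class] objects.
#' @param catalogs Catalog data frame or list of them.
#' @param track Conservation track data frame.
#' @param reference Target sequence.
#' @param feature_tracks Named list of feature `GRanges` (optional).
#' @param controls Optional control panel data frame (`pos`, `ref`, `alt`,
#'   `carrier_count`, `n`).
#' @return The cohort table with columns `class`, `gene`, `aa_change`,
#'   `known`, `catalog_id`, `phastcons` (max per-base), `phastcons_bases`,
#'   `phylop`, `cons_missing`, `control_freq`, `features` added.
#' @export
annotateCohort <- function(cohort, models, catalogs, track, reference,
                           feature_tracks = list(), controls = NULL) {
  n <- nrow(cohort)
  cls <- gene <- aa <- id <- feat <- rep(NA_character_, n)
  known <- logical(n)
  phast <- rep(NA_real_, n)
  phast_bases <- phylo <- rep(NA_character_, n)
  missing <- logical(n)
  ctrl <- rep(NA_real_, n)
  L <- nchar(reference)
  for (i in seq_len(n)) {
    p <- cohort$pos[i]
    c0 <- classifySite(p, models, target_length = L)
    gene[i] <- if (!is.null(attr(c0, "gene"))) attr(c0, "gene") else NA
    if (c0 == "coding") {
      model <- models[[which(vapply(models, function(m) {
        identical(m@gene, gene[i])
      }, logical(1L)))[1L]]]
      ac <- if (cohort$type[i] == "SNV") {
        aaChange(p, cohort$ref[i], cohort$alt[i], model, reference)
      } else {
        aaChange(p, cohort$ref[i], cohort$alt[i], model, reference)
      }
      cls[i] <- ac$class
      aa[i] <- ac$aa_change
    } else {
      cls[i] <- as.character(c0)
    }
    km <- catalogMembership(p, cohort$ref[i], cohort$alt[i], catalogs)
    known[i] <- km$known
    id[i] <- km$id
    w <- nchar(cohort$ref[i])
    cons <- lookupConservation(p, w, track)
    phast[i] <- if (all(cons$missing)) NA_real_ else max(cons$phastcons)
    phast_bases[i] <- paste(cons$phastcons, collapse = "/")
    phylo[i] <- paste(cons$phylop, collapse = "/")
    missing[i] <- any(cons$missing)
    if (!is.null(controls)) {
      hit <- which(controls$pos == p & controls$ref == cohort$ref[i] &
        controls$alt == cohort$alt[i])
      if (length(hit)) {
        ctrl[i] <- controls$carrier_count[hit[1L]] / controls$n[hit[1L]]
      }
    }
    feat[i] <- paste(overlapFeatures(p, w, feature_tracks), collapse = ",")
  }
  out <- cohort
  out$class <- cls
  out$gene <- gene
  out$aa_change <- aa
  out$known <- known
  out$catalog_id <- id
  out$phastcons <- phast
  out$phastcons_bases <- phast_bases
  out$phylop <- phylo
  out$cons_missing <- missing
  out$control_freq <- ctrl
  out$features <- feat
  out
}
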