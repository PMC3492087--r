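# Centralized readers/writers.  Conventions: FASTA/FASTQ through Biostrings,
# catalog VCF through vcfR, feature BED through rtracklayer.  BED inputs are
# 0-based half-open; everything emitted by this package (VCF, cohort/annotated
# tables, gene models, conservation track) is 1-based inclusive.

#' Read a single-sequence reference FASTA
#' @param path FASTA file.
#' @return Named character scalar (name = sequence id).
#' @export
readReference <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) != 1L) stop("reference FASTA must contain exactly one sequence")
  setNames(as.character(x[[1L]]), names(x)[1L])
}

#' Write a reference FASTA
#' @param sequence Character sequence.
#' @param path Output file.
#' @param name Sequence id.
#' @return `path`, invisibly.
#' @export
writeReference <- function(sequence, path, name = "target") {
  x <- Biostrings::DNAStringSet(setNames(sequence, name))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write paired reads as two FASTQ files
#'
#' Qualities are constant Q30 ("?"); the callers in this package do not use
#' base qualities.
#'
#' @param reads1,reads2 Character vectors of mate sequences.
#' @param names Read names (without the /1 /2 suffix).
#' @param prefix Output path prefix; files are `<prefix>_1.fastq` and
#'   `<prefix>_2.fastq`.
#' @return Character vector of the two paths, invisibly.
#' @export
writeFastqPair <- function(reads1, reads2, names, prefix) {
  paths <- paste0(prefix, c("_1.fastq", "_2.fastq"))
  for (m in 1:2) {
    reads <- if (m == 1L) reads1 else reads2
    qual <- vapply(nchar(reads), function(n) {
      strrep("?", n)
    }, character(1L))
    rec <- as.vector(rbind(paste0("@", names, "/", m), reads, "+", qual))
    writeLines(rec, paths[m])
  }
  invisible(paths)
}

#' Read a FASTQ file (sequences and names only)
#' @param path FASTQ file.
#' @return Named character vector of read sequences.
#' @export
readFastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write a variant catalog or per-sample calls as minimal VCF
#'
#' @param df Data frame with columns `pos`, `id`, `ref`, `alt`; optional
#'   `info` column.
#' @param path Output file.
#' @param chrom Chromosome/target name.
#' @return `path`, invisibly.
#' @export
writeVcf <- function(df, path, chrom = "target") {
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", chrom),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Non-reference fraction\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
      sep = "\t"
    )
  )
  info <- if ("info" %in% names(df)) df$info else rep(".", nrow(df))
  id <- if ("id" %in% names(df)) df$id else rep(".", nrow(df))
  body <- if (nrow(df)) {
    paste(chrom, df$pos, id, df$ref, df$alt, ".", ".", info, sep = "\t")
  } else {
    character()
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a variant catalog VCF
#' @param path VCF file.
#' @return Data frame with columns `pos`, `id`, `ref`, `alt`.
#' @export
readCatalogVcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    return(data.frame(
      pos = integer(), id = character(), ref = character(),
      alt = character(), stringsAsFactors = FALSE
    ))
  }
  data.frame(
    pos = as.integer(fix$POS), id = fix$ID, ref = fix$REF, alt = fix$ALT,
    stringsAsFactors = FALSE
  )
}

#' Write / read the two-score per-base conservation track
#'
#' The track is bedGraph-like with two score columns: chrom, start (0-based),
#' end (half-open), PhastCons, PhyloP, one row per base.
#'
#' @param track Data frame with columns `pos` (1-based), `phastcons`,
#'   `phylop`.
#' @param path File path.
#' @param chrom Chromosome/target name.
#' @return `path` (writer) or the track data frame (reader).
#' @export
writeConservationTrack <- function(track, path, chrom = "target") {
  out <- data.frame(
    chrom = chrom, start = track$pos - 1L, end = track$pos,
    phastcons = track$phastcons, phylop = track$phylop
  )
  write.table(out, path,
    sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE
  )
  invisible(path)
}

#' @rdname writeConservationTrack
#' @export
readConservationTrack <- function(path) {
  raw <- tryCatch(
    read.table(path,
      sep = "\t", stringsAsFactors = FALSE,
      col.names = c("chrom", "start", "end", "phastcons", "phylop")
    ),
    error = function(e) stop("malformed conservation track: ", conditionMessage(e))
  )
  if (any(!is.finite(raw$phastcons)) || any(!is.finite(raw$phylop))) {
    bad <- which(!is.finite(raw$phastcons) | !is.finite(raw$phylop))[1L]
    stop("malformed conservation track at line ", bad)
  }
  data.frame(
    pos = raw$end, phastcons = raw$phastcons, phylop = raw$phylop,
    stringsAsFactors = FALSE
  )
}

#' Read a BED feature track as genomic ranges
#'
#' BED is 0-based half-open; the returned GRanges is 1-based inclusive as
#' usual for Bioconductor ranges.
#'
#' @param path BED file.
#' @param track_name Name attached to the track (defaults to the file stem).
#' @return A `GRanges` with metadata column `track`.
#' @export
readFeatureBed <- function(path, track_name = NULL) {
  if (is.null(track_name)) {
    track_name <- sub("\\.bed$", "", basename(path))
  }
  gr <- rtracklayer::import(path, format = "bed")
  gr <- GenomicRanges::sort(gr)
  S4Vectors::mcols(gr)$track <- track_name
  gr
}

#' Write intervals as BED (0-based half-open)
#' @param starts,ends 1-based inclusive interval coordinates.
#' @param path Output file.
#' @param chrom Chromosome/target name.
#' @param names Optional interval names.
#' @return `path`, invisibly.
#' @export
writeBed <- function(starts, ends, path, chrom = "target", names = NULL) {
  if (is.null(names)) names <- paste0("feature", seq_along(starts))
  df <- data.frame(chrom = chrom, start = starts - 1L, end = ends,
                   name = names)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write / read a gene model as a BED12-like TSV
#'
#' Columns: gene, strand, exon_starts, exon_ends (comma-joined, 1-based
#' inclusive), cds_start, cds_end.
#'
#' @param model A [GeneModel-class] (writer) or file path (reader).
#' @param path File path.
#' @return `path` (writer) or a list of `GeneModel` (reader).
#' @export
writeGeneModel <- function(model, path) {
  df <- data.frame(
    gene = model@gene, strand = model@strand,
    exon_starts = paste(model@exon_starts, collapse = ","),
    exon_ends = paste(model@exon_ends, collapse = ","),
    cds_start = model@cds_start, cds_end = model@cds_end
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeGeneModel
#' @export
readGeneModels <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    geneModel(
      gene = df$gene[i], strand = df$strand[i],
      exon_starts = as.integer(strsplit(df$exon_starts[i], ",")[[1L]]),
      exon_ends = as.integer(strsplit(df$exon_ends[i], ",")[[1L]]),
      cds_start = df$cds_start[i], cds_end = df$cds_end[i]
    )
  })
}

#' Write / read PWM files
#'
#' Format per motif: a `>name` line, then four tab-separated rows of column
#' frequencies in row order A, C, G, T.  Several motifs may share one file.
#'
#' @param pwms List of [PWM-class] objects (writer) or file path (reader).
#' @param path File path.
#' @param pseudocount Pseudocount attached to read matrices.
#' @return `path` (writer) or a named list of `PWM` (reader).
#' @export
writePwms <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(paste0(">", p@name), con)
    for (r in 1:4) {
      writeLines(paste(format(p@matrix[r, ], digits = 10), collapse = "\t"),
        con
      )
    }
  }
  invisible(path)
}

#' @rdname writePwms
#' @export
readPwms <- function(path, pseudocount = 0.01) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  out <- list()
  for (h in heads) {
    name <- sub("^>", "", lines[h])
    rows <- lapply(lines[h + 1:4], function(l) {
      as.numeric(strsplit(l, "\t")[[1L]])
    })
    m <- do.call(rbind, rows)
    rownames(m) <- c("A", "C", "G", "T")
    out[[name]] <- pwm(name, m, pseudocount = pseudocount)
  }
  out
}

#' Write / read read placements as a SAM-like TSV
#'
#' Columns: read, mate, mapped, pos (1-based leftmost aligned base), strand,
#' score, cigar, seq (forward-oriented), concordant.
#'
#' @param placements Placement data frame from [mapReads()].
#' @param path File path.
#' @return `path` (writer) or the placement data frame (reader).
#' @export
writePlacements <- function(placements, path) {
  write.table(placements, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePlacements
#' @export
readPlacements <- function(path) {
  read.table(path,
    sep = "\t", header = TRUE, stringsAsFactors = FALSE,
    colClasses = list(character = c("strand", "cigar", "seq"))
  )
}

#' Write a generic TSV table
#' @param df Data frame.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a generic TSV table
#' @param path File path.
#' @return Data frame.
#' @export
readTsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
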