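# Paired-end mapping: hashed k-mer index -> candidate locations -> local
# Smith-Waterman at each candidate -> concordant pair selection.  The heavy
# lifting is compiled; these wrappers define the module surface.

#' Build a hashed k-mer index of the target
#'
#' @param reference Target sequence (character).
#' @param k Seed length, 4 <= k <= 32 (default 16; short seeds are only
#'   useful for toy targets).
#' @return A [HashIndex-class].
#' @examples
#' idx <- buildIndex("ACGTACGT", k = 4)
#' indexLookup(idx, "ACGT")
#' @export
buildIndex <- function(reference, k = 16) {
  if (!nzchar(reference)) stop("reference must be non-empty")
  if (k < 4 || k > 32) stop("k must be between 4 and 32")
  if (k > nchar(reference)) stop("k exceeds target length")
  res <- cpp_index_table(reference, as.integer(k))
  new("HashIndex",
    k = as.integer(k), reference = reference, table = res$table,
    n_stored = as.integer(res$n_stored)
  )
}

#' Look up a k-mer in a [HashIndex-class]
#' @param index A `HashIndex`.
#' @param kmer Query k-mer (length must equal `index@k`).
#' @return Integer vector of 0-based target offsets (possibly empty).
#' @export
indexLookup <- function(index, kmer) {
  if (nchar(kmer) != index@k) stop("kmer length must equal index k")
  hit <- index@table[[kmer]]
  if (is.null(hit)) integer(0L) else hit
}

#' Candidate mapping locations for a read
#'
#' Seeds are sampled every `k/2` bases (plus the final window) on both
#' strands; each seed hit votes for the implied read start offset.
#' Candidates are deduplicated and capped at `max_candidates` per strand by
#' seed-hit count.
#'
#' @param read Read sequence.
#' @param index A [HashIndex-class].
#' @param max_candidates Cap per strand.
#' @return Data frame with 0-based `offset`, `hits`, `strand`; zero rows
#'   signal an unmapped read.
#' @export
candidateLocations <- function(read, index, max_candidates = 8) {
  if (nchar(read) < index@k) stop("read shorter than seed length k")
  cpp_candidates(
    index@reference, index@k, max(1L, index@k %/% 2L), read,
    as.integer(max_candidates)
  )
}

#' Local Smith-Waterman alignment with affine gaps
#'
#' Full (unbanded) dynamic programming over read x window; a gap of length g
#' costs `gap_open + (g - 1) * gap_extend`.  Deterministic tie handling:
#' the first maximal cell in row-major order ends the alignment and traceback
#' prefers diagonal moves, so ties resolve to the leftmost start with the
#' fewest gaps.
#'
#' @param read Read sequence (non-empty).
#' @param window Target window (non-empty).
#' @param scoring A [ScoringScheme-class].
#' @return List with `score`, `target_start` (0-based), `target_end`
#'   (half-open), `query_start`, `query_end`, `cigar` (run-length ops over
#'   `=XIDS`), `n_gaps`.
#' @examples
#' smithWaterman("ACGTACGTACGTACGTACGT", "ACGTACGTACGTACGTACGT")$score
#' @export
smithWaterman <- function(read, window, scoring = scoringScheme()) {
  if (!nzchar(read)) stop("read must be non-empty")
  if (!nzchar(window)) stop("window must be non-empty")
  cpp_sw(
    read, window, scoring@match, scoring@mismatch, scoring@gap_open,
    scoring@gap_extend
  )
}

#' Map one read pair
#'
#' Evaluates Smith-Waterman at every candidate location of both mates and
#' picks the concordant combination (opposite strands, inferred fragment
#' length within `fragment_bounds`) maximizing the summed score; when no
#' concordant pair exists, each mate keeps its best single placement and the
#' pair is flagged discordant.
#'
#' @param read1,read2 Mate sequences.
#' @param index A [HashIndex-class].
#' @param scoring A [ScoringScheme-class].
#' @param fragment_bounds Length-2 numeric: min and max fragment length.
#' @param max_candidates Candidate cap per strand.
#' @param min_score Minimum alignment score to accept a placement.
#' @param name Read name.
#' @return Two-row data frame (one row per mate) with `read`, `mate`,
#'   `mapped`, `pos` (0-based), `strand`, `score`, `cigar`, `seq`
#'   (forward-oriented), `concordant`.
#' @export
mapReadPair <- function(read1, read2, index, scoring = scoringScheme(),
                        fragment_bounds = c(100, 1000), max_candidates = 8,
                        min_score = 30, name = "pair1") {
  if (!nzchar(read1) || !nzchar(read2)) stop("both mates must be non-empty")
  cpp_map_pairs(
    index@reference, name, read1, read2, index@k,
    max(1L, index@k %/% 2L), as.integer(max_candidates),
    scoring@match, scoring@mismatch, scoring@gap_open, scoring@gap_extend,
    as.integer(fragment_bounds[1L]), as.integer(fragment_bounds[2L]),
    20L, as.integer(min_score)
  )
}

#' Map a batch of read pairs
#'
#' @param reads1,reads2 Character vectors of mate sequences.
#' @param names Read names.
#' @param reference Target sequence.
#' @param k Seed length.
#' @param scoring A [ScoringScheme-class].
#' @param fragment_bounds Min/max fragment length.
#' @param max_candidates Candidate cap per strand.
#' @param min_score Minimum accepted alignment score.
#' @return Placement data frame, two rows per pair (see [mapReadPair()]).
#' @export
mapReads <- function(reads1, reads2, names, reference, k = 16,
                     scoring = scoringScheme(),
                     fragment_bounds = c(100, 1000), max_candidates = 8,
                     min_score = 30) {
  stopifnot(length(reads1) == length(reads2),
            length(names) == length(reads1))
  cpp_map_pairs(
    reference, names, reads1, reads2, as.integer(k),
    max(1L, as.integer(k) %/% 2L), as.integer(max_candidates),
    scoring@match, scoring@mismatch, scoring@gap_open, scoring@gap_extend,
    as.integer(fragment_bounds[1L]), as.integer(fragment_bounds[2L]),
    20L, as.integer(min_score)
  )
}

#' Map a sample's FASTQ pair against a reference
#'
#' @param fastq1,fastq2 FASTQ paths.
#' @param reference Target sequence.
#' @param ... Passed to [mapReads()].
#' @return Placement data frame.
#' @export
mapFastqPair <- function(fastq1, fastq2, reference, ...) {
  r1 <- readFastq(fastq1)
  r2 <- readFastq(fastq2)
  nm <- sub("/1$", "", names(r1))
  if (!identical(nm, sub("/2$", "", names(r2)))) {
    stop("mate files are not in the same read order")
  }
  mapReads(unname(r1), unname(r2), nm, reference, ...)
}
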