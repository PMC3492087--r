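# Pileup accumulation and hemizygous genotype calling.  Samples are haploid
# (hemizygous males), so each sample carries exactly one allele per site and
# a single dominant non-reference event is expected at a true variant.

#' Accumulate per-base pileup columns from placements
#'
#' Every aligned read base increments exactly one column's base count; each
#' deleted reference base increments that column's deletion count; each
#' insertion is tallied at the column immediately preceding the inserted
#' bases.  Placements extending beyond the reference end are rejected and
#' counted.
#'
#' @param placements Placement data frame (see [mapReads()]).
#' @param reference Target sequence.
#' @return List with `counts` (5 x L matrix, rows A, C, G, T, DEL),
#'   `ins_count` (per-column anchored insertions), `ins_events` (col 0-based,
#'   seq), `del_events` (start 0-based, len), `depth` (base + deletion counts
#'   per column), and `rejected`.
#' @export
accumulatePileup <- function(placements, reference) {
  mapped <- placements[placements$mapped, , drop = FALSE]
  res <- cpp_pileup(
    nchar(reference), as.integer(mapped$pos), mapped$cigar,
    mapped$seq
  )
  rownames(res$counts) <- c("A", "C", "G", "T", "DEL")
  res$depth <- colSums(res$counts)
  if (res$rejected > 0L) {
    warning(res$rejected, " placement(s) beyond reference end rejected")
  }
  res
}

#' Call one pileup column under the hemizygous model
#'
#' No-call when depth (base + deletion counts) is below `min_depth`; a
#' variant call for the most frequent non-reference event (alternate base,
#' deletion, or anchored insertion) when its fraction of depth reaches
#' `min_fraction`; otherwise a reference call.  A tie between two
#' non-reference events at the threshold is a flagged no-call.
#'
#' @param column Named numeric vector with entries `A`, `C`, `G`, `T`, `DEL`
#'   and optionally `INS` (anchored insertion count).
#' @param ref_base Reference base at the column.
#' @param min_depth Callability threshold (default 8).
#' @param min_fraction Minimum non-reference fraction (default 0.75).
#' @return List with `call` in `no_call`/`ref`/`variant`, and for variants
#'   `event` (the winning event label), `fraction`, `depth`; ties carry
#'   `tie = TRUE`.
#' @examples
#' callSite(c(A = 5, C = 0, G = 0, T = 95, DEL = 0), "A")
#' @export
callSite <- function(column, ref_base, min_depth = 8, min_fraction = 0.75) {
  bases <- c("A", "C", "G", "T")
  depth <- sum(column[c(bases, "DEL")], na.rm = TRUE)
  if (depth < min_depth) {
    return(list(call = "no_call", depth = depth, tie = FALSE))
  }
  events <- column[setdiff(names(column), ref_base)]
  events <- events[!is.na(events)]
  top <- max(events)
  frac <- top / depth
  if (frac >= min_fraction) {
    if (sum(events == top) > 1L) {
      return(list(call = "no_call", depth = depth, tie = TRUE))
    }
    return(list(
      call = "variant", event = names(events)[which.max(events)],
      fraction = unname(frac), depth = unname(depth), tie = FALSE
    ))
  }
  list(call = "ref", depth = unname(depth), tie = FALSE)
}

#' Call variants for one sample from its pileup
#'
#' Vectorized application of the [callSite()] rule over all columns, with
#' indel alleles reconstructed from the grouped insertion/deletion events and
#' left-normalized against the reference.  Emitted positions are 1-based.
#'
#' @param pileup Result of [accumulatePileup()].
#' @param reference Target sequence.
#' @param sample_id Sample name.
#' @param min_depth,min_fraction Calling thresholds (defaults 8 and 0.75).
#' @return List with `calls` (pos, ref, alt, type, depth, fraction, sample),
#'   `no_call` (integer positions with depth below `min_depth`), and
#'   `coverage` (the [coverageSummary()] of the sample).
#' @export
callVariants <- function(pileup, reference, sample_id = "S1", min_depth = 8,
                         min_fraction = 0.75) {
  counts <- pileup$counts
  L <- ncol(counts)
  depth <- pileup$depth
  refv <- strsplit(reference, "")[[1L]]
  bases <- c("A", "C", "G", "T")
  refIdx <- match(refv, bases)

  callable <- depth >= min_depth
  no_call <- which(!callable)

  # deletions: group identical (start, len) events, judge at the anchor
  dels <- pileup$del_events
  del_calls <- NULL
  del_cols <- integer(0L)
  if (nrow(dels)) {
    grp <- stats::aggregate(
      list(support = rep(1L, nrow(dels))),
      by = list(start = dels$start, len = dels$len), FUN = sum
    )
    for (i in seq_len(nrow(grp))) {
      p1 <- grp$start[i] + 1L # 1-based first deleted base
      len <- grp$len[i]
      d <- depth[p1]
      if (d < min_depth || grp$support[i] / d < min_fraction) next
      if (p1 + len - 1L > L || p1 < 2L) next
      norm <- leftNormalizeVariant(
        p1 - 1L,
        substr(reference, p1 - 1L, p1 + len - 1L),
        substr(reference, p1 - 1L, p1 - 1L), reference
      )
      del_calls <- rbind(del_calls, data.frame(
        pos = norm$pos, ref = norm$ref, alt = norm$alt, type = "indel",
        depth = d, fraction = grp$support[i] / d,
        stringsAsFactors = FALSE
      ))
      del_cols <- c(del_cols, seq.int(p1, p1 + len - 1L))
    }
  }

  # insertions: group identical (anchor, sequence) events
  ins <- pileup$ins_events
  ins_calls <- NULL
  if (nrow(ins)) {
    key <- paste(ins$col, ins$seq, sep = "|")
    tab <- table(key)
    for (k in names(tab)) {
      parts <- strsplit(k, "|", fixed = TRUE)[[1L]]
      anchor <- as.integer(parts[1L]) + 1L # 1-based anchor column
      d <- depth[anchor]
      if (d < min_depth || tab[[k]] / d < min_fraction) next
      norm <- leftNormalizeVariant(
        anchor, substr(reference, anchor, anchor),
        paste0(substr(reference, anchor, anchor), parts[2L]), reference
      )
      ins_calls <- rbind(ins_calls, data.frame(
        pos = norm$pos, ref = norm$ref, alt = norm$alt, type = "indel",
        depth = d, fraction = unname(tab[[k]]) / d,
        stringsAsFactors = FALSE
      ))
    }
  }

  # SNVs: dominant alternate base outside called deletion spans
  alt_counts <- counts[1:4, , drop = FALSE]
  ok <- callable & !is.na(refIdx)
  alt_counts[cbind(refIdx[ok], which(ok))] <- -1L # mask the reference base
  top <- apply(alt_counts, 2L, max)
  topBase <- bases[apply(alt_counts, 2L, which.max)]
  frac <- ifelse(depth > 0, top / depth, 0)
  snv_at <- which(ok & frac >= min_fraction)
  snv_at <- setdiff(snv_at, del_cols)
  # a tie between two alternate bases at threshold is a no-call
  if (length(snv_at)) {
    tied <- vapply(snv_at, function(j) {
      sum(alt_counts[, j] == top[j]) > 1L
    }, logical(1L))
    no_call <- sort(union(no_call, snv_at[tied]))
    snv_at <- snv_at[!tied]
  }
  snv_calls <- if (length(snv_at)) {
    data.frame(
      pos = snv_at, ref = refv[snv_at], alt = topBase[snv_at],
      type = "SNV", depth = depth[snv_at], fraction = frac[snv_at],
      stringsAsFactors = FALSE
    )
  } else {
    NULL
  }

  calls <- rbind(snv_calls, del_calls, ins_calls)
  if (is.null(calls)) {
    calls <- data.frame(
      pos = integer(), ref = character(), alt = character(),
      type = character(), depth = numeric(), fraction = numeric(),
      stringsAsFactors = FALSE
    )
  }
  calls <- calls[order(calls$pos), , drop = FALSE]
  calls$sample <- rep(sample_id, nrow(calls))
  rownames(calls) <- NULL
  list(
    calls = calls, no_call = no_call,
    coverage = coverageSummary(depth, threshold = min_depth)
  )
}

#' Coverage summary over pileup columns
#'
#' @param depths Per-column depth vector (base + deletion counts).
#' @param threshold Callability depth threshold (default 8).
#' @return List with `fraction_at_least` (share of columns with depth >=
#'   threshold), `median_depth`, and the `threshold`.
#' @examples
#' coverageSummary(c(0, 10, 10, 10))
#' @export
coverageSummary <- function(depths, threshold = 8) {
  if (!length(depths)) stop("at least one column required")
  list(
    fraction_at_least = mean(depths >= threshold),
    median_depth = median(depths), threshold = threshold
  )
}

#' Merge per-sample calls into a cohort site table
#'
#' One row per (position, ref, alt) with the carrier sample list; samples
#' no-called at a site are counted separately so a callable denominator can
#' be derived.  Case frequency uses the full cohort size, matching how rare
#' carrier counts are reported (k of n sequenced males).
#'
#' @param sample_calls List of [callVariants()] results, one per sample.
#' @param n_samples Cohort size (defaults to `length(sample_calls)`).
#' @return Data frame: pos, ref, alt, type, carriers, carrier_count,
#'   case_freq, n_no_call, mean_fraction.
#' @export
mergeCohort <- function(sample_calls, n_samples = length(sample_calls)) {
  all_calls <- do.call(rbind, lapply(sample_calls, `[[`, "calls"))
  if (is.null(all_calls) || nrow(all_calls) == 0L) {
    return(data.frame(
      pos = integer(), ref = character(), alt = character(),
      type = character(), carriers = character(), carrier_count = integer(),
      case_freq = numeric(), n_no_call = integer(), mean_fraction = numeric(),
      stringsAsFactors = FALSE
    ))
  }
  key <- paste(all_calls$pos, all_calls$ref, all_calls$alt, sep = "|")
  ref_at <- tapply(all_calls$ref, all_calls$pos, unique)
  if (any(vapply(ref_at, length, integer(1L)) > 1L)) {
    multi <- names(ref_at)[vapply(ref_at, length, integer(1L)) > 1L]
    # distinct ref alleles at one position are legitimate only for indels
    # anchored at the same base; a ref/ref SNV conflict is a reference error
    snv_keys <- split(all_calls$ref[all_calls$type == "SNV"],
                      all_calls$pos[all_calls$type == "SNV"])
    if (any(vapply(snv_keys[names(snv_keys) %in% multi], function(x) {
      length(unique(x)) > 1L
    }, logical(1L)))) {
      stop("conflicting reference alleles at one position")
    }
  }
  no_call <- lapply(sample_calls, `[[`, "no_call")
  ord <- !duplicated(key)
  sites <- all_calls[ord, c("pos", "ref", "alt", "type"), drop = FALSE]
  skey <- key[ord]
  sites$carriers <- vapply(skey, function(k) {
    paste(sort(all_calls$sample[key == k]), collapse = ",")
  }, character(1L), USE.NAMES = FALSE)
  sites$carrier_count <- as.integer(table(key)[skey])
  sites$case_freq <- sites$carrier_count / n_samples
  sites$n_no_call <- vapply(sites$pos, function(p) {
    sum(vapply(no_call, function(nc) p %in% nc, logical(1L)))
  }, integer(1L))
  sites$mean_fraction <- vapply(skey, function(k) {
    mean(all_calls$fraction[key == k])
  }, numeric(1L), USE.NAMES = FALSE)
  sites <- sites[order(sites$pos, sites$ref, sites$alt), , drop = FALSE]
  rownames(sites) <- NULL
  sites
}
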