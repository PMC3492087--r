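# Prioritization: reduce the annotated cohort to rare, novel variants at
# evolutionarily conserved sites, and summarize how much of the discovered
# variation is new.

#' Filter an annotated table to rare, conserved, novel variants
#'
#' A row is kept iff its PhastCons (maximum per-base value for multi-base
#' variants) reaches `phastcons_min`, its case frequency is at most
#' `case_freq_max`, and (when `exclude_known`) it is absent from the variant
#' catalog.  The threshold comparison is inclusive (`>=`); rows lacking a
#' conservation score are excluded and counted in the `unscored` attribute.
#' The filter is monotone and idempotent.
#'
#' @param annotated Table from [annotateCohort()].
#' @param phastcons_min Conservation threshold (default 0.7).
#' @param case_freq_max Maximum case frequency (default 0.01, i.e. below 1%
#'   at the 144-sample study scale).
#' @param exclude_known Drop catalog variants (default TRUE).
#' @return The filtered table, sorted by position, with attribute
#'   `unscored` (number of rows dropped for missing conservation).
#' @export
filterConservedRare <- function(annotated, phastcons_min = 0.7,
                                case_freq_max = 0.01, exclude_known = TRUE) {
  if (phastcons_min < 0 || phastcons_min > 1) {
    stop("phastcons_min must be in [0,1]")
  }
  if (case_freq_max < 0 || case_freq_max > 1) {
    stop("case_freq_max must be in [0,1]")
  }
  unscored <- is.na(annotated$phastcons)
  keep <- !unscored &
    annotated$phastcons >= phastcons_min &
    annotated$case_freq <= case_freq_max &
    (!exclude_known | !annotated$known)
  out <- annotated[keep, , drop = FALSE]
  out <- out[order(out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unscored") <- sum(unscored)
  out
}

#' Novelty summary by variant type
#'
#' Counts, per variant type, how many variants are absent from the catalog,
#' with the novel percentage rounded to the nearest integer; a per-gene
#' breakdown is added when gene labels are present.
#'
#' @param annotated Table with `type` and `known` columns (a `gene` column
#'   enables the per-gene breakdown).
#' @return Data frame with `type`, `total`, `novel`, `novel_pct` (NA for an
#'   empty type), plus attribute `by_gene` when genes are labelled.
#' @examples
#' tab <- data.frame(type = rep("SNV", 10), known = rep(TRUE, 10))
#' noveltySummary(tab)
#' @export
noveltySummary <- function(annotated) {
  types <- c("SNV", "indel")
  out <- do.call(rbind, lapply(types, function(tp) {
    sub <- annotated[annotated$type == tp, , drop = FALSE]
    total <- nrow(sub)
    novel <- sum(!sub$known)
    data.frame(
      type = tp, total = total, novel = novel,
      novel_pct = if (total > 0L) round(100 * novel / total) else NA_real_
    )
  }))
  if ("gene" %in% names(annotated)) {
    genes <- unique(annotated$gene[!is.na(annotated$gene)])
    attr(out, "by_gene") <- do.call(rbind, lapply(genes, function(g) {
      sub <- annotated[!is.na(annotated$gene) & annotated$gene == g, ,
        drop = FALSE
      ]
      data.frame(
        gene = g, total = nrow(sub), novel = sum(!sub$known)
      )
    }))
  }
  out
}

#' Frequency-vs-conservation records for the site-frequency figure
#'
#' One record per variant: minor-allele case frequency, conservation, and
#' catalog status; plotting is left to the caller.
#'
#' @param annotated Table from [annotateCohort()].
#' @return Data frame with `pos`, `type`, `case_freq`, `phastcons`, `known`.
#' @export
frequencySpectrumTable <- function(annotated) {
  data.frame(
    pos = annotated$pos, type = annotated$type,
    case_freq = annotated$case_freq, phastcons = annotated$phastcons,
    known = annotated$known, stringsAsFactors = FALSE
  )
}
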