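test_that("pileup columns count aligned bases, deletions, and insertions", {
  ref <- strrep("ACGT", 10) # 40 bp
  # ten identical perfect reads covering 1..20
  pl <- data.frame(
    read = paste0("r", 1:10), mate = 1L, mapped = TRUE, pos = 0L,
    strand = "+", score = 20L, cigar = "20=",
    seq = substr(ref, 1, 20), concordant = TRUE,
    stringsAsFactors = FALSE
  )
  pile <- accumulatePileup(pl, ref)
  expect_equal(unname(pile$depth[1:20]), rep(10, 20))
  expect_equal(unname(pile$depth[21:40]), rep(0, 20))
  for (j in 1:20) {
    expect_equal(unname(pile$counts[substr(ref, j, j), j]), 10L)
  }

  # a read with a 2-base deletion spanning columns 11..12
  del <- data.frame(
    read = "d", mate = 1L, mapped = TRUE, pos = 0L, strand = "+",
    score = 0L, cigar = "10=2D8=",
    seq = paste0(substr(ref, 1, 10), substr(ref, 13, 20)),
    concordant = TRUE, stringsAsFactors = FALSE
  )
  pd <- accumulatePileup(del, ref)
  expect_equal(unname(pd$counts["DEL", 11L]), 1L)
  expect_equal(unname(pd$counts["DEL", 12L]), 1L)
  expect_equal(nrow(pd$del_events), 1L)
  expect_equal(pd$del_events$start, 10L) # 0-based first deleted base

  # an insertion after column 5 is tallied at column 5
  ins <- data.frame(
    read = "i", mate = 1L, mapped = TRUE, pos = 0L, strand = "+",
    score = 0L, cigar = "5=2I15=",
    seq = paste0(substr(ref, 1, 5), "TT", substr(ref, 6, 20)),
    concordant = TRUE, stringsAsFactors = FALSE
  )
  pi_ <- accumulatePileup(ins, ref)
  expect_equal(pi_$ins_count[5L], 1L)
  expect_equal(pi_$ins_events$seq, "TT")

  # a placement running beyond the reference end is rejected with a warning
  bad <- pl[1L, ]
  bad$pos <- 30L
  expect_warning(pb <- accumulatePileup(rbind(pl, bad), ref), "rejected")
  expect_equal(unname(pb$depth[1:20]), rep(10, 20))
})

test_that("pileup counts equal a brute-force recount on simulated data", {
  cfg <- simulationConfig(
    target_length = 5000, n_amplicons = 1, n_samples = 1,
    mean_depth = 50, n_variants = 15, seed = 13
  )
  ref <- makeReference(cfg)$sequence
  rd <- simulateReads(ref, cfg, "S1")
  pl <- mapReads(rd$read1, rd$read2, rd$names, ref)
  pile <- accumulatePileup(pl, ref)
  expect_equal(unname(pile$depth), as.numeric(depthOracle(pl, nchar(ref))))
  # column count conservation: total base counts = total aligned read bases
  aligned <- sum(vapply(pl$cigar[pl$mapped], function(cig) {
    ops <- regmatches(cig, gregexpr("[0-9]+[=XM]", cig))[[1L]]
    sum(as.integer(sub("[=XM]", "", ops)))
  }, numeric(1L)))
  expect_equal(sum(pile$counts[1:4, ]), aligned)
})

test_that("single-column hemizygous calling follows the stated rule", {
  # dominant non-reference base above both thresholds
  v <- callSite(c(A = 5, C = 0, G = 0, T = 95, DEL = 0), "A")
  expect_equal(v$call, "variant")
  expect_equal(v$event, "T")
  expect_equal(v$fraction, 0.95)
  # depth below the callability threshold
  expect_equal(callSite(c(A = 0, C = 0, G = 0, T = 7, DEL = 0), "A")$call,
    "no_call"
  )
  # pure reference column
  expect_equal(
    callSite(c(A = 100, C = 0, G = 0, T = 0, DEL = 0), "A")$call,
    "ref"
  )
  # deletions and insertions compete as events
  expect_equal(
    callSite(c(A = 10, C = 0, G = 0, T = 0, DEL = 90), "A")$event, "DEL"
  )
  expect_equal(
    callSite(c(A = 20, C = 0, G = 0, T = 0, DEL = 0, INS = 80), "A")$event,
    "INS"
  )
  # tie between two non-reference alleles at threshold: flagged no-call
  tie <- callSite(c(A = 0, C = 40, G = 0, T = 40, DEL = 0), "A",
    min_fraction = 0.5
  )
  expect_equal(tie$call, "no_call")
  expect_true(tie$tie)
})

test_that("coverage summary counts thresholds and medians correctly", {
  expect_equal(
    coverageSummary(rep(100, 7))[c("fraction_at_least", "median_depth")],
    list(fraction_at_least = 1.0, median_depth = 100)
  )
  cs <- coverageSummary(c(0, 10, 10, 10))
  expect_equal(cs$fraction_at_least, 0.75)
  expect_equal(cs$median_depth, 10)
  expect_error(coverageSummary(numeric(0L)), "at least one")
})

test_that("per-sample calling recovers planted variants and is order-invariant", {
  cfg <- simulationConfig(
    target_length = 6000, n_amplicons = 1, n_samples = 2,
    mean_depth = 50, n_variants = 25, rare_fraction = 0.5,
    indel_fraction = 0.3, seed = 17
  )
  ref <- makeReference(cfg)$sequence
  pl <- plantVariants(ref, cfg)
  s <- "S1"
  rd <- simulateReads(pl$haplotypes[[s]], cfg, s, seed = 101)
  placements <- mapReads(rd$read1, rd$read2, rd$names, ref)
  pile <- accumulatePileup(placements, ref)
  res <- callVariants(pile, ref, s)
  mine <- pl$truth[grepl("\\bS1\\b", gsub(",", " ", pl$truth$carriers)), ]
  expect_setequal(variantKey(res$calls), variantKey(mine))
  # call set is invariant to read input order
  perm <- sample(nrow(placements))
  res2 <- callVariants(
    accumulatePileup(placements[perm, ], ref), ref, s
  )
  expect_equal(res$calls, res2$calls)
})

test_that("cohort merging tracks carriers, denominators, and ref conflicts", {
  mk <- function(sample, pos, ref, alt, type = "SNV", no_call = integer()) {
    list(
      calls = data.frame(
        pos = pos, ref = ref, alt = alt,
        type = rep(type, length.out = length(pos)),
        depth = rep(50, length(pos)), fraction = rep(0.98, length(pos)),
        sample = rep(sample, length(pos)), stringsAsFactors = FALSE
      ),
      no_call = no_call,
      coverage = list(fraction_at_least = 1, median_depth = 50)
    )
  }
  merged <- mergeCohort(
    list(
      mk("S1", c(10L, 20L), c("A", "C"), c("T", "G")),
      mk("S2", 20L, "C", "G", no_call = 10L),
      mk("S3", integer(), character(), character())
    ),
    n_samples = 144
  )
  expect_equal(nrow(merged), 2L)
  expect_equal(merged$carrier_count, c(1L, 2L))
  expect_equal(merged$case_freq[1L], 1 / 144)
  expect_equal(merged$carriers[2L], "S1,S2")
  expect_equal(merged$n_no_call, c(1L, 0L))
  # a site carried by no sample is simply absent
  expect_false(30L %in% merged$pos)
  # conflicting reference alleles at one position abort the merge
  expect_error(
    mergeCohort(list(
      mk("S1", 10L, "A", "T"),
      mk("S2", 10L, "C", "T")
    ), n_samples = 2),
    "conflicting reference"
  )
})
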