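test_that("reference generation is seeded, tiled, and alphabet-clean", {
  cfg <- simulationConfig(
    target_length = 1000, n_amplicons = 2,
    n_variants = 30, seed = 7
  )
  a <- makeReference(cfg)
  b <- makeReference(cfg)
  expect_identical(a$sequence, b$sequence)
  expect_identical(a$amplicons, b$amplicons)
  expect_false(grepl("[^ACGT]", a$sequence))
  # amplicons tile [1, L] without gaps
  expect_equal(a$amplicons$start[1L], 1L)
  expect_equal(a$amplicons$end[nrow(a$amplicons)], 1000L)
  expect_equal(a$amplicons$start[-1L], a$amplicons$end[-2L] + 1L)

  big <- makeReference(simulationConfig(
    target_length = 65000,
    n_amplicons = 13, seed = 1
  ))
  expect_equal(nrow(big$amplicons), 13L)
  expect_true(all(big$amplicons$end - big$amplicons$start + 1L >= 100L))
})

test_that("invalid simulation configurations are rejected", {
  expect_error(simulationConfig(target_length = -5), "non-positive|100 bases")
  expect_error(simulationConfig(error_rate = 1.5), "probability")
  expect_error(
    simulationConfig(fragment_mean = 150, read_length = 100),
    "allow_overlap"
  )
  expect_silent(simulationConfig(
    fragment_mean = 150, read_length = 100,
    allow_overlap = TRUE
  ))
  expect_error(
    simulationConfig(target_length = 1500, n_amplicons = 2,
                     n_variants = 400),
    "n_variants"
  )
})

test_that("planted variants honor carrier structure, catalog, conservation", {
  cfg <- simulationConfig(
    target_length = 8000, n_amplicons = 2, n_samples = 144,
    n_variants = 50, rare_fraction = 0.8, conserved_fraction = 0.5,
    catalog_fraction = 1.0, seed = 3
  )
  ref <- makeReference(cfg)
  pl <- plantVariants(ref$sequence, cfg)
  tr <- pl$truth
  expect_equal(nrow(tr), 50L)
  expect_equal(sum(tr$carrier_count == 1L), 40L) # rare_fraction 0.8
  expect_true(all(tr$case_freq[tr$carrier_count == 1L] == 1 / 144))
  # common variants exceed 5% carrier fraction and land in the catalog
  common <- tr[tr$carrier_count > 1L, ]
  expect_true(all(common$carrier_count / 144 > 0.05))
  expect_true(all(common$in_catalog))
  expect_false(any(tr$in_catalog[tr$carrier_count == 1L]))
  # conserved rare variants sit on PhastCons-1.0 track positions
  cons <- tr[tr$conserved, ]
  expect_equal(nrow(cons), round(0.5 * 40))
  expect_true(all(pl$track$phastcons[cons$pos] == 1.0))
  expect_true(all(pl$track$phastcons[tr$pos[!tr$conserved]] < 0.7))
  # every variant position is unique and inside the target
  expect_false(any(duplicated(tr$pos)))
  expect_true(all(tr$pos >= 1L & tr$pos <= 8000L))

  # rare_fraction 1 forces every variant to a singleton
  cfg1 <- simulationConfig(
    target_length = 8000, n_amplicons = 2, n_samples = 144,
    n_variants = 30, rare_fraction = 1.0, seed = 4
  )
  tr1 <- plantVariants(makeReference(cfg1)$sequence, cfg1)$truth
  expect_true(all(tr1$case_freq == 1 / 144))

  # catalog_fraction 0 leaves the catalog empty
  cfg0 <- simulationConfig(
    target_length = 8000, n_amplicons = 2, n_samples = 144,
    n_variants = 30, rare_fraction = 0.5, catalog_fraction = 0, seed = 5
  )
  pl0 <- plantVariants(makeReference(cfg0)$sequence, cfg0)
  expect_equal(nrow(pl0$catalog), 0L)
})

test_that("haplotypes differ from the reference exactly at carried variants", {
  cfg <- simulationConfig(
    target_length = 5000, n_amplicons = 1, n_samples = 5,
    n_variants = 20, rare_fraction = 0.5, indel_fraction = 0.3, seed = 9
  )
  ref <- makeReference(cfg)$sequence
  pl <- plantVariants(ref, cfg)
  for (s in seq_len(5L)) {
    sid <- paste0("S", s)
    hap <- pl$haplotypes[[sid]]
    mine <- pl$truth[grepl(paste0("\\b", sid, "\\b"), gsub(
      ",", " ",
      pl$truth$carriers
    )), ]
    # reconstruct the haplotype independently from the truth records
    expected <- ref
    for (i in rev(order(mine$pos))) {
      p <- mine$pos[i]
      expected <- paste0(
        substr(expected, 1L, p - 1L), mine$alt[i],
        substr(expected, p + nchar(mine$ref[i]), nchar(expected))
      )
    }
    expect_identical(hap, expected)
  }
})

test_that("error-free reads are exact haplotype substrings at expected depth", {
  cfg <- simulationConfig(
    target_length = 10000, n_amplicons = 2, n_samples = 1,
    mean_depth = 50, error_rate = 0, n_variants = 10, seed = 21
  )
  hap <- makeReference(cfg)$sequence
  rd <- simulateReads(hap, cfg, "S1")
  expect_true(all(vapply(rd$read1, function(r) {
    grepl(r, hap, fixed = TRUE)
  }, logical(1L))))
  expect_true(all(vapply(rd$read2, function(r) {
    grepl(revcompOracle(r), hap, fixed = TRUE)
  }, logical(1L))))
  # mean depth within 3 Poisson standard errors of the target
  nm <- do.call(rbind, strsplit(rd$names, ":"))
  starts <- as.integer(nm[, 3L]) + 1L
  depth <- integer(10000L)
  fl <- as.integer(nm[, 4L]) + 100L - starts + 1L
  for (i in seq_along(starts)) {
    s1 <- starts[i]
    depth[s1:(s1 + 99L)] <- depth[s1:(s1 + 99L)] + 1L
    s2 <- as.integer(nm[i, 4L]) + 1L
    depth[s2:(s2 + 99L)] <- depth[s2:(s2 + 99L)] + 1L
  }
  interior <- depth[500:9500]
  expect_lt(abs(mean(interior) - 50), 3 * sqrt(50 / length(interior)) + 1)
})

test_that("read simulation and FASTQ output are byte-deterministic", {
  cfg <- simulationConfig(
    target_length = 3000, n_amplicons = 1, n_samples = 1,
    mean_depth = 10, n_variants = 5, seed = 33
  )
  hap <- makeReference(cfg)$sequence
  d1 <- tempfile()
  d2 <- tempfile()
  for (d in c(d1, d2)) {
    rd <- simulateReads(hap, cfg, "S1")
    dir.create(d)
    writeFastqPair(rd$read1, rd$read2, rd$names, file.path(d, "S1"))
  }
  for (m in c("_1", "_2")) {
    expect_identical(
      readLines(file.path(d1, paste0("S1", m, ".fastq"))),
      readLines(file.path(d2, paste0("S1", m, ".fastq")))
    )
  }
})

test_that("PWM sets are normalized, seeded, and plant scannable consensus", {
  set.seed(1)
  ref <- randomSeq(2000)
  a <- makePwmSet(n_motifs = 2, widths = c(8, 10), seed = 6, reference = ref)
  b <- makePwmSet(n_motifs = 2, widths = c(8, 10), seed = 6, reference = ref)
  expect_identical(
    lapply(a$pwms, function(p) p@matrix),
    lapply(b$pwms, function(p) p@matrix)
  )
  for (p in a$pwms) {
    expect_true(all(abs(colSums(p@matrix) - 1) < 1e-9))
  }
  expect_error(makePwmSet(widths = 3), ">= 4")
  # the planted instance is the exact consensus at the recorded position
  for (i in seq_len(nrow(a$planted))) {
    p <- a$pwms[[a$planted$name[i]]]
    expect_identical(
      substr(a$reference, a$planted$start[i], a$planted$end[i]),
      pwmConsensus(p)
    )
  }
})

test_that("left normalization anchors indels with one shared leading base", {
  #        123456789
  refseq <- "GATTTACGT"
  # deleting one T of the TTT run, any representation, normalizes to pos 2
  norm <- leftNormalizeVariant(4L, "TT", "T", refseq)
  expect_equal(norm, list(pos = 2L, ref = "AT", alt = "A"))
  # insertion of A after the G at pos 1
  norm2 <- leftNormalizeVariant(1L, "G", "GA", refseq)
  expect_equal(norm2, list(pos = 1L, ref = "G", alt = "GA"))
  # SNVs pass through untouched
  expect_equal(
    leftNormalizeVariant(5L, "T", "C", refseq),
    list(pos = 5L, ref = "T", alt = "C")
  )
})
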