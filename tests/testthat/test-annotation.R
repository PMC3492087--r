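# toy plus-strand gene: exons 101-200 and 301-400, CDS 151-352 (102 bp)
plusGene <- function() {
  geneModel("plus", "+",
    exon_starts = c(101L, 301L), exon_ends = c(200L, 400L),
    cds_start = 151L, cds_end = 352L
  )
}

# toy minus-strand gene with the same geometry: 5'UTR at high coordinates
minusGene <- function() {
  geneModel("minus", "-",
    exon_starts = c(101L, 301L), exon_ends = c(200L, 400L),
    cds_start = 151L, cds_end = 352L
  )
}

test_that("site classification follows coding > UTR > intron > intergenic", {
  models <- list(plusGene())
  expect_equal(as.character(classifySite(160L, models)), "coding")
  expect_equal(as.character(classifySite(120L, models)), "5'UTR")
  expect_equal(as.character(classifySite(380L, models)), "3'UTR")
  expect_equal(as.character(classifySite(250L, models)), "intron")
  expect_equal(as.character(classifySite(500L, models)), "intergenic")
  expect_equal(attr(classifySite(160L, models), "gene"), "plus")
  expect_error(classifySite(0L, models), "outside")
  expect_error(classifySite(900L, models, target_length = 800L), "outside")
  # on the minus strand the UTR sides flip
  mm <- list(minusGene())
  expect_equal(as.character(classifySite(120L, mm)), "3'UTR")
  expect_equal(as.character(classifySite(380L, mm)), "5'UTR")
})

test_that("gene model validity enforces exon ordering and CDS frame", {
  expect_error(
    geneModel("bad", "+", c(101L, 150L), c(200L, 250L), 110L, 190L),
    "non-overlapping"
  )
  expect_error(
    geneModel("bad", "+", 101L, 200L, 110L, 191L),
    "divisible by 3"
  )
})

test_that("amino-acid changes match hand translation on both strands", {
  # build a reference whose CDS starts ATG GCT ... on the plus strand
  set.seed(5)
  ref <- randomSeq(500)
  substr(ref, 151, 159) <- "ATGGCTTGG" # M A W
  g <- plusGene()
  # ATG -> ACG at codon 1: M1T
  expect_equal(
    aaChange(152L, "T", "C", g, ref),
    list(class = "coding-missense", aa_change = "M1T")
  )
  # GCT -> GCC: synonymous (A -> A)
  expect_equal(
    aaChange(156L, "T", "C", g, ref)$class,
    "coding-synonymous"
  )
  # TGG -> TGA: nonsense
  expect_equal(
    aaChange(159L, "G", "A", g, ref),
    list(class = "coding-nonsense", aa_change = "W3*")
  )
  # indels in the CDS are labelled by frame
  expect_equal(
    aaChange(160L, "GT", "G", g, ref)$class,
    "coding-frameshift"
  )
  expect_equal(
    aaChange(160L, "GTTT", "G", g, ref)$class,
    "coding-inframe"
  )

  # minus-strand gene: the CDS is the reverse complement of the genomic
  # span, so the last genomic codon is codon 1
  refm <- ref
  substr(refm, 344, 352) <- "CCAAGCCAT" # revcomp = ATG GCT TGG
  gm <- minusGene()
  # hand translation: genomic A>G at 351 => cds base 2 T>C => ATG->ACG: M1T
  got <- aaChange(351L, "A", "G", gm, refm)
  expect_equal(got, list(class = "coding-missense", aa_change = "M1T"))
})

test_that("conservation lookup is exact per base with missing-base flags", {
  track <- data.frame(
    pos = c(1:5, 7L),
    phastcons = c(0.1, 1, 1, 0.3, 0.2, 0.9),
    phylop = c(0, 0.85, 1.76, -0.4, 0.1, 2.2)
  )
  one <- lookupConservation(2L, 1L, track)
  expect_equal(one$phastcons, 1)
  expect_false(any(one$missing))
  # a 2-base span returns both per-base values
  two <- lookupConservation(2L, 2L, track)
  expect_equal(two$phastcons, c(1, 1))
  expect_equal(two$phylop, c(0.85, 1.76))
  # an uncovered base scores (0, 0) and is flagged
  gap <- lookupConservation(6L, 1L, track)
  expect_equal(gap$phastcons, 0)
  expect_equal(gap$phylop, 0)
  expect_true(gap$missing)
  # malformed track lines surface as parse errors
  bad <- tempfile()
  writeLines(c("target\t0\t1\t0.5\t1.2", "target\t1\t2\tx\t0.3"), bad)
  expect_error(readConservationTrack(bad), "malformed")
})

test_that("catalog membership is allele-aware and ordered across catalogs", {
  cat1 <- data.frame(
    pos = 100L, id = "rs1", ref = "A", alt = "T",
    stringsAsFactors = FALSE
  )
  cat2 <- data.frame(
    pos = c(100L, 200L), id = c("alt1", "rs2"), ref = c("A", "C"),
    alt = c("T", "G"), stringsAsFactors = FALSE
  )
  expect_equal(
    catalogMembership(100L, "A", "T", cat1),
    list(known = TRUE, id = "rs1")
  )
  # same position, different alternate allele: novel
  expect_false(catalogMembership(100L, "A", "G", cat1)$known)
  # catalogs are consulted in order; the first hit wins
  expect_equal(
    catalogMembership(100L, "A", "T", list(cat1, cat2))$id, "rs1"
  )
  expect_equal(
    catalogMembership(200L, "C", "G", list(cat1, cat2))$id, "rs2"
  )
})

test_that("feature overlap uses half-open BED semantics", {
  bed <- tempfile(fileext = ".bed")
  writeLines("target\t90\t110\tpeak1", bed) # 1-based 91..110
  gr <- readFeatureBed(bed, "h3k4me1")
  expect_equal(overlapFeatures(100L, 1L, list(h3k4me1 = gr)), "h3k4me1")
  expect_equal(overlapFeatures(110L, 1L, list(h3k4me1 = gr)), "h3k4me1")
  expect_equal(
    overlapFeatures(111L, 1L, list(h3k4me1 = gr)),
    character(0L)
  )
  # random variants vs random intervals equal a brute-force intersection
  set.seed(23)
  starts <- sample(1:900, 25L)
  widths <- sample(5:40, 25L, replace = TRUE)
  bed2 <- tempfile(fileext = ".bed")
  writeBed(starts, pmin(starts + widths, 1000L), bed2)
  gr2 <- readFeatureBed(bed2, "rand")
  for (v in sample(1:1000, 40L)) {
    brute <- any(v >= starts & v <= pmin(starts + widths, 1000L))
    expect_equal(
      length(overlapFeatures(v, 1L, list(rand = gr2))) > 0L,
      brute
    )
  }
})

test_that("cohort annotation is pure and covers every class exactly once", {
  set.seed(31)
  ref <- randomSeq(600)
  substr(ref, 151, 153) <- "ATG"
  cohort <- data.frame(
    pos = c(120L, 160L, 250L, 380L, 550L),
    ref = c("A", "A", "C", "G", "T"),
    alt = c("T", "G", "T", "A", "C"),
    type = "SNV", carriers = "S1", carrier_count = 1L,
    case_freq = 1 / 144, n_no_call = 0L, mean_fraction = 0.99,
    stringsAsFactors = FALSE
  )
  cohort$ref <- vapply(cohort$pos, function(p) substr(ref, p, p),
    character(1L)
  )
  cohort$alt <- vapply(cohort$ref, function(b) {
    setdiff(c("A", "C", "G", "T"), b)[1L]
  }, character(1L))
  track <- data.frame(
    pos = 1:600, phastcons = rep(0.5, 600),
    phylop = rep(0.1, 600)
  )
  catalog <- data.frame(
    pos = 250L, id = "rs9", ref = cohort$ref[3L],
    alt = cohort$alt[3L], stringsAsFactors = FALSE
  )
  ann <- annotateCohort(cohort, list(plusGene()), catalog, track, ref)
  ann2 <- annotateCohort(cohort, list(plusGene()), catalog, track, ref)
  expect_identical(ann, ann2)
  expect_equal(
    ann$class,
    c("5'UTR", ann$class[2L], "intron", "3'UTR", "intergenic")
  )
  expect_match(ann$class[2L], "^coding-")
  expect_equal(ann$known, c(FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(ann$catalog_id[3L], "rs9")
  expect_false(any(is.na(ann$class)))
})
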