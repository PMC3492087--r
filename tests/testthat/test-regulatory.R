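uniformPwm <- function(w = 6) {
  pwm("uniform", matrix(0.25, 4, w,
    dimnames = list(c("A", "C", "G", "T"), NULL)
  ))
}

consensusPwm <- function(seqc, weight = 1, pseudocount = 0) {
  bases <- strsplit(seqc, "")[[1L]]
  m <- matrix((1 - weight) / 3, 4, length(bases),
    dimnames = list(c("A", "C", "G", "T"), NULL)
  )
  for (j in seq_along(bases)) m[bases[j], j] <- weight
  pwm(paste0("cons_", seqc), m, pseudocount = pseudocount)
}

test_that("raw PWM scores follow the log-odds definition", {
  # uniform matrix scores 0 everywhere
  expect_equal(pwmScore("ACGTAC", uniformPwm()), 0, tolerance = 1e-12)
  # deterministic consensus with zero pseudocount: w * log2(4)
  cp <- consensusPwm("ACGT")
  expect_equal(pwmScore("ACGT", cp), 4 * log2(4), tolerance = 1e-12)
  # ambiguous bases contribute the background score 0
  expect_equal(pwmScore("ANGT", cp), 3 * log2(4), tolerance = 1e-12)
  expect_error(pwmScore("ACG", cp), "motif width")
  # random matrix/window pairs equal a per-column hand summation
  set.seed(59)
  for (rep in seq_len(10L)) {
    m <- matrix(runif(4 * 8), 4, 8)
    m <- sweep(m, 2L, colSums(m), "/")
    rownames(m) <- c("A", "C", "G", "T")
    p <- pwm("rand", m, pseudocount = 0.01)
    win <- randomSeq(8)
    hand <- 0
    for (j in 1:8) {
      b <- substr(win, j, j)
      hand <- hand + log2((m[b, j] + 0.01 * 0.25) / (0.25 * 1.01))
    }
    expect_equal(pwmScore(win, p), unname(hand), tolerance = 1e-12)
  }
})

test_that("PWM validity enforces normalization and width", {
  m <- matrix(0.3, 4, 5, dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_error(pwm("bad", m), "sum to 1")
  m3 <- matrix(0.25, 4, 3, dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_error(pwm("narrow", m3), ">= 4")
})

test_that("background calibration rejects degenerate sets and centers z", {
  cp <- consensusPwm("ACGTACGT", weight = 0.9, pseudocount = 0.01)
  # identical regions have zero variance across maxima
  same <- rep(paste0("TTTT", "ACGTACGT", "TTTT"), 40L)
  expect_error(calibratePwm(cp, same), "zero variance")
  expect_error(calibratePwm(cp, rep(randomSeq(50), 10L)), ">= 30")
  # regions each holding a one-mismatch near-consensus anchor the mean just
  # below the consensus score, so the exact consensus sits mildly above
  # background (the consensus is the maximal achievable score, so a set in
  # which every region contains it verbatim would have zero variance and be
  # rejected like the identical-region case above)
  set.seed(61)
  cons_score <- pwmScore("ACGTACGT", cp)
  near <- vapply(seq_len(60L), function(i) {
    inst <- "ACGTACGT"
    at <- sample(1:8, 1L)
    substr(inst, at, at) <- sample(setdiff(
      c("A", "C", "G", "T"),
      substr(inst, at, at)
    ), 1L)
    paste0(randomSeq(20), inst, randomSeq(20))
  }, character(1L))
  cal <- calibratePwm(cp, near)
  expect_lt(cal@mean, cons_score)
  z_near <- (cons_score - cal@mean) / cal@sd
  expect_gt(z_near, 0)
  # random background: planted consensus scores z >= 2
  rnd <- vapply(seq_len(200L), function(i) randomSeq(120),
    character(1L)
  )
  cal2 <- calibratePwm(cp, rnd)
  expect_gte((cons_score - cal2@mean) / cal2@sd, 2)
})

test_that("scanning finds planted sites symmetrically on both strands", {
  set.seed(67)
  cp <- consensusPwm("ACGTTGCA", weight = 0.9, pseudocount = 0.01)
  cal <- calibratePwm(cp, vapply(
    seq_len(60L),
    function(i) randomSeq(100), character(1L)
  ))
  seqc <- paste0(randomSeq(40), "ACGTTGCA", randomSeq(40))
  hits <- scanPwm(seqc, cp, cal, z_min = 2)
  expect_true(41L %in% hits$pos)
  top <- hits[which.max(hits$score), ]
  expect_equal(top$pos, 41L)
  expect_equal(top$strand, "+")
  # scanning the reverse complement mirrors positions and flips strands
  rc_hits <- scanPwm(revcomp(seqc), cp, cal, z_min = 2)
  L <- nchar(seqc)
  w <- pwmWidth(cp)
  expect_setequal(
    paste(L - w + 2L - rc_hits$pos, chartr("+-", "-+", rc_hits$strand)),
    paste(hits$pos, hits$strand)
  )
  # a sequence of exactly motif width has two windows (one per strand)
  short <- scanPwm("ACGTTGCA", cp, cal, z_min = -Inf)
  expect_equal(nrow(short), 2L)
  expect_setequal(short$strand, c("+", "-"))
  expect_error(scanPwm("ACG", cp, cal), "shorter")
  expect_error(scanPwm(seqc, cp, NULL), "calibration")
})

test_that("upper-tail p-values match the reported z bounds", {
  expect_equal(pNormUpper(0), 0.5)
  expect_equal(pNormUpper(2.86), 0.00212, tolerance = 2e-3)
  expect_lt(pNormUpper(2.86), 0.003)
  expect_equal(pNormUpper(2.68), 0.00368, tolerance = 2e-3)
  expect_lt(pNormUpper(2.68), 0.004)
  expect_error(pNormUpper(Inf), "finite")
  # strictly decreasing in z; complements sum to one
  zs <- seq(-4, 4, by = 0.25)
  expect_true(all(diff(pNormUpper(zs)) < 0))
  expect_true(all(abs(pNormUpper(zs) + pNormUpper(-zs) - 1) < 1e-12))
})

test_that("variant effects on hits are recomputed window differences", {
  set.seed(71)
  cp <- consensusPwm("ACGTACAC", weight = 0.9, pseudocount = 0.01)
  cal <- calibratePwm(cp, vapply(
    seq_len(40L),
    function(i) randomSeq(80), character(1L)
  ))
  # reference carries a one-off version of the consensus; the alt restores it
  ref <- paste0(randomSeq(30), "ACGTACAA", randomSeq(30))
  hits <- scanPwm(ref, cp, cal, z_min = -Inf)
  hit <- hits[hits$pos == 31L & hits$strand == "+", ]
  vd <- variantDelta(hit, pos = 38L, ref = "A", alt = "C", cp, ref)
  expect_equal(vd$direction, "increase")
  expect_equal(
    vd$delta,
    pwmScore("ACGTACAC", cp) - pwmScore("ACGTACAA", cp),
    tolerance = 1e-12
  )
  # alt equal to ref is neutral
  expect_equal(
    variantDelta(hit, 38L, "A", "A", cp, ref)$direction,
    "neutral"
  )
  # indels are unsupported
  expect_equal(
    variantDelta(hit, 38L, "AC", "A", cp, ref)$direction,
    "unsupported"
  )
  expect_error(variantDelta(hit, 5L, "A", "C", cp, ref), "intersect")
  # random SNVs: delta equals the two independently computed window scores
  for (rep in seq_len(10L)) {
    at <- sample(31:38, 1L)
    alt <- sample(c("A", "C", "G", "T"), 1L)
    win_ref <- substr(ref, 31L, 38L)
    win_alt <- win_ref
    substr(win_alt, at - 30L, at - 30L) <- alt
    vd2 <- variantDelta(hit, at, substr(ref, at, at), alt, cp, ref)
    expect_equal(vd2$delta,
      pwmScore(win_alt, cp) - pwmScore(win_ref, cp),
      tolerance = 1e-12
    )
  }
})
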