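boundSet <- boundSequences()

test_that("PFM counts equal a hand tally and conserve the sequence count", {
  toy <- c("CCTCGTGCATATCG", "CTTAGATTATATCG", "CATCGTTTATATCG")
  pfm <- buildPFM(toy)
  # independent per-column tally
  m <- do.call(rbind, strsplit(toy, ""))
  for (slot in 1:14)
    for (b in c("A", "C", "G", "T"))
      expect_equal(pfm@counts[slot, b], sum(m[, slot] == b))
  expect_equal(unname(rowSums(pfm@counts)), rep(3L, 14))

  single <- buildPFM("CCTCGTGCATATCG")
  expect_equal(unname(rowSums(single@counts == 1L)), rep(1L, 14))

  full <- buildPFM(boundSet)
  expect_equal(full@nSequences, 18L)
  expect_equal(unname(rowSums(full@counts)), rep(18L, 14))
  expect_error(buildPFM("CCTCG"), "14-mers")
  expect_error(buildPFM("ACTCGTGCATATCG"), "pattern")
})

test_that("PFM agrees with the Biostrings consensusMatrix oracle", {
  cm <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(boundSet))
  pfm <- buildPFM(boundSet)
  expect_equal(unname(t(cm[c("A", "C", "G", "T"), ])),
               unname(pfm@counts))
})

test_that("forbidden bases are exactly the zero-count bases per N position", {
  rep <- forbiddenAndBias(buildPFM(boundSet))
  expect_true("G" %in% rep@forbidden$N1)
  expect_true("G" %in% rep@forbidden$N2)
  expect_true("C" %in% rep@forbidden$N3)
  expect_true("A" %in% rep@forbidden$N4)
  expect_true("C" %in% rep@forbidden$N6)
  expect_true("G" %in% rep@forbidden$N8)
  expect_true("G" %in% rep@forbidden$N9)
  # N5 and N7 admit all four bases in the packaged bound set
  expect_equal(rep@forbidden$N5, character(0))
  expect_equal(rep@forbidden$N7, character(0))
  expect_equal(rep@bias$N2$base, "C")
  expect_equal(rep@bias$N6$base, "A")
  # a single sequence forbids every base it does not show
  one <- forbiddenAndBias(buildPFM("CCTCGTGCATATCG"))
  expect_true(all(vapply(one@forbidden, length, integer(1)) == 3L))
  expect_true(all(vapply(one@bias, function(b) b$prob, numeric(1)) == 1))
})

test_that("forbidden/bias detection ignores input order and ties report sets", {
  set.seed(9)
  a <- forbiddenAndBias(buildPFM(boundSet))
  b <- forbiddenAndBias(buildPFM(sample(boundSet)))
  expect_equal(a@forbidden, b@forbidden)
  expect_equal(a@bias, b@bias)
  tie <- forbiddenAndBias(buildPFM(c("CATCGAAAAAAACG", "CCTCGAAAAAAACG")))
  expect_setequal(tie@bias$N1$base, c("A", "C"))
})

test_that("no training sequence contains a base forbidden by its own set", {
  rep <- forbiddenAndBias(buildPFM(boundSet))
  nSlots <- c(2, 4, 6, 7, 8, 9, 10, 11, 12)
  for (s in boundSet) {
    ch <- substring(s, 1:14, 1:14)
    for (k in 1:9)
      expect_false(ch[nSlots[k]] %in% rep@forbidden[[paste0("N", k)]])
  }
})

test_that("PPM normalisation follows the pseudocount arithmetic", {
  pfm <- buildPFM(rep("CCTCGTGCATATCG", 18))
  ppm0 <- buildPPM(pfm, 0)
  expect_equal(unname(ppm0@probs[2, ]), c(0, 1, 0, 0))  # counts (0,18,0,0)
  expect_equal(unname(rowSums(ppm0@probs)), rep(1, 14))
  # counts (9,9,0,0) with pseudocount 1 -> (10, 10, 1, 1)/22
  mix <- buildPPM(buildPFM(c(rep("CATCGAAAAAAACG", 9),
                             rep("CCTCGAAAAAAACG", 9))), 1)
  expect_equal(unname(mix@probs[2, ]), c(10, 10, 1, 1) / 22)
  expect_error(buildPPM(pfm, -1), "pseudocount")
})

test_that("PWM weights are per-cell log2 odds against the background", {
  ppm <- buildPPM(buildPFM(boundSet), 0.5)
  bg <- c(0.3, 0.2, 0.2, 0.3)
  pwm <- buildPWM(ppm, bg)
  for (slot in c(1, 4, 9, 14))
    for (j in 1:4)
      expect_equal(pwm@weights[slot, j], log2(ppm@probs[slot, j] / bg[j]))
  # uniform vs uniform is identically zero
  u <- new("PositionProbabilityMatrix",
           probs = matrix(0.25, 14, 4, dimnames = list(paste0("pos", 1:14),
                                                       c("A", "C", "G", "T"))),
           pseudocount = 0)
  expect_true(all(buildPWM(u)@weights == 0))
  expect_error(buildPWM(ppm, c(1, 0, 0, 0)), "background")
})

test_that("sequence scoring equals a brute-force per-position lookup", {
  pwm <- buildPWM(buildPPM(buildPFM(boundSet), 0.5))
  set.seed(31)
  for (rep in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 14, replace = TRUE),
               collapse = "")
    manual <- sum(vapply(1:14, function(i)
      pwm@weights[i, substr(s, i, i)], numeric(1)))
    expect_equal(scoreSequence(pwm, s), manual)
  }
  # the per-slot argmax sequence outscores any single substitution
  best <- paste(c("A", "C", "G", "T")[apply(pwm@weights, 1, which.max)],
                collapse = "")
  for (i in 1:14) for (b in c("A", "C", "G", "T")) {
    v <- best; substr(v, i, i) <- b
    expect_lte(scoreSequence(pwm, v), scoreSequence(pwm, best))
  }
})

test_that("the bound-set consensus reproduces the sunflower motif", {
  ppm <- buildPPM(buildPFM(boundSet), 0)
  expect_equal(iupacConsensus(ppm), "CHTCGWKWAYWYCG")
})

test_that("IUPAC consensus thresholds behave as documented", {
  ppm <- buildPPM(buildPFM(boundSet), 0)
  # inclusion mode at a vanishing threshold covers every observed base
  wide <- iupacConsensus(ppm, mode = "inclusion", includeThreshold = 1e-9)
  m <- buildPFM(boundSet)@counts
  codes <- list(A = "A", C = "C", G = "G", T = "T", AC = "M", AG = "R",
                AT = "W", CG = "S", CT = "Y", GT = "K", ACG = "V",
                ACT = "H", AGT = "D", CGT = "B", ACGT = "N")
  for (slot in c(2, 4, 6, 7, 8, 9, 10, 11, 12)) {
    observed <- sort(c("A", "C", "G", "T")[m[slot, ] > 0])
    expect_equal(substr(wide, slot, slot),
                 codes[[paste(observed, collapse = "")]])
  }
  # raising the threshold never widens any slot's code
  degeneracy <- c(A = 1, C = 1, G = 1, T = 1, M = 2, R = 2, W = 2, S = 2,
                  Y = 2, K = 2, V = 3, H = 3, D = 3, B = 3, N = 4)
  prev <- rep(5, 14)
  for (t in c(0.01, 0.1, 0.2, 0.3, 0.45)) {
    cons <- iupacConsensus(ppm, mode = "inclusion", includeThreshold = t)
    cur <- degeneracy[strsplit(cons, "")[[1]]]
    expect_true(all(cur <= prev))
    prev <- cur
  }
  # collapse rule: a dominant base wins the slot outright
  toy <- buildPPM(buildPFM(c(rep("CATCGAAAAAAACG", 17),
                             "CCTCGAAAAAAACG")), 0)
  expect_equal(substr(iupacConsensus(toy, collapseThreshold = 0.6), 2, 2),
               "A")
  expect_error(iupacConsensus(ppm, includeThreshold = 0), "thresholds")
})

test_that("matrix exports are readable and MEME probabilities are intact", {
  ppm <- buildPPM(buildPFM(boundSet), 0.5)
  tsv <- tempfile(fileext = ".tsv")
  writeMatrixTSV(ppm, tsv)
  back <- read.delim(tsv)
  expect_equal(as.matrix(back[, c("A", "C", "G", "T")]),
               unname(ppm@probs), ignore_attr = TRUE, tolerance = 1e-12)
  meme <- tempfile(fileext = ".meme")
  writeMEME(ppm, meme)
  lines <- readLines(meme)
  expect_true(any(grepl("^MOTIF", lines)))
  probLines <- lines[grepl("^[0-9]", lines)]
  expect_equal(length(probLines), 14L)
  vals <- do.call(rbind, lapply(strsplit(probLines, " "), as.numeric))
  expect_equal(vals, unname(ppm@probs), tolerance = 1e-6)
  logo <- textLogo(ppm, file = tempfile())
  expect_equal(length(logo), 14L)
})
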