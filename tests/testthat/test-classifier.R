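fx <- loadAWBoxFixtures()
prof <- fitProfile(boundSequences(fx))

test_that("the fitted profile mirrors the forbidden-base analysis", {
  expect_false("G" %in% prof@allowed$N2)
  expect_false("C" %in% prof@allowed$N6)
  expect_equal(prof@bias$N2, "C")
  expect_equal(prof@bias$N6, "A")
  expect_equal(prof@nSequences, 18L)
  # training order does not matter
  set.seed(4)
  prof2 <- fitProfile(sample(boundSequences(fx)))
  expect_equal(prof@allowed, prof2@allowed)
  # single-sequence training yields singleton allowed sets
  solo <- fitProfile("CCTCGTGCATATCG")
  expect_true(all(vapply(solo@allowed, length, integer(1)) == 1L))
  expect_error(fitProfile(character(0)), "empty")
})

test_that("published non-binders are rejected with the right position named", {
  p1 <- predictBinding(prof, "CTTGGAGTACTCCG")  # single violation at N2
  expect_equal(p1$label, "not-bindable")
  expect_equal(p1$reasons, "forbidden base G at N2")
  p2 <- predictBinding(prof, "CATCGTCTCCTCCG")  # single violation at N6
  expect_equal(p2$label, "not-bindable")
  expect_equal(p2$reasons, "forbidden base C at N6")
  p3 <- predictBinding(prof, "CCTCGTGCATATCG", tisStart = -110)
  expect_equal(p3$label, "bindable")
  expect_equal(p3$reasons, character(0))
  expect_error(predictBinding(prof, "ACTCGTGCATATCG"), "canonical")
})

test_that("the distance gate folds into predictions when coordinates are given", {
  near <- predictBinding(prof, "CCTCGTGCATATCG", tisStart = -110)
  far <- predictBinding(prof, "CCTCGTGCATATCG", tisStart = -900)
  expect_equal(near$label, "bindable")
  expect_equal(far$label, "not-bindable")
  expect_match(far$reasons, "max distance")
})

test_that("insertion variants are routed past the canonical rule", {
  p <- predictBinding(prof, "CTTTAGGTTATATCG")
  expect_equal(p$variant, "insertion")
  expect_equal(p$label, "bindable")  # extra-base boxes have bound precedent
  expect_error(predictBinding(prof, "CTTCGTGCATATCGG"), "not a valid")
})

test_that("predictions are pure and deterministic", {
  a <- predictBinding(prof, "CTTGGAGTACTCCG", tisStart = -277)
  b <- predictBinding(prof, "CTTGGAGTACTCCG", tisStart = -277)
  expect_identical(a, b)
})

test_that("no training sequence is rejected by the rule it trained", {
  for (s in boundSequences(fx)) {
    expect_equal(predictBinding(prof, s)$label, "bindable")
    expect_equal(predictBinding(prof, s, mode = "allowed-profile")$label,
                 "bindable")
  }
})

test_that("N-position mutagenesis reproduces the published probe sequences", {
  kar1 <- "CTTAGATTATATCG"
  expect_equal(mutateNPosition(kar1, 2, "C"), "CTTCGATTATATCG")  # mut A/C
  expect_equal(mutateNPosition(kar1, 3, "G"), "CTTAGGTTATATCG")  # mut A/G
  expect_equal(mutateNPosition(kar1, 2, "A"), kar1)              # identity
  # reverting a mutation restores the original
  m <- mutateNPosition(kar1, 5, "G")
  expect_equal(mutateNPosition(m, 5, "T"), kar1)
  expect_error(mutateNPosition(kar1, 10, "A"), "1..9")
})

test_that("15-mer mutagenesis respects the inserted-base offset", {
  kar2 <- "CTTTAGGTTATATCG"
  # N2 sits one slot later than in a 14-mer when the extra base precedes it
  expect_equal(mutateNPosition(kar2, 2, "C", insertionOffset = 4),
               "CTTTCGGTTATATCG")
  expect_error(mutateNPosition(kar2, 2, "C"), "insertionOffset")
  expect_equal(substituteInsertedBase(kar2, "C", offset = 4),
               "CTTCAGGTTATATCG")                               # mut T/C
  expect_equal(substituteInsertedBase(kar2, "T", offset = 4), kar2)
  expect_error(substituteInsertedBase("CTTAGATTATATCG", "C", 4), "15-mer")
  # the substituted probe still scans as an insertion variant
  h <- scanAWBox(embedBox(substituteInsertedBase(kar2, "C", 4)),
                 strands = "plus", maxInsertions = 1)
  expect_equal(nrow(h), 1L)
  expect_equal(h$variant, "insertion")
})

test_that("EMSA probes pad the box with exact-complement flanks", {
  p <- buildProbe("CCTCGTGCATATCG", flankLength = 5, seed = 7)
  expect_equal(p$length, 24L)
  expect_equal(p$bottom, revComp(p$top))
  expect_equal(substr(p$top, 6, 19), "CCTCGTGCATATCG")
  expect_identical(buildProbe("CCTCGTGCATATCG", 5, seed = 7), p)
  p0 <- buildProbe("CCTCGTGCATATCG", 0)
  expect_equal(p0$top, "CCTCGTGCATATCG")
  given <- buildProbe("CCTCGTGCATATCG", 2, flanks = c("AA", "TT"))
  expect_equal(given$top, "AACCTCGTGCATATCGTT")
})

test_that("evaluation matches a per-record brute-force forbidden check", {
  res <- evaluateProfile(prof, fx)
  expect_equal(nrow(res$table), 43L)  # 18 bound + 25 unbound
  expect_equal(nrow(res$smear), 9L)
  expect_equal(unname(res$confusion["bound", "bindable"]), 18L)
  expect_equal(unname(res$confusion["bound", "not-bindable"]), 0L)

  # independent route: recompute forbidden content from raw tallies
  nSlots <- c(2, 4, 6, 7, 8, 9, 10, 11, 12)
  bound <- boundSequences(fx)
  forb <- lapply(nSlots, function(slot) {
    seen <- unique(substr(bound, slot, slot))
    setdiff(c("A", "C", "G", "T"), seen)
  })
  unbound <- selectBoxes(fx, testedOnly = TRUE, label = "unbound",
                         canonicalOnly = TRUE)
  hasForbidden <- vapply(unbound$seq, function(s)
    any(mapply(function(slot, f) substr(s, slot, slot) %in% f,
               nSlots, forb)), logical(1))
  expect_equal(unname(res$confusion["unbound", "not-bindable"]),
               sum(hasForbidden))
  # the documented exceptions: unbound boxes free of forbidden bases
  expect_equal(unname(res$confusion["unbound", "bindable"]),
               sum(!hasForbidden))
  expect_error(evaluateProfile(prof, fx[0, ]), "empty")
})

test_that("allowed-profile mode rejects at least whatever strict mode rejects", {
  narrowed <- prof
  narrowed@allowed$N5 <- c("A", "T")  # externally narrowed profile
  set.seed(19)
  for (rep in 1:50) {
    s <- paste(c("C", sample(c("A", "C", "G", "T"), 1), "T",
                 sample(c("A", "C", "G", "T"), 1), "G",
                 sample(c("A", "C", "G", "T"), 7, replace = TRUE),
                 "C", "G")[c(1:5, 6:12, 13, 14)], collapse = "")
    strict <- predictBinding(prof, s, mode = "strict-forbidden")$label
    allowed <- predictBinding(narrowed, s, mode = "allowed-profile")$label
    if (strict == "not-bindable") expect_equal(allowed, "not-bindable")
  }
})

test_that("profiles survive a JSON round-trip", {
  f <- tempfile(fileext = ".json")
  writeProfileJSON(prof, f)
  back <- readProfileJSON(f)
  expect_equal(back@allowed, prof@allowed)
  expect_equal(back@bias, prof@bias)
  expect_equal(back@pwm@weights, prof@pwm@weights)
  expect_equal(predictBinding(back, "CTTGGAGTACTCCG"),
               predictBinding(prof, "CTTGGAGTACTCCG"))
})
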