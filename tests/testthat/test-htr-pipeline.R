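test_that("threshold calibration reproduces the control-pair rule", {
  # control set whose maximum identity is 98.21% with near-identical
  # matches of 11,414 and 6,972 bp
  lens <- c(11414, 6972, 3000, 1500)
  b <- mkBlocks(rep(0, 4), lens, matched = round(c(0.9821, 0.982, 0.98, 0.9) *
                                                   lens),
                qlen = 2e6, tlen = 2e6)
  thr <- calibrateThresholds(b)
  expect_equal(identityThreshold(thr), 98)
  expect_equal(lengthThreshold(thr), 7000)
  expect_false(thr@underpowered)
  expect_equal(thr@provenance$longest_control_match, 11414)
  expect_equal(thr@provenance$second_longest_control_match, 6972)

  # single qualifying match: longest used, flagged under-powered
  one <- mkBlocks(0, 5000, matched = 4950, qlen = 1e5, tlen = 1e5)
  thr1 <- calibrateThresholds(one)
  expect_equal(identityThreshold(thr1), 99)
  expect_equal(lengthThreshold(thr1), 5000)
  expect_true(thr1@underpowered)

  # implausibly low identities floor below 50 and warn
  low <- mkBlocks(c(0, 0), c(2000, 1500), matched = c(900, 600),
                  qlen = 1e5, tlen = 1e5)
  expect_warning(thr2 <- calibrateThresholds(low), "implausibly low")
  expect_lte(identityThreshold(thr2), 49)

  # no qualifying matches at all
  short <- mkBlocks(0, 500, matched = 500, qlen = 1e5, tlen = 1e5)
  expect_error(calibrateThresholds(short), "control")
})

test_that("candidate detection keeps, projects and merges matches correctly", {
  thr <- thresholds98()
  # below length threshold: excluded
  pm <- list(list(strainA = "ra", strainB = "rb",
                  blocks = mkBlocks(0, 6900, matched = 6831,
                                    qname = "ra_c1", tname = "rb_c1",
                                    qlen = 1e5, tlen = 1e5)))
  cand <- detectCandidates(pm, thr, "ra", "rb")
  expect_equal(nrow(cand), 0L)
  # two kept matches overlapping by 1 bp merge into one candidate
  b <- mkBlocks(c(0, 9999), c(10000, 20000), matched = c(9900, 9901),
                qname = "ra_c1", tname = "rb_c1", qlen = 1e5, tlen = 1e5)
  cand <- detectCandidates(list(list(strainA = "ra", strainB = "rb",
                                     blocks = b)), thr, "ra", "rb")
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$start, 0)
  expect_equal(cand$end, 20000)
  # weighted mean identity
  expect_equal(cand$meanIdentity, 100 * (9900 + 9901) / 20001)
  # missing reference designation
  expect_error(detectCandidates(list(), thr, "", "rb"), "reference")
})

test_that("a planted HTR seen by several strain pairs yields one candidate near truth", {
  p <- smallPanel(seed = 41, htrs = 20000, identity = 0.995, strains = 2)
  pm <- panelPairMatches(p)
  expect_equal(length(pm$pairMatches), 4L)
  cand <- detectCandidates(pm$pairMatches, thresholds98(), pm$refA, pm$refB,
                           pm$liftA, pm$liftB)
  expect_equal(nrow(cand), 1L)
  expect_gte(cand$nPairs, 3L)
  truth <- p$truth$htrs[p$truth$htrs$species == 1, ]
  expect_lte(abs(cand$start - truth$start), 1000)
  expect_lte(abs(cand$end - truth$end), 1000)
  # detection is invariant under permutation of the match input order
  perm <- pm$pairMatches[c(3, 1, 4, 2)]
  perm <- lapply(perm, function(e) {
    e$blocks <- e$blocks[rev(seq_len(length(e$blocks)))]
    e
  })
  cand2 <- detectCandidates(perm, thresholds98(), pm$refA, pm$refB,
                            pm$liftA, pm$liftB)
  expect_equal(as.data.frame(cand2), as.data.frame(cand))
})

test_that("TE masking drops candidates below the unmasked floor", {
  te <- GenomicRanges::GRanges("c1", IRanges::IRanges(1, 9700))
  cand <- S4Vectors::DataFrame(id = c("HTR_01", "HTR_02"), contig = "c1",
                               start = c(0, 20000), end = c(10000, 30000))
  cons <- maskAndFilter(cand, te)
  expect_equal(nrow(cons), 1L)
  expect_equal(cons$id, "HTR_02")
  expect_equal(cons$teFraction, 0)
  expect_equal(cons$unmaskedLength, 10000)
  expect_equal(S4Vectors::metadata(cons)$nDropped, 1L)
})

test_that("a 26-candidate set with 3 falling below 500 bp unmasked retains 23", {
  # 23 TE-free candidates plus 3 whose TE overlap leaves under 500 bp
  starts <- seq(0, by = 20000, length.out = 26)
  cand <- S4Vectors::DataFrame(id = sprintf("HTR_%02d", 1:26),
                               contig = "c1", start = starts,
                               end = starts + 10000)
  te <- GenomicRanges::GRanges("c1",
                               IRanges::IRanges(starts[24:26] + 1,
                                                starts[24:26] + 9700))
  cons <- maskAndFilter(cand, te)
  expect_equal(nrow(cons), 23L)
  expect_equal(S4Vectors::metadata(cons)$nDropped, 3L)
})

test_that("extremity report flags TE context and uses an infinite sentinel", {
  cons <- S4Vectors::DataFrame(id = "HTR_01", contig = "c1", start = 0,
                               end = 10000)
  te <- GenomicRanges::GRanges("c1", IRanges::IRanges(1, 50))
  rep <- extremityTeReport(cons, te)
  left <- rep$perExtremity[rep$perExtremity$side == "left", ]
  right <- rep$perExtremity[rep$perExtremity$side == "right", ]
  expect_true(left$in_te)
  expect_equal(left$distance, 0)
  expect_false(right$in_te)
  expect_equal(right$distance, 10000 - 50 - 1)
  # no TE on the contig: infinite distance
  rep2 <- extremityTeReport(cons, GenomicRanges::GRanges("other",
                                                         IRanges::IRanges(1, 10)))
  expect_true(all(is.infinite(rep2$perExtremity$distance)))
})

test_that("edge-planted TEs are recovered at the expected extremity fraction", {
  p <- smallPanel(seed = 51, htrs = c(20000, 15000, 12000), identity = 0.995,
                  strains = 1, te = TRUE, L = 2.5e5)
  truth <- p$truth$htrs[p$truth$htrs$species == 1, ]
  cons <- S4Vectors::DataFrame(id = truth$htr_id, contig = truth$contig,
                               start = truth$start, end = truth$end)
  rep <- extremityTeReport(cons, p$te[p$te$species == 1])
  expect_equal(rep$summary$fracInTe, 1)  # every planted end overlaps a TE
})

test_that("plotting merge is an overlap merge with a length floor", {
  cons <- S4Vectors::DataFrame(id = c("a", "b"), contig = "c1",
                               start = c(0, 40000), end = c(20000, 60000))
  m <- mergeForPlotting(cons, minMerged = 35000)
  expect_equal(nrow(m$merged), 0L)   # 20 kbp apart, both below floor
  cons2 <- S4Vectors::DataFrame(id = c("a", "b"), contig = "c1",
                                start = c(0, 15000), end = c(20000, 35000))
  m2 <- mergeForPlotting(cons2, minMerged = 35000)
  expect_equal(nrow(m2$merged), 1L)
  expect_equal(m2$cumulativeLength, 35000)
  expect_equal(mergeForPlotting(S4Vectors::DataFrame(
    id = character(0), contig = character(0), start = numeric(0),
    end = numeric(0)))$cumulativeLength, 0)
  # merging is idempotent
  m3 <- mergeForPlotting(S4Vectors::DataFrame(
    id = "x", contig = m2$merged$contig, start = m2$merged$start,
    end = m2$merged$end), minMerged = 35000)
  expect_equal(m3$merged, m2$merged)
  # candidate length sum bounds the merged-for-plotting sum
  expect_gte(sum(cons2$end - cons2$start), m2$cumulativeLength)
})
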