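test_that("match-keeping applies the three rules and the edge cap", {
  clen <- c(big = 5e5, small = 12000)
  # rule 1: spans the whole HTR
  full <- mkBlocks(0, 10000, ts = 1000, te = 11000, matched = 9900,
                   qname = "HTR_01", tname = "big", qlen = 10000,
                   tlen = 5e5)
  kept <- keepMatches(full, 10000, clen)
  expect_equal(kept$rule, "full_htr")
  # rule 2: covers an entire (small) contig with >= 1 kbp matched
  contig <- mkBlocks(0, 11800, ts = 100, te = 11900, matched = 11700,
                     qname = "HTR_01", tname = "small", qlen = 20000,
                     tlen = 12000)
  expect_equal(keepMatches(contig, 20000, clen)$rule, "full_contig")
  # rule 3: three 12-kbp edge matches, only the two longest kept
  edges <- mkBlocks(c(0, 20000, 40000), c(12000, 32500, 52000),
                    ts = c(0, 0, 488000), te = c(12000, 12500, 5e5),
                    matched = c(11900, 12400, 11880),
                    qname = "HTR_01", tname = "big", qlen = 60000,
                    tlen = 5e5)
  k3 <- keepMatches(edges, 60000, clen)
  expect_equal(nrow(k3), 2L)
  expect_true(all(k3$rule == "contig_edge"))
  expect_equal(sort(k3$block_length), c(12000, 12500))
  # 9-kbp edge match failing every rule is dropped
  small9 <- mkBlocks(0, 9000, ts = 0, te = 9000, matched = 8900,
                     qname = "HTR_01", tname = "big", qlen = 60000,
                     tlen = 5e5)
  expect_equal(nrow(keepMatches(small9, 60000, clen)), 0L)
  # unknown contig errors
  expect_error(keepMatches(full, 10000, c(other = 100)), "unknown contig")
})

test_that("presence fraction and identity follow the union formulas", {
  k1 <- as.data.frame(mkBlocks(c(0, 5000), c(4000, 8000),
                               ts = c(0, 6000), te = c(4000, 9000),
                               matched = c(3960, 2970),
                               qname = "HTR_01", tname = "c1",
                               qlen = 10000, tlen = 5e5))
  k1$rule <- "full_contig"
  pr <- presenceIdentity(k1, 10000)
  expect_equal(pr$fraction, 0.70)
  expect_equal(pr$identity, 100 * (3960 + 2970) / 7000)
  # overlapping matches: union counted once
  k2 <- as.data.frame(mkBlocks(c(0, 3000), c(4000, 6000),
                               ts = c(0, 3000), te = c(4000, 6000),
                               matched = c(4000, 3000),
                               qname = "HTR_01", tname = "c1",
                               qlen = 10000, tlen = 5e5))
  expect_equal(presenceIdentity(k2, 10000)$fraction, 0.60)
  # empty input
  pr0 <- presenceIdentity(k1[0, ], 10000)
  expect_equal(pr0$fraction, 0)
  expect_true(is.na(pr0$identity))
  # permutation invariance
  expect_equal(presenceIdentity(k1[2:1, ], 10000)[c("fraction", "identity")],
               pr[c("fraction", "identity")])
  # ambiguous positions can be excluded from both terms
  pra <- presenceIdentity(k2, 10000, excludeAmbiguous = TRUE)
  # [3000,4000) is doubly covered: union once-only = 5000, denom = 9000
  expect_equal(pra$fraction, 5000 / 9000)
})

test_that("a match failing every rule never changes the presence record", {
  clen <- c(c1 = 5e5)
  base <- as.data.frame(mkBlocks(0, 10000, ts = 1000, te = 11000,
                                 matched = 9900, qname = "HTR_01",
                                 tname = "c1", qlen = 10000, tlen = 5e5))
  failing <- as.data.frame(mkBlocks(2000, 7000, ts = 100000, te = 105000,
                                    matched = 4500, qname = "HTR_01",
                                    tname = "c1", qlen = 10000, tlen = 5e5))
  k_with <- keepMatches(MatchBlocks(rbind(base, failing)), 10000, clen)
  k_without <- keepMatches(MatchBlocks(base), 10000, clen)
  expect_equal(presenceIdentity(k_with, 10000)[c("fraction", "identity")],
               presenceIdentity(k_without, 10000)[c("fraction", "identity")])
})

test_that("panel scanning recovers planted presence and absence", {
  p <- smallPanel(seed = 61, htrs = c(20000, 12000), identity = 0.995,
                  strains = 1, L = 2e5)
  truth <- p$truth$htrs[p$truth$htrs$species == 1, ]
  cons <- Biostrings::DNAStringSet(vapply(seq_len(nrow(truth)), function(i)
    substr(as.character(p$assemblies[["sp1_s1"]][[1]]),
           truth$start[i] + 1, truth$end[i]), character(1)))
  names(cons) <- truth$htr_id
  # a third, unrelated genome carries no HTR
  absent <- simulatePanel(simulationConfig(seed = 999, genomeLength = 1e5,
                                           nStrainsPerSpecies = 1,
                                           theta = 0))$assemblies[["sp1_s1"]]
  panel <- c(p$assemblies, list(outgroup = absent))
  pmat <- panelMatrix(panel, cons)
  expect_true(all(pmat$fraction["sp1_s1", ] > 0.9))
  expect_true(all(pmat$fraction["sp2_s1", ] > 0.9))
  expect_true(all(pmat$fraction["outgroup", ] < 0.05))
  expect_true(all(pmat$identity["sp1_s1", ] > 99.5))
  # tree ordering errors on mismatched leaves
  tr <- ape::read.tree(text = "((sp1_s1,sp2_s1),wrong);")
  expect_error(panelMatrix(panel, cons, tree = tr), "wrong")
})

test_that("genome size regresses on HTR content as expected", {
  r <- suppressWarnings(genomeSizeRegression(1:5, 1:5))
  expect_equal(r$adjR2, 1.0)
  expect_equal(r$slope, 1.0)
  set.seed(71)
  x <- rnorm(100)
  y <- rnorm(100)
  expect_lte(genomeSizeRegression(x, y)$adjR2, 0.05)
  # sizes differing only by HTR content plus small noise
  set.seed(72)
  htr <- runif(20, 0, 5e5)
  size <- 3e7 + htr + rnorm(20, 0, 2e4)
  expect_gte(genomeSizeRegression(htr, size)$adjR2, 0.9)
  expect_error(genomeSizeRegression(rep(1, 5), 1:5), "variance")
  expect_error(genomeSizeRegression(1:2, 1:2), "3 genomes")
})
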