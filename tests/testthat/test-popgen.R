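test_that("hard filters remove and tally failing sites", {
  path <- tempfile(fileext = ".vcf")
  hdr <- c("##fileformat=VCFv4.2",
           "##contig=<ID=chr1,length=10000>",
           "##INFO=<ID=QD,Number=1,Type=Float,Description=\"x\">",
           "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"x\">",
           "##INFO=<ID=FS,Number=1,Type=Float,Description=\"x\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"x\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3")
  rec <- function(pos, ref, alt, info, gts)
    paste(c("chr1", pos, ".", ref, alt, "100", "PASS", info, "GT", gts),
          collapse = "\t")
  ok <- "QD=20;MQ=55;FS=3"
  writeLines(c(hdr,
               rec(100, "A", "T", ok, c("0", "1", "1")),
               rec(200, "A", "T", "QD=1.5;MQ=55;FS=3", c("0", "1", "1")),
               rec(300, "A", "T", "QD=20;MQ=30;FS=3", c("0", "1", "1")),
               rec(400, "A", "T", "QD=20;MQ=55;FS=70", c("0", "1", "1")),
               rec(500, "A", "T,G", ok, c("0", "1", "2")),
               rec(600, "AT", "A", ok, c("0", "1", "1")),
               rec(700, "A", "T", ok, c(".", ".", "1"))), path)
  vt <- filterVcf(path)
  expect_equal(nSites(vt), 1L)
  expect_equal(variantInfo(vt)$pos, 100)
  log <- filterLog(vt)
  expect_equal(log$removed[log$filter == "QD"], 1L)
  expect_equal(log$removed[log$filter == "MQ"], 1L)
  expect_equal(log$removed[log$filter == "FS"], 1L)
  expect_equal(log$removed[log$filter == "non_biallelic"], 1L)
  expect_equal(log$removed[log$filter == "indel"], 1L)
  expect_equal(log$removed[log$filter == "missing"], 1L)
  expect_equal(genomeLength(vt), 10000)
  # diploid records are rejected with advice
  writeLines(c(hdr, rec(100, "A", "T", ok, c("0/0", "0/1", "1/1"))), path)
  expect_error(filterVcf(path), "haploid")
})

test_that("the worked diversity example matches the independent oracle", {
  geno <- rbind(c(0L, 0L, 1L, 1L), c(0L, 1L, 0L, 1L))
  vt <- vtFromGeno(geno, 10, pos = c(3, 7))
  d <- diversity(vt)
  expect_equal(d@pi, 0.13333, tolerance = 1e-4)
  expect_equal(d@thetaW, 0.10909, tolerance = 1e-4)
  expect_equal(d@tajimaD, 1.89, tolerance = 0.01)
  o <- bruteDiversity(geno, 10)
  expect_equal(d@pi, o$pi)
  expect_equal(d@thetaW, o$thetaW)
  expect_equal(d@tajimaD, o$D)
})

test_that("diversity agrees with brute force across random instances", {
  set.seed(81)
  for (i in 1:200) {
    n <- sample(2:8, 1)
    S <- sample(1:50, 1)
    L <- S + sample(10:100, 1)
    geno <- matrix(sample(0:1, S * n, replace = TRUE), S, n)
    # ensure at least one segregating row to exercise D
    geno[1, ] <- c(0L, 1L, sample(0:1, n - 2, replace = TRUE))
    vt <- vtFromGeno(geno, L, pos = sort(sample.int(L, S)))
    d <- diversity(vt)
    o <- bruteDiversity(geno, L)
    expect_equal(d@pi, o$pi)
    expect_equal(d@thetaW, o$thetaW)
    expect_equal(d@S, o$S)
    if (o$S > 0) expect_equal(d@tajimaD, o$D)
  }
})

test_that("identical haplotypes and missing data behave sensibly", {
  vt <- vtFromGeno(matrix(0L, 0, 4), 100)
  d <- diversity(vt)
  expect_equal(d@pi, 0)
  expect_equal(d@thetaW, 0)
  expect_true(is.na(d@tajimaD))
  # a site that is only missing-vs-one-allele is not segregating
  geno <- rbind(c(0L, NA, 0L, 0L), c(0L, 1L, NA, 1L))
  d2 <- diversity(vtFromGeno(geno, 100))
  expect_equal(d2@S, 1)
  # pairwise-complete pi at the informative site: n0=1, n1=2, nt=3
  expect_equal(d2@pi, (2 * 1 * 2 / (3 * 2)) / 100)
})

test_that("neutral coalescent D is centred near zero with a calibrated null interval", {
  ds <- vapply(1:100, function(i) {
    vt <- simulateVariants(simulationConfig(seed = 8200 + i, theta = 0.005,
                                            genomeLength = 2e4,
                                            nStrainsPerSpecies = 20))
    diversity(vt)@tajimaD
  }, numeric(1))
  # band scaled to 100 replicates: |bias| ~0.05 plus ~1.7 se (0.089)
  expect_lt(abs(mean(ds, na.rm = TRUE)), 0.2)
  ci <- tajimaNullCI(20, 40, reps = 2000)
  expect_lt(ci[1], -1)
  expect_gt(ci[2], 1)
})

test_that("r-squared matches the allelic-correlation oracle and LD decays as built", {
  set.seed(83)
  # identical vectors give r2 = 1
  x <- sample(0:1, 50, replace = TRUE)
  g <- rbind(x, x)
  vt <- vtFromGeno(g, 10000, pos = c(100, 600))
  ld <- ldDecay(vt, window = 15000, mafMin = 0.2, binWidth = 1000)
  expect_equal(ld$mean_r2, 1)
  # independent 50/50 vectors, many strains: mean r2 near zero
  n <- 1000
  g2 <- matrix(sample(0:1, 50 * n, replace = TRUE), 50, n)
  vt2 <- vtFromGeno(g2, 5e4, pos = sort(sample.int(5e4, 50)))
  ld2 <- ldDecay(vt2, window = 5e4, mafMin = 0.2, binWidth = 5e4)
  expect_lte(sum(ld2$mean_r2 * ld2$n_pairs) / sum(ld2$n_pairs), 0.01)
  # oracle agreement on a handful of site pairs
  for (i in 1:5) {
    a <- sample(0:1, 40, replace = TRUE)
    b <- sample(0:1, 40, replace = TRUE)
    vt3 <- vtFromGeno(rbind(a, b), 1000, pos = c(10, 20))
    ld3 <- ldDecay(vt3, window = 1000, mafMin = 0, binWidth = 1000)
    expect_equal(ld3$mean_r2, bruteR2(a, b), tolerance = 1e-10)
  }
})

test_that("LD pruning follows the window rule and is a fixed point", {
  x <- c(rep(0L, 10), rep(1L, 10))
  y <- sample(0:1, 20, replace = TRUE)
  # duplicate sites 500 bp apart: second dropped
  vt <- vtFromGeno(rbind(x, x), 5000, pos = c(1000, 1500))
  pr <- ldPrune(vt)
  expect_equal(nSites(pr), 1L)
  expect_equal(variantInfo(pr)$pos, 1000)
  # same duplicates 2 kbp apart: outside the window, both retained
  vt2 <- vtFromGeno(rbind(x, x), 5000, pos = c(1000, 3000))
  expect_equal(nSites(ldPrune(vt2)), 2L)
  # singletons dropped by the minor-allele rule
  s <- c(1L, rep(0L, 29))
  vt3 <- vtFromGeno(rbind(x[1:30], s), 5000, pos = c(1000, 3000))
  expect_equal(nSites(ldPrune(vt3)), 1L)
  # pruning twice changes nothing
  set.seed(84)
  g <- matrix(sample(0:1, 60 * 12, replace = TRUE), 60, 12)
  vt4 <- vtFromGeno(g, 2e4, pos = sort(sample.int(2e4, 60)))
  p1 <- ldPrune(vt4)
  p2 <- ldPrune(p1)
  expect_equal(variantInfo(p2)$pos, variantInfo(p1)$pos)
  # every retained pair within the window is below the threshold
  ip <- variantInfo(p1)$pos
  gg <- genotypes(p1)
  for (i in seq_along(ip))
    for (j in seq_len(i - 1))
      if (ip[i] - ip[j] <= 1000) {
        r <- suppressWarnings(cor(gg[i, ], gg[j, ]))
        if (!is.na(r)) expect_lt(r^2, 0.2)
      }
})

test_that("mating types are called from planted idiomorphs", {
  cfg <- simulationConfig(seed = 91, genomeLength = 6e4,
                          nStrainsPerSpecies = 5, theta = 0.002,
                          nSpecies = 1)
  mt_truth <- c("MAT1-1", "MAT1-2", "MAT1-2", "MAT1-1", "MAT1-2")
  p <- simulatePanel(cfg, matingTypes = mt_truth)
  res <- matingTypeSummary(p$assemblies, p$matRefs)
  expect_equal(unname(res$calls), mt_truth)
  expect_equal(unname(res$counts["MAT1-1"]), 2L)
  # neither idiomorph present
  p0 <- simulatePanel(simulationConfig(seed = 92, genomeLength = 3e4,
                                       nStrainsPerSpecies = 1,
                                       nSpecies = 1, theta = 0))
  one <- matingType(p0$assemblies[[1]], p$matRefs)
  expect_equal(one$call, "none")
  expect_error(matingType(p0$assemblies[[1]], NULL), "required")
})
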