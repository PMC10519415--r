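test_that("MK counting matches hand-constructed codon truths", {
  DSS <- Biostrings::DNAStringSet
  # in-group monomorphic, outgroup differs at a 4-fold third position
  expect_equal(mkCounts(DSS(c("ATGGGA", "ATGGGA", "ATGGGA")),
                        DSS("ATGGGG"))[, c("PS", "PR", "DS", "DR")],
               data.frame(PS = 0, PR = 0, DS = 1, DR = 0))
  # in-group segregating synonymous site; outgroup matches the major allele
  expect_equal(mkCounts(DSS(c("ATGGGA", "ATGGGG", "ATGGGA")),
                        DSS("ATGGGA"))[, c("PS", "PR", "DS", "DR")],
               data.frame(PS = 1, PR = 0, DS = 0, DR = 0))
  # nonsynonymous fixed difference (ATG -> ACG, M -> T)
  expect_equal(mkCounts(DSS(c("ATGGGA", "ATGGGA")),
                        DSS("ACGGGA"))[, c("PS", "PR", "DS", "DR")],
               data.frame(PS = 0, PR = 0, DS = 0, DR = 1))
  # alignment-contract errors
  expect_error(mkCounts(DSS(c("ATGG", "ATGG")), DSS("ATGG")), "divisible")
  expect_error(mkCounts(DSS("ATG"), DSS("ATG")), "2 in-group")
})

test_that("MK counts match a per-codon oracle on a 100-codon gene", {
  # single-difference codons only, so the expected counts follow from
  # direct per-site accounting without path enumeration
  set.seed(101)
  # 4-fold families whose first-position A/C swap is always nonsynonymous
  four_fold <- c("GG", "CC", "GC", "TC", "AC", "GT", "CT")
  n_ds <- 7; n_dr <- 11; n_ps <- 5; n_pr <- 3
  codons <- rep("ATG", 100)
  base <- function() paste0(sample(four_fold, 1), sample(c("A", "G"), 1))
  ing1 <- ing2 <- ing3 <- outg <- vapply(1:100, function(i) base(), "")
  idx <- sample(100, n_ds + n_dr + n_ps + n_pr)
  i_ds <- idx[seq_len(n_ds)]
  i_dr <- idx[n_ds + seq_len(n_dr)]
  i_ps <- idx[n_ds + n_dr + seq_len(n_ps)]
  i_pr <- idx[n_ds + n_dr + n_ps + seq_len(n_pr)]
  swap3 <- function(cd) paste0(substr(cd, 1, 2),
                               ifelse(substr(cd, 3, 3) == "A", "G", "A"))
  swap1 <- function(cd) paste0(ifelse(substr(cd, 1, 1) == "A", "C", "A"),
                               substr(cd, 2, 3))
  outg[i_ds] <- vapply(outg[i_ds], swap3, "")          # fixed synonymous
  outg[i_dr] <- vapply(outg[i_dr], swap1, "")          # fixed replacement
  ing1[i_ps] <- vapply(ing1[i_ps], swap3, "")          # polymorphic syn
  ing1[i_pr] <- vapply(ing1[i_pr], swap1, "")          # polymorphic rep
  mk <- mkCounts(Biostrings::DNAStringSet(c(paste(ing1, collapse = ""),
                                            paste(ing2, collapse = ""),
                                            paste(ing3, collapse = ""))),
                 Biostrings::DNAStringSet(paste(outg, collapse = "")))
  expect_equal(mk$DS, n_ds)
  expect_equal(mk$DR, n_dr)
  expect_equal(mk$PS, n_ps)
  expect_equal(mk$PR, n_pr)
  expect_lte(mk$Lsyn + mk$Lrep, 300)
  # invariance under permutation of in-group order
  mk2 <- mkCounts(Biostrings::DNAStringSet(c(paste(ing3, collapse = ""),
                                             paste(ing1, collapse = ""),
                                             paste(ing2, collapse = ""))),
                  Biostrings::DNAStringSet(paste(outg, collapse = "")))
  expect_equal(mk2[, c("PS", "PR", "DS", "DR", "Lsyn", "Lrep")],
               mk[, c("PS", "PR", "DS", "DR", "Lsyn", "Lrep")])
})

test_that("the exact MK test agrees with hypergeometric enumeration", {
  tabs <- list(c(2, 42, 7, 17), c(10, 10, 10, 10), c(0, 5, 9, 3),
               c(15, 30, 2, 40), c(1, 1, 20, 2))
  for (t in tabs) {
    res <- mkFisher(data.frame(PR = t[1], PS = t[2], DR = t[3], DS = t[4]))
    expect_equal(res$p, bruteFisherP(t[1], t[2], t[3], t[4]),
                 tolerance = 1e-8)
  }
  r <- mkFisher(data.frame(PR = 2, PS = 42, DR = 7, DS = 17))
  expect_equal(r$p, 7e-3, tolerance = 0.1)
  expect_equal(mkFisher(data.frame(PR = 10, PS = 10, DR = 10, DS = 10))$NI, 1)
  expect_true(is.na(mkFisher(data.frame(PR = 5, PS = 5, DR = 0, DS = 3))$NI))
})

test_that("exact-test p-values are honest under a null with fixed margins", {
  # null tables drawn from the conditional hypergeometric with the
  # margins of a typical gene; the discrete exact p-value is valid
  # (conservative): P(p <= a) <= a for every level
  set.seed(102)
  r1 <- 30; r2 <- 60; c1 <- 40
  n <- r1 + r2
  ps <- vapply(1:2000, function(i) {
    a <- stats::rhyper(1, r1, r2, c1)
    mkFisher(data.frame(PR = a, PS = r1 - a, DR = c1 - a,
                        DS = r2 - (c1 - a)))$p
  }, numeric(1))
  for (alpha in c(0.01, 0.05, 0.1, 0.25, 0.5))
    expect_lte(mean(ps <= alpha), alpha + 0.02)
  # and not wildly conservative either at moderate levels
  expect_gte(mean(ps <= 0.5), 0.3)
})

test_that("the hierarchical classifier recovers planted selection", {
  sel <- data.frame(class = rep(c("positive", "negative", "neutral"),
                                c(8, 8, 64)), effect = 1.5)
  sim <- simulateMKCounts(sel, seed = 7)
  fit <- snipreFit(sim$counts, iterations = 6000, burnIn = 2000, thin = 4,
                   seed = 7)
  expect_equal(nrow(fit), 80L)
  cls <- fit$class
  tr <- sim$truth$class
  expect_gte(mean(cls[tr == "positive"] == "positive"), 0.75)
  expect_gte(mean(cls[tr == "negative"] == "negative"), 0.75)
  expect_lte(mean(cls[tr == "neutral"] != "neutral"), 0.10)
  # classification is consistent with the credible intervals
  expect_true(all((fit$ciLower > 0) == (cls == "positive")))
  expect_true(all((fit$ciUpper < 0) == (cls == "negative")))
  expect_error(snipreFit(sim$counts[1:10, ]), "20 genes")
})

test_that("COG enrichment flags a loaded category and spares a uniform one", {
  genes <- sprintf("g%04d", 1:1000)
  calls <- data.frame(gene_id = genes,
                      class = c(rep("positive", 40),
                                rep("neutral", 960)))
  cog <- data.frame(gene_id = genes,
                    category = c(rep("Q", 10), rep("C", 300),
                                 rep("E", 690)))
  # category Q: 10/10 positive; genome-wide 40/1000
  res <- categoryEnrichment(calls, cog)
  expect_lt(res$p[res$category == "Q"], 1e-6)
  expect_true(all(res$q >= res$p - 1e-12))
  # a category whose focal fraction equals the genome-wide rate exactly
  calls2 <- data.frame(gene_id = genes,
                       class = rep(c("positive", rep("neutral", 19)), 50))
  cog2 <- data.frame(gene_id = genes,
                     category = rep(c("A", "B"), c(250, 750)))
  res2 <- categoryEnrichment(calls2, cog2)
  expect_gt(min(res2$p), 0.5)
  # gene-set interface and error handling
  res3 <- categoryEnrichment(genes[1:40], cog)
  expect_lt(res3$p[res3$category == "Q"], 1e-6)
  expect_error(categoryEnrichment(calls, cog[0, ]), "non-empty")
})
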