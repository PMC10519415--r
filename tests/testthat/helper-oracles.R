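# Independent oracles and small fixture builders used across the suite.

# Build a MatchBlocks from terse arguments.
mkBlocks <- function(qs, qe, ts = qs, te = qe, matched = qe - qs,
                     qname = "q", tname = "t", qlen = max(qe) + 10,
                     tlen = max(te) + 10, strand = "+") {
  MatchBlocks(data.frame(
    query_name = qname, query_length = qlen, query_start = qs,
    query_end = qe, strand = strand, target_name = tname,
    target_length = tlen, target_start = ts, target_end = te,
    matched_bases = matched, block_length = qe - qs))
}

# Brute-force diversity statistics from a complete 0/1 genotype matrix
# (sites x strains): pi as the literal average pairwise Hamming distance,
# theta from the site count, D from an independently coded Tajima (1989)
# normalization.
bruteDiversity <- function(geno, L) {
  n <- ncol(geno)
  pairs <- utils::combn(n, 2)
  ham <- apply(pairs, 2, function(p) sum(geno[, p[1]] != geno[, p[2]]))
  pi_total <- mean(ham)
  seg <- apply(geno, 1, function(r) length(unique(r)) > 1)
  S <- sum(seg)
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n * n + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  v <- c1 / a1 * S + c2 / (a1^2 + a2) * S * (S - 1)
  D <- if (S == 0 || n < 3 || v <= 1e-12) NA_real_ else
    (pi_total - S / a1) / sqrt(v)
  list(pi = pi_total / L, thetaW = S / (a1 * L), S = S, D = D)
}

# Exact two-sided conditional test of a 2x2 table by hypergeometric
# enumeration (sum of outcome probabilities not exceeding the observed).
bruteFisherP <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(ks, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Brute-force r^2 between two haploid vectors.
bruteR2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  pA <- mean(x); pB <- mean(y); pAB <- mean(x & y)
  D <- pAB - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}

# VariantTable from a bare genotype matrix.
vtFromGeno <- function(geno, L, pos = NULL, contig = "chr1") {
  S <- nrow(geno)
  if (is.null(pos)) pos <- if (S) sort(sample.int(L, S)) else integer(0)
  VariantTable(data.frame(contig = rep(contig, S), pos = pos,
                          ref = rep("A", S), alt = rep("T", S)),
               geno, L)
}

# Small two-species panel with planted HTRs, shared by detection tests.
smallPanel <- function(seed = 1, htrs = c(20000, 12000), identity = 0.995,
                       L = 2e5, strains = 2, te = TRUE) {
  cfg <- simulationConfig(seed = seed, genomeLength = L,
                          nStrainsPerSpecies = strains, theta = 0.005,
                          htrSpecs = htrSpec(htrs, identity,
                                             te_at_edges = te),
                          teDensity = 0.05)
  simulatePanel(cfg)
}

thresholds98 <- function() {
  new("ThresholdSet", identityThreshold = 98, lengthThreshold = 7000,
      provenance = list(), underpowered = FALSE)
}
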