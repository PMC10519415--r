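#' Tajima's D from summary quantities
#'
#' Standard normalization of the difference between the mean pairwise
#' difference count and the Watterson estimate, with the usual a/b/c/e
#' constants for sample size n.
#'
#' @param n sample size.
#' @param S number of segregating sites.
#' @param piTotal sum over sites of mean pairwise differences (not
#'   per-site scaled).
#' @return Tajima's D (NA when S = 0 or n < 3, where the normalizing
#'   variance is zero).
#' @export
tajimaDFromSummary <- function(n, S, piTotal) {
  if (S == 0 || n < 3) return(NA_real_)
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  v <- e1 * S + e2 * S * (S - 1)
  # n = 3 makes both variance constants vanish (pi is then a fixed
  # multiple of S); D is undefined there
  if (v <= 1e-12) return(NA_real_)
  (piTotal - S / a1) / sqrt(v)
}

#' Within-species diversity statistics from a variant table
#'
#' Computes per-site nucleotide diversity pi (average pairwise
#' differences, missing calls handled pairwise-complete via per-site
#' allele counts), Watterson's theta \code{S / (a1 * L)}, and Tajima's D,
#' scaled to the reference genome length. Segregating sites are those
#' with at least two non-missing calls carrying distinct alleles.
#' Optionally a 95\% null interval for D is obtained by fixed-S neutral
#' coalescent resampling conditioned on (n, S).
#'
#' @param vt A [VariantTable-class] with n >= 2 strains.
#' @param nullCI compute the fixed-S null interval for D.
#' @param nullReps replicates for the null interval.
#' @param seed optional seed for the null resampling.
#' @return A [DiversityStats-class].
#' @examples
#' geno <- rbind(c(0L, 0L, 1L, 1L), c(0L, 1L, 0L, 1L))
#' vt <- VariantTable(data.frame(contig = "c", pos = c(3, 7),
#'                               ref = "A", alt = "T"), geno, 10)
#' diversity(vt)
#' @export
diversity <- function(vt, nullCI = FALSE, nullReps = 10000, seed = NULL) {
  n <- nStrains(vt)
  if (n < 2) stop("at least 2 strains are required")
  L <- genomeLength(vt)
  g <- genotypes(vt)
  n1 <- rowSums(g == 1L, na.rm = TRUE)
  n0 <- rowSums(g == 0L, na.rm = TRUE)
  nt <- n0 + n1
  seg <- nt >= 2 & n0 >= 1 & n1 >= 1
  S <- sum(seg)
  pi_total <- sum(ifelse(seg, 2 * n0 * n1 / (nt * (nt - 1)), 0))
  a1 <- sum(1 / seq_len(n - 1))
  d <- tajimaDFromSummary(n, S, pi_total)
  ci <- c(NA_real_, NA_real_)
  if (nullCI && S > 0) {
    if (!is.null(seed)) set.seed(seed)
    nd <- tajimaNullSample(n, S, reps = nullReps)
    ci <- unname(stats::quantile(nd, c(0.025, 0.975)))
  }
  new("DiversityStats", pi = pi_total / L, thetaW = S / (a1 * L),
      S = as.numeric(S), tajimaD = d, dNullCI = ci, n = as.numeric(n),
      L = L)
}

#' Fixed-S null interval for Tajima's D
#'
#' @param n sample size.
#' @param S segregating sites to condition on.
#' @param reps number of neutral coalescent replicates.
#' @param level interval coverage.
#' @return length-2 numeric (lower, upper).
#' @export
tajimaNullCI <- function(n, S, reps = 10000, level = 0.95) {
  d <- tajimaNullSample(n, S, reps = reps)
  a <- (1 - level) / 2
  unname(stats::quantile(d, c(a, 1 - a)))
}
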