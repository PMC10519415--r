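#' Sample branches of a neutral coalescent genealogy
#'
#' Simulates the standard (Kingman) coalescent for \code{n} haploid
#' lineages and returns the branches of the genealogy with their lengths
#' (in coalescent units, where the waiting time while k lineages remain is
#' exponential with rate k(k-1)/2) and the number of sampled tips
#' descending from each branch. Mutations dropped uniformly on the tree
#' hit a branch with probability proportional to its length and produce a
#' derived allele carried by that branch's descendants.
#'
#' @param n number of sampled lineages (>= 2).
#' @return data.frame with columns \code{length} and \code{size} (number
#'   of descendant tips, 1..n-1), one row per branch (2n - 2 rows).
#' @keywords internal
coalescentBranches <- function(n) {
  stopifnot(n >= 2)
  sizes <- rep(1L, n)       # tips below each active lineage
  acc <- rep(0, n)          # branch length accrued by each active lineage
  out_len <- numeric(2 * n - 2)
  out_size <- integer(2 * n - 2)
  nout <- 0L
  while (length(sizes) > 1L) {
    k <- length(sizes)
    t_k <- stats::rexp(1, rate = k * (k - 1) / 2)
    acc <- acc + t_k
    pair <- sample.int(k, 2L)
    out_len[nout + 1:2] <- acc[pair]
    out_size[nout + 1:2] <- sizes[pair]
    nout <- nout + 2L
    newsize <- sum(sizes[pair])
    sizes <- c(sizes[-pair], newsize)
    acc <- c(acc[-pair], 0)
  }
  data.frame(length = out_len, size = out_size)
}

#' Simulate haplotypes under the neutral coalescent
#'
#' Draws a genealogy for \code{n} haploid samples, then either drops a
#' Poisson number of mutations (rate theta/2 per site per unit branch
#' length, so that the expected number of segregating sites is
#' \code{theta * L * a1}) or conditions on a fixed number of segregating
#' sites \code{S}. Infinite-sites positions are uniform on \code{1..L}
#' without replacement.
#'
#' @param n sample size.
#' @param L sequence length in bp.
#' @param theta per-site diversity; ignored when \code{S} is given.
#' @param S optional fixed number of segregating sites.
#' @return list with \code{positions} (sorted, 1-based), \code{geno}
#'   (S x n matrix of 0/1 with 1 = derived) and \code{counts} (derived
#'   allele count per site).
#' @keywords internal
coalescentHaplotypes <- function(n, L, theta = NULL, S = NULL) {
  stopifnot(n >= 2)
  # genealogy with explicit tip membership per branch
  members <- as.list(seq_len(n))
  acc <- rep(0, n)
  branches <- list()
  blen <- numeric(0)
  while (length(members) > 1L) {
    k <- length(members)
    t_k <- stats::rexp(1, rate = k * (k - 1) / 2)
    acc <- acc + t_k
    pair <- sample.int(k, 2L)
    branches <- c(branches, members[pair])
    blen <- c(blen, acc[pair])
    merged <- c(members[[pair[1]]], members[[pair[2]]])
    members <- c(members[-pair], list(merged))
    acc <- c(acc[-pair], 0)
  }
  total <- sum(blen)
  nmut <- if (!is.null(S)) S else stats::rpois(1, theta / 2 * L * total)
  nmut <- min(nmut, L)  # infinite-sites positions without replacement
  if (nmut == 0L)
    return(list(positions = integer(0),
                geno = matrix(0L, 0, n), counts = integer(0)))
  hit <- sample.int(length(blen), nmut, replace = TRUE, prob = blen)
  pos <- sort(sample.int(L, nmut))
  geno <- matrix(0L, nmut, n)
  for (i in seq_len(nmut)) geno[i, branches[[hit[i]]]] <- 1L
  # a branch ancestral to all samples cannot occur (root excluded), but
  # guard against monomorphic rows anyway
  keep <- rowSums(geno) > 0L & rowSums(geno) < n
  list(positions = pos[keep], geno = geno[keep, , drop = FALSE],
       counts = rowSums(geno[keep, , drop = FALSE]))
}

#' Null distribution of Tajima's D conditioned on S
#'
#' Simulates neutral coalescent genealogies for \code{n} samples, places
#' exactly \code{S} mutations on each (branch chosen proportionally to its
#' length), and computes Tajima's D for each replicate. Used to build the
#' 95\% null interval around zero against which observed D is compared.
#'
#' @param n sample size.
#' @param S number of segregating sites to condition on.
#' @param reps number of replicates.
#' @return numeric vector of D values (NA-free; replicates are
#'   conditioned on S > 0).
#' @keywords internal
tajimaNullSample <- function(n, S, reps = 10000) {
  stopifnot(S >= 1, n >= 2)
  vapply(seq_len(reps), function(i) {
    br <- coalescentBranches(n)
    hit <- sample.int(nrow(br), S, replace = TRUE, prob = br$length)
    counts <- br$size[hit]
    pi_total <- sum(2 * counts * (n - counts)) / (n * (n - 1))
    tajimaDFromSummary(n, S, pi_total)
  }, numeric(1))
}
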