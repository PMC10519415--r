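# minor allele frequency and minor allele count per site
.mafCounts <- function(g) {
  n1 <- rowSums(g == 1L, na.rm = TRUE)
  n0 <- rowSums(g == 0L, na.rm = TRUE)
  nt <- n0 + n1
  minor <- pmin(n0, n1)
  list(maf = ifelse(nt > 0, minor / nt, 0), minorCount = minor)
}

# squared allelic correlation between two haploid 0/1 vectors
.r2 <- function(x, y) {
  r <- suppressWarnings(stats::cor(x, y, use = "pairwise.complete.obs"))
  if (is.na(r)) NA_real_ else r^2
}

#' Linkage-disequilibrium decay with physical distance
#'
#' Computes r-squared between all pairs of sites within \code{window} bp
#' on the same contig, after a minor-allele-frequency cut-off, and
#' averages it in distance bins. Flat profiles (no decay) indicate
#' clonality; decay indicates recombination.
#'
#' @param vt A [VariantTable-class].
#' @param window maximum pair distance in bp.
#' @param mafMin minor allele frequency cut-off.
#' @param binWidth distance bin width in bp.
#' @return data.frame with \code{bin_start}, \code{bin_mid},
#'   \code{mean_r2}, \code{n_pairs}; zero rows (with a warning) when no
#'   pair qualifies.
#' @export
ldDecay <- function(vt, window = 15000, mafMin = 0.2, binWidth = 500) {
  g <- genotypes(vt)
  info <- variantInfo(vt)
  mc <- .mafCounts(g)
  keep <- mc$maf >= mafMin
  dists <- list()
  r2s <- list()
  for (ctg in unique(info$contig[keep])) {
    idx <- which(keep & info$contig == ctg)
    idx <- idx[order(info$pos[idx])]
    if (length(idx) < 2) next
    pos <- info$pos[idx]
    cm <- suppressWarnings(stats::cor(t(g[idx, , drop = FALSE]),
                                      use = "pairwise.complete.obs"))
    dd <- outer(pos, pos, function(a, b) b - a)
    sel <- upper.tri(dd) & dd > 0 & dd <= window & !is.na(cm)
    if (!any(sel)) next
    dists[[ctg]] <- dd[sel]
    r2s[[ctg]] <- cm[sel]^2
  }
  if (!length(dists)) {
    warning("no qualifying site pairs for LD decay")
    return(data.frame(bin_start = numeric(0), bin_mid = numeric(0),
                      mean_r2 = numeric(0), n_pairs = integer(0)))
  }
  res <- data.frame(dist = unlist(dists, use.names = FALSE),
                    r2 = unlist(r2s, use.names = FALSE))
  bin <- floor(res$dist / binWidth) * binWidth
  agg <- stats::aggregate(res$r2, list(bin_start = bin),
                          function(x) c(mean(x), length(x)))
  data.frame(bin_start = agg$bin_start,
             bin_mid = agg$bin_start + binWidth / 2,
             mean_r2 = agg$x[, 1], n_pairs = as.integer(agg$x[, 2]))
}

#' Prune SNPs to low pairwise linkage disequilibrium
#'
#' Greedy left-to-right scan per contig: after a minor-allele filter
#' (frequency >= \code{mafMin} and minor allele carried by at least
#' \code{minMinorCount} individuals), a site is dropped when its
#' r-squared with any already-retained site within \code{window} bp
#' upstream reaches \code{r2Max}. The result is a fixed point: pruning
#' twice changes nothing.
#'
#' @param vt A [VariantTable-class].
#' @param r2Max r-squared threshold (sites at or above it are dropped).
#' @param window upstream window in bp.
#' @param mafMin minor allele frequency cut-off.
#' @param minMinorCount minimum individuals carrying the minor allele.
#' @return A pruned [VariantTable-class]; the filter log gains
#'   \code{maf} and \code{ld} rows.
#' @export
ldPrune <- function(vt, r2Max = 0.2, window = 1000, mafMin = 0.05,
                    minMinorCount = 2) {
  g <- genotypes(vt)
  info <- variantInfo(vt)
  mc <- .mafCounts(g)
  maf_keep <- mc$maf >= mafMin & mc$minorCount >= minMinorCount
  keep <- logical(nrow(info))
  for (ctg in unique(info$contig)) {
    idx <- which(maf_keep & info$contig == ctg)
    idx <- idx[order(info$pos[idx])]
    retained <- integer(0)
    for (i in idx) {
      near <- retained[info$pos[i] - info$pos[retained] <= window]
      drop <- FALSE
      for (j in near) {
        r2 <- .r2(g[i, ], g[j, ])
        if (!is.na(r2) && r2 >= r2Max) { drop <- TRUE; break }
      }
      if (!drop) {
        keep[i] <- TRUE
        retained <- c(retained, i)
      }
    }
  }
  log <- rbind(filterLog(vt),
               data.frame(filter = c("maf", "ld"),
                          removed = c(sum(!maf_keep),
                                      sum(maf_keep) - sum(keep))))
  VariantTable(info[keep, , drop = FALSE], g[keep, , drop = FALSE],
               genomeLength(vt), filterLog = log)
}
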