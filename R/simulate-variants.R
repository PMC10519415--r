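#' Simulate haploid variant calls
#'
#' Generates a haploid biallelic SNP table for one species, either from a
#' neutral coalescent at the configured theta (site-frequency spectrum
#' and expected segregating-site count \code{theta * L * a1} follow the
#' standard coalescent) or in a two-clonal-lineage mode in which every
#' SNP carries the same lineage-diagnostic bipartition, mimicking purely
#' asexual populations: within-lineage diversity is near zero and linkage
#' disequilibrium shows no decay with distance. INFO metrics (QD, MQ, FS,
#' MQRankSum, ReadPosRankSum) are drawn from distributions that pass the
#' standard hard filters.
#'
#' @param config A [SimulationConfig-class]; uses \code{seed},
#'   \code{nStrainsPerSpecies}, \code{genomeLength} and \code{theta}.
#' @param mode "coalescent" or "clonal".
#' @param path optional path; when given, a VCF 4.2 file is written.
#' @param contig contig name used in the VCF.
#' @return A [VariantTable-class] with attribute-free truth available as
#'   \code{config@theta}.
#' @examples
#' cfg <- simulationConfig(seed = 1, genomeLength = 1e5, theta = 0.01,
#'                         nStrainsPerSpecies = 10)
#' vt <- simulateVariants(cfg)
#' nSites(vt)
#' @export
simulateVariants <- function(config, mode = c("coalescent", "clonal"),
                             path = NULL, contig = "chr1") {
  mode <- match.arg(mode)
  n <- config@nStrainsPerSpecies
  if (n < 2) stop("n_strains_per_species must be >= 2 to simulate variants")
  L <- config@genomeLength
  theta <- config@theta
  set.seed(config@seed)
  if (theta == 0) {
    geno <- matrix(integer(0), 0, n)
    pos <- integer(0)
  } else if (mode == "coalescent") {
    hap <- coalescentHaplotypes(n, L, theta = theta)
    geno <- hap$geno
    pos <- hap$positions
  } else {
    a1 <- sum(1 / seq_len(n - 1))
    S <- stats::rpois(1, theta * L * a1)
    S <- min(S, L)
    pos <- sort(sample.int(L, S))
    half <- sample.int(n, floor(n / 2))
    patt <- integer(n)
    patt[half] <- 1L
    geno <- matrix(rep(patt, each = S), S, n)
  }
  S <- length(pos)
  info <- data.frame(
    contig = rep(contig, S), pos = pos,
    ref = .NT[sample.int(4L, S, replace = TRUE)],
    alt = rep(NA_character_, S),
    QD = stats::runif(S, 15, 35), MQ = stats::runif(S, 50, 60),
    FS = stats::runif(S, 0, 5),
    MQRankSum = stats::rnorm(S, 0, 1), ReadPosRankSum = stats::rnorm(S, 0, 1))
  if (S)
    info$alt <- vapply(info$ref, function(r)
      sample(setdiff(.NT, r), 1L), character(1))
  colnames(geno) <- sprintf("s%02d", seq_len(n))
  vt <- VariantTable(info, geno, genomeLength = L)
  if (!is.null(path)) writeVcf(vt, path)
  vt
}

#' Write a VariantTable as a haploid VCF 4.2 file
#'
#' @param vt A [VariantTable-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeVcf <- function(vt, path) {
  info <- variantInfo(vt)
  geno <- genotypes(vt)
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>",
                   unique(info$contig), as.integer(genomeLength(vt))),
           "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
           "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mapping quality\">",
           "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Fisher strand bias\">",
           "##INFO=<ID=MQRankSum,Number=1,Type=Float,Description=\"Mapping quality rank sum\">",
           "##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description=\"Read position rank sum\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Haploid genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", colnames(geno)), collapse = "\t"))
  lines <- hdr
  if (nrow(info)) {
    gt <- apply(geno, 1, function(g) {
      g <- as.character(g)
      g[is.na(g)] <- "."
      paste(g, collapse = "\t")
    })
    infostr <- sprintf("QD=%.2f;MQ=%.2f;FS=%.2f;MQRankSum=%.3f;ReadPosRankSum=%.3f",
                       info$QD, info$MQ, info$FS, info$MQRankSum,
                       info$ReadPosRankSum)
    lines <- c(lines, paste(info$contig, info$pos, ".", info$ref, info$alt,
                            "100", "PASS", infostr, "GT", gt, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
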