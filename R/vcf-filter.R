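#' Read and hard-filter a haploid VCF into a VariantTable
#'
#' Applies the standard GATK-style hard filters for haploid fungal
#' variant calls: sites are removed when QD < \code{qdMin}, MQ <
#' \code{mqMin}, FS > \code{fsMax}, MQRankSum < \code{mqrsMin},
#' ReadPosRankSum < \code{rprsMin}, or when more than \code{maxMissing}
#' of the calls are missing. Indels and non-biallelic sites are removed
#' entirely. Missing INFO metrics pass their filter (the rank-sum
#' annotations are undefined for sites without heterozygous-quality
#' evidence). The two rank-sum bounds default to the negative GATK
#' convention (-12.5, -8.0); both are overridable.
#'
#' @param vcf path to a VCF 4.x file, or a \code{vcfR} object.
#' @param qdMin,mqMin,fsMax,mqrsMin,rprsMin,maxMissing filter thresholds.
#' @param genomeLength reference length in bp; when NULL, taken from the
#'   VCF contig headers (sum of lengths), falling back to the maximum
#'   position.
#' @return A [VariantTable-class]; its \code{filterLog} tallies the sites
#'   failing each filter (a site failing several is tallied under each).
#' @export
filterVcf <- function(vcf, qdMin = 2, mqMin = 40, fsMax = 60,
                      mqrsMin = -12.5, rprsMin = -8.0, maxMissing = 0.10,
                      genomeLength = NULL) {
  v <- if (is.character(vcf)) vcfR::read.vcfR(vcf, verbose = FALSE) else vcf
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (is.null(genomeLength)) {
    meta <- v@meta
    m <- regmatches(meta, regexpr("##contig=<[^>]*>", meta))
    lens <- suppressWarnings(as.numeric(sub(".*length=([0-9]+).*", "\\1", m)))
    genomeLength <- if (length(lens) && all(is.finite(lens))) sum(lens)
    else max(as.numeric(fix$POS))
  }
  gt <- vcfR::extract.gt(v)
  if (any(grepl("[/|]", gt), na.rm = TRUE))
    stop("diploid genotypes found; this pipeline expects haploid calls ",
         "(re-call with ploidy 1)")
  n <- nrow(fix)
  info_num <- function(tag) suppressWarnings(
    as.numeric(vcfR::extract.info(v, tag)))
  QD <- info_num("QD"); MQ <- info_num("MQ"); FS <- info_num("FS")
  MQRS <- info_num("MQRankSum"); RPRS <- info_num("ReadPosRankSum")
  is_indel <- nchar(fix$REF) > 1 |
    vapply(strsplit(fix$ALT, ","), function(a) any(nchar(a) > 1), logical(1))
  multi <- grepl(",", fix$ALT)
  missing_frac <- rowMeans(is.na(gt) | gt == ".")
  fails <- list(
    indel = is_indel,
    non_biallelic = multi & !is_indel,
    QD = !is.na(QD) & QD < qdMin,
    MQ = !is.na(MQ) & MQ < mqMin,
    FS = !is.na(FS) & FS > fsMax,
    MQRankSum = !is.na(MQRS) & MQRS < mqrsMin,
    ReadPosRankSum = !is.na(RPRS) & RPRS < rprsMin,
    missing = missing_frac > maxMissing)
  log <- data.frame(filter = names(fails),
                    removed = vapply(fails, sum, integer(1)))
  keep <- !Reduce(`|`, fails)
  geno <- matrix(NA_integer_, sum(keep), ncol(gt))
  colnames(geno) <- colnames(gt)
  gk <- gt[keep, , drop = FALSE]
  geno[gk == "0"] <- 0L
  geno[gk == "1"] <- 1L
  info <- data.frame(contig = fix$CHROM[keep],
                     pos = as.numeric(fix$POS[keep]),
                     ref = fix$REF[keep], alt = fix$ALT[keep],
                     QD = QD[keep], MQ = MQ[keep], FS = FS[keep],
                     MQRankSum = MQRS[keep], ReadPosRankSum = RPRS[keep])
  VariantTable(info, geno, genomeLength, filterLog = log)
}
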