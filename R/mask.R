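#' @importFrom GenomicRanges GRanges seqnames start end width
#'   findOverlaps distance
#' @importFrom IRanges IRanges IRangesList subsetByOverlaps
#' @importFrom Biostrings subseq
NULL

.candidateGRanges <- function(candidates) {
  GRanges(candidates$contig,
          IRanges(candidates$start + 1L, candidates$end))
}

#' TE-mask candidates and drop those with too little unmasked sequence
#'
#' For each candidate region, subtracts the union of overlapping
#' transposable-element annotations; candidates whose unmasked length
#' falls below \code{minUnmasked} (default 500 bp) are discarded. The
#' per-candidate TE fraction is reported. When reference sequences are
#' supplied, the representative (consensus) sequence of each retained
#' region is the reference strain's subsequence. TE intervals extending
#' beyond a known contig end are clipped with a warning.
#'
#' @param candidates candidate table from [detectCandidates()] (or any
#'   data.frame with \code{id}, \code{contig}, \code{start}, \code{end},
#'   0-based half-open).
#' @param teAnnotation [GenomicRanges::GRanges] of TE intervals on the
#'   same reference coordinates.
#' @param minUnmasked minimum unmasked length in bp.
#' @param refSeqs optional named [Biostrings::DNAStringSet] of reference
#'   contigs; adds a \code{sequence} column.
#' @param genes optional [GenomicRanges::GRanges] with a \code{gene_id}
#'   column; adds a comma-separated \code{memberGenes} column.
#' @return A [S4Vectors::DataFrame] of retained consensus HTRs with
#'   columns \code{id}, \code{contig}, \code{start}, \code{end},
#'   \code{length}, \code{unmaskedLength}, \code{teFraction},
#'   \code{maskedIntervals} (an [IRanges::IRangesList], 1-based relative
#'   to each HTR start) and optionally \code{sequence},
#'   \code{memberGenes}. Metadata records how many candidates were
#'   dropped.
#' @export
maskAndFilter <- function(candidates, teAnnotation, minUnmasked = 500,
                          refSeqs = NULL, genes = NULL) {
  candidates <- as.data.frame(candidates)
  te <- teAnnotation
  if (!is.null(refSeqs)) {
    lens <- stats::setNames(Biostrings::width(refSeqs), names(refSeqs))
    known <- as.character(seqnames(te)) %in% names(lens)
    over <- known & end(te) > lens[as.character(seqnames(te))]
    if (any(over)) {
      warning(sum(over), " TE interval(s) extend beyond their contig; clipped")
      end(te)[over] <- lens[as.character(seqnames(te))[over]]
    }
  }
  te <- reduce(te, min.gapwidth = 0L)
  n_in <- nrow(candidates)
  rows <- NULL
  masked_rel <- list()
  seqs <- character(0)
  member <- character(0)
  for (i in seq_len(n_in)) {
    cand <- GRanges(candidates$contig[i],
                    IRanges(candidates$start[i] + 1L, candidates$end[i]))
    len <- width(cand)
    ov <- suppressWarnings(GenomicRanges::intersect(te, cand,
                                                    ignore.strand = TRUE))
    masked <- sum(width(ov))
    unmasked <- len - masked
    if (unmasked < minUnmasked) next
    rel <- IRanges(start(ov) - start(cand) + 1L, end(ov) - start(cand) + 1L)
    rows <- rbind(rows, data.frame(
      id = candidates$id[i], contig = candidates$contig[i],
      start = candidates$start[i], end = candidates$end[i],
      length = len, unmaskedLength = unmasked,
      teFraction = masked / len))
    masked_rel <- c(masked_rel, list(rel))
    if (!is.null(refSeqs))
      seqs <- c(seqs, as.character(subseq(refSeqs[[candidates$contig[i]]],
                                          candidates$start[i] + 1L,
                                          candidates$end[i])))
    if (!is.null(genes)) {
      g <- subsetByOverlaps(genes, cand)
      member <- c(member, paste(g$gene_id, collapse = ","))
    }
  }
  if (is.null(rows)) {
    out <- DataFrame(id = character(0), contig = character(0),
                     start = numeric(0), end = numeric(0),
                     length = numeric(0), unmaskedLength = numeric(0),
                     teFraction = numeric(0))
    out$maskedIntervals <- IRangesList()
  } else {
    out <- DataFrame(rows)
    out$maskedIntervals <- IRangesList(masked_rel)
    if (!is.null(refSeqs)) out$sequence <- DNAStringSet(seqs)
    if (!is.null(genes)) out$memberGenes <- member
  }
  rownames(out) <- NULL
  metadata(out) <- list(nIn = n_in, nDropped = n_in - nrow(out),
                        minUnmasked = minUnmasked)
  out
}

#' Report TE context of consensus-HTR extremities
#'
#' For each of the two extremities (very first and very last base) of
#' every consensus HTR: whether the terminal base lies inside an
#' annotated TE, and the distance to the nearest TE on the same contig
#' (0 when inside; \code{Inf} when the contig carries no TE). The summary
#' counts extremities in TEs and extremities with a TE within
#' \code{window} bp.
#'
#' @param consensus table from [maskAndFilter()] (or compatible).
#' @param teAnnotation [GenomicRanges::GRanges] of TE intervals.
#' @param window context window in bp.
#' @return list with \code{perExtremity} (data.frame: id, side, position,
#'   in_te, distance) and \code{summary} (nExtremities, nInTe, fracInTe,
#'   nWithinWindow).
#' @export
extremityTeReport <- function(consensus, teAnnotation, window = 1000) {
  consensus <- as.data.frame(consensus)
  te <- reduce(teAnnotation, min.gapwidth = 0L)
  per <- NULL
  for (i in seq_len(nrow(consensus))) {
    for (side in c("left", "right")) {
      pos0 <- if (side == "left") consensus$start[i] else consensus$end[i] - 1
      pt <- GRanges(consensus$contig[i], IRanges(pos0 + 1L, pos0 + 1L))
      same <- te[as.character(seqnames(te)) == consensus$contig[i]]
      if (!length(same)) {
        d <- Inf
      } else {
        d <- min(distance(pt, same))
        # GenomicRanges distance counts the gap; inside an overlap it is 0
      }
      in_te <- length(same) > 0 &&
        any(start(same) <= pos0 + 1L & end(same) >= pos0 + 1L)
      per <- rbind(per, data.frame(id = consensus$id[i], side = side,
                                   position = pos0, in_te = in_te,
                                   distance = if (in_te) 0 else d))
    }
  }
  if (is.null(per))
    per <- data.frame(id = character(0), side = character(0),
                      position = numeric(0), in_te = logical(0),
                      distance = numeric(0))
  list(perExtremity = per,
       summary = list(nExtremities = nrow(per),
                      nInTe = sum(per$in_te),
                      fracInTe = if (nrow(per)) mean(per$in_te) else NA_real_,
                      nWithinWindow = sum(per$distance <= window)))
}

#' Merge overlapping consensus HTRs for genome-scale plotting
#'
#' Overlap-merges consensus regions (single linkage, >= 1 bp overlap) and
#' keeps merged regions of at least \code{minMerged} bp, the working set
#' used when plotting similarity along whole genomes. Reports the
#' cumulative length retained.
#'
#' @param consensus table from [maskAndFilter()] (or compatible).
#' @param minMerged minimum merged length in bp.
#' @return list with \code{merged} (data.frame contig/start/end/length,
#'   0-based half-open) and \code{cumulativeLength}.
#' @export
mergeForPlotting <- function(consensus, minMerged = 35000) {
  consensus <- as.data.frame(consensus)
  if (!nrow(consensus))
    return(list(merged = data.frame(contig = character(0),
                                    start = numeric(0), end = numeric(0),
                                    length = numeric(0)),
                cumulativeLength = 0))
  gr <- reduce(.candidateGRanges(consensus), min.gapwidth = 0L)
  gr <- gr[width(gr) >= minMerged]
  merged <- data.frame(contig = as.character(seqnames(gr)),
                       start = start(gr) - 1L, end = end(gr),
                       length = width(gr))
  merged <- merged[order(merged$contig, merged$start), , drop = FALSE]
  rownames(merged) <- NULL
  list(merged = merged, cumulativeLength = sum(merged$length))
}
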