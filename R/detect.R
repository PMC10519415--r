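#' @importFrom IRanges IRanges reduce findOverlaps
#' @importFrom S4Vectors queryHits subjectHits
NULL

# Lift a 0-based half-open interval on one strain onto the species
# reference through strain-to-reference match blocks (gapless mapping by
# offset within the covering block; minus-strand blocks reverse the
# interval). Returns NULL when no block covers at least minCover of it.
.liftInterval <- function(contig, start, end, lift, minCover = 0.5) {
  b <- as.data.frame(lift)
  b <- b[b$query_name == contig, , drop = FALSE]
  if (!nrow(b)) return(NULL)
  ov <- pmin(end, b$query_end) - pmax(start, b$query_start)
  i <- which.max(ov)
  if (ov[i] < minCover * (end - start)) return(NULL)
  s <- max(start, b$query_start[i])
  e <- min(end, b$query_end[i])
  if (b$strand[i] == "+") {
    off <- b$target_start[i] - b$query_start[i]
    list(contig = b$target_name[i], start = s + off, end = e + off)
  } else {
    list(contig = b$target_name[i],
         start = b$target_end[i] - (e - b$query_start[i]),
         end = b$target_end[i] - (s - b$query_start[i]))
  }
}

#' Detect HTR candidates from inter-species strain-pair matches
#'
#' Keeps matches passing both calibrated thresholds (length >= length
#' threshold and identity >= identity threshold), projects them onto the
#' designated reference strain of each species, and single-linkage merges
#' projected intervals that overlap by at least 1 bp on the species-A
#' reference into candidate regions. Candidate identity is the
#' matched-bases-weighted mean over member matches. Matches involving
#' non-reference strains are lifted through that strain's matches to its
#' reference; matches that cannot be lifted are counted and excluded.
#'
#' @param pairMatches list of inter-species strain pairs, each a list
#'   with elements \code{strainA}, \code{strainB} and \code{blocks} (a
#'   [MatchBlocks-class]; query = species-A strain contigs, target =
#'   species-B strain contigs).
#' @param thresholds A [ThresholdSet-class].
#' @param refA,refB reference strain names for species A and B.
#' @param liftA,liftB named lists of [MatchBlocks-class] mapping each
#'   non-reference strain's contigs (query) to its species reference
#'   (target); entries for the reference strains themselves are not
#'   needed.
#' @return A [S4Vectors::DataFrame] of candidates with columns \code{id},
#'   \code{contig}, \code{start}, \code{end} (0-based half-open on the
#'   species-A reference), \code{contigB}, \code{startB}, \code{endB},
#'   \code{length}, \code{meanIdentity}, \code{nPairs}; metadata records
#'   the thresholds and the number of unliftable matches. IDs are
#'   assigned by descending length, ties by reference coordinate.
#' @export
detectCandidates <- function(pairMatches, thresholds, refA, refB,
                             liftA = list(), liftB = list()) {
  if (is.null(refA) || is.null(refB) || !nzchar(refA) || !nzchar(refB))
    stop("a reference strain must be designated for each species")
  id_thr <- identityThreshold(thresholds)
  len_thr <- lengthThreshold(thresholds)
  projected <- NULL
  unliftable <- 0L
  for (pm in pairMatches) {
    b <- as.data.frame(pm$blocks)
    if (!nrow(b)) next
    keep <- b$block_length >= len_thr &
      100 * b$matched_bases / b$block_length >= id_thr
    b <- b[keep, , drop = FALSE]
    for (i in seq_len(nrow(b))) {
      if (pm$strainA == refA) {
        pa <- list(contig = b$query_name[i], start = b$query_start[i],
                   end = b$query_end[i])
      } else {
        pa <- .liftInterval(b$query_name[i], b$query_start[i],
                            b$query_end[i], liftA[[pm$strainA]])
      }
      if (pm$strainB == refB) {
        pb <- list(contig = b$target_name[i], start = b$target_start[i],
                   end = b$target_end[i])
      } else {
        pb <- .liftInterval(b$target_name[i], b$target_start[i],
                            b$target_end[i], liftB[[pm$strainB]])
      }
      if (is.null(pa) || is.null(pb)) {
        unliftable <- unliftable + 1L
        next
      }
      projected <- rbind(projected, data.frame(
        contigA = pa$contig, startA = pa$start, endA = pa$end,
        contigB = pb$contig, startB = pb$start, endB = pb$end,
        matched = b$matched_bases[i], blen = b$block_length[i],
        pair = paste(pm$strainA, pm$strainB, sep = "|")))
    }
  }
  if (is.null(projected)) {
    out <- DataFrame(id = character(0), contig = character(0),
                     start = numeric(0), end = numeric(0),
                     contigB = character(0), startB = numeric(0),
                     endB = numeric(0), length = numeric(0),
                     meanIdentity = numeric(0), nPairs = integer(0))
    metadata(out) <- list(thresholds = thresholds, unliftable = unliftable)
    return(out)
  }
  # single-linkage merge of overlapping intervals per reference contig
  res <- NULL
  for (ctg in unique(projected$contigA)) {
    p <- projected[projected$contigA == ctg, , drop = FALSE]
    ir <- IRanges(p$startA + 1L, p$endA)
    merged <- reduce(ir, min.gapwidth = 0L)
    hits <- findOverlaps(ir, merged)
    for (m in seq_along(merged)) {
      mem <- p[queryHits(hits)[subjectHits(hits) == m], , drop = FALSE]
      # species-B span: contig carrying most matched bases
      bctg <- names(which.max(tapply(mem$matched, mem$contigB, sum)))
      memB <- mem[mem$contigB == bctg, , drop = FALSE]
      res <- rbind(res, data.frame(
        contig = ctg,
        start = min(mem$startA), end = max(mem$endA),
        contigB = bctg, startB = min(memB$startB), endB = max(memB$endB),
        meanIdentity = 100 * sum(mem$matched) / sum(mem$blen),
        nPairs = length(unique(mem$pair))))
    }
  }
  res$length <- res$end - res$start
  res <- res[order(-res$length, res$contig, res$start), , drop = FALSE]
  res$id <- sprintf("HTR_%02d", seq_len(nrow(res)))
  out <- DataFrame(res[, c("id", "contig", "start", "end", "contigB",
                           "startB", "endB", "length", "meanIdentity",
                           "nPairs")])
  rownames(out) <- NULL
  metadata(out) <- list(thresholds = thresholds, unliftable = unliftable)
  out
}
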