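#' @importFrom IRanges IRanges reduce coverage slice width start end
NULL

#' Keep panel-scan matches by the three coverage rules
#'
#' A match of an HTR consensus against a panel genome is kept iff it
#' (1) covers the entire HTR, (2) covers an entire contig of the assembly
#' with at least \code{minContigMatch} matched bases, or (3) is larger
#' than \code{edgeMin} bp and sits at the edge of a larger contig (start
#' or end within \code{edgeWindow} bp of a contig terminus, contig longer
#' than the HTR), with at most \code{maxEdge} such matches per HTR (the
#' longest are kept). "Entire" is softened to a span coverage of
#' \code{spanFrac} (default 95\%) to tolerate alignment end trimming.
#'
#' @param matches A [MatchBlocks-class]; query = HTR consensus, target =
#'   genome contigs.
#' @param htrLength length of the focal HTR consensus in bp.
#' @param contigLengths named numeric vector of contig lengths for the
#'   scanned genome; every match target must be present.
#' @param spanFrac span-coverage fraction meaning "entire".
#' @param minContigMatch minimum matched bases for rule 2.
#' @param edgeMin minimum block length for rule 3.
#' @param edgeWindow distance from a contig terminus meaning "edge".
#' @param maxEdge maximum rule-3 matches kept per HTR.
#' @return data.frame of kept matches (the [MatchBlocks-class] columns
#'   plus \code{rule} in \code{full_htr}, \code{full_contig},
#'   \code{contig_edge}); zero rows when nothing qualifies.
#' @export
keepMatches <- function(matches, htrLength, contigLengths,
                        spanFrac = 0.95, minContigMatch = 1000,
                        edgeMin = 10000, edgeWindow = 1000, maxEdge = 2) {
  b <- as.data.frame(matches)
  if (!nrow(b)) return(cbind(b, rule = character(0)))
  unknown <- setdiff(unique(b$target_name), names(contigLengths))
  if (length(unknown))
    stop("match references unknown contig(s): ",
         paste(unknown, collapse = ", "))
  clen <- contigLengths[b$target_name]
  r1 <- (b$query_end - b$query_start) >= spanFrac * htrLength
  r2 <- (b$target_end - b$target_start) >= spanFrac * clen &
    b$matched_bases >= minContigMatch
  r3 <- b$block_length > edgeMin & clen > htrLength &
    (b$target_start <= edgeWindow | b$target_end >= clen - edgeWindow)
  rule <- rep(NA_character_, nrow(b))
  rule[r3] <- "contig_edge"
  rule[r2] <- "full_contig"
  rule[r1] <- "full_htr"
  # cap rule-3 matches at the maxEdge longest
  edge_idx <- which(rule == "contig_edge")
  if (length(edge_idx) > maxEdge) {
    ord <- edge_idx[order(-b$block_length[edge_idx])]
    rule[ord[-seq_len(maxEdge)]] <- NA_character_
  }
  kept <- b[!is.na(rule), , drop = FALSE]
  kept$rule <- rule[!is.na(rule)]
  rownames(kept) <- NULL
  kept
}

#' Fraction present and identity of one HTR in one genome
#'
#' The fraction of the HTR present is the length of the union of kept
#' match intervals on HTR coordinates divided by the HTR length; the
#' identity is the number of matched bases over the nonoverlapping union,
#' counting each overlapping portion once and attributing it to the match
#' of higher identity (matched bases are pro-rated over the attributed
#' portion). With \code{excludeAmbiguous}, HTR positions hit by more than
#' one kept match are treated as ambiguous (typically repetitive
#' sequence) and excluded from both numerator and denominator.
#'
#' @param kept data.frame from [keepMatches()] (or a
#'   [MatchBlocks-class]); all matches must reference one HTR.
#' @param htrLength HTR consensus length in bp.
#' @param excludeAmbiguous drop multiply-hit positions.
#' @return list with \code{fraction} (in [0, 1]), \code{identity}
#'   (percent, NA when fraction is 0), \code{keptMatches} and
#'   \code{rules} (table of rules used).
#' @examples
#' b <- data.frame(query_name = "HTR_01", query_length = 10000,
#'                 query_start = c(0, 5000), query_end = c(4000, 8000),
#'                 strand = "+", target_name = "c1", target_length = 5e5,
#'                 target_start = c(0, 6000), target_end = c(4000, 9000),
#'                 matched_bases = c(3960, 2970), block_length = c(4000, 3000))
#' presenceIdentity(b, 10000)$fraction  # 0.70
#' @export
presenceIdentity <- function(kept, htrLength, excludeAmbiguous = FALSE) {
  b <- as.data.frame(kept)
  rules <- if (nrow(b) && !is.null(b$rule)) table(b$rule) else table(character(0))
  if (!nrow(b))
    return(list(fraction = 0, identity = NA_real_, keptMatches = 0L,
                rules = rules))
  ir <- IRanges(b$query_start + 1L, b$query_end)
  cov <- coverage(ir, width = htrLength)
  if (excludeAmbiguous) {
    usable <- slice(cov, lower = 1, upper = 1, rangesOnly = TRUE)
    ambiguous <- slice(cov, lower = 2, rangesOnly = TRUE)
    denom <- htrLength - sum(width(ambiguous))
  } else {
    usable <- slice(cov, lower = 1, rangesOnly = TRUE)
    denom <- htrLength
  }
  union_len <- sum(width(usable))
  fraction <- if (denom > 0) union_len / denom else 0
  if (union_len == 0)
    return(list(fraction = 0, identity = NA_real_,
                keptMatches = nrow(b), rules = rules))
  # attribute each usable position to the highest-identity covering match
  o <- order(-(b$matched_bases / b$block_length), b$query_start)
  claimed <- IRanges()
  num <- 0
  for (i in o) {
    mine <- IRanges::intersect(IRanges(b$query_start[i] + 1L, b$query_end[i]),
                               usable)
    mine <- IRanges::setdiff(mine, claimed)
    if (sum(width(mine)) == 0) next
    num <- num + b$matched_bases[i] * sum(width(mine)) / b$block_length[i]
    claimed <- IRanges::union(claimed, mine)
  }
  list(fraction = fraction,
       identity = 100 * num / sum(width(claimed)),
       keptMatches = nrow(b), rules = rules)
}

#' Presence/identity matrix of consensus HTRs across a genome panel
#'
#' Scans every genome of a panel for every HTR consensus sequence with
#' the built-in matcher, applies the three match-keeping rules, and
#' computes the fraction present and the identity per (genome, HTR).
#' Genomes can be ordered by a species tree.
#'
#' @param assemblies named list of [Biostrings::DNAStringSet], one per
#'   genome.
#' @param consensusSeqs named [Biostrings::DNAStringSet] of HTR consensus
#'   sequences.
#' @param tree optional [ape::phylo]; row order follows its tip labels,
#'   which must match the assembly names exactly.
#' @param excludeAmbiguous passed to [presenceIdentity()].
#' @param k,minBlock passed to [anchorMatch()].
#' @param path optional TSV output path (long format).
#' @param ... passed to [keepMatches()].
#' @return list with matrices \code{fraction} and \code{identity}
#'   (genomes x HTRs), and \code{records} (long data.frame).
#' @export
panelMatrix <- function(assemblies, consensusSeqs, tree = NULL,
                        excludeAmbiguous = FALSE, k = 15L, minBlock = 1000L,
                        path = NULL, ...) {
  genomes <- names(assemblies)
  if (!is.null(tree)) {
    mism <- c(setdiff(tree$tip.label, genomes), setdiff(genomes, tree$tip.label))
    if (length(mism))
      stop("tree leaves and genome ids do not match: ",
           paste(unique(mism), collapse = ", "))
    genomes <- tree$tip.label
  }
  htrs <- names(consensusSeqs)
  frac <- matrix(NA_real_, length(genomes), length(htrs),
                 dimnames = list(genomes, htrs))
  ident <- frac
  rec <- NULL
  for (g in genomes) {
    clen <- stats::setNames(Biostrings::width(assemblies[[g]]),
                            names(assemblies[[g]]))
    for (h in htrs) {
      hlen <- Biostrings::width(consensusSeqs[h])
      mb <- matchToGenome(consensusSeqs[h], assemblies[[g]],
                          k = k, minBlock = minBlock)
      kept <- keepMatches(mb, hlen, clen, ...)
      pr <- presenceIdentity(kept, hlen, excludeAmbiguous = excludeAmbiguous)
      frac[g, h] <- pr$fraction
      ident[g, h] <- pr$identity
      rec <- rbind(rec, data.frame(genome = g, htr = h,
                                   fraction = pr$fraction,
                                   identity = pr$identity,
                                   kept_matches = pr$keptMatches))
    }
  }
  if (!is.null(path))
    utils::write.table(rec, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  list(fraction = frac, identity = ident, records = rec)
}

#' Regress genome size on total HTR content
#'
#' Ordinary least squares of genome size on the per-genome total length
#' of HTR sequence present, quantifying how much HTR content accounts
#' for genome-size differences between strains. The adjusted R-squared is
#' \code{1 - (1 - R2) * (n - 1) / (n - 2)}.
#'
#' @param htrLength per-genome total kept HTR length (bp).
#' @param genomeSize per-genome assembly size (bp).
#' @return list with \code{slope}, \code{intercept}, \code{adjR2},
#'   \code{n} and the fitted \code{model}.
#' @export
genomeSizeRegression <- function(htrLength, genomeSize) {
  n <- length(genomeSize)
  if (n < 3) stop("at least 3 genomes are required")
  if (length(htrLength) != n)
    stop("htrLength and genomeSize must have equal length")
  if (stats::var(htrLength) == 0)
    stop("zero variance in HTR content; regression undefined")
  fit <- stats::lm(genomeSize ~ htrLength)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       adjR2 = summary(fit)$adj.r.squared, n = n, model = fit)
}
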