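#' @importFrom Biostrings DNAString DNAStringSet reverseComplement
NULL

# Encode a nucleotide string as integers 0..3 (A,C,G,T), NA otherwise.
.encodeSeq <- function(x) {
  s <- toupper(as.character(x))
  v <- utf8ToInt(s)
  code <- rep(NA_integer_, length(v))
  code[v == 65L] <- 0L  # A
  code[v == 67L] <- 1L  # C
  code[v == 71L] <- 2L  # G
  code[v == 84L] <- 3L  # T
  code
}

# Rolling exact k-mer codes as doubles (collision-free for k <= 26).
.kmerCodes <- function(code, k) {
  n <- length(code)
  if (n < k) return(numeric(0))
  m <- n - k + 1L
  out <- numeric(m)
  bad <- logical(m)
  for (j in 0:(k - 1L)) {
    v <- code[(1L + j):(m + j)]
    bad <- bad | is.na(v)
    v[is.na(v)] <- 0L
    out <- out + v * 4^j
  }
  out[bad] <- NA_real_
  out
}

# Anchor pairs (0-based query/target positions) for one orientation.
.anchorPairs <- function(ka, kb, maxOcc = 8L) {
  ok_a <- !is.na(ka)
  if (!any(ok_a)) return(NULL)
  ua <- unique(ka[ok_a])
  m_b <- match(kb, ua)
  ib <- which(!is.na(m_b))
  if (!length(ib)) return(NULL)
  bpos <- split(ib, m_b[ib])
  bpos <- bpos[lengths(bpos) <= maxOcc]
  if (!length(bpos)) return(NULL)
  codeids <- as.integer(names(bpos))
  m_a <- match(ka, ua)
  sel <- logical(length(ua))
  sel[codeids] <- TRUE
  ia <- which(ok_a & sel[m_a])
  if (!length(ia)) return(NULL)
  lst <- bpos[match(m_a[ia], codeids)]
  data.frame(q = rep(ia, lengths(lst)) - 1L,
             t = unlist(lst, use.names = FALSE) - 1L)
}

# Chain same-diagonal anchors into gapless blocks and score them.
.diagonalBlocks <- function(pairs, codeA, codeB, k, maxGap) {
  d <- pairs$q - pairs$t
  o <- order(d, pairs$q)
  dq <- pairs$q[o]
  dd <- d[o]
  n <- length(dq)
  newrun <- c(TRUE, dd[-1] != dd[-n] | (dq[-1] - dq[-n]) > maxGap)
  runid <- cumsum(newrun)
  qs <- tapply(dq, runid, min)
  qe <- tapply(dq, runid, max) + k
  diag <- dd[newrun]
  ts <- qs - diag
  te <- qe - diag
  matched <- vapply(seq_along(qs), function(i) {
    av <- codeA[(qs[i] + 1L):qe[i]]
    bv <- codeB[(ts[i] + 1L):te[i]]
    sum(av == bv, na.rm = TRUE)
  }, numeric(1))
  data.frame(query_start = as.numeric(qs), query_end = as.numeric(qe),
             target_start = as.numeric(ts), target_end = as.numeric(te),
             matched_bases = matched,
             block_length = as.numeric(qe - qs))
}

.overlapFrac <- function(s1, e1, s2, e2) {
  ov <- pmax(0, pmin(e1, e2) - pmax(s1, s2))
  ov / pmin(e1 - s1, e2 - s2)
}

#' Seed-and-extend pairwise matcher
#'
#' Finds local matches between two nucleotide sequences by exact k-mer
#' anchoring followed by per-diagonal chaining: anchors sharing a diagonal
#' (query position minus target position) and separated by at most
#' \code{maxGap} bp are merged into a single gapless block whose identity
#' is computed by exact column comparison over the full block span. Both
#' orientations are searched; minus-strand blocks are reported with
#' ascending target coordinates and strand \code{"-"}. Blocks shorter than
#' \code{minBlock} are suppressed, and of two blocks overlapping by more
#' than half (on query or target) only the one with more matched bases is
#' kept (ties broken towards the leftmost query start).
#'
#' The matcher is gapless by design: an indel splits a match into blocks
#' on different diagonals. External aligner output in PAF (e.g. minimap2
#' \code{-cx asm20}) is a drop-in substitute via [readPaf()].
#'
#' @param a,b sequences (character, [Biostrings::DNAString] or length-1
#'   [Biostrings::DNAStringSet]); names (if present) become
#'   query/target names.
#' @param k anchor length (>= 11; exact-match seed).
#' @param minBlock minimum reported block length in bp.
#' @param maxGap maximum anchor spacing chained into one block.
#' @param queryName,targetName sequence names used in the output.
#' @return A [MatchBlocks-class] object.
#' @examples
#' set.seed(1)
#' s <- paste(sample(c("A", "C", "G", "T"), 5000, replace = TRUE), collapse = "")
#' anchorMatch(s, s, minBlock = 1000)
#' @export
anchorMatch <- function(a, b, k = 15L, minBlock = 1000L, maxGap = 500L,
                        queryName = NULL, targetName = NULL) {
  getseq <- function(x, default) {
    nm <- default
    if (is(x, "DNAStringSet")) {
      stopifnot(length(x) == 1L)
      if (!is.null(names(x))) nm <- names(x)[1]
      x <- x[[1]]
    }
    list(seq = as.character(x), name = nm)
  }
  qa <- getseq(a, "query")
  tb <- getseq(b, "target")
  if (!is.null(queryName)) qa$name <- queryName
  if (!is.null(targetName)) tb$name <- targetName
  la <- nchar(qa$seq)
  lb <- nchar(tb$seq)
  if (la == 0L || lb == 0L) stop("sequences must be non-empty")
  if (k < 11L) stop("k must be >= 11")
  if (k > min(la, lb)) stop("k exceeds the shorter sequence length")
  codeA <- .encodeSeq(qa$seq)
  codeB <- .encodeSeq(tb$seq)
  ka <- .kmerCodes(codeA, k)
  blocks <- list()
  # forward
  kb <- .kmerCodes(codeB, k)
  pairs <- .anchorPairs(ka, kb)
  if (!is.null(pairs)) {
    fw <- .diagonalBlocks(pairs, codeA, codeB, k, maxGap)
    if (nrow(fw)) {
      fw$strand <- "+"
      blocks <- c(blocks, list(fw))
    }
  }
  # reverse complement of target
  codeBrc <- rev(3L - codeB)
  kbrc <- .kmerCodes(codeBrc, k)
  pairs <- .anchorPairs(ka, kbrc)
  if (!is.null(pairs)) {
    rc <- .diagonalBlocks(pairs, codeA, codeBrc, k, maxGap)
    if (nrow(rc)) {
      ts <- lb - rc$target_end
      rc$target_end <- lb - rc$target_start
      rc$target_start <- ts
      rc$strand <- "-"
      blocks <- c(blocks, list(rc))
    }
  }
  if (!length(blocks)) return(MatchBlocks())
  bl <- do.call(rbind, blocks)
  bl <- bl[bl$block_length >= minBlock, , drop = FALSE]
  if (!nrow(bl)) return(MatchBlocks())
  # Resolve alternative chains of the same region pair (same strand,
  # nearby diagonal, overlapping on both sides): most matched bases wins,
  # ties towards the leftmost query start. Matches of one query region to
  # distinct target loci are all legitimate and kept.
  bl <- bl[order(-bl$matched_bases, bl$query_start), , drop = FALSE]
  diag <- ifelse(bl$strand == "+", bl$query_start - bl$target_start,
                 bl$query_start + bl$target_end)
  keep <- logical(nrow(bl))
  for (i in seq_len(nrow(bl))) {
    kept <- which(keep)
    if (length(kept)) {
      qo <- .overlapFrac(bl$query_start[i], bl$query_end[i],
                         bl$query_start[kept], bl$query_end[kept])
      to <- .overlapFrac(bl$target_start[i], bl$target_end[i],
                         bl$target_start[kept], bl$target_end[kept])
      same <- bl$strand[kept] == bl$strand[i] &
        abs(diag[kept] - diag[i]) <= maxGap
      if (any(qo > 0.5 & to > 0.5 & same)) next
    }
    keep[i] <- TRUE
  }
  bl <- bl[keep, , drop = FALSE]
  bl <- bl[order(bl$query_start, bl$target_start), , drop = FALSE]
  bl$query_name <- qa$name
  bl$query_length <- la
  bl$target_name <- tb$name
  bl$target_length <- lb
  MatchBlocks(bl)
}

#' Match a query sequence against every contig of a genome
#'
#' Runs [anchorMatch()] of one query (e.g. an HTR consensus sequence)
#' against each contig of a genome assembly and concatenates the blocks.
#'
#' @param query character/DNAString/length-1 DNAStringSet.
#' @param genome a named [Biostrings::DNAStringSet] of contigs.
#' @param ... passed to [anchorMatch()].
#' @return A [MatchBlocks-class] object with \code{target_name} set to
#'   contig names.
#' @export
matchToGenome <- function(query, genome, ...) {
  res <- lapply(seq_along(genome), function(i) {
    nm <- names(genome)[i]
    if (is.null(nm)) nm <- paste0("contig", i)
    as.data.frame(anchorMatch(query, genome[[i]], targetName = nm, ...))
  })
  MatchBlocks(do.call(rbind, res))
}

#' Match all contigs of one genome against another genome
#'
#' All-vs-all contig comparison between two assemblies via
#' [anchorMatch()]; the workhorse for inter-strain comparisons on
#' synthetic panels when no external PAF is supplied.
#'
#' @param genomeA,genomeB named [Biostrings::DNAStringSet] assemblies.
#' @param ... passed to [anchorMatch()].
#' @return A [MatchBlocks-class] object.
#' @export
matchGenomes <- function(genomeA, genomeB, ...) {
  res <- list()
  for (i in seq_along(genomeA)) {
    qn <- names(genomeA)[i]
    if (is.null(qn)) qn <- paste0("contig", i)
    for (j in seq_along(genomeB)) {
      tn <- names(genomeB)[j]
      if (is.null(tn)) tn <- paste0("contig", j)
      res <- c(res, list(as.data.frame(
        anchorMatch(genomeA[[i]], genomeB[[j]],
                    queryName = qn, targetName = tn, ...))))
    }
  }
  MatchBlocks(do.call(rbind, res))
}
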