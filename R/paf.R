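#' Read pairwise matches from a PAF file
#'
#' Parses the 12 mandatory columns of the Pairwise mApping Format as
#' emitted by whole-genome aligners (e.g. minimap2 with \code{-cx asm20}).
#' Column 10 (number of matching bases) and column 11 (block length)
#' define the percent identity of each block as
#' \code{100 * matches / block_length}. Optional SAM-style tags beyond
#' column 12 are ignored.
#'
#' @param path path to a PAF file (may be empty).
#' @return A [MatchBlocks-class] object, one block per line.
#' @examples
#' paf <- tempfile(fileext = ".paf")
#' writeLines(paste("q", 1000, 0, 900, "+", "t", 2000, 100, 1000, 900, 1000, 60,
#'                  sep = "\t"), paf)
#' readPaf(paf)
#' @export
readPaf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(MatchBlocks())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12))
    stop("malformed PAF line ", which(nf < 12)[1],
         ": fewer than 12 mandatory columns")
  m <- t(vapply(fields, function(f) f[1:12], character(12)))
  num <- function(j) {
    v <- suppressWarnings(as.numeric(m[, j]))
    if (anyNA(v))
      stop("malformed PAF line ", which(is.na(v))[1],
           ": column ", j, " is not numeric")
    v
  }
  b <- data.frame(query_name = m[, 1], query_length = num(2),
                  query_start = num(3), query_end = num(4),
                  strand = m[, 5], target_name = m[, 6],
                  target_length = num(7), target_start = num(8),
                  target_end = num(9), matched_bases = num(10),
                  block_length = num(11))
  bad <- b$query_end <= b$query_start | b$target_end <= b$target_start
  if (any(bad))
    stop("malformed PAF line ", which(bad)[1], ": end coordinate <= start")
  MatchBlocks(b)
}

#' Write match blocks to a PAF file
#'
#' Emits the 12 mandatory PAF columns (mapping quality written as 255,
#' i.e. unavailable). \code{readPaf(writePaf(x))} round-trips exactly.
#'
#' @param x A [MatchBlocks-class] object.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writePaf <- function(x, path) {
  b <- as.data.frame(x)
  fmt <- function(v) format(v, scientific = FALSE, trim = TRUE)
  lines <- paste(b$query_name, fmt(b$query_length), fmt(b$query_start),
                 fmt(b$query_end), b$strand, b$target_name,
                 fmt(b$target_length), fmt(b$target_start),
                 fmt(b$target_end), fmt(b$matched_bases),
                 fmt(b$block_length), 255L, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
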