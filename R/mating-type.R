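#' @importFrom Biostrings translate subseq DNAStringSet
NULL

# amino-acid k-mers of all 3 forward frames of a DNA string
.aaFrames <- function(dna) {
  s <- DNAString(gsub("[^ACGTacgt]", "A", as.character(dna)))
  lapply(0:2, function(f) {
    sub <- subseq(s, start = f + 1,
                  end = f + ((length(s) - f) %/% 3) * 3)
    if (length(sub) < 3) return("")
    as.character(suppressWarnings(translate(sub, if.fuzzy.codon = "solve")))
  })
}

.aaKmers <- function(aa, k = 8L) {
  n <- nchar(aa)
  if (n < k) return(character(0))
  unique(substring(aa, seq_len(n - k + 1L), seq(k, n)))
}

# translated k-mer similarity of a genome against one idiomorph:
# fraction of the idiomorph's translated k-mers (best frame) found
# anywhere in the six-frame translation of the genome
.idiomorphScore <- function(genome, ref, k = 8L) {
  gk <- unique(unlist(lapply(seq_along(genome), function(i) {
    fwd <- .aaFrames(genome[[i]])
    rev <- .aaFrames(reverseComplement(genome[[i]]))
    unlist(lapply(c(fwd, rev), .aaKmers, k = k))
  })))
  best <- 0
  for (fr in .aaFrames(ref)) {
    rk <- .aaKmers(fr, k)
    if (!length(rk)) next
    best <- max(best, mean(rk %in% gk))
  }
  best
}

#' Classify the mating-type idiomorph carried by an assembly
#'
#' Fungal mating-type loci carry one of two non-homologous idiomorphs
#' (MAT1-1 or MAT1-2). The assembly is scanned against reference
#' idiomorph sequences by six-frame translated similarity (shared
#' amino-acid k-mers between the translated idiomorph and the six-frame
#' translation of the assembly, in the spirit of a tblastx search): the
#' call is the idiomorph whose score exceeds \code{minScore}, "both" is
#' flagged as an anomaly, "none" when neither scores.
#'
#' @param assembly a [Biostrings::DNAStringSet] of contigs.
#' @param references named [Biostrings::DNAStringSet] with elements
#'   \code{MAT1-1} and \code{MAT1-2}.
#' @param minScore minimum fraction of idiomorph translated k-mers found.
#' @param k amino-acid k-mer length.
#' @return list with \code{call} in \code{MAT1-1}, \code{MAT1-2},
#'   \code{none}, \code{both}, and the two \code{scores}.
#' @export
matingType <- function(assembly, references, minScore = 0.25, k = 8L) {
  if (is.null(references) || length(references) < 2 ||
      !all(c("MAT1-1", "MAT1-2") %in% names(references)))
    stop("reference idiomorph sequences MAT1-1 and MAT1-2 are required")
  s1 <- .idiomorphScore(assembly, references[["MAT1-1"]], k)
  s2 <- .idiomorphScore(assembly, references[["MAT1-2"]], k)
  call <- if (s1 >= minScore && s2 >= minScore) "both"
  else if (s1 >= minScore) "MAT1-1"
  else if (s2 >= minScore) "MAT1-2"
  else "none"
  list(call = call, scores = c("MAT1-1" = s1, "MAT1-2" = s2))
}

#' Mating-type composition of a strain panel
#'
#' Classifies every assembly and tabulates idiomorph counts; a population
#' carrying a single idiomorph can only reproduce asexually.
#'
#' @param assemblies named list of [Biostrings::DNAStringSet].
#' @param references as in [matingType()].
#' @param ... passed to [matingType()].
#' @return list with \code{calls} (named character) and \code{counts}
#'   (table).
#' @export
matingTypeSummary <- function(assemblies, references, ...) {
  calls <- vapply(assemblies, function(a)
    matingType(a, references, ...)$call, character(1))
  list(calls = calls, counts = table(factor(calls, levels =
    c("MAT1-1", "MAT1-2", "none", "both"))))
}
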