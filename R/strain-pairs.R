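#' Compute all inter-species strain-pair matches for a simulated panel
#'
#' Convenience wrapper around [matchGenomes()] producing exactly the
#' inputs [detectCandidates()] expects from a [simulatePanel()] result:
#' matches for every strain pair between two species, plus the
#' strain-to-reference lift matches for non-reference strains.
#'
#' @param panel result of [simulatePanel()].
#' @param speciesA,speciesB species indices to compare.
#' @param k,minBlock passed to [anchorMatch()].
#' @return list with \code{pairMatches}, \code{liftA}, \code{liftB},
#'   \code{refA}, \code{refB}, ready to splice into [detectCandidates()].
#' @export
panelPairMatches <- function(panel, speciesA = 1, speciesB = 2, k = 15L,
                             minBlock = 1000L) {
  strainsA <- names(panel$species)[panel$species == speciesA]
  strainsB <- names(panel$species)[panel$species == speciesB]
  refA <- sprintf("sp%d_s1", speciesA)
  refB <- sprintf("sp%d_s1", speciesB)
  pairMatches <- list()
  for (sa in strainsA) {
    for (sb in strainsB) {
      pairMatches[[length(pairMatches) + 1L]] <-
        list(strainA = sa, strainB = sb,
             blocks = matchGenomes(panel$assemblies[[sa]],
                                   panel$assemblies[[sb]],
                                   k = k, minBlock = minBlock))
    }
  }
  liftA <- lapply(setdiff(strainsA, refA), function(sa)
    matchGenomes(panel$assemblies[[sa]], panel$assemblies[[refA]],
                 k = k, minBlock = minBlock))
  names(liftA) <- setdiff(strainsA, refA)
  liftB <- lapply(setdiff(strainsB, refB), function(sb)
    matchGenomes(panel$assemblies[[sb]], panel$assemblies[[refB]],
                 k = k, minBlock = minBlock))
  names(liftB) <- setdiff(strainsB, refB)
  list(pairMatches = pairMatches, liftA = liftA, liftB = liftB,
       refA = refA, refB = refB)
}
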