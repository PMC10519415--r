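#' Calibrate HTR detection thresholds from a control species pair
#'
#' Given pairwise matches between a control pair of species whose
#' phylogenetic distance equals that of the focal pair (but which share no
#' recent gene flow), derives the thresholds above which a focal match is
#' longer and more similar than vertical descent can explain. The
#' identity threshold is the highest control identity among matches of at
#' least \code{minMatch} bp, rounded down to an integer percent; the
#' length threshold is the second-longest control match among those at or
#' above that identity, rounded up to the nearest 100 bp (the longest is
#' tolerated as a one-off). With fewer than two qualifying matches the
#' longest is used and the result flagged under-powered. Both rounding
#' rules can be overridden.
#'
#' @param controlMatches A [MatchBlocks-class] of control-pair matches.
#' @param minMatch minimum control match length considered (bp).
#' @param roundIdentity,roundLength functions applied to the raw identity
#'   percent and length before reporting.
#' @return A [ThresholdSet-class].
#' @examples
#' b <- data.frame(query_name = "q", query_length = 2e6,
#'                 query_start = 0, query_end = c(11414, 6972, 3000),
#'                 strand = "+", target_name = "t", target_length = 2e6,
#'                 target_start = 0, target_end = c(11414, 6972, 3000),
#'                 matched_bases = round(0.9821 * c(11414, 6972, 3000)),
#'                 block_length = c(11414, 6972, 3000))
#' calibrateThresholds(MatchBlocks(b))
#' @export
calibrateThresholds <- function(controlMatches, minMatch = 1000,
                                roundIdentity = floor,
                                roundLength = function(x) ceiling(x / 100) * 100) {
  b <- as.data.frame(controlMatches)
  qual <- b[b$block_length >= minMatch, , drop = FALSE]
  if (!nrow(qual))
    stop("no control matches of length >= ", minMatch,
         "; provide a larger control match set")
  ids <- 100 * qual$matched_bases / qual$block_length
  max_id <- max(ids)
  id_thr <- roundIdentity(max_id)
  if (id_thr < 50)
    warning("calibrated identity threshold (", id_thr,
            "%) is implausibly low; check the control pair")
  top <- sort(qual$block_length[ids >= id_thr], decreasing = TRUE)
  underpowered <- length(top) < 2
  len_raw <- if (underpowered) top[1] else top[2]
  new("ThresholdSet",
      identityThreshold = as.numeric(id_thr),
      lengthThreshold = as.numeric(roundLength(len_raw)),
      provenance = list(max_control_identity = max_id,
                        longest_control_match = top[1],
                        second_longest_control_match =
                          if (underpowered) NA_real_ else top[2]),
      underpowered = underpowered)
}
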