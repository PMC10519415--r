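#' Simulate per-gene McDonald-Kreitman count tables
#'
#' Draws per-gene (PS, PR, DS, DR) counts from the same hierarchical
#' Poisson log-linear model fitted by [snipreFit()]: the log mean of each
#' cell is a site-count offset plus shared fixed effects for the
#' replacement indicator, the divergence indicator and their interaction,
#' plus gene-level random effects for mutation rate (intercept) and
#' divergence, and a gene-level selection effect on the
#' replacement-by-divergence interaction. Genes of class "positive"
#' ("negative") get selection effect \code{+effect} (\code{-effect});
#' neutral genes get 0.
#'
#' @param selection data.frame with one row per gene and columns
#'   \code{class} (\code{positive}/\code{negative}/\code{neutral}) and
#'   optionally \code{effect} (log-scale magnitude, default 1.5).
#' @param seed integer RNG seed.
#' @param baseline named list of model parameters: \code{beta0}
#'   (log per-site synonymous polymorphism rate), \code{betaR}
#'   (replacement), \code{betaD} (divergence), \code{betaRD}
#'   (interaction), \code{sigmaU} and \code{sigmaD} (gene random-effect
#'   scales), \code{meanCodons} (mean gene length in codons).
#' @return list with \code{counts} (data.frame gene_id, PS, PR, DS, DR,
#'   Lsyn, Lrep), \code{truth} (planted class, effect and random effects)
#'   and \code{baseline}.
#' @examples
#' sel <- data.frame(class = rep(c("positive", "neutral"), c(5, 45)))
#' sim <- simulateMKCounts(sel, seed = 1)
#' head(sim$counts)
#' @export
simulateMKCounts <- function(selection, seed = 1L,
                             baseline = list(beta0 = log(0.03), betaR = -1,
                                             betaD = 0.5, betaRD = 0,
                                             sigmaU = 0.5, sigmaD = 0.2,
                                             meanCodons = 400)) {
  if (!is.data.frame(selection) || is.null(selection$class))
    stop("selection must be a data.frame with a 'class' column")
  cls <- as.character(selection$class)
  if (!all(cls %in% c("positive", "negative", "neutral")))
    stop("selection$class must be positive, negative or neutral")
  eff <- if (is.null(selection$effect)) rep(1.5, length(cls)) else
    selection$effect
  if (any(!is.finite(eff))) stop("effect sizes must be finite")
  nG <- length(cls)
  set.seed(seed)
  codons <- pmax(50, round(stats::rlnorm(nG, log(baseline$meanCodons), 0.3)))
  Lsyn <- 3 * codons * 0.25
  Lrep <- 3 * codons * 0.75
  if (any(Lsyn <= 0) || any(Lrep <= 0) || !is.finite(baseline$beta0) ||
      exp(baseline$beta0) <= 0)
    stop("degenerate generator: expected counts are zero everywhere")
  u <- stats::rnorm(nG, 0, baseline$sigmaU)
  d <- stats::rnorm(nG, 0, baseline$sigmaD)
  s <- ifelse(cls == "positive", eff, ifelse(cls == "negative", -eff, 0))
  lam <- function(R, D) {
    off <- if (R) log(Lrep) else log(Lsyn)
    exp(off + baseline$beta0 + baseline$betaR * R + baseline$betaD * D +
          baseline$betaRD * R * D + u + d * D + s * R * D)
  }
  counts <- data.frame(
    gene_id = sprintf("g%04d", seq_len(nG)),
    PS = stats::rpois(nG, lam(0, 0)), PR = stats::rpois(nG, lam(1, 0)),
    DS = stats::rpois(nG, lam(0, 1)), DR = stats::rpois(nG, lam(1, 1)),
    Lsyn = Lsyn, Lrep = Lrep)
  truth <- data.frame(gene_id = counts$gene_id, class = cls,
                      effect = s, u = u, d = d)
  list(counts = counts, truth = truth, baseline = baseline)
}
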