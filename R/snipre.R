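.snipre_model <- "
model {
  for (i in 1:N) {
    y[i] ~ dpois(mu[i])
    log(mu[i]) <- off[i] + beta0 + betaR * R[i] + betaD * D[i] +
      betaRD * R[i] * D[i] +
      u[gene[i]] + d[gene[i]] * D[i] + s[gene[i]] * R[i] * D[i]
  }
  for (g in 1:G) {
    u[g] ~ dnorm(0, tau_u)
    d[g] ~ dnorm(0, tau_d)
    s[g] ~ dnorm(0, tau_s)
  }
  beta0 ~ dnorm(0, 0.01)
  betaR ~ dnorm(0, 0.01)
  betaD ~ dnorm(0, 0.01)
  betaRD ~ dnorm(0, 0.01)
  sigma_u ~ dnorm(0, 0.16) T(0,)
  sigma_d ~ dnorm(0, 0.16) T(0,)
  sigma_s ~ dnorm(0, 0.16) T(0,)
  tau_u <- pow(sigma_u, -2)
  tau_d <- pow(sigma_d, -2)
  tau_s <- pow(sigma_s, -2)
}"

#' Bayesian Poisson log-linear selection classifier
#'
#' Hierarchical generalization of the McDonald-Kreitman framework: the
#' four per-gene counts (PS, PR, DS, DR) are modelled as Poisson with a
#' log mean built from a synonymous/replacement site-count offset, shared
#' fixed effects for the replacement indicator R, the divergence
#' indicator D and their interaction, and gene-level random effects for
#' mutation rate (intercept), divergence rate, and a selection effect on
#' the R x D interaction. A gene whose selection effect has its 95\%
#' credible interval entirely above (below) zero shows more (less)
#' nonsynonymous divergence than its own polymorphism predicts and is
#' classified as under positive (purifying) selection; otherwise neutral.
#' No assumption on demography or reproductive mode is made, which is
#' what makes the approach usable for clonal or recently bottlenecked
#' populations. Priors are weakly informative: normal(0, 10) on fixed
#' effects, half-normal(0, 2.5) on random-effect scales. Posterior
#' sampling is by MCMC (JAGS) with a split-chain convergence diagnostic.
#'
#' @param counts data.frame with columns \code{gene_id}, \code{PS},
#'   \code{PR}, \code{DS}, \code{DR}, \code{Lsyn}, \code{Lrep}; at least
#'   20 genes (the hierarchical shrinkage needs replication).
#' @param iterations total MCMC iterations per chain.
#' @param burnIn iterations discarded as burn-in.
#' @param thin thinning interval.
#' @param seed integer seed (chains use seed, seed + 1, ...).
#' @param chains number of chains (>= 2 for the convergence diagnostic).
#' @return A [S4Vectors::DataFrame] with one row per gene:
#'   \code{gene_id}, \code{selectionEffect} (posterior mean),
#'   \code{ciLower}, \code{ciUpper}, \code{class}, \code{rhat},
#'   \code{converged}; metadata holds the fixed-effect posterior summary
#'   and the model string. A warning is issued when any split-chain
#'   diagnostic exceeds 1.1.
#' @export
snipreFit <- function(counts, iterations = 25000, burnIn = 10000,
                      thin = 4, seed = 1L, chains = 2L) {
  if (nrow(counts) < 20)
    stop("at least 20 genes are required for the hierarchical fit")
  if (any(counts$Lsyn <= 0) || any(counts$Lrep <= 0))
    stop("site counts must be positive")
  G <- nrow(counts)
  y <- c(counts$PS, counts$PR, counts$DS, counts$DR)
  R <- rep(c(0, 1, 0, 1), each = G)
  D <- rep(c(0, 0, 1, 1), each = G)
  off <- c(log(counts$Lsyn), log(counts$Lrep),
           log(counts$Lsyn), log(counts$Lrep))
  dat <- list(y = round(y), R = R, D = D, off = off,
              gene = rep(seq_len(G), 4), N = 4 * G, G = G)
  inits <- lapply(seq_len(chains), function(ch)
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = as.integer(seed) + ch - 1L))
  model <- rjags::jags.model(textConnection(.snipre_model), data = dat,
                             inits = inits, n.chains = chains, quiet = TRUE)
  update(model, burnIn, progress.bar = "none")
  monitors <- c("s", "beta0", "betaR", "betaD", "betaRD",
                "sigma_u", "sigma_d", "sigma_s")
  samp <- rjags::coda.samples(model, monitors, n.iter = iterations - burnIn,
                              thin = thin, progress.bar = "none")
  m <- do.call(rbind, lapply(samp, as.matrix))
  rhat <- tryCatch(
    coda::gelman.diag(samp, multivariate = FALSE, autoburnin = FALSE)$psrf[, 1],
    error = function(e) stats::setNames(rep(NA_real_, ncol(m)), colnames(m)))
  s_cols <- sprintf("s[%d]", seq_len(G))
  eff <- colMeans(m[, s_cols, drop = FALSE])
  qs <- apply(m[, s_cols, drop = FALSE], 2, stats::quantile,
              probs = c(0.025, 0.975))
  cls <- ifelse(qs[1, ] > 0, "positive",
                ifelse(qs[2, ] < 0, "negative", "neutral"))
  s_rhat <- rhat[s_cols]
  out <- DataFrame(gene_id = counts$gene_id,
                   selectionEffect = unname(eff),
                   ciLower = unname(qs[1, ]), ciUpper = unname(qs[2, ]),
                   class = unname(cls), rhat = unname(s_rhat),
                   converged = unname(is.na(s_rhat) | s_rhat <= 1.1))
  fixed <- setdiff(colnames(m), s_cols)
  metadata(out) <- list(
    fixedEffects = data.frame(
      parameter = fixed,
      mean = colMeans(m[, fixed, drop = FALSE]),
      lower = apply(m[, fixed, drop = FALSE], 2, stats::quantile, 0.025),
      upper = apply(m[, fixed, drop = FALSE], 2, stats::quantile, 0.975),
      rhat = rhat[fixed]),
    mcmc = list(iterations = iterations, burnIn = burnIn, thin = thin,
                chains = chains, seed = seed))
  bad <- !is.na(rhat) & rhat > 1.1
  if (any(bad))
    warning(sum(bad), " parameter(s) with split-chain diagnostic > 1.1; ",
            "results flagged, consider more iterations")
  out
}

#' Functional-category enrichment of selection classes or gene sets
#'
#' Per COG category, a two-sided exact test of the 2x2 table (focal vs
#' non-focal genes) x (in category vs not), where focal genes are either
#' those with a given selection class or an explicit gene set (e.g. the
#' genes carried by HTRs). Categories absent from the tested genes are
#' omitted with a note. Benjamini-Hochberg q-values accompany the raw
#' p-values.
#'
#' @param x either a data.frame with \code{gene_id} and \code{class}
#'   (e.g. from [snipreFit()]) or a character vector of focal gene ids.
#' @param cogMap data.frame with \code{gene_id} and \code{category}; the
#'   universe is every mapped gene also present among the tested genes
#'   (or all mapped genes when \code{x} is a gene set).
#' @param class focal selection class when \code{x} is a calls table.
#' @return data.frame: \code{category}, \code{n_focal_in},
#'   \code{n_focal}, \code{n_in}, \code{n_universe}, \code{odds},
#'   \code{p}, \code{q}; attribute \code{omitted} lists categories
#'   without tested genes.
#' @export
categoryEnrichment <- function(x, cogMap, class = "positive") {
  if (is.null(cogMap) || !nrow(cogMap))
    stop("a non-empty gene-to-category map is required")
  if (is.data.frame(x) || is(x, "DataFrame")) {
    x <- as.data.frame(x)
    universe <- intersect(cogMap$gene_id, x$gene_id)
    focal <- intersect(x$gene_id[x$class == class], universe)
  } else {
    universe <- unique(cogMap$gene_id)
    focal <- intersect(as.character(x), universe)
  }
  if (!length(universe))
    stop("category map covers none of the tested genes")
  map <- cogMap[cogMap$gene_id %in% universe, , drop = FALSE]
  cats <- unique(map$category)
  res <- NULL
  omitted <- character(0)
  for (cc in cats) {
    in_cat <- unique(map$gene_id[map$category == cc])
    if (!length(in_cat)) { omitted <- c(omitted, cc); next }
    a <- length(intersect(focal, in_cat))
    b <- length(focal) - a
    c_ <- length(in_cat) - a
    d <- length(universe) - a - b - c_
    ft <- stats::fisher.test(matrix(c(a, b, c_, d), 2))
    res <- rbind(res, data.frame(category = cc, n_focal_in = a,
                                 n_focal = length(focal),
                                 n_in = length(in_cat),
                                 n_universe = length(universe),
                                 odds = unname(ft$estimate), p = ft$p.value))
  }
  res$q <- stats::p.adjust(res$p, method = "BH")
  rownames(res) <- NULL
  attr(res, "omitted") <- omitted
  res
}
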