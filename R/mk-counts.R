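#' @importFrom Biostrings GENETIC_CODE
NULL

.codonAA <- function(codon) GENETIC_CODE[[codon]]

# Count synonymous/nonsynonymous changes along the mutational paths
# between two codons: all orderings of the differing positions are
# enumerated, paths passing through a stop codon are excluded (all paths
# are used if every path hits a stop), and counts are averaged over the
# admissible paths (ties between minimal paths split equally).
.codonPathCounts <- function(c1, c2) {
  diffpos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  nd <- length(diffpos)
  if (nd == 0) return(c(syn = 0, rep = 0))
  perms <- if (nd == 1) list(diffpos) else {
    idx <- if (nd == 2) list(1:2, 2:1) else
      list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
           c(3, 1, 2), c(3, 2, 1))
    lapply(idx, function(p) diffpos[p])
  }
  paths <- lapply(perms, function(ord) {
    cur <- strsplit(c1, "")[[1]]
    tgt <- strsplit(c2, "")[[1]]
    syn <- 0; rp <- 0; valid <- TRUE
    for (p in ord) {
      aa_from <- .codonAA(paste(cur, collapse = ""))
      cur[p] <- tgt[p]
      aa_to <- .codonAA(paste(cur, collapse = ""))
      if (aa_to == "*" && paste(cur, collapse = "") != c2) valid <- FALSE
      if (aa_from == aa_to) syn <- syn + 1 else rp <- rp + 1
    }
    c(syn = syn, rep = rp, valid = valid)
  })
  m <- do.call(rbind, paths)
  use <- if (any(m[, "valid"] == 1)) m[m[, "valid"] == 1, , drop = FALSE] else m
  c(syn = mean(use[, "syn"]), rep = mean(use[, "rep"]))
}

# NG86-style synonymous/replacement site counts of one codon: each of
# the 3 positions contributes 1 site, split by the fraction of non-stop
# single-base alternatives that are synonymous.
.codonSites <- function(codon) {
  if (.codonAA(codon) == "*") return(c(syn = 0, rep = 0))
  nts <- strsplit(codon, "")[[1]]
  syn <- 0
  for (p in 1:3) {
    alts <- setdiff(c("A", "C", "G", "T"), nts[p])
    aa <- vapply(alts, function(a) {
      v <- nts; v[p] <- a
      .codonAA(paste(v, collapse = ""))
    }, character(1))
    ok <- aa != "*"
    if (any(ok)) syn <- syn + sum(aa[ok] == .codonAA(codon)) / sum(ok)
  }
  c(syn = syn, rep = 3 - syn)
}

.splitCodons <- function(s) {
  substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
}

#' Per-gene McDonald-Kreitman counts from codon alignments
#'
#' Walks a codon alignment of in-group sequences plus outgroup
#' sequence(s) and tallies synonymous (S) and replacement (R) changes as
#' polymorphic (P; the in-group varies, regardless of the outgroup state)
#' or fixed/divergent (D; the in-group is monomorphic and differs from
#' the outgroup consensus). Multi-position codons are resolved by
#' averaging over mutational paths (stop-free paths preferred, ties split
#' equally); polymorphic codons with more than two states are decomposed
#' as a star from the in-group consensus codon. Codons containing gaps or
#' ambiguity codes in a sequence exclude that sequence at that codon; a
#' codon is skipped (and tallied) when fewer than two in-group or one
#' outgroup sequence remain, and skipped with a warning when a stop codon
#' is met mid-sequence. Synonymous and replacement site totals are NG86
#' per-codon counts averaged over all sequences, weighted by each
#' sequence's non-missing codon count.
#'
#' @param ingroup,outgroup [Biostrings::DNAStringSet] codon alignments of
#'   equal width divisible by 3; at least 2 in-group and 1 outgroup
#'   sequences.
#' @param geneId gene identifier for the output row.
#' @return one-row data.frame: \code{gene_id}, \code{PS}, \code{PR},
#'   \code{DS}, \code{DR}, \code{Lsyn}, \code{Lrep},
#'   \code{skipped_codons}.
#' @export
mkCounts <- function(ingroup, outgroup, geneId = "gene") {
  wi <- unique(c(Biostrings::width(ingroup), Biostrings::width(outgroup)))
  if (length(wi) != 1) stop("all sequences must be aligned to equal length")
  if (wi %% 3 != 0) stop("alignment length must be divisible by 3")
  if (length(ingroup) < 2) stop("at least 2 in-group sequences required")
  if (length(outgroup) < 1) stop("at least 1 outgroup sequence required")
  ncod <- wi / 3
  in_cod <- lapply(as.character(ingroup), .splitCodons)
  out_cod <- lapply(as.character(outgroup), .splitCodons)
  valid <- function(cd) grepl("^[ACGT]{3}$", cd)
  PS <- PR <- DS <- DR <- 0
  skipped <- 0L
  stop_warned <- FALSE
  # site counts per sequence over its valid codons
  all_cod <- c(in_cod, out_cod)
  Ls <- vapply(all_cod, function(cods) {
    v <- cods[valid(cods) & vapply(cods, function(x)
      .codonAA(x) != "*", logical(1))]
    if (!length(v)) return(c(0, 0, 0))
    m <- vapply(v, .codonSites, numeric(2))
    c(sum(m["syn", ]), sum(m["rep", ]), length(v))
  }, numeric(3))
  w <- Ls[3, ]
  Lsyn <- if (sum(w)) sum(Ls[1, ] * w) / sum(w) else 0
  Lrep <- if (sum(w)) sum(Ls[2, ] * w) / sum(w) else 0
  for (ci in seq_len(ncod)) {
    ic <- toupper(vapply(in_cod, `[`, character(1), ci))
    oc <- toupper(vapply(out_cod, `[`, character(1), ci))
    ic <- ic[valid(ic)]
    oc <- oc[valid(oc)]
    if (length(ic) < 2 || length(oc) < 1) { skipped <- skipped + 1L; next }
    has_stop <- any(vapply(c(ic, oc), function(x) .codonAA(x) == "*",
                           logical(1)))
    if (has_stop && ci < ncod) {
      if (!stop_warned) {
        warning("stop codon mid-sequence; codon(s) skipped")
        stop_warned <- TRUE
      }
      skipped <- skipped + 1L
      next
    }
    if (has_stop) { skipped <- skipped + 1L; next }
    tab_o <- sort(table(oc), decreasing = TRUE)
    out_cons <- names(tab_o)[tab_o == max(tab_o)][1]
    uin <- unique(ic)
    if (length(uin) == 1L) {
      if (uin != out_cons) {
        ct <- .codonPathCounts(uin, out_cons)
        DS <- DS + ct["syn"]; DR <- DR + ct["rep"]
      }
    } else {
      tab_i <- sort(table(ic), decreasing = TRUE)
      in_cons <- names(tab_i)[tab_i == max(tab_i)][1]
      for (alt in setdiff(uin, in_cons)) {
        ct <- .codonPathCounts(in_cons, alt)
        PS <- PS + ct["syn"]; PR <- PR + ct["rep"]
      }
    }
  }
  data.frame(gene_id = geneId, PS = unname(PS), PR = unname(PR),
             DS = unname(DS), DR = unname(DR), Lsyn = Lsyn, Lrep = Lrep,
             skipped_codons = skipped)
}

#' Classical McDonald-Kreitman test of one gene
#'
#' Neutrality index \code{NI = (PR/PS) / (DR/DS)} and the two-sided exact
#' conditional test on the 2x2 polymorphism/divergence x
#' synonymous/replacement table.
#'
#' @param mk one-row data.frame with PS, PR, DS, DR (e.g. from
#'   [mkCounts()]).
#' @return list with \code{NI} (NA when undefined by a zero margin) and
#'   \code{p}.
#' @examples
#' mkFisher(data.frame(PS = 42, PR = 2, DS = 17, DR = 7))
#' @export
mkFisher <- function(mk) {
  PS <- round(mk$PS); PR <- round(mk$PR)
  DS <- round(mk$DS); DR <- round(mk$DR)
  NI <- if (PS * DR == 0) NA_real_ else (PR / PS) / (DR / DS)
  tab <- matrix(c(PR, PS, DR, DS), 2,
                dimnames = list(c("R", "S"), c("P", "D")))
  list(NI = NI, p = stats::fisher.test(tab)$p.value)
}
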