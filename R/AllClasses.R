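#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' Pairwise local-alignment match blocks
#'
#' An S4 container for pairwise local-alignment matches between two
#' sequences, the atom of all HTR logic. Coordinates are 0-based
#' half-open on both query and target, as in the PAF format. Identity is
#' defined as the number of matching bases divided by the block length,
#' expressed in percent.
#'
#' @slot blocks A \code{data.frame} with columns \code{query_name},
#'   \code{query_length}, \code{query_start}, \code{query_end},
#'   \code{strand}, \code{target_name}, \code{target_length},
#'   \code{target_start}, \code{target_end}, \code{matched_bases},
#'   \code{block_length}.
#'
#' @seealso [MatchBlocks()], [readPaf()], [anchorMatch()]
#' @export
setClass("MatchBlocks", representation(blocks = "data.frame"))

.matchblock_cols <- c("query_name", "query_length", "query_start",
                      "query_end", "strand", "target_name", "target_length",
                      "target_start", "target_end", "matched_bases",
                      "block_length")

setValidity("MatchBlocks", function(object) {
  b <- object@blocks
  missing <- setdiff(.matchblock_cols, names(b))
  if (length(missing))
    return(paste("missing columns:", paste(missing, collapse = ", ")))
  if (nrow(b) == 0L) return(TRUE)
  if (!all(b$strand %in% c("+", "-")))
    return("strand must be '+' or '-'")
  bad <- b$query_start < 0 | b$query_end <= b$query_start |
    b$target_start < 0 | b$target_end <= b$target_start
  if (any(bad))
    return(sprintf("invalid coordinates in %d block(s): start must be >= 0 and < end",
                   sum(bad)))
  if (any(b$query_end > b$query_length) || any(b$target_end > b$target_length))
    return("block end beyond sequence length")
  if (any(b$matched_bases > b$block_length))
    return("matched_bases exceeds block_length")
  if (any(b$matched_bases < 0) || any(b$block_length <= 0))
    return("matched_bases must be >= 0 and block_length > 0")
  TRUE
})

#' Construct a MatchBlocks object
#'
#' @param blocks data.frame of match blocks (see class description).
#' @return A [MatchBlocks-class] object.
#' @export
MatchBlocks <- function(blocks = NULL) {
  if (is.null(blocks))
    blocks <- as.data.frame(setNames(rep(list(numeric(0)), length(.matchblock_cols)),
                                     .matchblock_cols))
  blocks$query_name <- as.character(blocks$query_name)
  blocks$target_name <- as.character(blocks$target_name)
  blocks$strand <- as.character(blocks$strand)
  rownames(blocks) <- NULL
  new("MatchBlocks", blocks = blocks[, .matchblock_cols, drop = FALSE])
}

#' @describeIn MatchBlocks-class number of match blocks
#' @param x A MatchBlocks object.
#' @export
setMethod("length", "MatchBlocks", function(x) nrow(x@blocks))

#' @export
setMethod("as.data.frame", "MatchBlocks", function(x, ...) x@blocks)

#' @export
setMethod("[", "MatchBlocks", function(x, i, j, ..., drop = TRUE) {
  MatchBlocks(x@blocks[i, , drop = FALSE])
})

setMethod("show", "MatchBlocks", function(object) {
  cat(sprintf("MatchBlocks with %d block(s)\n", length(object)))
  if (length(object)) {
    b <- object@blocks
    cat(sprintf("  identity: %.2f-%.2f%%, block length: %d-%d bp\n",
                min(identityPercent(object)), max(identityPercent(object)),
                min(b$block_length), max(b$block_length)))
  }
})

#' Percent identity of match blocks
#'
#' Identity is \code{100 * matched_bases / block_length}.
#'
#' @param x A [MatchBlocks-class] object.
#' @return Numeric vector of percent identities.
#' @export
identityPercent <- function(x) {
  b <- as.data.frame(x)
  100 * b$matched_bases / b$block_length
}

#' Detection thresholds calibrated from a control species pair
#'
#' Holds the identity (percent) and length (bp) thresholds above which a
#' match between two focal genomes is considered a horizontal-transfer
#' candidate rather than background similarity, together with the control
#' statistics they were derived from.
#'
#' @slot identityThreshold percent identity threshold.
#' @slot lengthThreshold length threshold in bp.
#' @slot provenance list with \code{max_control_identity},
#'   \code{longest_control_match}, \code{second_longest_control_match}.
#' @slot underpowered logical; TRUE when fewer than two qualifying control
#'   matches were available and the longest had to be used.
#' @export
setClass("ThresholdSet",
         representation(identityThreshold = "numeric",
                        lengthThreshold = "numeric",
                        provenance = "list",
                        underpowered = "logical"))

setValidity("ThresholdSet", function(object) {
  if (length(object@identityThreshold) != 1 ||
      object@identityThreshold <= 0 || object@identityThreshold > 100)
    return("identityThreshold must be a single value in (0, 100]")
  if (length(object@lengthThreshold) != 1 || object@lengthThreshold <= 0)
    return("lengthThreshold must be a single positive value")
  TRUE
})

setMethod("show", "ThresholdSet", function(object) {
  cat(sprintf("ThresholdSet: identity >= %g%%, length >= %g bp\n",
              object@identityThreshold, object@lengthThreshold))
  p <- object@provenance
  if (length(p))
    cat(sprintf("  control: max identity %.2f%%, longest %g bp, second longest %g bp\n",
                p$max_control_identity, p$longest_control_match,
                p$second_longest_control_match))
  if (isTRUE(object@underpowered))
    cat("  WARNING: under-powered control set (fewer than 2 qualifying matches)\n")
})

#' @rdname ThresholdSet-class
#' @param x A ThresholdSet.
#' @export
identityThreshold <- function(x) x@identityThreshold

#' @rdname ThresholdSet-class
#' @export
lengthThreshold <- function(x) x@lengthThreshold

#' Haploid biallelic SNP table
#'
#' Per-site metadata (VCF INFO metrics) plus a sites-by-strains haploid
#' genotype matrix coded 0 (reference allele), 1 (alternate allele) or NA
#' (missing). Positions are 1-based as in VCF.
#'
#' @slot info data.frame with columns \code{contig}, \code{pos},
#'   \code{ref}, \code{alt}, \code{QD}, \code{MQ}, \code{FS},
#'   \code{MQRankSum}, \code{ReadPosRankSum}.
#' @slot geno integer matrix, sites x strains, entries 0/1/NA.
#' @slot genomeLength reference genome length in bp used for per-site
#'   scaling of diversity statistics.
#' @slot filterLog data.frame tallying sites removed per filter.
#' @export
setClass("VariantTable",
         representation(info = "data.frame", geno = "matrix",
                        genomeLength = "numeric", filterLog = "data.frame"))

setValidity("VariantTable", function(object) {
  if (nrow(object@info) != nrow(object@geno))
    return("info and geno must have the same number of sites")
  if (length(object@genomeLength) != 1 || object@genomeLength <= 0)
    return("genomeLength must be a single positive number")
  g <- object@geno
  if (length(g) && !all(g %in% c(0L, 1L) | is.na(g)))
    return("genotypes must be 0, 1 or NA (haploid biallelic)")
  TRUE
})

#' Construct a VariantTable
#' @param info per-site data.frame (see class description); missing INFO
#'   columns are filled with NA.
#' @param geno sites x strains integer matrix of 0/1/NA haploid calls.
#' @param genomeLength reference length in bp.
#' @param filterLog optional data.frame of per-filter removal counts.
#' @return A [VariantTable-class] object.
#' @export
VariantTable <- function(info, geno, genomeLength,
                         filterLog = data.frame(filter = character(0),
                                                removed = integer(0))) {
  for (col in c("QD", "MQ", "FS", "MQRankSum", "ReadPosRankSum"))
    if (is.null(info[[col]])) info[[col]] <- rep(NA_real_, nrow(info))
  if (is.null(info$contig)) info$contig <- rep("chr1", nrow(info))
  storage.mode(geno) <- "integer"
  rownames(info) <- NULL
  new("VariantTable", info = info, geno = geno,
      genomeLength = as.numeric(genomeLength), filterLog = filterLog)
}

#' @rdname VariantTable-class
#' @param x A VariantTable.
#' @export
genotypes <- function(x) x@geno

#' @rdname VariantTable-class
#' @export
variantInfo <- function(x) x@info

#' @rdname VariantTable-class
#' @export
genomeLength <- function(x) x@genomeLength

#' @rdname VariantTable-class
#' @export
filterLog <- function(x) x@filterLog

#' @rdname VariantTable-class
#' @export
nSites <- function(x) nrow(x@geno)

#' @rdname VariantTable-class
#' @export
nStrains <- function(x) ncol(x@geno)

setMethod("show", "VariantTable", function(object) {
  cat(sprintf("VariantTable: %d site(s) x %d strain(s), L = %g bp\n",
              nSites(object), nStrains(object), genomeLength(object)))
  if (nrow(object@filterLog))
    cat("  filters applied:",
        paste(sprintf("%s=%d", object@filterLog$filter,
                      object@filterLog$removed), collapse = ", "), "\n")
})

#' Within-species diversity statistics
#'
#' @slot pi per-site nucleotide diversity (mean pairwise differences / L).
#' @slot thetaW per-site Watterson estimator S / (a1 * L).
#' @slot S number of segregating sites.
#' @slot tajimaD Tajima's D; NA when S = 0.
#' @slot dNullCI 95\% null interval for D from fixed-S coalescent
#'   resampling (length-2 numeric, NA when not computed).
#' @slot n sample size (number of strains).
#' @slot L reference length used for scaling.
#' @export
setClass("DiversityStats",
         representation(pi = "numeric", thetaW = "numeric", S = "numeric",
                        tajimaD = "numeric", dNullCI = "numeric",
                        n = "numeric", L = "numeric"))

setValidity("DiversityStats", function(object) {
  if (object@pi < 0 || object@thetaW < 0 || object@S < 0)
    return("pi, thetaW and S must be non-negative")
  TRUE
})

setMethod("show", "DiversityStats", function(object) {
  cat(sprintf("DiversityStats (n = %d, L = %g bp)\n",
              as.integer(object@n), object@L))
  cat(sprintf("  pi = %.4g /bp, thetaW = %.4g /bp, S = %d\n",
              object@pi, object@thetaW, as.integer(object@S)))
  if (is.na(object@tajimaD)) {
    cat("  Tajima's D: undefined (S = 0)\n")
  } else {
    cat(sprintf("  Tajima's D = %.3f", object@tajimaD))
    if (!anyNA(object@dNullCI))
      cat(sprintf(" (95%% null interval [%.3f; %.3f])",
                  object@dNullCI[1], object@dNullCI[2]))
    cat("\n")
  }
})

#' Synthetic-panel simulation configuration
#'
#' Defines the study conditions the synthetic-genome generator emulates:
#' two (or more) focal species separated by substantial background
#' divergence, each with several near-clonal strains, planted
#' near-identical HTR insertions at different loci per species, TE
#' annotations (optionally overlapping HTR termini), within-species SNPs
#' at a given theta, and per-gene selection classes for the
#' McDonald-Kreitman layer.
#'
#' @slot seed integer RNG seed; all generator output is a deterministic
#'   function of seed + configuration.
#' @slot nSpecies number of focal species.
#' @slot backgroundDivergence per-site substitution divergence between
#'   focal species; must exceed 1 - identityThreshold/100 used downstream
#'   so that background never passes detection.
#' @slot genomeLength genome length in bp (single contig per genome unless
#'   \code{nContigs} > 1).
#' @slot nStrainsPerSpecies strains per species.
#' @slot theta per-site within-species diversity.
#' @slot htrSpecs data.frame with columns \code{length} (bp),
#'   \code{identity} (fraction, donor-to-copy), \code{species}
#'   (comma-separated recipient species indices), \code{te_at_edges}
#'   (logical).
#' @slot teDensity fraction of the genome annotated as TE.
#' @slot nGenes number of gene models to annotate.
#' @slot selectionSpec data.frame with columns \code{class}
#'   (positive/negative/neutral) and \code{effect} (log-scale effect on
#'   nonsynonymous divergence rate).
#' @slot gcContent GC fraction of the i.i.d. genome composition.
#' @slot nContigs number of contigs each genome is split into.
#' @export
setClass("SimulationConfig",
         representation(seed = "numeric", nSpecies = "numeric",
                        backgroundDivergence = "numeric",
                        genomeLength = "numeric",
                        nStrainsPerSpecies = "numeric", theta = "numeric",
                        htrSpecs = "data.frame", teDensity = "numeric",
                        nGenes = "numeric", selectionSpec = "data.frame",
                        gcContent = "numeric", nContigs = "numeric"))

setValidity("SimulationConfig", function(object) {
  chk <- function(cond, msg) if (!cond) msg else NULL
  errs <- c(
    chk(object@genomeLength > 0, "genome_length: must be positive"),
    chk(object@nSpecies >= 1, "n_species: must be >= 1"),
    chk(object@nStrainsPerSpecies >= 1, "n_strains_per_species: must be >= 1"),
    chk(object@backgroundDivergence >= 0 && object@backgroundDivergence < 1,
        "background_divergence: must be in [0, 1)"),
    chk(object@theta >= 0, "theta: must be >= 0"),
    chk(object@teDensity >= 0 && object@teDensity < 1,
        "te_density: must be in [0, 1)"),
    chk(object@gcContent > 0 && object@gcContent < 1,
        "gc_content: must be in (0, 1)"))
  h <- object@htrSpecs
  if (nrow(h)) {
    errs <- c(errs,
      chk(all(h$length > 0), "htr_specs$length: must be positive"),
      chk(all(h$length < object@genomeLength / 4),
          "htr_specs$length: must be < genome_length / 4"),
      chk(all(h$identity > 0 & h$identity <= 1),
          "htr_specs$identity: must be in (0, 1]"))
  }
  errs <- errs[!vapply(errs, is.null, logical(1))]
  if (length(errs)) return(unlist(errs))
  TRUE
})

#' Construct a SimulationConfig
#'
#' Defaults emulate two distant fungal species (12\% background
#' divergence, as between the dry-cured-meat species pair and well above
#' the 2\% similarity allowance of the detection threshold) with a handful
#' of near-clonal strains each, moderate within-species diversity, and a
#' 5\% TE load.
#'
#' @param seed integer RNG seed.
#' @param nSpecies,backgroundDivergence,genomeLength,nStrainsPerSpecies
#'   see [SimulationConfig-class].
#' @param theta,htrSpecs,teDensity,nGenes,selectionSpec,gcContent,nContigs
#'   see [SimulationConfig-class].
#' @return A validated [SimulationConfig-class].
#' @export
simulationConfig <- function(seed = 1L, nSpecies = 2, backgroundDivergence = 0.12,
                             genomeLength = 3e5, nStrainsPerSpecies = 3,
                             theta = 0.005, htrSpecs = htrSpec(),
                             teDensity = 0.05, nGenes = 50,
                             selectionSpec = data.frame(class = character(0),
                                                        effect = numeric(0)),
                             gcContent = 0.5, nContigs = 1) {
  cfg <- new("SimulationConfig", seed = as.numeric(seed), nSpecies = nSpecies,
             backgroundDivergence = backgroundDivergence,
             genomeLength = genomeLength,
             nStrainsPerSpecies = nStrainsPerSpecies, theta = theta,
             htrSpecs = htrSpecs, teDensity = teDensity, nGenes = nGenes,
             selectionSpec = selectionSpec, gcContent = gcContent,
             nContigs = nContigs)
  msg <- validObject(cfg, test = TRUE)
  if (is.character(msg)) stop("invalid configuration: ", paste(msg, collapse = "; "))
  cfg
}

#' Describe planted HTR insertions
#'
#' @param length HTR lengths in bp.
#' @param identity donor-to-copy identity fraction (>= 0.98 mimics the
#'   near-identity of recent horizontal transfers).
#' @param species recipient species, comma-separated indices per HTR
#'   ("1,2" plants the region in both focal species, at different loci).
#' @param te_at_edges plant a TE annotation overlapping each HTR terminus.
#' @return data.frame suitable for the \code{htrSpecs} slot.
#' @export
htrSpec <- function(length = numeric(0), identity = 0.995, species = "1,2",
                    te_at_edges = FALSE) {
  if (!length(length))
    return(data.frame(length = numeric(0), identity = numeric(0),
                      species = character(0), te_at_edges = logical(0)))
  data.frame(length = length, identity = identity, species = species,
             te_at_edges = te_at_edges)
}

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf("SimulationConfig (seed %d): %d species x %d strains, L = %g bp\n",
              as.integer(object@seed), object@nSpecies,
              object@nStrainsPerSpecies, object@genomeLength))
  cat(sprintf("  divergence %.3f, theta %.4g, TE density %.2f, %d planted HTR(s)\n",
              object@backgroundDivergence, object@theta, object@teDensity,
              nrow(object@htrSpecs)))
})
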