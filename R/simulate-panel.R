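#' @importFrom Biostrings writeXStringSet
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
NULL

.NT <- c("A", "C", "G", "T")

# i.i.d. genome as integer codes 0..3 with a given GC fraction
.randomGenomeCode <- function(L, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  sample.int(4L, L, replace = TRUE, prob = p) - 1L
}

# substitute exactly m (or rate*L) positions to a different base
.mutateCode <- function(code, rate = NULL, m = NULL, positions = NULL) {
  L <- length(code)
  if (is.null(positions)) {
    if (is.null(m)) m <- round(rate * L)
    if (m == 0L) return(code)
    positions <- sample.int(L, m)
  }
  code[positions] <- (code[positions] + sample.int(3L, length(positions),
                                                   replace = TRUE)) %% 4L
  code
}

.codeToString <- function(code) {
  intToUtf8(c(65L, 67L, 71L, 84L)[code + 1L])
}

# place an interval of a given width avoiding occupied intervals
# (0-based half-open); returns c(start, end) or errors after many tries
.placeInterval <- function(width, L, occupied, margin = 1000, tries = 1000) {
  for (i in seq_len(tries)) {
    s <- sample.int(L - width, 1L) - 1L
    e <- s + width
    if (!nrow(occupied) ||
        all(e + margin <= occupied$start | s >= occupied$end + margin))
      return(c(s, e))
  }
  stop("could not place an interval of width ", width,
       "; genome too crowded")
}

#' Simulate a genome panel with planted horizontally transferred regions
#'
#' Generates \code{nSpecies} focal species as i.i.d. nucleotide genomes
#' separated by \code{backgroundDivergence} per-site substitutions, each
#' with \code{nStrainsPerSpecies} strains carrying within-species SNPs
#' drawn from a neutral coalescent at \code{theta}. Each HTR spec plants a
#' freshly drawn donor segment into every recipient species at an
#' independent locus, each copy mutated away from the donor so that the
#' expected pairwise identity between recipient copies equals the
#' configured identity. TE annotations are simulated intervals covering
#' \code{teDensity} of the genome; with \code{te_at_edges}, a TE interval
#' is planted across each HTR terminus. Mating-type idiomorphs (two
#' unrelated reference sequences) are planted at a species-specific locus
#' according to \code{matingTypes}.
#'
#' Coordinates in the truth tables are 0-based half-open on the species
#' reference strain (strain 1); substitution-only evolution keeps them
#' exact across all strains. Output is byte-identical for identical seed
#' and configuration.
#'
#' @param config A [SimulationConfig-class].
#' @param matingTypes optional character vector (values "MAT1-1"/"MAT1-2")
#'   recycled over strains within each species; NULL plants none.
#' @param outDir optional directory; when given, writes one FASTA per
#'   strain, GFF3 of genes and TEs, BED and TSV truth tables.
#' @return A list with elements \code{assemblies} (named list of
#'   [Biostrings::DNAStringSet], one per strain), \code{te} and
#'   \code{genes} (GRanges on reference-strain contigs), \code{truth}
#'   (list with \code{htrs} data.frame, \code{theta},
#'   \code{matingType} per strain), \code{matRefs} (DNAStringSet of the
#'   two idiomorph reference sequences), and \code{referenceStrains}.
#' @examples
#' cfg <- simulationConfig(seed = 1, genomeLength = 1e5,
#'                         htrSpecs = htrSpec(20000, 0.995))
#' panel <- simulatePanel(cfg)
#' names(panel$assemblies)
#' panel$truth$htrs
#' @export
simulatePanel <- function(config, matingTypes = NULL, outDir = NULL) {
  msg <- validObject(config, test = TRUE)
  if (is.character(msg))
    stop("invalid configuration: ", paste(msg, collapse = "; "))
  set.seed(config@seed)
  L <- config@genomeLength
  nsp <- config@nSpecies
  nst <- config@nStrainsPerSpecies
  hs <- config@htrSpecs

  base <- .randomGenomeCode(L, config@gcContent)
  species <- vector("list", nsp)
  species[[1]] <- base
  if (nsp > 1)
    for (s in 2:nsp)
      species[[s]] <- .mutateCode(base, rate = config@backgroundDivergence)

  occupied <- lapply(seq_len(nsp), function(s)
    data.frame(start = numeric(0), end = numeric(0)))
  truth_htr <- NULL

  # mating-type idiomorphs: two unrelated 3-kbp references
  mat_refs <- DNAStringSet(c("MAT1-1" = .codeToString(.randomGenomeCode(3000, 0.5)),
                             "MAT1-2" = .codeToString(.randomGenomeCode(3000, 0.5))))
  mat_locus <- integer(nsp)
  if (!is.null(matingTypes)) {
    for (s in seq_len(nsp)) {
      iv <- .placeInterval(3000, L, occupied[[s]])
      occupied[[s]] <- rbind(occupied[[s]], data.frame(start = iv[1], end = iv[2]))
      mat_locus[s] <- iv[1]
    }
  }

  if (nrow(hs)) {
    for (i in seq_len(nrow(hs))) {
      len <- hs$length[i]
      donor <- .randomGenomeCode(len, config@gcContent)
      recip <- as.integer(strsplit(as.character(hs$species[i]), ",")[[1]])
      r <- (1 - hs$identity[i]) / 2  # per-copy rate so copies differ at ~2r
      for (s in recip) {
        iv <- .placeInterval(len, L, occupied[[s]])
        occupied[[s]] <- rbind(occupied[[s]],
                               data.frame(start = iv[1], end = iv[2]))
        copy <- .mutateCode(donor, rate = r)
        species[[s]][(iv[1] + 1L):iv[2]] <- copy
        truth_htr <- rbind(truth_htr, data.frame(
          htr_id = sprintf("HTR_%02d", i), species = s,
          start = iv[1], end = iv[2], length = len,
          identity = hs$identity[i], te_at_edges = hs$te_at_edges[i]))
      }
    }
  }

  # strains: coalescent SNPs on top of each species sequence
  assemblies <- list()
  strain_names <- character(0)
  strain_species <- integer(0)
  mating <- character(0)
  for (s in seq_len(nsp)) {
    if (nst >= 2 && config@theta > 0) {
      hap <- coalescentHaplotypes(nst, L, theta = config@theta)
    } else {
      hap <- list(positions = integer(0), geno = matrix(0L, 0, nst))
    }
    alt_shift <- sample.int(3L, length(hap$positions), replace = TRUE)
    mt_s <- if (is.null(matingTypes)) rep(NA_character_, nst) else
      rep(matingTypes, length.out = nst)
    for (j in seq_len(nst)) {
      g <- species[[s]]
      der <- hap$positions[hap$geno[, j] == 1L]
      if (length(der))
        g[der] <- (g[der] + alt_shift[hap$geno[, j] == 1L]) %% 4L
      nm <- sprintf("sp%d_s%d", s, j)
      if (!is.null(matingTypes)) {
        idio <- .encodeSeq(as.character(mat_refs[[mt_s[j]]]))
        g[(mat_locus[s] + 1L):(mat_locus[s] + 3000L)] <- idio
      }
      assemblies[[nm]] <- .splitContigs(g, nm, config@nContigs, occupied[[s]])
      strain_names <- c(strain_names, nm)
      strain_species <- c(strain_species, s)
      mating <- c(mating, mt_s[j])
    }
  }

  # TE annotations on reference-strain coordinates, per species
  te_all <- NULL
  for (s in seq_len(nsp)) {
    ref <- sprintf("sp%d_s1", s)
    te <- data.frame(start = numeric(0), end = numeric(0))
    target <- config@teDensity * L
    placed <- 0
    while (placed < target) {
      w <- max(200, round(stats::rexp(1, 1 / 2000)))
      st <- sample.int(L - w, 1L) - 1L
      if (nrow(te) && any(st < te$end & st + w > te$start)) next
      te <- rbind(te, data.frame(start = st, end = st + w))
      placed <- placed + w
    }
    if (nrow(hs) && !is.null(truth_htr)) {
      th <- truth_htr[truth_htr$species == s & truth_htr$te_at_edges, ,
                      drop = FALSE]
      for (i in seq_len(nrow(th))) {
        te <- rbind(te,
                    data.frame(start = max(0, th$start[i] - 300),
                               end = min(L, th$start[i] + 300)),
                    data.frame(start = max(0, th$end[i] - 300),
                               end = min(L, th$end[i] + 300)))
      }
    }
    te_all <- rbind(te_all, data.frame(contig = .contigOf(te$start, ref,
                                                          config@nContigs, L)$contig,
                                       start = te$start, end = te$end,
                                       species = s, strain = ref))
  }
  te_gr <- GRanges(te_all$contig, IRanges(te_all$start + 1L, te_all$end),
                   species = te_all$species)

  # gene models on reference-strain coordinates (species 1 reference and
  # mirrored per species; genes are annotation intervals, not sequences)
  genes_all <- NULL
  for (s in seq_len(nsp)) {
    ref <- sprintf("sp%d_s1", s)
    used <- data.frame(start = numeric(0), end = numeric(0))
    for (g in seq_len(config@nGenes)) {
      iv <- tryCatch(.placeInterval(1500, L, used, margin = 100),
                     error = function(e) NULL)
      if (is.null(iv)) break
      used <- rbind(used, data.frame(start = iv[1], end = iv[2]))
      genes_all <- rbind(genes_all, data.frame(
        contig = .contigOf(iv[1], ref, config@nContigs, L)$contig,
        start = iv[1], end = iv[2], species = s,
        gene_id = sprintf("sp%d_g%03d", s, g)))
    }
  }
  genes_gr <- GRanges(genes_all$contig,
                      IRanges(genes_all$start + 1L, genes_all$end),
                      gene_id = genes_all$gene_id, species = genes_all$species)

  truth <- list(htrs = if (is.null(truth_htr))
    data.frame(htr_id = character(0), species = integer(0),
               start = numeric(0), end = numeric(0), length = numeric(0),
               identity = numeric(0), te_at_edges = logical(0)) else truth_htr,
    theta = config@theta,
    matingType = stats::setNames(mating, strain_names))
  # contig-local truth coordinates
  if (nrow(truth$htrs)) {
    refs <- sprintf("sp%d_s1", truth$htrs$species)
    loc <- .contigOf(truth$htrs$start, refs, config@nContigs, L)
    truth$htrs$contig <- loc$contig
    truth$htrs$contig_start <- truth$htrs$start - loc$offset
    truth$htrs$contig_end <- truth$htrs$end - loc$offset
  }

  out <- list(assemblies = assemblies,
              species = stats::setNames(strain_species, strain_names),
              te = te_gr, genes = genes_gr, truth = truth,
              matRefs = mat_refs,
              referenceStrains = sprintf("sp%d_s1", seq_len(nsp)))
  if (!is.null(outDir)) .writePanel(out, outDir, config)
  out
}

# deterministic contig split: nContigs equal-width contigs; intervals from
# .placeInterval never span a boundary because splitting uses fixed
# boundaries and placement leaves a margin >= 1000 around occupied blocks
# only; HTR intervals may span boundaries when nContigs > 1, which is why
# the default is a single contig per genome.
.contigBounds <- function(nContigs, L) {
  round(seq(0, L, length.out = nContigs + 1))
}

.contigOf <- function(start0, strain, nContigs, L) {
  b <- .contigBounds(nContigs, L)
  idx <- findInterval(start0, b, rightmost.closed = FALSE)
  idx[idx > nContigs] <- nContigs
  list(contig = sprintf("%s_c%d", strain, idx), offset = b[idx])
}

.splitContigs <- function(code, strain, nContigs, occupied) {
  L <- length(code)
  b <- .contigBounds(nContigs, L)
  seqs <- vapply(seq_len(nContigs), function(i)
    .codeToString(code[(b[i] + 1L):b[i + 1L]]), character(1))
  DNAStringSet(stats::setNames(seqs, sprintf("%s_c%d", strain,
                                             seq_len(nContigs))))
}

.writePanel <- function(panel, outDir, config) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(panel$assemblies))
    writeXStringSet(panel$assemblies[[nm]],
                    file.path(outDir, paste0(nm, ".fasta")))
  rtracklayer::export(panel$te, file.path(outDir, "te.gff3"), format = "gff3")
  rtracklayer::export(panel$genes, file.path(outDir, "genes.gff3"),
                      format = "gff3")
  th <- panel$truth$htrs
  if (nrow(th)) {
    bed <- data.frame(chrom = th$contig, start = th$contig_start,
                      end = th$contig_end, name = th$htr_id)
    utils::write.table(bed, file.path(outDir, "truth_htrs.bed"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  utils::write.table(th, file.path(outDir, "truth_htrs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  mt <- data.frame(strain = names(panel$truth$matingType),
                   mating_type = unname(panel$truth$matingType))
  utils::write.table(mt, file.path(outDir, "truth_mating.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeXStringSet(panel$matRefs, file.path(outDir, "mat_refs.fasta"))
  invisible(outDir)
}
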