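#' Default pipeline configuration
#'
#' Every numeric threshold of the pipeline surfaced as a named key with
#' its calibrated default: detection identity 98 (percent) and minimum
#' length 7000 (bp), control match floor 1000 bp, post-mask minimum 500
#' bp, plotting merge floor 35,000 bp, LD decay window 15,000 bp at MAF
#' 0.2, pruning window 1000 bp at r-squared 0.2 and MAF 0.05, and MCMC
#' defaults 25,000 iterations / 10,000 burn-in / thinning 4. Simulation
#' keys control the synthetic panel used when no genome paths are given.
#'
#' @return named list of configuration defaults.
#' @export
defaultConfig <- function() {
  list(
    seed = 1L,
    out_dir = "htrscan_out",
    genomes = NULL,            # optional: named FASTA paths; NULL = simulate
    identity = 98, min_length = 7000, min_match = 1000,
    min_unmasked = 500, min_merged = 35000,
    ld_window = 15000, ld_maf = 0.2,
    prune_window = 1000, prune_r2 = 0.2, prune_maf = 0.05,
    snipre_iterations = 25000, snipre_burnin = 10000, snipre_thin = 4,
    null_reps = 2000,
    sim = list(genome_length = 2e5, n_strains = 2, divergence = 0.12,
               theta = 0.005, te_density = 0.05, n_genes = 30,
               htr_lengths = c(20000, 12000), htr_identity = 0.995,
               te_at_edges = TRUE),
    mk = list(n_genes = 60, n_positive = 6, effect = 1.5),
    stages = list(simulate = TRUE, detect = TRUE, scan = TRUE,
                  popgen = TRUE, selection = TRUE))
}

.mergeConfig <- function(config) {
  def <- defaultConfig()
  for (nm in names(config)) {
    if (is.list(def[[nm]]) && is.list(config[[nm]]))
      def[[nm]][names(config[[nm]])] <- config[[nm]]
    else def[[nm]] <- config[[nm]]
  }
  def
}

.writeTsv <- function(df, path, seed, stage) {
  con <- file(path, "w")
  writeLines(sprintf("# htrscan %s | stage %s | seed %d",
                     as.character(utils::packageVersion("htrscan")),
                     stage, as.integer(seed)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  path
}

#' Run the full pipeline on a synthetic or supplied panel
#'
#' Executes the stages in dependency order — simulate (or load genomes),
#' detect (match, threshold, merge, TE-mask), scan (panel presence and
#' identity), popgen (variants, filters, diversity, LD pruning, mating
#' types) and selection (MK counts and the Bayesian classifier) — writing
#' every output file under \code{config$out_dir} and recording each in a
#' manifest with its MD5 hash. Reruns with the same configuration and
#' seed reproduce the manifest hashes. A stage failure aborts with the
#' stage name; the partial manifest is still written.
#'
#' @param config named list (see [defaultConfig()]) or path to a YAML
#'   file of overrides.
#' @return data.frame manifest (file, md5, stage), invisibly; also
#'   written to \code{manifest.tsv}.
#' @export
runPipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .mergeConfig(config)
  if (!is.null(cfg$genomes)) {
    missing <- cfg$genomes[!file.exists(unlist(cfg$genomes))]
    if (length(missing))
      stop("configuration invalid: genome path(s) do not exist: ",
           paste(missing, collapse = ", "))
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- data.frame(file = character(0), md5 = character(0),
                         stage = character(0))
  add <- function(paths, stage) {
    prefix <- paste0(cfg$out_dir, "/")
    rel <- ifelse(startsWith(paths, prefix),
                  substring(paths, nchar(prefix) + 1L), basename(paths))
    manifest <<- rbind(manifest, data.frame(
      file = rel, md5 = unname(tools::md5sum(paths)), stage = stage))
  }
  run_stage <- function(name, fun) {
    if (!isTRUE(cfg$stages[[name]])) return(NULL)
    message("[htrscan] stage ", name)
    tryCatch(fun(), error = function(e) {
      utils::write.table(manifest, file.path(cfg$out_dir, "manifest.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  env <- new.env()

  run_stage("simulate", function() {
    if (is.null(cfg$genomes)) {
      sim <- cfg$sim
      scfg <- simulationConfig(
        seed = cfg$seed, genomeLength = sim$genome_length,
        nStrainsPerSpecies = sim$n_strains,
        backgroundDivergence = sim$divergence, theta = sim$theta,
        teDensity = sim$te_density, nGenes = sim$n_genes,
        htrSpecs = htrSpec(sim$htr_lengths, sim$htr_identity,
                           te_at_edges = sim$te_at_edges))
      env$panel <- simulatePanel(scfg, matingTypes = c("MAT1-2", "MAT1-1"),
                                 outDir = file.path(cfg$out_dir, "simulate"))
      add(list.files(file.path(cfg$out_dir, "simulate"), full.names = TRUE),
          "simulate")
    } else {
      env$panel <- list(
        assemblies = lapply(cfg$genomes, Biostrings::readDNAStringSet),
        species = NULL)
    }
  })

  run_stage("detect", function() {
    pm <- panelPairMatches(env$panel)
    thr <- new("ThresholdSet", identityThreshold = cfg$identity,
               lengthThreshold = cfg$min_length, provenance = list(),
               underpowered = FALSE)
    cand <- detectCandidates(pm$pairMatches, thr, pm$refA, pm$refB,
                             pm$liftA, pm$liftB)
    message("[htrscan] detect: ", nrow(cand), " candidate(s) in, ",
            "thresholds ", cfg$identity, "% / ", cfg$min_length, " bp")
    teA <- env$panel$te[env$panel$te$species == 1]
    cons <- maskAndFilter(cand, teA, minUnmasked = cfg$min_unmasked,
                          refSeqs = env$panel$assemblies[[pm$refA]],
                          genes = env$panel$genes[env$panel$genes$species == 1])
    message("[htrscan] mask: ", nrow(cons), " retained, ",
            metadata(cons)$nDropped, " dropped below ",
            cfg$min_unmasked, " bp unmasked")
    env$consensus <- cons
    p1 <- .writeTsv(as.data.frame(cand), file.path(cfg$out_dir,
                                                   "candidates.tsv"),
                    cfg$seed, "detect")
    keep_cols <- c("id", "contig", "start", "end", "length",
                   "unmaskedLength", "teFraction")
    p2 <- .writeTsv(as.data.frame(cons)[, keep_cols],
                    file.path(cfg$out_dir, "consensus.tsv"),
                    cfg$seed, "detect")
    p3 <- file.path(cfg$out_dir, "consensus.fasta")
    seqs <- cons$sequence
    names(seqs) <- cons$id
    Biostrings::writeXStringSet(seqs, p3)
    env$consensusSeqs <- seqs
    ext <- extremityTeReport(cons, teA)
    p4 <- .writeTsv(ext$perExtremity, file.path(cfg$out_dir,
                                                "extremities.tsv"),
                    cfg$seed, "detect")
    add(c(p1, p2, p3, p4), "detect")
  })

  run_stage("scan", function() {
    pmat <- panelMatrix(env$panel$assemblies, env$consensusSeqs)
    env$scan <- pmat
    add(.writeTsv(pmat$records, file.path(cfg$out_dir, "scan.tsv"),
                  cfg$seed, "scan"), "scan")
  })

  run_stage("popgen", function() {
    divs <- NULL
    for (s in unique(env$panel$species)) {
      scfg <- simulationConfig(seed = cfg$seed + s,
                               genomeLength = cfg$sim$genome_length,
                               nStrainsPerSpecies = max(4, cfg$sim$n_strains),
                               theta = cfg$sim$theta)
      vcf <- file.path(cfg$out_dir, sprintf("species%d.vcf", s))
      simulateVariants(scfg, path = vcf)
      vt <- filterVcf(vcf)
      dv <- diversity(vt, nullCI = TRUE, nullReps = cfg$null_reps,
                      seed = cfg$seed)
      pruned <- ldPrune(vt, r2Max = cfg$prune_r2,
                        window = cfg$prune_window, mafMin = cfg$prune_maf)
      divs <- rbind(divs, data.frame(
        species = s, n = dv@n, S = dv@S, pi = dv@pi, thetaW = dv@thetaW,
        tajimaD = dv@tajimaD, d_lo = dv@dNullCI[1], d_hi = dv@dNullCI[2],
        sites_pruned_in = nSites(vt), sites_pruned_out = nSites(pruned)))
      add(vcf, "popgen")
    }
    mt <- matingTypeSummary(env$panel$assemblies, env$panel$matRefs)
    env$mating <- mt
    p <- .writeTsv(divs, file.path(cfg$out_dir, "diversity.tsv"),
                   cfg$seed, "popgen")
    p2 <- .writeTsv(data.frame(strain = names(mt$calls),
                               mating_type = unname(mt$calls)),
                    file.path(cfg$out_dir, "mating.tsv"), cfg$seed,
                    "popgen")
    env$diversity <- divs
    add(c(p, p2), "popgen")
  })

  run_stage("selection", function() {
    mk <- cfg$mk
    sel <- data.frame(class = rep(c("positive", "neutral"),
                                  c(mk$n_positive,
                                    mk$n_genes - mk$n_positive)),
                      effect = mk$effect)
    sim <- simulateMKCounts(sel, seed = cfg$seed)
    fit <- snipreFit(sim$counts, iterations = cfg$snipre_iterations,
                     burnIn = cfg$snipre_burnin, thin = cfg$snipre_thin,
                     seed = cfg$seed)
    res <- as.data.frame(fit)
    res$truth <- sim$truth$class
    env$selection <- res
    add(.writeTsv(res, file.path(cfg$out_dir, "selection.tsv"),
                  cfg$seed, "selection"), "selection")
  })

  utils::write.table(manifest, file.path(cfg$out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Summary report tables from a completed run
#'
#' Rebuilds the headline tables from a run's output directory: HTR
#' presence per strain (fraction and identity), the diversity table,
#' selection-call counts per class, and per-genome total HTR length. An
#' incomplete run yields the available tables with a warning.
#'
#' @param outDir output directory of [runPipeline()].
#' @return named list of data.frames.
#' @export
summarizeRun <- function(outDir) {
  rd <- function(f) {
    p <- file.path(outDir, f)
    if (!file.exists(p)) return(NULL)
    utils::read.delim(p, comment.char = "#")
  }
  out <- list()
  scan <- rd("scan.tsv")
  if (!is.null(scan)) {
    out$presence <- stats::reshape(
      scan[, c("genome", "htr", "fraction")],
      idvar = "genome", timevar = "htr", direction = "wide")
    tot <- stats::aggregate(fraction ~ genome, scan, sum)
    out$htrContent <- data.frame(genome = tot$genome,
                                 total_fraction = tot$fraction)
  }
  out$diversity <- rd("diversity.tsv")
  selp <- rd("selection.tsv")
  if (!is.null(selp))
    out$selectionSummary <- as.data.frame(table(class = selp$class))
  out$mating <- rd("mating.tsv")
  missing <- setdiff(c("scan.tsv", "diversity.tsv", "selection.tsv"),
                     list.files(outDir))
  if (length(missing))
    warning("incomplete run; missing: ", paste(missing, collapse = ", "))
  out
}
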