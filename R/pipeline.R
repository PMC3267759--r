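## End-to-end orchestration: simulate -> clean -> collapse -> annotate ->
## map -> conserved identification -> isomiR clustering -> novel prediction
## -> conservation partition -> report. Deterministic under a fixed seed.

#' Pipeline run configuration
#'
#' Bundles the simulation settings with every stage parameter. Serializable
#' to YAML; a saved configuration reproduces a run bit-identically.
#'
#' @param sim simulation settings from [simulationConfig()].
#' @param k k-mer length of the genome index.
#' @param maxLoci mapping locus cap per read.
#' @param knownFraction fraction of planted matures entered into the
#'   catalog (exercises the conserved route; 0 sends everything through
#'   novel prediction).
#' @param catalog extra mature catalog (data.frame name/species/sequence),
#'   appended to the planted entries; NULL for none.
#' @param clean cleaning thresholds from [cleanParams()].
#' @param criteria novel-miRNA thresholds from [criteriaParams()].
#' @return named list.
#' @export
pipelineConfig <- function(sim = simulationConfig(), k = 12L,
                           maxLoci = 20L, knownFraction = 0,
                           catalog = NULL, clean = cleanParams(),
                           criteria = criteriaParams()) {
  list(sim = sim, k = as.integer(k), maxLoci = as.integer(maxLoci),
       knownFraction = knownFraction, catalog = catalog,
       clean = clean, criteria = criteria)
}

#' Run the full small-RNA analysis pipeline on simulated data
#'
#' Executes the stages in order, checks the count-conservation identities
#' between stages, and (optionally) writes every intermediate plus a
#' report to `outdir`. Rerunning with the same configuration yields an
#' identical report.
#'
#' @param config from [pipelineConfig()].
#' @param outdir output directory; NULL to skip writing.
#' @return list with elements `report` ([PipelineReport-class]), `sim`,
#'   `cleaning`, `reads` (collapsed [UniqueReadSet-class]), `lengthDist`,
#'   `annotated`, `remaining`, `mapping`, `matches`, `categories`,
#'   `conservation`, `novel`, `catalog`.
#' @export
runPipeline <- function(config = pipelineConfig(), outdir = NULL) {
  gen <- generateGenome(config$sim, params = config$criteria)
  sim <- simulateReads(config$sim, gen$hairpins, gen$ncrnaRef)
  catalog <- rbind(buildCatalog(gen$hairpins, config$knownFraction),
                   config$catalog)

  cleaned <- cleanReads(as.character(sim$reads),
                        as.character(sim$qualities),
                        adapter3p = config$sim$adapter3p,
                        adapter5p = config$sim$adapter5p,
                        params = config$clean)
  reads <- collapseReads(cleaned$inserts)
  ldist <- lengthDistribution(reads)

  ann <- annotateNcRNA(reads, gen$ncrnaRef)
  stopifnot(length(ann$annotated) + length(ann$remaining) == length(reads))

  index <- buildGenomeIndex(gen$genome, k = config$k)
  mapping <- mapReads(ann$remaining, index, maxLoci = config$maxLoci)

  w <- Biostrings::width(readSequences(ann$remaining))
  eligible <- which(w >= 18L & w <= 23L)
  mk <- matchKnown(ann$remaining[eligible], catalog)
  cats <- clusterCategories(mk$matched, mk$matchName)
  conservation <- conservationPartition(cats, catalog)

  matchedIdx <- eligible[mk$matches$readIndex]
  novelCandIdx <- setdiff(which(mapping$mapped), matchedIdx)
  novelCand <- ann$remaining[novelCandIdx]
  novelMapping <- list(hits = {
    h <- mapping$hits[mapping$hits$readIndex %in% novelCandIdx, ,
                      drop = FALSE]
    h$readIndex <- match(h$readIndex, novelCandIdx)
    h
  }, mapped = mapping$mapped[novelCandIdx],
     multiMapped = mapping$multiMapped[novelCandIdx])
  novel <- predictNovel(novelCand, novelMapping, gen$genome,
                        params = config$criteria)

  counts <- c(
    rawReads = length(sim$reads),
    cleanReads = cleaned$report@cleanTotal,
    uniqueReads = length(reads),
    ncrnaAnnotatedUnique = length(ann$annotated),
    mappedUnique = sum(mapping$mapped),
    mappedReads = sum(readCounts(ann$remaining)[mapping$mapped]),
    conservedCandidateUnique = length(mk$matched),
    conservedCandidateReads = sum(readCounts(mk$matched)),
    categoryCount = length(cats),
    novelCount = nrow(novel))
  stopifnot(counts[["rawReads"]] ==
              counts[["cleanReads"]] + sum(cleaned$report@discarded),
            sum(readCounts(reads)) == counts[["cleanReads"]])
  report <- new("PipelineReport", counts = counts,
                params = list(k = config$k, maxLoci = config$maxLoci,
                              knownFraction = config$knownFraction,
                              eMax = config$criteria$eMax,
                              cMin = config$criteria$cMin,
                              seed = config$sim$seed))

  out <- list(report = report, sim = c(gen, sim), cleaning = cleaned,
              reads = reads, lengthDist = ldist,
              annotated = ann$annotated, remaining = ann$remaining,
              mapping = mapping, matches = mk, categories = cats,
              conservation = conservation, novel = novel,
              catalog = catalog)
  if (!is.null(outdir)) writePipelineOutputs(out, outdir)
  out
}

#' Write pipeline outputs
#'
#' Writes the simulated inputs, the collapsed FASTA (counts in headers),
#' the cleaning report, length distribution, categories, conservation and
#' novel-miRNA TSVs, precursor FASTA and Vienna dot-bracket file, a GFF3 of
#' precursor loci, and the per-stage count report.
#'
#' @param result list from [runPipeline()].
#' @param outdir output directory (created if missing).
#' @return invisibly, the output directory.
#' @export
writePipelineOutputs <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  writeSimulation(result$sim, outdir)
  writeCollapsedFasta(result$reads, file.path(outdir, "collapsed.fa"))

  rpt <- result$cleaning$report
  write.table(data.frame(reason = c(names(rpt@discarded), "clean"),
                         count = c(unname(rpt@discarded), rpt@cleanTotal)),
              file.path(outdir, "cleaning_report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(result$lengthDist, file.path(outdir, "length_dist.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  catDf <- do.call(rbind, c(lapply(result$categories, function(cat) {
    rep_seq <- as.character(
      readSequences(cat@members)[[cat@representative]])
    data.frame(miRNA = cat@name, Sequence = rep_seq,
               members = length(cat@members),
               Frequency = sum(readCounts(cat@members)))
  }), list(data.frame(miRNA = character(0), Sequence = character(0),
                      members = integer(0), Frequency = integer(0)))))
  write.table(catDf, file.path(outdir, "categories.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(result$conservation, file.path(outdir, "conservation.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  nv <- result$novel
  write.table(nv[c("name", "sequence", "count")],
              file.path(outdir, "novel.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE,
              col.names = c("miRNA", "Sequence", "Frequency"))
  if (nrow(nv) > 0L) {
    prec <- Biostrings::RNAStringSet(nv$precursor)
    names(prec) <- nv$name
    Biostrings::writeXStringSet(prec, file.path(outdir, "precursors.fa"))
    writeViennaFile(nv$precursor, nv$structure, nv$energy, nv$name,
                    file.path(outdir, "precursors.dbn"))
    gr <- GenomicRanges::GRanges(
      nv$contig, IRanges::IRanges(nv$start + 1L, nv$end),
      strand = nv$strand)
    S4Vectors::mcols(gr)$ID <- nv$name
    S4Vectors::mcols(gr)$type <- "pre_miRNA"
    rtracklayer::export(gr, file.path(outdir, "precursors.gff3"),
                        format = "gff3")
  }

  write.table(data.frame(stage = names(stageCounts(result$report)),
                         count = unname(stageCounts(result$report))),
              file.path(outdir, "report.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(outdir)
}

#' Write a collapsed FASTA with counts in headers
#'
#' Headers follow the `>u1 count=107` convention.
#'
#' @param reads a [UniqueReadSet-class].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeCollapsedFasta <- function(reads, path) {
  x <- readSequences(reads)
  names(x) <- sprintf("u%d count=%d", seq_along(x), readCounts(reads))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a collapsed FASTA with counts in headers
#'
#' @param path FASTA path with `count=` header tags.
#' @return A [UniqueReadSet-class].
#' @export
readCollapsedFasta <- function(path) {
  x <- Biostrings::readRNAStringSet(path)
  counts <- as.integer(sub(".*count=(\\d+).*", "\\1", names(x)))
  UniqueReadSet(unname(as.character(x)), counts)
}

#' Write sequences and structures in Vienna dot-bracket format
#'
#' @param sequences,structures,energies,names parallel vectors.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeViennaFile <- function(sequences, structures, energies, names, path) {
  lines <- unlist(mapply(function(s, db, e, nm) {
    c(paste0(">", nm), s, sprintf("%s (%.2f)", db, e))
  }, sequences, structures, energies, names, SIMPLIFY = FALSE))
  writeLines(lines, path)
  invisible(path)
}

#' Serialize / restore a pipeline configuration as YAML
#'
#' @param config from [pipelineConfig()].
#' @param path YAML file path.
#' @return `writePipelineConfig` returns the path invisibly;
#'   `readPipelineConfig` returns a configuration list.
#' @export
writePipelineConfig <- function(config, path) {
  cfg <- config
  cfg$criteria$precursorLength <- as.list(cfg$criteria$precursorLength)
  cfg$criteria$matureLength <- as.list(cfg$criteria$matureLength)
  cfg$sim$junkProfile <- as.list(cfg$sim$junkProfile)
  cfg$sim$isomirProfile <- as.list(cfg$sim$isomirProfile)
  cfg$clean <- as.list(cfg$clean)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  sim <- cfg$sim
  sim$isomirProfile <- unlist(sim$isomirProfile)
  sim$junkProfile <- unlist(sim$junkProfile)
  sim <- do.call(simulationConfig, sim)
  crit <- cfg$criteria
  crit$precursorLength <- unlist(crit$precursorLength)
  crit$matureLength <- unlist(crit$matureLength)
  pipelineConfig(sim = sim, k = cfg$k, maxLoci = cfg$maxLoci,
                 knownFraction = cfg$knownFraction,
                 catalog = if (!is.null(cfg$catalog))
                   as.data.frame(cfg$catalog) else NULL,
                 clean = do.call(cleanParams, cfg$clean),
                 criteria = do.call(criteriaParams, crit))
}
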