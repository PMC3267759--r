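# Independent oracles used across the suite.

# Exhaustive enumeration of every nested structure of a short RNA (valid
# pairs only, hairpin loops >= 3 nt), scored one by one with the direct
# structure scorer. Independent of the folding dynamic program.
enumerateStructures <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  canPair <- function(a, b) paste0(chars[a], chars[b]) %in%
    c("AU", "UA", "GC", "CG", "GU", "UG")
  memo <- new.env()
  rec <- function(i, j) {
    if (i > j) return("")
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- paste0(".", rec(i + 1L, j))
    if (j >= i + 4L) for (k in (i + 4L):j) {
      if (!canPair(i, k)) next
      inner <- rec(i + 1L, k - 1L)
      after <- rec(k + 1L, j)
      out <- c(out, as.vector(outer(paste0("(", inner, ")"), after,
                                    paste0)))
    }
    memo[[key]] <- out
    out
  }
  rec(1L, n)
}

minEnergyByEnumeration <- function(seq, params = foldParams()) {
  structs <- enumerateStructures(seq)
  min(vapply(structs, function(db) structureEnergy(seq, db, params),
             numeric(1)))
}

randomRNA <- function(n) paste(sample(c("A", "C", "G", "U"), n,
                                      replace = TRUE), collapse = "")

# Naive full-scan exact mapping on both strands via gregexpr.
naiveScanLoci <- function(read, genomeSeqs) {
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(read)))
  out <- NULL
  for (nm in names(genomeSeqs)) {
    for (strand in c("+", "-")) {
      probe <- if (strand == "+") read else rc
      hits <- gregexpr(probe, genomeSeqs[[nm]], fixed = TRUE)[[1]]
      if (hits[1] != -1L)
        out <- rbind(out, data.frame(contig = nm, start = as.integer(hits) - 1L,
                                     strand = strand))
    }
  }
  if (is.null(out))
    out <- data.frame(contig = character(0), start = integer(0),
                      strand = character(0))
  out[order(out$contig, out$start, out$strand), , drop = FALSE]
}

# One shared small simulation, built once per test run.
.simCache <- new.env()
smallSim <- function() {
  if (is.null(.simCache$sim)) {
    cfg <- simulationConfig(nHairpins = 6L, genomeLength = 12000L,
                            totalReads = 20000L, seed = 3L)
    gen <- generateGenome(cfg)
    rd <- simulateReads(cfg, gen$hairpins, gen$ncrnaRef)
    .simCache$sim <- c(list(config = cfg), gen, rd)
  }
  .simCache$sim
}

# Manifest junk class -> cleaning discard reason.
junkReasonMap <- c(low_quality = "low_quality",
                   adapter5 = "adapter5_pollution",
                   no_adapter = "no_3p_adapter",
                   adapter_dimer = "no_insert",
                   polyA = "polyA",
                   short_insert = "too_short")

# Random isomiR cloud around a random mature (3' trims/extensions with
# distinct counts), plus the expected representative.
randomIsomirCloud <- function(matureLength = 22L) {
  mature <- randomRNA(matureLength)
  offs <- sample(-4:5, sample(3:8, 1))
  offs <- unique(c(0L, offs))
  ext <- randomRNA(6L)
  seqs <- vapply(offs, function(o)
    substr(paste0(mature, ext), 1L, matureLength + o), character(1))
  counts <- sample(seq(10L, 1000L, by = 7L), length(seqs))
  counts[which(offs == 0L)] <- max(counts) + 50L # true mature dominates
  list(sequences = seqs, counts = counts, mature = mature)
}
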