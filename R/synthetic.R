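## Synthetic small-RNA study generator: a toy genome with planted pre-miRNA
## hairpins, an ncRNA contaminant reference, a raw FASTQ read set with a
## ground-truth manifest, and simulated qPCR Ct tables. Every planted
## precursor is pre-verified against the package's own novel-miRNA criteria,
## and every simulated read is constructed so that its cleaning fate is
## exactly the one recorded in the manifest (rejection-resampling against
## the cleaner's rules), so end-to-end recovery failures indicate pipeline
## bugs, not generator artifacts.

.JUNK_CLASSES <- c("adapter_dimer", "polyA", "short_insert", "no_adapter",
                   "adapter5", "low_quality")

## Illumina TruSeq small-RNA adapters; configurable, used only as defaults.
.DEFAULT_ADAPTER_3P <- "TGGAATTCTCGGGTGCCAAGG"
.DEFAULT_ADAPTER_5P <- "GTTCAGAGTTCTACAGTCCGACGATC"

#' Default isomiR 3'-end offset profile
#'
#' Probabilities over 3'-end offsets -5..+5 relative to the planted mature.
#' With the default 22 nt matures, offsets -1..+1 carry probability 0.9349
#' exactly, so 93.49% of miRNA-origin inserts are 21-23 nt long. Offset -5
#' has probability 0 by default because a 17 nt insert would fall below the
#' 18 nt length filter.
#'
#' @return named numeric vector over offsets "-5".."5", summing to 1.
#' @export
defaultIsomirProfile <- function() {
  p <- c(0, 0.0025, 0.01, 0.0195, 0.17, 0.60, 0.1649, 0.02, 0.01,
         0.0025, 0.0006)
  names(p) <- as.character(-5:5)
  p
}

#' Simulation configuration
#'
#' @param nHairpins number of pre-miRNA hairpins planted in the genome.
#' @param genomeLength toy genome length (nt); must be at least
#'   `200 * nHairpins`.
#' @param totalReads raw reads to simulate.
#' @param contaminantFraction fraction of reads drawn from the ncRNA
#'   reference (rRNA/tRNA/snRNA/snoRNA substrings).
#' @param junkFraction fraction of junk reads (adapter dimers, poly(A)
#'   inserts, short inserts, adapter-less reads, 5'-adapter pollution,
#'   low-quality reads); the remainder `1 - contaminantFraction -
#'   junkFraction` is miRNA-origin.
#' @param junkProfile probabilities over the six junk classes.
#' @param isomirProfile named probabilities over 3'-end offsets "-5".."5";
#'   see [defaultIsomirProfile()].
#' @param matureLength planted mature length (nt).
#' @param readLength sequencer read length (nt); long enough that a 30 nt
#'   insert still leaves a detectable 3' adapter.
#' @param adapter3p,adapter5p adapter sequences (DNA).
#' @param seed integer RNG seed; a fixed seed makes all outputs
#'   byte-identical across runs.
#' @return named list, validated.
#' @export
simulationConfig <- function(nHairpins = 20L, genomeLength = 50000L,
                             totalReads = 100000L,
                             contaminantFraction = 0.08,
                             junkFraction = 0.12,
                             junkProfile = c(adapter_dimer = 0.25,
                                             polyA = 0.20,
                                             short_insert = 0.20,
                                             no_adapter = 0.15,
                                             adapter5 = 0.10,
                                             low_quality = 0.10),
                             isomirProfile = defaultIsomirProfile(),
                             matureLength = 22L, readLength = 44L,
                             adapter3p = .DEFAULT_ADAPTER_3P,
                             adapter5p = .DEFAULT_ADAPTER_5P,
                             seed = 1L) {
  stopifnot(contaminantFraction >= 0, junkFraction >= 0,
            contaminantFraction + junkFraction <= 1)
  if (abs(sum(isomirProfile) - 1) > 1e-9)
    stop("isomirProfile probabilities must sum to 1")
  if (!identical(names(isomirProfile), as.character(-5:5)))
    stop("isomirProfile must be named over offsets -5..5")
  if (abs(sum(junkProfile) - 1) > 1e-9 ||
      !identical(sort(names(junkProfile)), sort(.JUNK_CLASSES)))
    stop("junkProfile must cover the six junk classes and sum to 1")
  if (genomeLength < nHairpins * 200L)
    stop("genome too short: need at least 200 nt per planted hairpin")
  if (readLength < 30L + 8L)
    stop("readLength must leave >= 8 nt of adapter after a 30 nt insert")
  list(nHairpins = as.integer(nHairpins),
       genomeLength = as.integer(genomeLength),
       totalReads = as.integer(totalReads),
       contaminantFraction = contaminantFraction,
       junkFraction = junkFraction,
       junkProfile = junkProfile[.JUNK_CLASSES],
       isomirProfile = isomirProfile,
       matureLength = as.integer(matureLength),
       readLength = as.integer(readLength),
       adapter3p = toupper(adapter3p), adapter5p = toupper(adapter5p),
       seed = as.integer(seed))
}

.randSeq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

## TRUE if any 3'-offset variant of this insert would violate the poly(A)
## rule, start like the 5' adapter, or hide an adapter-like match that the
## cleaner would trim at the wrong place.
.insertUnsafe <- function(insert, config) {
  if (nchar(gsub("[^A]", "", insert)) / nchar(insert) >= 0.8) return(TRUE)
  if (grepl("AAAAAAAAAA", insert, fixed = TRUE)) return(TRUE)
  if (startsWith(insert, substr(config$adapter5p, 1L, 10L))) return(TRUE)
  read <- substr(paste0(insert, strrep(config$adapter3p, 4L)), 1L,
                 config$readLength)
  pos <- locate3pAdapter(read, config$adapter3p)
  !identical(pos, nchar(insert) + 1L)
}

## All 3' variants an isomiR profile can produce from a mature context.
.variantSet <- function(context, matureLength, isomirProfile) {
  offs <- as.integer(names(isomirProfile))[isomirProfile > 0]
  vapply(offs, function(o) substr(context, 1L, matureLength + o),
         character(1))
}

#' Construct a synthetic pre-miRNA precursor around a mature sequence
#'
#' Constructive stem-loop design: the arm carrying the mature is the mature
#' plus short random flanks, the opposite arm is its reverse complement
#' with 0-3 random mismatches, and a 6-10 nt loop joins them. The precursor
#' is accepted only if it passes all [hairpinCriteria()] rules, so planting
#' is guaranteed to produce recoverable hairpins. Uses the current RNG
#' state.
#'
#' @param mature mature sequence (RNA or DNA; NULL to sample a random
#'   mature of `matureLength` nt).
#' @param arm which arm carries the mature ("5p" or "3p"; NA to pick at
#'   random).
#' @param matureLength mature length when sampling.
#' @param params criteria from [criteriaParams()].
#' @param maxTries attempts before giving up.
#' @return list with `precursor` (RNA), `mature` (RNA), `matureStart`
#'   (1-based within precursor), `arm`.
#' @export
syntheticPrecursorForMature <- function(mature = NULL, arm = NA,
                                        matureLength = 22L,
                                        params = criteriaParams(),
                                        maxTries = 200L) {
  for (try in seq_len(maxTries)) {
    mat <- if (is.null(mature)) chartr("T", "U", .randSeq(matureLength))
           else chartr("Tt", "Uu", toupper(mature))
    mlen <- nchar(mat)
    thisArm <- if (is.na(arm)) sample(c("5p", "3p"), 1L) else arm
    pad5 <- sample(2:5, 1L)
    pad3 <- sample(2:5, 1L)
    armSeq <- paste0(chartr("T", "U", .randSeq(pad5)), mat,
                     chartr("T", "U", .randSeq(pad3)))
    other <- as.character(Biostrings::reverseComplement(
      Biostrings::RNAStringSet(armSeq)))
    nMM <- sample(0:3, 1L)
    if (nMM > 0L) {
      posns <- sample(nchar(other), nMM)
      oc <- strsplit(other, "")[[1]]
      for (p in posns) oc[p] <- sample(setdiff(c("A", "C", "G", "U"), oc[p]), 1L)
      other <- paste(oc, collapse = "")
    }
    loop <- chartr("T", "U", .randSeq(sample(6:10, 1L)))
    if (thisArm == "5p") {
      precursor <- paste0(armSeq, loop, other)
      matureStart <- pad5 + 1L
    } else {
      precursor <- paste0(other, loop, armSeq)
      matureStart <- nchar(other) + nchar(loop) + pad5 + 1L
    }
    if (nchar(precursor) < params$precursorLength[1] ||
        nchar(precursor) > params$precursorLength[2]) next
    if (grepl("AAAAAAAAAA", precursor, fixed = TRUE)) next
    fold <- foldMFE(precursor)
    crit <- hairpinCriteria(fold, matureStart, matureStart + mlen - 1L,
                            count = Inf, params = params)
    if (crit[["verdict"]])
      return(list(precursor = precursor, mature = mat,
                  matureStart = matureStart, arm = thisArm))
  }
  stop("failed to construct a passing precursor in ", maxTries, " tries")
}

#' Generate the toy genome with planted hairpins
#'
#' The background is i.i.d. uniform A/C/G/T; `nHairpins` pre-verified
#' precursors are embedded at non-overlapping loci, alternating strands
#' (half on each). For each hairpin the `matureContext` (mature plus 5 nt
#' of downstream sense sequence, for 3'-extension isomiRs) is taken from
#' the assembled genome, and the few flanking background bases are
#' resampled if any isomiR variant would collide with the cleaning rules.
#' Re-running with the same config reproduces identical bytes.
#'
#' @param config from [simulationConfig()].
#' @param params criteria from [criteriaParams()].
#' @return list with `genome` ([Biostrings::DNAStringSet], one contig
#'   "toy1"), `hairpins` (data.frame: name, precursor, contig, start, end
#'   (0-based half-open), strand, arm, mature, matureStart, matureContext,
#'   expressionWeight) and `ncrnaRef` (data.frame: id, class, sequence).
#' @export
generateGenome <- function(config = simulationConfig(),
                           params = criteriaParams()) {
  set.seed(config$seed)
  n <- config$nHairpins
  glen <- config$genomeLength

  hairpins <- NULL
  seeds <- character(0)
  i <- 0L
  while (i < n) {
    hp <- syntheticPrecursorForMature(matureLength = config$matureLength,
                                      params = params)
    sd <- substr(hp$mature, 2L, 8L)
    if (sd %in% seeds) next  # distinct seeds keep planted clusters apart
    if (.insertUnsafe(chartr("U", "T", hp$mature), config)) next
    i <- i + 1L
    seeds <- c(seeds, sd)
    hairpins <- rbind(hairpins, data.frame(
      name = sprintf("hp%03d", i), precursor = hp$precursor,
      mature = hp$mature, matureStart = hp$matureStart, arm = hp$arm,
      stringsAsFactors = FALSE))
  }

  gchars <- sample(c("A", "C", "G", "T"), glen, replace = TRUE)
  if (n > 0L) {
    slot <- glen %/% n
    starts0 <- integer(n)
    strands <- rep(c("+", "-"), length.out = n)
    for (i in seq_len(n)) {
      plen <- nchar(hairpins$precursor[i])
      lo <- (i - 1L) * slot + 10L
      hi <- i * slot - plen - 10L
      s0 <- sample(lo:hi, 1L)  # 0-based start
      starts0[i] <- s0
      dna <- chartr("U", "T", hairpins$precursor[i])
      if (strands[i] == "-") dna <- .revcomp(dna)
      gchars[(s0 + 1L):(s0 + plen)] <- strsplit(dna, "")[[1]]
    }
    hairpins$contig <- "toy1"
    hairpins$start <- starts0
    hairpins$end <- starts0 + nchar(hairpins$precursor)
    hairpins$strand <- strands
  } else {
    hairpins <- data.frame(name = character(0), precursor = character(0),
                           mature = character(0), matureStart = integer(0),
                           arm = character(0), contig = character(0),
                           start = integer(0), end = integer(0),
                           strand = character(0))
  }

  # mature context = mature + 5 nt downstream sense sequence; resample the
  # flanking background bases until every isomiR variant is cleaning-safe
  if (n > 0L) {
    contexts <- character(n)
    for (i in seq_len(n)) {
      plen <- nchar(hairpins$precursor[i])
      s0 <- hairpins$start[i]
      repeat {
        if (hairpins$strand[i] == "+") {
          flank <- paste(gchars[(s0 + plen + 1L):(s0 + plen + 5L)],
                         collapse = "")
        } else {
          flank <- .revcomp(paste(gchars[(s0 - 4L):s0], collapse = ""))
        }
        ctx <- substr(paste0(hairpins$precursor[i], chartr("T", "U", flank)),
                      hairpins$matureStart[i],
                      hairpins$matureStart[i] + config$matureLength + 4L)
        vars <- .variantSet(ctx, config$matureLength, config$isomirProfile)
        bad <- any(vapply(chartr("U", "T", vars), .insertUnsafe,
                          logical(1), config = config))
        if (!bad) break
        fresh <- sample(c("A", "C", "G", "T"), 5L, replace = TRUE)
        if (hairpins$strand[i] == "+") {
          gchars[(s0 + plen + 1L):(s0 + plen + 5L)] <- fresh
        } else {
          gchars[(s0 - 4L):s0] <- fresh
        }
      }
      contexts[i] <- ctx
    }
    hairpins$matureContext <- contexts
    hairpins$expressionWeight <- exp(rnorm(n, 0, 1))
  } else {
    hairpins$matureContext <- character(0)
    hairpins$expressionWeight <- numeric(0)
  }

  genome <- Biostrings::DNAStringSet(paste(gchars, collapse = ""))
  names(genome) <- "toy1"

  # ncRNA contaminant reference: random records per class, rejecting any
  # record that contains a planted mature core (first matureLength-5 nt)
  classLens <- list(rRNA = c(600L, 400L), tRNA = c(76L, 82L),
                    snRNA = c(150L, 120L), snoRNA = c(110L, 90L))
  cores <- if (n > 0L)
    chartr("U", "T", substr(hairpins$mature, 1L,
                            config$matureLength - 5L)) else character(0)
  recs <- NULL
  ridx <- 0L
  for (cls in names(classLens)) {
    for (len in classLens[[cls]]) {
      repeat {
        sq <- .randSeq(len)
        if (grepl("AAAAAAAAAA", sq, fixed = TRUE)) next
        if (length(cores) > 0L &&
            any(vapply(cores, grepl, logical(1), x = sq, fixed = TRUE))) next
        break
      }
      ridx <- ridx + 1L
      recs <- rbind(recs, data.frame(id = sprintf("nc%02d", ridx),
                                     class = cls, sequence = sq))
    }
  }
  list(genome = genome, hairpins = hairpins, ncrnaRef = recs)
}

#' Simulate a raw small-RNA FASTQ read set with a ground-truth manifest
#'
#' miRNA-origin reads are planted matures with 3'-end offsets drawn from
#' the isomiR profile, hairpins sampled proportionally to their expression
#' weights; contaminants are random substrings (18-30 nt) of the ncRNA
#' reference; junk covers adapter dimers, poly(A) inserts, short inserts,
#' adapter-less reads, 5'-adapter pollution and low-quality reads. Each
#' read is the insert followed by the 3' adapter, truncated to the read
#' length; base qualities are uniform "I" (Phred 40) except low-quality
#' reads ("#", Phred 2). Every emitted read has exactly one manifest entry.
#'
#' @param config from [simulationConfig()].
#' @param hairpins hairpin table from [generateGenome()] (may have zero
#'   rows only if the miRNA fraction is 0).
#' @param ncrnaRef ncRNA reference data.frame (required when
#'   `contaminantFraction > 0`).
#' @return list with `reads` (named [Biostrings::DNAStringSet]),
#'   `qualities` ([Biostrings::BStringSet]) and `manifest` (data.frame:
#'   id, origin, name, insert, insertLength).
#' @export
simulateReads <- function(config, hairpins, ncrnaRef = NULL) {
  set.seed(config$seed + 1L)
  nTot <- config$totalReads
  miFrac <- 1 - config$contaminantFraction - config$junkFraction
  if (miFrac > 0 && (is.null(hairpins) || nrow(hairpins) == 0L))
    stop("hairpins required when the miRNA fraction is positive")
  if (config$contaminantFraction > 0 &&
      (is.null(ncrnaRef) || nrow(ncrnaRef) == 0L))
    stop("ncRNA reference required when contaminantFraction > 0")

  origin <- sample(c("miRNA", "contaminant", "junk"), nTot, replace = TRUE,
                   prob = c(miFrac, config$contaminantFraction,
                            config$junkFraction))
  nJunk <- sum(origin == "junk")
  junkCls <- if (nJunk > 0L)
    sample(.JUNK_CLASSES, nJunk, replace = TRUE,
           prob = config$junkProfile) else character(0)

  insert <- character(nTot)
  label <- character(nTot)
  name <- rep(NA_character_, nTot)
  qual <- rep(strrep("I", config$readLength), nTot)
  adapterPad <- strrep(config$adapter3p, 4L)

  # miRNA reads (vectorized; variants were pre-verified cleaning-safe)
  mi <- which(origin == "miRNA")
  if (length(mi) > 0L) {
    hidx <- sample(nrow(hairpins), length(mi), replace = TRUE,
                   prob = hairpins$expressionWeight)
    offs <- as.integer(sample(names(config$isomirProfile), length(mi),
                              replace = TRUE, prob = config$isomirProfile))
    insert[mi] <- chartr("U", "T",
                         substr(hairpins$matureContext[hidx], 1L,
                                config$matureLength + offs))
    label[mi] <- "miRNA"
    name[mi] <- hairpins$name[hidx]
  }

  # contaminant reads
  co <- which(origin == "contaminant")
  if (length(co) > 0L) {
    open <- co
    while (length(open) > 0L) {
      rec <- sample(nrow(ncrnaRef), length(open), replace = TRUE)
      len <- sample(18:30, length(open), replace = TRUE)
      len <- pmin(len, nchar(ncrnaRef$sequence[rec]))
      maxStart <- nchar(ncrnaRef$sequence[rec]) - len + 1L
      st <- floor(runif(length(open)) * maxStart) + 1L
      ins <- substr(ncrnaRef$sequence[rec], st, st + len - 1L)
      bad <- vapply(ins, .insertUnsafe, logical(1), config = config,
                    USE.NAMES = FALSE)
      insert[open[!bad]] <- ins[!bad]
      label[open[!bad]] <- ncrnaRef$class[rec[!bad]]
      name[open[!bad]] <- ncrnaRef$id[rec[!bad]]
      open <- open[bad]
    }
  }

  # junk reads
  ju <- which(origin == "junk")
  reads <- character(nTot)
  if (length(ju) > 0L) {
    label[ju] <- junkCls
    for (k in seq_along(ju)) {
      i <- ju[k]
      cls <- junkCls[k]
      if (cls == "adapter_dimer") {
        reads[i] <- substr(adapterPad, 1L, config$readLength)
        insert[i] <- ""
      } else if (cls == "polyA") {
        insert[i] <- strrep("A", 20L)
      } else if (cls == "short_insert") {
        repeat {
          ins <- .randSeq(sample(1:17, 1L))
          nA <- nchar(gsub("[^A]", "", ins))
          if (nA / nchar(ins) < 0.8 &&
              !grepl("AAAAAAAAAA", ins, fixed = TRUE) &&
              !.spuriousAdapter(ins, config)) break
        }
        insert[i] <- ins
      } else if (cls == "no_adapter") {
        repeat {
          rd <- .randSeq(config$readLength)
          if (is.na(locate3pAdapter(rd, config$adapter3p)) &&
              !startsWith(rd, substr(config$adapter5p, 1L, 10L))) break
        }
        reads[i] <- rd
        insert[i] <- rd
      } else if (cls == "adapter5") {
        pre <- substr(config$adapter5p, 1L,
                      sample(10:min(20L, nchar(config$adapter5p)), 1L))
        insert[i] <- paste0(pre, .randSeq(12L))
      } else if (cls == "low_quality") {
        insert[i] <- .randSeq(22L)
        qual[i] <- strrep("#", config$readLength)
      }
    }
  }

  # assemble reads: insert + adapter, truncated to read length (dimer and
  # adapter-less reads were assembled above)
  todo <- which(reads == "")
  reads[todo] <- substr(paste0(insert[todo], adapterPad), 1L,
                        config$readLength)

  ids <- sprintf("r%07d", seq_len(nTot))
  readSet <- Biostrings::DNAStringSet(reads)
  names(readSet) <- ids
  qualSet <- Biostrings::BStringSet(qual)
  names(qualSet) <- ids
  manifest <- data.frame(id = ids, origin = label, name = name,
                         insert = insert, insertLength = nchar(insert))
  list(reads = readSet, qualities = qualSet, manifest = manifest)
}

## a short insert followed by the adapter must be trimmed exactly at the
## insert boundary (leftmost match); inserts hiding an earlier valid match
## are rejected
.spuriousAdapter <- function(ins, config) {
  read <- substr(paste0(ins, strrep(config$adapter3p, 4L)), 1L,
                 config$readLength)
  !identical(locate3pAdapter(read, config$adapter3p), nchar(ins) + 1L)
}

#' Simulate a qPCR Ct table with known fold changes
#'
#' Per replicate, `Ct(target) = baselineCt - log2(fold) + N(0, noiseSd)`
#' and `Ct(reference) = referenceCt + N(0, noiseSd)`, so that
#' [deltaDeltaCt()] recovers `trueFolds` up to noise. The calibrator group
#' must be present with fold 1.
#'
#' @param trueFolds named positive numeric vector, group -> fold change.
#' @param nReplicates replicates per group (>= 2).
#' @param noiseSd Ct noise standard deviation (cycles).
#' @param seed RNG seed.
#' @param calibrator calibrator group name (default: first group).
#' @param mirna miRNA label for the table.
#' @param baselineCt,referenceCt baseline target and reference Ct (cycles).
#' @return data.frame with columns `mirna`, `group`, `replicate`,
#'   `ct_target`, `ct_reference` (a Ct table for [deltaDeltaCt()]).
#' @export
simulateCtTable <- function(trueFolds, nReplicates = 3L, noiseSd = 0.1,
                            seed = 1L, calibrator = names(trueFolds)[1],
                            mirna = "miR-1", baselineCt = 25,
                            referenceCt = 18) {
  if (any(trueFolds <= 0)) stop("fold changes must be positive")
  if (is.null(names(trueFolds))) stop("trueFolds must be named by group")
  if (!calibrator %in% names(trueFolds) ||
      trueFolds[[calibrator]] != 1)
    stop("calibrator group must be present with fold 1")
  if (nReplicates < 2L) stop("at least 2 replicates are required")
  set.seed(seed)
  rows <- lapply(names(trueFolds), function(g) {
    data.frame(mirna = mirna, group = g, replicate = seq_len(nReplicates),
               ct_target = baselineCt - log2(trueFolds[[g]]) +
                 rnorm(nReplicates, 0, noiseSd),
               ct_reference = referenceCt + rnorm(nReplicates, 0, noiseSd))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build a mature catalog holding a subset of the planted matures
#'
#' Utility for exercising the conserved-miRNA route on synthetic data: the
#' first `round(knownFraction * n)` planted matures are entered into the
#' catalog under a given species code.
#'
#' @param hairpins hairpin table from [generateGenome()].
#' @param knownFraction fraction of planted matures to include.
#' @param species species code for the entries.
#' @return data.frame with columns `name`, `species`, `sequence`.
#' @export
buildCatalog <- function(hairpins, knownFraction = 0.5, species = "dre") {
  nKnown <- round(knownFraction * nrow(hairpins))
  if (nKnown == 0L)
    return(data.frame(name = character(0), species = character(0),
                      sequence = character(0)))
  idx <- seq_len(nKnown)
  data.frame(name = sprintf("sim-miR-%02d", idx), species = species,
             sequence = hairpins$mature[idx])
}

#' Write a simulated data set to disk
#'
#' Writes `genome.fa`, `reads.fastq` (Phred+33), `ncrna_ref.fa` (class in
#' header), `truth.tsv` (manifest) and `hairpins.tsv` under `outdir`.
#' Deterministic bytes for a fixed config.
#'
#' @param sim list from [generateGenome()] merged with [simulateReads()]
#'   output (elements genome, hairpins, ncrnaRef, reads, qualities,
#'   manifest).
#' @param outdir output directory (created if missing).
#' @return invisibly, the output directory.
#' @export
writeSimulation <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(sim$genome, file.path(outdir, "genome.fa"))
  Biostrings::writeXStringSet(sim$reads, file.path(outdir, "reads.fastq"),
                              format = "fastq",
                              qualities = sim$qualities)
  writeNcRNAReference(sim$ncrnaRef, file.path(outdir, "ncrna_ref.fa"))
  write.table(sim$manifest, file.path(outdir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$hairpins, file.path(outdir, "hairpins.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(outdir)
}
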