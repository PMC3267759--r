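## Novel miRNA prediction: fold candidate precursor windows around
## genome-mapped reads and apply stem-loop / minimum-free-energy / Dicer
## cleavage-site criteria (a desk-scale stand-in for a Mireap + mfold
## workflow).

#' Pre-miRNA acceptance thresholds
#'
#' @param eMax maximum (most positive) folding free energy, kcal/mol.
#' @param precursorLength allowed precursor length range (nt).
#' @param minMaturePaired minimum paired bases within the mature.
#' @param maxMatureBulge maximum consecutive unpaired run (asymmetric
#'   bulge) within the mature (nt).
#' @param matureLength allowed mature length range (nt).
#' @param cMin minimum read count for the mature.
#' @param windowUp,windowDown flank sizes (nt) for the two candidate
#'   windows folded around each mapped read (read on the 5' arm uses
#'   `windowUp` upstream / `windowDown` downstream; the other window is
#'   reversed).
#' @return named list of criteria parameters.
#' @export
criteriaParams <- function(eMax = -18, precursorLength = c(55L, 120L),
                           minMaturePaired = 14L, maxMatureBulge = 4L,
                           matureLength = c(18L, 23L), cMin = 5L,
                           windowUp = 20L, windowDown = 120L) {
  list(eMax = eMax, precursorLength = as.integer(precursorLength),
       minMaturePaired = as.integer(minMaturePaired),
       maxMatureBulge = as.integer(maxMatureBulge),
       matureLength = as.integer(matureLength), cMin = as.integer(cMin),
       windowUp = as.integer(windowUp), windowDown = as.integer(windowDown))
}

#' Evaluate pre-miRNA criteria on a folded candidate
#'
#' Six independently reported rules: (a) single stem-loop (exactly one
#' hairpin loop); (b) folding energy at most `eMax`; (c) mature entirely on
#' one arm with at least `minMaturePaired` bases paired and no unpaired run
#' longer than `maxMatureBulge` inside the mature; (d) Dicer-site
#' plausibility (the mature 5' end sits on the stem, and the 3' end lies
#' within 2 nt of a paired position, the 2 nt 3'-overhang geometry);
#' (e) precursor length within range; (f) mature length within range and
#' read count at least `cMin`. The verdict is the conjunction.
#'
#' @param structure a [SecondaryStructure-class] of the candidate
#'   precursor.
#' @param matureStart,matureEnd 1-based inclusive mature position within
#'   the precursor.
#' @param count read count of the mature (use `Inf` when evaluating a bare
#'   precursor without expression).
#' @param params thresholds from [criteriaParams()].
#' @return named logical vector with elements `singleStem`, `energy`,
#'   `matureArm`, `dicerSite`, `precursorLength`, `matureLength`, and
#'   attribute-free conjunction in element `verdict`.
#' @export
hairpinCriteria <- function(structure, matureStart, matureEnd, count = Inf,
                            params = criteriaParams()) {
  if (!methods::is(structure, "SecondaryStructure"))
    stop("candidate must be folded first")
  n <- nchar(structure@sequence)
  pairs <- dotBracketPairs(structure@dotBracket)
  loops <- hairpinLoops(pairs)
  singleStem <- nrow(loops) == 1L
  energyOk <- structure@energy <= params$eMax

  matureArm <- FALSE
  dicer <- FALSE
  if (nrow(loops) >= 1L && matureStart >= 1L && matureEnd <= n) {
    lp <- loops[1L, ] # with a single stem-loop this is the loop
    onArm <- matureEnd <= lp["i"] || matureStart >= lp["j"]
    mslice <- pairs[matureStart:matureEnd]
    pairedCount <- sum(mslice != 0L)
    runs <- rle(mslice == 0L)
    maxRun <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
    matureArm <- onArm && pairedCount >= params$minMaturePaired &&
      maxRun <= params$maxMatureBulge
    dicer <- pairs[matureStart] != 0L &&
      any(pairs[max(1L, matureEnd - 2L):matureEnd] != 0L)
  }
  lenOk <- n >= params$precursorLength[1] && n <= params$precursorLength[2]
  mlen <- matureEnd - matureStart + 1L
  matureOk <- mlen >= params$matureLength[1] &&
    mlen <= params$matureLength[2] && count >= params$cMin

  out <- c(singleStem = singleStem, energy = energyOk,
           matureArm = matureArm, dicerSite = dicer,
           precursorLength = lenOk, matureLength = matureOk)
  c(out, verdict = all(out))
}

## Walk outward from the hairpin loop closest to the mature through stacked
## and interior-loop pairs (stopping at a multiloop branch or the exterior)
## to delimit the stem-loop span that contains the mature.
.extractStemSpan <- function(pairs, matureStart, matureEnd) {
  loops <- hairpinLoops(pairs)
  if (nrow(loops) == 0L) return(NULL)
  walkOut <- function(a, b) {
    repeat {
      x <- a - 1L
      while (x >= 1L && pairs[x] == 0L) x <- x - 1L
      if (x < 1L || pairs[x] < b) break
      y <- pairs[x]
      between <- if (y - b > 1L) pairs[(b + 1L):(y - 1L)] else integer(0)
      if (any(between != 0L)) break # sibling branch: multiloop boundary
      a <- x; b <- y
    }
    c(start = a, end = b)
  }
  # candidate spans: pick the stem whose extent contains the mature on one
  # arm (not overlapping the loop); nearest loop wins on ties
  best <- NULL
  bestDist <- Inf
  for (r in seq_len(nrow(loops))) {
    lp <- loops[r, ]
    dist <- if (matureEnd < lp[["i"]]) lp[["i"]] - matureEnd
            else if (matureStart > lp[["j"]]) matureStart - lp[["j"]]
            else 0L
    sp <- walkOut(lp[["i"]], lp[["j"]])
    if (matureStart >= sp[["start"]] && matureEnd <= sp[["end"]] &&
        dist < bestDist) {
      best <- sp
      bestDist <- dist
    }
  }
  best
}

#' Predict novel miRNAs from genome-mapped, unannotated reads
#'
#' For each mapped locus of each candidate read, two windows are folded
#' (read plus `windowUp` nt upstream / `windowDown` nt downstream, and the
#' reverse), the stem-loop containing the read is excised from the window
#' fold, refolded, and tested with [hairpinCriteria()]; a read is a novel
#' miRNA if at least one window passes all criteria. Candidates whose
#' precursor loci overlap are merged into one precursor whose mature is the
#' highest-count read; names are assigned in descending count order in the
#' pattern `CM1-mNNNN_5p`/`_3p`, the suffix naming the arm carrying the
#' mature.
#'
#' @param reads a [UniqueReadSet-class] of unannotated, catalog-unmatched
#'   reads.
#' @param mapping result of [mapReads()] for `reads`.
#' @param genome [Biostrings::DNAStringSet].
#' @param params thresholds from [criteriaParams()].
#' @return data.frame with one row per novel miRNA: `name`, `sequence`
#'   (mature, RNA), `count`, `precursor` (RNA), `structure` (dot-bracket),
#'   `energy`, `contig`, `start`, `end` (0-based half-open precursor
#'   locus), `strand`, `arm`. Zero rows when nothing passes.
#' @export
predictNovel <- function(reads, mapping, genome, params = criteriaParams()) {
  emptyOut <- data.frame(name = character(0), sequence = character(0),
                         count = integer(0), precursor = character(0),
                         structure = character(0), energy = numeric(0),
                         contig = character(0), start = integer(0),
                         end = integer(0), strand = character(0),
                         arm = character(0))
  hits <- mapping$hits
  if (length(reads) == 0L || nrow(hits) == 0L) return(emptyOut)
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  counts <- readCounts(reads)
  rseqs <- as.character(readSequences(reads))
  keep <- counts[hits$readIndex] >= params$cMin
  hits <- hits[keep, , drop = FALSE]
  if (nrow(hits) == 0L) return(emptyOut)

  cands <- NULL
  for (h in seq_len(nrow(hits))) {
    ri <- hits$readIndex[h]
    contig <- hits$contig[h]
    csq <- as.character(genome[[contig]])
    clen <- nchar(csq)
    p0 <- hits$start[h]          # 0-based
    L <- hits$end[h] - hits$start[h]
    strand <- hits$strand[h]
    for (flanks in list(c(params$windowUp, params$windowDown),
                        c(params$windowDown, params$windowUp))) {
      up <- flanks[1]; down <- flanks[2]
      if (strand == "+") {
        a <- max(1L, p0 + 1L - up)
        b <- min(clen, p0 + L + down)
        wseq <- chartr("Tt", "Uu", substr(csq, a, b))
        mStart <- p0 + 1L - a + 1L
      } else {
        a <- max(1L, p0 + 1L - down)
        b <- min(clen, p0 + L + up)
        wseq <- chartr("Tt", "Uu", .revcomp(substr(csq, a, b)))
        mStart <- b - (p0 + L) + 1L
      }
      mEnd <- mStart + L - 1L
      if (nchar(wseq) < 10L || nchar(wseq) > 200L) next
      wfold <- foldMFE(wseq)
      span <- .extractStemSpan(dotBracketPairs(wfold@dotBracket),
                               mStart, mEnd)
      if (is.null(span)) next
      if (mStart < span["start"] || mEnd > span["end"]) next
      prec <- substr(wseq, span["start"], span["end"])
      if (nchar(prec) < 10L) next
      pfold <- foldMFE(prec)
      pmStart <- mStart - span["start"] + 1L
      pmEnd <- mEnd - span["start"] + 1L
      crit <- hairpinCriteria(pfold, pmStart, pmEnd,
                              count = counts[ri], params = params)
      if (!crit[["verdict"]]) next
      # precursor genomic locus (0-based half-open, + strand coordinates)
      if (strand == "+") {
        gs <- a - 1L + span[["start"]] - 1L
        ge <- a - 1L + span[["end"]]
      } else {
        wlen <- b - a + 1L
        gs <- a - 1L + wlen - span[["end"]]
        ge <- a - 1L + wlen - span[["start"]] + 1L
      }
      ploops <- hairpinLoops(dotBracketPairs(pfold@dotBracket))
      arm <- if (pmEnd <= ploops[1L, "i"]) "5p" else "3p"
      cands <- rbind(cands, data.frame(
        readIndex = ri, sequence = rseqs[ri], count = counts[ri],
        precursor = prec, structure = pfold@dotBracket,
        energy = pfold@energy, contig = contig, start = gs, end = ge,
        strand = strand, arm = arm))
      break # one passing window per locus is enough
    }
  }
  if (is.null(cands)) return(emptyOut)

  # merge candidates with overlapping precursor loci; strand is ignored so
  # that a near-palindromic stem mapping on both strands stays one precursor
  gr <- GenomicRanges::GRanges(cands$contig,
                               IRanges::IRanges(cands$start + 1L, cands$end),
                               strand = cands$strand)
  merged <- GenomicRanges::reduce(gr, ignore.strand = TRUE)
  grp <- S4Vectors::subjectHits(
    GenomicRanges::findOverlaps(gr, merged, ignore.strand = TRUE))
  rows <- lapply(unique(grp), function(g) {
    idx <- which(grp == g)
    sub <- cands[idx, , drop = FALSE]
    best <- order(-sub$count, sub$sequence)[1]
    sub[best, , drop = FALSE]
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$count, out$sequence), , drop = FALSE]
  out$name <- sprintf("CM1-m%04d_%s", seq_len(nrow(out)), out$arm)
  rownames(out) <- NULL
  out[c("name", "sequence", "count", "precursor", "structure", "energy",
        "contig", "start", "end", "strand", "arm")]
}
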