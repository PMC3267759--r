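## Read cleaning, collapsing to unique sequences, length distribution.

#' Parameters for read cleaning
#'
#' @param minMeanQuality minimum mean Phred quality; reads below are
#'   discarded as `low_quality`.
#' @param adapter5MinPrefix a read starting with at least this many
#'   nucleotides of the 5' adapter is discarded as `adapter5_pollution`.
#' @param adapterMinOverlap minimum 3' adapter overlap (nt) for a match.
#' @param adapterMaxMismatchRate maximum fraction of mismatches in the
#'   matched adapter overlap.
#' @param minInsert,maxInsert insert length window retained after trimming
#'   (inserts longer than `maxInsert` with a genuine adapter are truncated
#'   to `maxInsert`, matching the gel-purification window).
#' @return named list of cleaning parameters.
#' @export
cleanParams <- function(minMeanQuality = 20, adapter5MinPrefix = 10L,
                        adapterMinOverlap = 8L, adapterMaxMismatchRate = 0.10,
                        minInsert = 18L, maxInsert = 30L) {
  list(minMeanQuality = minMeanQuality,
       adapter5MinPrefix = as.integer(adapter5MinPrefix),
       adapterMinOverlap = as.integer(adapterMinOverlap),
       adapterMaxMismatchRate = adapterMaxMismatchRate,
       minInsert = as.integer(minInsert), maxInsert = as.integer(maxInsert))
}

#' Locate the 3' adapter in reads
#'
#' Finds, per read, the leftmost start position of an ungapped match to a
#' prefix of the 3' adapter with at least `minOverlap` overlapping
#' nucleotides and at most `maxMismatchRate` mismatches in the overlap
#' (partial matches running off the read end are allowed).
#'
#' @param reads character vector of read sequences (DNA alphabet).
#' @param adapter3p 3' adapter sequence.
#' @param minOverlap minimum overlap length.
#' @param maxMismatchRate maximum mismatch fraction in the overlap.
#' @return integer vector of 1-based match start positions, NA where no
#'   valid match exists.
#' @export
locate3pAdapter <- function(reads, adapter3p, minOverlap = 8L,
                            maxMismatchRate = 0.10) {
  if (nchar(adapter3p) < minOverlap)
    stop("3' adapter shorter than the minimum overlap")
  pos <- rep(NA_integer_, length(reads))
  if (length(reads) == 0L) return(pos)
  adChars <- strsplit(adapter3p, "")[[1]]
  la <- length(adChars)
  for (rl in sort(unique(nchar(reads)))) {
    sel <- which(nchar(reads) == rl & is.na(pos))
    if (length(sel) == 0L || rl < minOverlap) next
    mat <- matrix(unlist(strsplit(reads[sel], ""), use.names = FALSE),
                  nrow = rl)
    found <- rep(NA_integer_, length(sel))
    for (s in 1:(rl - minOverlap + 1L)) {
      open <- is.na(found)
      if (!any(open)) break
      L <- min(la, rl - s + 1L)
      block <- mat[s:(s + L - 1L), open, drop = FALSE]
      mm <- colSums(block != adChars[seq_len(L)])
      hit <- mm <= floor(maxMismatchRate * L)
      found[open][hit] <- s
    }
    pos[sel] <- found
  }
  pos
}

#' Clean raw small-RNA reads
#'
#' Applies the cleaning rules in a fixed order, each read stopping at the
#' first rule it violates: (1) low mean quality; (2) 5'-adapter pollution
#' (read begins with a long prefix of the 5' adapter); (3) no 3' adapter
#' found (leftmost ungapped match, >= 8 nt overlap, <= 10% mismatches);
#' (4) empty insert after trimming; (5) poly(A) insert (>= 80% A or a run
#' of >= 10 A); (6) insert shorter than 18 nt. Surviving inserts longer
#' than 30 nt are truncated to 30 nt.
#'
#' @param reads character vector, [Biostrings::DNAStringSet], or path to a
#'   FASTQ file (Phred+33).
#' @param qualities character vector of quality strings (Phred+33); taken
#'   from the FASTQ file when `reads` is a path. May be NULL, in which case
#'   the quality filter passes everything.
#' @param adapter3p,adapter5p adapter sequences (DNA alphabet, non-empty).
#' @param params cleaning thresholds from [cleanParams()].
#' @return list with elements `inserts` (character vector of clean insert
#'   sequences, DNA alphabet), `keptIndex` (indices of surviving reads in
#'   the input), `reason` (per input read: "clean" or the discard reason)
#'   and `report` (a [CleaningReport-class]).
#' @export
cleanReads <- function(reads, qualities = NULL, adapter3p, adapter5p,
                       params = cleanParams()) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads) &&
      grepl("\\.(fastq|fq)$", reads)) {
    fq <- Biostrings::readDNAStringSet(reads, format = "fastq",
                                       with.qualities = TRUE)
    qualities <- as.character(S4Vectors::mcols(fq)$qualities)
    reads <- as.character(fq)
  } else if (methods::is(reads, "DNAStringSet")) {
    reads <- as.character(reads)
  }
  if (nchar(adapter3p) == 0L || nchar(adapter5p) == 0L)
    stop("adapters must be non-empty")
  n <- length(reads)
  reason <- rep("clean", n)

  # (1) low quality
  if (!is.null(qualities)) {
    if (length(qualities) != n)
      stop("reads and qualities differ in length")
    if (any(nchar(qualities) != nchar(reads)))
      stop("sequence and quality strings differ in length")
    meanQ <- vapply(qualities,
                    function(q) mean(utf8ToInt(q)) - 33, numeric(1),
                    USE.NAMES = FALSE)
    reason[meanQ < params$minMeanQuality] <- "low_quality"
  }

  # (2) 5'-adapter pollution
  open <- reason == "clean"
  p5 <- substr(adapter5p, 1L, params$adapter5MinPrefix)
  if (nchar(p5) >= params$adapter5MinPrefix) {
    polluted <- open & startsWith(reads, p5)
    reason[polluted] <- "adapter5_pollution"
  }

  # (3) 3'-adapter search
  open <- reason == "clean"
  pos <- rep(NA_integer_, n)
  pos[open] <- locate3pAdapter(reads[open], adapter3p,
                               params$adapterMinOverlap,
                               params$adapterMaxMismatchRate)
  reason[open & is.na(pos)] <- "no_3p_adapter"

  # (4) empty insert
  open <- reason == "clean"
  reason[open & pos == 1L] <- "no_insert"

  # (5) poly(A)
  open <- reason == "clean"
  insert <- character(n)
  insert[open] <- substr(reads[open], 1L, pos[open] - 1L)
  fracA <- ifelse(nchar(insert) > 0,
                  nchar(gsub("[^A]", "", insert)) / nchar(insert), 0)
  isPolyA <- open & (fracA >= 0.8 | grepl("AAAAAAAAAA", insert, fixed = TRUE))
  reason[isPolyA] <- "polyA"

  # (6) too short
  open <- reason == "clean"
  reason[open & nchar(insert) < params$minInsert] <- "too_short"

  kept <- which(reason == "clean")
  inserts <- substr(insert[kept], 1L, params$maxInsert)
  discarded <- vapply(.DISCARD_REASONS, function(r) sum(reason == r),
                      integer(1))
  report <- new("CleaningReport", discarded = discarded,
                cleanTotal = length(kept), rawTotal = n)
  list(inserts = inserts, keptIndex = kept, reason = reason, report = report)
}

#' Collapse clean inserts into unique reads with counts
#'
#' One [UniqueReadSet-class] record per distinct sequence; counts sum to
#' the number of input inserts. Output is sorted by descending count, ties
#' broken by lexicographic sequence order, so collapsing is independent of
#' input order and idempotent on already-unique input.
#'
#' @param inserts character vector of insert sequences (DNA or RNA
#'   alphabet; stored as RNA).
#' @param counts optional integer vector of pre-existing counts per insert
#'   (defaults to 1 per entry), so that collapsed sets can be re-collapsed.
#' @return A [UniqueReadSet-class].
#' @export
collapseReads <- function(inserts, counts = NULL) {
  inserts <- chartr("Tt", "Uu", toupper(inserts))
  if (length(inserts) == 0L)
    return(UniqueReadSet(character(0), integer(0)))
  if (is.null(counts)) counts <- rep(1L, length(inserts))
  tot <- rowsum(as.numeric(counts), group = inserts)
  seqs <- rownames(tot)
  cts <- as.integer(tot[, 1])
  ord <- order(-cts, seqs, method = "radix")
  UniqueReadSet(seqs[ord], cts[ord])
}

#' Length distribution of unique reads
#'
#' Read fractions are weighted by read count (not by unique sequences) and
#' sum to 1.
#'
#' @param reads a [UniqueReadSet-class].
#' @return data.frame with columns `length`, `uniqueCount`, `readCount`,
#'   `readFraction`, one row per observed length, ascending.
#' @export
lengthDistribution <- function(reads) {
  w <- Biostrings::width(readSequences(reads))
  if (length(w) == 0L)
    return(data.frame(length = integer(0), uniqueCount = integer(0),
                      readCount = integer(0), readFraction = numeric(0)))
  lens <- sort(unique(w))
  uc <- vapply(lens, function(l) sum(w == l), integer(1))
  rc <- vapply(lens, function(l) sum(readCounts(reads)[w == l]), integer(1))
  data.frame(length = lens, uniqueCount = uc, readCount = rc,
             readFraction = rc / sum(rc))
}
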