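## ncRNA annotation by exact substring match and exact-match genome mapping
## over a k-mer index. Short 18-30 nt reads make heuristic alignment (BLAST,
## seed-and-extend) unnecessary: matching is exact and fully verifiable.

.NCRNA_CLASSES <- c("rRNA", "tRNA", "snRNA", "snoRNA")

#' Read an ncRNA reference FASTA
#'
#' Headers carry the class as a `class=` tag, e.g. `>rrna1 class=rRNA`.
#'
#' @param path FASTA file path.
#' @return data.frame with columns `id`, `class`, `sequence` (DNA).
#' @export
readNcRNAReference <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  cls <- sub(".*class=(\\S+).*", "\\1", names(x))
  id <- sub("\\s.*", "", names(x))
  if (!all(cls %in% .NCRNA_CLASSES))
    stop("ncRNA classes must be one of: ",
         paste(.NCRNA_CLASSES, collapse = ", "))
  data.frame(id = id, class = cls, sequence = as.character(x))
}

#' Write an ncRNA reference FASTA
#'
#' @param ref data.frame with columns `id`, `class`, `sequence`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeNcRNAReference <- function(ref, path) {
  x <- Biostrings::DNAStringSet(ref$sequence)
  names(x) <- paste0(ref$id, " class=", ref$class)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Annotate unique reads against an ncRNA reference
#'
#' A read is annotated if and only if it is an exact sense-strand substring
#' of a reference record. On multiple hits the class priority is
#' rRNA > tRNA > snRNA > snoRNA. Annotated reads are excluded from all
#' downstream miRNA analysis.
#'
#' @param reads a [UniqueReadSet-class] (collapsed).
#' @param ref data.frame with columns `id`, `class`, `sequence` (see
#'   [readNcRNAReference()]).
#' @return list with elements `annotated` and `remaining`, both
#'   [UniqueReadSet-class]; together they partition the input.
#' @export
annotateNcRNA <- function(reads, ref) {
  n <- length(reads)
  if (n == 0L) return(list(annotated = reads, remaining = reads))
  if (is.null(ref) || nrow(ref) == 0L) {
    warning("empty ncRNA reference; no reads annotated")
    return(list(annotated = reads[integer(0)], remaining = reads))
  }
  if (!all(ref$class %in% .NCRNA_CLASSES))
    stop("ncRNA classes must be one of: ",
         paste(.NCRNA_CLASSES, collapse = ", "))
  dna <- chartr("Uu", "Tt", as.character(readSequences(reads)))
  ann <- rep(NA_character_, n)
  for (cls in .NCRNA_CLASSES) {             # priority order
    seqs <- ref$sequence[ref$class == cls]
    if (length(seqs) == 0L) next
    haystack <- paste(seqs, collapse = "|") # '|' never matches a read
    open <- which(is.na(ann))
    if (length(open) == 0L) break
    hit <- vapply(dna[open], function(s) grepl(s, haystack, fixed = TRUE),
                  logical(1), USE.NAMES = FALSE)
    ann[open[hit]] <- cls
  }
  idx <- which(!is.na(ann))
  annotated <- reads[idx]
  if (length(idx) > 0L) annotated@annotation <- ann[idx]
  list(annotated = annotated, remaining = reads[setdiff(seq_len(n), idx)])
}

#' Build a k-mer index over a genome
#'
#' Indexes every plus-strand k-mer start position per contig. Minus-strand
#' queries are handled by [mapReads()] via reverse complementation, so the
#' index itself stores one strand. Contigs shorter than k are skipped with
#' a warning.
#'
#' @param genome [Biostrings::DNAStringSet] or named character vector.
#' @param k k-mer length, between 8 and the shortest read to be mapped.
#' @return A [GenomeIndex-class].
#' @export
buildGenomeIndex <- function(genome, k = 12L) {
  k <- as.integer(k)
  if (k < 8L) stop("k must be at least 8")
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  if (is.null(names(genome)))
    names(genome) <- paste0("contig", seq_along(genome))
  tabs <- list()
  for (nm in names(genome)) {
    sq <- as.character(genome[[nm]])
    n <- nchar(sq)
    if (n < k) {
      warning("contig '", nm, "' shorter than k; skipped")
      next
    }
    starts <- seq_len(n - k + 1L)
    kmers <- substring(sq, starts, starts + k - 1L)
    tabs[[nm]] <- list2env(split(starts, kmers), hash = TRUE,
                           size = length(starts))
  }
  new("GenomeIndex", k = k, contigs = genome, table = tabs)
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Map unique reads to the genome by exact full-length match
#'
#' Zero-mismatch, full-length matching only (the stand-in for "perfectly
#' mapped"): candidate loci come from the k-mer index and every candidate
#' is verified by direct substring comparison. Both strands are searched;
#' minus-strand hits are reported at the plus-strand coordinate of the
#' matched window. Reads with more than `maxLoci` loci are flagged
#' multi-mapped and truncated to the first `maxLoci` (deterministic order:
#' contig, position, strand).
#'
#' @param reads a [UniqueReadSet-class].
#' @param index a [GenomeIndex-class] built with k at most the shortest
#'   read length.
#' @param maxLoci locus cap per read.
#' @return list with `hits` (data.frame: readIndex, contig, start (0-based),
#'   end (0-based half-open), strand), `mapped` and `multiMapped` logical
#'   vectors over the input reads.
#' @export
mapReads <- function(reads, index, maxLoci = 20L) {
  k <- index@k
  n <- length(reads)
  dna <- chartr("Uu", "Tt", as.character(readSequences(reads)))
  if (n > 0L && min(nchar(dna)) < k)
    stop("index k exceeds the shortest read length")
  contigSeqs <- vapply(names(index@table),
                       function(nm) as.character(index@contigs[[nm]]),
                       character(1))
  hits <- vector("list", n)
  mapped <- logical(n)
  multi <- logical(n)
  for (i in seq_len(n)) {
    fwd <- dna[i]
    rc <- .revcomp(fwd)
    L <- nchar(fwd)
    found <- NULL
    for (nm in names(index@table)) {
      env <- index@table[[nm]]
      csq <- contigSeqs[[nm]]
      for (strand in c("+", "-")) {
        probe <- if (strand == "+") fwd else rc
        key <- substr(probe, 1L, k)
        cand <- env[[key]]
        if (is.null(cand)) next
        ok <- cand[substring(csq, cand, cand + L - 1L) == probe]
        if (length(ok) > 0L)
          found <- rbind(found,
                         data.frame(readIndex = i, contig = nm,
                                    start = ok - 1L, end = ok - 1L + L,
                                    strand = strand))
      }
    }
    if (!is.null(found)) {
      found <- found[order(found$contig, found$start, found$strand), ,
                     drop = FALSE]
      mapped[i] <- TRUE
      if (nrow(found) > maxLoci) {
        multi[i] <- TRUE
        found <- found[seq_len(maxLoci), , drop = FALSE]
      }
      hits[[i]] <- found
    }
  }
  hits <- do.call(rbind, c(hits[!vapply(hits, is.null, logical(1))],
                           list(data.frame(readIndex = integer(0),
                                           contig = character(0),
                                           start = integer(0),
                                           end = integer(0),
                                           strand = character(0)))))
  rownames(hits) <- NULL
  list(hits = hits, mapped = mapped, multiMapped = multi)
}
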