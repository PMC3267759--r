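## Central S4 containers. Sequences are RNA (U alphabet) everywhere inside
## the package; the DNA alphabet (T) appears only at I/O boundaries
## (FASTA/FASTQ on disk, genome sequence).

.ANNOTATION_LEVELS <- c("unannotated", "rRNA", "tRNA", "snRNA", "snoRNA",
                        "known_miRNA", "novel_miRNA")

.DISCARD_REASONS <- c("low_quality", "adapter5_pollution", "no_3p_adapter",
                      "no_insert", "polyA", "too_short")

#' UniqueReadSet: collapsed unique small-RNA sequences with counts
#'
#' One record per distinct insert sequence (RNA alphabet, 18-30 nt), with
#' the number of raw reads it represents and an annotation state that moves
#' monotonically from \code{"unannotated"} to exactly one class.
#'
#' @slot sequences [Biostrings::RNAStringSet] of unique insert sequences.
#' @slot counts integer read count per sequence (>= 1).
#' @slot annotation character annotation class per sequence, one of
#'   unannotated, rRNA, tRNA, snRNA, snoRNA, known_miRNA, novel_miRNA.
#'
#' @seealso [collapseReads()], [annotateNcRNA()], [matchKnown()]
#' @export
setClass("UniqueReadSet",
  representation(sequences = "RNAStringSet",
                 counts = "integer",
                 annotation = "character"),
  validity = function(object) {
    n <- length(object@sequences)
    if (length(object@counts) != n || length(object@annotation) != n)
      return("sequences, counts and annotation must have equal length")
    if (n > 0L && any(object@counts < 1L))
      return("all counts must be >= 1")
    w <- Biostrings::width(object@sequences)
    if (n > 0L && (any(w < 18L) || any(w > 30L)))
      return("unique read lengths must be within 18-30 nt")
    if (!all(object@annotation %in% .ANNOTATION_LEVELS))
      return("invalid annotation class")
    TRUE
  })

#' Construct a UniqueReadSet
#'
#' @param sequences character vector or RNAStringSet of unique sequences
#'   (T is converted to U).
#' @param counts integer vector of read counts.
#' @param annotation annotation class per read (recycled if length 1).
#' @return A [UniqueReadSet-class] object.
#' @export
UniqueReadSet <- function(sequences, counts,
                          annotation = "unannotated") {
  if (is.character(sequences))
    sequences <- Biostrings::RNAStringSet(chartr("Tt", "Uu", sequences))
  counts <- rep_len(as.integer(counts), length(sequences))
  annotation <- rep_len(annotation, length(sequences))
  new("UniqueReadSet", sequences = sequences, counts = counts,
      annotation = annotation)
}

#' SecondaryStructure: a nested RNA secondary structure
#'
#' Sequence, dot-bracket pairing string and free energy (kcal/mol; more
#' negative is more stable) under the package energy model. Pairs are
#' Watson-Crick or G-U wobble; pseudoknots are excluded; hairpin loops
#' span at least 3 nt.
#'
#' @slot sequence character(1), RNA alphabet.
#' @slot dotBracket character(1), same length as sequence.
#' @slot energy numeric(1), kcal/mol.
#' @seealso [foldMFE()], [structureEnergy()]
#' @export
setClass("SecondaryStructure",
  representation(sequence = "character", dotBracket = "character",
                 energy = "numeric"),
  validity = function(object) {
    if (nchar(object@sequence) != nchar(object@dotBracket))
      return("sequence and dot-bracket strings must have equal length")
    db <- strsplit(object@dotBracket, "")[[1]]
    if (!all(db %in% c("(", ")", ".")))
      return("dot-bracket may only contain '(', ')' and '.'")
    depth <- cumsum(ifelse(db == "(", 1L, ifelse(db == ")", -1L, 0L)))
    if (length(depth) > 0 && (any(depth < 0L) || depth[length(depth)] != 0L))
      return("unbalanced brackets")
    TRUE
  })

#' CleaningReport: per-reason discard counts from read cleaning
#'
#' Raw read total is conserved: rawTotal = cleanTotal + sum of discards.
#'
#' @slot discarded named integer, counts per discard reason (low_quality,
#'   adapter5_pollution, no_3p_adapter, no_insert, polyA, too_short).
#' @slot cleanTotal integer(1) reads surviving all filters.
#' @slot rawTotal integer(1) reads in the input.
#' @seealso [cleanReads()]
#' @export
setClass("CleaningReport",
  representation(discarded = "integer", cleanTotal = "integer",
                 rawTotal = "integer"),
  validity = function(object) {
    if (!identical(names(object@discarded), .DISCARD_REASONS))
      return("discard reasons must be the six canonical reasons, in order")
    if (object@rawTotal != object@cleanTotal + sum(object@discarded))
      return("raw total must equal clean total plus discards")
    TRUE
  })

#' GenomeIndex: k-mer lookup index over a genome
#'
#' Maps every fixed-length k-mer of the plus strand to its 1-based start
#' positions, per contig. Minus-strand matches are resolved at query time
#' by looking up the reverse complement of the query.
#'
#' @slot k integer(1) k-mer length.
#' @slot contigs [Biostrings::DNAStringSet] genome sequences.
#' @slot table list of environments, one per contig, keyed by k-mer.
#' @seealso [buildGenomeIndex()], [mapReads()]
#' @export
setClass("GenomeIndex",
  representation(k = "integer", contigs = "DNAStringSet", table = "list"))

#' MiRNACategory: an isomiR cluster with a representative sequence
#'
#' Members are sequence-similar length variants (identical seed, small end
#' offsets); the representative is the member with the highest read count
#' (ties broken by lexicographically smallest sequence).
#'
#' @slot members [UniqueReadSet-class] of member reads.
#' @slot representative integer(1) index of the representative member.
#' @slot name character(1) assigned miRNA name (from the representative's
#'   catalog match).
#' @slot seed character(1) 7 nt seed (positions 2-8 of the representative).
#' @seealso [clusterCategories()]
#' @export
setClass("MiRNACategory",
  representation(members = "UniqueReadSet", representative = "integer",
                 name = "character", seed = "character"),
  validity = function(object) {
    i <- object@representative
    cts <- object@members@counts
    if (i < 1L || i > length(cts)) return("representative index out of range")
    if (any(cts > cts[i])) return("representative must have maximal count")
    rep_seq <- as.character(object@members@sequences[[i]])
    if (object@seed != substr(rep_seq, 2L, 8L))
      return("seed must be positions 2-8 of the representative")
    TRUE
  })

#' ExpressionResult: relative expression from the 2^-ddCt procedure
#'
#' Per (miRNA, group): mean delta-Ct, delta-delta-Ct versus the calibrator,
#' fold change 2^-ddCt with SEM over per-replicate folds, plus a one-way
#' ANOVA over groups per miRNA. The calibrator group's fold is identically 1.
#'
#' @slot table data.frame with columns mirna, group, n, deltaCt, ddCt,
#'   fold, foldSem.
#' @slot anova data.frame with columns mirna, F, p, dfBetween, dfWithin,
#'   degenerate.
#' @slot calibrator character(1) calibrator group name.
#' @seealso [deltaDeltaCt()]
#' @export
setClass("ExpressionResult",
  representation(table = "data.frame", anova = "data.frame",
                 calibrator = "character"),
  validity = function(object) {
    cal <- object@table$fold[object@table$group == object@calibrator]
    if (length(cal) > 0 && any(cal != 1))
      return("calibrator fold must be identically 1")
    if (any(object@table$fold <= 0)) return("folds must be positive")
    TRUE
  })

#' PipelineReport: per-stage counts of a full pipeline run
#'
#' Mirrors the narrative of a small-RNA study: raw reads, clean reads,
#' unique reads, ncRNA-annotated uniques, genome-mapped uniques and reads,
#' conserved-candidate uniques and reads, category count, novel count.
#'
#' @slot counts named numeric vector of stage counts.
#' @slot params list of run parameters.
#' @seealso [runPipeline()]
#' @export
setClass("PipelineReport",
  representation(counts = "numeric", params = "list"))
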