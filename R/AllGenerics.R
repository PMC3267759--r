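#' Accessors for carpmiR classes
#'
#' @param x a carpmiR object.
#' @param i index for subsetting.
#' @param ... unused.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("readSequences", function(x) standardGeneric("readSequences"))

#' @rdname accessors
#' @export
setGeneric("readCounts", function(x) standardGeneric("readCounts"))

#' @rdname accessors
#' @export
setGeneric("readAnnotations", function(x) standardGeneric("readAnnotations"))

#' @rdname accessors
#' @export
setGeneric("dotBracket", function(x) standardGeneric("dotBracket"))

#' @rdname accessors
#' @export
setGeneric("foldEnergy", function(x) standardGeneric("foldEnergy"))

#' @rdname accessors
#' @export
setGeneric("discardCounts", function(x) standardGeneric("discardCounts"))

#' @rdname accessors
#' @export
setGeneric("representativeRead",
           function(x) standardGeneric("representativeRead"))

#' @rdname accessors
#' @export
setGeneric("categoryName", function(x) standardGeneric("categoryName"))

#' @rdname accessors
#' @export
setGeneric("seedSequence", function(x) standardGeneric("seedSequence"))

#' @rdname accessors
#' @export
setGeneric("foldChanges", function(x) standardGeneric("foldChanges"))

#' @rdname accessors
#' @export
setGeneric("anovaTable", function(x) standardGeneric("anovaTable"))

#' @rdname accessors
#' @export
setGeneric("stageCounts", function(x) standardGeneric("stageCounts"))

## ---- UniqueReadSet ----

#' @rdname accessors
#' @export
setMethod("readSequences", "UniqueReadSet", function(x) x@sequences)

#' @rdname accessors
#' @export
setMethod("readCounts", "UniqueReadSet", function(x) x@counts)

#' @rdname accessors
#' @export
setMethod("readAnnotations", "UniqueReadSet", function(x) x@annotation)

#' @rdname accessors
#' @export
setMethod("length", "UniqueReadSet", function(x) length(x@sequences))

#' @rdname accessors
#' @export
setMethod("[", "UniqueReadSet", function(x, i, ...) {
  new("UniqueReadSet", sequences = x@sequences[i],
      counts = x@counts[i], annotation = x@annotation[i])
})

setMethod("show", "UniqueReadSet", function(object) {
  cat("UniqueReadSet with", length(object), "unique reads,",
      sum(object@counts), "total reads\n")
  if (length(object) > 0) {
    tab <- table(object@annotation)
    cat("  annotation:",
        paste(names(tab), as.integer(tab), sep = "=", collapse = ", "), "\n")
    n <- min(3L, length(object))
    for (i in seq_len(n))
      cat("  ", as.character(object@sequences[[i]]),
          " (count ", object@counts[i], ")\n", sep = "")
    if (length(object) > n) cat("  ...\n")
  }
})

## ---- SecondaryStructure ----

#' @rdname accessors
#' @export
setMethod("dotBracket", "SecondaryStructure", function(x) x@dotBracket)

#' @rdname accessors
#' @export
setMethod("foldEnergy", "SecondaryStructure", function(x) x@energy)

setMethod("show", "SecondaryStructure", function(object) {
  cat(object@sequence, "\n", object@dotBracket,
      sprintf(" (%.2f kcal/mol)\n", object@energy), sep = "")
})

## ---- CleaningReport ----

#' @rdname accessors
#' @export
setMethod("discardCounts", "CleaningReport", function(x) x@discarded)

setMethod("show", "CleaningReport", function(object) {
  cat("CleaningReport:", object@rawTotal, "raw reads,",
      object@cleanTotal, "clean\n")
  for (r in names(object@discarded))
    cat(sprintf("  %-18s %d\n", r, object@discarded[[r]]))
})

## ---- GenomeIndex ----

setMethod("show", "GenomeIndex", function(object) {
  cat("GenomeIndex: k =", object@k, "over",
      length(object@contigs), "contig(s),",
      sum(Biostrings::width(object@contigs)), "bp\n")
})

## ---- MiRNACategory ----

#' @rdname accessors
#' @export
setMethod("representativeRead", "MiRNACategory",
          function(x) x@members[x@representative])

#' @rdname accessors
#' @export
setMethod("categoryName", "MiRNACategory", function(x) x@name)

#' @rdname accessors
#' @export
setMethod("seedSequence", "MiRNACategory", function(x) x@seed)

#' @rdname accessors
#' @export
setMethod("length", "MiRNACategory", function(x) length(x@members))

setMethod("show", "MiRNACategory", function(object) {
  rep_seq <- as.character(object@members@sequences[[object@representative]])
  cat("MiRNACategory", object@name, "with", length(object@members),
      "member(s); representative", rep_seq,
      "(count", object@members@counts[object@representative], ")\n")
})

## ---- ExpressionResult ----

#' @rdname accessors
#' @export
setMethod("foldChanges", "ExpressionResult", function(x) x@table)

#' @rdname accessors
#' @export
setMethod("anovaTable", "ExpressionResult", function(x) x@anova)

setMethod("show", "ExpressionResult", function(object) {
  cat("ExpressionResult: calibrator =", object@calibrator, "\n")
  print(head(object@table, 10))
  if (nrow(object@table) > 10) cat("...\n")
})

## ---- PipelineReport ----

#' @rdname accessors
#' @export
setMethod("stageCounts", "PipelineReport", function(x) x@counts)

setMethod("show", "PipelineReport", function(object) {
  cat("PipelineReport:\n")
  for (nm in names(object@counts))
    cat(sprintf("  %-26s %s\n", nm,
                format(object@counts[[nm]], big.mark = ",")))
})
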