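## Published reference tables shipped as verbatim TSV fixtures: the 7 novel
## carp miRNAs (T1), the 31 teleost-only carp miRNAs with their conserved
## species (T2), and the 16 muscle-related miRNAs found in the carp with
## the species in which a muscle role was shown (T3). Transcribed once and
## checksummed; never regenerated.

.TABLE_FILES <- c(T1 = "table1.tsv", T2 = "table2.tsv", T3 = "table3.tsv")

.TABLE_MD5 <- c(T1 = "8f05e93122beb3a4ba06511a29427946",
                T2 = "b1f47b955cd4f84929a746694ffeab18",
                T3 = "7f5c336e2ac1f1cedc27eea64904ac1c")

#' Load a published reference table
#'
#' Reads one of the shipped miRNA tables (`"T1"`: novel carp miRNAs,
#' `"T2"`: teleost-only carp miRNAs with conserved-species column, `"T3"`:
#' muscle-related miRNAs with literature-species column) and verifies its
#' checksum against the value recorded at transcription time.
#'
#' @param tableId one of "T1", "T2", "T3".
#' @return data.frame with columns `miRNA`, `Sequence` (uppercase RNA),
#'   `Frequency` (positive integer) and, depending on the table,
#'   `Conserved` or `Species` (space-separated species codes).
#' @export
loadPublishedTable <- function(tableId = c("T1", "T2", "T3")) {
  tableId <- match.arg(tableId)
  path <- system.file("extdata", "published_tables", .TABLE_FILES[[tableId]],
                      package = "carpmiR", mustWork = TRUE)
  sum <- unname(tools::md5sum(path))
  if (!identical(sum, .TABLE_MD5[[tableId]]))
    stop("fixture corruption: checksum mismatch for ", tableId)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  tab$Frequency <- as.integer(tab$Frequency)
  tab
}

#' Summarize a reference table
#'
#' @param rows non-empty data.frame from [loadPublishedTable()].
#' @return list with `nRows`, `maxFrequency`, `maxFrequencyRow` (miRNA name
#'   of the most frequent row) and `totalFrequency`.
#' @export
tableSummary <- function(rows) {
  if (is.null(rows) || nrow(rows) == 0L) stop("empty table")
  i <- which.max(rows$Frequency)
  list(nRows = nrow(rows), maxFrequency = rows$Frequency[i],
       maxFrequencyRow = rows$miRNA[i],
       totalFrequency = sum(as.numeric(rows$Frequency)))
}

#' Species presence sets from a table's species column
#'
#' @param rows data.frame with a `Conserved` or `Species` column.
#' @return named list of character vectors of species codes per miRNA.
#' @export
tableSpeciesSets <- function(rows) {
  col <- if ("Conserved" %in% names(rows)) "Conserved" else "Species"
  out <- strsplit(trimws(rows[[col]]), "\\s+")
  names(out) <- rows$miRNA
  out
}

#' Build a mature catalog from the shipped tables
#'
#' Flattens T2 (species from the Conserved column, plus the carp entry
#' itself) and T3 (species "cca") into a `name`/`species`/`sequence`
#' catalog usable with [matchKnown()] and [conservationPartition()].
#'
#' @return data.frame with columns `name`, `species`, `sequence`.
#' @export
publishedTableCatalog <- function() {
  t2 <- loadPublishedTable("T2")
  t3 <- loadPublishedTable("T3")
  rows <- list(data.frame(name = t3$miRNA, species = "cca",
                          sequence = t3$Sequence))
  sets <- tableSpeciesSets(t2)
  for (i in seq_len(nrow(t2))) {
    sp <- c("cca", sets[[i]])
    rows[[length(rows) + 1L]] <-
      data.frame(name = t2$miRNA[i], species = sp,
                 sequence = t2$Sequence[i])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
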