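## Conserved miRNA identification: catalog matching, isomiR clustering with
## representative selection, seed extraction, conservation partitioning.

#' Extract the seed sequence of a mature miRNA
#'
#' The seed is nucleotides 2-8 (1-based, inclusive) of the mature sequence,
#' the primary determinant of target recognition and family membership.
#'
#' @param sequence RNA string of length >= 8.
#' @return 7 nt character string.
#' @examples
#' extractSeed("UGGAAUGUAAAGAAGUAUGUAU")  # "GGAAUGU"
#' @export
extractSeed <- function(sequence) {
  if (any(nchar(sequence) < 8L))
    stop("sequence must be at least 8 nt to carry a seed")
  substr(sequence, 2L, 8L)
}

## Prefix-aligned mismatch count over the shared length of a and b.
.prefixMismatch <- function(a, b) {
  L <- min(nchar(a), nchar(b))
  sum(strsplit(substr(a, 1L, L), "")[[1]] !=
      strsplit(substr(b, 1L, L), "")[[1]])
}

#' Match unique reads against a known-mature catalog
#'
#' A read matches a catalog entry when one is obtainable from the other by
#' trimming or extending the 3' end by at most `maxLenDiff` nucleotides and
#' at most `maxMismatch` internal substitutions, with identical seed
#' (positions 2-8). The best match minimizes total edits (length difference
#' plus substitutions); ties go to catalog order. Matched reads are
#' conserved-miRNA candidates.
#'
#' @param reads a [UniqueReadSet-class], unannotated and length-filtered to
#'   18-23 nt (longer or shorter reads never match).
#' @param catalog data.frame with columns `name`, `species`, `sequence`
#'   (RNA), e.g. from [readMatureCatalog()].
#' @param maxLenDiff maximum end-length difference (nt).
#' @param maxMismatch maximum internal substitutions.
#' @return list with `matches` (data.frame: readIndex, name, species,
#'   catalogSequence, edits), `matched` and `unmatched`
#'   [UniqueReadSet-class] subsets, and `matchName` (per matched read).
#' @export
matchKnown <- function(reads, catalog, maxLenDiff = 5L, maxMismatch = 2L) {
  n <- length(reads)
  emptyMatches <- data.frame(readIndex = integer(0), name = character(0),
                             species = character(0),
                             catalogSequence = character(0),
                             edits = integer(0))
  if (n == 0L || is.null(catalog) || nrow(catalog) == 0L)
    return(list(matches = emptyMatches, matched = reads[integer(0)],
                unmatched = reads, matchName = character(0)))
  seqs <- as.character(readSequences(reads))
  catSeed <- extractSeed(catalog$sequence)
  matches <- vector("list", n)
  for (i in seq_len(n)) {
    s <- seqs[i]
    sd <- substr(s, 2L, 8L)
    cand <- which(catSeed == sd &
                  abs(nchar(catalog$sequence) - nchar(s)) <= maxLenDiff)
    if (length(cand) == 0L) next
    best <- NULL
    bestEdits <- Inf
    for (ci in cand) {
      mm <- .prefixMismatch(s, catalog$sequence[ci])
      if (mm > maxMismatch) next
      edits <- mm + abs(nchar(catalog$sequence[ci]) - nchar(s))
      if (edits < bestEdits) {
        bestEdits <- edits
        best <- ci
      }
    }
    if (!is.null(best))
      matches[[i]] <- data.frame(readIndex = i, name = catalog$name[best],
                                 species = catalog$species[best],
                                 catalogSequence = catalog$sequence[best],
                                 edits = as.integer(bestEdits))
  }
  hit <- !vapply(matches, is.null, logical(1))
  matchDf <- if (any(hit)) do.call(rbind, matches[hit]) else emptyMatches
  rownames(matchDf) <- NULL
  matched <- reads[matchDf$readIndex]
  if (length(matched) > 0L)
    matched@annotation <- rep("known_miRNA", length(matched))
  list(matches = matchDf, matched = matched,
       unmatched = reads[setdiff(seq_len(n), matchDf$readIndex)],
       matchName = matchDf$name)
}

## isomiR compatibility: identical seed, end-length difference 0-5 nt,
## <= 1 internal mismatch over the shared prefix. Identical sequences never
## co-occur (collapsing removed them), so 0 nt difference means a 1-edit
## same-length variant.
.isomirCompatible <- function(a, b, maxLenDiff = 5L, maxMismatch = 1L) {
  if (abs(nchar(a) - nchar(b)) > maxLenDiff) return(FALSE)
  if (substr(a, 2L, 8L) != substr(b, 2L, 8L)) return(FALSE)
  .prefixMismatch(a, b) <= maxMismatch
}

#' Cluster catalog-matched reads into isomiR categories
#'
#' Single-linkage clustering under the isomiR compatibility predicate
#' (identical seed, end-length difference at most `maxLenDiff`, at most
#' `maxMismatch` internal substitution). Each category's representative is
#' the member with the highest read count (count ties broken by
#' lexicographically smallest sequence) and the category is named after the
#' representative's catalog match. Clustering is order-independent.
#'
#' @param reads a [UniqueReadSet-class] of catalog-matched candidates.
#' @param matchNames character vector, the matched catalog name per read.
#' @param maxLenDiff,maxMismatch compatibility predicate parameters.
#' @return list of [MiRNACategory-class], ordered by descending
#'   representative count (ties by representative sequence).
#' @export
clusterCategories <- function(reads, matchNames, maxLenDiff = 5L,
                              maxMismatch = 1L) {
  n <- length(reads)
  if (n == 0L) return(list())
  if (length(matchNames) != n)
    stop("matchNames must align with reads")
  seqs <- as.character(readSequences(reads))
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(max(0L, n - 1L))) {
    for (j in (i + 1L):n) {
      if (.isomirCompatible(seqs[i], seqs[j], maxLenDiff, maxMismatch)) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  cats <- lapply(unique(comp), function(cc) {
    idx <- which(comp == cc)
    members <- reads[idx]
    cts <- readCounts(members)
    mseqs <- as.character(readSequences(members))
    repIdx <- which(cts == max(cts))
    repIdx <- repIdx[order(mseqs[repIdx])][1]
    new("MiRNACategory", members = members,
        representative = as.integer(repIdx),
        name = matchNames[idx[repIdx]],
        seed = substr(mseqs[repIdx], 2L, 8L))
  })
  repCount <- vapply(cats, function(cat)
    readCounts(cat@members)[cat@representative], integer(1))
  repSeq <- vapply(cats, function(cat)
    as.character(readSequences(cat@members)[[cat@representative]]),
    character(1))
  cats[order(-repCount, repSeq, method = "radix")]
}

#' Species groups for conservation analysis
#'
#' Mirrors the model-animal comparison set: worm and fly as invertebrates,
#' frog, zebrafish, chicken, mouse and human as the vertebrate models, and
#' the six teleost catalogs (zebrafish, medaka, fugu, tetraodon, bighead
#' and silver carp).
#'
#' @return named list of character vectors of miRBase species codes.
#' @export
speciesGroups <- function() {
  list(vertebrateModels = c("xtr", "dre", "gga", "mmu", "hsa"),
       teleosts = c("dre", "ola", "fru", "tni", "hno", "hmo"),
       invertebrates = c("cel", "dme"),
       mammals = c("mmu", "hsa", "rno"))
}

#' Classify a conservation profile
#'
#' Pure function of the species-presence set: `pan_bilaterian` if present
#' in an invertebrate and a mammal; otherwise `vertebrate_conserved` if
#' present in all five vertebrate models; otherwise `teleost_only` if the
#' non-empty set lies within the teleosts; `carp_specific` if empty; any
#' other combination is `partially_conserved`.
#'
#' @param presentIn character vector of species codes (may be empty).
#' @param groups species groups from [speciesGroups()].
#' @return character(1) conservation class.
#' @export
conservationClass <- function(presentIn, groups = speciesGroups()) {
  known <- unique(c(unlist(groups), "cca"))
  unknown <- setdiff(presentIn, known)
  if (length(unknown) > 0L)
    stop("unknown species code: ", paste(unknown, collapse = ", "))
  presentIn <- setdiff(presentIn, "cca")
  if (length(presentIn) == 0L) return("carp_specific")
  if (any(presentIn %in% groups$invertebrates) &&
      any(presentIn %in% groups$mammals)) return("pan_bilaterian")
  if (all(groups$vertebrateModels %in% presentIn))
    return("vertebrate_conserved")
  if (all(presentIn %in% groups$teleosts)) return("teleost_only")
  "partially_conserved"
}

#' Partition miRNA categories by cross-species conservation
#'
#' For each category, the presence set is the species whose catalog holds a
#' mature matching the representative under the [matchKnown()] predicate
#' (identical seed, end-length difference <= 5 nt, <= 2 substitutions);
#' conservation is mature-sequence presence only.
#'
#' @param categories list of [MiRNACategory-class].
#' @param catalog data.frame with columns `name`, `species`, `sequence`.
#' @param groups species groups from [speciesGroups()].
#' @return data.frame with columns `mirna`, `presentIn` (comma-separated
#'   codes) and `class`.
#' @export
conservationPartition <- function(categories, catalog,
                                  groups = speciesGroups()) {
  rows <- lapply(categories, function(cat) {
    rep_seq <- as.character(
      readSequences(cat@members)[[cat@representative]])
    single <- UniqueReadSet(rep_seq, readCounts(cat@members)[cat@representative])
    sp <- character(0)
    if (!is.null(catalog) && nrow(catalog) > 0L) {
      sd <- substr(rep_seq, 2L, 8L)
      cand <- which(extractSeed(catalog$sequence) == sd &
                    abs(nchar(catalog$sequence) - nchar(rep_seq)) <= 5L)
      hit <- cand[vapply(cand, function(ci)
        .prefixMismatch(rep_seq, catalog$sequence[ci]) <= 2L, logical(1))]
      sp <- setdiff(unique(catalog$species[hit]), "cca")
    }
    data.frame(mirna = cat@name,
               presentIn = paste(sort(sp), collapse = ","),
               class = conservationClass(sp, groups))
  })
  out <- do.call(rbind, c(rows, list(data.frame(mirna = character(0),
                                                presentIn = character(0),
                                                class = character(0)))))
  rownames(out) <- NULL
  out
}

#' Overlap fraction with an external miRNA name set
#'
#' Names are normalized before comparison: species prefix stripped,
#' case-folded, and (optionally) the -5p/-3p arm suffix removed.
#'
#' @param categories list of [MiRNACategory-class] (non-empty).
#' @param otherNames character vector of miRNA names from another study.
#' @param stripArm drop -5p/-3p suffixes before comparing.
#' @return numeric(1), the fraction of category names found in `otherNames`.
#' @export
compareExternalSet <- function(categories, otherNames, stripArm = TRUE) {
  if (length(categories) == 0L) stop("empty category list")
  norm <- function(x) {
    x <- tolower(x)
    x <- sub("^[a-z]{3,4}-", "", x)
    if (stripArm) x <- sub("-[35]p$", "", x)
    x
  }
  mine <- unique(norm(vapply(categories, categoryName, character(1))))
  length(intersect(mine, unique(norm(otherNames)))) / length(mine)
}

#' Read a mature miRNA catalog
#'
#' Accepts either a miRBase-style mature FASTA (`>cca-miR-1 ...` headers,
#' U alphabet; the species code is the header prefix) or a TSV with columns
#' `name`, `species`, `sequence`.
#'
#' @param path file path (.fa/.fasta or .tsv).
#' @return data.frame with columns `name`, `species`, `sequence` (RNA).
#' @export
readMatureCatalog <- function(path) {
  if (grepl("\\.(fa|fasta)$", path)) {
    x <- Biostrings::readRNAStringSet(path)
    nm <- sub("\\s.*", "", names(x))
    cat <- data.frame(name = nm, species = sub("-.*", "", nm),
                      sequence = as.character(x))
  } else {
    cat <- read.delim(path, stringsAsFactors = FALSE)
    stopifnot(all(c("name", "species", "sequence") %in% names(cat)))
    cat$sequence <- chartr("Tt", "Uu", toupper(cat$sequence))
  }
  if (anyDuplicated(cat[c("name", "species")]))
    stop("(name, species) pairs must be unique in the catalog")
  cat
}
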