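## RNA secondary-structure prediction (simplified nearest-neighbor model).

.PAIR_CLASSES <- c("AU", "UA", "GC", "CG", "GU", "UG")

.pairStrength <- c(AU = 0.55, UA = 0.55, GC = 1.60, CG = 1.60,
                   GU = 0.25, UG = 0.25)

#' Energy-model parameters for RNA folding
#'
#' Defaults are calibrated to the Turner kcal/mol scale so that the common
#' Mireap-style minimum-free-energy threshold of -18 kcal/mol is meaningful:
#' a stack of two pairs contributes minus the sum of the pair strengths
#' (G-C 1.6, A-U 0.55, G-U 0.25 kcal/mol each, so a G-C on G-C stack is
#' -3.2 kcal/mol), hairpin/bulge/interior loops cost an offset plus a
#' per-nucleotide term, and multiloops are affine in unpaired bases and
#' branches (the closing pair counts as a branch).
#'
#' @param stack 6x6 numeric matrix of stacking energies indexed by pair
#'   class (AU, UA, GC, CG, GU, UG), outer pair in rows.
#' @param hairpinA,hairpinB hairpin loop penalty: `hairpinA + hairpinB * L`.
#' @param bulgeA,bulgeB bulge loop penalty (one side unpaired).
#' @param interiorA,interiorB interior loop penalty (total unpaired L).
#' @param mlA,mlB,mlC multiloop penalty: `mlA + mlB * unpaired + mlC *
#'   branches` (branches include the closing pair).
#' @param minLoop minimum hairpin loop size (nt).
#' @param maxInterior maximum total unpaired nucleotides in an interior or
#'   bulge loop.
#' @return A named list of parameters, used by [foldMFE()] and
#'   [structureEnergy()].
#' @export
foldParams <- function(stack = NULL,
                       hairpinA = 4.0, hairpinB = 0.30,
                       bulgeA = 3.0, bulgeB = 0.30,
                       interiorA = 1.5, interiorB = 0.25,
                       mlA = 3.4, mlB = 0.10, mlC = 0.40,
                       minLoop = 3L, maxInterior = 30L) {
  if (is.null(stack)) {
    stack <- -outer(.pairStrength, .pairStrength, "+")
    dimnames(stack) <- list(.PAIR_CLASSES, .PAIR_CLASSES)
  }
  stopifnot(is.matrix(stack), all(dim(stack) == c(6L, 6L)))
  list(stack = stack, hairpinA = hairpinA, hairpinB = hairpinB,
       bulgeA = bulgeA, bulgeB = bulgeB,
       interiorA = interiorA, interiorB = interiorB,
       mlA = mlA, mlB = mlB, mlC = mlC,
       minLoop = as.integer(minLoop), maxInterior = as.integer(maxInterior))
}

.baseCodes <- function(sequence) {
  chars <- strsplit(sequence, "")[[1]]
  codes <- match(chars, c("A", "C", "G", "U")) - 1L
  if (anyNA(codes))
    stop("invalid RNA base '", chars[which(is.na(codes))[1]],
         "' at position ", which(is.na(codes))[1])
  codes
}

.pairsToDotBracket <- function(pairs) {
  db <- rep(".", length(pairs))
  db[pairs > seq_along(pairs)] <- "("
  db[pairs != 0L & pairs < seq_along(pairs)] <- ")"
  paste(db, collapse = "")
}

#' Parse a dot-bracket string into a pairing vector
#'
#' @param db dot-bracket string.
#' @return integer vector; position i holds the 1-based partner of base i,
#'   or 0 if unpaired.
#' @export
dotBracketPairs <- function(db) {
  chars <- strsplit(db, "")[[1]]
  pairs <- integer(length(chars))
  stack <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (length(stack) == 0L) stop("unbalanced dot-bracket string")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pairs[i] <- j
      pairs[j] <- i
    }
  }
  if (length(stack) > 0L) stop("unbalanced dot-bracket string")
  pairs
}

#' Fold an RNA sequence to its minimum-free-energy structure
#'
#' Dynamic-programming minimum-energy nested structure under the package
#' energy model (see [foldParams()]): Watson-Crick and G-U pairs, hairpin
#' loops of at least 3 nt, no pseudoknots, interior loops bounded at
#' `maxInterior` unpaired nucleotides. Tie-breaking is deterministic: the
#' traceback prefers the 5'-most inner pair and helix extension over loop
#' closure.
#'
#' @param sequence RNA string (A/C/G/U), length 10-200 nt.
#' @param params energy model from [foldParams()].
#' @return A [SecondaryStructure-class] object. The empty structure has
#'   energy 0, so the reported energy is always <= 0.
#' @examples
#' foldMFE("GGGGAAAACCCC")
#' @export
foldMFE <- function(sequence, params = foldParams()) {
  sequence <- chartr("Tt", "Uu", toupper(sequence))
  n <- nchar(sequence)
  if (n < 10L) stop("sequence must be at least 10 nt")
  if (n > 200L) stop("sequence must be at most 200 nt")
  codes <- .baseCodes(sequence)
  res <- .fold_mfe_cpp(codes, params$stack,
                       params$hairpinA, params$hairpinB,
                       params$bulgeA, params$bulgeB,
                       params$interiorA, params$interiorB,
                       params$mlA, params$mlB, params$mlC,
                       params$minLoop, params$maxInterior)
  new("SecondaryStructure", sequence = sequence,
      dotBracket = .pairsToDotBracket(res$pairs),
      energy = res$energy)
}

#' Score a given structure under the package energy model
#'
#' Direct evaluation of the free energy of an explicit dot-bracket
#' structure, independent of the folding dynamic program: each base pair
#' closes a loop (stack, hairpin, bulge, interior or multiloop) that is
#' classified and scored from the [foldParams()] tables. Used as the
#' scoring half of the exhaustive-enumeration oracle in the test suite.
#'
#' @param sequence RNA string.
#' @param db dot-bracket string of equal length.
#' @param params energy model from [foldParams()].
#' @return numeric free energy (kcal/mol).
#' @export
structureEnergy <- function(sequence, db, params = foldParams()) {
  sequence <- chartr("Tt", "Uu", toupper(sequence))
  chars <- strsplit(sequence, "")[[1]]
  pairs <- dotBracketPairs(db)
  ptype <- function(i, j) {
    pt <- paste0(chars[i], chars[j])
    if (!pt %in% .PAIR_CLASSES) stop("non-complementary pair at ", i, "-", j)
    pt
  }
  energy <- 0
  opening <- which(pairs > seq_along(pairs))
  for (i in opening) {
    j <- pairs[i]
    # scan the loop closed by (i, j)
    inner <- list()
    unpaired <- 0L
    k <- i + 1L
    while (k < j) {
      if (pairs[k] == 0L) {
        unpaired <- unpaired + 1L
        k <- k + 1L
      } else {
        inner[[length(inner) + 1L]] <- c(k, pairs[k])
        k <- pairs[k] + 1L
      }
    }
    nb <- length(inner)
    if (nb == 0L) {
      if (unpaired < params$minLoop) stop("hairpin loop shorter than minimum")
      energy <- energy + params$hairpinA + params$hairpinB * unpaired
    } else if (nb == 1L) {
      k <- inner[[1]][1]; l <- inner[[1]][2]
      s1 <- k - i - 1L; s2 <- j - l - 1L
      if (s1 == 0L && s2 == 0L) {
        energy <- energy + params$stack[ptype(i, j), ptype(k, l)]
      } else if (s1 == 0L || s2 == 0L) {
        energy <- energy + params$bulgeA + params$bulgeB * (s1 + s2)
      } else {
        energy <- energy + params$interiorA + params$interiorB * (s1 + s2)
      }
    } else {
      energy <- energy + params$mlA + params$mlB * unpaired +
        params$mlC * (nb + 1L)
    }
  }
  energy
}

#' Hairpin loops of a structure
#'
#' @param pairs pairing vector (as from [dotBracketPairs()]).
#' @return two-column matrix of the closing pairs (i, j) of every hairpin
#'   loop (pairs enclosing no other pair), ordered 5' to 3'.
#' @export
hairpinLoops <- function(pairs) {
  out <- NULL
  opening <- which(pairs > seq_along(pairs))
  for (i in opening) {
    j <- pairs[i]
    if (j - i > 1L && all(pairs[(i + 1L):(j - 1L)] == 0L))
      out <- rbind(out, c(i, j))
  }
  if (is.null(out)) out <- matrix(integer(0), ncol = 2)
  colnames(out) <- c("i", "j")
  out
}
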