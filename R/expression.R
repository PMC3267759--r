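## Relative quantification of miRNA expression from qPCR Ct tables:
## 2^-ddCt with an endogenous reference (U6 by default), replicate SEM,
## one-way ANOVA across groups, and tissue-specificity calls.

#' Validate and coerce a Ct table
#'
#' @param x data.frame or TSV path with columns `mirna`, `group`,
#'   `replicate`, `ct_target`, `ct_reference`.
#' @return the validated data.frame.
#' @export
readCtTable <- function(x) {
  if (is.character(x)) x <- read.delim(x, stringsAsFactors = FALSE)
  need <- c("mirna", "group", "replicate", "ct_target", "ct_reference")
  if (!all(need %in% names(x)))
    stop("Ct table must have columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(x$ct_target)) || any(!is.finite(x$ct_reference)) ||
      any(x$ct_target <= 0) || any(x$ct_reference <= 0))
    stop("Ct values must be finite and positive")
  x
}

#' Relative expression by the 2^-ddCt method
#'
#' Per (miRNA, group): `dCt = mean(ct_target) - mean(ct_reference)`;
#' `ddCt = dCt(group) - dCt(calibrator)`; `fold = 2^-ddCt`. The calibrator
#' group's fold is identically 1. The SEM is computed on per-replicate
#' folds (`2^-(dCt_rep - dCt(calibrator))`), matching a mean-plus-SEM bar
#' presentation; with a single replicate the fold is computed and the SEM
#' is NA. Amplification efficiency is fixed at 2 (no efficiency
#' correction). A one-way ANOVA on per-replicate dCt across groups is
#' reported per miRNA (NA when fewer than 2 groups or insufficient error
#' degrees of freedom).
#'
#' @param ctTable Ct table (see [readCtTable()]).
#' @param calibrator calibrator group name; must be present for every
#'   miRNA.
#' @return An [ExpressionResult-class].
#' @examples
#' ct <- simulateCtTable(c(`30dph` = 1, `1y` = 2, `2y` = 8), nReplicates = 5,
#'                       noiseSd = 0.1, seed = 42)
#' deltaDeltaCt(ct, "30dph")
#' @export
deltaDeltaCt <- function(ctTable, calibrator) {
  ctTable <- readCtTable(ctTable)
  rows <- NULL
  anovaRows <- NULL
  for (mi in unique(ctTable$mirna)) {
    sub <- ctTable[ctTable$mirna == mi, , drop = FALSE]
    if (!calibrator %in% sub$group)
      stop("calibrator group '", calibrator, "' missing for miRNA ", mi)
    sub$dct <- sub$ct_target - sub$ct_reference
    calDct <- mean(sub$dct[sub$group == calibrator])
    for (g in unique(sub$group)) {
      reps <- sub$dct[sub$group == g]
      n <- length(reps)
      dct <- mean(reps)
      ddct <- if (g == calibrator) 0 else dct - calDct
      repFolds <- 2^-(reps - calDct)
      rows <- rbind(rows, data.frame(
        mirna = mi, group = g, n = n, deltaCt = dct, ddCt = ddct,
        fold = 2^-ddct,
        foldSem = if (n > 1L) sd(repFolds) / sqrt(n) else NA_real_))
    }
    grps <- unique(sub$group)
    av <- if (length(grps) >= 2L && nrow(sub) - length(grps) >= 2L)
      oneWayAnova(sub$dct, sub$group)
    else list(F = NA_real_, p = NA_real_, dfBetween = NA_integer_,
              dfWithin = NA_integer_, degenerate = FALSE)
    anovaRows <- rbind(anovaRows, data.frame(
      mirna = mi, F = av$F, p = av$p, dfBetween = av$dfBetween,
      dfWithin = av$dfWithin, degenerate = av$degenerate))
  }
  rownames(rows) <- rownames(anovaRows) <- NULL
  new("ExpressionResult", table = rows, anova = anovaRows,
      calibrator = calibrator)
}

#' One-way analysis of variance
#'
#' Classic between/within mean-square ratio with the p-value from the F
#' distribution. Zero within-group variance with unequal means yields an
#' infinite F, p = 0 and `degenerate = TRUE`; equal group means yield
#' F = 0, p = 1.
#'
#' @param values numeric response vector.
#' @param groups grouping vector of equal length (>= 2 levels, >= 2 error
#'   degrees of freedom).
#' @return list with `F`, `p`, `dfBetween`, `dfWithin`, `degenerate`.
#' @export
oneWayAnova <- function(values, groups) {
  groups <- as.character(groups)
  if (length(values) != length(groups))
    stop("values and groups must align")
  k <- length(unique(groups))
  N <- length(values)
  if (k < 2L) stop("at least 2 groups are required")
  dfb <- k - 1L
  dfw <- N - k
  if (dfw < 2L) stop("at least 2 error degrees of freedom are required")
  gm <- mean(values)
  means <- tapply(values, groups, mean)
  sizes <- tapply(values, groups, length)
  ssb <- sum(sizes * (means - gm)^2)
  ssw <- sum((values - means[groups])^2)
  if (ssw <= .Machine$double.eps * sum(values^2)) {
    if (ssb <= .Machine$double.eps * max(1, sum(values^2)))
      return(list(F = 0, p = 1, dfBetween = dfb, dfWithin = dfw,
                  degenerate = FALSE))
    return(list(F = Inf, p = 0, dfBetween = dfb, dfWithin = dfw,
                degenerate = TRUE))
  }
  Fval <- (ssb / dfb) / (ssw / dfw)
  list(F = Fval, p = stats::pf(Fval, dfb, dfw, lower.tail = FALSE),
       dfBetween = dfb, dfWithin = dfw, degenerate = FALSE)
}

#' Tissue-specificity calls from a fold-change matrix
#'
#' A miRNA is called specific to the tissue set whose expression is at
#' least `tau` times its row maximum, provided that set has at most
#' `maxTissues` members (the breadth of a muscle/heart/gut/eye pattern);
#' otherwise it is ubiquitous. All-zero rows are ubiquitous with a warning.
#'
#' @param foldMatrix numeric matrix, miRNAs in rows, tissues in columns
#'   (>= 2 tissues).
#' @param tau fraction of the row maximum defining "expressed".
#' @param maxTissues maximum breadth of a specific pattern.
#' @return data.frame with columns `mirna`, `call` ("specific" or
#'   "ubiquitous") and `tissues` (comma-separated set for specific calls).
#' @export
tissueSpecificity <- function(foldMatrix, tau = 0.25, maxTissues = 4L) {
  if (ncol(foldMatrix) < 2L) stop("at least 2 tissues are required")
  if (is.null(rownames(foldMatrix)))
    rownames(foldMatrix) <- paste0("mirna", seq_len(nrow(foldMatrix)))
  rows <- lapply(seq_len(nrow(foldMatrix)), function(i) {
    v <- foldMatrix[i, ]
    if (max(v) == 0) {
      warning("all-zero expression row: ", rownames(foldMatrix)[i])
      return(data.frame(mirna = rownames(foldMatrix)[i],
                        call = "ubiquitous", tissues = ""))
    }
    hot <- colnames(foldMatrix)[v >= tau * max(v)]
    if (length(hot) <= maxTissues)
      data.frame(mirna = rownames(foldMatrix)[i], call = "specific",
                 tissues = paste(hot, collapse = ","))
    else
      data.frame(mirna = rownames(foldMatrix)[i], call = "ubiquitous",
                 tissues = "")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
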