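# pairwise identity matrices over MSAs with gap-aware denominators,
# distribution summaries, column filtering, and logo (conservation) data

.AA20 <- c("A","C","D","E","F","G","H","I","K","L",
           "M","N","P","Q","R","S","T","V","W","Y")
.AMBIG <- c("B", "Z", "X")   # never count as identities

#' Read a multiple sequence alignment from aligned FASTA
#'
#' @param path aligned-FASTA file; all rows must have equal length.
#' @return an \code{AAStringSet} (\pkg{Biostrings}) with unique names.
#' @export
readMSA <- function(path) {
  msa <- Biostrings::readAAStringSet(path)
  if (length(msa) == 0)
    stop("no sequences in ", path)
  .checkMSA(msa)
  msa
}

.checkMSA <- function(msa) {
  w <- Biostrings::width(msa)
  if (length(unique(w)) != 1) {
    bad <- names(msa)[w != w[1]][1]
    stop("ragged alignment: sequence '", bad, "' has length ", w[w != w[1]][1],
         ", expected ", w[1])
  }
  if (is.null(names(msa)) || anyDuplicated(names(msa)))
    stop("alignment rows must carry unique ids")
  invisible(msa)
}

# MSA (AAStringSet or named character) -> uppercase character matrix,
# '.' treated as '-'
.msaMatrix <- function(msa) {
  if (is(msa, "XStringSet")) {
    .checkMSA(msa)
    rows <- as.character(msa)
  } else {
    nms <- names(msa)
    rows <- as.character(msa)
    names(rows) <- if (is.null(nms)) paste0("seq", seq_along(rows)) else nms
    if (length(unique(nchar(rows))) != 1)
      stop("ragged alignment")
  }
  m <- do.call(rbind, strsplit(toupper(rows), ""))
  m[m == "."] <- "-"
  rownames(m) <- names(rows)
  m
}

#' Pairwise sequence identity with the longer-sequence denominator
#'
#' Columns gapped in both sequences are removed; identities are the columns
#' with equal non-gap letters (case-insensitive; the ambiguity codes B, Z, X
#' never count); the denominator is the longer of the two ungapped sequence
#' lengths. Gap-gap column removal cannot change either ungapped length, so
#' the score is invariant under it.
#'
#' @param a,b aligned rows of equal length (single strings, gap '-').
#' @return identity fraction in [0, 1].
#' @examples
#' pairwiseIdentity("AC-DE", "AG-DE")  # 3 / max(4, 4) = 0.75
#' pairwiseIdentity("ACDEF", "AC-EF")  # 4 / max(5, 4) = 0.8
#' @export
pairwiseIdentity <- function(a, b) {
  ca <- strsplit(toupper(a), "")[[1]]
  cb <- strsplit(toupper(b), "")[[1]]
  if (length(ca) != length(cb))
    stop("aligned rows must have equal length")
  ca[ca == "."] <- "-"
  cb[cb == "."] <- "-"
  lenA <- sum(ca != "-")
  lenB <- sum(cb != "-")
  if (lenA == 0 || lenB == 0) return(0)
  ident <- sum(ca == cb & ca != "-" & !(ca %in% .AMBIG))
  ident / max(lenA, lenB)
}

#' Pairwise identity matrix over an alignment
#'
#' Computes [pairwiseIdentity()] for every unordered pair of rows. The
#' implementation is vectorized (per-letter indicator cross-products), so
#' matrices over hundreds of sequences are immediate; a toy oracle using
#' \code{pairwiseIdentity} directly gives identical values.
#'
#' @param msa an \code{AAStringSet} or named character vector of aligned
#'   rows.
#' @return an [IdentityMatrix-class].
#' @export
identityMatrix <- function(msa) {
  m <- .msaMatrix(msa)
  n <- nrow(m)
  if (n < 2)
    stop("need at least 2 sequences")
  ungapped <- rowSums(m != "-")
  # identities[i, j] = number of columns where both rows carry the same
  # countable letter
  counted <- setdiff(unique(as.vector(m)), c("-", .AMBIG))
  ident <- matrix(0, n, n)
  for (a in counted) {
    ind <- (m == a) * 1
    ident <- ident + tcrossprod(ind)
  }
  denom <- outer(ungapped, ungapped, pmax)
  v <- ifelse(denom > 0, ident / denom, 0)
  diag(v) <- 1
  v <- (v + t(v)) / 2   # kill last-bit asymmetry from the float division
  new("IdentityMatrix", ids = rownames(m), values = v)
}

#' Distribution summary of pairwise identities
#'
#' Summaries over the off-diagonal upper triangle: a histogram of scores
#' multiplied by 100 and rounded half-up to integer percent (bin mass as a
#' percentage of pairs), and a five-number summary plus the median on the
#' unrounded values. The median is the statistic used to rank families by
#' conservation.
#'
#' @param m an [IdentityMatrix-class].
#' @param rounding "half-up" (default) or "half-even" for the histogram
#'   binning.
#' @return list: \code{histogram} (named numeric, percent of pairs per
#'   integer-percent bin), \code{fiveNumber} (min, Q1, median, Q3, max),
#'   \code{median}, \code{nPairs}.
#' @export
distributionSummary <- function(m, rounding = c("half-up", "half-even")) {
  stopifnot(is(m, "IdentityMatrix"))
  rounding <- match.arg(rounding)
  off <- m@values[upper.tri(m@values)]
  if (length(off) == 0)
    stop("need at least one off-diagonal pair")
  pct <- if (rounding == "half-up") floor(off * 100 + 0.5)
         else round(off * 100)
  tab <- table(pct)
  hist <- as.numeric(tab) / length(off) * 100
  names(hist) <- names(tab)
  q <- stats::quantile(off, c(0, 0.25, 0.5, 0.75, 1), names = FALSE,
                       type = 7)
  list(histogram = hist,
       fiveNumber = c(min = q[1], q1 = q[2], median = q[3], q3 = q[4],
                      max = q[5]),
       median = q[3],
       nPairs = length(off))
}

#' Filter alignment columns by gap fraction
#'
#' Keeps columns whose gap fraction is at most the threshold, and reports
#' the kept-column indices so logo positions remain traceable to the
#' original alignment numbering. This simple documented filter stands in
#' for more elaborate block-selection tools; pre-filtered alignments can of
#' course be supplied directly.
#'
#' @param msa \code{AAStringSet} or named character vector.
#' @param maxGapFraction keep a column iff its fraction of gap characters
#'   is <= this value (default 0.5).
#' @return list: \code{msa} (same type as input, filtered),
#'   \code{keptColumns} (integer indices into the original alignment).
#' @export
filterColumns <- function(msa, maxGapFraction = 0.5) {
  if (maxGapFraction < 0 || maxGapFraction > 1)
    stop("maxGapFraction must lie in [0, 1]")
  m <- .msaMatrix(msa)
  gapFrac <- colMeans(m == "-")
  keep <- which(gapFrac <= maxGapFraction)
  filtered <- apply(m[, keep, drop = FALSE], 1, paste, collapse = "")
  out <- if (is(msa, "XStringSet")) {
    res <- Biostrings::AAStringSet(filtered)
    names(res) <- rownames(m)
    res
  } else {
    names(filtered) <- rownames(m)
    filtered
  }
  list(msa = out, keptColumns = keep)
}

#' Per-column conservation (sequence-logo data)
#'
#' For each alignment column: residue frequencies over the 20 standard
#' amino acids scaled by the column's non-gap fraction (so gap mass is
#' excluded and the frequencies sum to the non-gap fraction), and the
#' information content in bits, \eqn{IC = \log_2 20 - H} with H the Shannon
#' entropy of the frequencies renormalized over non-gap letters. No
#' small-sample correction is applied. Letters outside the 20 standard
#' codes are treated as gaps. All-gap columns report IC 0 and zero
#' frequencies.
#'
#' @param msa \code{AAStringSet} or named character vector.
#' @return list: \code{frequencies} (L x 20 matrix, rows = columns of the
#'   alignment, scaled as above), \code{ic} (numeric L, bits),
#'   \code{nonGapFraction} (numeric L), \code{column} (integer L).
#' @export
columnConservation <- function(msa) {
  m <- .msaMatrix(msa)
  L <- ncol(m)
  freq <- matrix(0, L, length(.AA20), dimnames = list(NULL, .AA20))
  ic <- numeric(L)
  nonGap <- numeric(L)
  for (j in seq_len(L)) {
    col <- m[, j]
    col <- col[col %in% .AA20]
    nonGap[j] <- length(col) / nrow(m)
    if (length(col) == 0) next
    p <- table(factor(col, levels = .AA20)) / length(col)
    p <- as.numeric(p)
    H <- -sum(ifelse(p > 0, p * log2(p), 0))
    ic[j] <- log2(20) - H
    freq[j, ] <- p * nonGap[j]
  }
  list(frequencies = freq, ic = ic, nonGapFraction = nonGap,
       column = seq_len(L))
}
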