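# residue correspondence between homologous chains:
# sequence extraction -> global alignment -> collinear residue map

# parent one-letter codes for common modified residues; everything else
# unknown maps to X
.MODRES <- c(MSE = "M", SEC = "U", PYL = "O", CSO = "C", PTR = "Y",
             SEP = "S", TPO = "T", MLY = "K", HYP = "P")

#' Extract the one-letter sequence of a chain
#'
#' One letter per residue possessing a CA atom (after altloc resolution),
#' in residue-number order. Modified residues are mapped to their parent
#' amino acid (e.g. MSE to M); unknown residue names give 'X'. Waters and
#' non-CA heteroatoms drop out naturally.
#'
#' @param s a [PDBStructure-class].
#' @param chainId chain identifier.
#' @return list with \code{sequence} (single string), \code{resno}
#'   (integer vector, parallel to the sequence).
#' @export
extractSequence <- function(s, chainId) {
  ca <- selectAtoms(s, atomSelection(chainId, atomNames = "CA"))
  if (nrow(ca) == 0)
    return(list(sequence = "", resno = integer(0)))
  aa1 <- suppressWarnings(bio3d::aa321(ca$resname))
  aa1[is.na(aa1) | !(aa1 %in% LETTERS)] <- "X"
  mod <- ca$resname %in% names(.MODRES)
  aa1[mod] <- .MODRES[ca$resname[mod]]
  list(sequence = paste(aa1, collapse = ""), resno = ca$resno)
}

#' Global pairwise sequence alignment
#'
#' End-to-end (Needleman-Wunsch) alignment with a substitution matrix and
#' affine gap penalties, computed with \pkg{Biostrings}. The default scoring
#' is BLOSUM62 with gap open 10 and gap extension 0.5 (matrix units),
#' suitable for remote homologs; \code{scoring = "identity"} gives the toy
#' match-1 / mismatch-0 / gap -1 scheme.
#'
#' @param a,b amino-acid sequences (single strings, 20 letters plus X).
#' @param scoring "blosum62" or "identity", or a list with elements
#'   \code{matrix} (a named substitution matrix), \code{gapOpen},
#'   \code{gapExt}.
#' @return list of class \code{AlignedPair}: \code{seqA}, \code{seqB}
#'   (aligned strings of equal length, gap '-'), \code{score}.
#' @examples
#' alignGlobal("ACDE", "ADE", scoring = "identity")
#' @export
alignGlobal <- function(a, b, scoring = "blosum62") {
  if (!nzchar(a) || !nzchar(b))
    stop("sequences must be non-empty")
  ok <- "^[ACDEFGHIKLMNPQRSTVWYX]+$"
  if (!grepl(ok, a) || !grepl(ok, b))
    stop("sequences may contain only the 20 amino-acid letters plus X")
  if (is.character(scoring)) {
    scoring <- match.arg(scoring, c("blosum62", "identity"))
    scoring <- if (scoring == "blosum62")
      list(matrix = .blosum62(), gapOpen = 10, gapExt = 0.5)
    else
      list(matrix = .identityScoreMatrix(), gapOpen = 0, gapExt = 1)
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = scoring$matrix,
    gapOpening = scoring$gapOpen, gapExtension = scoring$gapExt,
    type = "global")
  out <- list(
    seqA = as.character(Biostrings::alignedPattern(pa)),
    seqB = as.character(Biostrings::alignedSubject(pa)),
    score = Biostrings::score(pa))
  names(out$seqA) <- names(out$seqB) <- NULL
  class(out) <- "AlignedPair"
  out
}

.blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

.identityScoreMatrix <- function() {
  letters20 <- c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y","X")
  m <- matrix(0, length(letters20), length(letters20),
              dimnames = list(letters20, letters20))
  diag(m) <- 1
  m["X", "X"] <- 0
  m
}

#' @export
print.AlignedPair <- function(x, ...) {
  cat("AlignedPair (length ", nchar(x$seqA), ", score ",
      format(x$score), ")\n", sep = "")
  cat(" A: ", x$seqA, "\n B: ", x$seqB, "\n", sep = "")
  invisible(x)
}

#' Write an aligned sequence pair as aligned FASTA
#'
#' @param pair an \code{AlignedPair} from [alignGlobal()].
#' @param path output file.
#' @param ids the two record ids.
#' @return invisibly, \code{path}.
#' @export
writeAlignedPair <- function(pair, path, ids = c("a", "b")) {
  stopifnot(inherits(pair, "AlignedPair"), length(ids) == 2)
  out <- Biostrings::AAStringSet(c(pair$seqA, pair$seqB))
  names(out) <- ids
  Biostrings::writeXStringSet(out, path)
  invisible(path)
}

#' Build an equivalent-residue map from an alignment
#'
#' One residue pair per alignment column in which both sequences carry a
#' non-gap letter; because extracted sequences contain only CA-bearing
#' residues, every such column maps a pair of CA atoms. Mismatched columns
#' are retained as equivalences (the superposition compares positions, not
#' identities). The result is collinear: author numbers strictly increase on
#' both sides.
#'
#' @param sA,sB [PDBStructure-class] objects.
#' @param chainA,chainB chain identifiers in \code{sA} / \code{sB}.
#' @param aln optional \code{AlignedPair} from [alignGlobal()] on these
#'   chains' extracted sequences; computed with default scoring if missing.
#' @param scoring passed to [alignGlobal()] when \code{aln} is missing.
#' @return a [ResidueMap-class].
#' @export
buildResidueMap <- function(sA, chainA, sB, chainB, aln = NULL,
                            scoring = "blosum62") {
  ea <- extractSequence(sA, chainA)
  eb <- extractSequence(sB, chainB)
  if (!nzchar(ea$sequence) || !nzchar(eb$sequence))
    stop("cannot map an empty chain (no CA atoms)")
  if (is.null(aln))
    aln <- alignGlobal(ea$sequence, eb$sequence, scoring = scoring)
  ca <- strsplit(aln$seqA, "")[[1]]
  cb <- strsplit(aln$seqB, "")[[1]]
  if (length(ca) != length(cb))
    stop("aligned sequences have unequal lengths")
  if (sum(ca != "-") != length(ea$resno) ||
      sum(cb != "-") != length(eb$resno))
    stop("alignment is inconsistent with the chains' extracted sequences")
  ia <- cumsum(ca != "-")
  ib <- cumsum(cb != "-")
  both <- ca != "-" & cb != "-"
  pairs <- data.frame(resnoA = ea$resno[ia[both]],
                      resnoB = eb$resno[ib[both]])
  new("ResidueMap", chainA = chainA, chainB = chainB, pairs = pairs)
}
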