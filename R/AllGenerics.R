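#' @describeIn PDBStructure chain identifiers present in the structure
#' @param x,object an object of the documented class
#' @export
setGeneric("chainIds", function(x) standardGeneric("chainIds"))

#' @describeIn SuperpositionResult fitted r.m.s.d. in angstrom
#' @export
setGeneric("rmsd", function(x) standardGeneric("rmsd"))

#' @describeIn SuperpositionResult 3x3 proper rotation matrix
#' @export
setGeneric("rotation", function(x) standardGeneric("rotation"))

#' @describeIn SuperpositionResult translation vector (angstrom)
#' @export
setGeneric("translation", function(x) standardGeneric("translation"))

#' @describeIn SuperpositionResult number of atom pairs fitted
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @describeIn SuperpositionResult per-pair deviations (angstrom)
#' @export
setGeneric("perPairDeviation", function(x) standardGeneric("perPairDeviation"))

#' @describeIn ResidueMap residue pairs as a data.frame
#' @export
setGeneric("residuePairs", function(x) standardGeneric("residuePairs"))

#' @describeIn ResidueMap number of mapped residue pairs
#' @export
setGeneric("nPairs", function(x) standardGeneric("nPairs"))

#' @describeIn IdentityMatrix identity fractions as a plain matrix
#' @export
setGeneric("identityValues", function(x) standardGeneric("identityValues"))

#' @describeIn DisorderReport missing segments as a two-column matrix
#' @export
setGeneric("missingSegments", function(x) standardGeneric("missingSegments"))

setMethod("chainIds", "PDBStructure", function(x) unique(x@atoms$chain))

setMethod("rmsd", "SuperpositionResult", function(x) x@rmsd)
setMethod("rotation", "SuperpositionResult", function(x) x@rotation)
setMethod("translation", "SuperpositionResult", function(x) x@translation)
setMethod("nAtoms", "SuperpositionResult", function(x) x@nAtoms)
setMethod("perPairDeviation", "SuperpositionResult",
          function(x) x@perPairDeviation)

setMethod("residuePairs", "ResidueMap", function(x) x@pairs)
setMethod("nPairs", "ResidueMap", function(x) nrow(x@pairs))

setMethod("identityValues", "IdentityMatrix", function(x) {
  v <- x@values
  dimnames(v) <- list(x@ids, x@ids)
  v
})

setMethod("missingSegments", "DisorderReport", function(x) x@missingSegments)

setMethod("show", "PDBStructure", function(object) {
  a <- object@atoms
  prot <- a[!a$het & !(a$resname %in% c("HOH", "WAT")), , drop = FALSE]
  cat("PDBStructure \"", object@id, "\": ",
      length(unique(a$chain)), " chain(s), ",
      nrow(unique(prot[, c("chain", "resno", "icode")])),
      " protein residue(s), ", nrow(a), " atom(s)\n", sep = "")
  if (length(object@cell) == 6)
    cat("  cell: ", paste(format(object@cell, trim = TRUE), collapse = " "),
        if (!is.na(object@spacegroup)) paste0("  (", object@spacegroup, ")"),
        "\n", sep = "")
  invisible(object)
})

setMethod("show", "AtomSelection", function(object) {
  fmtRanges <- function(r) {
    if (nrow(r) == 0) return("-")
    paste(apply(r, 1, function(z) paste(z[1], z[2], sep = "-")),
          collapse = ",")
  }
  cat("AtomSelection chain ", object@chainId,
      " include [", fmtRanges(object@includeRanges),
      "] exclude [", fmtRanges(object@excludeRanges),
      "] atoms {", paste(object@atomNames, collapse = ","), "}\n", sep = "")
  invisible(object)
})

setMethod("show", "ResidueMap", function(object) {
  cat("ResidueMap ", object@chainA, " -> ", object@chainB, ": ",
      nrow(object@pairs), " equivalent residue pair(s)\n", sep = "")
  invisible(object)
})

setMethod("show", "SuperpositionResult", function(object) {
  cat("SuperpositionResult: r.m.s.d. ",
      formatC(object@rmsd, format = "f", digits = 3), " A over ",
      object@nAtoms, " atoms\n", sep = "")
  invisible(object)
})

setMethod("show", "IdentityMatrix", function(object) {
  n <- length(object@ids)
  off <- object@values[upper.tri(object@values)]
  cat("IdentityMatrix: ", n, " sequences, ", length(off), " pairs",
      if (length(off)) sprintf(", median identity %.3f", stats::median(off)),
      "\n", sep = "")
  invisible(object)
})

setMethod("show", "DisorderReport", function(object) {
  seg <- object@missingSegments
  lab <- if (nrow(seg) == 0) "none" else
    paste(ifelse(seg[, 1] == seg[, 2], seg[, 1],
                 paste(seg[, 1], seg[, 2], sep = "-")), collapse = ", ")
  cat("DisorderReport chain ", object@chainId, " expected ",
      object@expectedRange[1], "-", object@expectedRange[2],
      ": modeled ", object@nModeled, ", missing ", object@nMissing,
      " (", lab, ")\n", sep = "")
  invisible(object)
})
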