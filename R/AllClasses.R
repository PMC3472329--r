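#' @import methods
NULL

#' Crystal-structure model
#'
#' An S4 container for a macromolecular model: a flat atom table carrying the
#' chain > residue > atom hierarchy in author numbering, plus optional crystal
#' metadata (unit cell, space group, asymmetric units per cell).
#'
#' The atom table has one row per atom with columns \code{chain},
#' \code{resno} (author residue number), \code{icode} (insertion code, ""
#' when absent), \code{resname} (3-letter code), \code{atom} (atom label,
#' e.g. "CA"), \code{element}, \code{x}, \code{y}, \code{z} (angstrom),
#' \code{occupancy}, \code{b} (isotropic B-factor, angstrom^2),
#' \code{altloc} ("" when absent) and \code{het} (logical, TRUE for HETATM
#' records). Waters (residue name HOH/WAT) stay in the table but are flagged
#' and excluded from all statistics unless explicitly requested.
#'
#' @slot id character(1), structure identifier.
#' @slot atoms data.frame as described above.
#' @slot cell numeric(6) \code{c(a, b, c, alpha, beta, gamma)} in angstrom /
#'   degrees, or numeric(0) when no cell is known.
#' @slot spacegroup character(1), e.g. "P41"; \code{NA_character_} if unknown.
#' @slot auPerCell integer(1), asymmetric units per unit cell (space-group
#'   multiplicity); \code{NA_integer_} if unknown.
#'
#' @seealso [readStructure()], [writeStructure()], [selectAtoms()]
#' @export
setClass("PDBStructure",
  representation(
    id = "character",
    atoms = "data.frame",
    cell = "numeric",
    spacegroup = "character",
    auPerCell = "integer"
  ),
  prototype(
    id = "structure",
    cell = numeric(0),
    spacegroup = NA_character_,
    auPerCell = NA_integer_
  )
)

.validStructure <- function(object) {
  msg <- character(0)
  a <- object@atoms
  need <- c("chain", "resno", "icode", "resname", "atom", "element",
            "x", "y", "z", "occupancy", "b", "altloc", "het")
  if (!all(need %in% names(a)))
    msg <- c(msg, paste("atom table missing columns:",
                        paste(setdiff(need, names(a)), collapse = ", ")))
  else {
    if (nrow(a) > 0) {
      if (any(!is.finite(a$occupancy)) || any(a$occupancy < 0 | a$occupancy > 1))
        msg <- c(msg, "occupancy must lie in [0, 1]")
      if (any(!is.finite(a$b)) || any(a$b < 0))
        msg <- c(msg, "B-factors must be finite and >= 0")
      if (any(!is.finite(c(a$x, a$y, a$z))))
        msg <- c(msg, "coordinates must be finite")
    }
  }
  if (length(object@cell) != 0) {
    if (length(object@cell) != 6)
      msg <- c(msg, "cell must have 6 parameters (a, b, c, alpha, beta, gamma)")
    else {
      if (any(object@cell[1:3] <= 0))
        msg <- c(msg, "cell lengths must be positive")
      if (any(object@cell[4:6] <= 0 | object@cell[4:6] >= 180))
        msg <- c(msg, "cell angles must lie in (0, 180) degrees")
    }
  }
  if (length(msg)) msg else TRUE
}
setValidity("PDBStructure", .validStructure)

#' Residue-range atom selection
#'
#' Selects atoms from one chain by inclusive author-number ranges and atom
#' names. A residue is selected iff it falls in some include range (or the
#' include set is empty, meaning the whole chain) and in no exclude range.
#'
#' @slot chainId character(1).
#' @slot includeRanges integer matrix with columns \code{start}, \code{end}
#'   (inclusive); zero rows = whole chain.
#' @slot excludeRanges same shape as \code{includeRanges}.
#' @slot atomNames character vector of atom labels; default \code{"CA"}.
#'
#' @seealso [atomSelection()], [selectAtoms()]
#' @export
setClass("AtomSelection",
  representation(
    chainId = "character",
    includeRanges = "matrix",
    excludeRanges = "matrix",
    atomNames = "character"
  )
)

.validSelection <- function(object) {
  msg <- character(0)
  if (length(object@chainId) != 1L || is.na(object@chainId))
    msg <- c(msg, "chainId must be a single chain identifier")
  for (nm in c("includeRanges", "excludeRanges")) {
    r <- slot(object, nm)
    if (ncol(r) != 2L)
      msg <- c(msg, paste(nm, "must have two columns (start, end)"))
    else if (nrow(r) > 0 && any(r[, 1] > r[, 2]))
      msg <- c(msg, paste(nm, "must satisfy start <= end"))
  }
  if (length(object@atomNames) < 1L)
    msg <- c(msg, "atomNames must name at least one atom")
  if (length(msg)) msg else TRUE
}
setValidity("AtomSelection", .validSelection)

#' Equivalent-residue map between two homologous chains
#'
#' Ordered list of residue pairs \code{(number_a, number_b)} that are
#' considered structurally equivalent, normally derived from a global
#' pairwise sequence alignment of the two chains' extracted sequences.
#' The mapping is collinear: author numbers strictly increase on both sides.
#'
#' @slot chainA,chainB character(1), chain identifiers in the two structures.
#' @slot pairs data.frame with integer columns \code{resnoA}, \code{resnoB}.
#'
#' @seealso [buildResidueMap()], [superposeMapped()]
#' @export
setClass("ResidueMap",
  representation(chainA = "character", chainB = "character",
                 pairs = "data.frame")
)

.validResidueMap <- function(object) {
  msg <- character(0)
  p <- object@pairs
  if (!all(c("resnoA", "resnoB") %in% names(p)))
    msg <- c(msg, "pairs must have columns resnoA, resnoB")
  else if (nrow(p) > 1) {
    if (any(diff(p$resnoA) <= 0) || any(diff(p$resnoB) <= 0))
      msg <- c(msg, "residue map must be strictly increasing on both sides")
  }
  if (length(msg)) msg else TRUE
}
setValidity("ResidueMap", .validResidueMap)

#' Rigid-body superposition result
#'
#' The proper rotation and translation minimizing the sum of squared
#' distances between paired atoms (Kabsch), the resulting r.m.s.d. and the
#' per-pair deviations in the fitted frame.
#'
#' The transform maps the mobile coordinates \code{a} onto the reference
#' \code{b}: \code{a' = a \%*\% t(R) + t}.
#'
#' @slot rotation 3x3 orthonormal matrix with determinant +1.
#' @slot translation numeric(3), angstrom.
#' @slot rmsd numeric(1), angstrom.
#' @slot nAtoms integer(1), atom pairs used for the fit.
#' @slot perPairDeviation numeric, one deviation (angstrom) per fitted pair.
#'
#' @seealso [kabsch()], [superposeMapped()], [perResidueProfile()]
#' @export
setClass("SuperpositionResult",
  representation(
    rotation = "matrix",
    translation = "numeric",
    rmsd = "numeric",
    nAtoms = "integer",
    perPairDeviation = "numeric"
  )
)

.validSuperposition <- function(object) {
  msg <- character(0)
  R <- object@rotation
  if (!all(dim(R) == c(3L, 3L)))
    msg <- c(msg, "rotation must be 3x3")
  else {
    if (max(abs(crossprod(R) - diag(3))) > 1e-8)
      msg <- c(msg, "rotation must be orthonormal (tol 1e-8)")
    if (abs(det(R) - 1) > 1e-8)
      msg <- c(msg, "rotation must be proper (det +1)")
  }
  if (length(object@translation) != 3L)
    msg <- c(msg, "translation must have length 3")
  d <- object@perPairDeviation
  if (length(d) > 0 &&
      abs(object@rmsd - sqrt(mean(d^2))) > 1e-10)
    msg <- c(msg, "rmsd must equal sqrt(mean(per-pair deviation^2))")
  if (length(msg)) msg else TRUE
}
setValidity("SuperpositionResult", .validSuperposition)

#' Pairwise sequence-identity matrix
#'
#' Symmetric matrix of pairwise identity fractions over the rows of a
#' multiple sequence alignment, with unit diagonal. The identity of a pair
#' is the number of identical non-gap columns divided by the longer of the
#' two ungapped sequence lengths, after removal of columns gapped in both
#' sequences.
#'
#' @slot ids character, sequence identifiers (unique).
#' @slot values numeric matrix, symmetric, entries in [0, 1], diagonal 1.
#'
#' @seealso [identityMatrix()], [distributionSummary()]
#' @export
setClass("IdentityMatrix",
  representation(ids = "character", values = "matrix")
)

.validIdentityMatrix <- function(object) {
  msg <- character(0)
  v <- object@values
  n <- length(object@ids)
  if (anyDuplicated(object@ids))
    msg <- c(msg, "sequence ids must be unique")
  if (!all(dim(v) == c(n, n)))
    msg <- c(msg, "values must be n x n for n ids")
  else if (n > 0) {
    if (max(abs(v - t(v))) > 1e-12)
      msg <- c(msg, "matrix must be symmetric (tol 1e-12)")
    if (any(abs(diag(v) - 1) > 0))
      msg <- c(msg, "diagonal must be exactly 1")
    if (any(v < 0 | v > 1))
      msg <- c(msg, "entries must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
}
setValidity("IdentityMatrix", .validIdentityMatrix)

#' Disordered-segment report
#'
#' Maximal runs of expected residue numbers that carry no CA atom in the
#' model — the crystallographic signature of segments with no interpretable
#' electron density.
#'
#' @slot chainId character(1).
#' @slot expectedRange integer(2), inclusive author-number span expected to
#'   be present.
#' @slot missingSegments integer matrix with columns \code{start},
#'   \code{end}; disjoint, sorted, within \code{expectedRange}.
#' @slot nModeled,nMissing integer(1); they sum to the expected span length.
#'
#' @seealso [detectDisorder()]
#' @export
setClass("DisorderReport",
  representation(
    chainId = "character",
    expectedRange = "integer",
    missingSegments = "matrix",
    nModeled = "integer",
    nMissing = "integer"
  )
)

.validDisorder <- function(object) {
  msg <- character(0)
  er <- object@expectedRange
  seg <- object@missingSegments
  if (length(er) != 2L || er[1] > er[2])
    msg <- c(msg, "expectedRange must be c(first, last) with first <= last")
  if (ncol(seg) != 2L)
    msg <- c(msg, "missingSegments must have columns start, end")
  else if (nrow(seg) > 0) {
    if (any(seg[, 1] > seg[, 2]))
      msg <- c(msg, "segments must satisfy start <= end")
    if (any(seg[, 1] < er[1]) || any(seg[, 2] > er[2]))
      msg <- c(msg, "segments must lie within expectedRange")
    if (nrow(seg) > 1 && any(seg[-1, 1] <= seg[-nrow(seg), 2]))
      msg <- c(msg, "segments must be sorted and disjoint")
  }
  span <- er[2] - er[1] + 1L
  if (object@nModeled + object@nMissing != span)
    msg <- c(msg, "nModeled + nMissing must equal the expected span length")
  if (sum(seg[, 2] - seg[, 1] + 1L) != object@nMissing)
    msg <- c(msg, "nMissing must equal the total segment length")
  if (length(msg)) msg else TRUE
}
setValidity("DisorderReport", .validDisorder)
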