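# unit-cell volume, Matthews coefficient, solvent content

#' Unit-cell volume
#'
#' Triclinic closed form
#' \eqn{V = abc\sqrt{1 - \cos^2\alpha - \cos^2\beta - \cos^2\gamma
#'                   + 2\cos\alpha\cos\beta\cos\gamma}}.
#'
#' @param cell numeric(6): a, b, c (angstrom), alpha, beta, gamma (degrees).
#' @return volume in cubic angstrom.
#' @examples
#' cellVolume(c(124.5, 124.5, 77.5, 90, 90, 90))
#' @export
cellVolume <- function(cell) {
  cell <- as.numeric(cell)
  if (length(cell) != 6 || any(!is.finite(cell)))
    stop("cell must be numeric(6): a, b, c, alpha, beta, gamma")
  if (any(cell[1:3] <= 0))
    stop("cell lengths must be positive")
  if (any(cell[4:6] <= 0 | cell[4:6] >= 180))
    stop("cell angles must lie in (0, 180) degrees")
  cs <- cos(cell[4:6] * pi / 180)
  disc <- 1 - sum(cs^2) + 2 * prod(cs)
  if (disc <= 0)
    stop("invalid cell: non-positive metric discriminant")
  prod(cell[1:3]) * sqrt(disc)
}

# asymmetric units per cell for common space groups; names normalized by
# stripping spaces, parentheses and underscores
.SG_MULTIPLICITY <- c(
  "P1" = 1L, "P-1" = 2L,
  "P2" = 2L, "P21" = 2L, "C2" = 4L,
  "P222" = 4L, "P2221" = 4L, "P21212" = 4L, "P212121" = 4L,
  "C2221" = 8L, "C222" = 8L, "F222" = 16L, "I222" = 8L, "I212121" = 8L,
  "P4" = 4L, "P41" = 4L, "P42" = 4L, "P43" = 4L, "I4" = 8L, "I41" = 8L,
  "P422" = 8L, "P4122" = 8L, "P41212" = 8L, "P4322" = 8L, "P43212" = 8L,
  "P3" = 3L, "P31" = 3L, "P32" = 3L, "R3" = 9L,
  "P312" = 6L, "P321" = 6L, "P3112" = 6L, "P3121" = 6L,
  "P3212" = 6L, "P3221" = 6L, "R32" = 18L,
  "P6" = 6L, "P61" = 6L, "P65" = 6L, "P62" = 6L, "P64" = 6L, "P63" = 6L,
  "P622" = 12L, "P6122" = 12L, "P6522" = 12L,
  "P23" = 12L, "F23" = 48L, "I23" = 24L, "P213" = 12L, "I213" = 24L,
  "P432" = 24L, "P4132" = 24L, "P4232" = 24L, "P4332" = 24L,
  "F432" = 96L, "F4132" = 96L, "I432" = 48L, "I4132" = 48L
)

#' Space-group multiplicity (asymmetric units per unit cell)
#'
#' Looks the name up in a small built-in table of common macromolecular
#' space groups; spaces, parentheses and underscores in the name are
#' ignored ("P 41", "P4(1)" and "P41" are equivalent). Use the
#' \code{auPerCell} argument of the crystal functions to override for
#' groups not in the table.
#'
#' @param name Hermann-Mauguin symbol.
#' @return integer multiplicity.
#' @examples
#' spacegroupMultiplicity("P 41")   # 4
#' @export
spacegroupMultiplicity <- function(name) {
  key <- toupper(gsub("[ _()]", "", name))
  m <- .SG_MULTIPLICITY[key]
  if (is.na(m))
    stop("space group not in the built-in table: ", name,
         " (supply auPerCell explicitly)")
  unname(m)
}

#' Matthews coefficient
#'
#' Crystal volume per Dalton of macromolecule,
#' \eqn{V_M = V_{cell} / (Z \cdot n \cdot M)} with Z asymmetric units per
#' cell, n molecules per asymmetric unit and M the molecular mass (Da).
#'
#' @param cell numeric(6) unit cell, as in [cellVolume()].
#' @param massDa molecular mass per molecule, Dalton.
#' @param nMolecules molecules per asymmetric unit.
#' @param auPerCell asymmetric units per cell; alternatively give
#'   \code{spacegroup} and the multiplicity is looked up.
#' @param spacegroup Hermann-Mauguin symbol (used when \code{auPerCell} is
#'   missing).
#' @return Matthews coefficient, cubic angstrom per Dalton.
#' @examples
#' # tetragonal P41 cell, two 66 kDa heterodimers per asymmetric unit
#' matthewsCoefficient(c(124.5, 124.5, 77.5, 90, 90, 90),
#'                     massDa = 66000, nMolecules = 2, spacegroup = "P41")
#' @export
matthewsCoefficient <- function(cell, massDa, nMolecules = 1,
                                auPerCell = NULL, spacegroup = NULL) {
  if (is.null(auPerCell)) {
    if (is.null(spacegroup))
      stop("give auPerCell or a spacegroup name")
    auPerCell <- spacegroupMultiplicity(spacegroup)
  }
  if (massDa <= 0) stop("molecular mass must be positive")
  if (nMolecules <= 0 || auPerCell <= 0)
    stop("contents counts must be positive")
  cellVolume(cell) / (auPerCell * nMolecules * massDa)
}

#' Fractional solvent content from the Matthews coefficient
#'
#' \eqn{f_{solv} = 1 - 1.660 \bar v / V_M}, with \eqn{\bar v} the protein
#' partial specific volume (default 0.74 cm^3/g, Matthews' convention, so
#' the constant is 1.228) and 1.660 = 10^24 / N_A folding the Dalton-to-gram
#' and angstrom^3-to-cm^3 conversions into one factor.
#'
#' @param vm Matthews coefficient, cubic angstrom per Dalton.
#' @param partialSpecificVolume protein partial specific volume, cm^3/g.
#' @return solvent fraction in [0, 1]; non-physical inputs
#'   (\code{vm <= 1.660 * vbar}) warn and clamp to 0.
#' @examples
#' solventContent(2.275)   # ~0.46
#' @export
solventContent <- function(vm, partialSpecificVolume = 0.74) {
  if (vm <= 0) stop("Matthews coefficient must be positive")
  f <- 1 - (1.660 * partialSpecificVolume) / vm
  if (f < 0) {
    warning("V_M below the protein close-packing limit; clamping to 0")
    f <- 0
  }
  f
}

#' The tetragonal capping-protein crystal fixture
#'
#' The crystal form used throughout the examples and tests: a tetragonal
#' P4(1) cell of 124.5 x 124.5 x 77.5 angstrom with two ~66 kDa heterodimers
#' per asymmetric unit (heterodimer mass taken as 32 + 34 kDa; the subunit
#' masses give the protein its name).
#'
#' @return list with \code{cell}, \code{spacegroup}, \code{auPerCell},
#'   \code{nMolecules}, \code{massDa}.
#' @export
crystalFixture <- function() {
  list(cell = c(124.5, 124.5, 77.5, 90, 90, 90),
       spacegroup = "P41",
       auPerCell = 4L,
       nMolecules = 2,
       massDa = 66000)
}
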