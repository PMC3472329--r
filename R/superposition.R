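#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation R and translation t minimizing
#' \eqn{\sum_i \| R a_i + t - b_i \|^2} over paired coordinates, via SVD of
#' the cross-covariance of the centered clouds. The reflection branch is
#' corrected by the sign of the determinant, so the result is always a
#' proper rotation (det +1), including the degenerate planar case where the
#' smallest singular value's axis carries the correction.
#'
#' The superposition is unweighted: every atom pair contributes equally,
#' regardless of occupancy or B-factor (an optional \code{weights} vector is
#' accepted for forward compatibility).
#'
#' @param coordsA,coordsB numeric n x 3 matrices of paired coordinates
#'   (angstrom); \code{coordsA} is the mobile set, \code{coordsB} the
#'   reference.
#' @param weights optional positive weights of length n.
#' @return a [SuperpositionResult-class]; the transform maps A onto B as
#'   \code{sweep(coordsA \%*\% t(rotation(r)), 2, translation(r), "+")}.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(30), ncol = 3)
#' r <- kabsch(x, x)            # identity transform, rmsd 0
#' rmsd(r)
#' @export
kabsch <- function(coordsA, coordsB, weights = NULL) {
  coordsA <- .asCoordMatrix(coordsA, "coordsA")
  coordsB <- .asCoordMatrix(coordsB, "coordsB")
  n <- nrow(coordsA)
  if (nrow(coordsB) != n)
    stop("coordinate sets must have equal length")
  if (n < 3)
    stop("degenerate geometry: need at least 3 points")
  w <- if (is.null(weights)) rep(1, n) else {
    stopifnot(length(weights) == n, all(weights > 0))
    weights
  }
  wn <- w / sum(w)
  ca <- colSums(coordsA * wn)
  cb <- colSums(coordsB * wn)
  A <- sweep(coordsA, 2, ca)
  B <- sweep(coordsB, 2, cb)
  H <- crossprod(A * wn, B)            # 3x3 cross-covariance
  sv <- svd(H)
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1))
    stop("degenerate geometry: points are (nearly) collinear")
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- cb - as.numeric(R %*% ca)
  fitted <- sweep(coordsA %*% t(R), 2, t, "+")
  dev <- sqrt(rowSums((fitted - coordsB)^2))
  new("SuperpositionResult",
      rotation = R, translation = t,
      rmsd = sqrt(mean(dev^2)), nAtoms = as.integer(n),
      perPairDeviation = dev)
}

.asCoordMatrix <- function(x, what) {
  x <- as.matrix(x)
  if (ncol(x) != 3)
    stop(what, " must be an n x 3 coordinate matrix")
  if (any(!is.finite(x)))
    stop(what, " contains non-finite coordinates")
  storage.mode(x) <- "double"
  x
}

# CA coordinates of mapped pairs; rows follow the map order. Pairs whose CA
# is absent on either side (after selection) are dropped.
.mappedCoords <- function(sA, sB, map, selA = NULL, selB = NULL) {
  caA <- selectAtoms(sA, atomSelection(map@chainA, atomNames = "CA"))
  caB <- selectAtoms(sB, atomSelection(map@chainB, atomNames = "CA"))
  p <- map@pairs
  keep <- rep(TRUE, nrow(p))
  if (!is.null(selA)) {
    inInc <- if (nrow(selA@includeRanges) == 0) rep(TRUE, nrow(p))
             else .inRanges(p$resnoA, selA@includeRanges)
    keep <- keep & inInc & !.inRanges(p$resnoA, selA@excludeRanges)
  }
  if (!is.null(selB)) {
    inInc <- if (nrow(selB@includeRanges) == 0) rep(TRUE, nrow(p))
             else .inRanges(p$resnoB, selB@includeRanges)
    keep <- keep & inInc & !.inRanges(p$resnoB, selB@excludeRanges)
  }
  ia <- match(p$resnoA, caA$resno)
  ib <- match(p$resnoB, caB$resno)
  keep <- keep & !is.na(ia) & !is.na(ib)
  list(
    a = as.matrix(caA[ia[keep], c("x", "y", "z")]),
    b = as.matrix(caB[ib[keep], c("x", "y", "z")]),
    bA = caA$b[ia[keep]],
    bB = caB$b[ib[keep]],
    pairs = p[keep, , drop = FALSE]
  )
}

#' Superpose two structures over a residue map, with fit/report separation
#'
#' The rigid fit is computed only on the residue pairs that survive the fit
#' selection; the fitted transform is then applied to all mapped CA atoms and
#' the r.m.s.d. is reported separately for each report selection, so a
#' region's deviation is measured in the global frame. This mirrors how
#' regional differences between homologs are quoted alongside a
#' whole-molecule superposition.
#'
#' Selections come in pairs (one per structure); pass a single
#' [AtomSelection-class] to constrain side A only, a list
#' \code{list(a = , b = )} to constrain both, or NULL for no constraint.
#'
#' @param sA,sB [PDBStructure-class] objects (A is mobile, B reference).
#' @param map a [ResidueMap-class] between a chain of \code{sA} and a chain
#'   of \code{sB}.
#' @param fitSel selection pair restricting which mapped pairs enter the fit.
#' @param reportSels named list of selection pairs; each gets a row in the
#'   region table.
#' @return list with \code{result} (a [SuperpositionResult-class] for the
#'   fit set), \code{regions} (data.frame: region, n_atoms, rmsd), and
#'   \code{profile} (per-pair deviations over the full map in the fitted
#'   frame: resnoA, resnoB, deviation).
#' @export
superposeMapped <- function(sA, sB, map, fitSel = NULL, reportSels = list()) {
  stopifnot(is(map, "ResidueMap"))
  fp <- .asSelectionPair(fitSel)
  fit <- .mappedCoords(sA, sB, map, fp$a, fp$b)
  if (nrow(fit$a) == 0)
    stop("fit selection does not intersect the residue map")
  res <- kabsch(fit$a, fit$b)

  full <- .mappedCoords(sA, sB, map)
  moved <- sweep(full$a %*% t(res@rotation), 2, res@translation, "+")
  dev <- sqrt(rowSums((moved - full$b)^2))
  profile <- data.frame(resnoA = full$pairs$resnoA,
                        resnoB = full$pairs$resnoB,
                        deviation = dev)

  regions <- data.frame(region = character(0), n_atoms = integer(0),
                        rmsd = numeric(0))
  for (nm in names(reportSels)) {
    rp <- .asSelectionPair(reportSels[[nm]])
    sub <- .mappedCoords(sA, sB, map, rp$a, rp$b)
    if (nrow(sub$a) == 0)
      stop("report selection '", nm, "' has no mapped residues")
    movedSub <- sweep(sub$a %*% t(res@rotation), 2, res@translation, "+")
    dsub <- sqrt(rowSums((movedSub - sub$b)^2))
    regions <- rbind(regions, data.frame(
      region = nm, n_atoms = nrow(sub$a), rmsd = sqrt(mean(dsub^2))))
  }
  list(result = res, regions = regions, profile = profile)
}

.asSelectionPair <- function(sel) {
  if (is.null(sel)) return(list(a = NULL, b = NULL))
  if (is(sel, "AtomSelection")) return(list(a = sel, b = NULL))
  if (is.list(sel) && all(c("a", "b") %in% names(sel)))
    return(list(a = sel$a, b = sel$b))
  stop("a selection pair must be an AtomSelection, list(a=, b=) or NULL")
}

#' Per-residue deviation profile of a superposition
#'
#' One row per mapped pair, with the deviation of the pair's CA atoms in the
#' fitted frame. By construction \code{sqrt(mean(deviation^2))} equals the
#' result's r.m.s.d. when the profile covers exactly the fitted pairs.
#'
#' @param result a [SuperpositionResult-class].
#' @param map the [ResidueMap-class] the result was produced from.
#' @return data.frame with columns \code{resnoA}, \code{resnoB},
#'   \code{deviation}.
#' @export
perResidueProfile <- function(result, map) {
  stopifnot(is(result, "SuperpositionResult"), is(map, "ResidueMap"))
  p <- map@pairs
  if (nrow(p) != length(result@perPairDeviation))
    stop("residue map length does not match the superposition result")
  data.frame(resnoA = p$resnoA, resnoB = p$resnoB,
             deviation = result@perPairDeviation)
}
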