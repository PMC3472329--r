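# B-factor statistics, cross-structure region comparison, and detection of
# disordered (unmodeled) segments

#' B-factor statistics over a region
#'
#' Mean and standard deviation of atomic B-factors over a selection
#' (CA atoms by default; widen \code{atomNames} in the selection or use
#' \code{mode = "all"} for all-atom statistics), plus a z-score of the
#' region mean against the whole-chain per-atom B distribution.
#'
#' @param s a [PDBStructure-class].
#' @param sel an [AtomSelection-class]; its \code{atomNames} are overridden
#'   when \code{mode = "all"}.
#' @param refSel reference selection for the z-score; defaults to the whole
#'   chain of \code{sel} with the same atom mode. Waters and heteroatoms are
#'   always excluded from the reference distribution.
#' @param mode "CA" (default, as set in the selection) or "all" (every
#'   protein atom of the selected residues).
#' @param label region name carried into the output.
#' @return one-row data.frame: \code{region}, \code{n_residues},
#'   \code{n_atoms}, \code{mean_b}, \code{sd_b}, \code{z_mean_b}, and a
#'   logical \code{constant_b} flag set when the reference distribution is
#'   degenerate (z reported as 0 with a warning).
#' @export
regionBStats <- function(s, sel, refSel = NULL, mode = c("CA", "all"),
                         label = sel@chainId) {
  mode <- match.arg(mode)
  if (mode == "all") {
    sel <- .allAtomSelection(sel)
    if (!is.null(refSel)) refSel <- .allAtomSelection(refSel)
  }
  atoms <- .proteinAtoms(selectAtoms(s, sel))
  if (nrow(atoms) == 0)
    stop("selection matches no atoms")
  if (is.null(refSel))
    refSel <- atomSelection(sel@chainId, atomNames = sel@atomNames)
  ref <- .proteinAtoms(selectAtoms(s, refSel))
  meanB <- mean(atoms$b)
  sdRef <- stats::sd(ref$b)
  constant <- !is.finite(sdRef) || sdRef == 0
  if (constant) {
    warning("reference B-factor distribution is constant; z-score set to 0")
    z <- 0
  } else {
    z <- (meanB - mean(ref$b)) / sdRef
  }
  data.frame(region = label,
             n_residues = length(unique(paste(atoms$resno, atoms$icode))),
             n_atoms = nrow(atoms),
             mean_b = meanB,
             sd_b = if (nrow(atoms) > 1) stats::sd(atoms$b) else 0,
             z_mean_b = z,
             constant_b = constant)
}

.proteinAtoms <- function(atoms)
  atoms[!atoms$het & !(atoms$resname %in% c("HOH", "WAT")), , drop = FALSE]

.allAtomSelection <- function(sel)
  new("AtomSelection", chainId = sel@chainId,
      includeRanges = sel@includeRanges, excludeRanges = sel@excludeRanges,
      atomNames = "*")

#' Compare a region between two homologous structures
#'
#' Reports the mean B-factor of the region on each side, their difference,
#' and the region's CA r.m.s.d. measured in the global-fit frame (the rigid
#' fit uses the whole residue map unless \code{fitSel} restricts it).
#'
#' @param sA,sB [PDBStructure-class] objects.
#' @param map a [ResidueMap-class] between the chains being compared.
#' @param regionA,regionB [AtomSelection-class] regions, one per structure.
#' @param mode "CA" or "all" for the B statistics (the r.m.s.d. is always
#'   over CA atoms).
#' @param fitSel optional selection pair for the rigid fit (default: whole
#'   map).
#' @return one-row data.frame: \code{mean_b_a}, \code{mean_b_b},
#'   \code{delta_mean_b} (A minus B), \code{rmsd}, \code{n_atoms}.
#' @export
compareRegions <- function(sA, sB, map, regionA, regionB,
                           mode = c("CA", "all"), fitSel = NULL) {
  mode <- match.arg(mode)
  sup <- superposeMapped(sA, sB, map, fitSel = fitSel,
                         reportSels = list(region = list(a = regionA,
                                                         b = regionB)))
  if (sup$regions$n_atoms[1] == 0)
    stop("region does not intersect the residue map")
  # the z-scores are not part of this report; a constant-B reference on
  # either side is fine here
  statA <- suppressWarnings(regionBStats(sA, regionA, mode = mode,
                                         label = "A"))
  statB <- suppressWarnings(regionBStats(sB, regionB, mode = mode,
                                         label = "B"))
  data.frame(mean_b_a = statA$mean_b,
             mean_b_b = statB$mean_b,
             delta_mean_b = statA$mean_b - statB$mean_b,
             rmsd = sup$regions$rmsd[1],
             n_atoms = sup$regions$n_atoms[1])
}

#' Detect disordered (unmodeled) segments of a chain
#'
#' Missing segments are the maximal runs of author numbers within the
#' expected range that have no CA-bearing residue in the model — the
#' standard signature of residues with no interpretable electron density.
#'
#' @param s a [PDBStructure-class].
#' @param chainId chain identifier.
#' @param expectedRange \code{c(first, last)} author numbers expected to be
#'   present.
#' @return a [DisorderReport-class].
#' @examples
#' # a 272-residue chain modeled 2-139 and 146-250
#' s <- makeChain(272, seed = 1)
#' s <- perturbStructure(s, perturbationSpec(
#'   missingRanges = list(1, c(140, 145), c(251, 272))))$structure
#' detectDisorder(s, "A", c(1, 272))
#' @export
detectDisorder <- function(s, chainId, expectedRange) {
  expectedRange <- as.integer(expectedRange)
  if (length(expectedRange) != 2L || expectedRange[1] > expectedRange[2])
    stop("expectedRange must be c(first, last) with first <= last")
  ca <- selectAtoms(s, atomSelection(chainId, atomNames = "CA"))
  expected <- seq.int(expectedRange[1], expectedRange[2])
  present <- intersect(expected, ca$resno)
  missing <- setdiff(expected, present)
  seg <- .runsToRanges(missing)
  new("DisorderReport",
      chainId = chainId,
      expectedRange = expectedRange,
      missingSegments = seg,
      nModeled = length(present),
      nMissing = length(missing))
}

#' Model-wide mean B-factor
#'
#' Mean isotropic B over all protein atoms of all protein chains,
#' altloc-resolved and occupancy-unweighted — the convention used for the
#' single "model B-factor" figure quoted in crystallographic tables. Set
#' \code{byChain = TRUE} to also get per-chain means (the table convention
#' is ambiguous between averaging chains and averaging atoms; both are
#' reported).
#'
#' @param s a [PDBStructure-class].
#' @param byChain logical.
#' @return numeric(1), or a list with \code{overall} and \code{perChain}.
#' @export
modelMeanB <- function(s, byChain = FALSE) {
  a <- .proteinAtoms(s@atoms)
  overall <- mean(a$b)
  if (!byChain) return(overall)
  list(overall = overall,
       perChain = tapply(a$b, a$chain, mean),
       meanOfChainMeans = mean(tapply(a$b, a$chain, mean)))
}
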