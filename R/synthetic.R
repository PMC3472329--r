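# generators with known ground truth: CA-trace chains, rigid + regional
# perturbations with painted B-factors and disorder masks, star-evolved
# alignments

# run expr with a private RNG stream so generator calls do not disturb (or
# depend on) the caller's random state
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Generate a synthetic CA-trace chain
#'
#' Cheap, deterministic protein-like geometry for pipeline tests:
#' \describe{
#'   \item{helix}{ideal alpha-helix parameters — 1.5 angstrom rise per
#'     residue, 2.3 angstrom radius, 100 degree twist (consecutive CA-CA
#'     distances ~3.8 angstrom).}
#'   \item{extended}{a beta-strand-like zigzag with 3.8 angstrom CA-CA
#'     steps.}
#'   \item{random-walk}{fixed 3.8 angstrom steps in uniformly random
#'     directions (seeded).}
#' }
#' Residue names cycle through the 20 standard amino acids so extracted
#' sequences are non-trivial; pass \code{sequence} to prescribe them.
#'
#' @param n number of residues (>= 1); ignored when \code{sequence} is
#'   given.
#' @param geometry "helix", "extended" or "random-walk".
#' @param seed integer seed (needed for random-walk determinism).
#' @param chainId chain identifier for the generated chain.
#' @param startResno author number of the first residue.
#' @param bfactor baseline B-factor painted on every atom.
#' @param sequence optional one-letter amino-acid string fixing the residue
#'   names (and n).
#' @return a [PDBStructure-class] with a single CA-only chain.
#' @export
makeChain <- function(n, geometry = c("helix", "extended", "random-walk"),
                      seed = NULL, chainId = "A", startResno = 1L,
                      bfactor = 20, sequence = NULL) {
  if (!is.null(sequence)) n <- nchar(sequence)
  if (n < 1) stop("n must be >= 1")
  geometry <- match.arg(geometry)
  i <- seq_len(n) - 1
  xyz <- switch(geometry,
    helix = cbind(2.3 * cos(i * 100 * pi / 180),
                  2.3 * sin(i * 100 * pi / 180),
                  1.5 * i),
    extended = cbind(3.68 * i, 0.95 * (i %% 2), 0),
    `random-walk` = .withSeed(seed, {
      steps <- matrix(stats::rnorm(3 * max(n - 1, 1)), ncol = 3)
      steps <- 3.8 * steps / sqrt(rowSums(steps^2))
      rbind(c(0, 0, 0),
            if (n > 1) apply(steps[seq_len(n - 1), , drop = FALSE],
                             2, cumsum))
    })
  )
  xyz <- matrix(xyz, ncol = 3)[seq_len(n), , drop = FALSE]
  aa1 <- if (is.null(sequence)) rep(.AA20, length.out = n)
         else strsplit(toupper(sequence), "")[[1]]
  aa3 <- bio3d::aa123(aa1)
  aa3[is.na(aa3) | aa3 == "NA"] <- "UNK"
  atoms <- data.frame(
    chain = chainId,
    resno = as.integer(startResno + i),
    icode = "",
    resname = aa3,
    atom = "CA",
    element = "C",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occupancy = 1,
    b = bfactor,
    altloc = "",
    het = FALSE,
    stringsAsFactors = FALSE
  )
  new("PDBStructure", id = paste0("synthetic-", geometry), atoms = atoms)
}

#' Specify a structure perturbation with known ground truth
#'
#' @param globalRotation list(axis = numeric(3), angle = degrees); default
#'   no rotation.
#' @param globalTranslation numeric(3), angstrom.
#' @param regionDisplacements list of \code{list(range = c(start, end),
#'   shift = numeric(3))}: residues in each (author-numbered, inclusive)
#'   range are rigidly displaced by \code{shift} after the global transform.
#'   Ranges must not overlap.
#' @param coordinateNoiseSd per-coordinate i.i.d. Gaussian noise, angstrom.
#' @param bfactorProfile list of \code{list(range, value)}: residues in each
#'   range get their B-factor set to \code{value} (angstrom^2).
#' @param missingRanges residue ranges deleted from the output (unmodeled /
#'   disordered segments); single numbers allowed.
#' @param seed integer seed for the noise stream.
#' @return a \code{PerturbationSpec} (list with class attribute).
#' @export
perturbationSpec <- function(globalRotation = list(axis = c(0, 0, 1),
                                                   angle = 0),
                             globalTranslation = c(0, 0, 0),
                             regionDisplacements = list(),
                             coordinateNoiseSd = 0,
                             bfactorProfile = list(),
                             missingRanges = NULL,
                             seed = NULL) {
  stopifnot(length(globalRotation$axis) == 3,
            length(globalRotation$angle) == 1,
            length(globalTranslation) == 3,
            coordinateNoiseSd >= 0)
  regs <- lapply(regionDisplacements, function(r) {
    list(range = .asRangeMatrix(r$range), shift = as.numeric(r$shift))
  })
  if (length(regs) > 1) {
    allr <- do.call(rbind, lapply(regs, `[[`, "range"))
    covered <- unlist(apply(allr, 1, function(z) seq(z[1], z[2]),
                            simplify = FALSE))
    if (anyDuplicated(covered))
      stop("region displacements must not overlap")
  }
  bprof <- lapply(bfactorProfile, function(r)
    list(range = .asRangeMatrix(r$range), value = as.numeric(r$value)))
  spec <- list(globalRotation = globalRotation,
               globalTranslation = as.numeric(globalTranslation),
               regionDisplacements = regs,
               coordinateNoiseSd = coordinateNoiseSd,
               bfactorProfile = bprof,
               missingRanges = .asRangeMatrix(missingRanges),
               seed = seed)
  class(spec) <- "PerturbationSpec"
  spec
}

# Rodrigues rotation matrix from axis + angle (degrees)
.rotationMatrix <- function(axis, angleDeg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angleDeg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Apply a perturbation to a structure
#'
#' Applies, in order: the global rigid transform, per-region rigid
#' displacements, i.i.d. Gaussian coordinate noise; then paints B-factors
#' and deletes the missing ranges. Noise is applied only to this (the
#' perturbed) member of a structure pair, so the expected CA r.m.s.d.
#' against the unperturbed original after refitting is
#' \eqn{\sigma\sqrt{3}} analytically.
#'
#' @param s a [PDBStructure-class].
#' @param spec a [perturbationSpec()].
#' @return list: \code{structure} (the perturbed copy) and
#'   \code{groundTruth}, a record of what was done — \code{rotation} (3x3
#'   matrix), \code{translation}, \code{regionDisplacements} (with the
#'   displacement magnitude per region), \code{noiseSd},
#'   \code{expectedNoiseRmsd} (= noiseSd * sqrt(3)),
#'   \code{bfactorProfile}, \code{missingSegments}.
#' @export
perturbStructure <- function(s, spec) {
  stopifnot(is(s, "PDBStructure"), inherits(spec, "PerturbationSpec"))
  a <- s@atoms
  R <- .rotationMatrix(spec$globalRotation$axis, spec$globalRotation$angle)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  xyz <- sweep(xyz %*% t(R), 2, spec$globalTranslation, "+")
  for (rd in spec$regionDisplacements) {
    hit <- .inRanges(a$resno, rd$range)
    xyz[hit, ] <- sweep(xyz[hit, , drop = FALSE], 2, rd$shift, "+")
  }
  if (spec$coordinateNoiseSd > 0) {
    noise <- .withSeed(spec$seed,
      matrix(stats::rnorm(length(xyz), sd = spec$coordinateNoiseSd),
             ncol = 3))
    xyz <- xyz + noise
  }
  a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
  for (bp in spec$bfactorProfile)
    a$b[.inRanges(a$resno, bp$range)] <- bp$value
  if (nrow(spec$missingRanges) > 0)
    a <- a[!.inRanges(a$resno, spec$missingRanges), , drop = FALSE]
  out <- new("PDBStructure", id = paste0(s@id, "-perturbed"), atoms = a,
             cell = s@cell, spacegroup = s@spacegroup,
             auPerCell = s@auPerCell)
  truth <- list(
    rotation = R,
    translation = spec$globalTranslation,
    regionDisplacements = lapply(spec$regionDisplacements, function(rd)
      c(rd, list(magnitude = sqrt(sum(rd$shift^2))))),
    noiseSd = spec$coordinateNoiseSd,
    expectedNoiseRmsd = spec$coordinateNoiseSd * sqrt(3),
    bfactorProfile = spec$bfactorProfile,
    missingSegments = spec$missingRanges
  )
  list(structure = out, groundTruth = truth)
}

#' Evolve a synthetic protein family on a star tree
#'
#' Draws a random ancestor over the 20 standard amino acids and derives each
#' sequence independently with per-site substitution probability q, where a
#' substitution replaces the letter uniformly over all 20. Two leaves are
#' then identical at a site with probability
#' \eqn{p(q) = (1 - 19q/20)^2 + 19 (q/20)^2}; q is chosen in closed form so
#' that p equals \code{targetIdentity}. Gaps are painted as deletion runs of
#' geometric length (mean 3) starting at rate \code{gapRate} per column, so
#' the alignment stays rectangular.
#'
#' @param length alignment length (columns).
#' @param nSeqs number of sequences.
#' @param targetIdentity expected pairwise identity, in (0.05, 1].
#' @param gapRate per-column probability of starting a deletion run in a
#'   given sequence.
#' @param seed integer seed.
#' @return list: \code{msa} (\code{AAStringSet}), \code{expectedIdentity},
#'   \code{substitutionProb}.
#' @export
evolveMSA <- function(length, nSeqs, targetIdentity, gapRate = 0,
                      seed = NULL) {
  if (targetIdentity <= 0.05 || targetIdentity > 1)
    stop("targetIdentity must lie in (0.05, 1]")
  if (gapRate < 0 || gapRate >= 1)
    stop("gapRate must lie in [0, 1)")
  # solve (1 - 19q/20)^2 + 19(q/20)^2 = t  =>  0.95 q^2 - 1.9 q + (1-t) = 0
  q <- (1.9 - sqrt(3.61 - 3.8 * (1 - targetIdentity))) / 1.9
  .withSeed(seed, {
    ancestor <- sample(.AA20, length, replace = TRUE)
    rows <- vapply(seq_len(nSeqs), function(i) {
      sub <- stats::runif(length) < q
      seqi <- ancestor
      seqi[sub] <- sample(.AA20, sum(sub), replace = TRUE)
      if (gapRate > 0) {
        starts <- which(stats::runif(length) < gapRate)
        for (st in starts) {
          len <- stats::rgeom(1, 1 / 3) + 1
          seqi[st:min(st + len - 1, length)] <- "-"
        }
      }
      paste(seqi, collapse = "")
    }, character(1))
    msa <- Biostrings::AAStringSet(rows)
    names(msa) <- sprintf("seq%03d", seq_len(nSeqs))
    list(msa = msa, expectedIdentity = targetIdentity, substitutionProb = q)
  })
}
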