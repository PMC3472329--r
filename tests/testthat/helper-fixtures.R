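# shared fixture builders; everything is generated in code

# random point cloud, reproducible
cloud <- function(n, seed, scale = 10) {
  set.seed(seed)
  matrix(rnorm(3 * n, sd = scale), ncol = 3)
}

# random proper rotation (QR of a Gaussian matrix, det fixed to +1)
randomRotation <- function() {
  qr <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

applyRigid <- function(x, R, t) sweep(x %*% t(R), 2, t, "+")

# rotation angle (degrees) between two rotation matrices
rotationAngle <- function(R1, R2) {
  tr <- sum(diag(crossprod(R1, R2)))
  acos(pmin(pmax((tr - 1) / 2, -1), 1)) * 180 / pi
}

# hand-written PDB fixture with altloc conflicts
altlocPdbFile <- function() {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00 10.00           N",
    "ATOM      2  CA AALA A   1      11.639   6.071  -5.147  0.60 11.00           C",
    "ATOM      3  CA BALA A   1      11.700   6.100  -5.200  0.40 12.00           C",
    "ATOM      4  CA  GLY A   2      12.000   7.000  -4.000  1.00 13.00           C",
    "TER", "END"), f)
  f
}

# numeric unit-cell volume oracle: build the three cell vectors explicitly
# and take |det| (vector triple product)
tripleProductVolume <- function(cell) {
  la <- cell[1]; lb <- cell[2]; lc <- cell[3]
  al <- cell[4] * pi / 180; be <- cell[5] * pi / 180; ga <- cell[6] * pi / 180
  va <- c(la, 0, 0)
  vb <- c(lb * cos(ga), lb * sin(ga), 0)
  cx <- lc * cos(be)
  cy <- lc * (cos(al) - cos(be) * cos(ga)) / sin(ga)
  cz2 <- lc^2 - cx^2 - cy^2
  if (cz2 <= 0) return(NA_real_)
  abs(det(rbind(va, vb, c(cx, cy, sqrt(cz2)))))
}

# tiny aligned-FASTA file
msaFile <- function(rows, ids = sprintf("s%d", seq_along(rows))) {
  f <- tempfile(fileext = ".fasta")
  writeLines(as.vector(rbind(paste0(">", ids), rows)), f)
  f
}
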