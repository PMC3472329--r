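#' Read a crystal structure from PDB or mmCIF
#'
#' Parses atom records via \pkg{bio3d} and returns a [PDBStructure-class]
#' with author residue numbering preserved. Alternate locations are resolved
#' to the highest-occupancy conformer (ties broken by file order). Waters and
#' heteroatoms are retained but flagged (column \code{het}; waters by residue
#' name HOH/WAT). For multi-model files only model 1 is used.
#'
#' The unit cell and space group are taken from the CRYST1 record (PDB) or
#' the \code{_cell.*} / \code{_symmetry.space_group_name_H-M} items (mmCIF)
#' when present; the space-group multiplicity is filled in from a small
#' built-in table of common groups (see [spacegroupMultiplicity()]).
#'
#' @param path file path.
#' @param format "pdb", "mmcif" or "auto" (by extension; .cif/.mmcif =
#'   mmCIF, anything else PDB).
#' @return a [PDBStructure-class].
#' @examples
#' s <- makeChain(5, geometry = "extended", seed = 1)
#' f <- tempfile(fileext = ".pdb")
#' writeStructure(s, f)
#' readStructure(f)
#' @export
readStructure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "pdb")
      bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
    else
      # read.cif warns about its own maturity and optional records;
      # parse failures still arrive as errors
      suppressWarnings(bio3d::read.cif(path, rm.alt = FALSE,
                                       verbose = FALSE)),
    error = function(e)
      stop("failed to parse ", path, " as ", format, ": ",
           conditionMessage(e), call. = FALSE)
  )
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0)
    stop("no atom records found in ", path)

  atoms <- data.frame(
    chain = ifelse(is.na(at$chain), "", as.character(at$chain)),
    resno = as.integer(at$resno),
    icode = ifelse(is.na(at$insert), "", as.character(at$insert)),
    resname = as.character(at$resid),
    atom = as.character(at$elety),
    element = ifelse(is.na(at$elesy), "", as.character(at$elesy)),
    x = as.numeric(at$x), y = as.numeric(at$y), z = as.numeric(at$z),
    occupancy = ifelse(is.na(at$o), 1, as.numeric(at$o)),
    b = ifelse(is.na(at$b), 0, as.numeric(at$b)),
    altloc = ifelse(is.na(at$alt), "", as.character(at$alt)),
    het = as.character(at$type) == "HETATM",
    stringsAsFactors = FALSE
  )
  atoms <- .resolveAltlocs(atoms)

  hdr <- .readCrystalHeader(path, format)
  new("PDBStructure",
      id = sub("\\.[^.]*$", "", basename(path)),
      atoms = atoms,
      cell = hdr$cell,
      spacegroup = hdr$spacegroup,
      auPerCell = hdr$auPerCell)
}

# keep, per (chain, resno, icode, atom name), the conformer with the highest
# occupancy; ties and the blank altloc resolve to first in file
.resolveAltlocs <- function(atoms) {
  if (nrow(atoms) == 0 || all(atoms$altloc == ""))
    return(atoms)
  key <- paste(atoms$chain, atoms$resno, atoms$icode, atoms$resname,
               atoms$atom, sep = "\r")
  ord <- order(key, -atoms$occupancy, seq_len(nrow(atoms)))
  keep <- ord[!duplicated(key[ord])]
  atoms[sort(keep), , drop = FALSE]
}

.readCrystalHeader <- function(path, format) {
  out <- list(cell = numeric(0), spacegroup = NA_character_,
              auPerCell = NA_integer_)
  lines <- readLines(path, warn = FALSE)
  if (format == "pdb") {
    cr <- grep("^CRYST1", lines, value = TRUE)
    if (length(cr) >= 1) {
      cr <- cr[1]
      cell <- suppressWarnings(as.numeric(c(
        substr(cr, 7, 15), substr(cr, 16, 24), substr(cr, 25, 33),
        substr(cr, 34, 40), substr(cr, 41, 47), substr(cr, 48, 54))))
      if (!any(is.na(cell)) && all(cell[1:3] > 0)) {
        # an all-90/1-1-1 dummy cell means "no crystal"
        if (!(all(cell[1:3] == 1) && all(cell[4:6] == 90))) {
          out$cell <- cell
          sg <- trimws(substr(cr, 56, 66))
          if (nzchar(sg)) out$spacegroup <- gsub(" ", "", sg)
        }
      }
    }
  } else {
    grab <- function(key) {
      ln <- grep(paste0("^", key, "\\s"), lines, value = TRUE)
      if (!length(ln)) return(NA)
      val <- trimws(sub(paste0("^", key, "\\s+"), "", ln[1]))
      gsub("^['\"]|['\"]$", "", val)
    }
    cell <- suppressWarnings(as.numeric(c(
      grab("_cell.length_a"), grab("_cell.length_b"), grab("_cell.length_c"),
      grab("_cell.angle_alpha"), grab("_cell.angle_beta"),
      grab("_cell.angle_gamma"))))
    if (!any(is.na(cell))) out$cell <- cell
    sg <- grab("_symmetry.space_group_name_H-M")
    if (!is.na(sg) && nzchar(sg)) out$spacegroup <- gsub(" ", "", sg)
  }
  if (!is.na(out$spacegroup)) {
    mult <- tryCatch(spacegroupMultiplicity(out$spacegroup),
                     error = function(e) NA_integer_)
    out$auPerCell <- mult
  }
  out
}

#' Write a structure in PDB format
#'
#' Emits standard fixed-width PDB records: CRYST1 (when a cell is present),
#' ATOM/HETATM, TER at chain ends, and END. Coordinates exceeding the fixed
#' column width (|x| >= 10000) are an error.
#'
#' @param s a [PDBStructure-class].
#' @param path output file path.
#' @param format only "pdb" is supported.
#' @return invisibly, \code{path}.
#' @export
writeStructure <- function(s, path, format = "pdb") {
  stopifnot(is(s, "PDBStructure"))
  format <- match.arg(format, "pdb")
  a <- s@atoms
  if (nrow(a) > 0) {
    if (any(!is.finite(c(a$x, a$y, a$z))))
      stop("coordinates must be finite")
    if (any(abs(c(a$x, a$y, a$z)) >= 10000))
      stop("coordinate overflows the fixed-width PDB field (|v| >= 10000)")
  }
  header <- character(0)
  if (length(s@cell) == 6) {
    sg <- if (is.na(s@spacegroup)) "P 1" else .formatSpacegroup(s@spacegroup)
    z <- if (is.na(s@auPerCell)) 1L else s@auPerCell
    header <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s%4d",
                      s@cell[1], s@cell[2], s@cell[3],
                      s@cell[4], s@cell[5], s@cell[6], sg, z)
  }
  if (nrow(a) == 0) {
    writeLines(c(header, "END"), path)
    return(invisible(path))
  }
  writeLines(header, path)
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    type = ifelse(a$het, "HETATM", "ATOM"),
    resno = a$resno,
    resid = a$resname,
    eleno = seq_len(nrow(a)),
    elety = a$atom,
    chain = ifelse(a$chain == "", " ", a$chain),
    insert = ifelse(a$icode == "", "", a$icode),
    alt = ifelse(a$altloc == "", "", a$altloc),
    o = a$occupancy,
    b = a$b,
    elesy = a$element,
    chainter = TRUE,
    end = TRUE,
    append = length(header) > 0
  )
  invisible(path)
}

.formatSpacegroup <- function(sg) {
  # "P41" -> "P 41" (PDB convention separates the lattice letter)
  if (grepl("^[A-Z][0-9-]", sg)) paste(substr(sg, 1, 1), substring(sg, 2))
  else sg
}

#' Construct an atom selection
#'
#' @param chainId chain identifier (single string).
#' @param include inclusive residue-number ranges to include: a
#'   \code{c(start, end)} pair, a list of such pairs (bare numbers allowed
#'   for single residues), or NULL for the whole chain.
#' @param exclude ranges to exclude, same shapes as \code{include}.
#' @param atomNames atom labels to keep; default CA only.
#' @return an [AtomSelection-class].
#' @examples
#' atomSelection("B", include = c(1, 272),
#'               exclude = list(1, c(140, 145), c(251, 272)))
#' @export
atomSelection <- function(chainId, include = NULL, exclude = NULL,
                          atomNames = "CA") {
  new("AtomSelection",
      chainId = as.character(chainId),
      includeRanges = .asRangeMatrix(include),
      excludeRanges = .asRangeMatrix(exclude),
      atomNames = atomNames)
}

#' Select atoms by chain, residue ranges and atom names
#'
#' Applies an [AtomSelection-class] to a structure and returns the matching
#' atoms ordered by residue number then insertion code. A residue is selected
#' iff it lies in some include range (or the include set is empty) and in no
#' exclude range; of its atoms only those named in \code{atomNames} are
#' returned. Residues that are selected but carry none of the requested atom
#' names are skipped silently; their count is reported in the
#' \code{nSkippedResidues} attribute. Waters (HOH/WAT) are excluded unless
#' \code{includeWaters = TRUE}. The atom name \code{"*"} matches every atom.
#'
#' @param s a [PDBStructure-class].
#' @param sel an [AtomSelection-class].
#' @param includeWaters logical.
#' @return data.frame of atom rows (same columns as the structure's atom
#'   table) with attributes \code{nResidues} (residues contributing atoms)
#'   and \code{nSkippedResidues}.
#' @export
selectAtoms <- function(s, sel, includeWaters = FALSE) {
  stopifnot(is(s, "PDBStructure"), is(sel, "AtomSelection"))
  a <- s@atoms
  if (!(sel@chainId %in% a$chain))
    stop("unknown chain id: ", sel@chainId)
  a <- a[a$chain == sel@chainId, , drop = FALSE]
  if (!includeWaters)
    a <- a[!(a$resname %in% c("HOH", "WAT")), , drop = FALSE]
  inInc <- if (nrow(sel@includeRanges) == 0) rep(TRUE, nrow(a))
           else .inRanges(a$resno, sel@includeRanges)
  inExc <- .inRanges(a$resno, sel@excludeRanges)
  selres <- a[inInc & !inExc, , drop = FALSE]
  hit <- if ("*" %in% sel@atomNames) selres
         else selres[selres$atom %in% sel@atomNames, , drop = FALSE]
  ord <- order(hit$resno, hit$icode)
  hit <- hit[ord, , drop = FALSE]
  resKey <- function(d) unique(paste(d$resno, d$icode, sep = "\r"))
  nSelRes <- length(resKey(selres))
  nHitRes <- length(resKey(hit))
  attr(hit, "nResidues") <- nHitRes
  attr(hit, "nSkippedResidues") <- nSelRes - nHitRes
  hit
}
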