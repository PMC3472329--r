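# report assembly: the three analyses (structure comparison, flexibility,
# conservation) wired together behind a validated run configuration, with
# stable TSV/JSON outputs

#' Read and validate a run configuration
#'
#' YAML schema (all residue ranges are author-numbered, inclusive):
#' \preformatted{
#' structures:
#'   a: path/to/first.pdb
#'   b: path/to/second.pdb
#' pairings:            # chains compared, in order
#'   - [A, A]
#'   - [B, B]
#' selections:          # named; each side optional
#'   beta_no_tentacle:
#'     a: {chain: B, include: [[1, 250]]}
#'     b: {chain: B, include: [[1, 250]]}
#' fit: beta_no_tentacle        # optional, per pairing or global
#' report: [beta_no_tentacle]   # optional list of selection names
#' b_mode: CA                   # CA | all
#' disorder:                    # optional expected ranges per chain
#'   - {chain: B, expected: [1, 272]}
#' seed: 1
#' outdir: results/
#' }
#'
#' Referenced chains and selections are resolved before any computation
#' starts (fail fast).
#'
#' @param path YAML file.
#' @return validated config list.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  .validateConfig(cfg, dirname(path))
}

.validateConfig <- function(cfg, base = ".") {
  if (is.null(cfg$structures) || length(cfg$structures) < 1)
    stop("config must name at least one structure")
  cfg$structures <- lapply(cfg$structures, function(p) {
    p2 <- if (file.exists(p)) p else file.path(base, p)
    if (!file.exists(p2)) stop("structure file not found: ", p)
    p2
  })
  cfg$b_mode <- match.arg(cfg$b_mode %||% "CA", c("CA", "all"))
  cfg$outdir <- cfg$outdir %||% "."
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.selFromConfig <- function(node) {
  if (is.null(node)) return(NULL)
  atomSelection(node$chain,
                include = node$include,
                exclude = node$exclude,
                atomNames = node$atoms %||% "CA")
}

.selPairFromConfig <- function(node, structures) {
  pair <- list(a = .selFromConfig(node$a), b = .selFromConfig(node$b))
  for (side in c("a", "b")) {
    sel <- pair[[side]]
    if (!is.null(sel) && !(sel@chainId %in% chainIds(structures[[side]])))
      stop("selection references unknown chain '", sel@chainId,
           "' in structure ", side)
  }
  pair
}

#' Run the structure-comparison analysis
#'
#' For each configured chain pairing: builds the residue correspondence,
#' superposes with the configured fit selection, and writes the transform
#' (JSON), global and per-region r.m.s.d. (TSV), the per-residue deviation
#' profile (TSV), per-region B statistics (TSV) and disorder reports
#' (JSON) into the output directory. Atom counts are logged alongside every
#' r.m.s.d. Outputs use fixed float formatting (r.m.s.d. 2 decimals, B 1
#' decimal), so re-running an identical config is byte-identical.
#'
#' @param config path to a YAML config or a config list (see
#'   [readRunConfig()]).
#' @param quiet suppress progress messages.
#' @return invisibly, a list with per-pairing results (residue map,
#'   superposition, regions, disorder reports) and the output paths.
#' @export
runCompare <- function(config, quiet = FALSE) {
  cfg <- if (is.character(config)) readRunConfig(config)
         else .validateConfig(config)
  if (length(cfg$structures) < 2 || is.null(cfg$pairings))
    stop("compare needs two structures and at least one chain pairing")
  say <- function(...) if (!quiet) message(...)
  sA <- readStructure(cfg$structures[[1]])
  sB <- readStructure(cfg$structures[[2]])
  structures <- list(a = sA, b = sB)
  for (p in cfg$pairings) {
    if (!(p[[1]] %in% chainIds(sA)) || !(p[[2]] %in% chainIds(sB)))
      stop("pairing references unknown chain: ", p[[1]], "/", p[[2]])
  }
  selPairs <- lapply(cfg$selections %||% list(), .selPairFromConfig,
                     structures = structures)
  for (nm in c(cfg$fit, unlist(cfg$report)))
    if (!is.null(nm) && !nm %in% names(selPairs))
      stop("config references undefined selection '", nm, "'")
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)

  out <- list()
  regionRows <- NULL
  profileRows <- NULL
  disorder <- list()
  for (p in cfg$pairings) {
    label <- paste0(p[[1]], ":", p[[2]])
    map <- buildResidueMap(sA, p[[1]], sB, p[[2]])
    say("pairing ", label, ": ", nPairs(map), " mapped residues")
    fitSel <- if (!is.null(cfg$fit)) selPairs[[cfg$fit]] else NULL
    reps <- selPairs[unlist(cfg$report) %||% character(0)]
    sup <- superposeMapped(sA, sB, map, fitSel = fitSel, reportSels = reps)
    say("  fit: r.m.s.d. ", sprintf("%.2f", rmsd(sup$result)), " A over ",
        nAtoms(sup$result), " CA atoms")
    regionRows <- rbind(regionRows,
      data.frame(pairing = label, region = "fit",
                 n_atoms = nAtoms(sup$result), rmsd = rmsd(sup$result)),
      if (nrow(sup$regions) > 0)
        cbind(pairing = label, sup$regions))
    profileRows <- rbind(profileRows, cbind(pairing = label, sup$profile))
    jsonlite::write_json(
      list(pairing = label,
           rotation = as.vector(t(rotation(sup$result))),
           translation = translation(sup$result),
           rmsd = rmsd(sup$result), n_atoms = nAtoms(sup$result)),
      file.path(cfg$outdir, paste0("transform_", p[[1]], "_", p[[2]],
                                   ".json")),
      auto_unbox = TRUE, digits = NA)
    out[[label]] <- list(map = map, superposition = sup)
  }
  for (d in cfg$disorder %||% list()) {
    side <- d$structure %||% "a"
    rep <- detectDisorder(structures[[side]], d$chain,
                          as.integer(d$expected))
    disorder[[paste0(side, ":", d$chain)]] <- list(
      chain = rep@chainId, expected = rep@expectedRange,
      missing_segments = lapply(seq_len(nrow(missingSegments(rep))),
        function(i) list(start = missingSegments(rep)[i, 1],
                         end = missingSegments(rep)[i, 2])),
      n_modeled = rep@nModeled, n_missing = rep@nMissing)
  }
  if (length(disorder))
    jsonlite::write_json(disorder, file.path(cfg$outdir, "disorder.json"),
                         auto_unbox = TRUE, digits = NA)

  regionRows$rmsd <- sprintf("%.2f", regionRows$rmsd)
  utils::write.table(regionRows, file.path(cfg$outdir, "rmsd_regions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  profileRows$deviation <- sprintf("%.2f", profileRows$deviation)
  utils::write.table(profileRows, file.path(cfg$outdir, "profile.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  bRows <- NULL
  for (nm in names(selPairs)) {
    for (side in c("a", "b")) {
      sel <- selPairs[[nm]][[side]]
      if (is.null(sel)) next
      st <- regionBStats(structures[[side]], sel, mode = cfg$b_mode,
                         label = paste0(nm, ":", side))
      bRows <- rbind(bRows, st)
    }
  }
  if (!is.null(bRows)) {
    for (col in c("mean_b", "sd_b")) bRows[[col]] <- sprintf("%.1f",
                                                             bRows[[col]])
    bRows$z_mean_b <- sprintf("%.2f", bRows$z_mean_b)
    utils::write.table(bRows, file.path(cfg$outdir, "bstats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(list(pairings = out, disorder = disorder, outdir = cfg$outdir))
}

#' Run the sequence-conservation analysis
#'
#' For each aligned-FASTA family: gap-fraction column filtering, the
#' pairwise identity matrix (TSV, identities to 3 decimals), its
#' distribution summary (JSON: integer-percent histogram, five-number
#' summary, median), and per-column conservation / logo data (TSV). With
#' two or more families the medians are compared and the conservation
#' ranking is reported.
#'
#' @param fastaFiles named character vector of aligned-FASTA paths (names =
#'   family labels).
#' @param outdir output directory.
#' @param maxGapFraction column filter threshold (see [filterColumns()]);
#'   NULL skips filtering.
#' @param quiet suppress progress messages.
#' @return invisibly, list with per-family summaries and (when >= 2
#'   families) \code{ranking}, family labels ordered by decreasing median
#'   identity.
#' @export
runSeqid <- function(fastaFiles, outdir = ".", maxGapFraction = 0.5,
                     quiet = FALSE) {
  if (length(fastaFiles) == 0) stop("no alignment files given")
  if (is.null(names(fastaFiles)))
    names(fastaFiles) <- sub("\\.[^.]*$", "", basename(fastaFiles))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  fam <- list()
  for (nm in names(fastaFiles)) {
    msa <- readMSA(fastaFiles[[nm]])
    kept <- seq_len(Biostrings::width(msa)[1])
    if (!is.null(maxGapFraction)) {
      fl <- filterColumns(msa, maxGapFraction)
      msa <- fl$msa
      kept <- fl$keptColumns
    }
    im <- identityMatrix(msa)
    ds <- distributionSummary(im)
    say("family ", nm, ": ", length(im@ids), " sequences, median identity ",
        sprintf("%.3f", ds$median))
    v <- identityValues(im)
    utils::write.table(format(round(v, 3), nsmall = 3),
                       file.path(outdir, paste0("identity_", nm, ".tsv")),
                       sep = "\t", quote = FALSE)
    jsonlite::write_json(
      list(family = nm, n_sequences = length(im@ids), n_pairs = ds$nPairs,
           median = ds$median, five_number = as.list(ds$fiveNumber),
           histogram = as.list(ds$histogram)),
      file.path(outdir, paste0("summary_", nm, ".json")),
      auto_unbox = TRUE, digits = NA)
    lc <- columnConservation(msa)
    logo <- data.frame(column = kept[lc$column],
                       ic_bits = sprintf("%.3f", lc$ic),
                       non_gap = sprintf("%.3f", lc$nonGapFraction),
                       round(lc$frequencies, 4))
    utils::write.table(logo, file.path(outdir, paste0("logo_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    fam[[nm]] <- ds
  }
  res <- list(families = fam, outdir = outdir)
  if (length(fam) >= 2) {
    med <- vapply(fam, `[[`, numeric(1), "median")
    res$medians <- med
    res$ranking <- names(sort(med, decreasing = TRUE))
    say("conservation ranking (most conserved first): ",
        paste(res$ranking, collapse = " > "))
    jsonlite::write_json(list(medians = as.list(med), ranking = res$ranking),
                         file.path(outdir, "median_comparison.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(res)
}
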