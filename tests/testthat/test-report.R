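# end-to-end report assembly on generator fixtures

makeComparePair <- function(dir) {
  s <- makeChain(120, "random-walk", seed = 41, bfactor = 24)
  s@atoms$b <- 24 + (seq_len(120) %% 7)   # non-degenerate B distribution
  pert <- perturbStructure(s, perturbationSpec(
    globalRotation = list(axis = c(1, 0, 2), angle = 30),
    globalTranslation = c(2, -1, 4),
    regionDisplacements = list(list(range = c(60, 75),
                                    shift = c(3, 0, 0))),
    bfactorProfile = list(list(range = c(60, 75), value = 84)),
    missingRanges = list(1, c(100, 105))))
  fA <- file.path(dir, "a.pdb"); writeStructure(s, fA)
  fB <- file.path(dir, "b.pdb"); writeStructure(pert$structure, fB)
  cfg <- list(
    structures = list(a = fA, b = fB),
    pairings = list(c("A", "A")),
    selections = list(
      rigid = list(a = list(chain = "A", exclude = list(c(60, 75))),
                   b = list(chain = "A", exclude = list(c(60, 75)))),
      displaced = list(a = list(chain = "A", include = list(c(60, 75))),
                       b = list(chain = "A", include = list(c(60, 75))))),
    fit = "rigid",
    report = list("displaced", "rigid"),
    b_mode = "CA",
    disorder = list(list(structure = "b", chain = "A",
                         expected = c(1, 120))),
    outdir = file.path(dir, "out"))
  list(cfg = cfg, truth = pert$groundTruth)
}

test_that("runCompare emits the full report bundle matching ground truth", {
  dir <- withr::local_tempdir()
  fx <- makeComparePair(dir)
  res <- runCompare(fx$cfg, quiet = TRUE)
  out <- fx$cfg$outdir

  expect_true(file.exists(file.path(out, "rmsd_regions.tsv")))
  expect_true(file.exists(file.path(out, "profile.tsv")))
  expect_true(file.exists(file.path(out, "bstats.tsv")))
  expect_true(file.exists(file.path(out, "disorder.json")))
  expect_true(file.exists(file.path(out, "transform_A_A.json")))

  reg <- read.delim(file.path(out, "rmsd_regions.tsv"))
  expect_equal(reg$rmsd[reg$region == "displaced"], 3, tolerance = 0.01)
  expect_lt(reg$rmsd[reg$region == "fit"], 0.01)

  dis <- jsonlite::read_json(file.path(out, "disorder.json"))[["b:A"]]
  expect_identical(dis$n_modeled, 113L)
  segs <- vapply(dis$missing_segments, function(z)
    c(z$start, z$end), numeric(2))
  expect_equal(unname(segs), rbind(c(1, 100), c(1, 105)))

  tr <- jsonlite::read_json(file.path(out, "transform_A_A.json"),
                            simplifyVector = TRUE)
  R <- matrix(tr$rotation, 3, 3, byrow = TRUE)
  expect_lt(max(abs(R - fx$truth$rotation)), 1e-4)

  b <- read.delim(file.path(out, "bstats.tsv"))
  expect_equal(b$mean_b[b$region == "displaced:b"], 84, tolerance = 1e-6)
})

test_that("re-running an identical config is byte-identical", {
  dir <- withr::local_tempdir()
  fx <- makeComparePair(dir)
  runCompare(fx$cfg, quiet = TRUE)
  first <- lapply(list.files(fx$cfg$outdir, full.names = TRUE), readLines)
  runCompare(fx$cfg, quiet = TRUE)
  second <- lapply(list.files(fx$cfg$outdir, full.names = TRUE), readLines)
  expect_identical(first, second)
})

test_that("self-comparison gives zero rmsd and identical disorder", {
  dir <- withr::local_tempdir()
  s <- makeChain(50, "helix")
  f <- file.path(dir, "s.pdb"); writeStructure(s, f)
  cfg <- list(structures = list(a = f, b = f),
              pairings = list(c("A", "A")),
              disorder = list(
                list(structure = "a", chain = "A", expected = c(1, 50)),
                list(structure = "b", chain = "A", expected = c(1, 50))),
              outdir = file.path(dir, "out"))
  res <- runCompare(cfg, quiet = TRUE)
  expect_lt(rmsd(res$pairings[["A:A"]]$superposition$result), 1e-6)
  expect_identical(res$disorder[["a:A"]]$n_modeled,
                   res$disorder[["b:A"]]$n_modeled)
})

test_that("config errors fail fast before computation", {
  dir <- withr::local_tempdir()
  s <- makeChain(10)
  f <- file.path(dir, "s.pdb"); writeStructure(s, f)
  cfg <- list(structures = list(a = f, b = f),
              pairings = list(c("A", "Z")),
              outdir = dir)
  expect_error(runCompare(cfg, quiet = TRUE), "unknown chain")
  cfg2 <- list(structures = list(a = f, b = f),
               pairings = list(c("A", "A")),
               fit = "nope", outdir = dir)
  expect_error(runCompare(cfg2, quiet = TRUE), "undefined selection")
  cfg3 <- list(structures = list(a = "missing.pdb", b = f))
  expect_error(runCompare(cfg3, quiet = TRUE), "not found")
})

test_that("YAML round trip of the run configuration", {
  dir <- withr::local_tempdir()
  fx <- makeComparePair(dir)
  yml <- file.path(dir, "run.yaml")
  yaml::write_yaml(fx$cfg, yml)
  cfg <- readRunConfig(yml)
  expect_identical(cfg$fit, "rigid")
  res <- runCompare(cfg, quiet = TRUE)
  expect_s4_class(res$pairings[["A:A"]]$superposition$result,
                  "SuperpositionResult")
})

test_that("runSeqid reports per-family summaries and the median ordering", {
  dir <- withr::local_tempdir()
  lo <- evolveMSA(200, 30, targetIdentity = 0.4, seed = 61)
  hi <- evolveMSA(200, 30, targetIdentity = 0.7, seed = 62)
  fLo <- file.path(dir, "alpha.fasta")
  fHi <- file.path(dir, "beta.fasta")
  Biostrings::writeXStringSet(lo$msa, fLo)
  Biostrings::writeXStringSet(hi$msa, fHi)
  res <- runSeqid(c(alpha = fLo, beta = fHi), outdir = file.path(dir, "o"),
                  quiet = TRUE)
  expect_identical(res$ranking, c("beta", "alpha"))
  expect_true(file.exists(file.path(dir, "o", "identity_alpha.tsv")))
  expect_true(file.exists(file.path(dir, "o", "summary_beta.json")))
  expect_true(file.exists(file.path(dir, "o", "logo_alpha.tsv")))
  expect_true(file.exists(file.path(dir, "o", "median_comparison.json")))
  sm <- jsonlite::read_json(file.path(dir, "o", "summary_beta.json"))
  expect_equal(sm$median, res$families$beta$median, tolerance = 1e-12)
  expect_equal(sum(unlist(sm$histogram)), 100, tolerance = 1e-9)

  # ragged input names the offending sequence
  bad <- msaFile(c("ACD", "ACDE"), ids = c("ok", "bad"))
  expect_error(runSeqid(c(x = bad)), "bad")
  # empty file errors
  empty <- tempfile(fileext = ".fasta"); file.create(empty)
  expect_error(runSeqid(c(x = empty)), "no sequences|read")
})
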