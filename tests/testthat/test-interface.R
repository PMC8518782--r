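test_that("build_hmm_library writes profiles that re-parse losslessly", {
  tmp <- withr::local_tempdir()
  fam <- evolve_family(family_spec("famA", 60, 6, 0.05), seed = 13)
  aln_dir <- file.path(tmp, "aln"); dir.create(aln_dir)
  Biostrings::writeXStringSet(Biostrings::AAStringSet(fam$members),
                              file.path(aln_dir, "famA.faa"))
  paths <- build_hmm_library(aln_dir, file.path(tmp, "hmms"))
  expect_named(paths, "famA")
  h <- parse_hmm3(paths[["famA"]])[[1]]
  expect_equal(h$name, "famA")
  direct <- build_from_alignment(fam$members, name = "famA")
  expect_lt(hmm_param_diff(h, direct), 1e-6)
  expect_error(build_hmm_library(character(0), tmp), "no seed alignments")
})

test_that("calibrate_hmms produces the specified report columns", {
  tmp <- withr::local_tempdir()
  fam <- evolve_family(family_spec("famB", 60, 8, 0.05), seed = 17)
  dec <- evolve_family(family_spec("decB", 60, 8, 0.05, role = "decoy",
                                   shared_fraction = 0.4),
                       seed = 17, base_root = fam$root)
  Biostrings::writeXStringSet(Biostrings::AAStringSet(fam$members),
                              file.path(tmp, "tp.faa"))
  Biostrings::writeXStringSet(Biostrings::AAStringSet(dec$members),
                              file.path(tmp, "fp.faa"))
  write_hmm3(build_from_alignment(fam$members, name = "famB"),
             file.path(tmp, "famB.hmm"))
  rep_path <- file.path(tmp, "report.tsv")
  rep <- calibrate_hmms(file.path(tmp, "famB.hmm"),
                        tp_fastas = c(famB = file.path(tmp, "tp.faa")),
                        fp_fastas = c(famB = file.path(tmp, "fp.faa")),
                        out_file = rep_path)
  expect_equal(names(rep), c("hmm_name", "trusted", "noise", "gathering",
                             "separable", "n_tp", "n_fp"))
  expect_true(rep$separable)
  expect_equal(rep$n_tp, 8)
  expect_equal(rep$n_fp, 8)
  expect_true(file.exists(rep_path))
  expect_error(
    calibrate_hmms(file.path(tmp, "famB.hmm"),
                   tp_fastas = c(famB = file.path(tmp, "absent.faa"))),
    "TP file not found")
})

## one small end-to-end run shared by the remaining blocks
small <- NULL
small_dir <- file.path(tempdir(), "markerscan-small-demo")
get_small <- function() {
  if (is.null(small)) {
    unlink(small_dir, recursive = TRUE)
    small <<- tiny_demo(small_dir, seed = 42)
  }
  small
}

test_that("the pipeline recovers the planted truth on a small dataset", {
  res <- get_small()
  expect_equal(attr(res$comparison, "precision"), 1)
  expect_equal(attr(res$comparison, "recall"), 1)
  scan_dir <- file.path(small_dir, "scan")
  expect_true(all(file.exists(file.path(scan_dir,
    c("hits.tsv", "inventory_table.tsv", "category_scores.tsv",
      "manifest.txt", "inventory_PM_05.tsv")))))
  ## manifest echoes the run configuration
  mf <- readLines(file.path(scan_dir, "manifest.txt"))
  expect_true(any(grepl("^min_aa_len = 30", mf)))
  expect_true(any(grepl("^seed = 42", mf)))
  expect_true(any(grepl("^contigs_md5 = ", mf)))
})

test_that("category scores aggregate the inventory by process", {
  res <- get_small()
  cs <- res$scan$category_scores
  inventory <- res$scan$inventory
  for (cat in setdiff(names(cs), "sample_id")) {
    expect_equal(sum(cs[[cat]]),
                 sum(inventory$transcript_copies[inventory$category == cat]))
  }
})

test_that("rescanning with identical inputs is byte-identical", {
  res <- get_small()
  ds <- res$data
  out2 <- file.path(small_dir, "scan2")
  run_scan(contig_fastas = ds$paths$contigs,
           registry = file.path(small_dir, "registry.tsv"),
           hmm_dir = file.path(small_dir, "hmms"),
           metadata = ds$paths$metadata,
           lineage_map = ds$paths$lineage_map,
           calibration = res$calibration,
           out_dir = out2, seed = 42)
  m1 <- dir_md5(file.path(small_dir, "scan"))
  m2 <- dir_md5(out2)
  expect_identical(unname(m1), unname(m2))
})

test_that("an empty contig file yields empty outputs with a warning", {
  res <- get_small()
  tmp <- withr::local_tempdir()
  empty_fa <- file.path(tmp, "empty.fasta")
  writeLines(character(0), empty_fa)
  md <- data.frame(sample_id = "E0", site = "X", depth_mbsf = 1,
                   sulfate_status = "present", stringsAsFactors = FALSE)
  expect_warning(
    out <- run_scan(contig_fastas = c(E0 = empty_fa),
                    registry = file.path(small_dir, "registry.tsv"),
                    hmm_dir = file.path(small_dir, "hmms"),
                    metadata = md, calibration = res$calibration,
                    out_dir = file.path(tmp, "out")),
    "no ORFs")
  expect_equal(nrow(out$inventory), 0)
  expect_true(file.exists(file.path(tmp, "out", "inventory_table.tsv")))
})

test_that("the command-line interface runs and uses documented exit codes", {
  cli <- system.file("scripts", "markerscan", package = "markerscan")
  skip_if(cli == "", "CLI script not installed")
  rscript <- file.path(R.home("bin"), "Rscript")
  tmp <- withr::local_tempdir()
  ## unknown subcommand and empty build-hmm directory are usage errors
  expect_equal(system2(rscript, c(cli, "frobnicate"),
                       stdout = FALSE, stderr = FALSE), 2)
  dir.create(file.path(tmp, "noaln"))
  expect_equal(system2(rscript,
                       c(cli, "build-hmm", "--alignments",
                         file.path(tmp, "noaln"), "--out", tmp),
                       stdout = FALSE, stderr = FALSE), 2)
  ## synth is deterministic across invocations
  s1 <- file.path(tmp, "s1"); s2 <- file.path(tmp, "s2")
  for (d in c(s1, s2))
    expect_equal(system2(rscript,
                         c(cli, "synth", "--out", d, "--seed", "7",
                           "--n-decoy-orfs", "1", "--n-random-contigs", "2"),
                         stdout = FALSE, stderr = FALSE), 0)
  expect_identical(unname(dir_md5(s1)), unname(dir_md5(s2)))
})
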