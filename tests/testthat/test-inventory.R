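test_that("count_variants dereplicates exact duplicates and substrings", {
  expect_equal(count_variants(rep("MKLV", 3))$n_variants, 1)
  expect_equal(count_variants(c("MKLVA", "MKLVC"))$n_variants, 2)
  # a fragment contained in a longer variant is not a new variant
  expect_equal(count_variants(c("ACDEFGHIKL", "DEFGH"))$n_variants, 1)
  expect_error(count_variants(character(0)), "at least one")
  expect_error(count_variants("A", identity_threshold = 0), "identity_threshold")
})

test_that("variant clustering respects the identity threshold", {
  fam <- evolve_family(family_spec("v", root_length = 300, n_members = 5,
                                   substitution_rate = 0.05), seed = 99)
  seqs <- unname(fam$members)
  ids <- combn(5, 2, function(p) pair_identity(seqs[p[1]], seqs[p[2]]))
  ## all-pairs identity verifies the expected outcome at both thresholds
  expect_true(all(ids < 0.97) && all(ids > 0.85))
  expect_equal(count_variants(seqs, identity_threshold = 0.97)$n_variants, 5)
  expect_equal(count_variants(seqs, identity_threshold = 0.85)$n_variants, 1)
})

test_that("pair_identity slides the shorter sequence over the longer", {
  expect_equal(pair_identity("ACD", "ACD"), 1)
  expect_equal(pair_identity("CDE", "ACDEF"), 1)      # internal exact match
  expect_equal(pair_identity("AAA", "CCCCC"), 0)
  expect_equal(pair_identity("ACD", "ACE"), 2 / 3)
})

make_inventory <- function(rows, meta = sample_meta("s1", "X", 10, "present")) {
  structure(list(meta = meta, rows = rows), class = "SampleInventory")
}

inv_rows <- function(...) {
  m <- matrix(c(...), ncol = 4, byrow = TRUE)
  data.frame(lineage = m[, 1], gene_symbol = m[, 2], category = m[, 3],
             variant_count = as.integer(m[, 4]),
             orf_ids = "", stringsAsFactors = FALSE)
}

test_that("category scores sum variant counts and normalize to proportions", {
  inv <- make_inventory(inv_rows("Chloroflexi", "sdo", "sulfur_oxidation", 2,
                                 "Chloroflexi", "sqr", "sulfur_oxidation", 1,
                                 "Firmicutes", "katG", "catalase", 1))
  cs <- category_scores(list(inv))
  expect_equal(cs$sulfur_oxidation, 3)
  expect_equal(cs$catalase, 1)
  csn <- category_scores(list(inv), normalize = TRUE)
  expect_equal(sum(csn[, -1]), 1, tolerance = 1e-9)
  ## empty inventory: an all-zero row
  empty <- data.frame(lineage = character(), gene_symbol = character(),
                      category = character(), variant_count = integer(),
                      orf_ids = character(), stringsAsFactors = FALSE)
  cs0 <- category_scores(list(make_inventory(empty)),
                         categories = c("catalase", "sulfur_oxidation"))
  expect_equal(unlist(cs0[, -1], use.names = FALSE), c(0, 0))
})

test_that("the inventory export is sorted by site, depth, lineage, gene", {
  a <- make_inventory(inv_rows("Chloroflexi", "sdo", "sulfur_oxidation", 1),
                      sample_meta("s42", "SITE", 42, "depleted"))
  b <- make_inventory(inv_rows("Firmicutes", "katG", "catalase", 2,
                               "Chloroflexi", "sqr", "sulfur_oxidation", 1),
                      sample_meta("s12", "SITE", 12, "present"))
  tab <- export_inventory_table(list(a, b))
  expect_equal(names(tab), c("site", "depth_mbsf", "sulfate_status",
                             "lineage", "gene_symbol", "category",
                             "transcript_copies"))
  expect_equal(tab$depth_mbsf, c(12, 12, 42))
  expect_equal(tab$lineage[1:2], c("Chloroflexi", "Firmicutes"))
  ## conservation
  expect_equal(sum(tab$transcript_copies),
               sum(a$rows$variant_count) + sum(b$rows$variant_count))
  ## single-row inventory: header + one data row
  tmp <- withr::local_tempfile()
  export_inventory_table(list(a), path = tmp)
  expect_length(readLines(tmp), 2)
})

scored_fixture <- function() {
  reg <- data.frame(
    gene_symbol = c("katG", "decoyX"),
    category = c("catalase", "decoy"),
    hmm_name = c("katG_hmm", "decoyX_hmm"),
    role = c("target", "decoy"),
    gathering = c(40, NA), stringsAsFactors = FALSE)
  orfs <- data.frame(
    orf_id = c("c1.o1", "c2.o1", "c3.o1"), contig_id = c("c1", "c2", "c3"),
    sample_id = "s1", strand = "+", frame = 0L,
    nt_start = 0L, nt_end = 30L,
    aa_seq = c("MKKKKKKKVV", "MKKKKKKKVA", "MLLLLLLLVV"),
    stringsAsFactors = FALSE)
  scores <- matrix(c(80, 75, 20,     # katG_hmm
                     10, 10, 60),    # decoyX_hmm
                   nrow = 3, dimnames = list(orfs$orf_id,
                                             c("katG_hmm", "decoyX_hmm")))
  list(reg = reg, orfs = orfs, scores = scores)
}

test_that("build_inventory screens, groups by lineage and counts variants", {
  f <- scored_fixture()
  meta <- sample_meta("s1", "SITE", 3, "present")
  lmap <- data.frame(id = c("c1", "c2"), lineage = "Firmicutes",
                     stringsAsFactors = FALSE)
  inv <- build_inventory(f$orfs, f$scores, f$reg, meta, lineage_map = lmap)
  expect_s3_class(inv, "SampleInventory")
  expect_equal(nrow(inv$rows), 1)    # c3 won by the decoy; c1+c2 = 2 variants
  expect_equal(inv$rows$lineage, "Firmicutes")
  expect_equal(inv$rows$variant_count, 2)
  expect_equal(inv$rows$category, "catalase")
  expect_equal(inv$rows$orf_ids, "c1.o1,c2.o1")
})

test_that("unmapped ORFs fall back to 'unclassified' and empty screens yield zero rows", {
  f <- scored_fixture()
  meta <- sample_meta("s1", "SITE", 3, "present")
  inv <- build_inventory(f$orfs, f$scores, f$reg, meta, lineage_map = NULL)
  expect_equal(inv$rows$lineage, "unclassified")
  low <- f$scores; low[, "katG_hmm"] <- 5
  inv0 <- build_inventory(f$orfs, low, f$reg, meta)
  expect_equal(nrow(inv0$rows), 0)
  bad <- f$orfs; bad$sample_id <- "other"
  expect_error(build_inventory(bad, f$scores, f$reg, meta),
               "sample_id mismatch")
})

test_that("adding a decoy HMM never increases accepted counts", {
  f <- scored_fixture()
  meta <- sample_meta("s1", "SITE", 3, "present")
  no_decoy <- f$reg[f$reg$role == "target", ]
  inv_with <- build_inventory(f$orfs, f$scores, f$reg, meta)
  inv_without <- build_inventory(f$orfs,
                                 f$scores[, "katG_hmm", drop = FALSE],
                                 no_decoy, meta)
  expect_lte(sum(inv_with$rows$variant_count),
             sum(inv_without$rows$variant_count))
})

test_that("load_registry validates the category vocabulary", {
  tmp <- withr::local_tempdir()
  h <- random_profile_hmm(M = 2, seed = 1)
  h$name <- "g1"
  h$cutoffs <- cutoff_pair(10, -Inf, 10, TRUE)
  write_hmm3(h, file.path(tmp, "g1.hmm"))
  reg <- data.frame(gene_symbol = "g1", category = "unobtainium",
                    hmm_file = "g1.hmm", role = "target",
                    stringsAsFactors = FALSE)
  expect_error(load_registry(reg, hmm_dir = tmp), "unknown categories")
  reg$category <- "catalase"
  lr <- load_registry(reg, hmm_dir = tmp)
  expect_equal(lr$table$gathering, 10)
  lr2 <- load_registry(transform(reg, category = "methanogenesis"),
                       hmm_dir = tmp, extra_categories = "methanogenesis")
  expect_equal(lr2$table$category, "methanogenesis")
})
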