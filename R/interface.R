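#' Build a profile-HMM library from seed alignments
#'
#' Wraps [build_from_alignment()] + [write_hmm3()] for every aligned FASTA
#' in `alignments`; the model name is the file name without extension.
#'
#' @param alignments Character vector of aligned-FASTA paths, or a
#'   directory containing them (`.faa`, `.fasta`, `.afa`).
#' @param out_dir Directory receiving one `<name>.hmm` per alignment.
#' @param pseudocount,match_fraction Passed to [build_from_alignment()].
#' @return Named character vector of written HMM paths.
#' @export
build_hmm_library <- function(alignments, out_dir, pseudocount = 1,
                              match_fraction = 0.5) {
  if (length(alignments) == 1 && dir.exists(alignments))
    alignments <- list.files(alignments, "\\.(faa|fasta|afa)$",
                             full.names = TRUE)
  if (length(alignments) == 0)
    stop("validation error: no seed alignments found")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- character(0)
  for (p in alignments) {
    nm <- sub("\\.[^.]*$", "", basename(p))
    aln <- tryCatch(Biostrings::readAAStringSet(p),
                    error = function(e) stop("failed to read alignment ", p,
                                             ": ", conditionMessage(e)))
    h <- build_from_alignment(aln, pseudocount = pseudocount,
                              match_fraction = match_fraction, name = nm)
    dest <- file.path(out_dir, paste0(nm, ".hmm"))
    write_hmm3(h, dest)
    out[nm] <- dest
  }
  out
}

## score one protein FASTA against one HMM; no positive local alignment is
## floored at 0 bits so labeled calibration scores stay finite
score_fasta <- function(hmm, fasta) {
  seqs <- if (methods::is(fasta, "AAStringSet")) fasta
          else Biostrings::readAAStringSet(fasta)
  vapply(seq_along(seqs), function(i) {
    hit <- score_local(hmm, as.character(seqs[[i]]))
    if (is.null(hit)) 0 else hit$bit_score
  }, numeric(1))
}

#' Calibrate bit-score cutoffs for a set of HMMs
#'
#' Scores each HMM's labeled true-homolog and non-target-homolog sequences
#' with [score_local()] (sequences with no positive-scoring alignment get
#' score 0), derives cutoffs with [derive_cutoffs()] and writes the
#' calibration report. Non-separable HMMs trigger a warning.
#'
#' @param hmm_files Named character vector of HMMER3 files (or a directory
#'   of `.hmm` files).
#' @param tp_fastas Named character vector, HMM name -> FASTA of curated
#'   true homologs.
#' @param fp_fastas Named character vector, HMM name -> FASTA of curated
#'   non-target homologs; HMMs absent from it get no false-positive set.
#' @param out_file Optional report TSV path.
#' @return The calibration report data frame (see [calibration_report()]).
#' @export
calibrate_hmms <- function(hmm_files, tp_fastas, fp_fastas = character(0),
                           out_file = NULL) {
  if (length(hmm_files) == 1 && dir.exists(hmm_files))
    hmm_files <- list.files(hmm_files, "\\.hmm$", full.names = TRUE)
  hmms <- list()
  for (p in hmm_files) {
    if (!file.exists(p)) stop("validation error: HMM file not found: ", p)
    h <- parse_hmm3(p)[[1]]
    hmms[[h$name]] <- h
  }
  cutoffs <- list(); n_tp <- integer(0); n_fp <- integer(0)
  for (nm in names(hmms)) {
    if (!nm %in% names(tp_fastas))
      stop("validation error: no TP set supplied for HMM '", nm, "'")
    if (!file.exists(tp_fastas[[nm]]))
      stop("validation error: TP file not found: ", tp_fastas[[nm]])
    tp <- score_fasta(hmms[[nm]], tp_fastas[[nm]])
    fp <- numeric(0)
    if (nm %in% names(fp_fastas)) {
      if (!file.exists(fp_fastas[[nm]]))
        stop("validation error: FP file not found: ", fp_fastas[[nm]])
      fp <- score_fasta(hmms[[nm]], fp_fastas[[nm]])
    }
    co <- derive_cutoffs(tp, fp)
    if (!co$separable)
      warning("HMM '", nm, "': labeled score sets are not separable; ",
              "gathering cutoff set by accuracy maximization")
    cutoffs[[nm]] <- co
    n_tp[nm] <- length(tp); n_fp[nm] <- length(fp)
  }
  calibration_report(cutoffs, n_tp, n_fp, path = out_file)
}

read_sample_metadata <- function(metadata) {
  df <- if (is.data.frame(metadata)) metadata
        else read.delim(metadata, stringsAsFactors = FALSE)
  need <- c("sample_id", "site", "depth_mbsf", "sulfate_status")
  if (!all(need %in% names(df)))
    stop("validation error: metadata must have columns ",
         paste(need, collapse = ", "))
  df
}

filter_categories <- function(tab, categories) {
  keep_cat <- switch(categories,
    all = unique(tab$category),
    litho = ENERGY_CATEGORIES,
    ros = ROS_CATEGORIES,
    strsplit(categories, ",")[[1]])
  tab[tab$role == "decoy" | tab$category %in% keep_cat, , drop = FALSE]
}

#' Run the full screening pipeline over per-sample assemblies
#'
#' For every sample: six-frame ORF extraction, local-Viterbi scoring of
#' each ORF against every registry HMM (targets and decoys), competitive
#' decoy screening with gathering cutoffs, and lineage x gene variant
#' counting. Writes `hits.tsv`, one `inventory_<sample>.tsv` per sample,
#' the combined inventory export `inventory_table.tsv`, the
#' `category_scores.tsv` matrix and a reproducibility `manifest.txt`.
#' Outputs are byte-deterministic for identical inputs.
#'
#' @param contig_fastas Named character vector `sample_id -> FASTA path`
#'   (or named list of `DNAStringSet`s).
#' @param registry Registry TSV path or data frame (see
#'   [load_registry()]).
#' @param hmm_dir Directory with the registry's HMM files.
#' @param metadata Sample metadata TSV/data frame: `sample_id, site,
#'   depth_mbsf, sulfate_status`.
#' @param lineage_map Optional TSV/data frame `(id, lineage)`.
#' @param calibration Optional calibration report TSV/data frame.
#' @param out_dir Output directory, created if needed.
#' @param min_aa_len Minimum ORF length (aa). Default 30.
#' @param identity_threshold Variant clustering identity. Default 1.0.
#' @param categories `"all"`, `"litho"`, `"ros"`, or a comma-separated
#'   category list; decoy models are always retained for screening.
#' @param normalize Normalize category scores to per-sample proportions.
#' @param seed Recorded in the manifest (the scan itself is
#'   deterministic).
#' @return Invisibly, a list with `inventories`, `inventory` (the export
#'   table), `category_scores`, `hits` and `orfs`.
#' @export
run_scan <- function(contig_fastas, registry, hmm_dir = ".", metadata,
                     lineage_map = NULL, calibration = NULL,
                     out_dir = "markerscan_out", min_aa_len = 30,
                     identity_threshold = 1.0, categories = "all",
                     normalize = FALSE, seed = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  reg <- load_registry(registry, hmm_dir = hmm_dir, calibration = calibration)
  reg$table <- filter_categories(reg$table, categories)
  reg$hmms <- reg$hmms[reg$table$hmm_name]
  meta_df <- read_sample_metadata(metadata)
  lmap <- NULL
  if (!is.null(lineage_map))
    lmap <- if (is.data.frame(lineage_map)) lineage_map
            else read.delim(lineage_map, stringsAsFactors = FALSE)

  sample_ids <- names(contig_fastas)
  if (is.null(sample_ids) || any(!nzchar(sample_ids)))
    stop("validation error: contig_fastas must be named by sample_id")
  missing_meta <- setdiff(sample_ids, meta_df$sample_id)
  if (length(missing_meta))
    stop("validation error: no metadata for sample(s): ",
         paste(missing_meta, collapse = ", "))

  inventories <- list(); all_hits <- list(); all_orfs <- list()
  for (sid in sort(sample_ids, method = "radix")) {
    orfs <- orf_scan(contig_fastas[[sid]], sample_id = sid,
                     min_aa_len = min_aa_len)
    if (nrow(orfs) == 0)
      warning("sample ", sid, ": no ORFs of length >= ", min_aa_len,
              " amino acids")
    scores <- matrix(-Inf, nrow(orfs), length(reg$hmms),
                     dimnames = list(orfs$orf_id, names(reg$hmms)))
    for (i in seq_len(nrow(orfs))) {
      for (nm in names(reg$hmms)) {
        hit <- score_local(reg$hmms[[nm]], orfs$aa_seq[i],
                           orf_id = orfs$orf_id[i])
        if (!is.null(hit)) {
          scores[i, nm] <- hit$bit_score
          all_hits[[length(all_hits) + 1]] <- hit
        }
      }
    }
    mrow <- meta_df[meta_df$sample_id == sid, , drop = FALSE][1, ]
    meta <- sample_meta(mrow$sample_id, mrow$site, mrow$depth_mbsf,
                        mrow$sulfate_status)
    inv <- build_inventory(orfs, scores, reg, meta, lineage_map = lmap,
                           identity_threshold = identity_threshold)
    inventories[[sid]] <- inv
    all_orfs[[sid]] <- orfs
    write.table(inv$rows, file.path(out_dir,
                                    paste0("inventory_", sid, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  hits_df <- write_hits_tsv(all_hits, file.path(out_dir, "hits.tsv"))
  inventory <- export_inventory_table(inventories,
                            path = file.path(out_dir, "inventory_table.tsv"))
  target_cats <- sort(unique(
    reg$table$category[reg$table$role == "target"]), method = "radix")
  cs <- category_scores(inventories, normalize = normalize,
                        categories = target_cats)
  write.table(cs, file.path(out_dir, "category_scores.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_manifest(file.path(out_dir, "manifest.txt"), list(
    tool = paste("markerscan", utils::packageVersion("markerscan")),
    command = "run_scan",
    registry = if (is.character(registry)) registry else "<data frame>",
    hmm_dir = hmm_dir,
    samples = paste(sort(sample_ids, method = "radix"), collapse = ","),
    contigs = if (is.character(contig_fastas))
      paste(contig_fastas[sort(sample_ids, method = "radix")], collapse = ",")
      else "<in-memory>",
    contigs_md5 = if (is.character(contig_fastas))
      paste(unname(tools::md5sum(
        contig_fastas[sort(sample_ids, method = "radix")])), collapse = ",")
      else "",
    min_aa_len = min_aa_len,
    identity_threshold = identity_threshold,
    categories = categories,
    normalize = normalize,
    seed = seed %||% ""))
  invisible(list(inventories = inventories, inventory = inventory,
                 category_scores = cs, hits = hits_df, orfs = all_orfs))
}

write_manifest <- function(path, fields) {
  writeLines(paste0(names(fields), " = ",
                    vapply(fields, function(x) paste(format(x), collapse = ","),
                           character(1))),
             path)
}

#' Run the end-to-end synthetic demonstration
#'
#' Generates the default synthetic dataset ([demo_plan()]), builds the HMM
#' library from its seed alignments, calibrates gathering cutoffs (true
#' homologs = each target family's members; non-target homologs = the
#' decoy families' members), screens all samples with [run_scan()] and
#' compares the resulting inventory export to the generator's truth table.
#'
#' @param out_dir Working directory for all artifacts.
#' @param seed Global seed for the generator. Default 42.
#' @param n_decoy_orfs,n_random_contigs Passed to [demo_plan()].
#' @return List with the dataset (`data`), scan result (`scan`), the
#'   calibration report (`calibration`), the truth/observed comparison
#'   (`comparison`: data frame with `precision` and `recall` attributes)
#'   and the output paths.
#' @export
demo_pipeline <- function(out_dir, seed = 42, n_decoy_orfs = 8,
                          n_random_contigs = 50) {
  ds <- write_synthetic_dataset(out_dir = file.path(out_dir, "data"),
                                plan = demo_plan(n_decoy_orfs,
                                                 n_random_contigs),
                                seed = seed)
  specs <- demo_family_specs()
  hmm_dir <- file.path(out_dir, "hmms")
  build_hmm_library(ds$paths$alignment_dir, hmm_dir)

  targets <- names(specs)[vapply(specs, function(s) s$role == "target",
                                 logical(1))]
  decoys <- setdiff(names(specs), targets)
  aln <- function(f) file.path(ds$paths$alignment_dir, paste0(f, ".faa"))
  ## one combined FP fasta: every decoy family member
  fp_all <- file.path(out_dir, "fp_members.faa")
  Biostrings::writeXStringSet(
    do.call(c, lapply(decoys, function(d) ds$alignments[[d]])), fp_all)
  cal <- calibrate_hmms(
    hmm_files = file.path(hmm_dir, paste0(targets, ".hmm")),
    tp_fastas = stats::setNames(vapply(targets, aln, character(1)), targets),
    fp_fastas = stats::setNames(rep(fp_all, length(targets)), targets),
    out_file = file.path(out_dir, "calibration_report.tsv"))

  reg_path <- file.path(out_dir, "registry.tsv")
  write.table(demo_registry(), reg_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  scan <- run_scan(contig_fastas = ds$paths$contigs, registry = reg_path,
                   hmm_dir = hmm_dir, metadata = ds$paths$metadata,
                   lineage_map = ds$paths$lineage_map, calibration = cal,
                   out_dir = file.path(out_dir, "scan"), seed = seed)
  comparison <- compare_to_truth(scan$inventory, ds$truth, ds$metadata)
  list(data = ds, scan = scan, calibration = cal, comparison = comparison,
       out_dir = out_dir)
}

#' Compare an inventory export against a synthetic truth table
#'
#' Joins on (sample, lineage, gene) tuples and checks the variant counts.
#'
#' @param inventory Export table from [export_inventory_table()] / [run_scan()].
#' @param truth Truth table from [make_dataset()].
#' @param metadata Sample metadata (to map truth sample ids onto the
#'   export's site/depth keys).
#' @return Data frame of the outer join with columns `expected` and
#'   `observed`; attributes `precision` and `recall` computed over
#'   (sample, lineage, gene, count) tuples.
#' @export
compare_to_truth <- function(inventory, truth, metadata) {
  md <- metadata
  truth$key <- paste(md$site[match(truth$sample_id, md$sample_id)],
                     md$depth_mbsf[match(truth$sample_id, md$sample_id)],
                     truth$lineage, truth$gene_symbol, sep = "|")
  obs <- data.frame(key = paste(inventory$site, inventory$depth_mbsf, inventory$lineage,
                                inventory$gene_symbol, sep = "|"),
                    observed = inventory$transcript_copies,
                    stringsAsFactors = FALSE)
  exp <- data.frame(key = truth$key, expected = truth$variant_count,
                    stringsAsFactors = FALSE)
  m <- merge(exp, obs, by = "key", all = TRUE)
  m <- m[order(m$key, method = "radix"), , drop = FALSE]
  rownames(m) <- NULL
  tp <- sum(!is.na(m$expected) & !is.na(m$observed) &
              m$expected == m$observed)
  attr(m, "precision") <- if (sum(!is.na(m$observed)) == 0) 1
                          else tp / sum(!is.na(m$observed))
  attr(m, "recall") <- if (sum(!is.na(m$expected)) == 0) 1
                       else tp / sum(!is.na(m$expected))
  m
}
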