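## stop-codon motif whose reverse complement is itself stop-dense; random
## contigs are interleaved with it so no reading frame can hold an ORF of
## benchmark length
STOP_MOTIF <- "TAATTAATTAATTAA"
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Specification of a simulated protein family
#'
#' @param family_id Identifier (also used to derive the family's subseed).
#' @param root_length Root sequence length in residues (>= 30).
#' @param n_members Number of family members to evolve (>= 1).
#' @param substitution_rate Per-site substitution probability in \[0, 1).
#' @param role `"target"` or `"decoy"`.
#' @param shared_with,shared_fraction Optional: derive the root from
#'   another family's root by copying `shared_fraction` of its sites
#'   (making decoy families a stated fractional identity from a target).
#' @return An object of class `FamilySpec`.
#' @export
family_spec <- function(family_id, root_length = 150, n_members = 30,
                        substitution_rate = 0.05, role = "target",
                        shared_with = NULL, shared_fraction = NULL) {
  if (root_length < 30) stop("validation error: root_length must be >= 30")
  if (n_members < 1) stop("validation error: n_members must be >= 1")
  if (substitution_rate < 0 || substitution_rate >= 1)
    stop("validation error: substitution_rate must lie in [0, 1)")
  structure(list(family_id = as.character(family_id),
                 root_length = as.integer(root_length),
                 n_members = as.integer(n_members),
                 substitution_rate = substitution_rate, role = role,
                 shared_with = shared_with, shared_fraction = shared_fraction),
            class = "FamilySpec")
}

#' Evolve a toy protein family from a random root
#'
#' The root is drawn uniformly over the 20 standard residues (seeded);
#' each member is derived from the root by independent per-site
#' substitution to a uniformly chosen *different* residue with probability
#' `substitution_rate`. No indels, so members are mutually aligned and
#' directly usable as a seed alignment. Deterministic given `seed`: the
#' family's stream is `subseed(seed, family_id)`, so other families never
#' perturb it.
#'
#' @param spec A [family_spec()].
#' @param seed Global integer seed.
#' @param base_root Optional root to share sites with (overrides the
#'   uniform draw; used with `spec$shared_fraction`).
#' @return List with `family_id`, `root` and named character vector
#'   `members`.
#' @export
evolve_family <- function(spec, seed = 1, base_root = NULL) {
  stopifnot(inherits(spec, "FamilySpec"))
  with_seed(subseed(seed, paste0("family:", spec$family_id)), {
    L <- spec$root_length
    if (is.null(base_root)) {
      root <- sample(AA20, L, replace = TRUE)
    } else {
      base <- strsplit(base_root, "")[[1]]
      if (length(base) != L)
        stop("validation error: base_root length must equal root_length")
      frac <- spec$shared_fraction %||% 0.4
      keep <- sample(L, round(frac * L))
      root <- vapply(seq_len(L), function(i) {
        if (i %in% keep) base[i]
        else sample(setdiff(AA20, base[i]), 1)
      }, character(1))
    }
    members <- vapply(seq_len(spec$n_members), function(m) {
      s <- root
      mut <- runif(L) < spec$substitution_rate
      for (i in which(mut)) s[i] <- sample(setdiff(AA20, root[i]), 1)
      paste(s, collapse = "")
    }, character(1))
    names(members) <- paste0(spec$family_id, "_m", seq_len(spec$n_members))
    list(family_id = spec$family_id, root = paste(root, collapse = ""),
         members = members)
  })
}

## inverted genetic code: codons per amino acid (stop codons excluded)
codons_by_aa <- function(table = "11") {
  code <- genetic_code_table(table)
  split(names(code), unname(code))
}

#' Reverse-translate a protein with uniform synonymous codon choice
#'
#' Table-11 back-translation; each residue's codon is drawn uniformly from
#' its synonymous set using the current RNG stream (seed management is the
#' caller's job). The result contains no internal stop codon by
#' construction.
#'
#' @param aa Protein string (20 standard residues).
#' @param table Genetic code id.
#' @return Nucleotide string of length `3 * nchar(aa)`.
#' @export
reverse_translate <- function(aa, table = "11") {
  cba <- codons_by_aa(table)
  chars <- strsplit(aa, "")[[1]]
  if (any(!chars %in% AA20))
    stop("validation error: cannot reverse-translate residue '",
         chars[!chars %in% AA20][1], "'")
  paste(vapply(chars, function(a) {
    cs <- cba[[a]]
    cs[sample.int(length(cs), 1)]
  }, character(1)), collapse = "")
}

## stop-rich flank; `boundary` ("TAA" or "TTA") is forced onto the end of
## a left flank / start of a right flank so the planted ORF is maximal on
## its strand
make_flank <- function(side, boundary) {
  k <- sample(9:17, 1)
  body <- paste(sample(STOP_CODONS, k, replace = TRUE), collapse = "")
  if (side == "left") paste0(body, boundary) else paste0(boundary, body)
}

## embed one protein-coding ORF in a contig with stop-rich flanks;
## returns forward-strand half-open coordinates
plant_orf <- function(aa, strand, table = "11") {
  orf_nt <- reverse_translate(aa, table)
  if (strand == "+") {
    left <- make_flank("left", "TAA"); right <- make_flank("right", "TAA")
    seq <- paste0(left, orf_nt, right)
  } else {
    left <- make_flank("left", "TTA"); right <- make_flank("right", "TTA")
    seq <- paste0(left, dna_revcomp(orf_nt), right)
  }
  list(seq = seq, nt_start = nchar(left),
       nt_end = nchar(left) + nchar(orf_nt), strand = strand)
}

## random contig with no ORF >= min_aa_len in any frame: random blocks
## (<= 30 nt) interleaved with the stop motif, then verified by a
## reject-and-regenerate guard
make_random_contig <- function(target_len, min_aa_len = 30) {
  repeat {
    parts <- character(0); len <- 0
    while (len < target_len) {
      b <- paste(sample(c("A", "C", "G", "T"), sample(15:30, 1),
                        replace = TRUE), collapse = "")
      parts <- c(parts, b, STOP_MOTIF)
      len <- len + nchar(b) + nchar(STOP_MOTIF)
    }
    seq <- paste(parts, collapse = "")
    orfs <- six_frame_orfs(contig("tmp", seq), min_aa_len = min_aa_len)
    if (nrow(orfs) == 0) return(seq)
  }
}

#' Default demo plant plan
#'
#' Three toy samples emulating the study design: two depths of an organic-
#' rich margin site with sulfate present (5 and 91 mbsf) and one brackish
#' basin sample below sulfate depletion (42 mbsf). Marker genes span iron
#' oxidation (`cyc2`), sulfur oxidation (`sdo`, `sqr`), nitrate reduction
#' (`nar`, planted exclusively in the 91-mbsf sample), catalase (`katG`)
#' and superoxide dismutase (`sodA`); each sample additionally receives
#' decoy-family ORFs and random (non-coding) contigs.
#'
#' @param n_decoy_orfs Decoy ORFs per sample. Default 8.
#' @param n_random_contigs Random contigs per sample. Default 50.
#' @return A plan list consumable by [make_dataset()].
#' @export
demo_plan <- function(n_decoy_orfs = 8, n_random_contigs = 50) {
  plant <- function(...) {
    m <- matrix(c(...), ncol = 3, byrow = TRUE)
    data.frame(gene_symbol = m[, 1], lineage = m[, 2],
               n_variants = as.integer(m[, 3]), stringsAsFactors = FALSE)
  }
  list(
    samples = list(
      list(meta = sample_meta("PM_05", "1229D", 5, "present"),
           plants = plant("cyc2", "Proteobacteria_Gamma", 2,
                          "katG", "Proteobacteria_Gamma", 3,
                          "sodA", "Firmicutes", 1),
           n_decoy_orfs = n_decoy_orfs, n_random_contigs = n_random_contigs),
      list(meta = sample_meta("PM_91", "1229D", 91, "present"),
           plants = plant("nar",  "Proteobacteria_Gamma", 2,
                          "sdo",  "Chloroflexi", 1,
                          "cyc2", "Actinobacteria", 1),
           n_decoy_orfs = n_decoy_orfs, n_random_contigs = n_random_contigs),
      list(meta = sample_meta("BS_42", "M0059E", 42, "depleted"),
           plants = plant("sdo",  "Chloroflexi", 2,
                          "sqr",  "Chloroflexi", 1,
                          "katG", "Firmicutes", 1,
                          "sodA", "Firmicutes", 2),
           n_decoy_orfs = n_decoy_orfs, n_random_contigs = n_random_contigs)))
}

#' Default demo family specifications
#'
#' Six marker-gene families plus two decoy families. The decoys share 40%
#' of their root sites with `cyc2` and `katG` respectively, making the
#' calibration and competitive screening genuinely non-trivial.
#'
#' @param n_members Members per family. Default 30.
#' @param substitution_rate Per-site substitution rate. Default 0.05.
#' @return Named list of [family_spec()]s.
#' @export
demo_family_specs <- function(n_members = 30, substitution_rate = 0.05) {
  fs <- function(id, len, role = "target", sw = NULL, sf = NULL)
    family_spec(id, root_length = len, n_members = n_members,
                substitution_rate = substitution_rate, role = role,
                shared_with = sw, shared_fraction = sf)
  list(cyc2 = fs("cyc2", 150), sdo = fs("sdo", 140), sqr = fs("sqr", 130),
       nar = fs("nar", 160), katG = fs("katG", 170), sodA = fs("sodA", 120),
       cyc2_paralog = fs("cyc2_paralog", 150, "decoy", "cyc2", 0.4),
       katG_paralog = fs("katG_paralog", 170, "decoy", "katG", 0.4))
}

#' Default demo gene-family registry table
#'
#' @return Data frame with columns `gene_symbol, category, hmm_file, role,
#'   gathering_override` referring to `<family>.hmm` files.
#' @export
demo_registry <- function() {
  data.frame(
    gene_symbol = c("cyc2", "sdo", "sqr", "nar", "katG", "sodA",
                    "cyc2_paralog", "katG_paralog"),
    category = c("iron_oxidation", "sulfur_oxidation", "sulfur_oxidation",
                 "nitrate_reduction", "catalase", "superoxide_dismutase",
                 "decoy", "decoy"),
    hmm_file = paste0(c("cyc2", "sdo", "sqr", "nar", "katG", "sodA",
                        "cyc2_paralog", "katG_paralog"), ".hmm"),
    role = c(rep("target", 6), rep("decoy", 2)),
    gathering_override = NA_real_,
    stringsAsFactors = FALSE)
}

#' Generate a synthetic benchmark dataset
#'
#' Emulates, at toy scale, per-sample metatranscriptome assemblies: each
#' planted gene variant is a distinct family member, reverse-translated
#' (uniform synonymous codons, table 11), embedded in a contig between
#' stop-rich flanks (>= 30 nt) on a random strand; decoy ORFs come from
#' decoy families; random contigs carry no ORF of benchmark length in any
#' frame. Everything is deterministic under `seed`, with per-family and
#' per-sample substreams derived by stable identifier hashing, so adding a
#' sample never perturbs existing ones.
#'
#' @param plan Plan list (see [demo_plan()]): per sample a
#'   [sample_meta()], a `plants` data frame `(gene_symbol, lineage,
#'   n_variants)`, `n_decoy_orfs` and `n_random_contigs`.
#' @param family_specs Named list of [family_spec()]s covering every
#'   planted gene plus the decoy families.
#' @param seed Global integer seed.
#' @param min_aa_len Benchmark ORF length floor used by the random-contig
#'   guard. Default 30.
#' @return List with `contigs` (named list of `Biostrings::DNAStringSet`
#'   per sample), `truth` (aggregated truth table), `planted_orfs`
#'   (per-ORF coordinates, targets and decoys), `lineage_map`, `metadata`,
#'   `families` and `alignments` (named list of `AAStringSet` seed
#'   alignments).
#' @export
make_dataset <- function(plan, family_specs = demo_family_specs(), seed = 42,
                         min_aa_len = 30) {
  genes <- unique(unlist(lapply(plan$samples, function(s)
    s$plants$gene_symbol)))
  missing <- setdiff(genes, names(family_specs))
  if (length(missing))
    stop("validation error: plan plants gene(s) without a family spec: ",
         paste(missing, collapse = ", "))

  ## evolve families (base families first so shared roots are available)
  families <- list()
  for (nm in names(family_specs)) {
    sp <- family_specs[[nm]]
    if (is.null(sp$shared_with)) families[[nm]] <- evolve_family(sp, seed)
  }
  for (nm in names(family_specs)) {
    sp <- family_specs[[nm]]
    if (!is.null(sp$shared_with)) {
      base <- families[[sp$shared_with]]
      if (is.null(base))
        stop("validation error: shared_with family not found: ", sp$shared_with)
      families[[nm]] <- evolve_family(sp, seed, base_root = base$root)
    }
  }
  decoy_ids <- names(family_specs)[vapply(family_specs,
                                          function(s) s$role == "decoy",
                                          logical(1))]

  contigs <- list(); truth <- list(); planted <- list(); lmap <- list()
  meta_rows <- list()
  for (s in plan$samples) {
    sid <- s$meta$sample_id
    meta_rows[[sid]] <- data.frame(sample_id = sid, site = s$meta$site,
                                   depth_mbsf = s$meta$depth_mbsf,
                                   sulfate_status = s$meta$sulfate_status,
                                   stringsAsFactors = FALSE)
    with_seed(subseed(seed, paste0("sample:", sid)), {
      seqs <- character(0); cnames <- character(0); ci <- 0
      add_contig <- function(seq) {
        ci <<- ci + 1
        nm <- sprintf("%s_c%03d", sid, ci)
        seqs <<- c(seqs, seq); cnames <<- c(cnames, nm)
        nm
      }
      if (nrow(s$plants %||% data.frame()) > 0) {
        for (r in seq_len(nrow(s$plants))) {
          g <- s$plants$gene_symbol[r]
          lin <- s$plants$lineage[r]
          nv <- s$plants$n_variants[r]
          pool <- unique(unname(families[[g]]$members))
          if (length(pool) < nv)
            stop("validation error: family ", g, " has only ", length(pool),
                 " distinct members, cannot plant ", nv, " variants")
          picks <- sample(pool, nv)
          for (aa in picks) {
            p <- plant_orf(aa, sample(c("+", "-"), 1))
            nm <- add_contig(p$seq)
            lmap[[length(lmap) + 1]] <- data.frame(id = nm, lineage = lin,
                                                   stringsAsFactors = FALSE)
            planted[[length(planted) + 1]] <- data.frame(
              sample_id = sid, contig_id = nm, role = "target",
              gene_symbol = g, lineage = lin, strand = p$strand,
              nt_start = p$nt_start, nt_end = p$nt_end, aa_seq = aa,
              stringsAsFactors = FALSE)
          }
          truth[[length(truth) + 1]] <- data.frame(
            sample_id = sid, lineage = lin, gene_symbol = g,
            variant_count = nv, stringsAsFactors = FALSE)
        }
      }
      lineage_pool <- unique(unlist(lapply(plan$samples, function(x)
        x$plants$lineage))) %||% "unclassified"
      nd <- s$n_decoy_orfs %||% 0
      if (nd > 0 && length(decoy_ids) == 0)
        stop("validation error: plan requests decoy ORFs but no decoy family",
             " is specified")
      for (d in seq_len(nd)) {
        fam <- decoy_ids[((d - 1) %% length(decoy_ids)) + 1]
        aa <- sample(unname(families[[fam]]$members), 1)
        p <- plant_orf(aa, sample(c("+", "-"), 1))
        nm <- add_contig(p$seq)
        lin <- sample(lineage_pool, 1)
        lmap[[length(lmap) + 1]] <- data.frame(id = nm, lineage = lin,
                                               stringsAsFactors = FALSE)
        planted[[length(planted) + 1]] <- data.frame(
          sample_id = sid, contig_id = nm, role = "decoy", gene_symbol = fam,
          lineage = lin, strand = p$strand, nt_start = p$nt_start,
          nt_end = p$nt_end, aa_seq = aa, stringsAsFactors = FALSE)
      }
      for (rr in seq_len(s$n_random_contigs %||% 0))
        add_contig(make_random_contig(sample(120:300, 1), min_aa_len))
      dna <- Biostrings::DNAStringSet(seqs)
      names(dna) <- cnames
      contigs[[sid]] <- dna
    })
  }
  bindrows <- function(lst, empty) if (length(lst)) do.call(rbind, lst) else empty
  truth_df <- bindrows(truth, data.frame(sample_id = character(),
                                         lineage = character(),
                                         gene_symbol = character(),
                                         variant_count = integer()))
  alignments <- lapply(families, function(f) Biostrings::AAStringSet(f$members))
  list(contigs = contigs,
       truth = truth_df,
       planted_orfs = bindrows(planted, data.frame()),
       lineage_map = bindrows(lmap, data.frame(id = character(),
                                               lineage = character())),
       metadata = do.call(rbind, unname(meta_rows)),
       families = families,
       alignments = alignments)
}

#' Write a synthetic dataset to disk
#'
#' Materializes [make_dataset()] output as standard text formats:
#' `contigs_<sample>.fasta`, `alignments/<family>.faa`,
#' `truth_table.tsv`, `planted_orfs.tsv`, `lineage_map.tsv` and
#' `sample_metadata.tsv`.
#'
#' @inheritParams make_dataset
#' @param out_dir Output directory (created if absent).
#' @return The dataset list, invisibly, with a `paths` element added.
#' @export
write_synthetic_dataset <- function(out_dir, plan = demo_plan(),
                                    family_specs = demo_family_specs(),
                                    seed = 42, min_aa_len = 30) {
  ds <- make_dataset(plan, family_specs, seed = seed, min_aa_len = min_aa_len)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "alignments"), showWarnings = FALSE)
  paths <- list(contigs = character(0))
  for (sid in names(ds$contigs)) {
    p <- file.path(out_dir, paste0("contigs_", sid, ".fasta"))
    Biostrings::writeXStringSet(ds$contigs[[sid]], p)
    paths$contigs[sid] <- p
  }
  for (fam in names(ds$alignments)) {
    p <- file.path(out_dir, "alignments", paste0(fam, ".faa"))
    Biostrings::writeXStringSet(ds$alignments[[fam]], p)
  }
  wt <- function(df, name) {
    p <- file.path(out_dir, name)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths$truth <- wt(ds$truth, "truth_table.tsv")
  paths$planted_orfs <- wt(ds$planted_orfs, "planted_orfs.tsv")
  paths$lineage_map <- wt(ds$lineage_map, "lineage_map.tsv")
  paths$metadata <- wt(ds$metadata, "sample_metadata.tsv")
  paths$alignment_dir <- file.path(out_dir, "alignments")
  ds$paths <- paths
  invisible(ds)
}
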