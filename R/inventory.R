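## Fixed category vocabulary; extensible via the `extra_categories`
## argument of load_registry()
ENERGY_CATEGORIES <- c("iron_oxidation", "sulfur_oxidation",
                       "nitrate_reduction", "arsenate_reduction",
                       "selenate_reduction", "sulfite_reduction")
ROS_CATEGORIES <- c("catalase", "peroxiredoxin", "superoxide_dismutase",
                    "hydroperoxide_reductase", "dyp_peroxidase",
                    "heme_peroxidase")

#' Load and validate a gene-family registry
#'
#' The registry maps each marker gene symbol to a process category and to
#' its target profile HMM; decoy rows name the non-target homolog profiles
#' used for competitive screening. File columns: `gene_symbol, category,
#' hmm_file, role` (`target` or `decoy`) and optional `gathering_override`.
#' The effective gathering cutoff of a target is its override when given,
#' otherwise the `GA` line of its HMM file, otherwise a calibration-report
#' row; lacking all three it stays `NA` and [competitive_assign()] raises a
#' configuration error on first use.
#'
#' @param registry A path to the registry TSV or an equivalent data frame.
#' @param hmm_dir Directory against which relative `hmm_file` paths are
#'   resolved.
#' @param calibration Optional calibration report (path or data frame from
#'   [calibration_report()]) supplying gathering cutoffs by HMM name.
#' @param extra_categories Additional category names to allow beyond the
#'   built-in energy-metabolism and ROS vocabularies.
#' @return List with `table` (columns `gene_symbol, category, hmm_name,
#'   role, gathering`) and `hmms` (named list of [profile_hmm()]s).
#' @export
load_registry <- function(registry, hmm_dir = ".", calibration = NULL,
                          extra_categories = character(0)) {
  df <- if (is.data.frame(registry)) registry
        else read.delim(registry, stringsAsFactors = FALSE)
  need <- c("gene_symbol", "category", "hmm_file", "role")
  if (!all(need %in% names(df)))
    stop("validation error: registry must have columns ",
         paste(need, collapse = ", "))
  if (!all(df$role %in% c("target", "decoy")))
    stop("validation error: registry role must be 'target' or 'decoy'")
  tgt <- df[df$role == "target", ]
  if (anyDuplicated(tgt$gene_symbol))
    stop("validation error: duplicate gene_symbol in registry")
  vocab <- c(ENERGY_CATEGORIES, ROS_CATEGORIES, extra_categories)
  bad <- setdiff(tgt$category, vocab)
  if (length(bad))
    stop("validation error: unknown categories: ", paste(bad, collapse = ", "),
         " (extend via extra_categories)")
  cal <- NULL
  if (!is.null(calibration))
    cal <- if (is.data.frame(calibration)) calibration
           else read.delim(calibration, stringsAsFactors = FALSE)
  hmms <- list()
  tab <- df
  tab$hmm_name <- NA_character_
  tab$gathering <- NA_real_
  for (i in seq_len(nrow(df))) {
    p <- df$hmm_file[i]
    if (!file.exists(p)) p <- file.path(hmm_dir, df$hmm_file[i])
    if (!file.exists(p))
      stop("validation error: HMM file not found: ", df$hmm_file[i])
    h <- parse_hmm3(p)[[1]]
    hmms[[h$name]] <- h
    tab$hmm_name[i] <- h$name
    if (df$role[i] == "target") {
      g <- suppressWarnings(as.numeric(df$gathering_override[i] %||% NA))
      if (is.na(g) && !is.null(h$cutoffs)) g <- h$cutoffs$gathering
      if (is.na(g) && !is.null(cal) && h$name %in% cal$hmm_name)
        g <- cal$gathering[match(h$name, cal$hmm_name)]
      tab$gathering[i] <- g
    }
  }
  if (anyDuplicated(tab$hmm_name))
    stop("validation error: duplicate HMM names in registry")
  list(table = tab[, c("gene_symbol", "category", "hmm_name", "role",
                       "gathering")],
       hmms = hmms)
}

#' Count gene variants by greedy sequence clustering
#'
#' The inventory quantifies "transcript copies" as the number of distinct
#' sequence variants of a gene in a sample. Sequences are sorted by length
#' (descending), then lexicographically, and greedily clustered: a sequence
#' joins the first cluster whose representative it matches at
#' `>= identity_threshold` over the shorter sequence, using the best
#' ungapped overlap. At the default threshold 1.0 this reduces to exact
#' substring/duplicate dereplication.
#'
#' @param aa_seqs Non-empty character vector of protein sequences (all
#'   assigned to the same gene).
#' @param identity_threshold Fraction in (0, 1\]. Default 1.0.
#' @return List with `n_variants`, `cluster` (integer assignment aligned
#'   with the input order) and `representatives`.
#' @export
count_variants <- function(aa_seqs, identity_threshold = 1.0) {
  if (length(aa_seqs) == 0)
    stop("validation error: count_variants requires at least one sequence")
  if (identity_threshold <= 0 || identity_threshold > 1)
    stop("validation error: identity_threshold must lie in (0, 1]")
  ord <- order(-nchar(aa_seqs), aa_seqs, method = "radix")
  reps <- character(0)
  assign <- integer(length(aa_seqs))
  for (i in ord) {
    placed <- 0L
    for (cl in seq_along(reps)) {
      if (pair_identity(aa_seqs[i], reps[cl]) >= identity_threshold) {
        placed <- cl; break
      }
    }
    if (placed == 0L) {
      reps <- c(reps, aa_seqs[i])
      placed <- length(reps)
    }
    assign[i] <- placed
  }
  list(n_variants = length(reps), cluster = assign, representatives = reps)
}

#' Ungapped pairwise identity over the shorter sequence
#'
#' Slides the shorter sequence along the longer and returns the best match
#' fraction (global identity of the best ungapped overlap, denominated by
#' the shorter length).
#'
#' @param a,b Protein strings.
#' @return Identity fraction in \[0, 1\].
#' @export
pair_identity <- function(a, b) {
  if (nchar(a) <= nchar(b)) { s <- a; l <- b } else { s <- b; l <- a }
  sv <- utf8ToInt(s); lv <- utf8ToInt(l)
  ns <- length(sv)
  best <- 0L
  for (off in 0:(length(lv) - ns)) {
    m <- sum(sv == lv[(off + 1):(off + ns)])
    if (m > best) best <- m
  }
  best / ns
}

#' Sample metadata record
#'
#' @param sample_id Sample identifier.
#' @param site Site identifier (e.g. `M0059E`, `1229D`).
#' @param depth_mbsf Depth in meters below seafloor (>= 0).
#' @param sulfate_status `"present"` or `"depleted"`.
#' @return An object of class `SampleMeta`.
#' @export
sample_meta <- function(sample_id, site, depth_mbsf, sulfate_status) {
  depth_mbsf <- as.numeric(depth_mbsf)
  if (is.na(depth_mbsf) || depth_mbsf < 0)
    stop("validation error: depth_mbsf must be >= 0")
  if (!sulfate_status %in% c("present", "depleted"))
    stop("validation error: sulfate_status must be 'present' or 'depleted'")
  structure(list(sample_id = as.character(sample_id),
                 site = as.character(site), depth_mbsf = depth_mbsf,
                 sulfate_status = sulfate_status),
            class = "SampleMeta")
}

#' Build the per-sample lineage x gene inventory
#'
#' Runs every scored ORF through [competitive_assign()], groups accepted
#' ORFs by (lineage, gene symbol), counts variants with [count_variants()]
#' and returns a `SampleInventory`. ORFs without a lineage mapping are kept
#' under `"unclassified"` so counts remain conserved; rows with zero
#' accepted ORFs are omitted.
#'
#' @param orfs ORF table for one sample ([orf_scan()] layout).
#' @param scores Numeric matrix of bit scores, rows = `orf_id`, columns =
#'   every registry HMM name (`-Inf` where no positive local alignment).
#' @param registry Registry list from [load_registry()] (or its `table`).
#' @param meta A [sample_meta()] for the sample.
#' @param lineage_map Optional data frame `(id, lineage)`; ids may be ORF
#'   or contig identifiers (ORF ids take precedence).
#' @param identity_threshold Passed to [count_variants()].
#' @return A `SampleInventory`: list with `meta` and `rows` (data frame
#'   `lineage, gene_symbol, category, variant_count, orf_ids`).
#' @export
build_inventory <- function(orfs, scores, registry, meta, lineage_map = NULL,
                            identity_threshold = 1.0) {
  tab <- if (is.data.frame(registry)) registry else registry$table
  stopifnot(inherits(meta, "SampleMeta"))
  if (nrow(orfs) > 0 && any(!is.na(orfs$sample_id) &
                            orfs$sample_id != meta$sample_id))
    stop("validation error: sample_id mismatch between ORFs and metadata")
  empty <- data.frame(lineage = character(), gene_symbol = character(),
                      category = character(), variant_count = integer(),
                      orf_ids = character(), stringsAsFactors = FALSE)
  inv <- structure(list(meta = meta, rows = empty), class = "SampleInventory")
  if (nrow(orfs) == 0) return(inv)

  gene <- vapply(orfs$orf_id, function(id) {
    sc <- scores[id, , drop = FALSE]     # keep HMM names for 1-column input
    competitive_assign(stats::setNames(as.numeric(sc), colnames(sc)), tab)
  }, character(1))
  keep <- !is.na(gene)
  if (!any(keep)) return(inv)
  acc <- orfs[keep, , drop = FALSE]
  acc$gene_symbol <- gene[keep]
  acc$lineage <- "unclassified"
  if (!is.null(lineage_map) && nrow(lineage_map) > 0) {
    byorf <- match(acc$orf_id, lineage_map$id)
    bycontig <- match(acc$contig_id, lineage_map$id)
    hit <- ifelse(is.na(byorf), bycontig, byorf)
    acc$lineage[!is.na(hit)] <- lineage_map$lineage[hit[!is.na(hit)]]
  }
  grp <- split(acc, paste(acc$lineage, acc$gene_symbol, sep = "\r"))
  rows <- do.call(rbind, lapply(grp, function(g) {
    cv <- count_variants(g$aa_seq, identity_threshold)
    data.frame(lineage = g$lineage[1], gene_symbol = g$gene_symbol[1],
               category = tab$category[match(g$gene_symbol[1],
                                             tab$gene_symbol)],
               variant_count = cv$n_variants,
               orf_ids = paste(sort(g$orf_id, method = "radix"),
                               collapse = ","),
               stringsAsFactors = FALSE)
  }))
  rows <- rows[order(rows$lineage, rows$gene_symbol, method = "radix"), ,
               drop = FALSE]
  rownames(rows) <- NULL
  inv$rows <- rows
  inv
}

#' @export
print.SampleInventory <- function(x, ...) {
  cat("SampleInventory for", x$meta$sample_id, "(", x$meta$site,
      x$meta$depth_mbsf, "mbsf,", x$meta$sulfate_status, "sulfate):",
      nrow(x$rows), "rows\n")
  invisible(x)
}

#' Per-sample process-category scores
#'
#' `score(sample, category)` is the sum of variant counts over the
#' inventory rows of that category; in normalized mode each sample's row is
#' divided by its total so the proportions sum to 1 (all-zero samples stay
#' zero).
#'
#' @param inventories List of `SampleInventory` objects.
#' @param normalize Logical; default `FALSE`.
#' @param categories Category columns to report; defaults to all categories
#'   observed across the inventories.
#' @return Data frame: `sample_id` plus one column per category.
#' @export
category_scores <- function(inventories, normalize = FALSE,
                            categories = NULL) {
  if (length(inventories) == 0)
    stop("validation error: need at least one inventory")
  if (is.null(categories))
    categories <- sort(unique(unlist(lapply(inventories,
                                            function(v) v$rows$category))),
                       method = "radix")
  out <- do.call(rbind, lapply(inventories, function(inv) {
    sc <- vapply(categories, function(cat)
      sum(inv$rows$variant_count[inv$rows$category == cat]), numeric(1))
    if (normalize && sum(sc) > 0) sc <- sc / sum(sc)
    cbind(data.frame(sample_id = inv$meta$sample_id,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(sc)))
  }))
  rownames(out) <- NULL
  out
}

#' Export the lineage x gene x sample inventory table
#'
#' One row per inventory row, with sample context: columns `site,
#' depth_mbsf, sulfate_status, lineage, gene_symbol, category,
#' transcript_copies`, sorted by site, then depth ascending, then lineage,
#' then gene. Byte-deterministic.
#'
#' @param inventories List of `SampleInventory` objects.
#' @param path Optional output TSV path.
#' @return The export data frame.
#' @export
export_inventory_table <- function(inventories, path = NULL) {
  out <- do.call(rbind, lapply(inventories, function(inv) {
    if (nrow(inv$rows) == 0) return(NULL)
    data.frame(site = inv$meta$site, depth_mbsf = inv$meta$depth_mbsf,
               sulfate_status = inv$meta$sulfate_status,
               lineage = inv$rows$lineage,
               gene_symbol = inv$rows$gene_symbol,
               category = inv$rows$category,
               transcript_copies = inv$rows$variant_count,
               stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    out <- data.frame(site = character(), depth_mbsf = numeric(),
                      sulfate_status = character(), lineage = character(),
                      gene_symbol = character(), category = character(),
                      transcript_copies = integer(), stringsAsFactors = FALSE)
  out <- out[order(out$site, out$depth_mbsf, out$lineage, out$gene_symbol,
                   method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(path))
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}
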