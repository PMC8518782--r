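#' An assembled contig
#'
#' Carrier for one assembled nucleotide sequence from a sample's
#' (meta)transcriptome. The sequence is uppercase-normalized and restricted
#' to the alphabet `A, C, G, T, N`.
#'
#' @param contig_id Identifier.
#' @param seq Nucleotide string.
#' @param sample_id Sample the contig belongs to.
#' @return An object of class `Contig`.
#' @export
contig <- function(contig_id, seq, sample_id = NA_character_) {
  seq <- toupper(as.character(seq))
  if (length(seq) != 1 || nchar(seq) < 1)
    stop("validation error: contig sequence must be a non-empty string")
  if (grepl("[^ACGTN]", seq))
    stop("validation error: contig ", contig_id,
         " contains characters outside {A,C,G,T,N}")
  structure(list(contig_id = as.character(contig_id),
                 sample_id = as.character(sample_id), seq = seq),
            class = "Contig")
}

genetic_code_table <- function(table = "11") {
  code <- Biostrings::getGeneticCode(as.character(table))
  names(code) <- toupper(names(code))
  code
}

dna_revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Translate an in-frame codon sequence
#'
#' Uses the bacterial/archaeal genetic code (NCBI translation table 11) by
#' default. Codons containing `N` (or any non-ACGT character) translate to
#' `X`; stop codons translate to `*`.
#'
#' @param codon_seq Nucleotide string whose length is divisible by 3.
#' @param table NCBI genetic code id (passed to
#'   [Biostrings::getGeneticCode()]).
#' @return The protein string (possibly containing `*` and `X`).
#' @export
translate <- function(codon_seq, table = "11") {
  codon_seq <- toupper(as.character(codon_seq))
  L <- nchar(codon_seq)
  if (L %% 3 != 0)
    stop("validation error: sequence length ", L, " is not divisible by 3")
  if (L == 0) return("")
  code <- genetic_code_table(table)
  codons <- substring(codon_seq, seq(1, L - 2, 3), seq(3, L, 3))
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Six-frame ORF extraction
#'
#' Finds all maximal stop-free stretches in the six reading frames of a
#' contig, stop-to-stop (no initiator codon is required, so gene fragments
#' on fragmentary transcripts are retained), translates them with the
#' bacterial/archaeal code and keeps those of at least `min_aa_len`
#' residues. Coordinates are always reported 0-based half-open on the
#' forward strand; rows are ordered by `nt_start`, then strand (`+` first),
#' then `nt_end`.
#'
#' @param contig A [contig()] (or anything coercible: a list with
#'   `contig_id` and `seq`).
#' @param min_aa_len Minimum ORF length in amino acids. Default 30.
#' @param table Genetic code id. Default `"11"`.
#' @return Data frame with columns `orf_id, contig_id, sample_id, strand,
#'   frame, nt_start, nt_end, aa_seq`. Zero rows when nothing qualifies.
#' @export
six_frame_orfs <- function(contig, min_aa_len = 30, table = "11") {
  if (!inherits(contig, "Contig"))
    contig <- contig(contig$contig_id, contig$seq,
                     contig$sample_id %||% NA_character_)
  if (min_aa_len < 1) stop("validation error: min_aa_len must be >= 1")
  L <- nchar(contig$seq)
  rows <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") contig$seq else dna_revcomp(contig$seq)
    for (frame in 0:2) {
      ncod <- (L - frame) %/% 3
      if (ncod < min_aa_len) next
      aa <- strsplit(translate(substr(s, frame + 1, frame + 3 * ncod), table),
                     "")[[1]]
      r <- rle(aa != "*")
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      for (run in which(r$values & r$lengths >= min_aa_len)) {
        a0 <- starts[run]; a1 <- ends[run]
        s_local <- frame + 3 * (a0 - 1)     # 0-based on this strand
        e_local <- frame + 3 * a1
        rows[[length(rows) + 1]] <- data.frame(
          contig_id = contig$contig_id, sample_id = contig$sample_id,
          strand = strand, frame = frame,
          nt_start = if (strand == "+") s_local else L - e_local,
          nt_end = if (strand == "+") e_local else L - s_local,
          aa_seq = paste(aa[a0:a1], collapse = ""),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0)
    return(data.frame(orf_id = character(), contig_id = character(),
                      sample_id = character(), strand = character(),
                      frame = integer(), nt_start = integer(),
                      nt_end = integer(), aa_seq = character(),
                      stringsAsFactors = FALSE))
  df <- do.call(rbind, rows)
  df <- df[order(df$nt_start, df$strand, df$nt_end, method = "radix"), ,
           drop = FALSE]
  df <- cbind(orf_id = paste0(contig$contig_id, ".o", seq_len(nrow(df))), df,
              stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}

#' Extract ORFs from every contig of a multi-FASTA
#'
#' @param fasta Path to a nucleotide multi-FASTA, or a named
#'   `Biostrings::DNAStringSet`.
#' @param sample_id Sample identifier attached to each ORF.
#' @inheritParams six_frame_orfs
#' @return Combined ORF table (see [six_frame_orfs()]).
#' @export
orf_scan <- function(fasta, sample_id = NA_character_, min_aa_len = 30,
                     table = "11") {
  seqs <- if (methods::is(fasta, "DNAStringSet")) fasta
          else Biostrings::readDNAStringSet(fasta)
  empty <- data.frame(orf_id = character(), contig_id = character(),
                      sample_id = character(), strand = character(),
                      frame = integer(), nt_start = integer(),
                      nt_end = integer(), aa_seq = character(),
                      stringsAsFactors = FALSE)
  if (length(seqs) == 0) return(empty)
  out <- lapply(seq_along(seqs), function(i)
    six_frame_orfs(contig(names(seqs)[i], as.character(seqs[[i]]), sample_id),
                   min_aa_len = min_aa_len, table = table))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Write ORF outputs
#'
#' Emits the protein multi-FASTA (headers encode contig, strand and
#' forward-strand coordinates) and the ORF table TSV.
#'
#' @param orfs ORF table from [six_frame_orfs()]/[orf_scan()].
#' @param faa_path,tsv_path Output paths (either may be `NULL` to skip).
#' @return `orfs`, invisibly.
#' @export
write_orfs <- function(orfs, faa_path = NULL, tsv_path = NULL) {
  if (!is.null(faa_path)) {
    aa <- Biostrings::AAStringSet(orfs$aa_seq)
    names(aa) <- sprintf("%s %s|%s|%d-%d", orfs$orf_id, orfs$contig_id,
                         orfs$strand, orfs$nt_start, orfs$nt_end)
    Biostrings::writeXStringSet(aa, faa_path)
  }
  if (!is.null(tsv_path))
    write.table(orfs, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(orfs)
}
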