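AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_protein <- function(len, alphabet = AA) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

## maximum absolute parameter difference between two ProfileHMMs
hmm_param_diff <- function(a, b) {
  max(abs(a$match_emissions - b$match_emissions),
      abs(a$insert_emissions - b$insert_emissions),
      abs(a$transitions - b$transitions),
      abs(a$background - b$background))
}

## compare score_local against the enumeration oracle on one case;
## returns the absolute score difference (0 when both report no hit)
oracle_diff <- function(hmm, protein) {
  a <- score_local(hmm, protein)
  b <- score_local_reference(hmm, protein)
  if (is.null(a) && is.null(b)) return(0)
  if (is.null(a)) return(abs(b$bit_score))
  if (is.null(b)) return(abs(a$bit_score))
  abs(a$bit_score - b$bit_score)
}

## a sharply peaked profile: match state k emits consensus[k] with
## probability `peak`, the rest spread uniformly
peaked_hmm <- function(consensus, peak = 0.99) {
  chars <- strsplit(consensus, "")[[1]]
  M <- length(chars)
  me <- matrix((1 - peak) / 19, M, 20, dimnames = list(NULL, AA))
  for (k in seq_len(M)) me[k, chars[k]] <- peak
  trans <- matrix(0, M + 1, 7,
                  dimnames = list(NULL, c("MM", "MI", "MD", "IM", "II",
                                          "DM", "DD")))
  trans[, c("MM", "MI", "MD")] <- rep(c(0.9, 0.05, 0.05), each = M + 1)
  trans[, c("IM", "II")] <- rep(c(0.8, 0.2), each = M + 1)
  trans[, c("DM", "DD")] <- rep(c(0.8, 0.2), each = M + 1)
  profile_hmm("peaked", me, matrix(1 / 20, M, 20), trans)
}

## tiny synthetic scenario (fast variant of the demo conditions)
tiny_demo <- function(dir, seed = 42, n_decoy_orfs = 2, n_random_contigs = 3) {
  demo_pipeline(dir, seed = seed, n_decoy_orfs = n_decoy_orfs,
                n_random_contigs = n_random_contigs)
}

dir_md5 <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE, full.names = TRUE))
  out <- tools::md5sum(files)
  names(out) <- sub(paste0("^", dir), "", names(out))
  out
}
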