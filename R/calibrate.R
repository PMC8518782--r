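#' Bit-score cutoff pair for one profile HMM
#'
#' `trusted` is the minimum score observed among curated true homologs,
#' `noise` the maximum among curated non-target homologs (`-Inf` when no
#' false positives exist), and `gathering` the operational acceptance
#' threshold applied by [competitive_assign()]. When the labeled sets are
#' separable, `noise < gathering <= trusted`.
#'
#' @param trusted,noise,gathering Bit scores.
#' @param separable Logical; whether the labeled score sets were separable.
#' @return An object of class `CutoffPair`.
#' @export
cutoff_pair <- function(trusted, noise, gathering, separable) {
  if (isTRUE(separable) &&
      !(noise < gathering && gathering <= trusted))
    stop("invalid CutoffPair: separable requires noise < gathering <= trusted")
  structure(list(trusted = trusted, noise = noise, gathering = gathering,
                 separable = isTRUE(separable)),
            class = "CutoffPair")
}

#' Derive bit-score cutoffs from labeled true/false homolog scores
#'
#' `trusted = min(tp_scores)`, `noise = max(fp_scores)` (or `-Inf` with no
#' false positives). If `trusted > noise` the sets are separable and
#' `gathering` is their midpoint (`trusted` itself when there are no false
#' positives). Otherwise the sets overlap: `separable = FALSE` and
#' `gathering` is the threshold maximizing classification accuracy over the
#' labeled scores (a score is called positive when `score >= gathering`),
#' with ties broken toward the larger threshold.
#'
#' @param tp_scores Non-empty numeric vector of bit scores of curated true
#'   homologs.
#' @param fp_scores Numeric vector of bit scores of curated non-target
#'   homologs (may be empty).
#' @return A [cutoff_pair()].
#' @export
derive_cutoffs <- function(tp_scores, fp_scores = numeric(0)) {
  tp_scores <- as.numeric(tp_scores); fp_scores <- as.numeric(fp_scores)
  if (length(tp_scores) == 0)
    stop("validation error: tp_scores must be non-empty")
  if (any(!is.finite(tp_scores)) || any(!is.finite(fp_scores)))
    stop("validation error: all labeled scores must be finite")
  trusted <- min(tp_scores)
  noise <- if (length(fp_scores)) max(fp_scores) else -Inf
  if (trusted > noise) {
    gathering <- if (is.finite(noise)) (trusted + noise) / 2 else trusted
    return(cutoff_pair(trusted, noise, gathering, TRUE))
  }
  ## overlapping sets: exhaustive threshold search over the observed scores
  ## (plus one value above all of them, i.e. "reject everything")
  cands <- sort(unique(c(tp_scores, fp_scores, max(tp_scores, fp_scores) + 1)))
  acc <- vapply(cands, function(t)
    sum(tp_scores >= t) + sum(fp_scores < t), numeric(1))
  gathering <- max(cands[acc == max(acc)])
  cutoff_pair(trusted, noise, gathering, FALSE)
}

#' Competitive decoy screening of one ORF's scores
#'
#' Given one ORF's bit scores against every target and decoy HMM of the
#' registry, the best-scoring model wins the ORF. A win by a decoy model
#' (a profile of a known non-target homolog family) rejects the ORF; a win
#' by a target model is accepted only when the score reaches that model's
#' gathering cutoff (inclusive). Ties go to the decoy; among tied targets
#' the lexicographically smallest HMM name wins.
#'
#' @param orf_scores Named numeric vector, `hmm_name -> bit score`,
#'   covering every HMM in the registry (use `-Inf` for "no positive local
#'   alignment").
#' @param registry Registry table (see [load_registry()]): columns
#'   `gene_symbol, category, hmm_name, role, gathering`.
#' @return The accepted gene symbol, or `NA_character_` when the ORF is
#'   screened out.
#' @export
competitive_assign <- function(orf_scores, registry) {
  missing <- setdiff(registry$hmm_name, names(orf_scores))
  if (length(missing))
    stop("validation error: no score supplied for HMM(s): ",
         paste(missing, collapse = ", "))
  sc <- orf_scores[registry$hmm_name]
  best <- max(sc)
  tied <- registry$hmm_name[sc == best]
  roles <- registry$role[match(tied, registry$hmm_name)]
  if (any(roles == "decoy")) return(NA_character_)
  win <- sort(tied, method = "radix")[1]
  row <- registry[registry$hmm_name == win, , drop = FALSE][1, ]
  if (is.na(row$gathering))
    stop("configuration error: target HMM '", win, "' lacks cutoffs")
  if (best >= row$gathering) row$gene_symbol else NA_character_
}

#' Write a calibration report
#'
#' One row per HMM: `hmm_name, trusted, noise, gathering, separable, n_tp,
#' n_fp`.
#'
#' @param cutoffs Named list of [cutoff_pair()]s (names = HMM names).
#' @param n_tp,n_fp Named integer vectors of labeled set sizes.
#' @param path Optional output TSV path.
#' @return The report data frame.
#' @export
calibration_report <- function(cutoffs, n_tp, n_fp, path = NULL) {
  df <- do.call(rbind, lapply(names(cutoffs), function(nm) {
    co <- cutoffs[[nm]]
    data.frame(hmm_name = nm, trusted = co$trusted, noise = co$noise,
               gathering = co$gathering, separable = co$separable,
               n_tp = unname(n_tp[nm]), n_fp = unname(n_fp[nm]),
               stringsAsFactors = FALSE)
  }))
  df <- df[order(df$hmm_name, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  if (!is.null(path))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  df
}
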