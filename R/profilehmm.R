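#' Construct a profile hidden Markov model
#'
#' A `ProfileHMM` is a position-specific probabilistic model of a protein
#' family with match/insert/delete states. It stores per-node emission and
#' transition probabilities (probability space, not negative logs) over the
#' 20 standard amino acids, a background (null) distribution, and optional
#' bit-score cutoffs.
#'
#' @param name Identifier string.
#' @param match_emissions `M x 20` matrix of match-state emission
#'   probabilities, rows = nodes 1..M, columns in the fixed alphabet order
#'   `ACDEFGHIKLMNPQRSTVWY`.
#' @param insert_emissions `M x 20` matrix of insert-state emission
#'   probabilities.
#' @param transitions `(M+1) x 7` matrix of transition probabilities, rows =
#'   nodes 0..M (node 0 is the begin node), columns `MM, MI, MD, IM, II,
#'   DM, DD` (e.g. `MM` at row k is the M_k -> M_{k+1} probability; at the
#'   last node the `M*` transitions lead to the end state).
#' @param background Length-20 background probability vector.
#' @param cutoffs Optional [cutoff_pair()] of bit-score thresholds.
#' @param tol Tolerance used when validating the probability-sum
#'   invariants; parsers reading fixed-precision text pass a looser value.
#' @return An object of class `ProfileHMM`.
#' @seealso [parse_hmm3()], [write_hmm3()], [build_from_alignment()],
#'   [score_local()]
#' @export
profile_hmm <- function(name, match_emissions, insert_emissions, transitions,
                        background = rep(1 / 20, 20), cutoffs = NULL,
                        tol = 1e-6) {
  match_emissions <- as.matrix(match_emissions)
  insert_emissions <- as.matrix(insert_emissions)
  transitions <- as.matrix(transitions)
  colnames(match_emissions) <- AA20
  colnames(insert_emissions) <- AA20
  colnames(transitions) <- TRANS7
  background <- as.numeric(background)
  names(background) <- AA20
  h <- structure(
    list(name = as.character(name), length = nrow(match_emissions),
         alphabet = AA20, match_emissions = match_emissions,
         insert_emissions = insert_emissions, transitions = transitions,
         background = background, cutoffs = cutoffs),
    class = "ProfileHMM")
  validate_profile_hmm(h, tol = tol)
  h
}

#' Validate ProfileHMM invariants
#'
#' Checks that every emission row, transition triple/pair and the background
#' distribution sum to 1 (within `tol`) and that all probabilities lie in
#' \[0, 1\]. Stops with a message naming the failed invariant.
#'
#' @param h A `ProfileHMM`.
#' @param tol Numerical tolerance on the sums.
#' @return `h`, invisibly.
#' @export
validate_profile_hmm <- function(h, tol = 1e-6) {
  stopifnot(inherits(h, "ProfileHMM"))
  M <- h$length
  if (M < 1) stop("invalid ProfileHMM: length must be >= 1")
  if (nrow(h$match_emissions) != M || nrow(h$insert_emissions) != M ||
      nrow(h$transitions) != M + 1)
    stop("invalid ProfileHMM: matrix dimensions inconsistent with length ", M)
  if (ncol(h$match_emissions) != 20 || ncol(h$insert_emissions) != 20)
    stop("invalid ProfileHMM: emission matrices must have 20 columns")
  allp <- c(h$match_emissions, h$insert_emissions, h$transitions, h$background)
  if (any(!is.finite(allp)) || any(allp < 0) || any(allp > 1 + tol))
    stop("invalid ProfileHMM: probabilities must lie in [0, 1]")
  chk <- function(x, what) {
    if (any(abs(x - 1) > tol))
      stop("invalid ProfileHMM: ", what, " does not sum to 1 (node ",
           which(abs(x - 1) > tol)[1] - 1L, ")")
  }
  chk(rowSums(h$match_emissions), "a match emission row")
  chk(rowSums(h$insert_emissions), "an insert emission row")
  chk(rowSums(h$transitions[, c("MM", "MI", "MD"), drop = FALSE]),
      "a match transition triple")
  chk(rowSums(h$transitions[, c("IM", "II"), drop = FALSE]),
      "an insert transition pair")
  chk(rowSums(h$transitions[, c("DM", "DD"), drop = FALSE]),
      "a delete transition pair")
  if (abs(sum(h$background) - 1) > tol)
    stop("invalid ProfileHMM: background does not sum to 1")
  invisible(h)
}

#' @export
print.ProfileHMM <- function(x, ...) {
  cat("ProfileHMM", x$name, "with", x$length, "match states\n")
  if (!is.null(x$cutoffs))
    cat("  gathering cutoff:", format(x$cutoffs$gathering), "bits\n")
  invisible(x)
}

#' A scored local profile-HMM hit
#'
#' @param orf_id Identifier of the scored sequence.
#' @param hmm_name Name of the profile.
#' @param bit_score Log2-odds score (bits) of the best local alignment.
#' @param seq_start,seq_end 0-based half-open residue interval on the
#'   protein.
#' @param node_start,node_end 0-based half-open node interval on the
#'   profile.
#' @return An object of class `HmmHit`.
#' @export
hmm_hit <- function(orf_id, hmm_name, bit_score, seq_start, seq_end,
                    node_start, node_end) {
  if (!is.finite(bit_score)) stop("invalid HmmHit: bit_score must be finite")
  if (!(seq_start < seq_end)) stop("invalid HmmHit: seq_start must be < seq_end")
  if (!(node_start <= node_end))
    stop("invalid HmmHit: node_start must be <= node_end")
  structure(list(orf_id = orf_id, hmm_name = hmm_name,
                 bit_score = bit_score,
                 seq_start = as.integer(seq_start),
                 seq_end = as.integer(seq_end),
                 node_start = as.integer(node_start),
                 node_end = as.integer(node_end)),
            class = "HmmHit")
}

## ---- HMMER3 ASCII ----------------------------------------------------------

hmm3_num <- function(tok, where) {
  out <- ifelse(tok == "*", Inf, suppressWarnings(as.numeric(tok)))
  if (any(is.na(out)))
    stop("parse error: non-numeric token '", tok[is.na(out)][1], "' in ", where)
  out
}

#' Read profile HMMs from HMMER3 ASCII text
#'
#' Parses the `HMMER3/f` ASCII profile format: parameters are encoded as
#' negative natural logarithms of probabilities, with `*` meaning
#' probability zero. The `COMPO` line, when present, is read as the model's
#' background (null) distribution; without it the background is uniform.
#' `GA`/`TC`/`NC` cutoff lines populate the model's [cutoff_pair()].
#'
#' @param x A file path, a single string containing the full text, or a
#'   character vector of lines.
#' @return A list of [profile_hmm()] objects.
#' @export
parse_hmm3 <- function(x) {
  lines <- if (length(x) == 1 && file.exists(x)) readLines(x)
           else if (length(x) == 1 && grepl("\n", x)) strsplit(x, "\n")[[1]]
           else as.character(x)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0 || !grepl("^HMMER3", lines[1]))
    stop("format error: expected a HMMER3 header, got: ",
         if (length(lines)) lines[1] else "<empty stream>")
  recs <- list()
  i <- 1
  while (i <= length(lines)) {
    if (!grepl("^HMMER3", lines[i]))
      stop("format error: expected a HMMER3 header, got: ", lines[i])
    i <- i + 1
    name <- NA_character_; leng <- NA_integer_
    ga <- tc <- nc <- NA_real_
    while (i <= length(lines) && !grepl("^HMM\\s", lines[i])) {
      toks <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      key <- toks[1]
      if (key == "NAME") name <- toks[2]
      else if (key == "LENG") leng <- as.integer(toks[2])
      else if (key == "ALPH" && tolower(toks[2]) != "amino")
        stop("parse error: only amino-acid profiles are supported")
      else if (key == "GA") ga <- as.numeric(sub(";", "", toks[2]))
      else if (key == "TC") tc <- as.numeric(sub(";", "", toks[2]))
      else if (key == "NC") nc <- as.numeric(sub(";", "", toks[2]))
      i <- i + 1
    }
    if (i > length(lines)) stop("format error: missing HMM line in record ", name)
    if (is.na(leng)) stop("parse error: record ", name, " lacks a LENG line")
    i <- i + 2                      # skip HMM alphabet line + transition header
    background <- rep(1 / 20, 20)
    toks <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (toks[1] == "COMPO") {
      if (length(toks) != 21)
        stop("parse error: COMPO line must carry 20 values")
      background <- exp(-hmm3_num(toks[-1], "COMPO line"))
      i <- i + 1
    }
    ## node 0: insert emission line (ignored; inserts are per-node 1..M
    ## in this model) then begin-state transition line
    i <- i + 1
    toks <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(toks) != 7)
      stop("parse error: node 0 transition line must carry 7 values")
    trans <- matrix(0, leng + 1, 7, dimnames = list(NULL, TRANS7))
    trans[1, ] <- exp(-hmm3_num(toks, "node 0 transitions"))
    i <- i + 1
    me <- matrix(0, leng, 20)
    ie <- matrix(0, leng, 20)
    for (k in seq_len(leng)) {
      toks <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      if (toks[1] != as.character(k))
        stop("parse error: expected node ", k, ", got line: ", lines[i])
      if (length(toks) < 21)
        stop("parse error: match emission row for node ", k,
             " has fewer than 20 values")
      me[k, ] <- exp(-hmm3_num(toks[2:21], paste("match row, node", k)))
      toks <- strsplit(trimws(lines[i + 1]), "\\s+")[[1]]
      if (length(toks) != 20)
        stop("parse error: insert emission row for node ", k,
             " must carry 20 values")
      ie[k, ] <- exp(-hmm3_num(toks, paste("insert row, node", k)))
      toks <- strsplit(trimws(lines[i + 2]), "\\s+")[[1]]
      if (length(toks) != 7)
        stop("parse error: transition row for node ", k, " must carry 7 values")
      trans[k + 1, ] <- exp(-hmm3_num(toks, paste("transition row, node", k)))
      i <- i + 3
    }
    if (i > length(lines) || trimws(lines[i]) != "//")
      stop("format error: record ", name, " not terminated by //")
    i <- i + 1
    cutoffs <- NULL
    if (!is.na(ga)) {
      noise <- if (is.na(nc)) -Inf else nc
      trusted <- if (is.na(tc)) ga else tc
      cutoffs <- cutoff_pair(trusted = trusted, noise = noise, gathering = ga,
                             separable = noise < ga && ga <= trusted)
    }
    ## values are re-exponentiated from fixed-precision text: five decimal
    ## digits of -ln p leave row sums up to ~1e-5 from 1
    recs[[length(recs) + 1]] <-
      profile_hmm(name = name, match_emissions = me, insert_emissions = ie,
                  transitions = trans, background = background,
                  cutoffs = cutoffs, tol = 1e-4)
  }
  recs
}

#' Write a profile HMM as HMMER3 ASCII text
#'
#' Emits the `HMMER3/f` dialect read back by [parse_hmm3()]: negative
#' natural logs, `*` for probability zero, background on the `COMPO` line,
#' and `GA`/`TC`/`NC` lines when the model carries cutoffs.
#'
#' @param hmm A valid `ProfileHMM`.
#' @param path Optional file path; when given the text is written there.
#' @return The lines of the record, invisibly when `path` is given.
#' @export
write_hmm3 <- function(hmm, path = NULL) {
  validate_profile_hmm(hmm)
  enc <- function(p) ifelse(p <= 0, "*", sprintf("%.7f", -log(p)))
  row <- function(p) paste(sprintf("%9s", enc(p)), collapse = " ")
  M <- hmm$length
  out <- c(
    sprintf("HMMER3/f [markerscan %s]",
            as.character(utils::packageVersion("markerscan"))),
    paste("NAME ", hmm$name),
    paste("LENG ", M),
    "ALPH  amino")
  if (!is.null(hmm$cutoffs)) {
    co <- hmm$cutoffs
    out <- c(out, sprintf("GA    %.5f %.5f;", co$gathering, co$gathering),
             sprintf("TC    %.5f %.5f;", co$trusted, co$trusted))
    if (is.finite(co$noise))
      out <- c(out, sprintf("NC    %.5f %.5f;", co$noise, co$noise))
  }
  out <- c(out,
    paste("HMM     ", paste(sprintf("%9s", AA20), collapse = " ")),
    paste("        ", paste(sprintf("%9s",
          c("m->m", "m->i", "m->d", "i->m", "i->i", "d->m", "d->d")),
          collapse = " ")),
    paste("  COMPO ", row(hmm$background)),
    paste("        ", row(hmm$background)),        # node-0 insert emissions
    paste("        ", row(hmm$transitions[1, ])))
  for (k in seq_len(M)) {
    out <- c(out,
      paste(sprintf("%7d ", k), row(hmm$match_emissions[k, ])),
      paste("        ", row(hmm$insert_emissions[k, ])),
      paste("        ", row(hmm$transitions[k + 1, ])))
  }
  out <- c(out, "//")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

## ---- construction from seed alignments -------------------------------------

#' Build a profile HMM from a gapped protein alignment
#'
#' Columns whose non-gap fraction is at least `match_fraction` become match
#' states, in order. Match emissions are Laplace-smoothed column counts,
#' `(count + pseudocount) / (column total + 20 * pseudocount)`; transitions
#' are counted from each sequence's observed match/insert/delete path with
#' the same pseudocount; the background is the overall residue frequency of
#' the alignment (smoothed); insert states emit from the background, so
#' inserted residues carry zero log-odds.
#'
#' @param aligned Character vector (or `Biostrings::AAStringSet`) of
#'   equal-length gapped protein sequences; gaps are `-` or `.`.
#' @param pseudocount Positive Laplace smoothing weight. Default 1.
#' @param match_fraction Column occupancy threshold in (0, 1\] for match
#'   states. Default 0.5.
#' @param name Model name.
#' @return A [profile_hmm()].
#' @export
build_from_alignment <- function(aligned, pseudocount = 1,
                                 match_fraction = 0.5, name = "family") {
  if (methods::is(aligned, "XStringSet")) aligned <- as.character(aligned)
  aligned <- toupper(as.character(aligned))
  if (length(aligned) < 2)
    stop("validation error: need at least 2 aligned sequences")
  if (length(unique(nchar(aligned))) != 1)
    stop("validation error: aligned sequences have inconsistent lengths")
  if (nchar(aligned[1]) < 1)
    stop("validation error: alignment length must be >= 1")
  if (pseudocount <= 0) stop("validation error: pseudocount must be positive")
  if (match_fraction <= 0 || match_fraction > 1)
    stop("validation error: match_fraction must lie in (0, 1]")

  mat <- do.call(rbind, strsplit(aligned, ""))
  is_res <- !(mat %in% c("-", ".")); dim(is_res) <- dim(mat)
  match_col <- colMeans(is_res) >= match_fraction
  M <- sum(match_col)
  if (M == 0) stop("construction error: no column passes the match rule")

  count20 <- function(chars) {
    tab <- table(factor(chars[chars %in% AA20], levels = AA20))
    as.numeric(tab)
  }
  me <- t(vapply(which(match_col), function(j) {
    cnt <- count20(mat[is_res[, j], j])
    (cnt + pseudocount) / (sum(cnt) + 20 * pseudocount)
  }, numeric(20)))
  bg_cnt <- count20(mat[is_res])
  background <- (bg_cnt + pseudocount) / (sum(bg_cnt) + 20 * pseudocount)
  ie <- matrix(rep(background, each = M), nrow = M)

  ## transition counts along each sequence's state path; begin = node 0,
  ## end counted as a *->M transition out of the last node
  cnt <- matrix(0, M + 1, 7, dimnames = list(NULL, TRANS7))
  node_of_col <- cumsum(match_col)          # insert cols belong to node k
  for (s in seq_len(nrow(mat))) {
    type <- "M"; node <- 0L
    step <- function(to_type, to_node) {
      key <- paste0(type, to_type)
      ## plan7 has no D->I or I->D transition; such steps (a deletion
      ## abutting an insertion in the alignment) update the state without
      ## contributing a count
      if (key %in% TRANS7)
        cnt[node + 1, key] <<- cnt[node + 1, key] + 1
      type <<- to_type; node <<- to_node
    }
    for (j in seq_len(ncol(mat))) {
      if (match_col[j]) {
        if (is_res[s, j]) step("M", node_of_col[j]) else step("D", node_of_col[j])
      } else if (is_res[s, j]) {
        if (type != "I" || node != node_of_col[j]) step("I", node_of_col[j])
        else cnt[node + 1, "II"] <- cnt[node + 1, "II"] + 1
      }
    }
    step("M", node + 1L)                    # to end state
  }
  norm <- function(x, pc) (x + pc) / (sum(x) + length(x) * pc)
  trans <- matrix(0, M + 1, 7, dimnames = list(NULL, TRANS7))
  for (k in 0:M) {
    r <- k + 1
    if (k < M) {
      trans[r, c("MM", "MI", "MD")] <- norm(cnt[r, c("MM", "MI", "MD")], pseudocount)
      if (k >= 1)
        trans[r, c("DM", "DD")] <- norm(cnt[r, c("DM", "DD")], pseudocount)
      else
        trans[r, c("DM", "DD")] <- c(1, 0)  # no delete state at the begin node
    } else {
      ## last node: no node M+1 insertable targets for MD/DD
      trans[r, c("MM", "MI")] <- norm(cnt[r, c("MM", "MI")], pseudocount)
      trans[r, "MD"] <- 0
      trans[r, c("DM", "DD")] <- c(1, 0)
    }
    trans[r, c("IM", "II")] <- norm(cnt[r, c("IM", "II")], pseudocount)
  }
  profile_hmm(name = name, match_emissions = me, insert_emissions = ie,
              transitions = trans, background = background)
}

## ---- scoring ---------------------------------------------------------------

protein_index <- function(protein) {
  if (!is.character(protein) || length(protein) != 1 || nchar(protein) < 1)
    stop("validation error: protein must be a non-empty string")
  chars <- strsplit(toupper(protein), "")[[1]]
  idx <- match(chars, AA20)
  bad <- is.na(idx) & chars != "X"
  if (any(bad))
    stop("validation error: protein contains invalid residue '",
         chars[bad][1], "'")
  idx                                        # NA marks 'X'
}

#' Score a protein against a profile HMM (best local alignment)
#'
#' Local Viterbi scoring: the best alignment of any subsequence of the
#' protein against any contiguous node interval of the profile, with
#' uniform entry into any match state, free exit after any match state and
#' no cost for unaligned flanks. The bit score is
#' `log2 P(aligned residues, path | hmm) / P(aligned residues | background)`.
#' Residue `X` carries zero log-odds. Dynamic programming runs in log2
#' space; ties are broken toward the smallest `seq_start`, then the
#' smallest `node_start`.
#'
#' @param hmm A `ProfileHMM`.
#' @param protein Protein string over the 20-letter alphabet (plus `X`).
#' @param orf_id Identifier recorded on the returned hit.
#' @return An [hmm_hit()] with 0-based half-open sequence and node
#'   intervals, or `NULL` when no alignment scores above 0 bits.
#' @export
score_local <- function(hmm, protein, orf_id = NA_character_) {
  stopifnot(inherits(hmm, "ProfileHMM"))
  idx <- protein_index(protein)
  n <- length(idx); M <- hmm$length
  mlo <- log2(hmm$match_emissions) - rep(log2(hmm$background), each = M)
  ilo <- log2(hmm$insert_emissions) - rep(log2(hmm$background), each = M)
  sm <- matrix(0, M, n); si <- matrix(0, M, n)
  known <- !is.na(idx)
  sm[, known] <- mlo[, idx[known], drop = FALSE]
  si[, known] <- ilo[, idx[known], drop = FALSE]
  tl <- log2(hmm$transitions)
  res <- viterbi_local_cpp(sm, si, tl)
  if (!is.finite(res$score) || res$score <= 0) return(NULL)
  hmm_hit(orf_id = orf_id, hmm_name = hmm$name, bit_score = res$score,
          seq_start = res$seq_start, seq_end = res$seq_end,
          node_start = res$node_start, node_end = res$node_end)
}

#' Reference local scorer by exhaustive path enumeration
#'
#' Independent implementation of the [score_local()] contract used for
#' validation: enumerates every local alignment (every subsequence, node
#' interval and match/insert/delete state path) and accumulates
#' probabilities in probability space, taking a single log2 at the end.
#' Exponential in sequence and model size; intended for tiny models only
#' (M <= 3, short peptides).
#'
#' @inheritParams score_local
#' @return Same contract as [score_local()].
#' @export
score_local_reference <- function(hmm, protein, orf_id = NA_character_) {
  stopifnot(inherits(hmm, "ProfileHMM"))
  idx <- protein_index(protein)
  n <- length(idx); M <- hmm$length
  tr <- hmm$transitions
  bg <- hmm$background
  modds <- function(k, i) if (is.na(idx[i])) 1 else
    hmm$match_emissions[k, idx[i]] / bg[idx[i]]
  iodds <- function(k, i) if (is.na(idx[i])) 1 else
    hmm$insert_emissions[k, idx[i]] / bg[idx[i]]

  best <- NULL   # list(odds, si, sk, ei, ek)
  consider <- function(cand) {
    if (is.null(best) || cand$odds > best$odds ||
        (cand$odds == best$odds &&
         (cand$si < best$si || (cand$si == best$si && cand$sk < best$sk))))
      best <<- cand
  }
  ## walk(type, node, i, odds): state just emitted/occupied; i = residues used
  walk <- function(type, node, i, odds, si, sk) {
    if (odds == 0) return()
    if (type == "M") consider(list(odds = odds, si = si, sk = sk,
                                   ei = i, ek = node))
    if (type == "M") {
      if (node < M && i < n)
        walk("M", node + 1, i + 1,
             odds * tr[node + 1, "MM"] * modds(node + 1, i + 1), si, sk)
      if (i < n)
        walk("I", node, i + 1,
             odds * tr[node + 1, "MI"] * iodds(node, i + 1), si, sk)
      if (node < M)
        walk("D", node + 1, i, odds * tr[node + 1, "MD"], si, sk)
    } else if (type == "I") {
      if (node < M && i < n)
        walk("M", node + 1, i + 1,
             odds * tr[node + 1, "IM"] * modds(node + 1, i + 1), si, sk)
      if (i < n)
        walk("I", node, i + 1,
             odds * tr[node + 1, "II"] * iodds(node, i + 1), si, sk)
    } else {
      if (node < M && i < n)
        walk("M", node + 1, i + 1,
             odds * tr[node + 1, "DM"] * modds(node + 1, i + 1), si, sk)
      if (node < M)
        walk("D", node + 1, i, odds * tr[node + 1, "DD"], si, sk)
    }
  }
  for (i0 in seq_len(n))
    for (k0 in seq_len(M))
      walk("M", k0, i0, (1 / M) * modds(k0, i0), i0, k0)
  if (is.null(best)) return(NULL)
  score <- log2(best$odds)
  if (!is.finite(score) || score <= 0) return(NULL)
  hmm_hit(orf_id = orf_id, hmm_name = hmm$name, bit_score = score,
          seq_start = best$si - 1, seq_end = best$ei,
          node_start = best$sk - 1, node_end = best$ek)
}

#' Random valid profile HMMs for validation
#'
#' Draws a random `ProfileHMM` with Dirichlet(1)-distributed emission and
#' transition rows; with probability `p_zero` one transition per row is set
#' to exact zero (exercising the `*` encoding). Deterministic under `seed`.
#'
#' @param M Number of match states.
#' @param seed Optional integer seed.
#' @param p_zero Probability that a transition row carries an exact zero.
#' @return A [profile_hmm()].
#' @export
random_profile_hmm <- function(M = 2, seed = NULL, p_zero = 0.2) {
  gen <- function() {
    rdir <- function(k) { x <- stats::rgamma(k, 1); x / sum(x) }
    me <- t(vapply(seq_len(M), function(i) rdir(20), numeric(20)))
    ie <- t(vapply(seq_len(M), function(i) rdir(20), numeric(20)))
    trans <- matrix(0, M + 1, 7, dimnames = list(NULL, TRANS7))
    for (r in seq_len(M + 1)) {
      tri <- rdir(3)
      if (stats::runif(1) < p_zero) { tri[sample(3, 1)] <- 0; tri <- tri / sum(tri) }
      trans[r, c("MM", "MI", "MD")] <- tri
      trans[r, c("IM", "II")] <- rdir(2)
      trans[r, c("DM", "DD")] <- rdir(2)
    }
    profile_hmm(name = sprintf("rand%d", M), match_emissions = me,
                insert_emissions = ie, transitions = trans,
                background = rdir(20))
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Write hits as TSV
#'
#' Columns `orf_id, hmm_name, bit_score, seq_start, seq_end, node_start,
#' node_end`; intervals are 0-based half-open.
#'
#' @param hits List of [hmm_hit()] objects (or a data frame already in hit
#'   layout).
#' @param path Output file.
#' @return The hit table, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  df <- if (is.data.frame(hits)) hits else
    do.call(rbind, lapply(hits, function(h)
      data.frame(orf_id = h$orf_id, hmm_name = h$hmm_name,
                 bit_score = h$bit_score, seq_start = h$seq_start,
                 seq_end = h$seq_end, node_start = h$node_start,
                 node_end = h$node_end, stringsAsFactors = FALSE)))
  if (is.null(df))
    df <- data.frame(orf_id = character(), hmm_name = character(),
                     bit_score = numeric(), seq_start = integer(),
                     seq_end = integer(), node_start = integer(),
                     node_end = integer())
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
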