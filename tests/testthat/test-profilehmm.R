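test_that("a handcrafted single-node HMMER3 record parses to probabilities", {
  val <- "2.99573"   # -ln 0.05
  txt <- c("HMMER3/f [test]",
           "NAME  toy",
           "LENG  1",
           "ALPH  amino",
           "HMM   A C D E F G H I K L M N P Q R S T V W Y",
           "      m->m m->i m->d i->m i->i d->m d->d",
           paste("     ", paste(rep(val, 20), collapse = " ")),  # node-0 I
           "      0.40546 1.09861 *       0.69315 0.69315 0.00000 *",
           paste("1    ", paste(rep(val, 20), collapse = " ")),
           paste("     ", paste(rep(val, 20), collapse = " ")),
           "      0.00000 *       *       0.69315 0.69315 0.00000 *",
           "//")
  h <- parse_hmm3(txt)[[1]]
  expect_equal(h$name, "toy")
  expect_equal(h$length, 1L)
  expect_true(all(abs(h$match_emissions[1, ] - 0.05) < 1e-5))
  expect_equal(unname(h$transitions[1, "MD"]), 0)   # "*" means probability 0
  expect_equal(unname(h$background), rep(1 / 20, 20))  # no COMPO line
})

test_that("non-HMMER3 input and malformed records raise format/parse errors", {
  expect_error(parse_hmm3(">seq1\nACDEF"), "format error")
  expect_error(parse_hmm3(character(0)), "format error")
  bad <- write_hmm3(random_profile_hmm(M = 1, seed = 3))
  bad[grep("^      1 ", bad)] <- "      1  1.0 2.0 oops"
  expect_error(parse_hmm3(bad), "parse error")
})

test_that("write/parse round-trip preserves parameters within 1e-6", {
  for (i in 1:30) {
    h <- random_profile_hmm(M = ((i - 1) %% 4) + 1, seed = 100 + i)
    h2 <- parse_hmm3(write_hmm3(h))[[1]]
    expect_lt(hmm_param_diff(h, h2), 1e-6)
  }
})

test_that("zero-probability transitions are encoded as * and cutoffs survive", {
  h <- random_profile_hmm(M = 2, seed = 11, p_zero = 1)
  expect_true(any(h$transitions == 0))
  expect_true(any(grepl("\\*", write_hmm3(h))))
  h$cutoffs <- cutoff_pair(trusted = 50, noise = 20, gathering = 35,
                           separable = TRUE)
  h2 <- parse_hmm3(write_hmm3(h))[[1]]
  expect_equal(h2$cutoffs$gathering, 35, tolerance = 1e-4)
  expect_equal(h2$cutoffs$trusted, 50, tolerance = 1e-4)
  expect_equal(h2$cutoffs$noise, 20, tolerance = 1e-4)
  expect_true(h2$cutoffs$separable)
})

test_that("uniform single-node model writes one line of 20 equal values", {
  trans <- matrix(c(0.9, 0.05, 0.05, 0.5, 0.5, 1, 0), 2, 7, byrow = TRUE,
                  dimnames = list(NULL, c("MM", "MI", "MD", "IM", "II",
                                          "DM", "DD")))
  trans[2, ] <- c(0.95, 0.05, 0, 0.5, 0.5, 1, 0)
  h <- profile_hmm("uni", matrix(1 / 20, 1, 20), matrix(1 / 20, 1, 20), trans)
  lines <- write_hmm3(h)
  mline <- strsplit(trimws(lines[grep("^ *1 ", lines)]), "\\s+")[[1]][-1]
  expect_length(unique(mline), 1)
  expect_length(mline, 20)
})

test_that("invalid models are rejected with the failed invariant named", {
  me <- matrix(1 / 20, 1, 20); me[1, 1] <- 0.5   # row sums to 1.45
  trans <- matrix(c(1, 0, 0, 1, 0, 1, 0), 1, 7)
  expect_error(profile_hmm("bad", me, matrix(1 / 20, 1, 20),
                           rbind(trans, trans)),
               "match emission row")
})

test_that("build_from_alignment applies the Laplace count rule", {
  h <- build_from_alignment(c("ACD", "ACD"), pseudocount = 1,
                            match_fraction = 0.5)
  expect_equal(h$length, 3L)
  expect_equal(unname(h$match_emissions[1, "A"]), 3 / 22)
  expect_equal(unname(h$match_emissions[2, "C"]), 3 / 22)
  # background: 2 each of A, C, D among 6 residues
  expect_equal(unname(h$background["A"]), (2 + 1) / (6 + 20))
  validate_profile_hmm(h)
})

test_that("columns below the occupancy threshold become insert columns", {
  aln <- c("A-D", "A-D", "A-D", "ACD")    # column 2 is 25% occupied
  h <- build_from_alignment(aln, match_fraction = 0.5)
  expect_equal(h$length, 2L)
  aln2 <- c("----", "----")
  expect_error(build_from_alignment(aln2), "no column passes")
  expect_error(build_from_alignment(c("AC", "ACD")), "inconsistent lengths")
})

test_that("an HMM matching the background yields no positive local score", {
  bg <- rep(1 / 20, 20)
  trans <- matrix(rep(c(0.9, 0.05, 0.05, 0.5, 0.5, 0.5, 0.5), each = 3), 3, 7,
                  dimnames = list(NULL, c("MM", "MI", "MD", "IM", "II",
                                          "DM", "DD")))
  h <- profile_hmm("null", matrix(1 / 20, 2, 20), matrix(1 / 20, 2, 20),
                   trans, background = bg)
  expect_null(score_local(h, "ACDEFGHIKL"))
  expect_null(score_local_reference(h, "ACDEF"))
})

test_that("score_local agrees with exhaustive enumeration on tiny models", {
  set.seed(202)
  mx <- 0
  for (i in 1:60) {
    M <- sample(1:3, 1)
    h <- random_profile_hmm(M = M, seed = 5000 + i)
    prot <- random_protein(sample(1:4, 1), alphabet = c(AA, "X"))
    mx <- max(mx, oracle_diff(h, prot))
  }
  expect_lt(mx, 1e-9)
})

test_that("the consensus outscores every single-substitution variant", {
  cons <- "ACDEF"
  h <- peaked_hmm(cons)
  s_cons <- score_local(h, cons)$bit_score
  chars <- strsplit(cons, "")[[1]]
  for (pos in seq_along(chars)) {
    for (sub in setdiff(AA, chars[pos])) {
      v <- chars; v[pos] <- sub
      s_var <- score_local(h, paste(v, collapse = ""))
      expect_true(is.null(s_var) || s_var$bit_score < s_cons)
    }
  }
})

test_that("appending residues never decreases the best local bit score", {
  set.seed(7)
  for (i in 1:20) {
    h <- random_profile_hmm(M = sample(2:5, 1), seed = 300 + i)
    prot <- random_protein(6)
    base <- score_local(h, prot)
    base_score <- if (is.null(base)) 0 else base$bit_score
    ext <- score_local(h, paste0(prot, random_protein(3)))
    ext_score <- if (is.null(ext)) 0 else ext$bit_score
    expect_gte(ext_score + 1e-12, base_score)
  }
})

test_that("bit scores are invariant to a negative-log round trip of the parameters", {
  for (i in 1:10) {
    h <- random_profile_hmm(M = 4, seed = 900 + i)
    relog <- function(p) exp(-(-log(p)))
    h2 <- profile_hmm(h$name, relog(h$match_emissions),
                      relog(h$insert_emissions), relog(h$transitions),
                      relog(h$background))
    prot <- random_protein(8)
    a <- score_local(h, prot); b <- score_local(h2, prot)
    if (is.null(a)) expect_null(b)
    else expect_lt(abs(a$bit_score - b$bit_score), 1e-9)
  }
})

test_that("score ties resolve to the smallest seq_start then node_start", {
  h <- peaked_hmm("AC")
  hit <- score_local(h, "ACACAC")   # three identical optimal placements
  expect_equal(hit$seq_start, 0L)
  expect_equal(hit$node_start, 0L)
  ref <- score_local_reference(h, "ACACAC")
  expect_equal(ref$seq_start, 0L)
  expect_equal(hit$seq_end, ref$seq_end)
})

test_that("hit intervals are half-open and within bounds", {
  h <- peaked_hmm("ACDEF")
  hit <- score_local(h, "GGACDEFGG")
  expect_equal(hit$seq_start, 2L)
  expect_equal(hit$seq_end, 7L)
  expect_equal(hit$node_start, 0L)
  expect_equal(hit$node_end, 5L)
  expect_error(hmm_hit("o", "h", Inf, 0, 1, 0, 1), "finite")
  expect_error(hmm_hit("o", "h", 1, 2, 2, 0, 1), "seq_start")
})
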