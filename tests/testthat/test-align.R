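make_pair <- function(seq_a, seq_b, idx = 1) {
  list(
    a = rad_loci(sprintf("spA|s1|L%03d", idx), "spA", "s1", seq_a),
    b = rad_loci(sprintf("spB|s1|L%03d", idx), "spB", "s1", seq_b)
  )
}

test_that("identical 60-mers give a perfect full-length plus-strand hit", {
  set.seed(20)
  s <- random_seq(60)
  p <- make_pair(s, s)
  h <- align_all_pairs(p$a, p$b)
  expect_equal(nrow(h), 1)
  expect_equal(h$aln_length, 60)
  expect_equal(h$identity, 1.0)
  expect_equal(h$mismatches, 0)
  expect_equal(h$strand, "+")
  expect_equal(h$score, 60)
})

test_that("two substitutions give identity 58/60 and match the DP oracle", {
  set.seed(21)
  s <- random_seq(60)
  s2 <- mutate_seq(s, c(15, 40))
  h <- align_all_pairs(make_pair(s, s2)$a, make_pair(s, s2)$b)
  ## optimal local alignment spans the full length here (interior mismatches)
  expect_equal(h$mismatches, 2)
  expect_equal(h$identity, 58 / 60)
  expect_equal(h$score, sw_score(s, s2))
})

test_that("a reverse-complement subject is found on the minus strand", {
  set.seed(22)
  s <- random_seq(60)
  h <- align_all_pairs(make_pair(s, revcomp_chr(s))$a,
                       make_pair(s, revcomp_chr(s))$b)
  expect_equal(h$strand, "-")
  expect_equal(h$identity, 1.0)
  expect_equal(h$aln_length, 60)
  expect_true(h$sstart > h$send)
})

test_that("alignment scores are symmetric in query and subject", {
  set.seed(23)
  for (i in 1:10) {
    s <- random_seq(60)
    s2 <- mutate_seq(s, sample(60, sample(0:5, 1)))
    if (i %% 3 == 0) s2 <- revcomp_chr(s2)
    p <- make_pair(s, s2)
    h_ab <- align_all_pairs(p$a, p$b)
    h_ba <- align_all_pairs(p$b, p$a)
    expect_equal(h_ab$score, h_ba$score)
    expect_equal(h_ab$identity, h_ba$identity)
    expect_equal(h_ab$strand, h_ba$strand)
  }
})

test_that("seeded aligner equals the exhaustive Smith-Waterman oracle on a locus panel", {
  ## panel: 12 base loci + 12 derived copies (<= 2 substitutions, some
  ## reverse-complemented), so related pairs carry a guaranteed seed and
  ## unrelated pairs stay below the score floor
  set.seed(24)
  bases <- vapply(1:12, function(i) random_seq(60), "")
  derived <- vapply(1:12, function(i) {
    d <- mutate_seq(bases[i], sample(60, sample(0:2, 1)))
    if (i %% 4 == 0) revcomp_chr(d) else d
  }, "")
  a <- rad_loci(sprintf("spA|s1|L%03d", 1:12), "spA", "s1", bases)
  b <- rad_loci(sprintf("spB|s1|L%03d", 1:12), "spB", "s1", derived)
  h <- align_all_pairs(a, b, score_floor = 20)
  key <- paste(h$query_id, h$subject_id)
  for (i in 1:12) {
    for (j in 1:12) {
      oracle <- sw_score_2str(bases[i], derived[j])
      k <- paste(sprintf("spA|s1|L%03d", i), sprintf("spB|s1|L%03d", j))
      if (oracle >= 20) {
        expect_true(k %in% key)
        expect_equal(h$score[key == k], oracle)
      } else {
        expect_false(k %in% key)
      }
    }
  }
})

test_that("best-hit extraction keeps the top score with deterministic tie-breaks", {
  h <- empty_hits()[0, ]
  add <- function(h, q, s, score, identity, len, sid) {
    rbind(h, data.frame(query_id = q, subject_id = sid,
                        query_species = "A", subject_species = "B",
                        strand = "+", aln_length = len, identity = identity,
                        mismatches = 0L, gaps = 0L, score = score,
                        qstart = 1L, qend = len, sstart = 1L, send = len,
                        rank = NA_integer_))
  }
  h <- add(h, "q1", "B", 55, 0.95, 55, "s1")
  h <- add(h, "q1", "B", 40, 0.99, 58, "s2")
  best <- extract_best_hits(h)
  expect_equal(nrow(best), 1)
  expect_equal(best$subject_id, "s1")
  expect_equal(best$rank, 1L)

  ## score tie: higher identity wins
  h2 <- add(add(empty_hits()[0, ], "q1", "B", 50, 0.97, 52, "sX"),
            "q1", "B", 50, 0.95, 52, "sY")
  expect_equal(extract_best_hits(h2)$subject_id, "sX")

  ## full tie: lexicographically smallest subject id
  h3 <- add(add(empty_hits()[0, ], "q1", "B", 50, 0.97, 52, "sB"),
            "q1", "B", 50, 0.97, 52, "sA")
  expect_equal(extract_best_hits(h3)$subject_id, "sA")
})

test_that("threshold presets bind the documented values and filter correctly", {
  strict <- alignment_thresholds("strict")
  relaxed <- alignment_thresholds("relaxed")
  expect_equal(unlist(strict[1:3], use.names = FALSE), c(0.95, 50, 2))
  expect_equal(unlist(relaxed[1:3], use.names = FALSE), c(0.85, 45, 10))

  mk <- function(identity, len, mm) {
    data.frame(query_id = "q", subject_id = "s", query_species = "A",
               subject_species = "B", strand = "+", aln_length = len,
               identity = identity, mismatches = mm, gaps = 0L,
               score = 50, qstart = 1L, qend = len, sstart = 1L, send = len,
               rank = 1L)
  }
  expect_equal(nrow(filter_hits(mk(0.94, 60, 3), strict)), 0)
  expect_equal(nrow(filter_hits(mk(0.90, 48, 5), strict)), 0)
  expect_equal(nrow(filter_hits(mk(0.90, 48, 5), relaxed)), 1)
  expect_equal(nrow(filter_hits(mk(1.0, 60, 0), strict)), 1)
  expect_equal(nrow(filter_hits(mk(1.0, 60, 0), relaxed)), 1)
})

test_that("strict-filtered hits are a subset of relaxed-filtered hits", {
  set.seed(25)
  strict <- alignment_thresholds("strict")
  relaxed <- alignment_thresholds("relaxed")
  for (rep in 1:5) {
    bases <- vapply(1:15, function(i) random_seq(60), "")
    derived <- vapply(1:15, function(i) mutate_seq(bases[i], sample(60, sample(0:8, 1))), "")
    a <- rad_loci(sprintf("spA|s1|L%03d", 1:15), "spA", "s1", bases)
    b <- rad_loci(sprintf("spB|s1|L%03d", 1:15), "spB", "s1", derived)
    best <- extract_best_hits(align_all_pairs(a, b))
    ks <- function(h) paste(h$query_id, h$subject_id)
    expect_true(all(ks(filter_hits(best, strict)) %in% ks(filter_hits(best, relaxed))))
  }
})

test_that("uniqueness filter removes multiply-hit subjects (degree oracle)", {
  mk <- function(q, s) {
    data.frame(query_id = q, subject_id = s, query_species = "A",
               subject_species = "B", strand = "+", aln_length = 60L,
               identity = 1, mismatches = 0L, gaps = 0L, score = 60,
               qstart = 1L, qend = 60L, sstart = 1L, send = 60L, rank = 1L)
  }
  ## S best-hit by two queries: both rows removed
  h <- rbind(mk("q1", "S"), mk("q2", "S"), mk("q3", "T"))
  out <- filter_unique(h)
  expect_equal(out$subject_id, "T")
  expect_equal(attr(out, "n_removed"), 2)

  ## bijective set unchanged
  h2 <- rbind(mk("q1", "s1"), mk("q2", "s2"), mk("q3", "s3"))
  expect_equal(nrow(filter_unique(h2)), 3)

  ## 5 queries -> 1 subject: all removed; matches incoming-degree count
  h3 <- do.call(rbind, lapply(1:5, function(i) mk(paste0("q", i), "hub")))
  expect_equal(nrow(filter_unique(h3)), 0)
  deg <- table(h3$subject_id)
  expect_equal(attr(filter_unique(h3), "n_removed"), sum(deg[deg >= 2]))
})

test_that("swap_hits preserves scores and reuses alignments for the reverse direction", {
  set.seed(26)
  bases <- vapply(1:8, function(i) random_seq(60), "")
  derived <- vapply(1:8, function(i) mutate_seq(bases[i], sample(60, 2)), "")
  a <- rad_loci(sprintf("spA|s1|L%03d", 1:8), "spA", "s1", bases)
  b <- rad_loci(sprintf("spB|s1|L%03d", 1:8), "spB", "s1", derived)
  fwd <- align_all_pairs(a, b)
  direct <- align_all_pairs(b, a)
  swapped <- swap_hits(fwd)
  key <- function(h) paste(h$query_id, h$subject_id)
  o1 <- order(key(direct)); o2 <- order(key(swapped))
  expect_equal(key(direct)[o1], key(swapped)[o2])
  expect_equal(direct$score[o1], swapped$score[o2])
  expect_equal(direct$query_species[o1], swapped$query_species[o2])
})
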