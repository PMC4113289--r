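mk_pair <- function(s1, q1, s2, q2, id = "p") {
  list(r1 = seq_records(id, s1, qual = q1), r2 = seq_records(id, s2, qual = q2))
}

test_that("quality filter drops a pair when either mate fails", {
  q40 <- function(n) strrep(intToUtf8(40 + 33), n)
  q25 <- function(n) strrep(intToUtf8(25 + 33), n)
  pairs <- list(
    r1 = seq_records(c("a", "b", "c"),
                     c(strrep("A", 200), strrep("A", 200), strrep("A", 149)),
                     qual = c(q40(200), q25(200), q40(149))),
    r2 = seq_records(c("a", "b", "c"),
                     c(strrep("T", 200), strrep("T", 200), strrep("T", 200)),
                     qual = c(q40(200), q40(200), q40(200))))
  res <- quality_filter_pairs(pairs, mean_q_min = 26, len_min = 150)
  expect_identical(res$pairs$r1$id, "a")
  expect_identical(res$report$n_in, 3L)
  expect_identical(res$report$reasons, c(too_short = 1L, low_quality = 1L))
  expect_identical(res$report$n_kept + res$report$n_discarded, res$report$n_in)
})

test_that("merge_pair matches hand-derived overlap cases", {
  I8 <- strrep("I", 8)
  r <- merge_pair(list(seq = "AAAACGTG", qual = I8),
                  list(seq = revcomp("CGTGTTTT"), qual = I8), min_overlap = 4)
  expect_identical(r$status, "merged")
  expect_identical(r$seq, "AAAACGTGTTTT")
  expect_identical(r$overlap, 4L)
  expect_identical(r$n_corrected, 0L)
  # full overlap: r2 is the exact reverse complement of r1
  s <- rand_seq(30)
  r <- merge_pair(list(seq = s, qual = strrep("I", 30)),
                  list(seq = revcomp(s), qual = strrep("I", 30)))
  expect_identical(r$seq, s)
  expect_identical(r$overlap, 30L)
  # disagreement resolved to the higher-quality base
  s1 <- "ACGTACGTAC"
  s2rc <- s1; substr(s2rc, 6, 6) <- "T"   # mismatch at overlap position 6
  q1 <- strrep(intToUtf8(40 + 33), 10)
  q2 <- strrep(intToUtf8(10 + 33), 10)
  r <- merge_pair(list(seq = s1, qual = q1),
                  list(seq = revcomp(s2rc), qual = q2))
  expect_identical(r$status, "merged")
  expect_identical(r$seq, s1)                      # r1's base (q40) wins
  expect_identical(r$n_corrected, 1L)
  expect_identical(phred_scores(r$qual)[6], 30L)   # |40 - 10|
})

test_that("merge_pair agrees with the brute-force oracle on simulated pairs", {
  set.seed(31)
  for (case in 1:250) {
    kind <- case %% 3
    if (kind == 0) {          # true overlap, clean
      amp <- rand_seq(sample(60:110, 1)); L <- sample(40:55, 1)
    } else if (kind == 1) {   # true overlap with substitution noise
      amp <- rand_seq(sample(60:110, 1)); L <- sample(40:55, 1)
    } else {                  # unrelated mates
      amp <- NULL
    }
    if (is.null(amp)) {
      s1 <- rand_seq(50); s2 <- rand_seq(50)
    } else {
      s1 <- substr(amp, 1, L)
      s2 <- revcomp(substr(amp, nchar(amp) - L + 1, nchar(amp)))
      if (kind == 1) { s1 <- mutate_seq(s1, 2); s2 <- mutate_seq(s2, 2) }
    }
    q1 <- intToUtf8(sample(2:40, nchar(s1), TRUE) + 33)
    q2 <- intToUtf8(sample(2:40, nchar(s2), TRUE) + 33)
    got <- merge_pair(list(seq = s1, qual = q1), list(seq = s2, qual = q2))
    want <- oracle_merge(s1, q1, s2, q2)
    expect_identical(got$status, want$status)
    if (want$status == "merged") {
      expect_identical(got$seq, want$seq)
      expect_identical(got$qual, want$qual)
      expect_identical(got$overlap, want$overlap)
      expect_identical(got$n_corrected, want$n_corrected)
      expect_identical(nchar(got$seq),
                       nchar(s1) + nchar(s2) - got$overlap)  # length identity
    }
  }
})

test_that("merge_stream reports categorized rejections and conserves counts", {
  set.seed(7)
  amp <- rand_seq(90)
  good <- mk_pair(substr(amp, 1, 60), strrep("I", 60),
                  revcomp(substr(amp, 31, 90)), strrep("I", 60), "good")
  disjoint <- mk_pair(rand_seq(60), strrep("I", 60), rand_seq(60),
                      strrep("I", 60), "disjoint")
  withN <- mk_pair(paste0(substr(amp, 1, 59), "N"), strrep("I", 60),
                   revcomp(substr(amp, 31, 90)), strrep("I", 60), "hasN")
  pairs <- list(r1 = rbind(good$r1, disjoint$r1, withN$r1),
                r2 = rbind(good$r2, disjoint$r2, withN$r2))
  res <- merge_stream(pairs)
  expect_identical(res$report$n_in, 3L)
  expect_identical(res$merged$id, "good")
  expect_true("contains_N" %in% names(res$report$reasons))
  expect_identical(sum(res$report$reasons), res$report$n_discarded)
  # empty input
  empty <- merge_stream(list(r1 = good$r1[0, ], r2 = good$r2[0, ]))
  expect_identical(empty$report$n_in, 0L)
  expect_identical(nrow(empty$merged), 0L)
})
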