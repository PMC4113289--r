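test_that("global_identity matches hand cases and is symmetric", {
  expect_equal(global_identity("ACGTACGT", "ACGTACGT"), 1.0)
  expect_equal(global_identity("ACGT", "ACGA"), 0.75)
  expect_equal(global_identity("ACGT", "ACGTACGT"), 1.0)  # containment
  set.seed(13)
  for (k in 1:20) {
    a <- rand_seq(sample(20:60, 1)); b <- rand_seq(sample(20:60, 1))
    expect_equal(global_identity(a, b), global_identity(b, a))
  }
})

test_that("global_identity equals the textbook DP oracle on random pairs", {
  set.seed(17)
  for (k in 1:60) {
    if (k %% 2 == 0) {
      a <- rand_seq(sample(30:70, 1)); b <- mutate_seq(a, sample(0:8, 1))
    } else {
      a <- rand_seq(sample(30:70, 1)); b <- rand_seq(sample(30:70, 1))
    }
    o <- oracle_nw(a, b)
    aln <- fungits:::cpp_nw_align(a, b)
    expect_identical(aln$score, o$score)
    expect_identical(aln$matches, o$matches)
    expect_identical(aln$columns, o$columns)
    expect_equal(global_identity(a, b), oracle_identity(a, b))
  }
})

test_that("alignment score agrees with an independent aligner", {
  set.seed(19)
  mat <- Biostrings::nucleotideSubstitutionMatrix(1, -1, baseOnly = TRUE)
  for (k in 1:25) {
    a <- rand_seq(60)
    b <- mutate_seq(a, sample(1:10, 1))
    if (k %% 3 == 0) b <- paste0(b, rand_seq(7))      # ragged end
    if (k %% 4 == 0) b <- substr(b, 4, nchar(b))       # ragged start
    # with affine gaps and a single aligned segment, an all-ends-free
    # alignment scores identically to a local alignment
    ref <- Biostrings::pairwiseAlignment(a, b, type = "local",
                                         substitutionMatrix = mat,
                                         gapOpening = 2, gapExtension = 1)
    expect_equal(fungits:::cpp_nw_align(a, b)$score, Biostrings::score(ref))
  }
})

test_that("dereplication counts replicates case-insensitively", {
  recs <- seq_records(paste0("r", 1:3), c("ACGT", "ACGT", "ACGA"))
  u <- dereplicate(recs)
  expect_identical(u$seq, c("ACGT", "ACGA"))
  expect_identical(u$size, c(ACGT = 2L, ACGA = 1L) |> unname())
  u2 <- dereplicate(seq_records(c("a", "b"), c("acgt", "ACGT")))
  expect_identical(u2$size, 2L)
  expect_identical(u2$seq, "ACGT")
  un <- dereplicate(seq_records(paste0("r", 1:3), c("AA", "CC", "GG")))
  expect_true(all(un$size == 1L))
  expect_identical(sum(u$size), 3L)  # size conservation
})

test_that("abundance sorting removes sub-minimum sizes deterministically", {
  u <- data.frame(seq = c("TTT", "AAA", "CCC", "GGG"), size = c(1L, 5L, 3L, 3L))
  s <- sort_by_size(u, min_size = 2)
  expect_identical(s$uniques$size, c(5L, 3L, 3L))
  expect_identical(s$uniques$seq, c("AAA", "CCC", "GGG"))  # tie lexicographic
  expect_identical(s$report$reasons, c(below_min_size = 1L))
  s1 <- sort_by_size(u, min_size = 1)
  expect_identical(nrow(s1$uniques), 4L)
})

test_that("greedy clustering recovers simulated species exactly", {
  set.seed(23)
  cfg <- sim_config(n_species = 10, its2_len = c(140, 180), read_len = 150,
                    seed = 23)
  sp <- make_species(cfg)
  sizes <- as.integer(seq(100, 10, by = -10))
  u <- data.frame(seq = unname(sp), size = sizes)
  cl <- greedy_cluster(u)
  expect_identical(nrow(cl$centroids), 10L)
  expect_identical(nrow(cl$chimeras), 0L)
  expect_identical(sum(cl$centroids$size), sum(sizes))
  audit_members(cl$centroids, u)
  # determinism
  cl2 <- greedy_cluster(u)
  expect_identical(cl$centroids$seq, cl2$centroids$seq)
  expect_error(greedy_cluster(u[order(u$size), ]), "sorted")
})

test_that("sequences inside/outside the OTU radius split as expected", {
  set.seed(29)
  a <- rand_seq(100)
  near <- mutate_seq(a, 2)    # 98% identity -> joins
  far <- mutate_seq(a, 4)     # 96% identity -> new centroid
  expect_gte(global_identity(a, near), 0.97)
  expect_lt(global_identity(a, far), 0.97)
  cl <- greedy_cluster(data.frame(seq = c(a, near, far), size = c(10L, 5L, 4L)))
  expect_identical(nrow(cl$centroids), 2L)
  expect_identical(cl$centroids$size, c(15L, 4L))
})

test_that("is_bimera flags exact crossovers and spares parents/random", {
  set.seed(37)
  cfg <- sim_config(n_species = 2, species_min_divergence = 0.10,
                    its2_len = c(150, 150), seed = 37)
  sp <- make_species(cfg)
  chim <- paste0(substr(sp[1], 1, 75), substr(sp[2], 76, 150))
  v <- is_bimera(chim, sp[[1]], sp[[2]])
  expect_true(v$bimeric)
  expect_gt(v$id_model, v$id_best_single)  # invariant
  expect_false(is_bimera(sp[[1]], sp[[1]], sp[[2]])$bimeric)
  expect_false(is_bimera(rand_seq(150), sp[[1]], sp[[2]])$bimeric)
})

test_that("is_bimera agrees with the exhaustive-crossover oracle", {
  set.seed(41)
  for (k in 1:60) {
    pa <- rand_seq(120)
    pb <- if (k %% 2 == 0) rand_seq(120) else mutate_seq(pa, 18)
    q <- switch(k %% 3 + 1,
                paste0(substr(pa, 1, sample(40:80, 1)),
                       substr(pb, sample(40:80, 1) + 1, 120)),  # true bimera
                mutate_seq(pa, sample(0:3, 1)),                 # near-parent
                rand_seq(120))                                  # unrelated
    got <- is_bimera(q, pa, pb)$bimeric
    want <- oracle_is_bimera(q, pa, pb)
    expect_identical(got, want)
  }
})

test_that("clustering flags an injected perfect bimera of abundant centroids", {
  set.seed(43)
  cfg <- sim_config(n_species = 2, species_min_divergence = 0.15,
                    its2_len = c(160, 160), seed = 43)
  sp <- make_species(cfg)
  chim <- paste0(substr(sp[1], 1, 80), substr(sp[2], 81, 160))
  u <- data.frame(seq = c(unname(sp), chim), size = c(50L, 40L, 3L))
  cl <- greedy_cluster(u)
  expect_identical(nrow(cl$centroids), 2L)
  expect_identical(cl$chimeras$seq, chim)
  # size conservation across centroids + chimeras
  expect_identical(sum(cl$centroids$size) + sum(cl$chimeras$size), 93L)
  # but the same bimera at high abundance is NOT flagged (skew rule)
  u2 <- data.frame(seq = c(unname(sp), chim), size = c(50L, 40L, 30L))
  u2 <- u2[order(-u2$size), ]
  cl2 <- greedy_cluster(u2)
  expect_identical(nrow(cl2$chimeras), 0L)
})

test_that("centroid records expose the size= header convention", {
  cl <- data.frame(seq = c("AAAA", "CCCC"), size = c(7L, 3L))
  rec <- centroid_records(cl)
  expect_identical(rec$id, c("centroid1;size=7;", "centroid2;size=3;"))
  # the spreadsheet-style grep/sed check stays usable
  expect_identical(sub(".*size=([0-9]+).*", "\\1", rec$id), c("7", "3"))
})
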