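test_that("simulation is deterministic under a fixed seed", {
  s1 <- tiny_sim(seed = 5)
  s2 <- tiny_sim(seed = 5)
  expect_identical(s1$r1, s2$r1)
  expect_identical(s1$r2, s2$r2)
  expect_identical(s1$truth, s2$truth)
  s3 <- tiny_sim(seed = 6)
  expect_false(identical(s1$r1$seq, s3$r1$seq))
})

test_that("per-sample read counts and truth bookkeeping are exact", {
  sim <- tiny_sim()
  expect_equal(as.vector(table(sim$truth$sample)[sim$sheet$name]), rep(60, 2))
  expect_identical(anyDuplicated(sim$truth$read_id), 0L)
  expect_identical(sum(sim$expected_table), sum(sim$truth$intact))
})

test_that("species cores respect the divergence floor (DP oracle agrees)", {
  set.seed(11)
  cfg <- sim_config(n_species = 5, species_min_divergence = 0.10,
                    its2_len = c(120, 150), read_len = 150, seed = 11)
  sp <- make_species(cfg)
  for (i in 1:4) for (j in (i + 1):5) {
    expect_lte(global_identity(sp[i], sp[j]), 0.90)
    expect_lte(oracle_nw(sp[i], sp[j])$identity, 0.90)
  }
  # determinism
  set.seed(11)
  expect_identical(make_species(cfg), sp)
})

test_that("amplicons carry the dual-tag structure at both ends", {
  cfg <- sim_config(seed = 3)
  amp <- make_amplicon("ACGTACGTACGTACGTACGTACGTACGTAC", "AAAAAAAA", cfg)
  expect_true(startsWith(amp, paste0("AAAAAAAA", cfg$primer_fwd)))
  expect_true(endsWith(amp, revcomp(paste0("AAAAAAAA", cfg$primer_rev))))
  expect_identical(nchar(amp),
                   2L * (8L + nchar(cfg$primer_fwd)) + nchar(cfg$anchor_5p) +
                     nchar(cfg$anchor_3p) + 30L)
})

test_that("reverse-orientation fraction respects revorient_prob", {
  sim <- simulate_reads(sim_config(n_samples = 3, reads_per_sample = 400,
                                   per_base_error = 0, chimera_rate = 0,
                                   multiprimer_rate = 0, seed = 9))
  n <- nrow(sim$truth)
  k <- sum(sim$truth$orientation == "rev")
  bounds <- qbinom(c(0.005, 0.995), n, 0.5)
  expect_gte(k, bounds[1]); expect_lte(k, bounds[2])
  fw <- simulate_reads(sim_config(n_samples = 2, reads_per_sample = 50,
                                  revorient_prob = 0, per_base_error = 0,
                                  chimera_rate = 0, multiprimer_rate = 0, seed = 2))
  expect_true(all(startsWith(fw$r1$seq, paste0(fw$sheet$tag[1], fw$config$primer_fwd)) |
                    startsWith(fw$r1$seq, paste0(fw$sheet$tag[2], fw$config$primer_fwd))))
})

test_that("forced chimera simulation records two parents per read", {
  sim <- simulate_reads(sim_config(n_species = 2, n_samples = 1,
                                   reads_per_sample = 30, chimera_rate = 1,
                                   multiprimer_rate = 0, per_base_error = 0,
                                   seed = 4))
  expect_true(all(sim$truth$is_chimera))
  expect_true(all(!is.na(sim$truth$parent_a) & !is.na(sim$truth$parent_b)))
  expect_true(all(sim$truth$parent_a != sim$truth$parent_b))
  expect_identical(sum(sim$expected_table), 0L)
})

test_that("error-free pairs merge back to their exact source amplicon", {
  sim <- tiny_sim(seed = 21)
  mg <- merge_stream(list(r1 = sim$r1, r2 = sim$r2))
  expect_identical(nrow(mg$merged), nrow(sim$r1))
  # reconstruct the amplicons from truth
  cfg <- sim$config
  sp <- sim$species
  for (i in sample(nrow(mg$merged), 12)) {
    tr <- sim$truth[sim$truth$read_id == mg$merged$id[i], ]
    amp <- make_amplicon(sp[[tr$species]], sim$sheet$tag[sim$sheet$name == tr$sample], cfg)
    got <- mg$merged$seq[i]
    if (tr$orientation == "rev") got <- revcomp(got)
    expect_identical(got, amp)
  }
})
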