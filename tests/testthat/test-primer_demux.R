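demo_cfg <- function(...) sim_config(n_species = 3, n_samples = 3,
                                     reads_per_sample = 40, per_base_error = 0,
                                     chimera_rate = 0, multiprimer_rate = 0,
                                     seed = 8, ...)

test_that("multi-primer screening counts both strands of both primers", {
  cfg <- demo_cfg()
  core <- rand_seq(80)
  good <- make_amplicon(core, "AACCGGTT", cfg)
  extra_f <- sub(substr(core, 10, 40), paste0(substr(core, 10, 22),
                                              cfg$primer_fwd), good, fixed = TRUE)
  extra_rc <- sub(substr(core, 10, 40), paste0(substr(core, 10, 22),
                                               revcomp(cfg$primer_rev)), good,
                  fixed = TRUE)
  none <- rand_seq(120)
  recs <- seq_records(c("ok", "f2", "r2", "none"),
                      c(good, extra_f, extra_rc, none))
  res <- remove_multiprimer(recs, cfg$primer_fwd, cfg$primer_rev)
  expect_identical(res$kept$id, c("ok", "none"))
  expect_identical(res$report$reasons, c(multiprimer = 2L))
  expect_error(remove_multiprimer(recs, "ACGY", cfg$primer_rev), "ambiguity")
})

test_that("reorientation flips reverse reads, drops primerless, is idempotent", {
  set.seed(2)
  cfg <- demo_cfg()
  fwd <- make_amplicon(rand_seq(70), "AACCGGTT", cfg)
  rev <- revcomp(make_amplicon(rand_seq(70), "CCAATTGG", cfg))
  junk <- rand_seq(100)
  recs <- seq_records(c("f", "r", "j"), c(fwd, rev, junk),
                      qual = strrep("I", nchar(c(fwd, rev, junk))))
  res <- orient_reads(recs, cfg$primer_fwd, mismatches = 1)
  expect_identical(res$oriented$id, c("f", "r"))
  expect_identical(res$oriented$seq[1], fwd)
  expect_identical(res$oriented$seq[2], revcomp(rev))
  expect_identical(res$report$reasons, c(no_primer = 1L))
  # idempotence
  res2 <- orient_reads(res$oriented, cfg$primer_fwd, mismatches = 1)
  expect_identical(res2$oriented, res$oriented)
  # one mismatch in the primer is still recognized
  fwd_mm <- fwd
  substr(fwd_mm, 10, 10) <- if (substr(fwd_mm, 10, 10) == "A") "C" else "A"
  res3 <- orient_reads(seq_records("m", fwd_mm), cfg$primer_fwd, mismatches = 1)
  expect_identical(nrow(res3$oriented), 1L)
})

test_that("demultiplexing requires a perfect dual-tag match on both ends", {
  cfg <- demo_cfg()
  sheet <- cfg$samples
  core <- rand_seq(90)
  ok <- make_amplicon(core, sheet$tag[1], cfg)
  corrupt <- ok
  substr(corrupt, 3, 3) <- if (substr(ok, 3, 3) == "A") "G" else "A"
  switched <- make_amplicon(core, sheet$tag[1], cfg, tag3 = sheet$tag[2])
  recs <- seq_records(c("ok", "corrupt", "switched"), c(ok, corrupt, switched))
  res <- demultiplex(recs, sheet, cfg$primer_fwd, cfg$primer_rev)
  expect_identical(res$samples[[sheet$name[1]]]$id, "ok")
  expect_identical(res$unassigned$id, c("corrupt", "switched"))
  expect_identical(res$report$n_in,
                   sum(vapply(res$samples, nrow, integer(1))) + nrow(res$unassigned))
  expect_error(demultiplex(recs, data.frame(name = c("a", "b"),
                                            tag = rep("AAAAAAAA", 2)),
                           cfg$primer_fwd, cfg$primer_rev), "duplicate")
})

test_that("every simulated intact read demultiplexes to its true sample", {
  cfg <- demo_cfg(tag_corrupt_rate = 0.1, tag_switch_rate = 0.1)
  sim <- simulate_reads(cfg)
  mg <- merge_stream(list(r1 = sim$r1, r2 = sim$r2))
  orr <- orient_reads(mg$merged, cfg$primer_fwd)
  res <- demultiplex(orr$oriented, sim$sheet, cfg$primer_fwd, cfg$primer_rev)
  truth <- sim$truth
  for (nm in names(res$samples)) {
    got <- res$samples[[nm]]$id
    # all assigned reads belong to the right sample and are uncorrupted
    expect_true(all(truth$sample[match(got, truth$read_id)] == nm))
    expect_true(all(!truth$tag_corrupted[match(got, truth$read_id)]))
    expect_true(all(!truth$tag_switched[match(got, truth$read_id)]))
    expect_true(all(startsWith(res$samples[[nm]]$seq,
                               sim$sheet$tag[sim$sheet$name == nm])))
  }
  # and all clean reads were assigned
  clean <- truth$read_id[!truth$tag_corrupted & !truth$tag_switched]
  assigned <- unlist(lapply(res$samples, `[[`, "id"))
  expect_setequal(assigned, clean)
})

test_that("pool_and_trim strips exactly tag+primer and renames headers", {
  cfg <- demo_cfg()
  core <- rand_seq(60)
  amp <- make_amplicon(core, cfg$samples$tag[2], cfg)
  m <- list(S1 = seq_records("r1", amp))
  names(m) <- cfg$samples$name[2]
  pooled <- pool_and_trim(m, 26, 26)
  expect_identical(pooled$id, paste0("sample=", cfg$samples$name[2], ";r1"))
  expect_identical(pooled$seq, paste0(cfg$anchor_5p, core, cfg$anchor_3p))
  expect_identical(sample_of(pooled$id), cfg$samples$name[2])
  # head = tail = 0 is the identity on sequences
  p0 <- pool_and_trim(m, 0, 0)
  expect_identical(p0$seq, amp)
  # too short to trim is an error
  expect_error(pool_and_trim(list(S = seq_records("x", rand_seq(52))), 26, 26),
               "shorter")
  expect_error(sample_of("plainid"), "sample=")
})
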