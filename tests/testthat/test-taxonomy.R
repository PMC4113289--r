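hit <- function(q, lineage, score) data.frame(qseqid = q, lineage = lineage,
                                              bitscore = score, evalue = 1e-10)

test_that("LCA assignment follows score gating and common-prefix rules", {
  h <- rbind(hit("q1", "Eukaryota;Fungi;Ascomycota", 200),
             hit("q2", "Eukaryota;Fungi;Ascomycota", 200),
             hit("q2", "Eukaryota;Fungi;Basidiomycota", 196),
             hit("q3", "Eukaryota;Fungi;Ascomycota", 150))
  a <- lca_assign(h)
  expect_identical(a$lineage[a$qseqid == "q1"], "Eukaryota;Fungi;Ascomycota")
  # 196 >= 0.95 * 200 -> both hits retained -> LCA at Fungi
  expect_identical(a$lineage[a$qseqid == "q2"], "Eukaryota;Fungi")
  # best hit below min_score 170 -> unassigned
  expect_true(is.na(a$lineage[a$qseqid == "q3"]))
  # hit just outside the 5% window is ignored
  h2 <- rbind(hit("q4", "Eukaryota;Fungi;Ascomycota", 200),
              hit("q4", "Eukaryota;Fungi;Basidiomycota", 189))
  expect_identical(lca_assign(h2)$lineage, "Eukaryota;Fungi;Ascomycota")
})

test_that("LCA is monotone under stricter parameters", {
  set.seed(71)
  taxa <- c("Eukaryota;Fungi;Ascomycota;Helotiales",
            "Eukaryota;Fungi;Ascomycota;Hypocreales",
            "Eukaryota;Fungi;Basidiomycota;Agaricales",
            "Eukaryota;Viridiplantae;Streptophyta")
  hits <- do.call(rbind, lapply(1:25, function(i) {
    k <- sample(1:4, sample(1:4, 1), replace = TRUE)
    hit(paste0("q", i), taxa[k], round(runif(length(k), 150, 250)))
  }))
  depth <- function(x) ifelse(is.na(x), 0L,
                              lengths(strsplit(x, ";", fixed = TRUE)))
  base <- lca_assign(hits, min_score = 170, top_percent = 5)
  wider_window <- lca_assign(hits, min_score = 170, top_percent = 50)
  strict_score <- lca_assign(hits, min_score = 500, top_percent = 5)
  for (q in base$qseqid) {
    d0 <- depth(base$lineage[base$qseqid == q])
    dw <- depth(wider_window$lineage[wider_window$qseqid == q])
    expect_lte(dw, d0)  # retaining more hits can only shorten the LCA
  }
  # a min_score nothing reaches leaves every query explicitly unassigned
  expect_true(all(is.na(strict_score$lineage)))
  expect_setequal(strict_score$qseqid, unique(hits$qseqid))
  # single hit per query: assignment is that hit's lineage (identity case)
  one <- hits[!duplicated(hits$qseqid), ]
  one <- one[one$bitscore >= 170, ]
  a1 <- lca_assign(one)
  expect_identical(a1$lineage[match(one$qseqid, a1$qseqid)], one$lineage)
})

test_that("min_support pushes weakly supported assignments to the parent", {
  h <- rbind(hit("q1", "Eukaryota;Fungi;Ascomycota", 200),
             hit("q2", "Eukaryota;Fungi;Ascomycota", 200),
             hit("q3", "Eukaryota;Fungi;Basidiomycota", 200))
  a <- lca_assign(h, min_support = 2)
  expect_identical(a$lineage[a$qseqid == "q3"], "Eukaryota;Fungi")
  expect_identical(a$lineage[a$qseqid == "q1"], "Eukaryota;Fungi;Ascomycota")
  # default support 1 is a no-op
  a1 <- lca_assign(h)
  expect_identical(a1$lineage[a1$qseqid == "q3"], "Eukaryota;Fungi;Basidiomycota")
})

test_that("fungal gating partitions OTUs and tallies excluded groups", {
  otus <- seq_records(c("OTU_1", "OTU_2", "OTU_3", "OTU_4"),
                      c("ACGTACGTA", "CCGTACGTA", "GCGTACGTA", "TCGTACGTA"))
  asg <- data.frame(qseqid = c("OTU_1", "OTU_2", "OTU_3"),
                    lineage = c("Eukaryota;Fungi;Ascomycota",
                                "Eukaryota;Viridiplantae;Streptophyta",
                                NA_character_),
                    stringsAsFactors = FALSE)
  res <- filter_fungal(otus, asg)
  expect_identical(res$fungal$id, "OTU_1")
  expect_identical(res$report$n_in, 4L)
  expect_identical(res$report$n_kept, 1L)
  s <- res$summary
  expect_identical(s$n_otus[s$group == "Viridiplantae"], 1L)
  expect_identical(s$n_otus[s$group == "No hits/unassigned"], 2L)
  expect_identical(s$n_otus[s$group == "Fungi"], 1L)
  expect_identical(sum(s$n_otus), 4L)
})
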