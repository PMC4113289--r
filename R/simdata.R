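#' Default 8-bp sample tags
#'
#' A small curated set of 8-bp multiplexing labels with high pairwise
#' Hamming distance, used when a simulation does not supply its own sample
#' sheet. The same label is attached to both ends of every amplicon
#' (double-labelling), which is what lets demultiplexing reject
#' tag-switched molecules.
#'
#' @param n number of tags requested (max 12).
#' @return character vector of 8-bp tags.
#' @export
default_tags <- function(n) {
  tags <- c("AACCGGTT", "CCAATTGG", "GGTTAACC", "TTGGCCAA",
            "ACACGTGT", "CACATGTG", "GTGTACAC", "TGTGCACA",
            "AGAGCTCT", "GAGATCTC", "CTCTAGAG", "TCTCGAGA")
  if (n > length(tags)) stop("at most ", length(tags), " default tags available")
  tags[seq_len(n)]
}

#' Simulation configuration
#'
#' Describes a synthetic soil-fungus-style ITS2 amplicon experiment:
#' dual-tagged amplicons of structure
#' `tag + primer_fwd + anchor_5p + ITS2 + anchor_3p + revcomp(primer_rev) + revcomp(tag)`,
#' sequenced as 2 x `read_len` paired-end reads with random strand
#' orientation. Defaults emulate a MiSeq 2 x 250 bp run with 8-bp tags and
#' an 18-bp primer pair (tag + primer = 26 bp on each end), conserved
#' rRNA-like anchors flanking a hypervariable ITS2 core, a modest
#' sequencing error rate, and low rates of PCR chimeras and multi-primer
#' artifacts.
#'
#' @param n_species number of species (distinct ITS2 cores).
#' @param its2_len length range `c(min, max)` of the ITS2 core, in bp.
#' @param species_min_divergence minimum pairwise divergence between
#'   species cores (1 - identity under the same global aligner used for
#'   clustering).
#' @param anchor_5p,anchor_3p conserved flanking regions (3' end of 5.8S /
#'   5' start of LSU analogues); the ITS2 extractor's default motifs.
#' @param primer_fwd,primer_rev amplification primers (plain ACGT).
#' @param samples data frame with columns `name`, `tag` (8 bp, unique), or
#'   `NULL` to derive `n_samples` defaults.
#' @param n_samples number of samples when `samples` is `NULL`.
#' @param reads_per_sample read pairs emitted per sample.
#' @param read_len read length (250 for MiSeq v2 chemistry).
#' @param per_base_error probability of a substitution error per sequenced
#'   base; qualities are written as the matching constant phred score
#'   `round(-10*log10(e))`, so rates above ~0.0025 encode below Q26 and
#'   such runs are (correctly) removed wholesale by the default mean-Q26
#'   quality filter.
#' @param chimera_rate probability a read pair derives from a single-
#'   crossover bimera of two same-sample amplicons.
#' @param multiprimer_rate probability a read pair carries an extra
#'   internal primer copy (length-preserving insertion).
#' @param revorient_prob probability the pair is sequenced from the reverse
#'   strand (R1 and R2 swapped), 0.5 on real instruments.
#' @param tag_corrupt_rate probability of a 1-substitution corruption of
#'   the 5' tag.
#' @param tag_switch_rate probability the 3' tag is replaced by another
#'   sample's tag (tag switching).
#' @param seed RNG seed; identical configurations give identical FASTQ.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_species = 10,
                       its2_len = c(160, 220),
                       species_min_divergence = 0.10,
                       anchor_5p = "AACTTTCAACAACGGATCTCTTGG",
                       anchor_3p = "TTGACCTCAAATCAGGTAGGACTA",
                       primer_fwd = "GATGAAGAACGCAGCGAA",
                       primer_rev = "CTCTTGCCGCTTCACTCG",
                       samples = NULL,
                       n_samples = 5,
                       reads_per_sample = 2000,
                       read_len = 250,
                       per_base_error = 0.002,
                       chimera_rate = 0.02,
                       multiprimer_rate = 0.01,
                       revorient_prob = 0.5,
                       tag_corrupt_rate = 0,
                       tag_switch_rate = 0,
                       seed = 1) {
  if (is.null(samples)) {
    samples <- data.frame(name = sprintf("S%02d", seq_len(n_samples)),
                          tag = default_tags(n_samples),
                          stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(samples), all(c("name", "tag") %in% names(samples)))
  if (any(nchar(samples$tag) != 8L)) stop("tags must be 8 bp long")
  if (anyDuplicated(samples$tag)) stop("tags must be unique")
  if (anyDuplicated(samples$name)) stop("sample names must be unique")
  rates <- c(per_base_error, chimera_rate, multiprimer_rate, revorient_prob,
             tag_corrupt_rate, tag_switch_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (chimera_rate + multiprimer_rate > 1)
    stop("chimera_rate + multiprimer_rate must not exceed 1")
  for (p in c(primer_fwd, primer_rev))
    if (grepl("[^ACGT]", p)) stop("simulation primers must be plain ACGT")
  stopifnot(length(its2_len) == 2, its2_len[1] >= 30, its2_len[2] >= its2_len[1])
  cfg <- list(n_species = as.integer(n_species), its2_len = as.integer(its2_len),
              species_min_divergence = species_min_divergence,
              anchor_5p = anchor_5p, anchor_3p = anchor_3p,
              primer_fwd = primer_fwd, primer_rev = primer_rev,
              samples = samples, reads_per_sample = as.integer(reads_per_sample),
              read_len = as.integer(read_len), per_base_error = per_base_error,
              chimera_rate = chimera_rate, multiprimer_rate = multiprimer_rate,
              revorient_prob = revorient_prob,
              tag_corrupt_rate = tag_corrupt_rate,
              tag_switch_rate = tag_switch_rate, seed = as.integer(seed))
  min_amp <- 2L * (8L + nchar(primer_fwd)) + nchar(anchor_5p) + nchar(anchor_3p) +
    its2_len[1]
  if (read_len > min_amp)
    stop("read_len exceeds the shortest possible amplicon (", min_amp,
         " bp); pairs would read through the molecule")
  class(cfg) <- "sim_config"
  cfg
}

rand_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# sample one element of x (safe for length-1 x, unlike sample())
sample1 <- function(x) x[sample.int(length(x), 1L)]

contains_motif <- function(seq, motifs) {
  any(vapply(motifs, function(m) {
    grepl(m, seq, fixed = TRUE) || grepl(revcomp(m), seq, fixed = TRUE)
  }, logical(1)))
}

#' Generate species ITS2 cores
#'
#' Draws random ITS2 cores until all pairwise identities (computed with the
#' same [global_identity()] used for OTU clustering) are at most
#' `1 - species_min_divergence`. Cores containing a primer or anchor motif
#' (either strand) are rejected so that simulated intact reads have exactly
#' one occurrence of each structural element. Uses the session RNG; seed it
#' (or call via [simulate_reads()]) for determinism.
#'
#' @param cfg a [sim_config()].
#' @return character vector of ITS2 core sequences, named `sp01`, `sp02`, ...
#' @export
make_species <- function(cfg) {
  n <- cfg$n_species
  stopifnot(n >= 1)
  max_id <- 1 - cfg$species_min_divergence
  motifs <- c(cfg$primer_fwd, cfg$primer_rev, cfg$anchor_5p, cfg$anchor_3p)
  cores <- character(0)
  for (k in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(100)) {
      len <- sample1(seq(cfg$its2_len[1], cfg$its2_len[2]))
      cand <- rand_dna(len)
      if (contains_motif(cand, motifs)) next
      ids <- vapply(cores, function(s) global_identity(cand, s), numeric(1))
      if (all(ids <= max_id)) { ok <- TRUE; break }
    }
    if (!ok) stop("could not satisfy species_min_divergence after 100 retries")
    cores[k] <- cand
  }
  names(cores) <- sprintf("sp%02d", seq_len(n))
  cores
}

#' Assemble a dual-tagged amplicon
#'
#' @param core ITS2 core sequence.
#' @param tag 8-bp sample tag (used at both ends).
#' @param cfg a [sim_config()].
#' @param tag3 optional different 3' tag (tag switching); defaults to `tag`.
#' @return amplicon sequence (plus strand, 5'->3').
#' @export
make_amplicon <- function(core, tag, cfg, tag3 = tag) {
  paste0(tag, cfg$primer_fwd, cfg$anchor_5p, core, cfg$anchor_3p,
         revcomp(cfg$primer_rev), revcomp(tag3))
}

mutate_tag <- function(tag) {
  pos <- sample(nchar(tag), 1)
  old <- substr(tag, pos, pos)
  substr(tag, pos, pos) <- sample1(setdiff(c("A", "C", "G", "T"), old))
  tag
}

chimeric_core <- function(coreA, coreB) {
  # single crossover, breakpoint uniform in the middle 60% of each core
  f <- stats::runif(1, 0.2, 0.8)
  left <- substr(coreA, 1, round(f * nchar(coreA)))
  right <- substr(coreB, round(f * nchar(coreB)) + 1, nchar(coreB))
  list(core = paste0(left, right), breakpoint_frac = f)
}

multiprimer_core <- function(core, primer) {
  # overwrite a length-matched internal segment with an extra primer copy,
  # keeping total amplicon length plausible
  lp <- nchar(primer); lc <- nchar(core)
  start <- sample1(seq(10, lc - lp - 10))
  paste0(substr(core, 1, start - 1), primer, substr(core, start + lp, lc))
}

apply_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  lens <- nchar(seqs)
  total <- sum(lens)
  hit <- which(stats::runif(total) < rate)
  if (!length(hit)) return(seqs)
  ends <- cumsum(lens)
  read_of <- findInterval(hit - 1L, ends) + 1L
  pos <- hit - c(0L, ends)[read_of]
  bases <- c("A", "C", "G", "T")
  for (k in seq_along(hit)) {
    i <- read_of[k]
    old <- substr(seqs[i], pos[k], pos[k])
    substr(seqs[i], pos[k], pos[k]) <- sample1(setdiff(bases, old))
  }
  seqs
}

#' Simulate a dual-tagged paired-end amplicon sequencing run
#'
#' Emits `reads_per_sample` read pairs per sample. Each pair derives from
#' one amplicon: an intact species amplicon, a single-crossover bimera of
#' two same-sample amplicons, or a multi-primer artifact, with optional
#' tag corruption/switching. With probability `revorient_prob` the molecule
#' is sequenced from the reverse strand (the two reads swap roles).
#' Sequencing errors are substitutions applied per base at
#' `per_base_error`; quality strings are the constant phred score
#' `round(-10*log10(e))`, capped to [2, 40] (40 when the error rate is 0).
#'
#' @param cfg a [sim_config()].
#' @param out_dir optional directory; when given, writes `R1.fastq`,
#'   `R2.fastq`, `truth.tsv`, `labels.csv` and `species.fasta`.
#' @return list with elements `r1`, `r2` (record frames), `truth` (per-read
#'   ground truth data frame), `species` (named cores), `expected_table`
#'   (species x sample counts of intact reads), `sheet` (sample sheet), and
#'   `config`.
#' @export
simulate_reads <- function(cfg, out_dir = NULL) {
  set.seed(cfg$seed)
  species <- make_species(cfg)
  n_sp <- length(species)
  sheet <- cfg$samples
  qchar <- if (cfg$per_base_error > 0) {
    intToUtf8(min(40L, max(2L, round(-10 * log10(cfg$per_base_error)))) + 33L)
  } else intToUtf8(40L + 33L)

  all <- vector("list", nrow(sheet))
  for (s in seq_len(nrow(sheet))) {
    sname <- sheet$name[s]; tag <- sheet$tag[s]
    n <- cfg$reads_per_sample
    # per-read category
    u <- stats::runif(n)
    is_chim <- u < cfg$chimera_rate
    is_mp <- !is_chim & u < cfg$chimera_rate + cfg$multiprimer_rate
    sp <- sample(n_sp, n, replace = TRUE)
    sp2 <- rep(NA_integer_, n)
    corrupt <- stats::runif(n) < cfg$tag_corrupt_rate
    switch <- stats::runif(n) < cfg$tag_switch_rate
    rev <- stats::runif(n) < cfg$revorient_prob

    intact_amp <- vapply(species, make_amplicon, character(1), tag = tag, cfg = cfg)
    amplicon <- intact_amp[sp]
    for (i in which(is_chim)) {
      sp2[i] <- sample1(setdiff(seq_len(n_sp), sp[i]))
      amplicon[i] <- make_amplicon(chimeric_core(species[sp[i]], species[sp2[i]])$core,
                                   tag, cfg)
    }
    for (i in which(is_mp)) {
      amplicon[i] <- make_amplicon(multiprimer_core(species[sp[i]], cfg$primer_fwd),
                                   tag, cfg)
    }
    for (i in which(corrupt)) {
      amplicon[i] <- sub(paste0("^", tag), mutate_tag(tag), amplicon[i])
    }
    for (i in which(switch)) {
      # replace the 3' tag with a foreign one (5' tag preserved)
      other <- sample1(setdiff(sheet$tag, tag))
      amplicon[i] <- paste0(substr(amplicon[i], 1, nchar(amplicon[i]) - 8),
                            revcomp(other))
    }
    r1 <- substr(amplicon, 1, cfg$read_len)
    r2 <- substr(revcomp(amplicon), 1, cfg$read_len)
    sw <- which(rev)
    tmp <- r1[sw]; r1[sw] <- r2[sw]; r2[sw] <- tmp
    r1 <- apply_errors(r1, cfg$per_base_error)
    r2 <- apply_errors(r2, cfg$per_base_error)
    ids <- sprintf("%s_read%06d", sname, seq_len(n))
    all[[s]] <- list(
      r1 = seq_records(ids, r1, qual = strrep(qchar, nchar(r1))),
      r2 = seq_records(ids, r2, qual = strrep(qchar, nchar(r2))),
      truth = data.frame(
        read_id = ids, sample = sname,
        species = ifelse(is_chim, NA_character_, names(species)[sp]),
        parent_a = ifelse(is_chim, names(species)[sp], NA_character_),
        parent_b = ifelse(is_chim, names(species)[sp2], NA_character_),
        orientation = ifelse(rev, "rev", "fwd"),
        is_chimera = is_chim, is_multiprimer = is_mp,
        tag_corrupted = corrupt, tag_switched = switch,
        intact = !is_chim & !is_mp & !corrupt & !switch,
        stringsAsFactors = FALSE))
  }
  r1 <- do.call(rbind, lapply(all, `[[`, "r1"))
  r2 <- do.call(rbind, lapply(all, `[[`, "r2"))
  truth <- do.call(rbind, lapply(all, `[[`, "truth"))

  keep <- truth$intact
  expected <- table(factor(truth$species[keep], levels = names(species)),
                    factor(truth$sample[keep], levels = sheet$name))
  expected <- matrix(as.integer(expected), nrow = n_sp,
                     dimnames = list(names(species), sheet$name))

  out <- list(r1 = r1, r2 = r2, truth = truth, species = species,
              expected_table = expected, sheet = sheet, config = cfg)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_fastq(r1, file.path(out_dir, "R1.fastq"))
    write_fastq(r2, file.path(out_dir, "R2.fastq"))
    utils::write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.csv(sheet, file.path(out_dir, "labels.csv"),
                     quote = FALSE, row.names = FALSE)
    write_fasta(seq_records(names(species), unname(species)),
                file.path(out_dir, "species.fasta"))
  }
  out
}
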