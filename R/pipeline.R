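#' Pipeline configuration
#'
#' Collects every stage's parameters with the pipeline's canonical
#' defaults: mean quality 26 and minimum length 150 for the paired
#' filter; minimum overlap 5 for assembly; 1 mismatch for primer-based
#' reorientation; 26-bp head/tail trims (8-bp tag + 18-bp primer);
#' singleton removal (min_size 2); 97% identity for both clustering and
#' read mapping; LCA gating at bitscore 170, top 5%, support 1.
#'
#' @param r1,r2 paths to the raw paired FASTQ files.
#' @param sample_sheet path to the `name,tag` CSV.
#' @param primer_fwd,primer_rev primer pair (plain ACGT).
#' @param out_dir directory for all stage outputs (created if needed).
#' @param ref_fasta optional trusted reference FASTA for reference-based
#'   chimera filtering (stage skipped when `NULL`).
#' @param tax_hits optional homology-hit TSV for fungal gating (stage
#'   skipped when `NULL`).
#' @param mean_q,len_min quality filter parameters.
#' @param min_overlap,max_overlap_mismatch_frac,reject_N merge parameters.
#' @param orient_mismatches reorientation mismatch allowance.
#' @param trim_head,trim_tail bases trimmed per end after demultiplexing.
#' @param anchors anchor model ([anchor_model()]) or `NULL` for the
#'   packaged ITS2 default.
#' @param min_its2_len minimum extracted ITS2 length.
#' @param min_size minimum replicate count entering clustering.
#' @param otu_id OTU clustering identity threshold.
#' @param map_id read-mapping identity threshold.
#' @param lca_min_score,lca_top_percent,lca_min_support LCA parameters.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(r1, r2, sample_sheet, primer_fwd, primer_rev,
                            out_dir, ref_fasta = NULL, tax_hits = NULL,
                            mean_q = 26, len_min = 150,
                            min_overlap = 5, max_overlap_mismatch_frac = 0.25,
                            reject_N = TRUE, orient_mismatches = 1,
                            trim_head = 26, trim_tail = 26,
                            anchors = NULL, min_its2_len = 30,
                            min_size = 2, otu_id = 0.97, map_id = 0.97,
                            lca_min_score = 170, lca_top_percent = 5,
                            lca_min_support = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  validate_config(cfg)
  cfg
}

#' Validate a pipeline configuration (no I/O beyond existence checks)
#'
#' @param cfg a [pipeline_config()].
#' @return `cfg` invisibly; errors describe the offending field.
#' @export
validate_config <- function(cfg) {
  frac <- function(x) length(x) == 1 && !is.na(x) && x > 0 && x <= 1
  if (!frac(cfg$otu_id)) stop("otu_id must lie in (0, 1]")
  if (!frac(cfg$map_id)) stop("map_id must lie in (0, 1]")
  if (cfg$max_overlap_mismatch_frac < 0 || cfg$max_overlap_mismatch_frac > 1)
    stop("max_overlap_mismatch_frac must lie in [0, 1]")
  if (cfg$mean_q < 0) stop("mean_q must be >= 0")
  if (cfg$len_min < 1) stop("len_min must be >= 1")
  if (cfg$min_overlap < 1) stop("min_overlap must be >= 1")
  if (cfg$orient_mismatches < 0) stop("orient_mismatches must be >= 0")
  if (cfg$trim_head < 0 || cfg$trim_tail < 0) stop("trims must be >= 0")
  if (cfg$min_size < 1) stop("min_size must be >= 1")
  if (cfg$lca_top_percent < 0 || cfg$lca_top_percent > 100)
    stop("lca_top_percent must lie in [0, 100]")
  for (f in c("r1", "r2", "sample_sheet"))
    if (!file.exists(cfg[[f]])) stop("input file missing: ", f, " = ", cfg[[f]])
  for (f in c("ref_fasta", "tax_hits"))
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop("input file missing: ", f, " = ", cfg[[f]])
  invisible(cfg)
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match [pipeline_config()] arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

report_row <- function(rep) as.data.frame(rep)

#' Run the full pruning pipeline
#'
#' Executes, in order: paired quality filtering, paired-end assembly,
#' multi-primer removal, 5'-3' reorientation, dual-label demultiplexing,
#' pooling + tag/primer trimming, ITS2 extraction, dereplication,
#' abundance sorting, greedy OTU clustering with de-novo bimera
#' rejection, reference-based chimera filtering (when a reference is
#' configured), LCA fungal gating (when homology hits are configured),
#' read mapping and OTU table construction. Every stage writes its
#' intermediate files under `out_dir` so any two stages can be
#' cross-checked by hand, and contributes one row to the pruning report.
#'
#' @param cfg a [pipeline_config()].
#' @param quiet suppress per-stage messages.
#' @return list with `otu_table` (matrix), `otus` (record frame),
#'   `readmap`, `pruning_report` (data frame, one row per stage),
#'   `reports` (the stage_report objects) and `taxa_summary` (or `NULL`).
#' @export
run_all <- function(cfg, quiet = FALSE) {
  validate_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(cfg$out_dir, ...)
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  reports <- list()
  push <- function(rep) {
    reports[[length(reports) + 1L]] <<- rep
    say("%-22s in=%d kept=%d discarded=%d [%s]",
        rep$stage, rep$n_in, rep$n_kept, rep$n_discarded, rep$unit)
  }

  sheet <- read_sample_sheet(cfg$sample_sheet)
  anchors <- cfg$anchors %||% load_anchor_model()

  pairs <- read_fastq_pairs(cfg$r1, cfg$r2)
  qf <- quality_filter_pairs(pairs, cfg$mean_q, cfg$len_min)
  push(qf$report)
  write_fastq(qf$pairs$r1, out("filtered_R1.fastq"))
  write_fastq(qf$pairs$r2, out("filtered_R2.fastq"))

  mg <- merge_stream(qf$pairs, cfg$min_overlap, cfg$max_overlap_mismatch_frac,
                     cfg$reject_N)
  push(mg$report)
  write_fastq(mg$merged[, c("id", "desc", "seq", "qual")], out("merged.fastq"))

  mp <- remove_multiprimer(mg$merged, cfg$primer_fwd, cfg$primer_rev)
  push(mp$report)
  write_fastq(mp$kept[, c("id", "desc", "seq", "qual")], out("deprimered.fastq"))

  orr <- orient_reads(mp$kept, cfg$primer_fwd, cfg$orient_mismatches)
  push(orr$report)
  write_fastq(orr$oriented[, c("id", "desc", "seq", "qual")], out("oriented.fastq"))

  dm <- demultiplex(orr$oriented, sheet, cfg$primer_fwd, cfg$primer_rev)
  push(dm$report)
  for (nm in names(dm$samples)) write_fasta(dm$samples[[nm]], out(paste0(nm, ".fasta")))
  write_fasta(dm$unassigned, out("unassigned.fasta"))

  pooled <- pool_and_trim(dm$samples, cfg$trim_head, cfg$trim_tail)
  push(stage_report("pool_and_trim", nrow(pooled), nrow(pooled)))
  write_fasta(pooled, out("pooled_trimmed.fasta"))

  ex <- extract_its2(pooled, anchors, cfg$min_its2_len)
  push(ex$report)
  write_fasta(ex$its2, out("its2.fasta"))
  write_fasta(ex$discarded[, c("id", "desc", "seq", "qual")], out("non_its.fasta"))

  uniques <- dereplicate(ex$its2)
  push(stage_report("dereplicate", nrow(ex$its2), nrow(ex$its2)))
  write_fasta(seq_records(sprintf("unique%d;size=%d;", seq_len(nrow(uniques)),
                                  uniques$size), uniques$seq), out("derep.fasta"))

  srt <- sort_by_size(uniques, cfg$min_size)
  push(srt$report)

  cl <- greedy_cluster(srt$uniques, cfg$otu_id)
  push(cl$report)
  cent <- centroid_records(cl$centroids)
  write_fasta(cent, out("otus.fasta"))
  if (nrow(cl$chimeras))
    write_fasta(seq_records(sprintf("chimera%d;size=%d;",
                                    seq_len(nrow(cl$chimeras)), cl$chimeras$size),
                            cl$chimeras$seq), out("denovo_chimeras.fasta"))

  otus_good <- cent
  if (!is.null(cfg$ref_fasta)) {
    db <- build_refdb(read_fasta(cfg$ref_fasta))
    uc <- uchime_ref(cent, db, cfg$otu_id)
    push(uc$report)
    otus_good <- uc$clean
    write_fasta(uc$clean, out("otus_good.fasta"))
    write_fasta(uc$chimeric, out("otus_chim.fasta"))
    utils::write.table(uc$verdicts, out("ref_chimera_verdicts.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  taxa_summary <- NULL
  if (!is.null(cfg$tax_hits)) {
    hits <- read_tax_hits(cfg$tax_hits)
    assignments <- lca_assign(hits, cfg$lca_min_score, cfg$lca_top_percent,
                              cfg$lca_min_support)
    fg <- filter_fungal(otus_good, assignments)
    push(fg$report)
    otus_good <- fg$fungal
    taxa_summary <- fg$summary
    write_fasta(otus_good, out("fungal_otus.fasta"))
    utils::write.table(taxa_summary, out("taxa_summary.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  if (nrow(otus_good) == 0L) stop("stage otu_table: no OTUs survive filtering")
  rl <- relabel_otus(otus_good)
  write_fasta(rl$otus, out("otus_numbered.fasta"))
  utils::write.table(rl$mapping, out("otu_relabel_map.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  mpd <- map_reads(ex$its2, rl$otus, cfg$map_id)
  push(mpd$report)
  tab <- build_otu_table(mpd$readmap, rl$otus$id, sheet$name)
  write_otu_table(tab, out("otu_table.tsv"))

  pruning <- do.call(rbind, lapply(reports, as.data.frame))
  utils::write.table(pruning, out("pruning_report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  assert_monotone_pruning(pruning)

  list(otu_table = tab, otus = rl$otus, readmap = mpd$readmap,
       pruning_report = pruning, reports = reports, taxa_summary = taxa_summary)
}

#' Check that read counts only decrease across read-level stages
#'
#' @param pruning pruning report data frame from [run_all()].
#' @return TRUE invisibly; errors if a read-level stage gained reads.
#' @export
assert_monotone_pruning <- function(pruning) {
  read_stages <- pruning[pruning$unit %in% c("reads", "read_pairs") &
                           pruning$stage != "map_reads", , drop = FALSE]
  kept <- read_stages$n_kept
  if (any(diff(kept) > 0))
    stop("pruning not monotone: a read-level stage gained reads")
  invisible(TRUE)
}

#' Chimera accounting across the two filtering steps
#'
#' Book-keeping used in the pruning report: given the number of clustered
#' OTUs and the counts flagged by the de-novo and reference-based chimera
#' filters, returns the combined chimeric fraction and the surviving OTU
#' count.
#'
#' @param n_otus OTUs produced by clustering (pre-filter total).
#' @param n_denovo OTUs flagged by the de-novo filter.
#' @param n_ref OTUs flagged by the reference-based filter.
#' @return list with `n_chimeric`, `pct_chimeric` (percent of all OTUs)
#'   and `n_surviving`.
#' @export
chimera_accounting <- function(n_otus, n_denovo, n_ref) {
  stopifnot(n_otus > 0, n_denovo >= 0, n_ref >= 0)
  n_chim <- as.integer(n_denovo) + as.integer(n_ref)
  list(n_chimeric = n_chim,
       pct_chimeric = 100 * n_chim / as.integer(n_otus),
       n_surviving = as.integer(n_otus) - n_chim)
}
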