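as_dna_set <- function(records) Biostrings::DNAStringSet(toupper(records$seq))

count_exact <- function(subject_set, pattern) {
  Biostrings::vcountPattern(pattern, subject_set, fixed = TRUE)
}

#' Remove reads with multiple primer occurrences
#'
#' Amplicon libraries occasionally contain molecules with primers repeated
#' internally or at the ends, at lengths similar to genuine inserts, so
#' they escape electrophoresis/Bioanalyzer QC. A read is kept only if each
#' primer occurs at most once counting BOTH strands: exact occurrences of
#' `fwd` plus `revcomp(fwd)` must be <= 1, and likewise for `rev`. Reads
#' containing neither primer are kept here; they fall out at reorientation.
#'
#' @param records record frame (merged reads).
#' @param primer_fwd,primer_rev primer sequences, plain ACGT (ambiguity
#'   codes are rejected because occurrence counting is exact).
#' @return list with `kept` (record frame, order preserved) and `report`
#'   (reason `multiprimer`).
#' @export
remove_multiprimer <- function(records, primer_fwd, primer_rev) {
  for (p in c(primer_fwd, primer_rev))
    if (grepl("[^ACGTacgt]", p))
      stop("primer contains ambiguity codes; exact occurrence counting requires plain ACGT")
  n <- nrow(records)
  if (n == 0L)
    return(list(kept = records, report = stage_report("remove_multiprimer", 0L, 0L)))
  set <- as_dna_set(records)
  nf <- count_exact(set, toupper(primer_fwd)) + count_exact(set, revcomp(primer_fwd))
  nr <- count_exact(set, toupper(primer_rev)) + count_exact(set, revcomp(primer_rev))
  keep <- nf <= 1L & nr <= 1L
  reasons <- c(multiprimer = sum(!keep))
  list(kept = records[keep, , drop = FALSE],
       report = stage_report("remove_multiprimer", n, sum(keep),
                             reasons[reasons > 0]))
}

#' Reorient reads to the 5'-3' strand
#'
#' MiSeq amplicons attach to the flow cell in either orientation, so about
#' half of all merged reads are reverse complements. A read containing the
#' forward primer (up to `mismatches` substitutions, any position) is kept
#' as-is; a read whose reverse complement contains it is flipped
#' (qualities reversed); a read with evidence in both orientations is
#' discarded as `ambiguous`; a read with neither is discarded as
#' `no_primer`. Idempotent: reapplying changes nothing.
#'
#' @param records record frame.
#' @param primer_fwd forward primer (IUPAC allowed; mismatch search).
#' @param mismatches allowed substitutions in the primer match (default 1).
#' @return list with `oriented` (record frame) and `report` (reasons
#'   `no_primer`, `ambiguous`).
#' @export
orient_reads <- function(records, primer_fwd, mismatches = 1) {
  stopifnot(mismatches >= 0)
  n <- nrow(records)
  if (n == 0L)
    return(list(oriented = records, report = stage_report("orient", 0L, 0L)))
  set <- as_dna_set(records)
  p <- Biostrings::DNAString(toupper(primer_fwd))
  fwd_hit <- Biostrings::vcountPattern(p, set, max.mismatch = mismatches,
                                       fixed = FALSE) > 0L
  rev_hit <- Biostrings::vcountPattern(Biostrings::reverseComplement(p), set,
                                       max.mismatch = mismatches, fixed = FALSE) > 0L
  keep_fwd <- fwd_hit & !rev_hit
  flip <- rev_hit & !fwd_hit
  oriented <- records
  if (any(flip)) {
    oriented$seq[flip] <- revcomp(oriented$seq[flip])
    has_q <- flip & !is.na(oriented$qual)
    oriented$qual[has_q] <- vapply(strsplit(oriented$qual[has_q], ""),
                                   function(x) paste(rev(x), collapse = ""),
                                   character(1))
  }
  keep <- keep_fwd | flip
  reasons <- c(no_primer = sum(!fwd_hit & !rev_hit),
               ambiguous = sum(fwd_hit & rev_hit))
  list(oriented = oriented[keep, , drop = FALSE],
       report = stage_report("orient", n, sum(keep), reasons[reasons > 0]))
}

#' Read a sample sheet (name,tag CSV)
#'
#' @param path CSV with header columns `name` and `tag` (8-bp labels).
#' @return data frame with columns `name`, `tag`.
#' @export
read_sample_sheet <- function(path) {
  sheet <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("name", "tag") %in% names(sheet)))
    stop("sample sheet must have columns 'name' and 'tag'")
  validate_sheet(sheet)
  sheet[, c("name", "tag")]
}

validate_sheet <- function(sheet) {
  if (anyDuplicated(sheet$tag)) stop("duplicate tag in sample sheet")
  if (anyDuplicated(sheet$name)) stop("duplicate sample name in sample sheet")
  if (length(unique(nchar(sheet$tag))) > 1) stop("tags must all have equal length")
  invisible(sheet)
}

#' Demultiplex oriented reads by dual tag + primer patterns
#'
#' A read is assigned to sample s only if it starts exactly with
#' `tag_s + primer_fwd` and ends exactly with
#' `revcomp(tag_s + primer_rev)` -- a perfect match of the full primer +
#' label combination on BOTH ends, zero mismatches. Requiring the same
#' label on both ends is what defends against tag switching. Patterns are
#' anchored (prefix/suffix) by default; `anchored = FALSE` accepts the
#' patterns anywhere in the read (grep semantics).
#'
#' @param records oriented record frame.
#' @param sheet sample sheet (`name`, `tag`).
#' @param primer_fwd,primer_rev primer pair.
#' @param anchored require the 5' pattern as prefix and 3' pattern as
#'   suffix (default TRUE).
#' @return list with `samples` (named list of record frames, sheet order),
#'   `unassigned` (record frame) and `report` (reason `no_tag_match`).
#' @export
demultiplex <- function(records, sheet, primer_fwd, primer_rev, anchored = TRUE) {
  validate_sheet(sheet)
  n <- nrow(records)
  pattern5 <- paste0(toupper(sheet$tag), toupper(primer_fwd))
  pattern3 <- revcomp(paste0(sheet$tag, primer_rev))
  assign <- rep(NA_integer_, n)
  n_hits <- integer(n)
  for (s in seq_len(nrow(sheet))) {
    hit <- if (anchored) {
      startsWith(records$seq, pattern5[s]) & endsWith(records$seq, pattern3[s])
    } else {
      grepl(pattern5[s], records$seq, fixed = TRUE) &
        grepl(pattern3[s], records$seq, fixed = TRUE)
    }
    n_hits <- n_hits + hit
    assign[hit & is.na(assign)] <- s
  }
  assign[n_hits > 1L] <- NA_integer_  # multi-sample matches are unassigned
  samples <- lapply(seq_len(nrow(sheet)), function(s)
    records[which(assign == s), , drop = FALSE])
  names(samples) <- sheet$name
  unassigned <- records[is.na(assign), , drop = FALSE]
  reasons <- c(no_tag_match = nrow(unassigned))
  list(samples = samples, unassigned = unassigned,
       report = stage_report("demultiplex", n, n - nrow(unassigned),
                             reasons[reasons > 0]))
}

#' Pool demultiplexed samples and trim tags + primers
#'
#' Renames each read to carry its sample (`sample=NAME;<original id>`),
#' strips the first `head` and last `tail` bases (tag + primer on each
#' end; 26 bp for 8-bp tags with 18-bp primers), and concatenates samples
#' in sheet order. Output is FASTA-style (qualities dropped), since
#' demultiplexed data continue through clustering as plain sequences.
#'
#' @param sample_map named list of record frames (from [demultiplex()]).
#' @param head,tail bases to remove from each end (default 26/26).
#' @return record frame with `sample=NAME;` id prefixes and `qual = NA`.
#' @export
pool_and_trim <- function(sample_map, head = 26, tail = 26) {
  stopifnot(head >= 0, tail >= 0)
  pooled <- lapply(names(sample_map), function(nm) {
    rec <- sample_map[[nm]]
    if (nrow(rec) == 0L) return(seq_records(character(), character()))
    if (any(nchar(rec$seq) <= head + tail))
      stop("read shorter than head+tail trim in sample '", nm, "'")
    seq_records(paste0("sample=", nm, ";", rec$id),
                substr(rec$seq, head + 1L, nchar(rec$seq) - tail),
                rec$desc)
  })
  do.call(rbind, c(pooled, list(make.row.names = FALSE)))
}

#' Sample name encoded in a pooled read header
#'
#' @param id character vector of `sample=NAME;<id>` identifiers.
#' @return character vector of sample names.
#' @export
sample_of <- function(id) {
  bad <- !grepl("^sample=[^;]+;", id)
  if (any(bad)) stop("read id without 'sample=NAME;' annotation: ", id[bad][1])
  sub("^sample=([^;]+);.*$", "\\1", id)
}
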