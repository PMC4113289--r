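#' Paired quality/length filtering of read pairs
#'
#' A pair survives only if BOTH mates have mean phred quality at or above
#' `mean_q_min` and length at or above `len_min`: removing a low-quality
#' read always removes its mate too, preserving the positional
#' synchronization the paired-end assembler requires. Each mate is judged
#' independently on its own length and quality.
#'
#' @param pairs list with `r1`, `r2` record frames (see
#'   [read_fastq_pairs()]); both mates must carry qualities.
#' @param mean_q_min minimum mean phred score (default 26).
#' @param len_min minimum read length in bases (default 150).
#' @return list with `pairs` (filtered, order preserved) and `report`
#'   (a [stage_report()] with reasons `too_short` and `low_quality`).
#' @export
quality_filter_pairs <- function(pairs, mean_q_min = 26, len_min = 150) {
  stopifnot(mean_q_min >= 0, len_min >= 1)
  r1 <- pairs$r1; r2 <- pairs$r2
  if (nrow(r1) && (any(is.na(r1$qual)) || any(is.na(r2$qual))))
    stop("quality filtering requires FASTQ qualities on both mates")
  n <- nrow(r1)
  if (n == 0L) {
    return(list(pairs = pairs,
                report = stage_report("quality_filter", 0L, 0L, unit = "read_pairs")))
  }
  short <- nchar(r1$seq) < len_min | nchar(r2$seq) < len_min
  lowq <- mean_phred(r1$qual) < mean_q_min | mean_phred(r2$qual) < mean_q_min
  keep <- !short & !lowq
  reasons <- c(too_short = sum(short), low_quality = sum(lowq & !short))
  list(pairs = list(r1 = r1[keep, , drop = FALSE], r2 = r2[keep, , drop = FALSE]),
       report = stage_report("quality_filter", n, sum(keep),
                             reasons[reasons > 0], unit = "read_pairs"))
}

#' Merge one read pair by overlap consensus
#'
#' Candidate overlaps are every length L from `min(len1, len2)` down to
#' `min_overlap` between the 3' end of R1 and the 5' end of
#' `revcomp(R2)`. Each candidate is scored as matches minus mismatches over
#' the overlap; the highest-scoring L wins (ties to the longest overlap).
#' In the consensus, agreeing positions take the shared base with quality
#' `min(q1 + q2, 41)`; disagreeing positions take the higher-quality base
#' with quality `|q1 - q2|` (quality tie: R1's base at quality 2). The pair
#' is rejected -- a categorized outcome, not an error -- when no candidate
#' overlap exists, when the best overlap's mismatch fraction exceeds
#' `max_overlap_mismatch_frac`, or (with `reject_N`) when the merged
#' sequence contains an N.
#'
#' @param r1,r2 single-row record frames (or lists with `seq`/`qual`).
#' @param min_overlap minimum overlap length (default 5).
#' @param max_overlap_mismatch_frac maximum tolerated mismatch fraction in
#'   the chosen overlap (default 0.25).
#' @param reject_N reject merged sequences containing N (default TRUE).
#' @return list with `status` (`"merged"`, `"no_overlap"`,
#'   `"too_many_mismatches"` or `"contains_N"`) and, when merged, `seq`,
#'   `qual`, `overlap`, `n_corrected`, `mismatch_frac`.
#' @export
merge_pair <- function(r1, r2, min_overlap = 5, max_overlap_mismatch_frac = 0.25,
                       reject_N = TRUE) {
  stopifnot(min_overlap >= 1)
  res <- cpp_merge_pair(toupper(r1$seq), r1$qual, revcomp(r2$seq),
                        paste(rev(strsplit(r2$qual, "")[[1]]), collapse = ""),
                        as.integer(min_overlap), max_overlap_mismatch_frac)
  if (identical(res$status, "merged") && reject_N && grepl("N", res$seq, fixed = TRUE))
    res$status <- "contains_N"
  res
}

#' Merge a stream of read pairs
#'
#' Applies the [merge_pair()] rule to every pair in order and collects the
#' merged reads plus a pruning report.
#'
#' @param pairs list with `r1`, `r2` record frames.
#' @inheritParams merge_pair
#' @return list with `merged` (record frame carrying extra columns
#'   `overlap` and `n_corrected`) and `report` (reasons `no_overlap`,
#'   `too_many_mismatches`, `contains_N`).
#' @export
merge_stream <- function(pairs, min_overlap = 5, max_overlap_mismatch_frac = 0.25,
                         reject_N = TRUE) {
  stopifnot(min_overlap >= 1)
  r1 <- pairs$r1; r2 <- pairs$r2
  n <- nrow(r1)
  if (n == 0L) {
    merged <- seq_records(character(), character())
    merged$overlap <- integer(0); merged$n_corrected <- integer(0)
    return(list(merged = merged,
                report = stage_report("merge", 0L, 0L, unit = "read_pairs")))
  }
  if (any(is.na(r1$qual)) || any(is.na(r2$qual)))
    stop("merging requires FASTQ qualities on both mates")
  q2r <- vapply(strsplit(r2$qual, ""), function(x)
    paste(rev(x), collapse = ""), character(1))
  res <- cpp_merge_pairs(toupper(r1$seq), r1$qual, revcomp(r2$seq), q2r,
                         as.integer(min_overlap), max_overlap_mismatch_frac)
  status <- res$status
  if (reject_N) {
    hasN <- status == "merged" & grepl("N", res$seq, fixed = TRUE)
    status[hasN] <- "contains_N"
  }
  keep <- status == "merged"
  merged <- seq_records(r1$id[keep], res$seq[keep], r1$desc[keep], res$qual[keep])
  merged$overlap <- res$overlap[keep]
  merged$n_corrected <- res$n_corrected[keep]
  reasons <- table(status[!keep])
  reasons <- stats::setNames(as.integer(reasons), names(reasons))
  list(merged = merged,
       report = stage_report("merge", n, sum(keep), reasons, unit = "read_pairs"))
}

#' Read length distribution
#'
#' Two-column length/count summary of a record frame, the analogue of the
#' quality filter's optional length-distribution output.
#'
#' @param records record frame.
#' @return data frame with columns `length`, `count`.
#' @export
length_distribution <- function(records) {
  tab <- table(nchar(records$seq))
  data.frame(length = as.integer(names(tab)), count = as.integer(tab))
}
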