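#' Construct a set of sequence records
#'
#' The package represents sequence sets as plain data frames with columns
#' `id` (first whitespace-delimited token of the header), `desc` (remainder
#' of the header, `""` if none), `seq` (DNA over A/C/G/T/N, uppercase by
#' convention) and `qual` (per-base phred+33 quality string, or `NA` for
#' FASTA-only records). This keeps every intermediate inspectable with
#' ordinary data-frame tools, in the spirit of a pipeline whose every stage
#' should be checkable by eye.
#'
#' @param id character vector of identifiers (nonempty, no whitespace).
#' @param seq character vector of DNA sequences.
#' @param desc character vector of description strings (recycled).
#' @param qual character vector of phred+33 quality strings, or `NA`.
#' @return data frame with columns `id`, `desc`, `seq`, `qual`.
#' @export
seq_records <- function(id, seq, desc = "", qual = NA_character_) {
  id <- as.character(id); seq <- as.character(seq)
  n <- length(id)
  stopifnot(length(seq) == n)
  desc <- rep_len(as.character(desc), n)
  qual <- rep_len(as.character(qual), n)
  if (n > 0) {
    if (any(!nzchar(id))) stop("record ids must be nonempty")
    if (any(grepl("[[:space:]]", id))) stop("record ids must not contain whitespace")
    if (any(!nzchar(seq))) stop("sequences must be nonempty")
    has_q <- !is.na(qual)
    if (any(nchar(qual[has_q]) != nchar(seq[has_q])))
      stop("quality string length differs from sequence length")
  }
  data.frame(id = id, desc = desc, seq = seq, qual = qual,
             stringsAsFactors = FALSE)
}

#' Read a FASTQ file (4-line records, phred+33)
#'
#' Only the canonical 4-line record layout is accepted. Quality characters
#' below ASCII 33 (which would decode to a negative phred score) are
#' rejected rather than reinterpreted: MiSeq-era FASTQ is uniformly
#' phred+33 and silent offset auto-detection can hide corrupted input.
#'
#' @param path FASTQ file path (plain or gzip).
#' @return sequence record data frame (see [seq_records()]).
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L)
    stop("malformed FASTQ '", path, "': line count not a multiple of 4")
  if (length(lines) == 0L) return(seq_records(character(), character()))
  i <- seq(1L, length(lines), by = 4L)
  hdr <- lines[i]; seq <- lines[i + 1L]; plus <- lines[i + 2L]; qual <- lines[i + 3L]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad)) stop("malformed FASTQ record ", bad[1], ": header must start with '@'")
  bad <- which(!startsWith(plus, "+"))
  if (length(bad)) stop("malformed FASTQ record ", bad[1], ": missing '+' separator line")
  bad <- which(nchar(seq) != nchar(qual))
  if (length(bad)) stop("malformed FASTQ record ", bad[1],
                        ": sequence and quality lengths differ")
  qr <- range(utf8ToInt(paste(qual, collapse = "")))
  if (length(qual) && qr[1] < 33L)
    stop("quality character below phred+33 offset (score < 0); ",
         "only phred+33 input is supported")
  hdr <- sub("^@", "", hdr)
  id <- sub("[[:space:]].*$", "", hdr)
  desc <- ifelse(grepl("[[:space:]]", hdr),
                 sub("^[^[:space:]]+[[:space:]]+", "", hdr), "")
  seq_records(id, seq, desc, qual)
}

#' Read a FASTA file
#'
#' Multi-line sequence blocks are accepted on input; [write_fasta()] always
#' writes single-line sequences so that downstream exact string checks
#' (grep-style revision techniques) behave predictably.
#'
#' @param path FASTA file path.
#' @return sequence record data frame with `qual = NA`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0L) return(seq_records(character(), character()))
  hdr <- names(x)
  id <- sub("[[:space:]].*$", "", hdr)
  desc <- ifelse(grepl("[[:space:]]", hdr),
                 sub("^[^[:space:]]+[[:space:]]+", "", hdr), "")
  seq_records(id, as.character(x), desc)
}

fastq_header <- function(records) {
  ifelse(nzchar(records$desc), paste(records$id, records$desc), records$id)
}

#' Write records as FASTQ
#'
#' @param records sequence record data frame; all records must carry
#'   quality strings.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(records, path) {
  if (nrow(records) && any(is.na(records$qual)))
    stop("cannot write FASTQ: records without quality strings")
  if (nrow(records) == 0L) { writeLines(character(), path); return(invisible(path)) }
  out <- rbind(paste0("@", fastq_header(records)), records$seq, "+", records$qual)
  writeLines(as.vector(out), path)
  invisible(path)
}

#' Write records as FASTA (single-line sequences; qualities dropped)
#'
#' @inheritParams write_fastq
#' @export
write_fasta <- function(records, path) {
  if (nrow(records) == 0L) { writeLines(character(), path); return(invisible(path)) }
  out <- rbind(paste0(">", fastq_header(records)), records$seq)
  writeLines(as.vector(out), path)
  invisible(path)
}

#' Read a pair of FASTQ files as synchronized read pairs
#'
#' Pair identity is positional: record i of the R1 file is mated with record
#' i of the R2 file, which is the contract the downstream paired-end
#' assembler relies on. A mismatch in record counts is an error; differing
#' id stems (after stripping a trailing `/1`, `/2` or mate field) only
#' trigger a warning, since many instruments rewrite mate suffixes.
#'
#' @param path_r1,path_r2 FASTQ paths for the forward and reverse mates.
#' @return list with elements `r1` and `r2`, equal-height record frames.
#' @export
read_fastq_pairs <- function(path_r1, path_r2) {
  r1 <- read_fastq(path_r1)
  r2 <- read_fastq(path_r2)
  if (nrow(r1) != nrow(r2))
    stop("paired FASTQ files desynchronized after pair ", min(nrow(r1), nrow(r2)),
         ": ", nrow(r1), " vs ", nrow(r2), " records")
  stem <- function(id) sub("[/ ._][12]$", "", id)
  bad <- which(stem(r1$id) != stem(r2$id))
  if (length(bad))
    warning(length(bad), " read pair(s) with differing id stems (first at record ",
            bad[1], "); pairing is positional")
  list(r1 = r1, r2 = r2)
}

#' Reverse complement DNA strings
#'
#' Vectorized; accepts the IUPAC alphabet (N maps to N) and errors on any
#' other character. An involution: `revcomp(revcomp(x)) == x`.
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements (uppercase).
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(toupper(x))))
}

#' Decode a phred+33 quality string to integer scores
#'
#' @param qual a single quality string.
#' @return integer vector of phred scores.
#' @export
phred_scores <- function(qual) {
  utf8ToInt(qual) - 33L
}

#' Mean phred score of quality strings
#'
#' @param qual character vector of phred+33 quality strings.
#' @return numeric vector of arithmetic mean scores.
#' @export
mean_phred <- function(qual) {
  if (length(qual) == 0L) stop("empty quality input")
  vapply(qual, function(q) {
    if (is.na(q) || !nzchar(q)) stop("empty quality string")
    mean(utf8ToInt(q)) - 33
  }, numeric(1), USE.NAMES = FALSE)
}

#' Per-stage pruning report
#'
#' Each pipeline stage accounts for every read (or cluster) it receives:
#' `n_in == n_kept + n_discarded`, and the per-reason discard counts sum to
#' `n_discarded`. These reports concatenate into the pipeline's pruning
#' table.
#'
#' @param stage stage name.
#' @param n_in number of items entering the stage.
#' @param n_kept number of items kept.
#' @param reasons named integer vector of discard reasons (may be empty).
#' @param unit `"reads"`, `"read_pairs"` or `"clusters"`.
#' @return object of class `stage_report`.
#' @export
stage_report <- function(stage, n_in, n_kept, reasons = integer(), unit = "reads") {
  n_in <- as.integer(n_in); n_kept <- as.integer(n_kept)
  reasons <- vapply(reasons, as.integer, integer(1))
  n_discarded <- n_in - n_kept
  if (n_discarded < 0L) stop("n_kept exceeds n_in in stage '", stage, "'")
  if (length(reasons) && sum(reasons) != n_discarded)
    stop("discard reasons do not sum to n_discarded in stage '", stage, "'")
  structure(list(stage = stage, unit = unit, n_in = n_in, n_kept = n_kept,
                 n_discarded = n_discarded, reasons = reasons),
            class = "stage_report")
}

#' @export
print.stage_report <- function(x, ...) {
  cat(sprintf("[%s] %s: in=%d kept=%d discarded=%d\n",
              x$unit, x$stage, x$n_in, x$n_kept, x$n_discarded))
  if (length(x$reasons))
    cat(paste0("  - ", names(x$reasons), ": ", x$reasons, collapse = "\n"), "\n")
  invisible(x)
}

#' @export
as.data.frame.stage_report <- function(x, ...) {
  data.frame(stage = x$stage, unit = x$unit, n_in = x$n_in, n_kept = x$n_kept,
             n_discarded = x$n_discarded,
             reasons = if (length(x$reasons))
               paste(names(x$reasons), x$reasons, sep = "=", collapse = ";")
             else "", stringsAsFactors = FALSE)
}
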