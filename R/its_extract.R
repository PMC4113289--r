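#' Anchor model for ITS2 extraction
#'
#' The ITS2 is delimited by conserved rRNA regions: the 3' end of the 5.8S
#' gene upstream and the 5' start of the LSU downstream. Extraction locates
#' one motif from each list near the respective read end and keeps only
#' the sequence strictly between them, because residual conserved bases
#' inflate similarity between unrelated sequences and bias both clustering
#' and database searches. Motifs are data, not code: the defaults ship as
#' a YAML file (`inst/extdata/its2_anchors.yml`) and can be replaced for
#' other primer systems or markers.
#'
#' @param motifs_5p,motifs_3p character vectors of IUPAC motifs (>= 8 bp).
#' @param max_mismatches allowed mismatches per motif match (default 1).
#' @param search_window_5p,search_window_3p window, in bases from the
#'   respective read end, within which the anchor must lie (default 80).
#' @return object of class `anchor_model`.
#' @export
anchor_model <- function(motifs_5p, motifs_3p, max_mismatches = 1,
                         search_window_5p = 80, search_window_3p = 80) {
  motifs_5p <- toupper(motifs_5p); motifs_3p <- toupper(motifs_3p)
  for (m in c(motifs_5p, motifs_3p)) {
    if (nchar(m) < 8) stop("anchor motifs must be at least 8 bp")
    if (grepl("[^ACGTMRWSYKVHDBN]", m))
      stop("invalid IUPAC character in motif: ", m)
  }
  if (search_window_5p < max(nchar(motifs_5p)) ||
      search_window_3p < max(nchar(motifs_3p)))
    stop("search window smaller than motif length")
  structure(list(motifs_5p = motifs_5p, motifs_3p = motifs_3p,
                 max_mismatches = as.integer(max_mismatches),
                 search_window_5p = as.integer(search_window_5p),
                 search_window_3p = as.integer(search_window_3p)),
            class = "anchor_model")
}

#' Load an anchor model from a YAML file
#'
#' @param path YAML file with keys `motifs_5p`, `motifs_3p` and optional
#'   `max_mismatches`, `search_window_5p`, `search_window_3p`. Default:
#'   the packaged ITS2 model.
#' @return an [anchor_model()].
#' @export
load_anchor_model <- function(path = system.file("extdata", "its2_anchors.yml",
                                                 package = "fungits")) {
  y <- yaml::read_yaml(path)
  anchor_model(motifs_5p = unlist(y$motifs_5p), motifs_3p = unlist(y$motifs_3p),
               max_mismatches = y$max_mismatches %||% 1,
               search_window_5p = y$search_window_5p %||% 80,
               search_window_3p = y$search_window_3p %||% 80)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# vectorized anchor search over a character vector of sequences within the
# window at the given end; returns a list with start/end (1-based, NA if no
# motif matches). Best match = fewest mismatches, then outermost (closest to
# the respective read end); motif list order breaks remaining ties.
find_anchor_many <- function(seqs, motifs, max_mm, window, end = c("5p", "3p")) {
  end <- match.arg(end)
  n <- length(seqs)
  lens <- nchar(seqs)
  if (any(window > lens)) stop("search window longer than sequence")
  win_seq <- if (end == "5p") substr(seqs, 1L, window)
             else substr(seqs, lens - window + 1L, lens)
  offset <- if (end == "5p") rep(0L, n) else lens - window
  set <- Biostrings::DNAStringSet(toupper(win_seq))
  start <- rep(NA_integer_, n); stop_ <- rep(NA_integer_, n)
  unresolved <- rep(TRUE, n)
  for (mm in 0:max_mm) {
    if (!any(unresolved)) break
    for (motif in motifs) {
      if (!any(unresolved)) break
      p <- Biostrings::DNAString(motif)
      hits <- Biostrings::vmatchPattern(p, set[unresolved], max.mismatch = mm,
                                        fixed = FALSE)
      starts <- Biostrings::startIndex(hits)
      idx <- which(unresolved)
      for (k in seq_along(idx)) {
        st <- starts[[k]]
        if (is.null(st) || length(st) == 0L) next
        best <- if (end == "5p") min(st) else max(st)
        i <- idx[k]
        start[i] <- best + offset[i]
        stop_[i] <- start[i] + nchar(motif) - 1L
        unresolved[i] <- FALSE
      }
    }
  }
  list(start = start, end = stop_)
}

#' Locate a conserved anchor motif near one end of a sequence
#'
#' Searches the window from the given end for the best match of any motif:
#' fewest mismatches first, then the outermost position (smallest start
#' for the 5' end, largest for the 3' end). IUPAC codes in the motif match
#' their base sets.
#'
#' @param seq a single DNA string.
#' @param motifs character vector of IUPAC motifs.
#' @param max_mm allowed mismatches.
#' @param window search window from the end, in bases.
#' @param end `"5p"` or `"3p"`.
#' @return list with 1-based `start` and `end` of the match, or `NULL` if
#'   no motif matches.
#' @export
find_anchor <- function(seq, motifs, max_mm = 1, window = 80, end = c("5p", "3p")) {
  res <- find_anchor_many(seq, motifs, max_mm, min(window, nchar(seq)), end)
  if (is.na(res$start[1])) return(NULL)
  list(start = res$start[1], end = res$end[1])
}

#' Extract the ITS2 region between conserved anchors
#'
#' For each read, locates a 5' anchor and a 3' anchor with
#' [find_anchor()]; the extracted ITS2 is the sequence strictly between
#' them (no anchor bases included). Reads missing either anchor, or whose
#' extraction would be shorter than `min_len`, go to the discard stream
#' with a reason; headers are preserved verbatim.
#'
#' @param records record frame (trimmed of tags and primers).
#' @param model an [anchor_model()].
#' @param min_len minimum extracted length (default 30 bp; shorter
#'   fragments are uninformative at a 97% clustering threshold).
#' @return list with `its2` (record frame), `discarded` (record frame with
#'   a `reason` column) and `report` (reasons `no_5p_anchor`,
#'   `no_3p_anchor`, `too_short`).
#' @export
extract_its2 <- function(records, model, min_len = 30) {
  n <- nrow(records)
  if (n == 0L) {
    disc <- records; disc$reason <- character(0)
    return(list(its2 = records, discarded = disc,
                report = stage_report("extract_its2", 0L, 0L)))
  }
  lens <- nchar(records$seq)
  w5 <- pmin(model$search_window_5p, lens)
  w3 <- pmin(model$search_window_3p, lens)
  # windows can differ per read; process in groups of equal window size
  a5 <- list(start = rep(NA_integer_, n), end = rep(NA_integer_, n))
  a3 <- list(start = rep(NA_integer_, n), end = rep(NA_integer_, n))
  for (w in unique(w5)) {
    i <- which(w5 == w)
    r <- find_anchor_many(records$seq[i], model$motifs_5p, model$max_mismatches,
                          w, "5p")
    a5$start[i] <- r$start; a5$end[i] <- r$end
  }
  for (w in unique(w3)) {
    i <- which(w3 == w)
    r <- find_anchor_many(records$seq[i], model$motifs_3p, model$max_mismatches,
                          w, "3p")
    a3$start[i] <- r$start; a3$end[i] <- r$end
  }
  reason <- rep(NA_character_, n)
  reason[is.na(a5$start)] <- "no_5p_anchor"
  reason[is.na(reason) & is.na(a3$start)] <- "no_3p_anchor"
  from <- a5$end + 1L; to <- a3$start - 1L
  short <- is.na(reason) & (to - from + 1L < min_len)
  reason[short] <- "too_short"
  keep <- is.na(reason)
  its2 <- records[keep, , drop = FALSE]
  its2$seq <- substr(its2$seq, from[keep], to[keep])
  has_q <- !is.na(its2$qual)
  its2$qual[has_q] <- substr(its2$qual[has_q], from[keep][has_q], to[keep][has_q])
  discarded <- records[!keep, , drop = FALSE]
  discarded$reason <- reason[!keep]
  reasons <- table(reason[!keep])
  list(its2 = its2, discarded = discarded,
       report = stage_report("extract_its2", n, sum(keep),
                             stats::setNames(as.integer(reasons), names(reasons))))
}
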