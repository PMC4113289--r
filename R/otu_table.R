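parse_size <- function(id) {
  hit <- grepl("size=[0-9]+", id)
  size <- rep(NA_integer_, length(id))
  size[hit] <- as.integer(sub(".*?size=([0-9]+).*", "\\1", id[hit]))
  size
}

#' Relabel OTU representatives OTU_1, OTU_2, ...
#'
#' Sequential labels in decreasing abundance (taken from the `;size=N;`
#' header annotation; ties broken lexicographically by sequence). Records
#' without a size annotation keep their order of appearance, with a
#' warning. Idempotent on its own output (sizes are preserved in the
#' description).
#'
#' @param otus record frame of OTU representatives.
#' @param prefix label prefix (default `"OTU_"`).
#' @return list with `otus` (relabelled record frame; size kept as
#'   `size=N` in `desc`) and `mapping` (data frame `old_id`, `new_id`).
#' @export
relabel_otus <- function(otus, prefix = "OTU_") {
  n <- nrow(otus)
  if (n == 0L) stop("no OTU sequences to relabel")
  size <- parse_size(otus$id)
  if (all(is.na(size))) size <- parse_size(paste0(";", otus$desc))
  if (anyNA(size)) {
    if (!all(is.na(size)))
      size[is.na(size)] <- 0L
    else {
      warning("missing ;size=N; annotations; using order of appearance")
      size <- rep(0L, n)
    }
  }
  ord <- order(-size, otus$seq)
  out <- otus[ord, , drop = FALSE]
  mapping <- data.frame(old_id = out$id,
                        new_id = paste0(prefix, seq_len(n)),
                        stringsAsFactors = FALSE)
  out$desc <- ifelse(size[ord] > 0L, paste0("size=", size[ord]), out$desc)
  out$id <- mapping$new_id
  rownames(out) <- NULL
  list(otus = out, mapping = mapping)
}

#' Map reads against OTU representatives
#'
#' Plus-strand global mapping of (unclustered) ITS2 reads against the
#' final OTU set: a read is assigned to the representative with the
#' highest [global_identity()] when that identity reaches `id_threshold`
#' (ties to the lower OTU index). Reads sharing no 8-mer with any OTU are
#' reported as `no_candidate`; reads whose best identity falls below the
#' threshold as `below_threshold`. Identical reads are collapsed before
#' alignment, so the cost scales with distinct sequences, not reads.
#'
#' @param reads record frame with `sample=NAME;` header annotations.
#' @param otus relabelled OTU record frame (from [relabel_otus()]).
#' @param id_threshold minimum identity (default 0.97).
#' @return list with `readmap` (data frame `read_id`, `sample`, `otu`,
#'   `identity`, `reason`) and `report` (reasons `below_threshold`,
#'   `no_candidate`).
#' @export
map_reads <- function(reads, otus, id_threshold = 0.97) {
  n <- nrow(reads)
  sample <- sample_of(reads$id)
  if (n == 0L)
    return(list(readmap = data.frame(read_id = character(), sample = character(),
                                     otu = character(), identity = numeric(),
                                     reason = character()),
                report = stage_report("map_reads", 0L, 0L)))
  qseq <- toupper(reads$seq)
  uniq <- unique(qseq)
  oseq <- toupper(otus$seq)
  exact <- match(uniq, oseq)
  otu_kmers <- lapply(oseq, seq_kmers)
  u_otu <- rep(NA_integer_, length(uniq))
  u_id <- rep(NA_real_, length(uniq))
  u_reason <- rep(NA_character_, length(uniq))
  for (u in seq_along(uniq)) {
    if (!is.na(exact[u])) { u_otu[u] <- exact[u]; u_id[u] <- 1; next }
    qk <- seq_kmers(uniq[u])
    cand <- which(vapply(otu_kmers, function(k) any(qk %in% k), logical(1)))
    if (!length(cand)) { u_reason[u] <- "no_candidate"; next }
    ids <- cpp_identity_many(uniq[u], oseq[cand])
    best <- which.max(ids)  # which.max: first max = lowest OTU index
    if (ids[best] >= id_threshold) {
      u_otu[u] <- cand[best]; u_id[u] <- ids[best]
    } else {
      u_reason[u] <- "below_threshold"; u_id[u] <- ids[best]
    }
  }
  ix <- match(qseq, uniq)
  readmap <- data.frame(read_id = reads$id, sample = sample,
                        otu = otus$id[u_otu[ix]],
                        identity = u_id[ix], reason = u_reason[ix],
                        stringsAsFactors = FALSE)
  mapped <- !is.na(readmap$otu)
  reasons <- table(readmap$reason[!mapped])
  list(readmap = readmap,
       report = stage_report("map_reads", n, sum(mapped),
                             stats::setNames(as.integer(reasons), names(reasons))))
}

#' Build the OTU x sample abundance table
#'
#' @param readmap data frame from [map_reads()].
#' @param otu_labels row order (default: `OTU_<k>` sorted by k, from the
#'   readmap's OTUs).
#' @param sample_names column order (default: samples in order of first
#'   appearance; pass the sample sheet's names for sheet order).
#' @return integer matrix, OTUs x samples; unmapped reads are excluded.
#' @export
build_otu_table <- function(readmap, otu_labels = NULL, sample_names = NULL) {
  mapped <- readmap[!is.na(readmap$otu), , drop = FALSE]
  if (is.null(otu_labels)) {
    otu_labels <- unique(mapped$otu)
    k <- suppressWarnings(as.integer(sub("^.*_", "", otu_labels)))
    if (!anyNA(k)) otu_labels <- otu_labels[order(k)]
  }
  if (is.null(sample_names)) sample_names <- unique(readmap$sample)
  tab <- table(factor(mapped$otu, levels = otu_labels),
               factor(mapped$sample, levels = sample_names))
  matrix(as.integer(tab), nrow = length(otu_labels),
         dimnames = list(otu_labels, sample_names))
}

#' Row and column sums of an OTU table (the recommended final check)
#'
#' @param tab OTU x sample matrix.
#' @return list with `per_otu`, `per_sample` and `total`.
#' @export
audit_table <- function(tab) {
  list(per_otu = rowSums(tab), per_sample = colSums(tab), total = sum(tab))
}

#' Write an OTU table as tab-delimited text
#'
#' First column `#OTU ID`, one column per sample, integer counts.
#'
#' @param tab OTU x sample matrix.
#' @param path output path.
#' @export
write_otu_table <- function(tab, path) {
  df <- data.frame(`#OTU ID` = rownames(tab), tab, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an OTU table written by [write_otu_table()]
#'
#' @param path TSV path.
#' @return integer matrix with OTU rownames.
#' @export
read_otu_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  m
}
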