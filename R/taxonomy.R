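#' Read tabular homology hits for taxonomy gating
#'
#' The homology search itself (e.g. blastn against a general nucleotide
#' database) runs outside this package; its results enter as a TSV with
#' columns `qseqid`, `lineage` (root-to-leaf path, ';'-separated),
#' `bitscore`, `evalue`.
#'
#' @param path TSV path (header required).
#' @return data frame of hits.
#' @export
read_tax_hits <- function(path) {
  hits <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("qseqid", "lineage", "bitscore", "evalue")
  if (!all(need %in% names(hits)))
    stop("hits table must have columns: ", paste(need, collapse = ", "))
  if (any(!nzchar(hits$lineage))) stop("empty lineage in hits table")
  if (any(hits$bitscore < 0)) stop("negative bitscore in hits table")
  hits[, need]
}

#' Lowest-common-ancestor taxonomy assignment
#'
#' Per query: hits below `min_score` bitscore are discarded; of the rest,
#' only hits within `top_percent` of the best bitscore (score >=
#' (1 - top_percent/100) * best) are retained; the assignment is the
#' longest common prefix of the retained lineages. Queries with no
#' surviving hit are unassigned (`NA`). `min_support` then prunes
#' assignments: each is trimmed to its deepest node supported by at least
#' `min_support` queries (support counts queries assigned at or below the
#' node); the default 1 makes this a no-op. Retaining more hits (a wider
#' score window) can only shorten an assignment, never lengthen it.
#'
#' @param hits data frame as from [read_tax_hits()].
#' @param min_score minimum bitscore (default 170).
#' @param top_percent retained-score window as percent of the best
#'   bitscore (default 5).
#' @param min_support minimum queries per assigned node (default 1).
#' @return data frame with columns `qseqid`, `lineage` (`NA` = unassigned).
#' @export
lca_assign <- function(hits, min_score = 170, top_percent = 5, min_support = 1) {
  stopifnot(top_percent >= 0, top_percent <= 100, min_support >= 1)
  all_q <- unique(hits$qseqid)
  hits <- hits[hits$bitscore >= min_score, , drop = FALSE]
  assign_one <- function(h) {
    keep <- h$bitscore >= (1 - top_percent / 100) * max(h$bitscore)
    paths <- strsplit(h$lineage[keep], ";", fixed = TRUE)
    lca <- Reduce(function(a, b) {
      k <- 0L
      while (k < min(length(a), length(b)) && a[k + 1L] == b[k + 1L]) k <- k + 1L
      a[seq_len(k)]
    }, paths)
    if (length(lca) == 0L) NA_character_ else paste(lca, collapse = ";")
  }
  res <- vapply(split(hits, hits$qseqid), assign_one, character(1))
  out <- data.frame(qseqid = all_q,
                    lineage = unname(res[match(all_q, names(res))]),
                    stringsAsFactors = FALSE)
  if (min_support > 1 && nrow(out)) {
    # support of a node = queries assigned at or below it (prefix count);
    # each assignment is trimmed to its deepest sufficiently supported node
    paths <- strsplit(ifelse(is.na(out$lineage), "", out$lineage), ";",
                      fixed = TRUE)
    node_support <- function(prefix) {
      k <- length(prefix)
      sum(vapply(paths, function(p)
        length(p) >= k && identical(p[seq_len(k)], prefix), logical(1)))
    }
    out$lineage <- vapply(paths, function(p) {
      while (length(p) && node_support(p) < min_support) p <- p[-length(p)]
      if (!length(p)) NA_character_ else paste(p, collapse = ";")
    }, character(1))
  }
  out
}

#' Retain fungal OTUs; tally the rest by top-level group
#'
#' An OTU is kept iff its assigned lineage contains the node `Fungi`.
#' Excluded OTUs are tallied by their top-level group (first informative
#' element after generic roots such as `root`, `cellular organisms`,
#' `Eukaryota`); OTUs absent from the assignments, or unassigned, count
#' under `No hits/unassigned`.
#'
#' @param otus record frame of OTU representatives.
#' @param assignments data frame from [lca_assign()].
#' @return list with `fungal` (record frame), `summary` (data frame
#'   `group`, `n_otus`, including a `Fungi` row) and `report` (unit
#'   `clusters`, reason `non_fungal`).
#' @export
filter_fungal <- function(otus, assignments) {
  n <- nrow(otus)
  lin <- assignments$lineage[match(otus$id, assignments$qseqid)]
  paths <- strsplit(ifelse(is.na(lin), "", lin), ";", fixed = TRUE)
  is_fungal <- vapply(paths, function(p) "Fungi" %in% p, logical(1))
  group <- vapply(paths, function(p) {
    p <- p[!(p %in% c("root", "cellular organisms"))]
    if (!length(p) || !nzchar(p[1])) return("No hits/unassigned")
    if (p[1] == "Eukaryota" && length(p) > 1L) p[2] else p[1]
  }, character(1))
  group[is_fungal] <- "Fungi"
  tab <- table(group)
  summary <- data.frame(group = names(tab), n_otus = as.integer(tab),
                        stringsAsFactors = FALSE)
  summary <- summary[order(-summary$n_otus, summary$group), , drop = FALSE]
  rownames(summary) <- NULL
  reasons <- c(non_fungal = sum(!is_fungal))
  list(fungal = otus[is_fungal, , drop = FALSE], summary = summary,
       report = stage_report("filter_fungal", n, sum(is_fungal),
                             reasons[reasons > 0], unit = "clusters"))
}
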