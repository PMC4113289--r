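seq_kmers <- function(seq, k = 8L) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  km <- substring(seq, 1:(n - k + 1L), k:n)
  unique(km[!grepl("N", km, fixed = TRUE)])
}

#' Build an in-memory reference database for chimera filtering
#'
#' Indexes every reference sequence by its distinct 8-mers (8-mers
#' containing N are skipped). The index only pre-ranks candidate parents;
#' chimera verdicts always come from the full alignment-based bimera
#' rule, so the index can never create a false positive.
#'
#' @param records record frame of trusted reference sequences (e.g. a
#'   curated ITS collection), unique ids required.
#' @return object of class `ref_db`.
#' @export
build_refdb <- function(records) {
  if (nrow(records) == 0L) stop("empty reference FASTA")
  if (anyDuplicated(records$id)) stop("duplicate ids in reference FASTA")
  seqs <- toupper(records$seq)
  kmers <- lapply(seqs, seq_kmers)
  structure(list(ids = records$id, seqs = seqs, kmers = kmers), class = "ref_db")
}

#' @export
print.ref_db <- function(x, ...) {
  cat("ref_db:", length(x$ids), "sequences\n"); invisible(x)
}

#' Reference-based chimera filtering of OTU centroids
#'
#' The plus-strand-only analogue of reference-database bimera checking:
#' each query is split into `n_chunks` contiguous chunks; for every chunk
#' the references are ranked by shared distinct 8-mers and the top
#' `candidates_per_chunk` kept; the union over chunks forms the candidate
#' parent set (a chimera's halves each recruit their own parent). Every
#' candidate pair is then evaluated with the same explicit bimera rule
#' used de novo ([is_bimera()]) -- with no abundance-skew requirement,
#' since references carry no abundances. A query is chimeric iff any pair
#' satisfies the rule. Queries must already be oriented 5'-3': no
#' reverse-strand search is performed, so reverse-complemented chimeras
#' are not detected.
#'
#' @param centroids record frame of OTU representatives (oriented 5'-3').
#' @param db a [build_refdb()] database.
#' @param threshold,model_gain,min_diffs bimera rule parameters.
#' @param candidates_per_chunk references kept per chunk (default 4).
#' @param n_chunks chunks per query (default 4).
#' @return list with `clean` and `chimeric` record frames partitioning the
#'   input, `verdicts` data frame (query, parents, crossover, id_model,
#'   id_best_single, verdict), and `report` (unit `clusters`, reason
#'   `ref_chimera`).
#' @export
uchime_ref <- function(centroids, db, threshold = 0.97, model_gain = 0.02,
                       min_diffs = 3, candidates_per_chunk = 4, n_chunks = 4) {
  stopifnot(inherits(db, "ref_db"))
  n <- nrow(centroids)
  verdicts <- vector("list", n)
  chimeric <- logical(n)
  nref <- length(db$ids)
  for (i in seq_len(n)) {
    q <- toupper(centroids$seq[i])
    L <- nchar(q)
    bounds <- unique(round(seq(0, L, length.out = n_chunks + 1L)))
    cand <- integer(0)
    for (c_ in seq_len(length(bounds) - 1L)) {
      chunk <- substr(q, bounds[c_] + 1L, bounds[c_ + 1L])
      ck <- seq_kmers(chunk)
      if (!length(ck)) next
      shared <- vapply(db$kmers, function(ref) sum(ck %in% ref), integer(1))
      ord <- order(-shared, seq_len(nref))  # ties: reference order
      top <- ord[seq_len(min(candidates_per_chunk, nref))]
      cand <- union(cand, top[shared[top] > 0L])
    }
    best <- NULL
    if (length(cand) >= 2) {
      pairs <- utils::combn(sort(cand), 2)
      for (p in seq_len(ncol(pairs))) {
        a <- pairs[1, p]; b <- pairs[2, p]
        v <- is_bimera(q, db$seqs[a], db$seqs[b], threshold, model_gain, min_diffs)
        if (v$bimeric && (is.null(best) || v$id_model > best$id_model)) {
          best <- c(v, list(a = a, b = b))
        }
      }
    }
    if (!is.null(best)) {
      chimeric[i] <- TRUE
      verdicts[[i]] <- data.frame(
        query = centroids$id[i], parent_a = db$ids[best$a],
        parent_b = db$ids[best$b], crossover = best$crossover,
        id_model = best$id_model, id_best_single = best$id_best_single,
        verdict = "chimeric", stringsAsFactors = FALSE)
    } else {
      verdicts[[i]] <- data.frame(
        query = centroids$id[i], parent_a = NA_character_,
        parent_b = NA_character_, crossover = NA_integer_,
        id_model = NA_real_, id_best_single = NA_real_,
        verdict = "clean", stringsAsFactors = FALSE)
    }
  }
  verdicts <- if (n) do.call(rbind, verdicts) else
    data.frame(query = character(), parent_a = character(),
               parent_b = character(), crossover = integer(),
               id_model = numeric(), id_best_single = numeric(),
               verdict = character())
  reasons <- c(ref_chimera = sum(chimeric))
  list(clean = centroids[!chimeric, , drop = FALSE],
       chimeric = centroids[chimeric, , drop = FALSE],
       verdicts = verdicts,
       report = stage_report("uchime_ref", n, sum(!chimeric),
                             reasons[reasons > 0], unit = "clusters"))
}
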