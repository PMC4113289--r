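#' Global pairwise identity
#'
#' Pairwise alignment scored as match +1, mismatch -1, gap open -2, gap
#' extend -1 (a length-L gap costs open + L*extend), with every terminal
#' gap run free: the alignment may start and end anywhere in either
#' sequence, and only its interior is constrained to be global. Identity is matches divided by (alignment columns + the smaller
#' side's unaligned base count): a pure length surplus of the longer
#' sequence -- containment, ragged extraction ends -- does not depress
#' identity (`"ACGT"` vs `"ACGTACGT"` gives 1.0), but a short spurious
#' overlap between dissimilar sequences is penalised by the bases it
#' leaves unexplained, so random sequences score low rather than
#' degenerately high. This single definition underlies the clustering
#' threshold, chimera models and read mapping.
#'
#' @param a,b DNA strings.
#' @return identity fraction in [0, 1].
#' @export
global_identity <- function(a, b) {
  stopifnot(nzchar(a), nzchar(b))
  cpp_nw_identity(toupper(a), toupper(b))
}

#' Dereplicate full-length identical sequences
#'
#' Case-insensitive exact full-length grouping; output sequences are
#' uppercase, ordered by decreasing replicate count (ties lexicographic by
#' sequence). The replicate count is the `size` annotation carried through
#' clustering.
#'
#' @param records record frame.
#' @return data frame with columns `seq`, `size` and a list-column
#'   `headers` of the contributing read ids.
#' @export
dereplicate <- function(records) {
  if (nrow(records) == 0L)
    return(data.frame(seq = character(), size = integer()))
  if (any(!nzchar(records$seq))) stop("empty sequence in dereplication input")
  seqs <- toupper(records$seq)
  grp <- split(records$id, seqs)
  out <- data.frame(seq = names(grp), size = lengths(grp),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$headers <- unname(grp)
  out <- out[order(-out$size, out$seq), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sort unique sequences by abundance and drop rare ones
#'
#' Descending size, ties broken lexicographically by sequence; entries
#' with `size < min_size` are removed (`min_size = 2` removes singletons,
#' the usual choice since singletons are enriched in sequencing errors).
#'
#' @param uniques data frame from [dereplicate()].
#' @param min_size minimum replicate count to keep (default 2).
#' @return list with `uniques` (filtered, sorted) and `report` (unit
#'   `clusters`, reason `below_min_size`).
#' @export
sort_by_size <- function(uniques, min_size = 2) {
  ord <- order(-uniques$size, uniques$seq)
  uniques <- uniques[ord, , drop = FALSE]
  keep <- uniques$size >= min_size
  reasons <- c(below_min_size = sum(!keep))
  out <- uniques[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(uniques = out,
       report = stage_report("sort_by_size", nrow(uniques), sum(keep),
                             reasons[reasons > 0], unit = "clusters"))
}

#' Test whether a query is a two-parent (bimeric) chimera
#'
#' Projects each parent onto the query through a pairwise alignment,
#' giving per-query-position match indicators, then scans every crossover
#' position c for the best two-segment model (left segment from one
#' parent, right from the other). With L the query length, the model
#' identity at c is the matched positions under the two-segment model
#' divided by L; single-parent identities use the same per-position
#' denominator, so the model can never score below the better parent. The
#' query is called bimeric iff some crossover achieves: model identity >=
#' `threshold`, an improvement of at least `model_gain` over the best
#' single parent, and at least `min_diffs` diagnostic differences on each
#' side (positions where the segment's own parent matches and the other
#' parent does not).
#'
#' @param query,parent_a,parent_b DNA strings.
#' @param threshold minimum model identity (default 0.97).
#' @param model_gain required improvement over the best single parent
#'   (default 0.02).
#' @param min_diffs minimum diagnostic differences per side (default 3).
#' @return list with `bimeric` (logical), `crossover` (query position of
#'   the boundary, 0-based count of left-segment bases), `id_model`,
#'   `id_best_single`, and `orientation` (`"AB"` = parent_a left).
#' @export
is_bimera <- function(query, parent_a, parent_b, threshold = 0.97,
                      model_gain = 0.02, min_diffs = 3) {
  mA <- cpp_query_match(query, parent_a)
  mB <- cpp_query_match(query, parent_b)
  L <- nchar(query)
  idA <- sum(mA) / L; idB <- sum(mB) / L
  id_best <- max(idA, idB)
  cumA <- c(0, cumsum(mA)); cumB <- c(0, cumsum(mB))
  dAB <- mA & !mB; dBA <- mB & !mA  # diagnostic positions
  cAB <- c(0, cumsum(dAB)); cBA <- c(0, cumsum(dBA))
  cs <- 0:L
  # orientation AB: A left of crossover, B right
  id_ab <- (cumA[cs + 1] + (cumB[L + 1] - cumB[cs + 1])) / L
  ok_ab <- id_ab >= threshold & (id_ab - id_best) >= model_gain &
    cAB[cs + 1] >= min_diffs & (cBA[L + 1] - cBA[cs + 1]) >= min_diffs
  id_ba <- (cumB[cs + 1] + (cumA[L + 1] - cumA[cs + 1])) / L
  ok_ba <- id_ba >= threshold & (id_ba - id_best) >= model_gain &
    cBA[cs + 1] >= min_diffs & (cAB[L + 1] - cAB[cs + 1]) >= min_diffs
  best <- list(bimeric = FALSE, crossover = NA_integer_,
               id_model = max(id_ab, id_ba), id_best_single = id_best,
               orientation = NA_character_)
  cand <- rbind(
    if (any(ok_ab)) data.frame(c = cs[ok_ab], id = id_ab[ok_ab], o = "AB"),
    if (any(ok_ba)) data.frame(c = cs[ok_ba], id = id_ba[ok_ba], o = "BA"))
  if (!is.null(cand) && nrow(cand)) {
    w <- which.max(cand$id)  # ties: first (smallest crossover, AB first)
    best$bimeric <- TRUE
    best$crossover <- as.integer(cand$c[w])
    best$id_model <- cand$id[w]
    best$orientation <- cand$o[w]
  }
  best
}

#' Greedy centroid OTU clustering with de-novo bimera rejection
#'
#' Processes unique sequences in decreasing abundance. Each unique joins
#' the first existing centroid (in centroid-creation order) with identity
#' >= `identity_threshold`; otherwise, if de-novo chimera checking is on,
#' it is tested as a bimera of every ordered pair of existing centroids
#' whose sizes are both at least twice its own (the abundance-skew rule: a
#' chimera cannot be more abundant than half of either parent, since it
#' arises after them in PCR). Bimeric uniques are set aside; all others
#' found a new centroid. Summed sizes are conserved across centroid
#' members plus chimeras.
#'
#' @param uniques sorted unique-sequence data frame (see [sort_by_size()]).
#' @param identity_threshold OTU radius (default 0.97).
#' @param denovo_chimera test non-joining uniques for bimeras (default TRUE).
#' @param model_gain,min_diffs bimera rule parameters (see [is_bimera()]).
#' @return list with `centroids` (data frame `seq`, `size`,
#'   `n_members`, plus list-column `members`), `chimeras` (data frame with
#'   verdict columns), and `report` (unit `clusters`; n_kept counts
#'   uniques absorbed into centroids, reason `denovo_chimera`).
#' @export
greedy_cluster <- function(uniques, identity_threshold = 0.97,
                           denovo_chimera = TRUE, model_gain = 0.02,
                           min_diffs = 3) {
  stopifnot(identity_threshold > 0, identity_threshold <= 1)
  n <- nrow(uniques)
  if (n > 1 && is.unsorted(rev(uniques$size)))
    stop("greedy_cluster requires input sorted by decreasing size")
  cent_seq <- character(0); cent_size <- numeric(0)
  members <- list()
  chim <- list()
  for (i in seq_len(n)) {
    q <- uniques$seq[i]; qsize <- uniques$size[i]
    joined <- FALSE
    if (length(cent_seq)) {
      for (k in seq_along(cent_seq)) {  # first centroid in creation order wins
        if (cpp_nw_identity(q, cent_seq[k]) >= identity_threshold) {
          cent_size[k] <- cent_size[k] + qsize
          members[[k]] <- c(members[[k]], i)
          joined <- TRUE
          break
        }
      }
    }
    if (joined) next
    flagged <- NULL
    if (denovo_chimera && length(cent_seq) >= 2) {
      elig <- which(cent_size >= 2 * qsize)
      if (length(elig) >= 2) {
        pairs <- utils::combn(elig, 2)
        for (p in seq_len(ncol(pairs))) {
          a <- pairs[1, p]; b <- pairs[2, p]
          v <- is_bimera(q, cent_seq[a], cent_seq[b], identity_threshold,
                         model_gain, min_diffs)
          if (v$bimeric) {
            flagged <- data.frame(seq = q, size = qsize,
                                  parent_a = a, parent_b = b,
                                  crossover = v$crossover,
                                  id_model = v$id_model,
                                  id_best_single = v$id_best_single,
                                  stringsAsFactors = FALSE)
            break
          }
        }
      }
    }
    if (!is.null(flagged)) {
      chim[[length(chim) + 1L]] <- flagged
    } else {
      cent_seq <- c(cent_seq, q)
      cent_size <- c(cent_size, qsize)
      members[[length(cent_seq)]] <- i
    }
  }
  chimeras <- if (length(chim)) do.call(rbind, chim) else
    data.frame(seq = character(), size = integer(), parent_a = integer(),
               parent_b = integer(), crossover = integer(),
               id_model = numeric(), id_best_single = numeric())
  centroids <- data.frame(seq = cent_seq, size = as.integer(cent_size),
                          n_members = lengths(members),
                          stringsAsFactors = FALSE)
  centroids$members <- members
  n_chim <- nrow(chimeras)
  reasons <- c(denovo_chimera = n_chim)
  list(centroids = centroids, chimeras = chimeras,
       report = stage_report("cluster_otus", n, n - n_chim,
                             reasons[reasons > 0], unit = "clusters"))
}

#' Centroids as FASTA records with size annotations
#'
#' Headers follow the `label;size=N;` convention so that spreadsheet-style
#' checks (`grep ">" otus.fasta | sed "s/size=/,/g"`) keep working.
#'
#' @param centroids centroid data frame from [greedy_cluster()].
#' @param prefix label prefix (default `"centroid"`).
#' @return record frame.
#' @export
centroid_records <- function(centroids, prefix = "centroid") {
  if (nrow(centroids) == 0L) return(seq_records(character(), character()))
  ids <- sprintf("%s%d;size=%d;", prefix, seq_len(nrow(centroids)), centroids$size)
  seq_records(ids, centroids$seq)
}

#' Audit member-to-representative identities
#'
#' Post-hoc check that every clustered unique is within the OTU radius of
#' its representative.
#'
#' @param centroids centroid data frame from [greedy_cluster()].
#' @param uniques the unique-sequence frame that was clustered.
#' @param identity_threshold the clustering threshold.
#' @return TRUE invisibly; errors when a member violates the radius.
#' @export
audit_members <- function(centroids, uniques, identity_threshold = 0.97) {
  for (k in seq_len(nrow(centroids))) {
    for (i in centroids$members[[k]]) {
      id <- cpp_nw_identity(uniques$seq[i], centroids$seq[k])
      if (id < identity_threshold)
        stop("member ", i, " of centroid ", k, " below threshold: ", id)
    }
  }
  invisible(TRUE)
}
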