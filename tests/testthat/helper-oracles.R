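# Independent pure-R oracles used to cross-check the package's C++ and R
# implementations. They share only the mathematical definitions, not code.

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# reverse complement without Biostrings
rc_plain <- function(x) {
  chartr("ACGTN", "TGCAN", vapply(x, function(s)
    paste(rev(strsplit(s, "")[[1]]), collapse = ""), character(1), USE.NAMES = FALSE))
}

mutate_seq <- function(seq, n_sub) {
  v <- strsplit(seq, "")[[1]]
  pos <- sample(length(v), n_sub)
  for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
  paste(v, collapse = "")
}

# Textbook Gotoh DP with all terminal gaps free (start and end anywhere,
# interior global); same scoring and tie-break conventions as documented for
# global_identity, implemented independently in plain R with full matrices
# and a value-based traceback.
oracle_nw <- function(a, b, match = 1, mismatch = -1, go = 2, ge = 1) {
  av <- strsplit(toupper(a), "")[[1]]; bv <- strsplit(toupper(b), "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e18
  M <- matrix(NEG, n + 1, m + 1); X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  for (i in 1:n) {
    si <- ifelse(bv == av[i], match, mismatch)
    for (j in 1:m) {
      prev <- max(M[i, j], X[i, j], Y[i, j], 0)
      M[i + 1, j + 1] <- prev + si[j]
      X[i + 1, j + 1] <- max(M[i, j + 1] - go - ge, X[i, j + 1] - ge,
                             Y[i, j + 1] - go - ge)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - go - ge, X[i + 1, j] - go - ge,
                             Y[i + 1, j] - ge)
    }
  }
  # endpoint: best cell anywhere, row-major scan with strict improvement;
  # state preference M > X > Y; empty alignment (score 0) is the fallback
  best <- 0; bi <- 0; bj <- 0; bstate <- "S"
  for (i in 1:n) {
    for (j in 1:m) {
      v <- M[i + 1, j + 1]; st <- "M"
      if (X[i + 1, j + 1] > v) { v <- X[i + 1, j + 1]; st <- "X" }
      if (Y[i + 1, j + 1] > v) { v <- Y[i + 1, j + 1]; st <- "Y" }
      if (v > best) { best <- v; bi <- i; bj <- j; bstate <- st }
    }
  }
  # traceback, re-deriving each predecessor with the same preference order
  i <- bi; j <- bj; st <- bstate
  matches <- 0L; columns <- 0L
  match_a <- rep(FALSE, n)
  while (st != "S") {
    if (st == "M") {
      columns <- columns + 1L
      if (av[i] == bv[j]) { matches <- matches + 1L; match_a[i] <- TRUE }
      v <- M[i, j]; nst <- "M"
      if (X[i, j] > v) { v <- X[i, j]; nst <- "X" }
      if (Y[i, j] > v) { v <- Y[i, j]; nst <- "Y" }
      if (v < 0) nst <- "S"
      i <- i - 1L; j <- j - 1L; st <- nst
    } else if (st == "X") {
      columns <- columns + 1L
      v <- M[i, j + 1] - go - ge; nst <- "M"
      if (X[i, j + 1] - ge > v) { v <- X[i, j + 1] - ge; nst <- "X" }
      if (Y[i, j + 1] - go - ge > v) { v <- Y[i, j + 1] - go - ge; nst <- "Y" }
      i <- i - 1L; st <- nst
    } else {
      columns <- columns + 1L
      v <- M[i + 1, j] - go - ge; nst <- "M"
      if (X[i + 1, j] - go - ge > v) { v <- X[i + 1, j] - go - ge; nst <- "X" }
      if (Y[i + 1, j] - ge > v) { v <- Y[i + 1, j] - ge; nst <- "Y" }
      j <- j - 1L; st <- nst
    }
  }
  ua <- i + (n - bi); ub <- j + (m - bj)
  denom <- columns + min(ua, ub)
  list(score = best, matches = matches, columns = columns,
       identity = if (denom > 0) matches / denom else 0,
       match_a = match_a)
}

# identity under the package's canonical argument order (identity is defined
# on the unordered pair; ties between co-optimal alignments are resolved on
# the lexicographically sorted pair)
oracle_identity <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  if (b < a) { tmp <- a; a <- b; b <- tmp }
  oracle_nw(a, b)$identity
}

# Brute-force paired-end merge oracle: scores every candidate overlap length
# explicitly and rebuilds the consensus per the documented rule.
oracle_merge <- function(s1, q1, s2, q2, min_overlap = 5, max_mm_frac = 0.25,
                         reject_N = TRUE) {
  s2rc <- rc_plain(toupper(s2))
  q2r <- paste(rev(strsplit(q2, "")[[1]]), collapse = "")
  v1 <- strsplit(toupper(s1), "")[[1]]; v2 <- strsplit(s2rc, "")[[1]]
  p1 <- utf8ToInt(q1) - 33L; p2 <- utf8ToInt(q2r) - 33L
  l1 <- length(v1); l2 <- length(v2)
  lmax <- min(l1, l2)
  if (lmax < min_overlap) return(list(status = "no_overlap"))
  Ls <- lmax:min_overlap
  scores <- vapply(Ls, function(L) {
    ov1 <- v1[(l1 - L + 1):l1]; ov2 <- v2[1:L]
    sum(ov1 == ov2) - sum(ov1 != ov2)
  }, numeric(1))
  L <- Ls[which.max(scores)]  # first max in decreasing-L order = longest
  off <- l1 - L
  a <- v1[(off + 1):l1]; b <- v2[1:L]
  qa <- p1[(off + 1):l1]; qb <- p2[1:L]
  cons <- character(L); cq <- integer(L)
  n_mm <- 0L
  for (k in 1:L) {
    if (a[k] == b[k]) { cons[k] <- a[k]; cq[k] <- min(qa[k] + qb[k], 41L) }
    else {
      n_mm <- n_mm + 1L
      if (qa[k] > qb[k]) { cons[k] <- a[k]; cq[k] <- qa[k] - qb[k] }
      else if (qb[k] > qa[k]) { cons[k] <- b[k]; cq[k] <- qb[k] - qa[k] }
      else { cons[k] <- a[k]; cq[k] <- 2L }
    }
  }
  if (n_mm / L > max_mm_frac)
    return(list(status = "too_many_mismatches", overlap = L))
  seq <- paste(c(v1[seq_len(off)], cons, v2[seq_len(l2 - L) + L]), collapse = "")
  if (reject_N && grepl("N", seq, fixed = TRUE))
    return(list(status = "contains_N"))
  qual <- intToUtf8(c(p1[seq_len(off)], cq, p2[seq_len(l2 - L) + L]) + 33L)
  list(status = "merged", seq = seq, qual = qual, overlap = L, n_corrected = n_mm)
}

# Exhaustive-crossover bimera oracle built on oracle_nw match vectors.
oracle_is_bimera <- function(q, pa, pb, threshold = 0.97, gain = 0.02,
                             min_diffs = 3) {
  mA <- oracle_nw(q, pa)$match_a
  mB <- oracle_nw(q, pb)$match_a
  L <- nchar(q)
  id_best <- max(sum(mA), sum(mB)) / L
  for (orient in 1:2) {
    l <- if (orient == 1) mA else mB
    r <- if (orient == 1) mB else mA
    for (c_ in 0:L) {
      left <- seq_len(c_); right <- setdiff(seq_len(L), left)
      id_model <- (sum(l[left]) + sum(r[right])) / L
      dl <- sum(l[left] & !r[left]); dr <- sum(r[right] & !l[right])
      if (id_model >= threshold && id_model - id_best >= gain &&
          dl >= min_diffs && dr >= min_diffs) return(TRUE)
    }
  }
  FALSE
}

# small simulated community shared by several tests
tiny_sim <- function(..., seed = 42) {
  cfg <- sim_config(n_species = 4, n_samples = 2, reads_per_sample = 60,
                    per_base_error = 0, chimera_rate = 0, multiprimer_rate = 0,
                    seed = seed, ...)
  simulate_reads(cfg)
}
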