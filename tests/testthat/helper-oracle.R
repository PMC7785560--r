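# Independent oracles used across the suite.
#
# oracleSw() is a pure-R affine-gap local-alignment DP, written and
# verified independently of the package's C++ kernel: row-vectorized
# fill (the horizontal-gap row uses the running-maximum identity
# F[j] = max_k<j (H[k] + ge*k) - go - ge*j, valid because a gap opening
# from a gap-valued cell never beats extending that gap), full-matrix
# storage, scalar traceback with fixed tie preferences
# (diagonal > vertical > horizontal; gap closure preferred on ties).

oracleSw <- function(pattern, subject, match = 2, mismatch = -3,
                     go = 5, ge = 2, traceback = TRUE) {
  p <- strsplit(pattern, "")[[1]]
  s <- strsplit(subject, "")[[1]]
  n <- length(p); m <- length(s)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(0, n + 1, m + 1)   # vertical gap (consumes pattern)
  F <- matrix(0, n + 1, m + 1)   # horizontal gap (consumes subject)
  ge_seq <- ge * seq_len(m + 1)
  for (i in seq_len(n)) {
    sub <- ifelse(p[i] == s, match, mismatch)
    e <- pmax(H[i, -1] - go - ge, E[i, -1] - ge, 0)
    h0 <- pmax(H[i, -(m + 1)] + sub, e, 0)
    ## F from running max over h-without-F to the left:
    ## F[j] = max_{k<j}(h0[k] + ge*k) - go - ge*j; the c(-Inf, .) shift
    ## aligns k to j-1
    runmax <- cummax(c(-Inf, h0[-m] + ge_seq[-c(m, m + 1)]))
    f <- pmax(runmax - go - ge_seq[-(m + 1)], 0)
    h <- pmax(h0, f)
    H[i + 1, -1] <- h
    E[i + 1, -1] <- e
    F[i + 1, -1] <- f
  }
  best <- max(H)
  if (!traceback)
    return(list(score = best))
  ## first best cell in the C++ kernel's scan order (rows outer)
  hit <- which(t(H) == best)[1] - 1
  bi <- hit %/% (m + 1)
  bj <- hit %% (m + 1)
  i <- bi; j <- bj
  n_match <- 0L; n_cols <- 0L; state <- "H"
  p_start <- i; s_start <- j
  while (i > 0 && j > 0) {
    if (state == "H") {
      h <- H[i + 1, j + 1]
      if (h == 0) break
      d <- H[i, j] + if (p[i] == s[j]) match else mismatch
      if (h == d) {
        if (p[i] == s[j]) n_match <- n_match + 1L
        n_cols <- n_cols + 1L
        i <- i - 1; j <- j - 1
      } else if (h == E[i + 1, j + 1]) state <- "E"
      else state <- "F"
    } else if (state == "E") {
      n_cols <- n_cols + 1L
      e <- E[i + 1, j + 1]
      state <- if (e == H[i, j + 1] - go - ge) "H" else "E"
      i <- i - 1
    } else {
      n_cols <- n_cols + 1L
      f <- F[i + 1, j + 1]
      state <- if (f == H[i + 1, j] - go - ge) "H" else "F"
      j <- j - 1
    }
    p_start <- i; s_start <- j
  }
  list(score = best, p_start = p_start, p_end = bi,
       s_start = s_start, s_end = bj, n_match = n_match,
       n_cols = n_cols,
       identity = if (n_cols > 0) n_match / n_cols else 0)
}

# oracle for the VDJ read filter: best hit over all V/J segments on
# both strands (score, ties by identity then allele id), then the
# identity/aligned-length rule -- computed entirely through oracleSw()
oracleFilterDecision <- function(read, seqs, min_identity = 0.80,
                                 min_aligned = 30L) {
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(read)))
  best <- NULL
  for (orient in c("+", "-")) {
    q <- if (orient == "+") read else rc
    for (id in sort(names(seqs))) {
      r <- oracleSw(q, seqs[[id]])
      r$id <- id; r$orient <- orient
      if (is.null(best) || r$score > best$score ||
          (r$score == best$score &&
           (r$identity > best$identity ||
            (r$identity == best$identity && r$id < best$id))))
        best <- r
    }
  }
  ## the package scans "+" candidates before "-" at equal score and
  ## identity; replicate by preferring "+" on full ties
  best$keep <- best$identity >= min_identity && best$n_cols >= min_aligned
  best
}

# brute-force three-layer clonality recomputation: plain sort and
# cumulative sums, no shared code with profileRepertoire()
oracleProfile <- function(counts, junctions) {
  total <- sum(counts)
  freq <- counts / total
  inner <- c(`1` = sum(freq[counts == 1]), `2` = sum(freq[counts == 2]),
             `3+` = sum(freq[counts >= 3]))
  ord <- order(-counts, junctions)
  n <- length(counts)
  sizes <- rep(n %/% 5, 5)
  if (n %% 5 > 0) sizes[seq_len(n %% 5)] <- sizes[seq_len(n %% 5)] + 1
  ends <- cumsum(sizes)
  starts <- c(1, head(ends, 4) + 1)
  q <- vapply(1:5, function(b)
    if (sizes[b] == 0) 0 else sum(freq[ord][starts[b]:ends[b]]),
    numeric(1))
  names(q) <- paste0("Q", 1:5)
  top <- ord[seq_len(min(5, n))]
  list(inner = inner, quantiles = q,
       top_freq = freq[top], top_junction = junctions[top])
}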