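# Shared fixtures, built once per test run. Everything is generated in
# code from fixed seeds; nothing is read from disk.

fixture_germline <- makeToyGermline(seed = 101)

# a compact single-locus reference for oracle-heavy tests (fewer,
# shorter segments keep the pure-R DP oracle affordable)
fixture_small_spec <- list(IGH = list(v = 2L, j = 1L, c = 1L,
                                      v_len = 150L, j_len = 48L,
                                      c_len = 60L))
fixture_small_germline <- makeToyGermline(fixture_small_spec, seed = 202)

# one dominant heavy clone plus nothing else: the noiseless single-clone
# scenario used by assembler tests
singleCloneStudy <- function(seed, shm_count = NULL, shm_rate = 0.02,
                             coverage = 20, frag_min = 60, frag_max = 180,
                             error_rate = 0, germline = fixture_germline,
                             read_len = 150) {
  cl <- simulateRepertoire(germline, n_clones = 1, dominance = 1,
                           shm_rate = shm_rate,
                           dominant_shm_count = shm_count,
                           chains = "heavy", seed = seed)
  tx_len <- nchar(cl$transcript[1])
  mean_len <- (frag_min + frag_max) / 2
  n_frag <- ceiling(coverage * tx_len / mean_len)
  model <- fragmentModel(meanlog = log(mean_len), sdlog = 0.25,
                         bounds = c(frag_min, frag_max), damage_rate = 0)
  fr <- fragmentAndDamage(cl, model, n_fragments = n_frag, seed = seed + 1)
  rn <- makeRnaseqReads(fr, read_len = read_len, paired = TRUE,
                        error_rate = error_rate, seed = seed + 2)
  list(clone = cl[1, ], reads = rn$reads, truth = rn$truth,
       fragments = fr)
}

# substrings of a germline segment with k substitutions planted at
# interior positions (>= 4 nt from either end, spacing >= 2), the
# identity-threshold straddling read design
plantMismatches <- function(seqs, id, start, len, k) {
  s <- substr(seqs[[id]], start, start + len - 1)
  b <- strsplit(s, "")[[1]]
  ok <- seq(4, len - 4)
  pos <- integer(0)
  while (length(pos) < k) {
    cand <- sample(ok, 1)
    if (all(abs(cand - pos) >= 2)) pos <- c(pos, cand)
  }
  for (p in pos) b[p] <- sample(setdiff(c("A", "C", "G", "T"), b[p]), 1)
  paste(b, collapse = "")
}

expect_sums_to_one <- function(x, tol = 1e-9) {
  expect_lt(abs(sum(x) - 1), tol)
}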