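# Synthetic repertoire and read generators: construction invariants,
# closed-form frequencies, degradation statistics, library chemistry.

test_that("zero SHM rate leaves every clone identical to germline", {
  cl <- simulateRepertoire(fixture_germline, n_clones = 8,
                           dominance = 0.5, shm_rate = 0, seed = 3)
  expect_identical(cl$transcript, cl$transcript_germ)
  expect_true(all(vapply(cl$shm, nrow, integer(1)) == 0L))
})

test_that("a single clone carries all frequency; bad configs error", {
  cl <- simulateRepertoire(fixture_germline, n_clones = 1, dominance = 1,
                           chains = "heavy", seed = 2)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$frequency, 1.0)
  expect_error(simulateRepertoire(fixture_germline, n_clones = 1,
                                  dominance = 0.6, seed = 1),
               "dominance")
  expect_error(simulateRepertoire(fixture_germline, n_clones = 5,
                                  dominance = 0, seed = 1))
})

test_that("background clone sizes follow the closed-form power law", {
  cl <- simulateRepertoire(fixture_germline, n_clones = 51,
                           dominance = 0.6, chains = "heavy",
                           shm_rate = 0, seed = 4)
  expect_equal(cl$frequency[1], 0.6)
  h50 <- sum(1 / 1:50)
  expect_equal(cl$frequency[-1], (0.4 / h50) / 1:50)
  expect_sums_to_one(cl$frequency)
})

test_that("paired mode puts the dominant clone at the configured share of each chain view", {
  cl <- simulateRepertoire(fixture_germline, n_clones = 21,
                           dominance = 0.6, shm_rate = 0, seed = 5)
  expect_sums_to_one(cl$frequency)
  for (ch in c("H", "L")) {
    v <- cl[cl$chain == ch, ]
    expect_equal(v$frequency[1] / sum(v$frequency), 0.6)
  }
  expect_identical(cl$locus[cl$clone_id == "C001_L"], "IGK")
  expect_match(cl$c_call[cl$clone_id == "C001_H"], "^IGHG")
})

test_that("clone transcripts decompose into germline V + junction + J + C", {
  cl <- simulateRepertoire(fixture_germline, n_clones = 4,
                           dominance = 0.7, shm_rate = 0, seed = 6)
  an <- as.data.frame(segmentAnno(fixture_germline))
  for (i in seq_len(nrow(cl))) {
    v <- segmentSeq(fixture_germline, cl$v_call[i])
    j <- segmentSeq(fixture_germline, cl$j_call[i])
    cseg <- segmentSeq(fixture_germline, cl$c_call[i])
    va <- an[an$allele_id == cl$v_call[i], "anchor_pos"]
    ja <- an[an$allele_id == cl$j_call[i], "anchor_pos"]
    expected <- paste0(substr(v, 1, va), cl$junction[i],
                       substr(j, ja + 4, nchar(j)), cseg)
    body <- substr(cl$transcript[i], cl$v_start[i] + 1,
                   cl$v_start[i] + nchar(expected))
    expect_identical(body, expected)
    # junction anchors: Cys first codon, W/F last codon
    jaa <- IgRescue:::translateNt(cl$junction[i])
    expect_identical(substr(jaa, 1, 1), "C")
    expect_true(substr(jaa, nchar(jaa), nchar(jaa)) %in% c("W", "F"))
  }
})

test_that("fragmentation respects the length model and damage settings", {
  cl <- simulateRepertoire(fixture_germline, n_clones = 1, dominance = 1,
                           chains = "heavy", shm_rate = 0, seed = 7)
  ## no damage: every fragment is an exact substring of the transcript
  fr <- fragmentAndDamage(cl, fragmentModel(damage_rate = 0),
                          n_fragments = 200, seed = 8)
  expect_true(all(vapply(fr$fragments, grepl, logical(1),
                         x = cl$transcript[1], fixed = TRUE)))
  ## degenerate length model: all fragments 120 nt (transcript is longer)
  m120 <- fragmentModel(meanlog = log(120), sdlog = 0,
                        bounds = c(30, 600), damage_rate = 0)
  fr120 <- fragmentAndDamage(cl, m120, n_fragments = 50, seed = 9)
  expect_true(all(nchar(fr120$fragments) == 120L))
  ## damage only ever converts C->T or G->A
  frd <- fragmentAndDamage(cl, fragmentModel(damage_rate = 0.05),
                           n_fragments = 100, seed = 10)
  orig <- fragmentAndDamage(cl, fragmentModel(damage_rate = 0),
                            n_fragments = 100, seed = 10)
  for (k in seq_along(frd$fragments)) {
    a <- strsplit(orig$fragments[[k]], "")[[1]]
    b <- strsplit(frd$fragments[[k]], "")[[1]]
    ch <- which(a != b)
    expect_true(all((a[ch] == "C" & b[ch] == "T") |
                    (a[ch] == "G" & b[ch] == "A")))
  }
})

test_that("the default length model yields DV200 of 50% (binomial CI)", {
  set.seed(1)
  lens <- sampleFragmentLengths(fragmentModel(), 10000)
  expect_lt(abs(dv200(lens) - 50), 2)
})

test_that("amplicons end at the constant-region primer site", {
  cl <- simulateRepertoire(fixture_germline, n_clones = 1, dominance = 1,
                           chains = "light", shm_rate = 0, seed = 11)
  expect_identical(cl$locus[1], "IGK")
  ig <- makeIgseqReads(cl, n_reads = 1, read_len = 5000,
                       error_rate = 0, paired = FALSE, seed = 12)
  amplicon <- IgRescue:::revComp(ig$reads[[1]])
  ## 5' end is the template-switch tail
  expect_identical(substr(amplicon, 1, 30), IgRescue:::TSO_TAIL)
  ## 3' end abuts the kappa RT primer site printed in the library design
  expect_identical(substr(amplicon, nchar(amplicon) - 15, nchar(amplicon)),
                   "CACACAACAGAGGCAG")
})

test_that("error-free amplicon reads are exact substrings; errors stay at rate", {
  cl <- simulateRepertoire(fixture_germline, n_clones = 2, dominance = 0.6,
                           chains = "heavy", shm_rate = 0, seed = 13)
  ig <- makeIgseqReads(cl, n_reads = 100, read_len = 150, error_rate = 0,
                       paired = TRUE, seed = 14)
  org <- readOrigins(ig$truth)
  amp <- function(cid) {
    tx <- cl$transcript[cl$clone_id == cid]
    site <- IgRescue:::findPrimerSite(tx, setNames(
      igseqPrimers("RT")$sequence, NULL))
    paste0(IgRescue:::TSO_TAIL, substr(tx, 1, site))
  }
  for (k in seq_along(ig$reads)) {
    a <- amp(org$clone_id[match(names(ig$reads)[k], org$read_id)])
    r <- ig$reads[[k]]
    expect_true(grepl(r, a, fixed = TRUE) ||
                grepl(IgRescue:::revComp(r), a, fixed = TRUE))
  }
})

test_that("read counts track clone frequencies (binomial check)", {
  cl <- simulateRepertoire(fixture_germline, n_clones = 2, dominance = 0.6,
                           chains = "heavy", shm_rate = 0, seed = 15)
  cl$frequency <- c(0.6, 0.4)
  ig <- makeIgseqReads(cl, n_reads = 1000, error_rate = 0,
                       paired = FALSE, seed = 16)
  counts <- table(readOrigins(ig$truth)$clone_id)
  ## 99.9% binomial band around 600
  expect_gt(counts[["C001"]], qbinom(5e-4, 1000, 0.6))
  expect_lt(counts[["C001"]], qbinom(1 - 5e-4, 1000, 0.6))
})

test_that("transcriptome reads respect fragment boundaries and pairing", {
  cl <- simulateRepertoire(fixture_germline, n_clones = 1, dominance = 1,
                           chains = "heavy", shm_rate = 0, seed = 17)
  short_model <- fragmentModel(meanlog = log(90), sdlog = 0.3,
                               bounds = c(40, 140), damage_rate = 0)
  fr <- fragmentAndDamage(cl, short_model, n_fragments = 60, seed = 18)
  rn <- makeRnaseqReads(fr, read_len = 150, paired = TRUE,
                        error_rate = 0, seed = 19)
  ## fragments shorter than the read length yield truncated reads
  idx <- as.integer(sub("rnaseq_(\\d+)(/[12])?$", "\\1", names(rn$reads)))
  flen <- nchar(fr$fragments)
  expect_true(all(nchar(rn$reads) == pmin(150L, flen[idx])))
  ## paired mates are the two ends of the same fragment, read inward:
  ## for fragments <= read_len, R2 is exactly the reverse complement of R1
  r1 <- rn$reads[endsWith(names(rn$reads), "/1")]
  r2 <- rn$reads[endsWith(names(rn$reads), "/2")]
  expect_identical(unname(IgRescue:::revComp(r1)), unname(r2))
})

test_that("generators are bit-reproducible under a fixed seed", {
  cl1 <- simulateRepertoire(fixture_germline, n_clones = 6,
                            dominance = 0.6, seed = 20)
  cl2 <- simulateRepertoire(fixture_germline, n_clones = 6,
                            dominance = 0.6, seed = 20)
  expect_identical(cl1$transcript, cl2$transcript)
  ig1 <- makeIgseqReads(cl1, n_reads = 50, seed = 21)
  ig2 <- makeIgseqReads(cl2, n_reads = 50, seed = 21)
  expect_identical(ig1$reads, ig2$reads)
  fr1 <- fragmentAndDamage(cl1, fragmentModel(), 50, seed = 22)
  fr2 <- fragmentAndDamage(cl2, fragmentModel(), 50, seed = 22)
  expect_identical(fr1$fragments, fr2$fragments)
})

test_that("clone read shares converge to configured frequencies (LLN)", {
  cl <- simulateRepertoire(fixture_germline, n_clones = 10,
                           dominance = 0.5, chains = "heavy",
                           shm_rate = 0, seed = 23)
  fr <- fragmentAndDamage(cl, fragmentModel(), n_fragments = 20000,
                          seed = 24)
  shares <- table(readOrigins(fr$truth)$clone_id) / 20000
  expect_true(all(abs(shares[cl$clone_id] - cl$frequency) < 0.02))
})
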