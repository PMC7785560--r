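# Seed-and-extend assembly: VDJ read filter, seed search, greedy
# overlap extension with its stop conditions, full reconstruction.

tileReads <- function(s, len = 80, step = 10, prefix = "t") {
  starts <- seq(1, max(1, nchar(s) - len + 1), by = step)
  setNames(substring(s, starts, pmin(starts + len - 1, nchar(s))),
           sprintf("%s%03d", prefix, seq_along(starts)))
}

test_that("the VDJ filter keeps germline-derived reads and drops junk", {
  gs <- fixture_germline
  vid <- alleleIds(gs, locus = "IGH", segment_class = "V")[1]
  exact <- unname(substr(segmentSeq(gs, vid), 51, 150))
  ## 25% mismatches, evenly spaced so no local window clears 80%
  junk <- strsplit(exact, "")[[1]]
  for (p in seq(2, length(junk), by = 4))
    junk[p] <- chartr("ACGT", "TGCA", junk[p])
  junk <- paste(junk, collapse = "")
  pool <- filterVdjReads(c(keep = exact, drop = junk), gs)
  expect_identical(names(pool), "keep")
  info <- attr(pool, "info")
  expect_equal(info$identity, 1.0)
})

test_that("filter decisions on threshold-straddling reads match the DP oracle", {
  gs <- fixture_small_germline
  seqs <- segmentSeq(gs, alleleIds(gs, segment_class = c("V", "J")))
  set.seed(61)
  vids <- alleleIds(gs, segment_class = "V")
  reads <- vapply(1:40, function(i) {
    id <- sample(vids, 1)
    r <- plantMismatches(seqs, id, sample(1:80, 1), 60,
                         sample(9:15, 1))
    if (i %% 3 == 0) IgRescue:::revComp(r) else r
  }, "")
  names(reads) <- sprintf("s%02d", 1:40)
  pool <- filterVdjReads(reads, gs)
  for (k in seq_along(reads)) {
    orc <- oracleFilterDecision(reads[[k]], seqs)
    expect_identical(names(reads)[k] %in% names(pool), orc$keep,
                     info = paste("read", k))
  }
})

test_that("the filter's read-fraction rule differs where it should", {
  gs <- fixture_small_germline
  vid <- alleleIds(gs, segment_class = "V")[1]
  ## 40 nt of perfect V plus a 60-nt random tail: local identity 1.0,
  ## but only 40% of the read aligns
  set.seed(62)
  tail60 <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  read <- paste0(substr(segmentSeq(gs, vid), 1, 40), tail60)
  by_identity <- filterVdjReads(setNames(read, "r"), gs,
                                rule = "identity")
  by_fraction <- filterVdjReads(setNames(read, "r"), gs,
                                rule = "read_fraction")
  expect_identical(names(by_identity), "r")
  expect_equal(length(by_fraction), 0L)
})

test_that("seed search demands the junction plus an in-frame YYC motif", {
  st <- singleCloneStudy(seed = 70)
  pool <- filterVdjReads(st$reads, fixture_germline)
  seeds <- findSeeds(pool, st$clone$junction)
  expect_gt(nrow(seeds), 0)
  expect_true(all(seeds$mismatches == 0))
  ## sorted by longest 5' flank
  expect_true(!is.unsorted(rev(seeds$flank5[seeds$mismatches == 0])))
  ## an absent junction yields no seeds
  absent <- paste0("TGT", paste(rep("ACG", 14), collapse = ""), "TGG")
  expect_equal(nrow(findSeeds(pool, absent)), 0L)
  ## a read whose junction match lost the anchor cysteine is excluded
  tx <- st$clone$transcript
  js <- st$clone$junction_start
  mut <- tx
  substr(mut, js + 1, js + 1) <- "A"  # Cys -> Ser
  read_mut <- substr(mut, js - 40, js + nchar(st$clone$junction) + 10)
  hits <- findSeeds(setNames(read_mut, "m"), st$clone$junction,
                    max_mismatches = 1)
  expect_equal(nrow(hits), 0L)
  ## the same read with the anchor intact is a valid (1-mismatch) seed
  read_ok <- substr(tx, js - 40, js + nchar(st$clone$junction) + 10)
  hits_ok <- findSeeds(setNames(read_ok, "m"), st$clone$junction,
                       max_mismatches = 1)
  expect_equal(nrow(hits_ok), 1L)
})

test_that("a constructed coverage gap stops extension at the gap edge", {
  set.seed(71)
  s <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  seed_start <- 301  # 1-based; contig seeded at s[301..360]
  contig <- substr(s, seed_start, seed_start + 59)
  reads <- tileReads(s, len = 80, step = 10)
  starts <- as.integer(sub("t", "", names(reads))) # tile index
  starts <- seq(1, 400 - 80 + 1, by = 10)[starts]
  gap <- c(181, 220)  # 40-nt uncovered window (1-based, inclusive)
  keep <- starts + 79 < gap[1] | starts > gap[2]
  pool <- reads[keep]
  res <- extendContig(contig, pool, direction = "5prime")
  expect_identical(res$termination, "no_overlap")
  ## the contig 5' end sits at the first covered base after the gap
  expect_identical(res$contig, substr(s, gap[2] + 1, seed_start + 59))
})

test_that("an equal-abundance upstream divergence stops as ambiguous_branch", {
  set.seed(72)
  shared <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  up_a <- paste(sample(c("A", "C", "G", "T"), 150, TRUE), collapse = "")
  up_b <- chartr("ACGT", "TGCA", up_a)  # guaranteed to differ everywhere
  hap_a <- paste0(up_a, shared)
  hap_b <- paste0(up_b, shared)
  pool <- c(tileReads(hap_a, prefix = "a"), tileReads(hap_b, prefix = "b"))
  contig <- substr(shared, 101, 160)
  res <- extendContig(contig, pool, direction = "5prime")
  expect_identical(res$termination, "ambiguous_branch")
  ## extension reached exactly the divergence point (start of `shared`)
  expect_identical(res$contig, substr(shared, 1, 160))
})

test_that("noiseless reconstruction recovers the exact V region and junction", {
  st <- singleCloneStudy(seed = 73)
  ch <- reconstructChain(st$reads, target_junction = st$clone$junction,
                         germline = fixture_germline,
                         v_call = st$clone$v_call)
  expect_identical(terminationReason(ch), "v_start_reached")
  truth <- substr(st$clone$transcript, st$clone$v_start + 1,
                  st$clone$junction_end)
  expect_identical(substr(contigSeq(ch), 1, nchar(truth)), truth)
  ## junction interval is recorded correctly
  jr <- junctionRange(ch)
  expect_identical(substr(contigSeq(ch), jr["start"] + 1, jr["end"]),
                   st$clone$junction)
  ## coverage/agreement track the contig
  cov <- contigCoverage(ch)
  expect_equal(nrow(cov), nchar(contigSeq(ch)))
  expect_true(all(cov$coverage >= 1))
})

test_that("enlarging the pool never shortens the contig (monotonicity)", {
  st <- singleCloneStudy(seed = 74)
  pool_all <- filterVdjReads(st$reads, fixture_germline)
  pool_half <- pool_all[seq(1, length(pool_all), by = 2)]
  p <- assemblyParams()
  r_half <- extendContig(st$clone$junction, pool_half, p, "5prime")
  r_all <- extendContig(st$clone$junction, pool_all, p, "5prime")
  expect_gte(nchar(r_all$contig), nchar(r_half$contig))
})

test_that("reconstruction is deterministic and matches an alignment oracle", {
  st <- singleCloneStudy(seed = 75)
  ch1 <- reconstructChain(st$reads, target_junction = st$clone$junction,
                          germline = fixture_germline,
                          v_call = st$clone$v_call)
  ch2 <- reconstructChain(st$reads, target_junction = st$clone$junction,
                          germline = fixture_germline,
                          v_call = st$clone$v_call)
  expect_identical(contigSeq(ch1), contigSeq(ch2))
  expect_identical(ch1@coverage, ch2@coverage)
  ## independent oracle: on noiseless single-clone input the consensus
  ## over reads placed on the known truth equals the truth itself, so
  ## the contig must be a substring of the transcript
  expect_true(grepl(contigSeq(ch1), st$clone$transcript, fixed = TRUE))
})

test_that("a junction at minimal coverage yields a partial contig", {
  st <- singleCloneStudy(seed = 76, coverage = 1.5)
  ch <- tryCatch(
    reconstructChain(st$reads, target_junction = st$clone$junction,
                     germline = fixture_germline,
                     v_call = st$clone$v_call),
    error = function(e) e)
  if (inherits(ch, "error")) {
    expect_match(conditionMessage(ch), "no_seed_reads|no_vdj_reads")
  } else {
    truth_len <- st$clone$junction_end - st$clone$v_start
    expect_true(terminationReason(ch) != "v_start_reached" ||
                nchar(contigSeq(ch)) < truth_len + 50)
  }
})

test_that("errors propagate as named failures", {
  gs <- fixture_germline
  expect_error(reconstructChain(character(0), "TGTAAATGG", gs),
               "no_vdj_reads")
  st <- singleCloneStudy(seed = 77)
  pool <- filterVdjReads(st$reads, gs)
  absent <- paste0("TGT", paste(rep("GCA", 14), collapse = ""), "TGG")
  expect_error(reconstructChain(target_junction = absent, germline = gs,
                                pool = pool),
               "no_seed_reads")
})
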