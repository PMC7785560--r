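# Germline annotation: allele assignment, CDR projection, SHM calls,
# isotype.

noiselessChain <- function(seed, shm_count = NULL, shm_rate = 0.02) {
  st <- singleCloneStudy(seed = seed, shm_count = shm_count,
                         shm_rate = shm_rate)
  ch <- reconstructChain(st$reads, target_junction = st$clone$junction,
                         germline = fixture_germline,
                         v_call = st$clone$v_call)
  list(chain = ch, clone = st$clone)
}

test_that("noiseless round-trip recovers alleles, SHM set and isotype", {
  for (k in c(0L, 5L)) {
    x <- noiselessChain(seed = 80 + k, shm_count = k)
    ann <- annotateChain(x$chain, fixture_germline, min_coverage = 1L)
    expect_identical(ann@v_call, x$clone$v_call)
    expect_identical(ann@j_call, x$clone$j_call)
    expect_equal(ann@shm_count_aa, k)
    expect_equal(ann@shm_count_nt, k)  # planted mutations are never silent
    expect_identical(ann@isotype, "IgG")
    expect_true(ann@productive)
    if (k > 0) {
      ## recovered codon positions equal the planted ones
      events <- x$clone$shm[[1]]
      truth_codons <- sort(unique(
        (events$pos - x$clone$v_start) %/% 3 + 1))
      expect_equal(sort(ann@shm$codon), truth_codons)
    }
  }
})

test_that("allele assignment survives heavy SHM when alleles are distinct", {
  x <- noiselessChain(seed = 90, shm_count = 15L)
  ann <- assignGermlineAlleles(x$chain, fixture_germline)
  expect_identical(ann$v_call, x$clone$v_call)
  expect_identical(ann$j_call, x$clone$j_call)
  expect_lt(ann$v_identity, 1)
})

test_that("a contig without V context fails with insufficient_v_context", {
  x <- noiselessChain(seed = 91)
  short <- new("AssembledChain", junction = x$chain@junction,
               contig = substr(contigSeq(x$chain),
                               x$chain@boundaries$junction_start - 49,
                               nchar(contigSeq(x$chain))),
               coverage = x$chain@coverage[
                 (x$chain@boundaries$junction_start - 49):
                   nchar(contigSeq(x$chain))],
               agreement = x$chain@agreement[
                 (x$chain@boundaries$junction_start - 49):
                   nchar(contigSeq(x$chain))],
               frame = 0L,
               boundaries = list(junction_start = 50L,
                                 junction_end =
                                   50L + nchar(x$chain@junction),
                                 v_start_reached = FALSE,
                                 contig_end = 0L),
               reads = character(0), termination = "no_overlap",
               termination3 = "no_overlap")
  expect_error(assignGermlineAlleles(short, fixture_germline),
               "insufficient_v_context")
})

test_that("CDR boundaries project through alignments, shifting with indels", {
  x <- noiselessChain(seed = 92, shm_count = 0L)
  ann <- annotateChain(x$chain, fixture_germline, min_coverage = 1L)
  an <- as.data.frame(segmentAnno(fixture_germline))
  row <- an[an$allele_id == x$clone$v_call, ]
  ## ungapped noiseless contig: boundaries map 1:1
  expect_equal(ann@cdr$cdr1, c(row$cdr1_start, row$cdr1_end))
  expect_equal(ann@cdr$cdr2, c(row$cdr2_start, row$cdr2_end))
  ## CDR3 is the junction minus both anchor codons
  js <- x$chain@boundaries$junction_start
  je <- x$chain@boundaries$junction_end
  expect_equal(ann@cdr$cdr3, c(js + 3L, je - 3L))
  ## delete 3 nt upstream of CDR1: projected boundaries shift by 3
  ctg <- contigSeq(x$chain)
  del <- paste0(substr(ctg, 1, 30), substr(ctg, 34, nchar(ctg)))
  chain_del <- new("AssembledChain", junction = x$chain@junction,
                   contig = del,
                   coverage = rep(5L, nchar(del)),
                   agreement = rep(1, nchar(del)),
                   frame = x$chain@frame,
                   boundaries = list(junction_start = js - 3L,
                                     junction_end = je - 3L,
                                     v_start_reached = TRUE,
                                     contig_end = nchar(del)),
                   reads = character(0),
                   termination = "v_start_reached",
                   termination3 = "no_overlap")
  alle <- assignGermlineAlleles(chain_del, fixture_germline)
  cdr_del <- annotateCdrs(chain_del, alle, fixture_germline)
  expect_equal(cdr_del$cdr1, ann@cdr$cdr1 - 3L)
  expect_equal(cdr_del$cdr2, ann@cdr$cdr2 - 3L)
})

test_that("silent and nonsilent mutations are separated; aa <= nt always", {
  for (seed in 93:97) {
    x <- noiselessChain(seed = seed, shm_rate = 0.03)
    ann <- annotateChain(x$chain, fixture_germline, min_coverage = 1L)
    events <- x$clone$shm[[1]]
    expect_lte(ann@shm_count_aa, ann@shm_count_nt)
    expect_equal(ann@shm_count_nt, nrow(events))
    ## aa-changing codons match the truth's nonsilent codon set
    truth_codons <- sort(unique(
      (events$pos[!events$silent] - x$clone$v_start) %/% 3 + 1))
    expect_equal(sort(unique(ann@shm$codon)), truth_codons)
  }
})

test_that("CDR3 positions are never reported as SHM", {
  x <- noiselessChain(seed = 98, shm_count = 10L)
  ann <- annotateChain(x$chain, fixture_germline, min_coverage = 1L)
  js <- x$chain@boundaries$junction_start
  je <- x$chain@boundaries$junction_end
  frame <- x$chain@frame
  jx_codons <- ((js - frame) %/% 3 + 1):((je - 1 - frame) %/% 3 + 1)
  expect_length(intersect(ann@shm$codon, jx_codons), 0)
})

test_that("isotype calls follow the constant-region evidence", {
  x <- noiselessChain(seed = 99)
  iso <- callIsotype(x$chain, fixture_germline)
  expect_identical(iso$isotype, "IgG")
  ## a contig ending right after the junction has no constant evidence
  je <- x$chain@boundaries$junction_end
  stub <- new("AssembledChain", junction = x$chain@junction,
              contig = substr(contigSeq(x$chain), 1, je),
              coverage = x$chain@coverage[1:je],
              agreement = x$chain@agreement[1:je],
              frame = x$chain@frame,
              boundaries = list(junction_start =
                                  x$chain@boundaries$junction_start,
                                junction_end = je,
                                v_start_reached = TRUE, contig_end = je),
              reads = character(0), termination = "v_start_reached",
              termination3 = "no_overlap")
  expect_identical(callIsotype(stub, fixture_germline)$isotype, "unknown")
  ## pooled constant-region reads vote with a support fraction
  g_seq <- segmentSeq(fixture_germline, "IGHG1*01")
  m_seq <- segmentSeq(fixture_germline, "IGHM*01")
  pool <- c(setNames(rep(substr(g_seq, 1, 50), 9), paste0("g", 1:9)),
            setNames(substr(m_seq, 1, 50), "m1"))
  vote <- callIsotype(germline = fixture_germline, pool = pool)
  expect_identical(vote$isotype, "IgG")
  expect_equal(vote$support, 0.9)
})

test_that("annotation is invariant to 3' padding beyond the variable region", {
  x <- noiselessChain(seed = 100, shm_count = 3L)
  ann <- annotateChain(x$chain, fixture_germline, min_coverage = 1L)
  ## trim the 3' constant tail down to 60 nt past the junction
  je <- x$chain@boundaries$junction_end
  keep <- min(nchar(contigSeq(x$chain)), je + 60L)
  trimmed <- new("AssembledChain", junction = x$chain@junction,
                 contig = substr(contigSeq(x$chain), 1, keep),
                 coverage = x$chain@coverage[1:keep],
                 agreement = x$chain@agreement[1:keep],
                 frame = x$chain@frame,
                 boundaries = list(
                   junction_start = x$chain@boundaries$junction_start,
                   junction_end = je, v_start_reached = TRUE,
                   contig_end = keep),
                 reads = character(0), termination = "v_start_reached",
                 termination3 = "no_overlap")
  ann2 <- annotateChain(trimmed, fixture_germline, min_coverage = 1L)
  expect_identical(ann2@v_call, ann@v_call)
  expect_equal(ann2@shm, ann@shm)
  expect_equal(ann2@cdr$cdr1, ann@cdr$cdr1)
})
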