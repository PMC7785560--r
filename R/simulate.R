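## Synthetic repertoire + degraded-RNA read simulator.
##
## The generator emulates the data regime the pipeline is built for: a
## B-cell repertoire dominated by one heavily hypermutated IgG clone,
## transcribed into short chemically damaged fragments (the DV200 ~ 50%
## degradation regime), sequenced as (i) constant-region-primed,
## template-switch amplicons read across the junction (Ig-seq) and (ii)
## whole-transcriptome fragment reads. Every read is traceable to its
## clone of origin through the emitted SimTruth, so pipeline output can
## be scored exactly.

TSO_TAIL <- "AAGCAGTGGTATCAACGCAGAGTACATGGG"  # template-switch tail (riboGs as G)

#' Constant-region primer sets from the library design
#'
#' Reads the shipped primer table (reverse-transcription, target-
#' enrichment and indexing-PCR pools) and returns one step as a
#' data.frame of `name`, `sequence`.
#' @param step one of "RT", "PCR1", "PCR2"
#' @return data.frame with columns `pool`, `name`, `sequence`
#' @export
igseqPrimers <- function(step = c("RT", "PCR1", "PCR2")) {
  step <- match.arg(step)
  tab <- read.delim(system.file("extdata", "primers_igseq.tsv",
                                package = "IgRescue"),
                    stringsAsFactors = FALSE)
  tab[tab$step == step, c("pool", "name", "sequence")]
}

## ---------------------------------------------------------------------
## repertoire
## ---------------------------------------------------------------------

sampleJunction <- function(v_seq, v_anchor, j_seq, j_anchor, len_range) {
  lens <- seq(len_range[1], len_range[2])
  lens <- lens[lens %% 3 == 0 & lens >= 12]
  len <- if (length(lens) > 1) sample(lens, 1) else lens
  k <- (len - 6L) %/% 3L
  paste0(substr(v_seq, v_anchor + 1L, v_anchor + 3L),
         randomCodons(k),
         substr(j_seq, j_anchor + 1L, j_anchor + 3L))
}

## one chain-level clone: recombine, then hypermutate V/J (junction and
## the YYC motif immediately upstream of the V anchor stay untouched)
makeChainClone <- function(germline, locus, clone_id, freq, shm_rate,
                           shm_count, junction_len_range, leader_len,
                           trailer_len, c_call = NULL,
                           v_call = NULL, j_call = NULL) {
  an <- segmentAnno(germline)
  vs <- alleleIds(germline, locus = locus, segment_class = "V")
  js <- alleleIds(germline, locus = locus, segment_class = "J")
  cs <- alleleIds(germline, locus = locus, segment_class = "C")
  if (is.null(v_call)) v_call <- sample(vs, 1)
  if (is.null(j_call)) j_call <- sample(js, 1)
  if (is.null(c_call)) c_call <- sample(cs, 1)
  v_seq <- segmentSeq(germline, v_call)
  j_seq <- segmentSeq(germline, j_call)
  c_seq <- segmentSeq(germline, c_call)
  v_anchor <- an[v_call, "anchor_pos"]
  j_anchor <- an[j_call, "anchor_pos"]
  junction <- sampleJunction(v_seq, v_anchor, j_seq, j_anchor,
                             junction_len_range)
  leader <- paste(sample(BASES, leader_len, replace = TRUE), collapse = "")
  trailer <- paste(sample(BASES, trailer_len, replace = TRUE), collapse = "")
  v_part <- substr(v_seq, 1L, v_anchor)            # germline V before anchor
  j_part <- substr(j_seq, j_anchor + 4L, nchar(j_seq))  # after anchor codon
  germ_tx <- paste0(leader, v_part, junction, j_part, c_seq, trailer)
  v_start <- leader_len
  jx_start <- v_start + v_anchor                   # junction interval on tx
  jx_end <- jx_start + nchar(junction)
  j_end <- jx_end + nchar(j_part)
  ## SHM-eligible transcript positions: V before the YYC motif, J after
  ## the anchor codon (0-based). The codons flanking segment boundaries
  ## (first V codon, first post-anchor J codon, last J codon) stay
  ## germline: a substitution in a boundary codon sits at a
  ## local-alignment edge where no caller can place it unambiguously
  elig_v <- if (v_anchor > 9L)
    seq(v_start + 3L, v_start + v_anchor - 7L) else integer(0)
  elig_j <- if (j_end - 6L > jx_end + 3L) seq(jx_end + 3L, j_end - 4L)
    else integer(0)
  tx <- strsplit(germ_tx, "", fixed = TRUE)[[1]]
  events <- data.frame(pos = integer(0), ref = character(0),
                       alt = character(0), region = character(0),
                       silent = logical(0))
  if (!is.null(shm_count)) {
    if (shm_count > 0) {
      cod_of <- function(p) (p - v_start) %/% 3L
      elig <- c(elig_v, elig_j)
      ## codons fully eligible (all 3 bases), distinct per event so the
      ## configured count equals the amino-acid-level count exactly
      cods <- as.integer(names(which(table(cod_of(elig)) == 3L)))
      if (length(cods) < shm_count)
        stop("not enough eligible codons for ", shm_count, " SHM events")
      pick <- sample(cods, shm_count)
      for (cd in pick) {
        cstart <- v_start + 3L * cd
        germ_cod <- paste(tx[(cstart + 1L):(cstart + 3L)], collapse = "")
        repeat {
          off <- sample(0:2, 1)
          alt <- sample(setdiff(BASES, tx[cstart + off + 1L]), 1)
          newc <- germ_cod
          substr(newc, off + 1L, off + 1L) <- alt
          if (!newc %in% c("TAA", "TAG", "TGA") &&
              translateNt(newc) != translateNt(germ_cod)) break
        }
        pos <- cstart + off
        events <- rbind(events, data.frame(
          pos = pos, ref = tx[pos + 1L], alt = alt,
          region = if (pos %in% elig_v || (pos + 2L) %in% elig_v) "V" else "J",
          silent = FALSE))
        tx[pos + 1L] <- alt
      }
    }
  } else if (shm_rate > 0) {
    hit <- c(elig_v, elig_j)[runif(length(elig_v) + length(elig_j)) < shm_rate]
    for (pos in hit) {
      alt <- sample(setdiff(BASES, tx[pos + 1L]), 1)
      events <- rbind(events, data.frame(
        pos = pos, ref = tx[pos + 1L], alt = alt,
        region = if (pos %in% elig_v) "V" else "J", silent = NA))
      tx[pos + 1L] <- alt
    }
    if (nrow(events)) {  # silent = codon-level synonymy after all events
      mut_tx <- paste(tx, collapse = "")
      for (k in seq_len(nrow(events))) {
        cd <- (events$pos[k] - v_start) %/% 3L
        cstart <- v_start + 3L * cd
        events$silent[k] <-
          translateNt(substr(mut_tx, cstart + 1L, cstart + 3L)) ==
          translateNt(substr(germ_tx, cstart + 1L, cstart + 3L))
      }
    }
  }
  data.frame(clone_id = clone_id, locus = locus, chain = chainOf(locus),
             v_call = v_call, j_call = j_call, c_call = c_call,
             junction = junction, frequency = freq,
             transcript = paste(tx, collapse = ""),
             transcript_germ = germ_tx, v_start = v_start,
             junction_start = jx_start, junction_end = jx_end,
             j_end = j_end, shm = I(list(events)),
             stringsAsFactors = FALSE)
}

#' Simulate a clonal B-cell repertoire with one dominant clone
#'
#' Clone 1 receives frequency `dominance`; the remaining mass is split
#' among background clones proportional to `1 / rank^power`. In the
#' default `"paired"` mode every B-cell clone contributes one heavy
#' (IGH) and one light (IGK or IGL) chain clone, each carrying half the
#' clone's frequency, so the dominant clone sits at `dominance` within
#' the heavy-chain view and within the light-chain view alike -- the
#' near-monoclonal one-H-one-L structure the pipeline is designed to
#' recover. `"heavy"`/`"light"` modes emit a single chain per clone.
#'
#' Hypermutations are drawn per base at `shm_rate` over the V and J
#' portions of the recombined transcript; the junction is excluded (it
#' is clone-specific already), as is the YYC motif directly upstream of
#' the V anchor. `dominant_shm_count`, when given, instead plants that
#' exact number of amino-acid-changing mutations in the dominant clone's
#' chains (distinct codons, never silent).
#'
#' @param germline a [GermlineSet-class]
#' @param n_clones number of B-cell clones (>= 1)
#' @param dominance frequency of clone 1, in (0, 1]
#' @param shm_rate per-base hypermutation probability for background
#'   clones (and the dominant clone unless `dominant_shm_count` is set)
#' @param junction_len_range nt length range for sampled junctions
#'   (rounded to codons); named list with `H` and `L` entries or a
#'   single range used for both
#' @param power power-law exponent for background clone sizes
#' @param chains `"paired"`, `"heavy"` or `"light"`
#' @param dominant_shm_count exact amino-acid-changing SHM count for the
#'   dominant clone's chains, or `NULL` to use `shm_rate`
#' @param leader_len,trailer_len untemplated transcript flanks (nt): the
#'   5' leader/UTR upstream of the V start and the 3' tail after C
#' @param seed integer seed; the generator is bit-reproducible
#' @return [S4Vectors::DataFrame]-like data.frame of chain clones (see
#'   [SimTruth-class] for columns), with `params` attribute
#' @export
simulateRepertoire <- function(germline, n_clones = 51, dominance = 0.6,
                               shm_rate = 0.02,
                               junction_len_range = list(H = c(36, 60),
                                                         L = c(27, 45)),
                               power = 1, chains = c("paired", "heavy",
                                                     "light"),
                               dominant_shm_count = NULL,
                               leader_len = 60L, trailer_len = 30L,
                               seed = 1) {
  chains <- match.arg(chains)
  if (n_clones < 1) stop("n_clones must be >= 1")
  if (dominance <= 0 || dominance > 1)
    stop("dominance must be in (0, 1]")
  if (n_clones == 1 && dominance < 1)
    stop("n_clones = 1 requires dominance = 1 ",
         "(a single clone carries all frequency mass)")
  if (n_clones > 1 && dominance == 1)
    stop("dominance = 1 leaves no mass for background clones")
  if (!is.list(junction_len_range))
    junction_len_range <- list(H = junction_len_range,
                               L = junction_len_range)
  set.seed(as.integer(seed))
  freq <- dominance
  if (n_clones > 1) {
    w <- 1 / seq_len(n_clones - 1)^power
    freq <- c(dominance, (1 - dominance) * w / sum(w))
  }
  loci_h <- "IGH"
  loci_l <- intersect(c("IGK", "IGL"), unique(segmentAnno(germline)$locus))
  rows <- list()
  seen <- character(0)
  addClone <- function(locus, clone_id, f, shm_count, c_call = NULL) {
    jr <- junction_len_range[[chainOf(locus)]]
    repeat {
      cl <- makeChainClone(germline, locus, clone_id, f,
                           shm_rate, shm_count, jr, leader_len,
                           trailer_len, c_call = c_call)
      key <- paste(locus, cl$junction)
      if (!key %in% seen) break
    }
    seen <<- c(seen, key)
    cl
  }
  hc <- alleleIds(germline, locus = "IGH", segment_class = "C")
  igg <- grep("^IGHG", hc, value = TRUE)
  for (i in seq_len(n_clones)) {
    f <- freq[i]
    id <- sprintf("C%03d", i)
    dom <- i == 1L
    shm_count <- if (dom) dominant_shm_count else NULL
    c_h <- if (dom && length(igg)) igg[1] else NULL
    if (chains == "paired") {
      loc_l <- if (dom) loci_l[1] else sample(loci_l, 1)
      rows[[length(rows) + 1L]] <-
        addClone("IGH", paste0(id, "_H"), f / 2, shm_count, c_call = c_h)
      rows[[length(rows) + 1L]] <-
        addClone(loc_l, paste0(id, "_L"), f / 2, shm_count)
    } else if (chains == "heavy") {
      rows[[length(rows) + 1L]] <-
        addClone("IGH", id, f, shm_count, c_call = c_h)
    } else {
      loc_l <- if (dom) loci_l[1] else sample(loci_l, 1)
      rows[[length(rows) + 1L]] <- addClone(loc_l, id, f, shm_count)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- out$clone_id
  attr(out, "params") <- list(n_clones = n_clones, dominance = dominance,
                              shm_rate = shm_rate, power = power,
                              chains = chains,
                              dominant_shm_count = dominant_shm_count,
                              seed = seed)
  out
}

## ---------------------------------------------------------------------
## fragmentation / FFPE damage
## ---------------------------------------------------------------------

#' Fragment length and damage model for degraded RNA
#'
#' Lengths follow a truncated log-normal; the default (median 200 nt,
#' sdlog 0.55, symmetric truncation at 200/3 and 200*3) gives a DV200 --
#' the percentage of fragments longer than 200 nt -- of 50%, the
#' borderline-usable degradation regime. Formalin damage is modelled as
#' strand-asymmetric deamination artifacts: C->T and G->A on the coding
#' strand, each at `damage_rate` per base (a low residual rate, as after
#' chemical reversal of formalin adducts).
#'
#' @param meanlog,sdlog log-normal parameters of the fragment length
#' @param bounds truncation bounds (nt); `sdlog = 0` gives fragments of
#'   fixed length `exp(meanlog)`
#' @param damage_rate per-base C->T / G->A artifact probability
#' @param bias_3prime probability that a fragment is anchored at the
#'   transcript 3' end (poly-A-side bias), 0 = uniform
#' @return a `fragment_model` list
#' @export
fragmentModel <- function(meanlog = log(200), sdlog = 0.55,
                          bounds = c(ceiling(200 / 3), 600),
                          damage_rate = 0.002, bias_3prime = 0) {
  stopifnot(damage_rate >= 0, damage_rate <= 1,
            bias_3prime >= 0, bias_3prime <= 1,
            length(bounds) == 2, bounds[1] >= 30, bounds[2] >= bounds[1])
  structure(list(meanlog = meanlog, sdlog = sdlog, bounds = bounds,
                 damage_rate = damage_rate, bias_3prime = bias_3prime),
            class = "fragment_model")
}

#' Sample fragment lengths from a fragment model
#' @param model a [fragmentModel()]
#' @param n number of lengths
#' @return integer vector
#' @export
sampleFragmentLengths <- function(model, n) {
  if (model$sdlog == 0) return(rep(round(exp(model$meanlog)), n))
  lo <- stats::plnorm(model$bounds[1], model$meanlog, model$sdlog)
  hi <- stats::plnorm(model$bounds[2], model$meanlog, model$sdlog)
  round(stats::qlnorm(runif(n, lo, hi), model$meanlog, model$sdlog))
}

#' DV200 of a fragment set
#'
#' Percentage of fragments longer than 200 nt, the standard quality
#' statistic for degraded RNA.
#' @param x character vector of fragment sequences, or numeric lengths
#' @return percentage in `[0, 100]`
#' @export
dv200 <- function(x) {
  len <- if (is.character(x)) nchar(x) else x
  100 * mean(len > 200)
}

applyDamage <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  vapply(seqs, function(s) {
    b <- strsplit(s, "", fixed = TRUE)[[1]]
    u <- runif(length(b))
    b[b == "C" & u < rate] <- "T"
    b[b == "G" & u < rate] <- "A"
    paste(b, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Fragment clone transcripts with FFPE-style damage
#'
#' Fragments are sampled from clones proportional to clone frequency,
#' with lengths from the model's truncated log-normal, clipped at the
#' transcript 3' end, and damaged base-wise (C->T / G->A).
#'
#' @param clones chain-clone table from [simulateRepertoire()]
#' @param model a [fragmentModel()]
#' @param n_fragments number of fragments (>= 1)
#' @param seed integer seed
#' @return list with `fragments` (named character vector), `truth`
#'   ([SimTruth-class] mapping each fragment to its clone and transcript
#'   offset) and `dv200` of the emitted set
#' @export
fragmentAndDamage <- function(clones, model = fragmentModel(),
                              n_fragments, seed = 1) {
  stopifnot(inherits(model, "fragment_model"), n_fragments >= 1)
  set.seed(as.integer(seed))
  idx <- sample(nrow(clones), n_fragments, replace = TRUE,
                prob = clones$frequency)
  lens <- sampleFragmentLengths(model, n_fragments)
  tx_len <- nchar(clones$transcript)[idx]
  ## fragments lie fully inside the transcript (standard shearing
  ## model); only transcripts shorter than the drawn length clip it
  lens <- pmin(lens, tx_len)
  anchor3 <- runif(n_fragments) < model$bias_3prime
  start <- ifelse(anchor3, tx_len - lens,
                  floor(runif(n_fragments) * (tx_len - lens + 1L)))
  end <- start + lens
  frags <- substr(clones$transcript[idx], start + 1L, end)
  frags <- applyDamage(frags, model$damage_rate)
  ids <- sprintf("frag_%06d", seq_len(n_fragments))
  names(frags) <- ids
  origins <- S4Vectors::DataFrame(read_id = ids,
                                  clone_id = clones$clone_id[idx],
                                  start = as.integer(start), strand = "+")
  truth <- new("SimTruth",
               clones = S4Vectors::DataFrame(clones),
               origins = origins,
               params = c(attr(clones, "params"),
                          list(fragment_model = unclass(model),
                               n_fragments = n_fragments,
                               fragment_seed = seed)))
  list(fragments = frags, truth = truth, dv200 = dv200(frags))
}

## ---------------------------------------------------------------------
## read simulation
## ---------------------------------------------------------------------

findPrimerSite <- function(transcript, primers) {
  for (k in seq_along(primers)) {
    p <- primers[k]
    hit <- regexpr(p, transcript, fixed = TRUE)
    if (hit < 0) hit <- regexpr(revComp(p), transcript, fixed = TRUE)
    if (hit > 0) return(as.integer(hit) + attr(hit, "match.length") - 1L)
  }
  NA_integer_
}

#' Simulate constant-region-primed amplicon reads (Ig-seq)
#'
#' Each amplicon is the template-switch tail plus the 5' transcript
#' portion down to (and including) the constant-region primer site, so
#' its 3' end abuts the primer site and every amplicon spans the
#' junction. Reads carry i.i.d. substitution errors. In paired mode an
#' amplicon yields an R1 from the 5' (TSO) end and an R2 from the 3'
#' (constant-region) end; in single-end mode the read is taken from the
#' constant-region end, reading upstream across the junction, as the
#' library chemistry is designed to do. Clones whose constant region
#' lacks a primer site are skipped with a warning.
#'
#' @param clones chain-clone table from [simulateRepertoire()]
#' @param primers named character vector of constant-region primer
#'   sequences; default the shipped RT primer pool
#' @param n_reads total number of reads (pairs count as two)
#' @param read_len read length (nt)
#' @param error_rate per-base substitution error probability
#' @param paired emit read pairs?
#' @param seed integer seed
#' @param out_prefix optional path prefix: writes `<prefix>.fastq` (and
#'   `_2.fastq` for pairs), `<prefix>_truth.tsv`, `<prefix>_params.json`
#' @return list with `reads` (named character vector) and `truth`
#'   ([SimTruth-class])
#' @export
makeIgseqReads <- function(clones, primers = NULL, n_reads = 20000,
                           read_len = 150, error_rate = 0.005,
                           paired = TRUE, seed = 1, out_prefix = NULL) {
  stopifnot(n_reads >= 1)
  if (is.null(primers)) {
    rt <- igseqPrimers("RT")
    rt <- rt[rt$pool == "RT_primer", , drop = FALSE]
    primers <- setNames(rt$sequence, rt$name)
  }
  set.seed(as.integer(seed))
  site <- vapply(clones$transcript, findPrimerSite, integer(1),
                 primers = primers, USE.NAMES = FALSE)
  ok <- !is.na(site)
  if (!all(ok))
    warning("no primer site in constant region; skipping clone(s): ",
            paste(clones$clone_id[!ok], collapse = ", "))
  if (!any(ok)) stop("no clone has a primer binding site")
  cl <- clones[ok, , drop = FALSE]
  site <- site[ok]
  amp <- paste0(TSO_TAIL, substr(cl$transcript, 1L, site))
  n_amp <- if (paired) ceiling(n_reads / 2) else n_reads
  idx <- sample(nrow(cl), n_amp, replace = TRUE,
                prob = cl$frequency / sum(cl$frequency))
  alen <- nchar(amp)[idx]
  tso <- nchar(TSO_TAIL)
  if (paired) {
    r1 <- substr(amp[idx], 1L, read_len)
    r2 <- revComp(substr(amp[idx], pmax(1L, alen - read_len + 1L), alen))
    ids1 <- sprintf("igseq_%06d/1", seq_len(n_amp))
    ids2 <- sprintf("igseq_%06d/2", seq_len(n_amp))
    reads <- setNames(c(mutateBases(r1, error_rate),
                        mutateBases(r2, error_rate)), c(ids1, ids2))
    origins <- S4Vectors::DataFrame(
      read_id = c(ids1, ids2),
      clone_id = rep(cl$clone_id[idx], 2),
      start = c(rep(-tso, n_amp), pmax(1L, alen - read_len + 1L) - 1L - tso),
      strand = rep(c("+", "-"), each = n_amp))
  } else {
    rd <- revComp(substr(amp[idx], pmax(1L, alen - read_len + 1L), alen))
    ids1 <- sprintf("igseq_%06d", seq_len(n_amp))
    reads <- setNames(mutateBases(rd, error_rate), ids1)
    origins <- S4Vectors::DataFrame(
      read_id = ids1, clone_id = cl$clone_id[idx],
      start = pmax(1L, alen - read_len + 1L) - 1L - tso, strand = "-")
  }
  truth <- new("SimTruth", clones = S4Vectors::DataFrame(clones),
               origins = origins,
               params = c(attr(clones, "params"),
                          list(n_reads = n_reads, read_len = read_len,
                               error_rate = error_rate, paired = paired,
                               igseq_seed = seed)))
  if (!is.null(out_prefix)) writeSimOutput(reads, truth, paired, out_prefix)
  list(reads = reads, truth = truth)
}

#' Simulate whole-transcriptome reads from damaged fragments
#'
#' Each fragment is sequenced in a random orientation (both strands are
#' emitted). Paired mode reads inward from the two fragment ends (insert
#' = fragment); single-end mode starts at a random position within the
#' fragment. Reads never extend past the fragment: a fragment shorter
#' than `read_len` yields a truncated read, no padding.
#'
#' @param fragments result of [fragmentAndDamage()] (or a named
#'   character vector of fragments plus `truth=`)
#' @param read_len read length (nt)
#' @param paired emit read pairs?
#' @param error_rate per-base substitution error probability
#' @param seed integer seed
#' @param truth [SimTruth-class] for the fragments (taken from
#'   `fragments$truth` when a [fragmentAndDamage()] result is passed)
#' @param out_prefix optional output prefix, as in [makeIgseqReads()]
#' @return list with `reads` and `truth`
#' @export
makeRnaseqReads <- function(fragments, read_len = 150, paired = TRUE,
                            error_rate = 0.005, seed = 1, truth = NULL,
                            out_prefix = NULL) {
  if (is.list(fragments) && !is.null(fragments$fragments)) {
    truth <- fragments$truth
    fragments <- fragments$fragments
  }
  if (is.null(truth)) stop("fragment truth required")
  set.seed(as.integer(seed))
  n <- length(fragments)
  flen <- nchar(fragments)
  fo <- readOrigins(truth)
  flip <- runif(n) < 0.5
  oriented <- ifelse(flip, revComp(fragments), fragments)
  if (paired) {
    r1 <- substr(oriented, 1L, read_len)
    r2 <- revComp(substr(oriented, pmax(1L, flen - read_len + 1L), flen))
    ids1 <- sprintf("rnaseq_%06d/1", seq_len(n))
    ids2 <- sprintf("rnaseq_%06d/2", seq_len(n))
    reads <- setNames(c(mutateBases(r1, error_rate),
                        mutateBases(r2, error_rate)), c(ids1, ids2))
    st1 <- ifelse(flip, fo$start + pmax(0L, flen - read_len), fo$start)
    st2 <- ifelse(flip, fo$start, fo$start + pmax(0L, flen - read_len))
    origins <- S4Vectors::DataFrame(
      read_id = c(ids1, ids2),
      clone_id = rep(fo$clone_id, 2),
      start = as.integer(c(st1, st2)),
      strand = c(ifelse(flip, "-", "+"), ifelse(flip, "+", "-")))
  } else {
    off <- floor(runif(n) * pmax(1L, flen - read_len + 1L))
    reads <- substr(oriented, off + 1L, pmin(off + read_len, flen))
    ids1 <- sprintf("rnaseq_%06d", seq_len(n))
    reads <- setNames(mutateBases(reads, error_rate), ids1)
    st <- ifelse(flip, fo$start + flen - (off + pmin(off + read_len, flen) -
                                            off), fo$start + off)
    origins <- S4Vectors::DataFrame(
      read_id = ids1, clone_id = fo$clone_id, start = as.integer(st),
      strand = ifelse(flip, "-", "+"))
  }
  truth2 <- new("SimTruth", clones = truth@clones, origins = origins,
                params = c(truth@params,
                           list(read_len = read_len, paired = paired,
                                error_rate = error_rate,
                                rnaseq_seed = seed)))
  if (!is.null(out_prefix)) writeSimOutput(reads, truth2, paired, out_prefix)
  list(reads = reads, truth = truth2)
}

writeSimOutput <- function(reads, truth, paired, prefix) {
  if (paired) {
    r1 <- grep("/1$", names(reads))
    writeFastq(unname(reads[r1]), names(reads)[r1],
               paste0(prefix, "_1.fastq"))
    r2 <- grep("/2$", names(reads))
    writeFastq(unname(reads[r2]), names(reads)[r2],
               paste0(prefix, "_2.fastq"))
  } else {
    writeFastq(unname(reads), names(reads), paste0(prefix, ".fastq"))
  }
  write.table(as.data.frame(readOrigins(truth)),
              paste0(prefix, "_truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  cl <- as.data.frame(truth@clones)
  cl$shm <- vapply(cl$shm, function(e)
    paste(sprintf("%d%s>%s", e$pos, e$ref, e$alt), collapse = ";"),
    character(1))
  write.table(cl, paste0(prefix, "_clones.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  p <- truth@params
  p <- p[!vapply(p, is.null, logical(1))]
  writeJson(p, paste0(prefix, "_params.json"))
  invisible(prefix)
}
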