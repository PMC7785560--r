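## CDR3-seeded reconstruction of full-length variable regions from
## whole-transcriptome fragments: filter reads to the VDJ loci (80%
## identity), find reads carrying the target junction (seeds, with the
## upstream YYC-class motif), then extend the junction 3'->5' across the
## V segment (and a bounded stretch 5'->3' into J/C) by column-wise
## majority vote over overlapping reads.

#' Assembly parameter defaults
#'
#' `min_identity`/`min_aligned` implement the "at least 80% alignment
#' to VDJ genes" read filter (identity over the locally aligned region,
#' with a minimum aligned length; set `rule = "read_fraction"` for the
#' alternative reading that 80% of the read must align). The remaining
#' knobs govern greedy overlap extension for 150-nt reads of fragmented
#' RNA: overlaps of at least `min_overlap` nt at `min_overlap_identity`,
#' a branch stop when the runner-up base reaches `branch_ratio` of the
#' winner's support, and a 3' cap of `cap3` nt past the junction --
#' enough constant region to call the isotype.
#' @return named list of parameters
#' @export
assemblyParams <- function() {
  list(min_identity = 0.80, min_aligned = 30L, rule = "identity",
       min_overlap = 20L, min_overlap_identity = 0.95,
       min_coverage = 2L, branch_ratio = 0.8, max_iterations = 10000L,
       extend_chunk = 12L, cap3 = 100L, seed_max_mismatches = 0L,
       polish_min_identity = 0.90)
}

#' Filter reads to those aligning to VDJ genes
#'
#' A read enters the pool iff its best local alignment to any V or J
#' allele (both strands) reaches `min_identity` over at least
#' `min_aligned` aligned nt (the 80% VDJ filter). Retained reads are
#' strand-normalized to the coding strand.
#'
#' @param reads named character vector of reads (or FASTQ path)
#' @param germline a [GermlineSet-class]
#' @param min_identity identity threshold (default 0.80)
#' @param min_aligned minimum aligned length (nt)
#' @param rule `"identity"` (identity over the aligned region) or
#'   `"read_fraction"` (>= `min_identity` of the read aligned, at >=
#'   `min_identity` identity)
#' @return named character vector (the pool, coding strand), with
#'   attribute `info` (per-read best hit) -- empty when nothing passes
#' @export
filterVdjReads <- function(reads, germline, min_identity = 0.80,
                           min_aligned = 30L, rule = c("identity",
                                                       "read_fraction")) {
  rule <- match.arg(rule)
  if (is.character(reads) && length(reads) == 1 && file.exists(reads))
    reads <- readFastq(reads)
  if (!length(reads)) {
    pool <- character(0)
    attr(pool, "info") <- data.frame(read_id = character(0),
                                     allele_id = character(0),
                                     score = numeric(0),
                                     identity = numeric(0),
                                     strand = character(0))
    return(pool)
  }
  if (is.null(names(reads)))
    names(reads) <- sprintf("read_%06d", seq_along(reads))
  par <- alignParams()
  ids <- alleleIds(germline, segment_class = c("V", "J"))
  subj <- segmentSeq(germline, ids)
  rc <- revComp(reads)
  fw <- swScores(reads, subj, par)
  rv <- swScores(rc, subj, par)
  n <- length(reads)
  keep <- logical(n)
  info <- data.frame(read_id = names(reads),
                     allele_id = NA_character_, score = NA_real_,
                     identity = NA_real_, strand = NA_character_)
  for (i in seq_len(n)) {
    best <- max(fw[i, ], rv[i, ])
    if (best <= 0) next
    ## all score-tied hits; tie-break by identity, then allele id
    cand <- rbind(
      if (any(fw[i, ] == best))
        data.frame(j = which(fw[i, ] == best), strand = "+"),
      if (any(rv[i, ] == best))
        data.frame(j = which(rv[i, ] == best), strand = "-"))
    trs <- lapply(seq_len(nrow(cand)), function(k) {
      q <- if (cand$strand[k] == "+") reads[[i]] else rc[[i]]
      swTrace(q, subj[[cand$j[k]]], par)
    })
    ident <- vapply(trs, `[[`, numeric(1), "identity")
    ord <- order(-ident, ids[cand$j])
    tr <- trs[[ord[1]]]
    pick <- ord[1]
    ok <- if (rule == "identity") {
      tr$identity >= min_identity && tr$n_cols >= min_aligned
    } else {
      (tr$p_end - tr$p_start) / nchar(reads[[i]]) >= min_identity &&
        tr$identity >= min_identity
    }
    keep[i] <- ok
    info$allele_id[i] <- ids[cand$j[pick]]
    info$score[i] <- tr$score
    info$identity[i] <- tr$identity
    info$strand[i] <- cand$strand[pick]
  }
  pool <- ifelse(info$strand == "-" & !is.na(info$strand), rc, reads)
  pool <- setNames(as.character(pool[keep]), names(reads)[keep])
  attr(pool, "info") <- info[keep, , drop = FALSE]
  pool
}

#' Find junction-carrying seed reads in the pool
#'
#' All occurrences of the target junction in the (strand-normalized)
#' pool within `max_mismatches` substitutions, each required to carry a
#' YYC-class motif (two aromatic residues then the conserved cysteine)
#' in frame immediately upstream of the junction. Sorted exact-first,
#' then by 5' flank length (longest first).
#'
#' @param pool strand-normalized reads from [filterVdjReads()]
#' @param target_junction junction nucleotides from the Ig-seq analysis
#' @param max_mismatches allowed substitutions within the junction match
#' @return data.frame (`read_id`, `offset` 0-based, `mismatches`,
#'   `flank5`); zero rows when there is no seed
#' @export
findSeeds <- function(pool, target_junction, max_mismatches = 0L) {
  if (!length(pool)) return(data.frame(read_id = character(0),
                                       offset = integer(0),
                                       mismatches = integer(0),
                                       flank5 = integer(0)))
  hits <- Biostrings::vmatchPattern(target_junction,
                                    Biostrings::DNAStringSet(pool),
                                    max.mismatch = max_mismatches,
                                    with.indels = FALSE)
  out <- list()
  jl <- nchar(target_junction)
  for (i in seq_along(pool)) {
    h <- hits[[i]]
    if (!length(h)) next
    for (s in BiocGenerics::start(h)) {
      if (s < 1 || s + jl - 1 > nchar(pool[[i]])) next
      if (s <= 6) next                    # no room for the upstream motif
      ctx <- substr(pool[[i]], s - 6L, s + 2L)   # YY + junction Cys codon
      if (!grepl("^[YF][YF]C$", translateNt(ctx))) next
      mm <- .hamming(substr(pool[[i]], s, s + jl - 1L), target_junction)
      out[[length(out) + 1L]] <- data.frame(
        read_id = names(pool)[i], offset = s - 1L, mismatches = mm,
        flank5 = s - 1L)
    }
  }
  if (!length(out)) return(data.frame(read_id = character(0),
                                      offset = integer(0),
                                      mismatches = integer(0),
                                      flank5 = integer(0)))
  res <- do.call(rbind, out)
  res[order(res$mismatches, -res$flank5, res$read_id), , drop = FALSE]
}

## qualifying overlaps of pool reads against the current contig 5' end:
## the contig prefix of length min_overlap must occur in the read
## (within the mismatch budget), the full overlap must reach
## min_overlap_identity, and the read must extend 5' of the contig
overlap5 <- function(contig, pool, par) {
  mo <- par$min_overlap
  if (nchar(contig) < mo) return(NULL)
  pref <- substr(contig, 1L, mo)
  mm_seed <- floor((1 - par$min_overlap_identity) * mo)
  hits <- Biostrings::vmatchPattern(pref, Biostrings::DNAStringSet(pool),
                                    max.mismatch = mm_seed,
                                    with.indels = FALSE)
  res <- list()
  for (i in seq_along(pool)) {
    st <- BiocGenerics::start(hits[[i]])
    if (!length(st)) next
    rl <- nchar(pool[[i]])
    for (s in st) {
      if (s < 1 || s + mo - 1L > rl) next
      o <- min(rl - s + 1L, nchar(contig))
      mm <- .hamming(substr(pool[[i]], s, s + o - 1L),
                     substr(contig, 1L, o))
      if (is.na(mm) || mm > floor((1 - par$min_overlap_identity) * o))
        next
      if (s == 1L) next                  # no 5' flank, nothing to add
      res[[length(res) + 1L]] <- list(read = pool[[i]], id = names(pool)[i],
                                      pos = s)
      break                              # one placement per read
    }
  }
  res
}

## detect whether the contig has reached (or passed) the start of the
## germline V segment; returns the contig position of the projected V
## start, or NA
projectedVStart <- function(contig, v_seqs, par) {
  sc <- swScores(contig, v_seqs, par)
  tr <- swTrace(contig, v_seqs[[which.max(sc[1, ])]], par)
  if (tr$s_start <= 6L && tr$p_start - tr$s_start >= 0L)
    return(tr$p_start - tr$s_start)
  NA_integer_
}

#' Extend a contig by greedy overlap consensus
#'
#' Iteratively collects pool reads overlapping the contig 5' end (at
#' least `min_overlap` nt at `min_overlap_identity`) and extends the
#' contig one column at a time by weighted majority vote over the bases
#' those reads contribute beyond the contig. Stops when (a) the
#' projected germline V start is reached (the contig is trimmed to it),
#' (b) no qualifying overlap remains, (c) the leading column is a tie or
#' the runner-up base has support >= `branch_ratio` times the winner
#' (`ambiguous_branch`), or (d) `max_iterations`. For `direction =
#' "3prime"` the same procedure runs on the reverse complement, bounded
#' by `cap3` added columns.
#'
#' @param contig starting contig (must contain the junction)
#' @param pool strand-normalized read pool
#' @param params [assemblyParams()]
#' @param direction `"5prime"` or `"3prime"`
#' @param germline_v optional named character vector of germline V
#'   sequences used for the V-start stop (5' direction only)
#' @param cap_cols maximum columns to add (3' direction; default
#'   `params$cap3`)
#' @return list: `contig`, `termination`, `stop_pos` (contig position of
#'   the stop event, 0-based, for branch stops), `added`, `used`
#'   (read ids), `trimmed5` (columns removed by the V-start trim)
#' @export
extendContig <- function(contig, pool, params = assemblyParams(),
                         direction = c("5prime", "3prime"),
                         germline_v = NULL, cap_cols = NULL) {
  direction <- match.arg(direction)
  par <- params
  if (direction == "3prime") {
    res <- extendContig(revComp(contig), setNames(revComp(pool),
                                                  names(pool)),
                        params, "5prime", germline_v = NULL,
                        cap_cols = if (is.null(cap_cols)) par$cap3 else
                          cap_cols)
    res$contig <- revComp(res$contig)
    if (res$termination == "v_start_reached")  # cannot happen without refs
      res$termination <- "no_overlap"
    return(res)
  }
  used <- character(0)
  added <- 0L
  termination <- NULL
  stop_pos <- NA_integer_
  trimmed5 <- 0L
  iter <- 0L
  ## a cap (used by the 3' wrapper) counts added columns
  repeat {
    iter <- iter + 1L
    if (iter > par$max_iterations) { termination <- "max_iterations"; break }
    if (!is.null(germline_v)) {
      vs <- projectedVStart(contig, v_seqs = germline_v, par = alignParams())
      if (!is.na(vs)) {
        trimmed5 <- vs
        if (vs > 0) contig <- substr(contig, vs + 1L, nchar(contig))
        termination <- "v_start_reached"
        break
      }
    }
    if (!is.null(cap_cols) && added >= cap_cols) {
      termination <- "c_cap_reached"
      break
    }
    ov <- overlap5(contig, pool, par)
    if (is.null(ov) || !length(ov)) { termination <- "no_overlap"; break }
    flanks <- vapply(ov, function(z) z$pos - 1L, integer(1))
    grew <- 0L
    stop_inner <- NULL
    t <- 1L
    ## extend at most extend_chunk columns before re-collecting
    ## overlaps: the live read set thins with depth, and votes taken at
    ## residual coverage 1-2 would turn single read errors into
    ## spurious branch stops
    chunk <- if (is.null(par$extend_chunk)) 12L else par$extend_chunk
    while (t <= chunk) {
      live <- flanks >= t
      if (!any(live)) break
      bases <- vapply(ov[live], function(z)
        substr(z$read, z$pos - t, z$pos - t), character(1))
      votes <- sort(table(bases), decreasing = TRUE)
      win <- votes[1]
      run <- if (length(votes) > 1) votes[2] else 0L
      if (run >= par$branch_ratio * win) {
        stop_inner <- "ambiguous_branch"
        stop_pos <- 0L                    # the un-added column boundary
        break
      }
      contig <- paste0(names(votes)[1], contig)
      used <- union(used, vapply(ov[live], `[[`, character(1), "id"))
      grew <- grew + 1L
      added <- added + 1L
      if (!is.null(cap_cols) && added >= cap_cols) break
      t <- t + 1L
    }
    if (!is.null(stop_inner)) { termination <- stop_inner; break }
    if (grew == 0L) { termination <- "no_overlap"; break }
  }
  ## a multi-column iteration can run past the V start into the
  ## untemplated leader before stopping there; if the projected V start
  ## lies within the contig the V region is complete regardless of how
  ## the leader extension ended -- trim to it
  if (!is.null(germline_v) && termination != "v_start_reached") {
    vs <- projectedVStart(contig, v_seqs = germline_v, par = alignParams())
    if (!is.na(vs) && vs >= 0) {
      trimmed5 <- vs
      if (vs > 0) contig <- substr(contig, vs + 1L, nchar(contig))
      termination <- "v_start_reached"
    }
  }
  list(contig = contig, termination = termination, stop_pos = stop_pos,
       added = added, used = used, trimmed5 = trimmed5)
}

## one polish round: re-map every pool read to the contig, column-wise
## majority vote (junction positions are pinned to the Ig-seq target)
polishContig <- function(contig, pool, junction_start, junction_end,
                         params) {
  par <- alignParams()
  L <- nchar(contig)
  cov <- integer(L)
  votes <- matrix(0L, nrow = 4, ncol = L,
                  dimnames = list(BASES, NULL))
  used <- character(0)
  for (i in seq_along(pool)) {
    tr <- swTrace(pool[[i]], contig, par)
    if (tr$identity < params$polish_min_identity ||
        tr$n_cols < params$min_overlap) next
    used <- c(used, names(pool)[i])
    ok <- tr$p_map >= 0 & tr$s_map >= 0
    rp <- tr$p_map[ok] + 1L
    cp <- tr$s_map[ok] + 1L
    b <- substring(pool[[i]], rp, rp)
    for (k in seq_along(cp)) {
      if (b[k] %in% BASES)
        votes[b[k], cp[k]] <- votes[b[k], cp[k]] + 1L
    }
    cov[cp] <- cov[cp] + 1L
  }
  cons <- strsplit(contig, "", fixed = TRUE)[[1]]
  agree <- rep(1, L)
  for (p in seq_len(L)) {
    tot <- sum(votes[, p])
    if (tot == 0) next
    if (p > junction_start && p <= junction_end) {
      agree[p] <- votes[cons[p], p] / tot
      next
    }
    w <- which.max(votes[, p])
    cons[p] <- BASES[w]
    agree[p] <- votes[w, p] / tot
  }
  list(contig = paste(cons, collapse = ""), coverage = pmax(cov, 1L),
       agreement = agree, used = unique(used))
}

#' Reconstruct a full-length chain from transcriptome reads
#'
#' The complete seed-and-extend path: filter reads to the VDJ loci (80%
#' identity), locate junction-bearing seed reads, extend 5' across the V
#' segment to the projected germline V start and 3' into J/C (bounded),
#' then polish the consensus with one round of re-mapping all pool reads
#' and majority vote. The translated protein is anchored at the junction
#' cysteine.
#'
#' @param reads named character vector / FASTQ path, or a pre-filtered
#'   pool from [filterVdjReads()] passed via `pool`
#' @param target_junction junction nucleotides (from the clonotype table)
#' @param germline a [GermlineSet-class]
#' @param params [assemblyParams()]
#' @param v_call optional V allele restricting the V-start projection
#'   (otherwise all V alleles are candidates)
#' @param pool optional pre-filtered pool
#' @return an [AssembledChain-class]; the report (protein, termination
#'   reasons, counts) is attached as attribute `report`
#' @export
reconstructChain <- function(reads = NULL, target_junction, germline,
                             params = assemblyParams(), v_call = NULL,
                             pool = NULL) {
  if (is.null(pool)) {
    pool <- filterVdjReads(reads, germline,
                           min_identity = params$min_identity,
                           min_aligned = params$min_aligned,
                           rule = params$rule)
  }
  if (!length(pool)) stop("no_vdj_reads")
  seeds <- findSeeds(pool, target_junction,
                     max_mismatches = params$seed_max_mismatches)
  if (!nrow(seeds)) stop("no_seed_reads")
  v_seqs <- if (!is.null(v_call)) segmentSeq(germline, v_call) else
    segmentSeq(germline, alleleIds(germline, segment_class = "V"))
  contig <- target_junction
  ext5 <- extendContig(contig, pool, params, "5prime",
                       germline_v = v_seqs)
  contig <- ext5$contig
  ## 5' extension prepends, so the junction sits at the contig end here
  junction_start <- nchar(contig) - nchar(target_junction)
  ext3 <- extendContig(contig, pool, params, "3prime")
  contig <- ext3$contig
  junction_end <- junction_start + nchar(target_junction)
  pol <- polishContig(contig, pool, junction_start, junction_end, params)
  contig <- pol$contig
  frame <- junction_start %% 3L
  chain <- new("AssembledChain",
               junction = target_junction, contig = contig,
               coverage = pol$coverage, agreement = pol$agreement,
               frame = as.integer(frame),
               boundaries = list(junction_start = junction_start,
                                 junction_end = junction_end,
                                 v_start_reached =
                                   ext5$termination == "v_start_reached",
                                 contig_end = nchar(contig)),
               reads = unique(c(seeds$read_id, ext5$used, ext3$used,
                                pol$used)),
               termination = ext5$termination,
               termination3 = ext3$termination)
  validObject(chain)
  prot <- translateNt(substr(contig, frame + 1L, nchar(contig)))
  attr(chain, "report") <- list(
    n_pool = length(pool), n_seeds = nrow(seeds),
    termination = ext5$termination, termination3 = ext3$termination,
    protein = prot, v_start_reached = ext5$termination == "v_start_reached")
  chain
}

#' Write an assembled chain (FASTA + coverage TSV + report JSON)
#' @param chain an [AssembledChain-class]
#' @param prefix output path prefix
#' @return invisibly the written paths
#' @export
writeAssembledChain <- function(chain, prefix) {
  fa <- paste0(prefix, ".fasta")
  writeLines(c(sprintf(">%s junction=%s termination=%s", basename(prefix),
                       chain@junction, chain@termination),
               chain@contig), fa)
  cv <- paste0(prefix, "_coverage.tsv")
  write.table(contigCoverage(chain), cv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  rp <- paste0(prefix, "_report.json")
  writeJson(attr(chain, "report"), rp)
  invisible(c(fa, cv, rp))
}
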