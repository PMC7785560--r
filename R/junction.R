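## CDR3/junction extraction from Ig-seq reads and clonotype aggregation.
##
## A read is assigned a V and a J allele by local alignment; the
## germline anchor positions (conserved Cys on V, conserved Trp/Phe on
## J) are projected through the alignments onto the read, and the
## junction is the anchor-inclusive span between them. Reads failing
## any step are tallied under a rejection reason, so accepted + rejected
## always equals input.

#' Default junction-caller thresholds
#'
#' `v_min_identity`/`v_min_len` gate the V assignment of Ig-seq reads
#' (this is the amplicon acceptance gate, distinct from the 80%
#' transcriptome VDJ filter of [filterVdjReads()]); `j_min_*` gate the
#' (shorter) J assignment. `merge_light` adds a combined "L" view over
#' IGK and IGL.
#' @return named list of thresholds
#' @export
junctionThresholds <- function() {
  list(v_min_identity = 0.85, v_min_len = 30L,
       j_min_identity = 0.85, j_min_len = 18L,
       v_min_score = 30, j_min_score = 20)
}

## project both anchors onto one read given its V and J tracebacks;
## returns a junction record or a rejection reason
#' Call the junction on a read from its V and J alignments
#'
#' Projects the germline anchor codons through the two alignments onto
#' the read and extracts the anchor-inclusive junction. The V and J hits
#' must be on the same strand with V upstream of J. Rejection reasons:
#' `anchor_uncovered` (an anchor codon is not covered by the read or its
#' alignment), `anchor_lost` (the anchor codon no longer translates to
#' C / W / F), `vj_inconsistent` (strand or order conflict).
#'
#' @param read read sequence (as sequenced)
#' @param v_aln,j_aln one-row alignment data.frames from
#'   [alignReadToGermline()] (with `maps` attributes)
#' @param germline a [GermlineSet-class]
#' @return list with `junction`, `junction_aa`, `cdr3`, `cdr3_aa`,
#'   `v_call`, `j_call`, `locus`, `productive`, or list with `reject`
#' @export
callJunction <- function(read, v_aln, j_aln, germline) {
  an <- segmentAnno(germline)
  if (v_aln$strand != j_aln$strand)
    return(list(reject = "vj_inconsistent"))
  q <- if (v_aln$strand == "+") read else revComp(read)
  junctionCore(q,
               v_maps = attr(v_aln, "maps"),
               j_maps = attr(j_aln, "maps"),
               v_anchor = an[v_aln$allele_id, "anchor_pos"],
               j_anchor = an[j_aln$allele_id, "anchor_pos"],
               v_call = v_aln$allele_id, j_call = j_aln$allele_id,
               locus = an[v_aln$allele_id, "locus"])
}

## the actual junction logic, on plain (pre-looked-up) arguments
junctionCore <- function(q, v_maps, j_maps, v_anchor, j_anchor,
                         v_call, j_call, locus) {
  ## all three anchor-codon bases must project through the alignment
  vpos <- vapply(v_anchor + 0:2, function(p) projectSegPos(v_maps, p),
                 integer(1))
  jpos <- vapply(j_anchor + 0:2, function(p) projectSegPos(j_maps, p),
                 integer(1))
  if (anyNA(vpos) || anyNA(jpos))
    return(list(reject = "anchor_uncovered"))
  if (any(diff(vpos) != 1L) || any(diff(jpos) != 1L))
    return(list(reject = "anchor_uncovered"))
  if (vpos[1] >= jpos[1])
    return(list(reject = "vj_inconsistent"))
  junction <- substr(q, vpos[1] + 1L, jpos[3] + 1L)
  first_aa <- translateNt(substr(junction, 1L, 3L))
  last_aa <- translateNt(substr(q, jpos[1] + 1L, jpos[3] + 1L))
  want <- if (locus == "IGH") "W" else "F"
  if (first_aa != "C" || last_aa != want)
    return(list(reject = "anchor_lost"))
  in_frame <- nchar(junction) %% 3L == 0L
  jaa <- if (in_frame) translateNt(junction) else NA_character_
  productive <- in_frame && !is.na(jaa) && !grepl("\\*", jaa)
  cdr3 <- substr(junction, 4L, nchar(junction) - 3L)
  list(junction = junction, junction_aa = jaa, cdr3 = cdr3,
       cdr3_aa = if (in_frame) substr(jaa, 2L, nchar(jaa) - 1L)
                 else NA_character_,
       v_call = v_call, j_call = j_call,
       locus = locus, productive = productive)
}

#' Build a clonotype table from Ig-seq reads
#'
#' Every read is attempted: best V allele (both strands), then best J
#' allele of the same locus on the V strand, then anchor projection via
#' [callJunction()]. Accepted reads are aggregated into clonotypes keyed
#' by (locus, V, J, junction). Frequencies are normalized per chain view
#' (H = IGH; L = IGK + IGL combined) over productive clonotypes;
#' non-productive clonotypes are reported with `frequency = NA`.
#'
#' @param reads named character vector of reads (or FASTQ path)
#' @param germline a [GermlineSet-class]
#' @param thresholds see [junctionThresholds()]
#' @param productive_only_freq exclude non-productive clonotypes from
#'   frequency normalization (default TRUE)
#' @return data.frame in AIRR-Rearrangement style (columns `locus`,
#'   `chain`, `v_call`, `j_call`, `junction`, `junction_aa`, `cdr3`,
#'   `cdr3_aa`, `consensus_count`, `frequency`, `productive`) sorted by
#'   count; QC tallies in attribute `qc`
#' @export
buildClonotypeTable <- function(reads, germline,
                                thresholds = junctionThresholds(),
                                productive_only_freq = TRUE) {
  if (is.character(reads) && length(reads) == 1 && file.exists(reads))
    reads <- readFastq(reads)
  n_in <- length(reads)
  qc <- c(input = n_in, accepted = 0, no_v_hit = 0, no_j_hit = 0,
          anchor_uncovered = 0, anchor_lost = 0, vj_inconsistent = 0)
  empty <- data.frame(locus = character(0), chain = character(0),
                      v_call = character(0), j_call = character(0),
                      junction = character(0), junction_aa = character(0),
                      cdr3 = character(0), cdr3_aa = character(0),
                      consensus_count = integer(0), frequency = numeric(0),
                      productive = logical(0))
  if (n_in == 0) {
    warning("empty read input")
    attr(empty, "qc") <- as.list(qc)
    return(empty)
  }
  par <- alignParams()
  ## plain-vector lookups, computed once (S4 accessors per read are the
  ## bottleneck at amplicon-library scale)
  plain_anno <- as.data.frame(segmentAnno(germline))
  seqs <- setNames(as.character(germline@sequences),
                   plain_anno$allele_id)
  anchor_of <- setNames(plain_anno$anchor_pos, plain_anno$allele_id)
  locus_of <- setNames(plain_anno$locus, plain_anno$allele_id)
  j_ids <- split(plain_anno$allele_id[plain_anno$segment_class == "J"],
                 plain_anno$locus[plain_anno$segment_class == "J"])
  rc <- revComp(reads)
  vbest <- bestHitBatch(reads, germline, "V", par, rc = rc)
  recs <- vector("list", n_in)
  for (i in seq_len(n_in)) {
    v_id <- vbest$allele_id[i]
    strand <- vbest$strand[i]
    q <- if (strand == "+") reads[[i]] else rc[[i]]
    v_tr <- swTrace(q, seqs[[v_id]], par)
    if (vbest$score[i] < thresholds$v_min_score ||
        v_tr$identity < thresholds$v_min_identity ||
        v_tr$n_cols < thresholds$v_min_len) {
      qc["no_v_hit"] <- qc["no_v_hit"] + 1; next
    }
    locus <- locus_of[[v_id]]
    jids <- j_ids[[locus]]
    jsc <- swScores(q, seqs[jids], par)
    jbest <- which.max(jsc[1, ])
    j_tr <- swTrace(q, seqs[[jids[jbest]]], par)
    if (max(jsc) < thresholds$j_min_score ||
        j_tr$identity < thresholds$j_min_identity ||
        j_tr$n_cols < thresholds$j_min_len) {
      qc["no_j_hit"] <- qc["no_j_hit"] + 1; next
    }
    res <- junctionCore(q,
                        v_maps = list(read = v_tr$p_map,
                                      segment = v_tr$s_map),
                        j_maps = list(read = j_tr$p_map,
                                      segment = j_tr$s_map),
                        v_anchor = anchor_of[[v_id]],
                        j_anchor = anchor_of[[jids[jbest]]],
                        v_call = v_id, j_call = jids[jbest],
                        locus = locus)
    if (!is.null(res$reject)) {
      qc[res$reject] <- qc[res$reject] + 1; next
    }
    qc["accepted"] <- qc["accepted"] + 1
    recs[[i]] <- res
  }
  recs <- recs[!vapply(recs, is.null, logical(1))]
  if (!length(recs)) {
    attr(empty, "qc") <- as.list(qc)
    return(empty)
  }
  df <- data.frame(
    locus = vapply(recs, `[[`, character(1), "locus"),
    v_call = vapply(recs, `[[`, character(1), "v_call"),
    j_call = vapply(recs, `[[`, character(1), "j_call"),
    junction = vapply(recs, `[[`, character(1), "junction"),
    junction_aa = vapply(recs, function(r)
      if (is.na(r$junction_aa)) NA_character_ else r$junction_aa,
      character(1)),
    cdr3 = vapply(recs, `[[`, character(1), "cdr3"),
    cdr3_aa = vapply(recs, function(r)
      if (is.na(r$cdr3_aa)) NA_character_ else r$cdr3_aa, character(1)),
    productive = vapply(recs, `[[`, logical(1), "productive"))
  key <- paste(df$locus, df$v_call, df$j_call, df$junction, sep = "|")
  agg <- df[!duplicated(key), , drop = FALSE]
  agg$consensus_count <- as.integer(table(key)[key[!duplicated(key)]])
  agg$chain <- chainOf(agg$locus)
  agg <- computeFrequencies(agg, productive_only_freq)
  agg <- agg[order(-agg$consensus_count, agg$junction),
             c("locus", "chain", "v_call", "j_call", "junction",
               "junction_aa", "cdr3", "cdr3_aa", "consensus_count",
               "frequency", "productive")]
  rownames(agg) <- NULL
  attr(agg, "qc") <- as.list(qc)
  agg
}

## per chain view (H / L), over productive clonotypes by default
computeFrequencies <- function(tab, productive_only = TRUE) {
  tab$frequency <- NA_real_
  for (ch in unique(tab$chain)) {
    sel <- tab$chain == ch & (!productive_only | tab$productive)
    tot <- sum(tab$consensus_count[sel])
    if (tot > 0)
      tab$frequency[sel] <- tab$consensus_count[sel] / tot
  }
  tab
}

#' Frequency-ratio error correction of a clonotype table
#'
#' A clonotype whose junction is within `max_mismatches` substitutions
#' of a clonotype at least `ratio_threshold` times more abundant (same
#' locus, V and J) is merged into it, counts added. Children are
#' processed in ascending count order and the rule is iterated to a
#' fixed point. Never increases the table size; conserves total count.
#'
#' @param table clonotype table from [buildClonotypeTable()]
#' @param ratio_threshold minimum parent/child count ratio (default 20)
#' @param max_mismatches maximum junction substitutions (default 2,
#'   sized for 150-nt reads at ~0.5% error where two-error junctions
#'   are common; the ratio gate keeps true clonotypes apart)
#' @return corrected table, re-sorted, frequencies recomputed
#' @export
errorCorrectClonotypes <- function(table, ratio_threshold = 20,
                                   max_mismatches = 2L) {
  if (!nrow(table)) stop("empty clonotype table")
  tab <- table
  count <- tab$consensus_count
  alive <- rep(TRUE, nrow(tab))
  grp <- paste(tab$locus, tab$v_call, tab$j_call, nchar(tab$junction))
  repeat {
    changed <- FALSE
    for (ci in order(count, tab$junction)) {
      if (!alive[ci]) next
      cand <- which(alive & grp == grp[ci] &
                    count >= ratio_threshold * count[ci])
      cand <- setdiff(cand, ci)
      if (!length(cand)) next
      d <- vapply(tab$junction[cand], .hamming, integer(1),
                  b = tab$junction[ci], USE.NAMES = FALSE)
      cand <- cand[!is.na(d) & d > 0 & d <= max_mismatches]
      if (!length(cand)) next
      parent <- cand[order(-count[cand], tab$junction[cand])][1]
      count[parent] <- count[parent] + count[ci]
      alive[ci] <- FALSE
      changed <- TRUE
    }
    if (!changed) break
  }
  tab$consensus_count <- count
  tab <- tab[alive, , drop = FALSE]
  tab <- computeFrequencies(tab)
  tab <- tab[order(-tab$consensus_count, tab$junction), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "qc") <- attr(table, "qc")
  tab
}

#' Write / read a clonotype table as AIRR-style TSV
#' @param table clonotype table
#' @param path TSV path
#' @return invisibly `path` (write) / the table (read)
#' @export
writeClonotypeTable <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  qc <- attr(table, "qc")
  if (!is.null(qc)) writeJson(qc, paste0(sub("\\.tsv$", "", path),
                                         "_qc.json"))
  invisible(path)
}

#' @rdname writeClonotypeTable
#' @export
readClonotypeTable <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
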