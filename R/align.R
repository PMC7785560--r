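## Thin R layer over the C++ affine-gap Smith-Waterman kernels.
##
## Scoring defaults follow the megablast convention (match +2, mismatch
## -3, gap open 5, gap extend 2); identity is matches / alignment
## columns (gap columns included). All intervals are 0-based half-open.

#' Default alignment scoring parameters
#' @return named list (`match`, `mismatch`, `gap_open`, `gap_ext`)
#' @export
alignParams <- function() {
  list(match = 2L, mismatch = -3L, gap_open = 5L, gap_ext = 2L)
}

swScores <- function(patterns, subjects, par = alignParams()) {
  .sw_batch_score(patterns, subjects, par$match, par$mismatch,
                  par$gap_open, par$gap_ext)
}

swTrace <- function(pattern, subject, par = alignParams()) {
  .sw_traceback(pattern, subject, par$match, par$mismatch,
                par$gap_open, par$gap_ext)
}

#' Align one read against all germline segments of a class
#'
#' Local (affine-gap) alignment of a read against every allele of the
#' requested segment class on both strands. The best hit is chosen by
#' score, ties broken by higher identity, then lexicographically by
#' allele id. Returns `NULL` when the best score is below `min_score`.
#'
#' @param read character, the read sequence
#' @param germline a [GermlineSet-class]
#' @param mode segment class to search, `"V"` or `"J"` (or `"C"`)
#' @param min_score minimum accepted alignment score
#' @param par scoring parameters, see [alignParams()]
#' @return a one-row data.frame (`allele_id`, `score`, `identity`,
#'   `read_start`, `read_end`, `seg_start`, `seg_end`, `strand`) or
#'   `NULL`; the traceback position maps are attached as attribute
#'   `maps`
#' @export
alignReadToGermline <- function(read, germline, mode = c("V", "J", "C"),
                                min_score = 30, par = alignParams()) {
  mode <- match.arg(mode)
  stopifnot(nchar(read) > 0)
  ids <- alleleIds(germline, segment_class = mode)
  if (!length(ids)) return(NULL)
  subj <- segmentSeq(germline, ids)
  sc <- swScores(c(read, revComp(read)), subj, par)
  best <- max(sc)
  if (best < min_score) return(NULL)
  hits <- which(sc == best, arr.ind = TRUE)
  cand <- lapply(seq_len(nrow(hits)), function(k) {
    ori <- hits[k, 1]; j <- hits[k, 2]
    q <- if (ori == 1) read else revComp(read)
    tr <- swTrace(q, subj[[j]], par)
    list(id = ids[j], strand = if (ori == 1) "+" else "-", tr = tr)
  })
  ident <- vapply(cand, function(z) z$tr$identity, numeric(1))
  ord <- order(-ident, vapply(cand, `[[`, character(1), "id"))
  pick <- cand[[ord[1]]]
  tr <- pick$tr
  out <- data.frame(allele_id = pick$id, score = tr$score,
                    identity = tr$identity, read_start = tr$p_start,
                    read_end = tr$p_end, seg_start = tr$s_start,
                    seg_end = tr$s_end, strand = pick$strand)
  attr(out, "maps") <- list(read = tr$p_map, segment = tr$s_map)
  out
}

## Batch best-hit search: per read, the best allele, orientation and
## score. A k-mer strand vote decides which orientation to score when
## it is decisive; weak votes and low-scoring winners fall back to
## scoring both orientations, so results match the exhaustive search.
## Tracebacks are left to the caller (only needed for accepted reads).
bestHitBatch <- function(reads, germline, mode, par = alignParams(),
                         rc = NULL, strand_heuristic = TRUE,
                         vote_margin = 3L, score_floor = 60) {
  ids <- alleleIds(germline, segment_class = mode)
  subj <- segmentSeq(germline, ids)
  if (is.null(rc)) rc <- revComp(reads)
  n <- length(reads)
  vote <- if (strand_heuristic && n > 0)
    .strand_vote(reads, unname(subj), 12L) else integer(n)
  score <- numeric(n); pickm <- integer(n); strand <- character(n)
  scoreSet <- function(idx, orientation) {
    if (!length(idx)) return()
    q <- if (orientation == "+") reads[idx] else rc[idx]
    sc <- swScores(q, subj, par)
    better <- sc[cbind(seq_along(idx), max.col(sc, "first"))] > score[idx]
    upd <- idx[better]
    if (length(upd)) {
      m <- max.col(sc, "first")[better]
      score[upd] <<- sc[cbind(which(better), m)]
      pickm[upd] <<- m
      strand[upd] <<- orientation
    }
  }
  scoreSet(which(vote >= -vote_margin), "+")
  scoreSet(which(vote <= vote_margin | score < score_floor), "-")
  ## anything still unscored in one orientation but weak: both done above
  data.frame(read_index = seq_len(n), allele_id = ids[pickm],
             score = score, strand = strand)
}

## project a 0-based segment position onto the read through an
## alignment's position maps; returns NA when the position falls outside
## the aligned span or on a gap column
projectSegPos <- function(maps, seg_pos) {
  hit <- which(maps$segment == seg_pos)
  if (length(hit) != 1 || maps$read[hit] < 0) return(NA_integer_)
  maps$read[hit]
}
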