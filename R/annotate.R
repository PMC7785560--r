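## Germline annotation of an assembled chain: allele assignment,
## IMGT-style CDR boundaries by projection, somatic hypermutation calls
## (junction excluded -- it is template-free), and isotype from the
## constant-region tail.

ISOTYPE_MAP <- c(IGHG = "IgG", IGHM = "IgM", IGHA = "IgA",
                 IGKC = "IgK", IGLC = "IgL")

isotypeOf <- function(allele_id) {
  for (p in names(ISOTYPE_MAP))
    if (startsWith(allele_id, p)) return(unname(ISOTYPE_MAP[p]))
  "unknown"
}

#' Assign germline V and J alleles to an assembled chain
#'
#' Best-scoring V allele over the contig region 5' of the junction and
#' best J allele over the region 3' of it; ties broken by identity,
#' then allele id. Requires at least 60 nt of V context upstream of the
#' junction.
#'
#' @param chain an [AssembledChain-class]
#' @param germline a [GermlineSet-class]
#' @return list (`v_call`, `j_call`, `v_identity`, `j_identity`), with
#'   the two tracebacks attached as attributes `v_trace` / `j_trace`
#' @export
assignGermlineAlleles <- function(chain, germline) {
  js <- chain@boundaries$junction_start
  je <- chain@boundaries$junction_end
  if (js < 60)
    stop("insufficient_v_context: only ", js,
         " nt upstream of the junction (need >= 60)")
  par <- alignParams()
  bestOf <- function(query, ids) {
    subj <- segmentSeq(germline, ids)
    sc <- swScores(query, subj, par)
    best <- max(sc)
    tie <- which(sc[1, ] == best)
    trs <- lapply(tie, function(j) swTrace(query, subj[[j]], par))
    ord <- order(-vapply(trs, `[[`, numeric(1), "identity"), ids[tie])
    list(id = ids[tie][ord[1]], tr = trs[[ord[1]]])
  }
  vq <- substr(chain@contig, 1L, js)
  v <- bestOf(vq, alleleIds(germline, segment_class = "V"))
  locus <- segmentAnno(germline)[v$id, "locus"]
  jq <- substr(chain@contig, je + 1L, nchar(chain@contig))
  j <- bestOf(jq, alleleIds(germline, locus = locus, segment_class = "J"))
  out <- list(v_call = v$id, j_call = j$id,
              v_identity = v$tr$identity, j_identity = j$tr$identity,
              locus = locus)
  attr(out, "v_trace") <- v$tr
  attr(out, "j_trace") <- j$tr
  out
}

## project a germline-V position onto the contig through the V
## traceback (query was the contig region before the junction, so
## query coordinates are contig coordinates); nearest-column
## extrapolation handles positions clipped or gapped in the alignment
projectVPos <- function(tr, v_pos) {
  ok <- tr$s_map >= 0 & tr$p_map >= 0
  s <- tr$s_map[ok]; p <- tr$p_map[ok]
  if (!length(s)) return(NA_integer_)
  hit <- which(s == v_pos)
  if (length(hit)) return(p[hit[1]])
  near <- which.min(abs(s - v_pos))
  p[near] + (v_pos - s[near])
}

#' Project IMGT-style CDR boundaries onto the contig
#'
#' CDR1/CDR2 boundaries come from the germline V allele's annotation
#' (nt coordinates on the segment, 0-based half-open) and are projected
#' through the contig-to-germline alignment, so germline-relative
#' insertions or deletions shift them correctly. CDR3 is the junction
#' minus its two anchor codons, by definition.
#'
#' @param chain an [AssembledChain-class]
#' @param alleles result of [assignGermlineAlleles()]
#' @param germline a [GermlineSet-class]
#' @return list of 0-based half-open contig intervals `cdr1`, `cdr2`,
#'   `cdr3`
#' @export
annotateCdrs <- function(chain, alleles, germline) {
  an <- segmentAnno(germline)
  v <- alleles$v_call
  if (is.na(an[v, "cdr1_start"]))
    stop("no CDR boundary scheme annotated for allele ", v)
  tr <- attr(alleles, "v_trace")
  cdr1 <- c(projectVPos(tr, an[v, "cdr1_start"]),
            projectVPos(tr, an[v, "cdr1_end"] - 1L) + 1L)
  cdr2 <- c(projectVPos(tr, an[v, "cdr2_start"]),
            projectVPos(tr, an[v, "cdr2_end"] - 1L) + 1L)
  js <- chain@boundaries$junction_start
  je <- chain@boundaries$junction_end
  list(cdr1 = as.integer(cdr1), cdr2 = as.integer(cdr2),
       cdr3 = c(js + 3L, je - 3L))
}

regionOf <- function(pos, cdr, junction_start) {
  if (pos < cdr$cdr1[1]) "FR1"
  else if (pos < cdr$cdr1[2]) "CDR1"
  else if (pos < cdr$cdr2[1]) "FR2"
  else if (pos < cdr$cdr2[2]) "CDR2"
  else if (pos < junction_start) "FR3"
  else "FR4"
}

#' Call somatic hypermutations against the assigned germline
#'
#' Position-wise comparison of the contig to the aligned germline V and
#' J segments, junction excluded. Nucleotide differences are classified
#' silent / non-silent at the codon level (frame anchored at the
#' junction cysteine); amino-acid-changing codons become SHM records.
#' Positions where the assembler consensus is weak (coverage below
#' `min_coverage` or agreement below `min_agreement`) are uncallable and
#' never reported as mutations.
#'
#' @param chain an [AssembledChain-class]
#' @param alleles result of [assignGermlineAlleles()]
#' @param germline a [GermlineSet-class]
#' @param cdr CDR intervals from [annotateCdrs()] (for region labels);
#'   optional
#' @param min_coverage,min_agreement callability thresholds
#' @return list: `shm` (amino-acid records), `silent_nt`,
#'   `shm_count_nt`, `shm_count_aa`, `uncallable` (positions)
#' @export
callShm <- function(chain, alleles, germline, cdr = NULL,
                    min_coverage = 2L, min_agreement = 0.7) {
  js <- chain@boundaries$junction_start
  je <- chain@boundaries$junction_end
  frame <- chain@frame
  contig <- chain@contig
  callable <- chain@coverage >= min_coverage &
    chain@agreement >= min_agreement
  ## collect aligned (contig_pos, germline_base) pairs for V and J
  pairs <- list()
  vt <- attr(alleles, "v_trace")
  vseq <- segmentSeq(germline, alleles$v_call)
  ok <- vt$p_map >= 0 & vt$s_map >= 0
  pairs$V <- data.frame(pos = vt$p_map[ok],
                        germ = substring(vseq, vt$s_map[ok] + 1L,
                                         vt$s_map[ok] + 1L))
  jt <- attr(alleles, "j_trace")
  jseq <- segmentSeq(germline, alleles$j_call)
  ok <- jt$p_map >= 0 & jt$s_map >= 0
  pairs$J <- data.frame(pos = jt$p_map[ok] + je,  # J query began at je
                        germ = substring(jseq, jt$s_map[ok] + 1L,
                                         jt$s_map[ok] + 1L))
  ali <- rbind(pairs$V, pairs$J)
  ali <- ali[ali$pos < js | ali$pos >= je, , drop = FALSE]  # junction out
  ali$obs <- substring(contig, ali$pos + 1L, ali$pos + 1L)
  ali$callable <- callable[ali$pos + 1L]
  diffs <- ali[ali$obs != ali$germ & ali$callable, , drop = FALSE]
  uncallable <- ali$pos[!ali$callable]
  ## codon-level classification
  germ_at <- function(p) {
    hit <- match(p, ali$pos)
    ifelse(is.na(hit), NA_character_, ali$germ[hit])
  }
  shm <- data.frame(codon = integer(0), germline_aa = character(0),
                    observed_aa = character(0),
                    germline_codon = character(0),
                    observed_codon = character(0), region = character(0))
  silent <- data.frame(pos = integer(0), germline_nt = character(0),
                       observed_nt = character(0))
  if (nrow(diffs)) {
    cods <- unique((diffs$pos - frame) %/% 3L)
    for (cd in sort(cods)) {
      p0 <- frame + 3L * cd
      gp <- germ_at(p0 + 0:2)
      op <- strsplit(substr(contig, p0 + 1L, p0 + 3L), "")[[1]]
      if (anyNA(gp) || length(op) < 3) {
        ## codon not fully aligned to germline: report nt-level only
        for (k in which(!is.na(gp) & gp != op[seq_along(gp)]))
          silent <- rbind(silent, data.frame(
            pos = p0 + k - 1L, germline_nt = gp[k],
            observed_nt = op[k]))
        next
      }
      gaa <- translateNt(paste(gp, collapse = ""))
      oaa <- translateNt(paste(op, collapse = ""))
      if (gaa != oaa) {
        shm <- rbind(shm, data.frame(
          codon = cd + 1L, germline_aa = gaa, observed_aa = oaa,
          germline_codon = paste(gp, collapse = ""),
          observed_codon = paste(op, collapse = ""),
          region = if (is.null(cdr)) NA_character_ else
            regionOf(p0, cdr, js)))
      } else {
        mism <- which(gp != op)
        silent <- rbind(silent, data.frame(
          pos = p0 + mism - 1L, germline_nt = gp[mism],
          observed_nt = op[mism]))
      }
    }
  }
  list(shm = shm, silent_nt = silent,
       shm_count_nt = nrow(diffs), shm_count_aa = nrow(shm),
       uncallable = uncallable)
}

#' Call the isotype from the constant-region evidence
#'
#' Contig mode: the contig tail 3' of the junction is aligned to the
#' leading window of every constant segment; the best-identity segment
#' names the isotype, `unknown` below the identity floor. Pool mode: C
#' reads vote, and the winning isotype's support fraction is reported.
#'
#' @param chain an [AssembledChain-class], or `NULL` with `pool`
#' @param germline a [GermlineSet-class] (its C segments)
#' @param pool optional strand-normalized read pool (vote mode)
#' @param window leading constant-region window (nt)
#' @param identity_floor minimum identity for a call
#' @param min_aligned minimum aligned nt for a read to vote
#' @return list (`isotype`, `support`, `identity`)
#' @export
callIsotype <- function(chain = NULL, germline, pool = NULL,
                        window = 60L, identity_floor = 0.7,
                        min_aligned = 20L) {
  par <- alignParams()
  cids <- alleleIds(germline, segment_class = "C")
  if (!length(cids)) return(list(isotype = "unknown", support = NA_real_,
                                 identity = NA_real_))
  cwin <- vapply(segmentSeq(germline, cids), substr, character(1),
                 start = 1L, stop = window)
  if (!is.null(pool) && length(pool)) {
    votes <- character(0)
    for (i in seq_along(pool)) {
      sc <- swScores(pool[[i]], cwin, par)
      b <- which.max(sc[1, ])
      tr <- swTrace(pool[[i]], cwin[[b]], par)
      if (tr$identity >= identity_floor && tr$n_cols >= min_aligned)
        votes <- c(votes, isotypeOf(cids[b]))
    }
    if (!length(votes)) return(list(isotype = "unknown",
                                    support = NA_real_,
                                    identity = NA_real_))
    tab <- sort(table(votes), decreasing = TRUE)
    return(list(isotype = names(tab)[1],
                support = as.numeric(tab[1]) / length(votes),
                identity = NA_real_))
  }
  je <- chain@boundaries$junction_end
  tail_seq <- substr(chain@contig, je + 1L, nchar(chain@contig))
  if (nchar(tail_seq) < min_aligned)
    return(list(isotype = "unknown", support = NA_real_,
                identity = NA_real_))
  sc <- swScores(tail_seq, cwin, par)
  b <- which.max(sc[1, ])
  tr <- swTrace(tail_seq, cwin[[b]], par)
  if (tr$identity < identity_floor || tr$n_cols < min_aligned)
    return(list(isotype = "unknown", support = NA_real_,
                identity = tr$identity))
  list(isotype = isotypeOf(cids[b]), support = 1, identity = tr$identity)
}

#' Annotate an assembled chain against germline
#'
#' Orchestrates [assignGermlineAlleles()], [annotateCdrs()], [callShm()]
#' and [callIsotype()] into a [ChainAnnotation-class].
#'
#' @inheritParams callShm
#' @param pool optional read pool for isotype voting
#' @param ... passed to [callShm()]
#' @return a [ChainAnnotation-class]
#' @export
annotateChain <- function(chain, germline, pool = NULL, ...) {
  alleles <- assignGermlineAlleles(chain, germline)
  cdr <- annotateCdrs(chain, alleles, germline)
  shm <- callShm(chain, alleles, germline, cdr = cdr, ...)
  iso <- callIsotype(chain, germline, pool = pool)
  jaa <- translateNt(chain@junction)
  productive <- nchar(chain@junction) %% 3L == 0L && !grepl("\\*", jaa) &&
    substr(jaa, 1, 1) == "C" &&
    substr(jaa, nchar(jaa), nchar(jaa)) %in% c("W", "F")
  new("ChainAnnotation",
      v_call = alleles$v_call, j_call = alleles$j_call,
      v_identity = alleles$v_identity, j_identity = alleles$j_identity,
      cdr = cdr, shm = shm$shm, shm_count_nt = as.integer(shm$shm_count_nt),
      shm_count_aa = as.integer(shm$shm_count_aa),
      silent_nt = shm$silent_nt, isotype = iso$isotype,
      isotype_support = as.numeric(if (is.null(iso$support)) NA else
        iso$support),
      productive = productive)
}

#' Write an annotation report (JSON + alignment-style text)
#'
#' The text report shows the germline-projected line, the contig line,
#' a CDR ruler and markers under mutated codons -- the conventional
#' germline-comparison figure as plain text.
#'
#' @param ann a [ChainAnnotation-class]
#' @param chain the annotated [AssembledChain-class]
#' @param germline a [GermlineSet-class]
#' @param prefix output path prefix
#' @return invisibly the written paths
#' @export
writeAnnotation <- function(ann, chain, germline, prefix) {
  js <- paste0(prefix, "_annotation.json")
  writeJson(list(v_call = ann@v_call, j_call = ann@j_call,
                 v_identity = ann@v_identity, j_identity = ann@j_identity,
                 cdr = ann@cdr, shm = ann@shm,
                 shm_count_nt = ann@shm_count_nt,
                 shm_count_aa = ann@shm_count_aa,
                 isotype = ann@isotype, productive = ann@productive), js)
  txt <- paste0(prefix, "_alignment.txt")
  frame <- chain@frame
  contig <- chain@contig
  prot <- translateNt(substr(contig, frame + 1L, nchar(contig)))
  n_aa <- nchar(prot)
  ruler <- rep("-", n_aa)
  markCdr <- function(iv, ch) {
    a <- (iv[1] - frame) %/% 3L + 1L
    b <- (iv[2] - 1L - frame) %/% 3L + 1L
    a <- max(1L, a); b <- min(n_aa, b)
    if (a <= b) ruler[a:b] <<- ch
  }
  markCdr(ann@cdr$cdr1, "1"); markCdr(ann@cdr$cdr2, "2")
  markCdr(ann@cdr$cdr3, "3")
  marks <- rep(" ", n_aa)
  if (nrow(ann@shm)) marks[ann@shm$codon[ann@shm$codon <= n_aa]] <- "*"
  lines <- c(sprintf("# %s / %s   isotype=%s   SHM(aa)=%d",
                     ann@v_call, ann@j_call, ann@isotype,
                     ann@shm_count_aa),
             paste0("CDR    ", paste(ruler, collapse = "")),
             paste0("chain  ", prot),
             paste0("SHM    ", paste(marks, collapse = "")))
  writeLines(lines, txt)
  invisible(c(js, txt))
}
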