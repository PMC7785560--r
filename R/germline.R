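## Germline segment references with junction-anchor annotations.
##
## Coordinates are 0-based half-open everywhere internally; only
## human-readable reports use 1-based positions. The V anchor is the
## second conserved cysteine codon (IMGT 104); the J anchor is the
## conserved tryptophan (heavy) or phenylalanine (light) codon (IMGT
## 118). The junction is anchor-inclusive; CDR3 excludes both anchors.

STOP_FREE_CODONS <- local({
  b <- c("A", "C", "G", "T")
  cod <- as.vector(outer(as.vector(outer(b, b, paste0)), b, paste0))
  cod[!cod %in% c("TAA", "TAG", "TGA")]
})

randomCodons <- function(n) {
  paste(sample(STOP_FREE_CODONS, n, replace = TRUE), collapse = "")
}

#' Load a germline segment reference
#'
#' Reads a germline FASTA plus its annotation sidecar (TSV with columns
#' `allele_id`, `locus`, `segment_class`, `frame`, `anchor_pos`, `motif`
#' and, for V segments, `cdr1_start`, `cdr1_end`, `cdr2_start`,
#' `cdr2_end`; coordinates 0-based half-open) and returns a validated
#' [GermlineSet-class]. Records whose anchor codon does not translate to
#' the conserved cysteine (V) or tryptophan/phenylalanine (J) are
#' rejected: validation fails with a report naming each offending record.
#'
#' @param fasta_path germline FASTA
#' @param annotation_path annotation TSV
#' @return a `GermlineSet`
#' @examples
#' gl <- makeToyGermline(seed = 1)
#' tmp <- tempfile()
#' writeGermline(gl, tmp)
#' gl2 <- loadGermline(paste0(tmp, ".fasta"), paste0(tmp, ".tsv"))
#' @export
loadGermline <- function(fasta_path, annotation_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  an <- read.delim(annotation_path, stringsAsFactors = FALSE)
  missing <- setdiff(names(seqs), an$allele_id)
  if (length(missing))
    stop("missing annotation for record(s): ", paste(missing, collapse = ", "))
  extra <- setdiff(an$allele_id, names(seqs))
  if (length(extra))
    stop("annotation without FASTA record(s): ", paste(extra, collapse = ", "))
  an <- an[match(names(seqs), an$allele_id), , drop = FALSE]
  for (col in c("cdr1_start", "cdr1_end", "cdr2_start", "cdr2_end"))
    if (!col %in% colnames(an)) an[[col]] <- NA_integer_
  gs <- new("GermlineSet", sequences = seqs,
            anno = S4Vectors::DataFrame(an, row.names = an$allele_id))
  validObject(gs)  # anchor invariants; names each failing record
  gs
}

#' Write a germline set to FASTA + annotation TSV
#'
#' @param x a [GermlineSet-class]
#' @param prefix output path prefix; writes `<prefix>.fasta` and
#'   `<prefix>.tsv`
#' @return invisibly, the two paths
#' @export
writeGermline <- function(x, prefix) {
  stopifnot(is(x, "GermlineSet"))
  fa <- paste0(prefix, ".fasta")
  tsv <- paste0(prefix, ".tsv")
  Biostrings::writeXStringSet(x@sequences, fa)
  write.table(as.data.frame(x@anno), tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(fasta = fa, annotation = tsv))
}

## constant-region primer sites planted in the toy constant segments;
## sequences as printed in the library-design primer tables shipped in
## inst/extdata/primers_igseq.tsv
toyPrimerSites <- function() {
  c(IGHG = "AGAGGTGCTCTTGGAG", IGHM = "GGGAATTCTCACAGGAG",
    IGKC = "CACACAACAGAGGCAG", IGLC = "CACCAGTGTGGCCTTG")
}

toyVSegment <- function(v_len) {
  n_cod <- v_len %/% 3L
  s <- randomCodons(n_cod)
  anchor_pos <- v_len - 12L               # 3 codons of V tail after the Cys
  ## plant the YYC motif: Tyr-Tyr at anchor-6..anchor-1, Cys at the anchor
  substr(s, anchor_pos - 5L, anchor_pos) <- paste0(
    sample(c("TAT", "TAC"), 1), sample(c("TAT", "TAC"), 1))
  substr(s, anchor_pos + 1L, anchor_pos + 3L) <- sample(c("TGT", "TGC"), 1)
  list(seq = s, anchor_pos = anchor_pos)
}

toyJSegment <- function(j_len, locus) {
  n_cod <- j_len %/% 3L
  s <- randomCodons(n_cod)
  anchor_pos <- 9L                        # 3 codons upstream of the anchor
  if (locus == "IGH") {
    substr(s, anchor_pos + 1L, anchor_pos + 6L) <-
      paste0("TGG", sample(c("GGA", "GGC", "GGT"), 1))          # W G
  } else {
    substr(s, anchor_pos + 1L, anchor_pos + 12L) <-
      paste0(sample(c("TTT", "TTC"), 1), "GGC",
             sample(STOP_FREE_CODONS, 1), "GGG")                # F G x G
  }
  list(seq = s, anchor_pos = anchor_pos)
}

## the primer site sits near the segment start: the RT-in primers are
## designed close to the J-C boundary so amplicon reads keep enough V
## context upstream of the junction
toyCSegment <- function(c_len, site) {
  s <- paste0(paste(sample(BASES, 4, replace = TRUE), collapse = ""), site)
  pad <- c_len - nchar(s)
  if (pad > 0)
    s <- paste0(s, paste(sample(BASES, pad, replace = TRUE), collapse = ""))
  s
}

#' Generate a synthetic germline reference set
#'
#' Emits a random germline set whose records satisfy every anchor
#' invariant by construction: V segments carry a planted YYC motif ending
#' in the conserved cysteine 12 nt before the segment end, heavy-chain J
#' segments a WG anchor and light-chain J segments an FGxG anchor at
#' position 9, and constant segments embed the constant-region RT primer
#' site of their isotype so that amplicon simulation can anneal to them.
#' V segments also carry IMGT-style CDR1 (codons 27-38) and CDR2 (codons
#' 56-65) boundary annotations. Deterministic for a given seed.
#'
#' @param locus_spec named list per locus with elements `v`, `j`, `c`
#'   (allele counts) and `v_len`, `j_len`, `c_len` (segment lengths,
#'   multiples of 3 for V/J); the default models IGH (IgG and IgM
#'   constant segments), IGK and IGL
#' @param seed integer seed
#' @param prefix optional path prefix; when given, FASTA + annotation TSV
#'   are written as by [writeGermline()]
#' @return a [GermlineSet-class] (with attribute `files` when `prefix`
#'   is given)
#' @examples
#' gl <- makeToyGermline(seed = 7)
#' alleleIds(gl, locus = "IGH", segment_class = "V")
#' @export
makeToyGermline <- function(locus_spec = NULL, seed = 1, prefix = NULL) {
  if (is.null(locus_spec))
    locus_spec <- list(
      IGH = list(v = 4L, j = 2L, c = 2L, v_len = 300L, j_len = 48L,
                 c_len = 100L),
      IGK = list(v = 3L, j = 2L, c = 1L, v_len = 300L, j_len = 48L,
                 c_len = 100L),
      IGL = list(v = 2L, j = 2L, c = 1L, v_len = 300L, j_len = 48L,
                 c_len = 100L))
  set.seed(as.integer(seed))
  rows <- list(); seqs <- character(0)
  sites <- toyPrimerSites()
  for (loc in names(locus_spec)) {
    sp <- locus_spec[[loc]]
    if (sp$v_len %% 3L != 0L || sp$v_len < 90L)
      stop("v_len must be a multiple of 3 and >= 90 (got ", sp$v_len,
           "): too short to host frame, CDRs and the YYC anchor")
    if (sp$j_len %% 3L != 0L || sp$j_len < 24L)
      stop("j_len must be a multiple of 3 and >= 24 (got ", sp$j_len, ")")
    min_c <- 4L + max(nchar(sites))
    if (sp$c_len < min_c)
      stop("c_len must be >= ", min_c, " to host the primer site")
    for (i in seq_len(sp$v)) {
      v <- toyVSegment(sp$v_len)
      id <- sprintf("%sV%d-%d*01", loc, i, (i %% 3L) + 1L)
      seqs[id] <- v$seq
      rows[[id]] <- data.frame(
        allele_id = id, locus = loc, segment_class = "V", frame = 0L,
        anchor_pos = v$anchor_pos, motif = "YYC",
        cdr1_start = 78L, cdr1_end = 114L,      # codons 27-38, 0-based nt
        cdr2_start = 165L, cdr2_end = 195L)     # codons 56-65
    }
    for (i in seq_len(sp$j)) {
      j <- toyJSegment(sp$j_len, loc)
      id <- sprintf("%sJ%d*01", loc, i)
      seqs[id] <- j$seq
      rows[[id]] <- data.frame(
        allele_id = id, locus = loc, segment_class = "J", frame = 0L,
        anchor_pos = j$anchor_pos,
        motif = if (loc == "IGH") "WG" else "FGxG",
        cdr1_start = NA_integer_, cdr1_end = NA_integer_,
        cdr2_start = NA_integer_, cdr2_end = NA_integer_)
    }
    iso <- if (loc == "IGH") c("IGHG", "IGHM")[seq_len(sp$c)] else
      paste0(substr(loc, 1, 3), "C")[seq_len(sp$c)]
    for (k in seq_len(sp$c)) {
      nm <- if (loc == "IGH") iso[k] else paste0(loc, "C")
      id <- paste0(nm, if (loc == "IGH" && iso[k] == "IGHG") "1" else "",
                   "*01")
      site <- sites[[if (loc == "IGH") iso[k] else paste0(loc, "C")]]
      seqs[id] <- toyCSegment(sp$c_len, site)
      rows[[id]] <- data.frame(
        allele_id = id, locus = loc, segment_class = "C", frame = 0L,
        anchor_pos = NA_integer_, motif = NA_character_,
        cdr1_start = NA_integer_, cdr1_end = NA_integer_,
        cdr2_start = NA_integer_, cdr2_end = NA_integer_)
    }
  }
  an <- do.call(rbind, rows)
  gs <- new("GermlineSet",
            sequences = Biostrings::DNAStringSet(seqs),
            anno = S4Vectors::DataFrame(an, row.names = an$allele_id))
  validObject(gs)
  if (!is.null(prefix)) {
    files <- writeGermline(gs, prefix)
    attr(gs, "files") <- files
  }
  gs
}

## anchor position and frame lookups used by simulator/caller
segmentField <- function(gs, id, field) {
  gs@anno[id, field]
}
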