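#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom Biostrings DNAStringSet
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

## ---------------------------------------------------------------------
## GermlineSet: germline V/J/C segment references with junction anchors
## ---------------------------------------------------------------------

#' GermlineSet: annotated germline segment references
#'
#' Holds germline V, J and C gene segments (as a
#' [Biostrings::DNAStringSet]) together with the annotation every
#' downstream stage relies on: locus, segment class, reading frame, the
#' 0-based position of the junction-anchor codon (the second conserved
#' cysteine for V segments; the conserved tryptophan for heavy-chain J,
#' phenylalanine for light-chain J), the anchor motif class, and -- for V
#' segments -- IMGT-style CDR1/CDR2 nucleotide boundaries used for
#' annotation by projection.
#'
#' Validity enforces the structural-guidepost invariants: the anchor codon
#' translates to C (V) or W/F (J) in the declared frame, heavy-chain J
#' anchors are followed by a WG dipeptide and light-chain J anchors start
#' an FGxG run, sequences are uppercase ACGT, and allele ids are unique.
#'
#' @slot sequences [Biostrings::DNAStringSet] named by allele id
#' @slot anno [S4Vectors::DataFrame] with columns `allele_id`, `locus`
#'   (IGH/IGK/IGL), `segment_class` (V/J/C), `frame` (0--2), `anchor_pos`
#'   (0-based first base of the anchor codon; `NA` for C segments),
#'   `motif`, and CDR boundary columns `cdr1_start`, `cdr1_end`,
#'   `cdr2_start`, `cdr2_end` (0-based half-open on the segment; `NA`
#'   except for V)
#' @exportClass GermlineSet
setClass("GermlineSet",
  slots = c(sequences = "DNAStringSet", anno = "DataFrame"))

validGermlineSet <- function(object) {
  msg <- character(0)
  an <- object@anno
  sq <- object@sequences
  need <- c("allele_id", "locus", "segment_class", "frame", "anchor_pos",
            "motif")
  if (!all(need %in% colnames(an)))
    return(paste("annotation missing columns:",
                 paste(setdiff(need, colnames(an)), collapse = ", ")))
  if (anyDuplicated(an$allele_id))
    msg <- c(msg, "duplicated allele_id values")
  if (!identical(names(sq), an$allele_id))
    msg <- c(msg, "sequence names do not match annotation allele_id order")
  if (!all(an$locus %in% c("IGH", "IGK", "IGL")))
    msg <- c(msg, "locus must be IGH, IGK or IGL")
  if (!all(an$segment_class %in% c("V", "J", "C")))
    msg <- c(msg, "segment_class must be V, J or C")
  seqs <- as.character(sq)
  if (any(grepl("[^ACGT]", seqs)))
    msg <- c(msg, "sequences must be uppercase ACGT only")
  for (i in seq_along(seqs)) {
    cls <- an$segment_class[i]
    if (cls == "C") next
    ap <- an$anchor_pos[i]
    fr <- an$frame[i]
    id <- an$allele_id[i]
    if (is.na(ap) || ap < 0 || ap + 3 > nchar(seqs[i])) {
      msg <- c(msg, sprintf("%s: anchor_pos out of bounds", id)); next
    }
    if ((ap - fr) %% 3 != 0)
      msg <- c(msg, sprintf("%s: anchor_pos not in declared frame", id))
    aa <- translateNt(substr(seqs[i], ap + 1, ap + 3))
    if (cls == "V" && aa != "C")
      msg <- c(msg, sprintf("%s: V anchor codon is %s, expected C", id, aa))
    if (cls == "J") {
      if (an$locus[i] == "IGH") {
        pep <- translateNt(substr(seqs[i], ap + 1, ap + 6))
        if (substr(pep, 1, 2) != "WG")
          msg <- c(msg, sprintf("%s: heavy J anchor must start WG (got %s)",
                                id, pep))
      } else {
        pep <- translateNt(substr(seqs[i], ap + 1, ap + 12))
        if (!grepl("^FG.G", pep))
          msg <- c(msg, sprintf("%s: light J anchor must start FGxG (got %s)",
                                id, pep))
      }
    }
  }
  ## every represented locus needs at least one V and one J
  for (loc in unique(an$locus)) {
    cls <- an$segment_class[an$locus == loc]
    if (!all(c("V", "J") %in% cls))
      msg <- c(msg, sprintf("locus %s lacks a V or J segment", loc))
  }
  if (length(msg)) msg else TRUE
}
setValidity("GermlineSet", validGermlineSet)

## ---------------------------------------------------------------------
## SimTruth: ground truth emitted beside every synthetic dataset
## ---------------------------------------------------------------------

#' SimTruth: ground truth for a synthetic repertoire dataset
#'
#' @slot clones [S4Vectors::DataFrame], one row per chain-level clone:
#'   `clone_id`, `locus`, `v_call`, `j_call`, `c_call`, `junction`
#'   (anchor-inclusive nucleotides), `frequency`, `transcript` (full
#'   mRNA-sense sequence), `v_start` (0-based offset of the germline V
#'   start on the transcript), and a list column `shm` of per-clone
#'   data.frames (`pos`, `ref`, `alt`, `region`, `silent`) with 0-based
#'   transcript positions of the planted hypermutations
#' @slot origins [S4Vectors::DataFrame] mapping every emitted read id to
#'   (`read_id`, `clone_id`, `start`, `strand`) on the clone transcript
#' @slot params list of generator parameters (rates, seed, ...)
#' @exportClass SimTruth
setClass("SimTruth",
  slots = c(clones = "DataFrame", origins = "DataFrame", params = "list"))

setValidity("SimTruth", function(object) {
  msg <- character(0)
  if (nrow(object@clones)) {
    f <- sum(object@clones$frequency)
    if (abs(f - 1) > 1e-9)
      msg <- c(msg, sprintf("clone frequencies sum to %.12f, not 1", f))
  }
  if (nrow(object@origins) && anyDuplicated(object@origins$read_id))
    msg <- c(msg, "duplicated read ids in origin map")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------
## RepertoireProfile: the three-layer clonality summary
## ---------------------------------------------------------------------

#' RepertoireProfile: three-layer clonality summary of a clonotype table
#'
#' Layers mirror the standard repertoire donut: an inner layer splitting
#' frequency mass by clonotype read count (singletons, doubletons, "3+"),
#' a middle layer splitting mass over five equal-size abundance-rank bins
#' of clonotypes (top 20% = Q1, ...), and an outer layer listing the five
#' most abundant clonotypes individually.
#'
#' @slot sample_id sample label
#' @slot chain_view one of "H", "L", "IGK", "IGL"
#' @slot inner named numeric: mass in count bins `1`, `2`, `3+`
#' @slot quantiles named numeric: mass in rank bins `Q1`..`Q5`
#' @slot top data.frame of the top clonotypes (`junction`, `v_call`,
#'   `j_call`, `count`, `frequency`), at most 5 rows
#' @slot n_clonotypes,n_reads sizes the profile was computed from
#' @exportClass RepertoireProfile
setClass("RepertoireProfile",
  slots = c(sample_id = "character", chain_view = "character",
            inner = "numeric", quantiles = "numeric", top = "data.frame",
            n_clonotypes = "integer", n_reads = "numeric"))

setValidity("RepertoireProfile", function(object) {
  msg <- character(0)
  if (abs(sum(object@inner) - 1) > 1e-9)
    msg <- c(msg, "inner layer masses must sum to 1")
  q <- object@quantiles
  if (abs(sum(q) - 1) > 1e-9)
    msg <- c(msg, "quantile layer masses must sum to 1")
  if (any(diff(q) > 1e-12))
    msg <- c(msg, "quantile masses must be non-increasing Q1 >= ... >= Q5")
  if (nrow(object@top) > 5)
    msg <- c(msg, "top layer holds at most 5 clonotypes")
  if (sum(object@top$frequency) > 1 + 1e-9)
    msg <- c(msg, "top layer frequencies exceed 1")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------
## AssembledChain: seed-and-extend reconstruction result
## ---------------------------------------------------------------------

#' AssembledChain: a CDR3-seeded full-length chain reconstruction
#'
#' @slot junction target junction (anchor-inclusive, coding strand)
#' @slot contig consensus contig nucleotides
#' @slot coverage integer per-contig-position read support
#' @slot agreement numeric per-position fraction of supporting reads that
#'   match the consensus base
#' @slot frame reading-frame offset of codon 1 on the contig (anchored at
#'   the junction cysteine)
#' @slot boundaries list: `junction_start`/`junction_end` (0-based
#'   half-open on the contig), `v_start_reached` (logical), `j_end`,
#'   `c_reached` (logical)
#' @slot reads ids of supporting reads
#' @slot termination one of `v_start_reached`, `no_overlap`,
#'   `ambiguous_branch`, `max_iterations` (the 5'-extension outcome)
#' @slot termination3 the 3'-extension outcome (`c_cap_reached`,
#'   `no_overlap`, `ambiguous_branch`, `max_iterations`)
#' @exportClass AssembledChain
setClass("AssembledChain",
  slots = c(junction = "character", contig = "character",
            coverage = "integer", agreement = "numeric", frame = "integer",
            boundaries = "list", reads = "character",
            termination = "character", termination3 = "character"))

setValidity("AssembledChain", function(object) {
  msg <- character(0)
  b <- object@boundaries
  js <- b$junction_start; je <- b$junction_end
  if (!is.null(js) &&
      substr(object@contig, js + 1, je) != object@junction)
    msg <- c(msg, "junction does not occur at the recorded contig interval")
  if (length(object@coverage) != nchar(object@contig))
    msg <- c(msg, "coverage length must equal contig length")
  if (length(object@coverage) && any(object@coverage < 1))
    msg <- c(msg, "coverage must be >= 1 everywhere")
  if (!object@termination %in%
      c("v_start_reached", "no_overlap", "ambiguous_branch",
        "max_iterations"))
    msg <- c(msg, "unknown termination reason")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------
## ChainAnnotation: germline comparison of an assembled chain
## ---------------------------------------------------------------------

#' ChainAnnotation: germline annotation of an assembled chain
#'
#' @slot v_call,j_call best germline allele assignments
#' @slot v_identity,j_identity alignment identities of those assignments
#' @slot cdr list of 0-based half-open contig intervals for CDR1, CDR2,
#'   CDR3 (CDR3 = junction minus its two anchor codons)
#' @slot shm data.frame of amino-acid-changing hypermutations: `codon`
#'   (1-based on the variable region), `germline_aa`, `observed_aa`,
#'   `germline_codon`, `observed_codon`, `region`
#' @slot shm_count_nt,shm_count_aa total nucleotide / amino-acid-changing
#'   mutation counts outside the junction
#' @slot silent_nt data.frame of silent nucleotide differences
#' @slot isotype one of IgG, IgM, IgA, IgK, IgL, unknown
#' @slot isotype_support fraction of evidence supporting the isotype call
#' @slot productive junction in frame, anchors intact, no stop codon
#' @exportClass ChainAnnotation
setClass("ChainAnnotation",
  slots = c(v_call = "character", j_call = "character",
            v_identity = "numeric", j_identity = "numeric", cdr = "list",
            shm = "data.frame", shm_count_nt = "integer",
            shm_count_aa = "integer", silent_nt = "data.frame",
            isotype = "character", isotype_support = "numeric",
            productive = "logical"))
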