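#' @useDynLib IgRescue, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats rbinom runif rlnorm setNames quantile
#' @importFrom utils read.delim write.table head modifyList
NULL

BASES <- c("A", "C", "G", "T")

## locus -> chain view ("H" or "L") used throughout
chainOf <- function(locus) ifelse(locus == "IGH", "H", "L")

#' Reverse complement of plain character DNA
#' @param x character vector of ACGTN strings
#' @return character vector
#' @keywords internal
revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## standard genetic code as a plain lookup, taken from Biostrings once
## at load time (repeated Biostrings::translate() calls on tiny strings
## dominate runtime otherwise)
CODON_TABLE <- Biostrings::GENETIC_CODE

#' Translate in-frame DNA to amino acids
#'
#' Incomplete trailing codons are dropped; stops are rendered as `*`,
#' codons with ambiguity characters as `X`.
#' @param x character vector of DNA strings (frame 0)
#' @return character vector of peptides
#' @keywords internal
translateNt <- function(x) {
  vapply(x, function(s) {
    n <- nchar(s) - nchar(s) %% 3L
    if (is.na(n) || n < 3L) return("")
    starts <- seq.int(1L, n, 3L)
    aa <- CODON_TABLE[substring(s, starts, starts + 2L)]
    aa[is.na(aa)] <- "X"
    paste(aa, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

## deterministic child seed per named stage, derived from one master seed
childSeed <- function(seed, stage) {
  offs <- c(germline = 11L, repertoire = 23L, fragments = 37L,
            igseq = 53L, rnaseq = 71L, misc = 97L)
  if (!stage %in% names(offs)) offs <- c(offs, setNames(131L, stage))
  (as.integer(seed) * 1009L + offs[[stage]]) %% 2147483647L
}

randomDna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(BASES, len, replace = TRUE), collapse = ""), character(1))
}

## substitution errors, i.i.d. over positions, uniform over the 3 alternatives
mutateBases <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0) return(seqs)
  vapply(seqs, function(s) {
    b <- strsplit(s, "", fixed = TRUE)[[1]]
    hit <- which(runif(length(b)) < rate)
    for (i in hit) b[i] <- sample(setdiff(BASES, b[i]), 1)
    paste(b, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Write sequences as FASTQ
#' @param seqs,ids character vectors of equal length
#' @param path output file
#' @param qual_char constant quality character (default "I", Q40)
#' @return invisibly, `path`
#' @export
writeFastq <- function(seqs, ids, path, qual_char = "I") {
  stopifnot(length(seqs) == length(ids))
  qual <- vapply(nchar(seqs), function(n)
    paste(rep(qual_char, n), collapse = ""), character(1))
  writeLines(paste0("@", ids, "\n", seqs, "\n+\n", qual), path)
  invisible(path)
}

#' Read a FASTQ file into a named character vector
#'
#' Accepts plain or gzipped files; sequence and quality lines must not wrap
#' (4-line records, the form every read simulator and sequencer emits).
#' @param path FASTQ file
#' @return named character vector (names = read ids)
#' @export
readFastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

## JSON helpers ---------------------------------------------------------
writeJson <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
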