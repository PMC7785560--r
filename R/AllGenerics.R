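## Generics, accessors and show methods for the package classes.

#' @rdname GermlineSet-class
#' @param object,x a `GermlineSet`
#' @export
setGeneric("alleleIds", function(x, ...) standardGeneric("alleleIds"))

#' @rdname GermlineSet-class
#' @param locus optional locus filter (IGH/IGK/IGL)
#' @param segment_class optional class filter (V/J/C)
#' @param ... unused
#' @export
setMethod("alleleIds", "GermlineSet", function(x, locus = NULL,
                                               segment_class = NULL, ...) {
  an <- x@anno
  keep <- rep(TRUE, nrow(an))
  if (!is.null(locus)) keep <- keep & an$locus %in% locus
  if (!is.null(segment_class)) keep <- keep & an$segment_class %in% segment_class
  an$allele_id[keep]
})

#' @rdname GermlineSet-class
#' @export
setGeneric("segmentAnno", function(x, ...) standardGeneric("segmentAnno"))

#' @rdname GermlineSet-class
#' @export
setMethod("segmentAnno", "GermlineSet", function(x, ...) x@anno)

#' @rdname GermlineSet-class
#' @export
setGeneric("segmentSeq", function(x, id) standardGeneric("segmentSeq"))

#' @rdname GermlineSet-class
#' @param id allele id(s)
#' @export
setMethod("segmentSeq", "GermlineSet", function(x, id) {
  if (!all(id %in% names(x@sequences)))
    stop("unknown allele id(s): ",
         paste(setdiff(id, names(x@sequences)), collapse = ", "))
  setNames(as.character(x@sequences[id]), id)
})

#' @rdname GermlineSet-class
#' @export
setMethod("show", "GermlineSet", function(object) {
  an <- object@anno
  cat("GermlineSet with", nrow(an), "segments\n")
  tab <- table(an$locus, an$segment_class)
  print(tab)
  invisible(NULL)
})

#' @rdname SimTruth-class
#' @param x,object a `SimTruth`
#' @param ... unused
#' @export
setGeneric("truthClones", function(x, ...) standardGeneric("truthClones"))

#' @rdname SimTruth-class
#' @export
setMethod("truthClones", "SimTruth", function(x, ...) x@clones)

#' @rdname SimTruth-class
#' @export
setGeneric("readOrigins", function(x, ...) standardGeneric("readOrigins"))

#' @rdname SimTruth-class
#' @export
setMethod("readOrigins", "SimTruth", function(x, ...) x@origins)

#' @rdname SimTruth-class
#' @export
setMethod("show", "SimTruth", function(object) {
  cat("SimTruth:", nrow(object@clones), "chain clones,",
      nrow(object@origins), "read origins\n")
  if (nrow(object@clones)) {
    top <- which.max(object@clones$frequency)
    cat(sprintf("  dominant: %s (%s, f = %.3f)\n",
                object@clones$clone_id[top], object@clones$locus[top],
                object@clones$frequency[top]))
  }
  invisible(NULL)
})

#' @rdname RepertoireProfile-class
#' @param x,object a `RepertoireProfile`
#' @param ... unused
#' @export
setGeneric("innerLayer", function(x, ...) standardGeneric("innerLayer"))
#' @rdname RepertoireProfile-class
#' @export
setMethod("innerLayer", "RepertoireProfile", function(x, ...) x@inner)

#' @rdname RepertoireProfile-class
#' @export
setGeneric("quantileLayer", function(x, ...) standardGeneric("quantileLayer"))
#' @rdname RepertoireProfile-class
#' @export
setMethod("quantileLayer", "RepertoireProfile", function(x, ...) x@quantiles)

#' @rdname RepertoireProfile-class
#' @export
setGeneric("topClonotypes", function(x, ...) standardGeneric("topClonotypes"))
#' @rdname RepertoireProfile-class
#' @export
setMethod("topClonotypes", "RepertoireProfile", function(x, ...) x@top)

#' @rdname RepertoireProfile-class
#' @export
setMethod("show", "RepertoireProfile", function(object) {
  cat(sprintf("RepertoireProfile [%s, view %s]: %d clonotypes, %g reads\n",
              object@sample_id, object@chain_view, object@n_clonotypes,
              object@n_reads))
  cat("  inner (count bins):",
      paste(sprintf("%s=%.3f", names(object@inner), object@inner),
            collapse = " "), "\n")
  cat("  quantiles:",
      paste(sprintf("%s=%.3f", names(object@quantiles), object@quantiles),
            collapse = " "), "\n")
  cat(sprintf("  top clonotype: %s (f = %.3f)\n",
              object@top$junction[1], object@top$frequency[1]))
  invisible(NULL)
})

#' @rdname AssembledChain-class
#' @param x,object an `AssembledChain`
#' @param ... unused
#' @export
setGeneric("contigSeq", function(x, ...) standardGeneric("contigSeq"))
#' @rdname AssembledChain-class
#' @export
setMethod("contigSeq", "AssembledChain", function(x, ...) x@contig)

#' @rdname AssembledChain-class
#' @export
setGeneric("contigCoverage", function(x, ...) standardGeneric("contigCoverage"))
#' @rdname AssembledChain-class
#' @export
setMethod("contigCoverage", "AssembledChain", function(x, ...)
  data.frame(pos = seq_len(nchar(x@contig)) - 1L,
             base = strsplit(x@contig, "")[[1]],
             coverage = x@coverage, agreement = x@agreement))

#' @rdname AssembledChain-class
#' @export
setGeneric("terminationReason", function(x, ...)
  standardGeneric("terminationReason"))
#' @rdname AssembledChain-class
#' @export
setMethod("terminationReason", "AssembledChain", function(x, ...)
  x@termination)

#' @rdname AssembledChain-class
#' @export
setGeneric("junctionRange", function(x, ...) standardGeneric("junctionRange"))
#' @rdname AssembledChain-class
#' @export
setMethod("junctionRange", "AssembledChain", function(x, ...)
  c(start = x@boundaries$junction_start, end = x@boundaries$junction_end))

#' @rdname AssembledChain-class
#' @export
setMethod("show", "AssembledChain", function(object) {
  cat(sprintf("AssembledChain: %d nt contig, junction at [%d, %d)\n",
              nchar(object@contig), object@boundaries$junction_start,
              object@boundaries$junction_end))
  cat(sprintf("  5' termination: %s; 3' termination: %s\n",
              object@termination, object@termination3))
  cat(sprintf("  coverage: median %d (range %d-%d)\n",
              as.integer(stats::median(object@coverage)),
              min(object@coverage), max(object@coverage)))
  invisible(NULL)
})

#' @rdname ChainAnnotation-class
#' @param x,object a `ChainAnnotation`
#' @param ... unused
#' @export
setGeneric("shmTable", function(x, ...) standardGeneric("shmTable"))
#' @rdname ChainAnnotation-class
#' @export
setMethod("shmTable", "ChainAnnotation", function(x, ...) x@shm)

#' @rdname ChainAnnotation-class
#' @export
setGeneric("isotype", function(x, ...) standardGeneric("isotype"))
#' @rdname ChainAnnotation-class
#' @export
setMethod("isotype", "ChainAnnotation", function(x, ...) x@isotype)

#' @rdname ChainAnnotation-class
#' @export
setMethod("show", "ChainAnnotation", function(object) {
  cat(sprintf("ChainAnnotation: %s / %s (identity %.3f / %.3f)\n",
              object@v_call, object@j_call, object@v_identity,
              object@j_identity))
  cat(sprintf("  SHM: %d nt (%d aa-changing, %d silent); isotype %s; %s\n",
              object@shm_count_nt, object@shm_count_aa,
              nrow(object@silent_nt), object@isotype,
              if (object@productive) "productive" else "non-productive"))
  invisible(NULL)
})
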