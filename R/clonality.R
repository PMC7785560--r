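## Three-layer clonality profiling and cross-sample clonotype tracking.

#' Profile repertoire clonality in three layers
#'
#' Computes the three-layer summary drawn as a donut in repertoire
#' reports: an inner layer with the frequency mass of clonotypes seen
#' once, twice, and three or more times ("3+"); a middle layer with the
#' mass of the top 20% ("Q1"), next 20% ("Q2") and further 20% (Q3, Q4,
#' Q5) of clonotypes ranked by abundance (a partition by clonotype rank,
#' equal numbers of clonotypes per bin, remainder clonotypes going to
#' the earlier bins); and an outer layer with the individual frequencies
#' of the top 5 clonotypes. Ranking ties are broken by junction sequence
#' so the profile is deterministic and invariant to row order.
#'
#' @param table clonotype table from [buildClonotypeTable()]
#' @param sample_id sample label
#' @param chain_view `"H"`, `"L"`, `"IGK"` or `"IGL"`
#' @param productive_only restrict to productive clonotypes
#' @return a [RepertoireProfile-class]
#' @examples
#' tab <- data.frame(locus = "IGH", chain = "H", v_call = "V", j_call = "J",
#'                   junction = c("AAA", "CCC", "GGG", "TTT", "ACG"),
#'                   consensus_count = c(60, 10, 10, 10, 10),
#'                   productive = TRUE)
#' quantileLayer(profileRepertoire(tab, "toy", "H"))
#' @export
profileRepertoire <- function(table, sample_id, chain_view = "H",
                              productive_only = TRUE) {
  sel <- switch(chain_view,
                H = table$chain == "H",
                L = table$chain == "L",
                IGK = table$locus == "IGK",
                IGL = table$locus == "IGL",
                stop("unknown chain view: ", chain_view))
  if (productive_only && "productive" %in% colnames(table))
    sel <- sel & table$productive
  tab <- table[sel, , drop = FALSE]
  if (!nrow(tab))
    stop("no clonotypes in view '", chain_view, "' for sample ", sample_id)
  cnt <- tab$consensus_count
  total <- sum(cnt)
  freq <- cnt / total
  inner <- c(`1` = sum(freq[cnt == 1]), `2` = sum(freq[cnt == 2]),
             `3+` = sum(freq[cnt >= 3]))
  ## rank by abundance, ties by junction; split ranks into 5 bins with
  ## remainder clonotypes assigned to the earlier quantiles
  ord <- order(-cnt, tab$junction)
  n <- length(ord)
  base <- n %/% 5L; rem <- n %% 5L
  sizes <- rep(base, 5L) + c(rep(1L, rem), rep(0L, 5L - rem))
  bin <- rep(seq_len(5L), sizes)
  q <- vapply(seq_len(5L), function(b) sum(freq[ord][bin == b]),
              numeric(1))
  names(q) <- paste0("Q", 1:5)
  topn <- head(ord, 5L)
  top <- data.frame(junction = tab$junction[topn],
                    v_call = tab$v_call[topn], j_call = tab$j_call[topn],
                    count = cnt[topn], frequency = freq[topn])
  new("RepertoireProfile", sample_id = sample_id, chain_view = chain_view,
      inner = inner, quantiles = q, top = top,
      n_clonotypes = as.integer(n), n_reads = as.numeric(total))
}

#' Serialize a profile to a plain list / JSON
#' @param profile a [RepertoireProfile-class]
#' @param path optional JSON output path
#' @return the list, invisibly when writing
#' @export
profileAsList <- function(profile, path = NULL) {
  x <- list(sample_id = profile@sample_id, chain_view = profile@chain_view,
            n_clonotypes = profile@n_clonotypes, n_reads = profile@n_reads,
            inner = as.list(profile@inner),
            quantiles = as.list(profile@quantiles),
            top = profile@top)
  if (!is.null(path)) { writeJson(x, path); return(invisible(x)) }
  x
}

#' Track clonotypes across samples
#'
#' Builds a per-sample frequency matrix over every clonotype present in
#' any sample (key: locus, V, J, junction), with zero where a clonotype
#' is absent, and flags clonotypes that are rank 1 in at least one
#' sample -- the cross-block consistency check behind calling one chain
#' "dominant everywhere".
#'
#' @param tables named list (>= 2) of clonotype tables
#' @param chain_view optional view filter as in [profileRepertoire()]
#' @return data.frame: key columns, one frequency column per sample,
#'   `rank1_in` (comma-separated samples where rank 1, "" otherwise)
#' @export
crossSampleTracking <- function(tables, chain_view = NULL) {
  if (length(tables) < 2) stop("need at least 2 samples")
  if (is.null(names(tables)) || any(names(tables) == ""))
    names(tables) <- paste0("sample", seq_along(tables))
  if (!is.null(chain_view))
    tables <- lapply(tables, function(t)
      t[switch(chain_view, H = t$chain == "H", L = t$chain == "L",
               IGK = t$locus == "IGK", IGL = t$locus == "IGL"), ,
        drop = FALSE])
  keyOf <- function(t) paste(t$locus, t$v_call, t$j_call, t$junction,
                             sep = "|")
  keys <- unique(unlist(lapply(tables, keyOf)))
  out <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
  out <- data.frame(locus = out[, 1], v_call = out[, 2],
                    j_call = out[, 3], junction = out[, 4])
  rank1 <- rep("", length(keys))
  for (s in names(tables)) {
    t <- tables[[s]]
    k <- keyOf(t)
    f <- t$consensus_count / sum(t$consensus_count)
    out[[s]] <- f[match(keys, k)]
    out[[s]][is.na(out[[s]])] <- 0
    top <- k[order(-t$consensus_count, t$junction)][1]
    hit <- keys == top
    rank1[hit] <- ifelse(rank1[hit] == "", s, paste(rank1[hit], s,
                                                    sep = ","))
  }
  out$rank1_in <- rank1
  out[order(-rowMeans(out[names(tables)])), , drop = FALSE]
}

#' Plot a three-layer clonality donut
#'
#' Optional reporting layer: renders the numerical profile (the
#' contract) as the familiar three-ring donut. Base graphics; write to
#' SVG by passing `file`.
#'
#' @param profile a [RepertoireProfile-class]
#' @param file optional `.svg` output path
#' @return invisibly `NULL`
#' @export
plotClonality <- function(profile, file = NULL) {
  if (!is.null(file)) grDevices::svg(file, width = 5, height = 5)
  op <- graphics::par(mar = c(1, 1, 2, 1))
  on.exit({ graphics::par(op); if (!is.null(file)) grDevices::dev.off() })
  ring <- function(fracs, r0, r1, cols, labels = NULL) {
    a0 <- c(0, cumsum(fracs)) * 2 * pi
    for (i in seq_along(fracs)) {
      th <- seq(a0[i], a0[i + 1], length.out = 64)
      graphics::polygon(c(r0 * cos(th), rev(r1 * cos(th))),
                        c(r0 * sin(th), rev(r1 * sin(th))),
                        col = cols[(i - 1) %% length(cols) + 1],
                        border = "white")
      if (!is.null(labels) && fracs[i] > 0.04) {
        mid <- (a0[i] + a0[i + 1]) / 2; rm <- (r0 + r1) / 2
        graphics::text(rm * cos(mid), rm * sin(mid), labels[i], cex = 0.6)
      }
    }
  }
  graphics::plot.new()
  graphics::plot.window(c(-1.1, 1.1), c(-1.1, 1.1), asp = 1)
  inner <- profile@inner
  q <- profile@quantiles
  top <- profile@top$frequency
  rest <- max(0, 1 - sum(top))
  ring(inner, 0.25, 0.5, c("#cccccc", "#9ecae1", "#3182bd"), names(inner))
  ring(q, 0.55, 0.8, c("#de2d26", "#fc9272", "#fcbba1", "#fee5d9",
                       "#fff5f0"), names(q))
  ring(c(top, rest), 0.85, 1.05,
       c("#54278f", "#756bb1", "#9e9ac8", "#bcbddc", "#dadaeb", "#f2f0f7"))
  graphics::title(sprintf("%s  [%s]", profile@sample_id,
                          profile@chain_view))
  invisible(NULL)
}
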