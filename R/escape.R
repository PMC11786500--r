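## Single-cell biallelic XCI-escape calling and gene annotation.
##
## The escape criterion is operational: a position observed in exactly one
## cell (one barcode) where BOTH phased alleles have sufficient
## UMI-collapsed support and the read coverage is in range is evidence of
## biallelic expression within that single cell, i.e. expression from the
## inactive X.

empty_escape_calls <- function() {
  data.frame(pos = integer(0), cell_barcode = character(0),
             x1 = integer(0), x2 = integer(0),
             barcoding_frequency = integer(0), genes = character(0),
             known_escape = logical(0), stringsAsFactors = FALSE)
}

#' Call candidate XCI-escape positions
#'
#' Retains positions seen in exactly one cell (`n_barcodes == 1`) with at
#' least `allele_min` UMI-collapsed molecules supporting *each* haplotype
#' and `barcoding_frequency` within `[freq_min, freq_max]` (all bounds
#' inclusive). Because only one barcode underlies the call, the per-cell
#' and per-position allele counts coincide.
#'
#' @param summaries per-position summaries from [summarize_positions()].
#' @param thresholds an [filter_thresholds()] object; `barcode_min/max`
#'   are not used here (the barcode count is pinned to 1).
#' @return a `data.frame` with columns `pos`, `cell_barcode`, `x1`, `x2`,
#'   `barcoding_frequency`, `genes` (empty until [map_to_genes()]),
#'   `known_escape` (`NA` until cross-referenced).
#' @export
call_escape <- function(summaries, thresholds = filter_thresholds()) {
  stopifnot(inherits(thresholds, "xci_thresholds"))
  keep <- summaries$n_barcodes == 1L &
    summaries$x1 >= thresholds$allele_min &
    summaries$x2 >= thresholds$allele_min &
    summaries$barcoding_frequency >= thresholds$freq_min &
    summaries$barcoding_frequency <= thresholds$freq_max
  hit <- summaries[keep, , drop = FALSE]
  if (nrow(hit) == 0L) return(empty_escape_calls())
  barcode <- if ("per_barcode" %in% names(hit)) {
    vapply(hit$per_barcode, function(pb) pb$cell_barcode[1L], character(1))
  } else {
    rep(NA_character_, nrow(hit))
  }
  data.frame(pos = hit$pos, cell_barcode = barcode, x1 = hit$x1, x2 = hit$x2,
             barcoding_frequency = hit$barcoding_frequency,
             genes = "", known_escape = NA, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Annotate escape calls with overlapping genes
#'
#' Assigns to each call every gene whose BED interval `[start, end)`
#' (0-based half-open) contains the call's 1-based position, i.e. contains
#' `pos - 1` in 0-based coordinates. Calls are never added or removed, only
#' annotated; positions with no overlapping gene keep an empty `genes`
#' field and are counted.
#'
#' @param calls escape calls from [call_escape()].
#' @param annotations gene annotations from [read_gene_bed()].
#' @param chrom chromosome the calls live on; annotations on other
#'   chromosomes are ignored. Default `"chrX"`.
#' @return `calls` with `genes` populated (semicolon-joined symbols) and an
#'   `"n_unmapped"` attribute counting calls with no overlapping gene.
#' @export
map_to_genes <- function(calls, annotations, chrom = "chrX") {
  ann <- annotations[annotations$chrom == chrom, , drop = FALSE]
  if (nrow(calls) == 0L) {
    attr(calls, "n_unmapped") <- 0L
    return(calls)
  }
  genes <- rep("", nrow(calls))
  if (nrow(ann) > 0L) {
    ## BED [start, end) contains pos-1  <=>  1-based [start+1, end] contains pos
    query <- IRanges::IRanges(start = calls$pos, width = 1L)
    subject <- IRanges::IRanges(start = ann$start + 1L, end = ann$end)
    hits <- IRanges::findOverlaps(query, subject)
    if (length(hits) > 0L) {
      by_call <- split(ann$gene[S4Vectors::subjectHits(hits)],
                       S4Vectors::queryHits(hits))
      for (k in names(by_call)) {
        genes[as.integer(k)] <- paste(sort(unique(by_call[[k]])),
                                      collapse = ";")
      }
    }
  }
  calls$genes <- genes
  attr(calls, "n_unmapped") <- sum(!nzchar(genes))
  calls
}

#' Cross-reference gene symbols against a known-escape list
#'
#' @param genes character vector of gene symbols (duplicates collapsed).
#' @param known character vector of previously reported escape genes.
#' @return a `data.frame` with columns `gene` and `known_flag` (logical),
#'   one row per distinct input gene, sorted alphabetically; attribute
#'   `"n_known"`/`"n_novel"` carry the flag tallies.
#' @export
cross_reference <- function(genes, known) {
  genes <- sort(unique(genes[nzchar(genes)]))
  out <- data.frame(gene = genes, known_flag = genes %in% known,
                    stringsAsFactors = FALSE)
  attr(out, "n_known") <- sum(out$known_flag)
  attr(out, "n_novel") <- sum(!out$known_flag)
  out
}

#' Expand semicolon-joined gene annotations to one symbol per row
#'
#' Convenience for turning annotated escape calls into a per-gene table.
#'
#' @param calls annotated escape calls (after [map_to_genes()]).
#' @return character vector of gene symbols, one entry per (call, gene)
#'   pair.
#' @export
escape_gene_symbols <- function(calls) {
  unlist(strsplit(calls$genes[nzchar(calls$genes)], ";", fixed = TRUE),
         use.names = FALSE)
}
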