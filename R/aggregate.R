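## UMI-level collapse of per-read records and per-position aggregation into
## the quantities the skewing analysis consumes: X1/X2 UMI counts,
## barcoding frequency (raw read coverage), and distinct barcode count,
## plus the filter funnel applied before skewing is assessed.

empty_umi_observations <- function() {
  data.frame(pos = integer(0), cell_barcode = character(0),
             umi = character(0), haplotype = character(0),
             read_support = integer(0), stringsAsFactors = FALSE)
}

empty_position_summaries <- function() {
  out <- data.frame(pos = integer(0), x1 = integer(0), x2 = integer(0),
                    barcoding_frequency = integer(0), n_barcodes = integer(0),
                    stringsAsFactors = FALSE)
  out$per_barcode <- list()
  out
}

#' Collapse per-read records to UMI-level allele observations
#'
#' Groups reads by (position, cell barcode, UMI). A group whose reads
#' unanimously support one haplotype yields a single molecule-level
#' observation with `read_support` equal to the group size; groups whose
#' reads disagree on the haplotype are discarded (they cannot provide
#' unambiguous allele support) and counted in a conflict report.
#'
#' @param records phased read records (see [read_phased_table()]).
#' @return a `data.frame` with columns `pos`, `cell_barcode`, `umi`,
#'   `haplotype`, `read_support`, ordered by position, barcode, UMI.
#'   Attribute `"n_conflicts"` carries the number of discarded UMI groups
#'   and `"conflicts"` their keys.
#' @export
collapse_umis <- function(records) {
  if (nrow(records) == 0L) {
    out <- empty_umi_observations()
    attr(out, "n_conflicts") <- 0L
    attr(out, "conflicts") <- out[, c("pos", "cell_barcode", "umi", "read_support")]
    return(out)
  }
  dt <- data.table::as.data.table(records)
  grp <- dt[, .(read_support = .N,
                n_hap = data.table::uniqueN(haplotype),
                haplotype = haplotype[1L]),
            by = .(pos, cell_barcode, umi)]
  conflicts <- grp[n_hap > 1L, .(pos, cell_barcode, umi, read_support)]
  obs <- grp[n_hap == 1L, .(pos, cell_barcode, umi, haplotype, read_support)]
  data.table::setorder(obs, pos, cell_barcode, umi)
  out <- data.table::setDF(obs)
  attr(out, "n_conflicts") <- nrow(conflicts)
  attr(out, "conflicts") <- data.table::setDF(conflicts)
  out
}

#' Aggregate phased reads into per-position summaries
#'
#' Produces one row per distinct position with the four quantities the
#' skewing and escape analyses are built on:
#' * `x1`, `x2` — UMI-collapsed molecule counts supporting each phased
#'   haplotype (conflicting UMI groups contribute to neither);
#' * `barcoding_frequency` — the raw read count at the position across all
#'   barcodes, a coverage measure that keeps reads inside conflicting UMI
#'   groups;
#' * `n_barcodes` — the number of distinct cell barcodes with at least one
#'   read at the position.
#'
#' The read > UMI > cell hierarchy is deliberate: coverage is measured in
#' reads, allele support in deduplicated molecules, breadth in cells.
#'
#' @param records phased read records.
#' @return a `data.frame` ordered by position with columns `pos`, `x1`,
#'   `x2`, `barcoding_frequency`, `n_barcodes`, and a list column
#'   `per_barcode` whose elements are data frames (`cell_barcode`, `x1`,
#'   `x2`) of per-cell UMI counts (cells whose UMIs all conflicted appear
#'   with zero counts).
#' @export
summarize_positions <- function(records) {
  if (nrow(records) == 0L) return(empty_position_summaries())
  dt <- data.table::as.data.table(records)
  coverage <- dt[, .(barcoding_frequency = .N,
                     n_barcodes = data.table::uniqueN(cell_barcode)),
                 by = pos]

  obs <- data.table::as.data.table(collapse_umis(records))
  cells <- unique(dt[, .(pos, cell_barcode)])
  if (nrow(obs) > 0L) {
    cell_counts <- obs[, .(x1 = sum(haplotype == "H1"),
                           x2 = sum(haplotype == "H2")),
                       by = .(pos, cell_barcode)]
    cells <- merge(cells, cell_counts, by = c("pos", "cell_barcode"),
                   all.x = TRUE)
    cells[is.na(x1), x1 := 0L]
    cells[is.na(x2), x2 := 0L]
  } else {
    cells[, `:=`(x1 = 0L, x2 = 0L)]
  }
  data.table::setorder(cells, pos, cell_barcode)
  per_cell <- cells[, .(x1 = sum(x1), x2 = sum(x2),
                        per_barcode = list(data.frame(
                          cell_barcode = cell_barcode,
                          x1 = x1, x2 = x2,
                          stringsAsFactors = FALSE))),
                    by = pos]

  res <- merge(coverage, per_cell, by = "pos")
  data.table::setorder(res, pos)
  data.table::setcolorder(res, c("pos", "x1", "x2", "barcoding_frequency",
                                 "n_barcodes", "per_barcode"))
  data.table::setDF(res)
}

#' Filter thresholds for the skewing/escape funnel
#'
#' Bundles the coverage and support thresholds applied before a position
#' enters the skewing analysis. All comparisons downstream are inclusive at
#' both ends, so the defaults admit a position with barcoding frequency
#' exactly 10 or 1000, 3 or 30 barcodes, and exactly 3 molecules per
#' allele.
#'
#' @param freq_min,freq_max admissible range of `barcoding_frequency`
#'   (reads at the position); defaults 10 and 1000.
#' @param barcode_min,barcode_max admissible range of distinct cell
#'   barcodes; defaults 3 and 30.
#' @param allele_min minimum UMI-collapsed count required of *each* allele;
#'   default 3.
#' @return an object of class `xci_thresholds` (a named list).
#' @export
filter_thresholds <- function(freq_min = 10L, freq_max = 1000L,
                              barcode_min = 3L, barcode_max = 30L,
                              allele_min = 3L) {
  t <- list(freq_min = as.integer(freq_min), freq_max = as.integer(freq_max),
            barcode_min = as.integer(barcode_min),
            barcode_max = as.integer(barcode_max),
            allele_min = as.integer(allele_min))
  if (anyNA(unlist(t))) stop("thresholds must be integer-valued", call. = FALSE)
  if (t$freq_min > t$freq_max) stop("freq_min > freq_max", call. = FALSE)
  if (t$barcode_min > t$barcode_max) stop("barcode_min > barcode_max", call. = FALSE)
  if (t$allele_min < 1L) stop("allele_min must be >= 1", call. = FALSE)
  structure(t, class = "xci_thresholds")
}

#' Apply the skewing filter funnel to position summaries
#'
#' Retains exactly the positions with
#' `freq_min <= barcoding_frequency <= freq_max`,
#' `barcode_min <= n_barcodes <= barcode_max`, and at least `allele_min`
#' UMI-collapsed molecules supporting *each* allele. All bounds inclusive;
#' input order preserved.
#'
#' @param summaries output of [summarize_positions()].
#' @param thresholds an [filter_thresholds()] object.
#' @return the retained subset of `summaries`.
#' @export
filter_for_skewing <- function(summaries, thresholds = filter_thresholds()) {
  stopifnot(inherits(thresholds, "xci_thresholds"))
  keep <- summaries$barcoding_frequency >= thresholds$freq_min &
    summaries$barcoding_frequency <= thresholds$freq_max &
    summaries$n_barcodes >= thresholds$barcode_min &
    summaries$n_barcodes <= thresholds$barcode_max &
    summaries$x1 >= thresholds$allele_min &
    summaries$x2 >= thresholds$allele_min
  out <- summaries[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tally the filter funnel
#'
#' Reports the counts a filtering strategy diagram is built from: total
#' input reads, distinct cell barcodes, candidate heterozygous positions,
#' and positions retained after filtering.
#'
#' @param records the raw phased read records.
#' @param summaries per-position summaries over those records.
#' @param filtered the post-filter subset of `summaries`.
#' @return a named list with `total_reads`, `n_barcodes`,
#'   `candidate_positions`, `retained_positions`.
#' @export
funnel_report <- function(records, summaries, filtered) {
  list(total_reads = nrow(records),
       n_barcodes = length(unique(records$cell_barcode)),
       candidate_positions = nrow(summaries),
       retained_positions = nrow(filtered))
}
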