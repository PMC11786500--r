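## End-to-end runners that read inputs, apply one analysis stage, and write
## its outputs (TSV/JSON) plus a manifest into a run directory. These are
## the programmatic equivalents of a command-line front end; the thin
## script in inst/scripts/xciskew wraps them for shell use.

write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  path
}

write_tsv <- function(df, path) {
  df <- df[, !vapply(df, is.list, logical(1)), drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_manifest <- function(out_dir, stage, files, params = list()) {
  files <- stats::setNames(as.list(basename(unlist(files))), names(files))
  write_json(list(stage = stage, files = files, parameters = params),
             file.path(out_dir, "manifest.json"))
}

#' Run the skewing analysis on one sample
#'
#' Reads a phased table, aggregates to position summaries, applies the
#' filter funnel, classifies skewing, and writes: `summaries.tsv`,
#' `skew_calls.tsv`, `category_distribution.json`, `skew_summary.tsv`
#' (descriptive statistics), `funnel.json`, and `manifest.json`.
#'
#' @param phased_path path to the per-read phased table.
#' @param out_dir output directory (created if needed).
#' @param thresholds an [filter_thresholds()] object.
#' @param sd_type passed to [skewing_summary_table()].
#' @return invisibly, a list with the in-memory results (`summaries`,
#'   `filtered`, `calls`, `distribution`, `funnel`) and output `paths`.
#' @export
run_skew <- function(phased_path, out_dir,
                     thresholds = filter_thresholds(),
                     sd_type = "sample") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  records <- read_phased_table(phased_path)
  summaries <- summarize_positions(records)
  filtered <- filter_for_skewing(summaries, thresholds)
  calls <- call_skewing(filtered)
  funnel <- funnel_report(records, summaries, filtered)
  if (nrow(filtered) == 0L) {
    warning("no positions pass the skewing filters", call. = FALSE)
  }
  dist <- suppressWarnings(category_distribution(calls))
  dist_json <- dist
  dist_json$counts <- as.list(dist$counts)
  dist_json$percentages <- as.list(dist$percentages)

  paths <- c(summaries = write_tsv(summaries, file.path(out_dir, "summaries.tsv")),
             calls = write_tsv(calls, file.path(out_dir, "skew_calls.tsv")),
             distribution = write_json(dist_json, file.path(out_dir, "category_distribution.json")),
             funnel = write_json(funnel, file.path(out_dir, "funnel.json")))
  if (nrow(filtered) > 0L) {
    paths["summary_table"] <- write_tsv(
      skewing_summary_table(filtered, sd_type = sd_type),
      file.path(out_dir, "skew_summary.tsv"))
  }
  write_manifest(out_dir, "skew", paths, unclass(thresholds))
  invisible(list(summaries = summaries, filtered = filtered, calls = calls,
                 distribution = dist, funnel = funnel, paths = paths))
}

#' Run the escape analysis on one sample
#'
#' Reads a phased table, calls single-cell biallelic escape positions,
#' optionally annotates them with genes and cross-references a
#' known-escape list. Writes `escape_calls.tsv`, `escape_summary.tsv`,
#' `gene_cross_reference.tsv` (when a BED is given) and `manifest.json`.
#'
#' @param phased_path path to the per-read phased table.
#' @param out_dir output directory.
#' @param bed_path optional BED4 gene-annotation path.
#' @param known_path optional known-escape gene list path.
#' @param thresholds an [filter_thresholds()] object.
#' @return invisibly, a list with `calls`, `cross_ref` (or `NULL`) and
#'   `paths`.
#' @export
run_escape <- function(phased_path, out_dir, bed_path = NULL,
                       known_path = NULL,
                       thresholds = filter_thresholds()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  records <- read_phased_table(phased_path)
  summaries <- summarize_positions(records)
  calls <- call_escape(summaries, thresholds)
  cross_ref <- NULL
  if (!is.null(bed_path)) {
    calls <- map_to_genes(calls, read_gene_bed(bed_path))
    known <- if (!is.null(known_path)) read_known_escape(known_path) else character(0)
    cross_ref <- cross_reference(escape_gene_symbols(calls), known)
  }
  if (nrow(calls) == 0L) warning("no escape positions called", call. = FALSE)

  paths <- c(calls = write_tsv(calls, file.path(out_dir, "escape_calls.tsv")))
  if (nrow(calls) > 0L) {
    paths["summary_table"] <- write_tsv(
      skewing_summary_table(transform(calls, n_barcodes = 1L)),
      file.path(out_dir, "escape_summary.tsv"))
  }
  if (!is.null(cross_ref)) {
    paths["cross_reference"] <- write_tsv(
      cross_ref, file.path(out_dir, "gene_cross_reference.tsv"))
  }
  write_manifest(out_dir, "escape", paths, unclass(thresholds))
  invisible(list(calls = calls, cross_ref = cross_ref, paths = paths))
}

#' Run the two-sample comparison
#'
#' Reads two phased tables (e.g. control and patient), aggregates and
#' filters both with the same thresholds, compares skewing at shared
#' positions, and writes `comparison.tsv` plus a `significance.json`
#' report with, per correction method, the number of positions significant
#' at `alpha`, and the direction tallies.
#'
#' @param nf_path,gd_path phased tables of the two samples.
#' @param out_dir output directory.
#' @param thresholds an [filter_thresholds()] object.
#' @param orientation,yates,alpha passed to [compare_samples()].
#' @return invisibly, a list with `comparisons`, `significance`, `paths`.
#' @export
run_compare <- function(nf_path, gd_path, out_dir,
                        thresholds = filter_thresholds(),
                        orientation = "major_minor", yates = FALSE,
                        alpha = 0.05) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  prep <- function(path) {
    filter_for_skewing(summarize_positions(read_phased_table(path)),
                       thresholds)
  }
  comparisons <- compare_samples(prep(nf_path), prep(gd_path),
                                 orientation = orientation, yates = yates,
                                 alpha = alpha)
  sig <- list(
    n_shared = nrow(comparisons),
    alpha = alpha,
    n_significant = lapply(
      c(bonferroni = "p_bonferroni", hochberg = "p_hochberg",
        hommel = "p_hommel", fdr = "p_fdr"),
      function(cl) sum(comparisons[[cl]] < alpha)),
    direction_tally = as.list(direction_tally(comparisons)))
  paths <- c(comparison = write_tsv(comparisons, file.path(out_dir, "comparison.tsv")),
             significance = write_json(sig, file.path(out_dir, "significance.json")))
  write_manifest(out_dir, "compare", paths,
                 c(unclass(thresholds),
                   list(orientation = orientation, yates = yates, alpha = alpha)))
  invisible(list(comparisons = comparisons, significance = sig, paths = paths))
}

#' Generate a synthetic fixture directory
#'
#' @param out_dir output directory.
#' @param config an [simulation_config()] object.
#' @return invisibly, the named vector of file paths from [write_fixture()].
#' @export
run_simulate <- function(out_dir, config = simulation_config()) {
  paths <- write_fixture(config, out_dir)
  write_manifest(out_dir, "simulate", paths, unclass(config))
  invisible(paths)
}
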