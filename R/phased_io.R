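## Reading and writing the per-read phased-variant table and auxiliary
## formats (gene BED, known-escape gene list), plus direct ingestion from
## tagged alignments.
##
## The phased table is a 7-column TSV with a mandatory "#"-prefixed header:
##   chrom  pos  base  haplotype  cell_barcode  umi  read_id
## One line per read observation of one allele at one (1-based) chrX
## position. Lines beginning "#" are comments; encoding is UTF-8; fields
## are never quoted.

PHASED_COLUMNS <- c("chrom", "pos", "base", "haplotype",
                    "cell_barcode", "umi", "read_id")
VALID_BASES <- c("A", "C", "G", "T")
VALID_HAPLOTYPES <- c("H1", "H2")

empty_phased_records <- function() {
  data.frame(chrom = character(0), pos = integer(0), base = character(0),
             haplotype = character(0), cell_barcode = character(0),
             umi = character(0), read_id = character(0),
             stringsAsFactors = FALSE)
}

## Validates a phased-record data frame; returns it invisibly or stops.
validate_phased_records <- function(records) {
  missing_cols <- setdiff(PHASED_COLUMNS, names(records))
  if (length(missing_cols)) {
    stop("phased records lack column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(records) == 0L) return(invisible(records))
  bad <- function(cond, what) {
    if (any(cond)) {
      stop(sprintf("invalid phased record(s) at row %d: %s",
                   which(cond)[1L], what), call. = FALSE)
    }
  }
  pos <- records$pos
  bad(is.na(pos) | pos < 1 | pos != trunc(pos), "pos must be a positive integer")
  bad(!(records$base %in% VALID_BASES), "base must be one of A/C/G/T")
  bad(!(records$haplotype %in% VALID_HAPLOTYPES), "haplotype must be H1 or H2")
  bad(!is_valid_tag(records$cell_barcode), "cell_barcode empty or malformed")
  bad(!is_valid_tag(records$umi), "umi empty or malformed")
  invisible(records)
}

#' Read a per-read phased-variant table
#'
#' Parses the tab-separated per-read table produced downstream of
#' `samtools phase` on a chrX-restricted BAM: one line per sequencing-read
#' observation of one phased allele (H1/H2) at one heterozygous position in
#' one cell. The first line must be a `#`-prefixed header; further
#' `#`-prefixed lines are comments.
#'
#' @param path path to the TSV file.
#' @return a `data.frame` with columns `chrom`, `pos` (1-based integer),
#'   `base` (A/C/G/T), `haplotype` ("H1"/"H2"), `cell_barcode`, `umi`,
#'   `read_id`, one row per non-comment input line, in file order.
#' @details Malformed lines are never dropped silently: any line with the
#'   wrong column count, a bad base or haplotype label, a non-positive
#'   position, or an empty barcode/UMI raises an error naming the file line
#'   number. A file containing only the header yields zero rows.
#' @seealso [write_phased_table()], [ingest_alignments()]
#' @export
read_phased_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines) == 0L || !startsWith(lines[1L], "#")) {
    stop(path, ": missing '#'-prefixed header line", call. = FALSE)
  }
  data_idx <- which(!startsWith(lines, "#") & nzchar(lines))
  if (length(data_idx) == 0L) return(empty_phased_records())

  fields <- strsplit(lines[data_idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 7L)) {
    i <- which(nf != 7L)[1L]
    stop_parse(path, data_idx[i],
               sprintf("expected 7 tab-separated fields, found %d", nf[i]))
  }
  m <- matrix(unlist(fields, use.names = FALSE), ncol = 7L, byrow = TRUE)

  check <- function(ok, msg) {
    if (!all(ok)) stop_parse(path, data_idx[which(!ok)[1L]], msg)
  }
  pos <- suppressWarnings(as.integer(m[, 2L]))
  check(!is.na(pos) & pos >= 1L & m[, 2L] == as.character(pos),
        "pos is not a positive integer")
  check(m[, 3L] %in% VALID_BASES, "base must be one of A/C/G/T")
  check(m[, 4L] %in% VALID_HAPLOTYPES, "haplotype must be H1 or H2")
  check(is_valid_tag(m[, 5L]), "cell_barcode empty or malformed")
  check(is_valid_tag(m[, 6L]), "umi empty or malformed")

  data.frame(chrom = m[, 1L], pos = pos, base = m[, 3L],
             haplotype = m[, 4L], cell_barcode = m[, 5L], umi = m[, 6L],
             read_id = m[, 7L], stringsAsFactors = FALSE)
}

#' Write a per-read phased-variant table
#'
#' Inverse of [read_phased_table()]: records written with this function are
#' read back unchanged.
#'
#' @param records data frame of phased read records (see
#'   [read_phased_table()] for the columns).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_phased_table <- function(records, path) {
  validate_phased_records(records)
  header <- paste0("#", paste(PHASED_COLUMNS, collapse = "\t"))
  if (nrow(records) == 0L) {
    body <- character(0)
  } else {
    body <- do.call(paste, c(unname(records[PHASED_COLUMNS]), sep = "\t"))
  }
  writeLines(c(header, body), path, useBytes = TRUE)
  invisible(path)
}

#' Read gene annotations from a BED file
#'
#' Reads a BED3+name (BED4) file of gene intervals used to assign escape
#' positions to genes. Coordinates follow the BED convention: 0-based,
#' half-open `[start, end)`.
#'
#' @param path path to a tab-separated BED4 file. Lines starting with `#`,
#'   `track` or `browser` are skipped.
#' @return a `data.frame` with columns `gene`, `chrom`, `start`, `end`.
#'   Overlapping intervals are retained as given.
#' @export
read_gene_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- nzchar(lines) & !startsWith(lines, "#") &
    !startsWith(lines, "track") & !startsWith(lines, "browser")
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(data.frame(gene = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 4L)) {
    i <- which(nf < 4L)[1L]
    stop_parse(path, idx[i], "expected at least 4 BED columns (chrom, start, end, name)")
  }
  m <- t(vapply(fields, function(f) f[1:4], character(4)))
  ok_int <- grepl("^[0-9]+$", m[, 2L]) & grepl("^[0-9]+$", m[, 3L])
  if (!all(ok_int)) {
    stop_parse(path, idx[which(!ok_int)[1L]], "non-integer BED coordinates")
  }
  start <- as.integer(m[, 2L])
  end <- as.integer(m[, 3L])
  bad <- start >= end
  if (any(bad)) {
    stop_parse(path, idx[which(bad)[1L]], "BED interval with start >= end")
  }
  data.frame(gene = m[, 4L], chrom = m[, 1L], start = start, end = end,
             stringsAsFactors = FALSE)
}

#' Read a known-escape gene list
#'
#' One gene symbol per line; blank lines and `#` comments ignored.
#'
#' @param path path to the plain-text list.
#' @return character vector of unique gene symbols.
#' @export
read_known_escape <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path, encoding = "UTF-8", warn = FALSE))
  unique(lines[nzchar(lines) & !startsWith(lines, "#")])
}

#' Build phased read records from tagged alignments
#'
#' Converts cell-barcoded (CB tag), UMI-tagged (UB tag) alignments into
#' per-read phased records given a set of heterozygous sites with their
#' allele-to-haplotype assignment. Emits one record per (read, site) pair
#' where the read's base at the site matches one of the two phased alleles;
#' reads with any other base there (or a deletion) are skipped and counted.
#'
#' @param path a SAM or BAM file. Alignments must carry `CB` and `UB`
#'   string tags; reads missing either tag are skipped and counted.
#' @param het_sites data frame with columns `pos` (1-based), `h1` and `h2`
#'   (the base assigned to each phased haplotype), and optionally `chrom`
#'   to restrict matching to one reference sequence.
#' @return a phased-record `data.frame` as from [read_phased_table()], with
#'   a `"skip_report"` attribute: a list with counts `n_alignments`,
#'   `n_unmapped`, `n_missing_tags`, `n_base_mismatch` and `n_records`.
#' @export
ingest_alignments <- function(path, het_sites) {
  stopifnot(all(c("pos", "h1", "h2") %in% names(het_sites)))
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                             indexDestination = FALSE)
  }
  n_total <- Rsamtools::countBam(path)$records
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "seq"),
    tag = c("CB", "UB"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  )
  gal <- GenomicAlignments::readGAlignments(path, param = param)
  n_unmapped <- n_total - length(gal)

  meta <- S4Vectors::mcols(gal)
  cb <- as.character(meta$CB)
  ub <- as.character(meta$UB)
  has_tags <- !is.na(cb) & !is.na(ub) & nzchar(cb) & nzchar(ub)
  n_missing_tags <- sum(!has_tags)
  gal <- gal[has_tags]
  cb <- cb[has_tags]
  ub <- ub[has_tags]
  qname <- as.character(S4Vectors::mcols(gal)$qname)

  ## lay read sequences out in reference space so a site's base is a
  ## simple offset from the alignment start
  aln <- as.data.frame(gal)
  ref_seq <- as.character(GenomicAlignments::sequenceLayer(
    S4Vectors::mcols(gal)$seq, aln$cigar))
  aln_start <- aln$start
  aln_end <- aln$end
  aln_chrom <- as.character(aln$seqnames)

  out <- vector("list", nrow(het_sites))
  n_mismatch <- 0L
  for (i in seq_len(nrow(het_sites))) {
    site_pos <- het_sites$pos[i]
    idx <- which(aln_start <= site_pos & aln_end >= site_pos)
    if (!is.null(het_sites$chrom)) {
      idx <- idx[aln_chrom[idx] == het_sites$chrom[i]]
    }
    if (length(idx) == 0L) next
    base <- substr(ref_seq[idx], site_pos - aln_start[idx] + 1L,
                   site_pos - aln_start[idx] + 1L)
    hap <- ifelse(base == het_sites$h1[i], "H1",
                  ifelse(base == het_sites$h2[i], "H2", NA_character_))
    n_mismatch <- n_mismatch + sum(is.na(hap))
    keep <- !is.na(hap)
    if (!any(keep)) next
    out[[i]] <- data.frame(
      chrom = aln_chrom[idx][keep], pos = site_pos, base = base[keep],
      haplotype = hap[keep], cell_barcode = cb[idx][keep],
      umi = ub[idx][keep], read_id = qname[idx][keep],
      stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, c(list(empty_phased_records()), out))
  rownames(records) <- NULL
  attr(records, "skip_report") <- list(
    n_alignments = n_total, n_unmapped = n_unmapped,
    n_missing_tags = n_missing_tags, n_base_mismatch = n_mismatch,
    n_records = nrow(records))
  records
}
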