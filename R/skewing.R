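## The XCI skewing statistic, its four-category classification, the
## category distribution, and descriptive summary tables.

SKEW_CATEGORIES <- c("R", "S", "SS", "E")
SKEW_BREAKS <- c(50, 70, 80, 90)

#' Allelic skewing percentage
#'
#' The per-position XCI skewing statistic:
#' `MAX(x1, x2) / (x1 + x2) * 100`, the percentage of molecules supporting
#' the major allele. Symmetric in its arguments and always in \[50, 100\].
#'
#' @param x1,x2 non-negative allele counts (vectorized).
#' @return numeric vector of percentages in \[50, 100\].
#' @export
skew_percent <- function(x1, x2) {
  if (length(x1) != length(x2)) stop("x1 and x2 must have equal length", call. = FALSE)
  if (any(x1 < 0 | x2 < 0)) stop("allele counts must be non-negative", call. = FALSE)
  total <- x1 + x2
  if (any(total == 0)) stop("skew undefined when x1 + x2 = 0", call. = FALSE)
  100 * pmax(x1, x2) / total
}

#' Classify a skewing percentage into the four-category scheme
#'
#' Categories partition \[50, 100\] into half-open bins (the last closed):
#' * `R`  relatively random, \[50, 70)
#' * `S`  skewing, \[70, 80)
#' * `SS` severe skewing, \[80, 90)
#' * `E`  extreme severe skewing, \[90, 100\]
#'
#' @param skew_pct numeric vector of percentages in \[50, 100\].
#' @return factor with levels `R`, `S`, `SS`, `E`.
#' @export
classify_skew <- function(skew_pct) {
  tol <- 1e-9
  if (any(skew_pct < 50 - tol | skew_pct > 100 + tol)) {
    stop("skew percentage outside [50, 100]", call. = FALSE)
  }
  x <- pmin(pmax(skew_pct, 50), 100)
  factor(SKEW_CATEGORIES[findInterval(x, SKEW_BREAKS)],
         levels = SKEW_CATEGORIES)
}

#' Compute skewing calls for filtered positions
#'
#' @param summaries per-position summaries, typically the output of
#'   [filter_for_skewing()].
#' @return a `data.frame` with columns `pos`, `x1`, `x2`, `skew_pct`,
#'   `category`.
#' @export
call_skewing <- function(summaries) {
  if (nrow(summaries) == 0L) {
    return(data.frame(pos = integer(0), x1 = integer(0), x2 = integer(0),
                      skew_pct = numeric(0),
                      category = factor(character(0), levels = SKEW_CATEGORIES)))
  }
  skew <- skew_percent(summaries$x1, summaries$x2)
  data.frame(pos = summaries$pos, x1 = summaries$x1, x2 = summaries$x2,
             skew_pct = skew, category = classify_skew(skew),
             row.names = NULL)
}

#' Distribution of positions over the skewing categories
#'
#' Tallies skewing calls per category and reports percentages rounded half
#' up to one decimal, together with the cumulative "skewing or higher"
#' (S+SS+E) and "severe skewing or higher" (SS+E) aggregates.
#'
#' @param x one of: a data frame with a `category` column; a character or
#'   factor vector of categories; or a *named* numeric vector of
#'   per-category counts (names among `R`, `S`, `SS`, `E`).
#' @return a list with `counts` (named integer vector over the four
#'   categories), `percentages` (named numeric, one decimal), `n_total`,
#'   `pct_skewing_or_higher`, `pct_severe_or_higher`. With empty input,
#'   `n_total` is 0 and the percentage fields are `NA` (with a warning).
#' @export
category_distribution <- function(x) {
  if (is.data.frame(x)) x <- x$category
  if (is.numeric(x)) {
    if (is.null(names(x)) || !all(names(x) %in% SKEW_CATEGORIES)) {
      stop("numeric input must be a named vector of per-category counts",
           call. = FALSE)
    }
    counts <- stats::setNames(integer(4L), SKEW_CATEGORIES)
    counts[names(x)] <- as.integer(x)
  } else {
    x <- factor(as.character(x), levels = SKEW_CATEGORIES)
    if (anyNA(x)) stop("unknown skew category in input", call. = FALSE)
    counts <- table(x)
    counts <- stats::setNames(as.integer(counts), names(counts))
  }
  n_total <- sum(counts)
  if (n_total == 0L) {
    warning("empty input: category percentages undefined", call. = FALSE)
    return(list(counts = counts,
                percentages = stats::setNames(rep(NA_real_, 4L), SKEW_CATEGORIES),
                n_total = 0L,
                pct_skewing_or_higher = NA_real_,
                pct_severe_or_higher = NA_real_))
  }
  pct_raw <- 100 * counts / n_total
  list(counts = counts,
       percentages = round_half_up(pct_raw, 1L),
       n_total = n_total,
       pct_skewing_or_higher =
         round_half_up(100 * sum(counts[c("S", "SS", "E")]) / n_total, 1L),
       pct_severe_or_higher =
         round_half_up(100 * sum(counts[c("SS", "E")]) / n_total, 1L))
}

#' Descriptive statistics of a numeric vector
#'
#' @param x non-empty numeric vector.
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @return a list with `n`, `minimum`, `maximum`, `mean`, `sd`.
#' @export
summary_stats <- function(x, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (length(x) == 0L || anyNA(x)) {
    stop("summary_stats requires a non-empty vector without NAs", call. = FALSE)
  }
  n <- length(x)
  s <- if (n == 1L) 0 else stats::sd(x)
  if (sd_type == "population") s <- s * sqrt((n - 1) / n)
  list(n = n, minimum = min(x), maximum = max(x), mean = mean(x), sd = s)
}

#' Descriptive summary table for a skewing analysis
#'
#' One row per metric (X1, X2, skew percentage, barcoding frequency, number
#' of barcodes) with n, minimum, maximum, mean and standard deviation,
#' mirroring the layout of a per-sample data-interpretation table.
#'
#' @param summaries per-position summaries (post-filter); the skew
#'   percentage is computed on the fly.
#' @param sd_type passed to [summary_stats()].
#' @return a `data.frame` with columns `metric`, `n`, `minimum`, `maximum`,
#'   `mean`, `sd`.
#' @export
skewing_summary_table <- function(summaries, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (nrow(summaries) == 0L) stop("no positions to summarize", call. = FALSE)
  metrics <- list(
    "X1" = summaries$x1,
    "X2" = summaries$x2,
    "%" = skew_percent(summaries$x1, summaries$x2),
    "Barcoding frequency" = summaries$barcoding_frequency,
    "Number of barcode" = summaries$n_barcodes)
  rows <- lapply(metrics, summary_stats, sd_type = sd_type)
  out <- do.call(rbind, lapply(rows, as.data.frame))
  out <- cbind(data.frame(metric = names(metrics), stringsAsFactors = FALSE),
               out)
  rownames(out) <- NULL
  out
}
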