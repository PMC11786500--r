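## Per-SNP comparison of skewing between two samples (e.g. a patient and a
## control) at shared heterozygous positions: 2x2 contingency tables,
## two-proportion Z test, Pearson chi-square, four multiple-testing
## corrections, and Haldane-corrected Woolf odds ratios.
##
## Haplotype labels from read-backed phasing are sample-local (no parental
## anchoring), so the default table contrasts each sample's (major, minor)
## counts: the comparison is of skew magnitude, not haplotype identity.

#' Build a 2x2 contingency table for one shared position
#'
#' Rows are the two samples, columns the allele counts. With the default
#' `"major_minor"` orientation each row is ordered (major, minor) by that
#' sample's own larger count (ties keep the (x1, x2) order, where the
#' orientation is immaterial by symmetry). The `"haplotype_labels"`
#' orientation keeps (x1, x2) as given, which is only meaningful when the
#' haplotype labels are comparable across samples.
#'
#' @param nf_x1,nf_x2 allele counts in the first sample.
#' @param gd_x1,gd_x2 allele counts in the second sample.
#' @param orientation `"major_minor"` (default) or `"haplotype_labels"`.
#' @return a 2x2 integer matrix with rows `NF`, `GD` and columns `major`,
#'   `minor` (or `H1`, `H2`).
#' @export
build_table <- function(nf_x1, nf_x2, gd_x1, gd_x2,
                        orientation = c("major_minor", "haplotype_labels")) {
  orientation <- match.arg(orientation)
  if (nf_x1 + nf_x2 <= 0 || gd_x1 + gd_x2 <= 0) {
    stop("each sample needs a positive allele total", call. = FALSE)
  }
  if (orientation == "major_minor") {
    nf <- if (nf_x1 >= nf_x2) c(nf_x1, nf_x2) else c(nf_x2, nf_x1)
    gd <- if (gd_x1 >= gd_x2) c(gd_x1, gd_x2) else c(gd_x2, gd_x1)
    cols <- c("major", "minor")
  } else {
    nf <- c(nf_x1, nf_x2)
    gd <- c(gd_x1, gd_x2)
    cols <- c("H1", "H2")
  }
  matrix(as.integer(c(nf, gd)), nrow = 2L, byrow = TRUE,
         dimnames = list(c("NF", "GD"), cols))
}

#' Two-proportion Z test on a 2x2 table
#'
#' Pooled-variance two-proportion Z statistic comparing the first-column
#' proportion between the two rows:
#' `z = (p1 - p2) / sqrt(p(1-p)(1/n1 + 1/n2))` with `p` the pooled
#' proportion, and a two-sided normal p-value. When the pooled proportion
#' is 0 or 1 there is no variation and the test degenerates to `z = 0`,
#' `p = 1`.
#'
#' @param tbl a 2x2 count matrix (rows = samples).
#' @return a list with `z` and `p`.
#' @export
two_proportion_z <- function(tbl) {
  stopifnot(is.matrix(tbl), all(dim(tbl) == 2L), all(tbl >= 0))
  n1 <- sum(tbl[1L, ])
  n2 <- sum(tbl[2L, ])
  if (n1 == 0 || n2 == 0) stop("both row sums must be positive", call. = FALSE)
  p1 <- tbl[1L, 1L] / n1
  p2 <- tbl[2L, 1L] / n2
  pooled <- (tbl[1L, 1L] + tbl[2L, 1L]) / (n1 + n2)
  if (pooled == 0 || pooled == 1) return(list(z = 0, p = 1))
  z <- (p1 - p2) / sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Pearson chi-square test on a 2x2 table
#'
#' Without continuity correction (the default), the statistic equals the
#' square of the pooled two-proportion Z statistic.
#'
#' @param tbl a 2x2 count matrix with all margins positive.
#' @param yates apply Yates continuity correction (default `FALSE`).
#' @return a list with `chi2` and `p` (df = 1).
#' @export
chi_square_2x2 <- function(tbl, yates = FALSE) {
  stopifnot(is.matrix(tbl), all(dim(tbl) == 2L), all(tbl >= 0))
  if (any(rowSums(tbl) == 0) || any(colSums(tbl) == 0)) {
    stop("chi-square undefined: zero margin", call. = FALSE)
  }
  res <- suppressWarnings(stats::chisq.test(tbl, correct = yates))
  list(chi2 = unname(res$statistic), p = res$p.value)
}

#' Haldane-corrected Woolf odds ratio with confidence interval
#'
#' Adds 1/2 to every cell (Haldane's correction), so the estimate is finite
#' and positive even with zero cells, and builds the Woolf log-OR interval:
#' `OR = ((a+.5)(d+.5)) / ((b+.5)(c+.5))`,
#' `SE(log OR) = sqrt(sum of 1/(cell+.5))`,
#' `CI = exp(log OR +/- z * SE)`.
#'
#' @param tbl a 2x2 count matrix `rbind(c(a, b), c(c, d))`.
#' @param alpha significance level for the interval (default 0.05).
#' @return a list with `or`, `ci_low`, `ci_high`.
#' @export
haldane_woolf_or <- function(tbl, alpha = 0.05) {
  stopifnot(is.matrix(tbl), all(dim(tbl) == 2L), all(tbl >= 0))
  a <- tbl[1L, 1L] + 0.5
  b <- tbl[1L, 2L] + 0.5
  c_ <- tbl[2L, 1L] + 0.5
  d <- tbl[2L, 2L] + 0.5
  or <- (a * d) / (b * c_)
  se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  zq <- qnorm(1 - alpha / 2)
  list(or = or, ci_low = or * exp(-zq * se), ci_high = or * exp(zq * se))
}

#' Multiple-testing correction
#'
#' Thin wrapper over [stats::p.adjust()] exposing the four corrections used
#' for the per-SNP comparison family, with `"fdr"` meaning the
#' Benjamini-Hochberg step-up procedure (`"by"` gives the more conservative
#' Benjamini-Yekutieli variant).
#'
#' @param p numeric vector of raw p-values in \[0, 1\].
#' @param method one of `"bonferroni"`, `"hochberg"`, `"hommel"`, `"fdr"`,
#'   `"by"`.
#' @return adjusted p-values, same length and order as `p`.
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "hochberg", "hommel",
                                         "fdr", "by")) {
  method <- match.arg(method)
  if (any(is.na(p) | p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = switch(method, fdr = "BH", by = "BY", method))
}

#' Compare skewing between two samples at shared positions
#'
#' For every position present in both (filtered) summary sets, builds the
#' 2x2 table, runs the Z and chi-square tests, computes the
#' Haldane-corrected Woolf odds ratio, and adjusts the Z-test p-values over
#' the whole family of shared positions with all four corrections. The
#' `direction` column compares the two samples' skew percentages
#' (`GD_greater` / `GD_less` / `equal`).
#'
#' When a table has a zero column margin (both samples fully skewed to
#' their major allele) there is no variation to test; both statistics are
#' set to 0 with p = 1, preserving the chi-square = Z-squared identity.
#'
#' @param nf,gd per-position summaries of the two samples, filtered with
#'   the same thresholds (columns `pos`, `x1`, `x2` required).
#' @param orientation,yates,alpha passed to [build_table()],
#'   [chi_square_2x2()] and [haldane_woolf_or()].
#' @return a `data.frame` with one row per shared position: `pos`, the four
#'   cell counts `a`, `b`, `c`, `d`, `z`, `p_z`, `chi2`, `p_chi2`,
#'   `p_bonferroni`, `p_hochberg`, `p_hommel`, `p_fdr`, `or`, `ci_low`,
#'   `ci_high`, `direction`. Empty (with a warning) when no position is
#'   shared.
#' @export
compare_samples <- function(nf, gd,
                            orientation = c("major_minor", "haplotype_labels"),
                            yates = FALSE, alpha = 0.05) {
  orientation <- match.arg(orientation)
  shared <- merge(nf[, c("pos", "x1", "x2")], gd[, c("pos", "x1", "x2")],
                  by = "pos", suffixes = c("_nf", "_gd"))
  if (nrow(shared) == 0L) {
    warning("no positions shared between the two samples", call. = FALSE)
    return(empty_comparisons())
  }
  shared <- shared[order(shared$pos), , drop = FALSE]
  n <- nrow(shared)
  res <- vector("list", n)
  for (i in seq_len(n)) {
    tbl <- build_table(shared$x1_nf[i], shared$x2_nf[i],
                       shared$x1_gd[i], shared$x2_gd[i],
                       orientation = orientation)
    if (any(colSums(tbl) == 0)) {
      zt <- list(z = 0, p = 1)
      ct <- list(chi2 = 0, p = 1)
    } else {
      zt <- two_proportion_z(tbl)
      ct <- chi_square_2x2(tbl, yates = yates)
    }
    or <- haldane_woolf_or(tbl, alpha = alpha)
    skew_nf <- skew_percent(shared$x1_nf[i], shared$x2_nf[i])
    skew_gd <- skew_percent(shared$x1_gd[i], shared$x2_gd[i])
    direction <- if (skew_gd > skew_nf) "GD_greater"
      else if (skew_gd < skew_nf) "GD_less" else "equal"
    res[[i]] <- data.frame(
      pos = shared$pos[i],
      a = tbl[1L, 1L], b = tbl[1L, 2L], c = tbl[2L, 1L], d = tbl[2L, 2L],
      z = zt$z, p_z = zt$p, chi2 = ct$chi2, p_chi2 = ct$p,
      or = or$or, ci_low = or$ci_low, ci_high = or$ci_high,
      direction = direction, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  for (m in c("bonferroni", "hochberg", "hommel", "fdr")) {
    out[[paste0("p_", m)]] <- adjust_pvalues(out$p_z, method = m)
  }
  out <- out[, c("pos", "a", "b", "c", "d", "z", "p_z", "chi2", "p_chi2",
                 "p_bonferroni", "p_hochberg", "p_hommel", "p_fdr",
                 "or", "ci_low", "ci_high", "direction")]
  rownames(out) <- NULL
  out
}

empty_comparisons <- function() {
  data.frame(pos = integer(0), a = integer(0), b = integer(0),
             c = integer(0), d = integer(0), z = numeric(0),
             p_z = numeric(0), chi2 = numeric(0), p_chi2 = numeric(0),
             p_bonferroni = numeric(0), p_hochberg = numeric(0),
             p_hommel = numeric(0), p_fdr = numeric(0), or = numeric(0),
             ci_low = numeric(0), ci_high = numeric(0),
             direction = character(0), stringsAsFactors = FALSE)
}

#' Tally skew-difference directions
#'
#' @param comparisons output of [compare_samples()].
#' @return named integer vector over `GD_greater`, `GD_less`, `equal`;
#'   sums to the number of shared positions.
#' @export
direction_tally <- function(comparisons) {
  lv <- c("GD_greater", "GD_less", "equal")
  tab <- table(factor(comparisons$direction, levels = lv))
  stats::setNames(as.integer(tab), lv)
}
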