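test_that("contingency tables use per-sample major/minor columns", {
  tbl <- build_table(8, 2, 3, 7)
  expect_identical(unname(tbl), matrix(c(8L, 2L, 7L, 3L), 2, byrow = TRUE))
  # tie is symmetric, kept in (x1, x2) order
  tbl <- build_table(5, 5, 6, 2)
  expect_identical(unname(tbl[1, ]), c(5L, 5L))
  # haplotype orientation preserves labels
  tbl <- build_table(2, 8, 3, 7, orientation = "haplotype_labels")
  expect_identical(unname(tbl), matrix(c(2L, 8L, 3L, 7L), 2, byrow = TRUE))
  expect_error(build_table(0, 0, 3, 7), "positive")

  # rows always conserve each sample's allele total
  set.seed(2)
  for (i in 1:50) {
    x <- sample(0:20, 4, replace = TRUE) + c(1, 0, 1, 0)
    tbl <- build_table(x[1], x[2], x[3], x[4])
    expect_identical(unname(rowSums(tbl)), c(x[1] + x[2], x[3] + x[4]))
  }
})

test_that("two-proportion Z follows the pooled formula and its symmetries", {
  expect_equal(two_proportion_z(rbind(c(8, 2), c(8, 2))), list(z = 0, p = 1))

  tbl <- rbind(c(80, 20), c(50, 50))
  got <- two_proportion_z(tbl)
  p1 <- 0.8; p2 <- 0.5; pp <- 130 / 200
  z_ref <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / 100 + 1 / 100))
  expect_equal(got$z, z_ref, tolerance = 1e-12)
  expect_equal(got$p, 2 * pnorm(-abs(z_ref)), tolerance = 1e-12)

  expect_equal(two_proportion_z(tbl[2:1, ])$z, -got$z)
  # degenerate pooled proportion
  expect_equal(two_proportion_z(rbind(c(5, 0), c(9, 0))), list(z = 0, p = 1))
})

test_that("chi-square equals Z-squared and the textbook formula", {
  expect_equal(chi_square_2x2(rbind(c(8, 2), c(8, 2)))$chi2, 0)
  expect_equal(chi_square_2x2(rbind(c(8, 2), c(8, 2)))$p, 1)

  tbl <- rbind(c(80, 20), c(50, 50))
  expect_equal(chi_square_2x2(tbl)$chi2, oracle_chi2(tbl), tolerance = 1e-12)

  set.seed(31)
  for (i in seq_len(1000)) {
    tbl <- matrix(sample(0:30, 4, replace = TRUE), 2)
    if (any(rowSums(tbl) == 0) || any(colSums(tbl) == 0)) next
    ct <- chi_square_2x2(tbl)
    expect_equal(ct$chi2, two_proportion_z(tbl)$z^2, tolerance = 1e-9)
    expect_equal(ct$chi2, oracle_chi2(tbl), tolerance = 1e-9)
  }
  expect_error(chi_square_2x2(rbind(c(5, 0), c(9, 0))), "margin")
})

test_that("Haldane-Woolf odds ratio is the +1/2 closed form", {
  res <- haldane_woolf_or(rbind(c(10, 10), c(10, 10)))
  expect_equal(res$or, 1)
  expect_true(res$ci_low < 1 && 1 < res$ci_high)

  res <- haldane_woolf_or(rbind(c(0, 10), c(10, 0)))
  expect_equal(res$or, (0.5 * 0.5) / (10.5 * 10.5))
  expect_true(is.finite(res$or) && res$or > 0)

  set.seed(33)
  for (i in 1:200) {
    tbl <- matrix(sample(0:25, 4, replace = TRUE), 2)
    res <- haldane_woolf_or(tbl)
    a <- tbl[1, 1] + .5; b <- tbl[1, 2] + .5
    cc <- tbl[2, 1] + .5; d <- tbl[2, 2] + .5
    expect_equal(res$or, a * d / (b * cc), tolerance = 1e-12)
    se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
    expect_equal(res$ci_low, exp(log(res$or) - qnorm(.975) * se),
                 tolerance = 1e-12)
    expect_true(res$ci_low <= res$or && res$or <= res$ci_high)
    # swapping rows inverts the estimate
    expect_equal(haldane_woolf_or(tbl[2:1, ])$or, 1 / res$or,
                 tolerance = 1e-12)
  }
})

test_that("p-value corrections match independent brute-force oracles", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03), "bonferroni"),
               c(0.03, 0.06, 0.09))
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03), "fdr"),
               oracle_bh(c(0.01, 0.02, 0.03)))
  expect_error(adjust_pvalues(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(41)
  for (i in 1:50) {
    m <- sample(2:8, 1)
    p <- round(runif(m)^2, 4)
    expect_equal(adjust_pvalues(p, "bonferroni"), oracle_bonferroni(p),
                 tolerance = 1e-12)
    expect_equal(adjust_pvalues(p, "hochberg"), oracle_hochberg(p),
                 tolerance = 1e-12)
    expect_equal(adjust_pvalues(p, "fdr"), oracle_bh(p), tolerance = 1e-12)
    expect_equal(adjust_pvalues(p, "hommel"), oracle_hommel(p),
                 tolerance = 1e-12)
    # dominance and monotonicity properties
    expect_true(all(adjust_pvalues(p, "bonferroni") >= p))
    expect_true(all(adjust_pvalues(p, "bonferroni") >=
                      adjust_pvalues(p, "hochberg") - 1e-12))
    expect_true(all(adjust_pvalues(p, "hochberg") >=
                      adjust_pvalues(p, "hommel") - 1e-12))
    # permuting inputs permutes outputs identically
    perm <- sample(m)
    for (meth in c("bonferroni", "hochberg", "hommel", "fdr")) {
      expect_equal(adjust_pvalues(p[perm], meth),
                   adjust_pvalues(p, meth)[perm])
    }
  }
})

test_that("sample comparison spans shared positions with family-wide correction", {
  nf <- make_summaries(pos = c(1, 2, 3), x1 = c(30, 12, 8),
                       x2 = c(10, 10, 9), barcoding_frequency = 60,
                       n_barcodes = 5)
  gd <- make_summaries(pos = c(2, 3, 4), x1 = c(5, 30, 10),
                       x2 = c(20, 4, 10), barcoding_frequency = 60,
                       n_barcodes = 5)

  expect_warning(out0 <- compare_samples(nf[1, ], gd[3, ]), "shared")
  expect_identical(nrow(out0), 0L)

  # single shared position: adjusted p equals raw p for every method
  out1 <- compare_samples(nf[2, ], gd[1, ])
  expect_identical(nrow(out1), 1L)
  for (cl in c("p_bonferroni", "p_hochberg", "p_hommel", "p_fdr")) {
    expect_equal(out1[[cl]], out1$p_z)
  }

  out <- compare_samples(nf, gd)
  expect_identical(out$pos, c(2L, 3L))
  # per-sample major-first: GD at pos 2 has x1=5 < x2=20
  expect_identical(out$c[out$pos == 2], 20L)
  expect_equal(out$p_bonferroni, pmin(1, 2 * out$p_z))
  expect_equal(out$chi2, out$z^2, tolerance = 1e-9)
  # directions: gd pos2 skew 80 > nf 54.5...; gd pos3 88.2 > nf 52.9
  expect_identical(out$direction, c("GD_greater", "GD_greater"))
  tal <- direction_tally(out)
  expect_identical(sum(tal), nrow(out))
})

test_that("planted skew differences are recovered across replicates", {
  set.seed(55)
  n_rep <- 200
  n_null <- 6
  hits <- 0L
  false_pos <- 0L
  total_sig <- 0L
  for (r in seq_len(n_rep)) {
    # 6 null positions (both samples share p = 0.7) and 1 planted difference
    nf_x1 <- rbinom(n_null + 1, 40, c(rep(0.7, n_null), 0.55))
    gd_x1 <- rbinom(n_null + 1, 40, c(rep(0.7, n_null), 0.97))
    nf <- make_summaries(pos = 1:(n_null + 1), x1 = nf_x1, x2 = 40 - nf_x1,
                         barcoding_frequency = 80, n_barcodes = 5)
    gd <- make_summaries(pos = 1:(n_null + 1), x1 = gd_x1, x2 = 40 - gd_x1,
                         barcoding_frequency = 80, n_barcodes = 5)
    out <- compare_samples(nf, gd)
    sig <- out$pos[out$p_fdr < 0.05]
    hits <- hits + ((n_null + 1) %in% sig)
    false_pos <- false_pos + sum(sig <= n_null)
    total_sig <- total_sig + length(sig)
  }
  expect_gte(hits / n_rep, 0.8)            # power at the planted position
  expect_lte(false_pos / max(1, total_sig), 0.10)  # empirical FDR in check
})
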