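# Builders and independent reference implementations used as oracles.

make_records <- function(pos, haplotype, cell_barcode = "CELL1",
                         umi = "UMIAAA", base = "A", chrom = "chrX",
                         read_id = NULL) {
  n <- max(length(pos), length(haplotype), length(cell_barcode), length(umi))
  if (is.null(read_id)) read_id <- sprintf("r%04d", seq_len(n))
  data.frame(chrom = rep_len(chrom, n), pos = as.integer(rep_len(pos, n)),
             base = rep_len(base, n), haplotype = rep_len(haplotype, n),
             cell_barcode = rep_len(cell_barcode, n),
             umi = rep_len(umi, n), read_id = rep_len(read_id, n),
             stringsAsFactors = FALSE)
}

make_summaries <- function(pos, x1, x2, barcoding_frequency, n_barcodes,
                           barcode = "CELLX") {
  n <- length(pos)
  out <- data.frame(pos = as.integer(pos), x1 = as.integer(x1),
                    x2 = as.integer(x2),
                    barcoding_frequency = as.integer(barcoding_frequency),
                    n_barcodes = as.integer(n_barcodes),
                    stringsAsFactors = FALSE)
  out$per_barcode <- lapply(seq_len(n), function(i) {
    data.frame(cell_barcode = barcode, x1 = x1[i], x2 = x2[i],
               stringsAsFactors = FALSE)
  })
  out
}

# ---- independent reference implementations (oracles) -----------------------

# Pearson chi-square from the textbook sum((O-E)^2/E) formula.
oracle_chi2 <- function(tbl) {
  expected <- outer(rowSums(tbl), colSums(tbl)) / sum(tbl)
  sum((tbl - expected)^2 / expected)
}

oracle_bonferroni <- function(p) pmin(1, length(p) * p)

# Hochberg step-up with running minima over the sorted p-values.
oracle_hochberg <- function(p) {
  m <- length(p)
  o <- order(p)
  sp <- p[o]
  adj <- numeric(m)
  adj[m] <- min(1, sp[m])
  if (m > 1) {
    for (i in (m - 1):1) adj[i] <- min(adj[i + 1], (m - i + 1) * sp[i])
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Benjamini-Hochberg step-up.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  sp <- p[o]
  adj <- numeric(m)
  adj[m] <- min(1, sp[m])
  if (m > 1) {
    for (i in (m - 1):1) adj[i] <- min(adj[i + 1], m / i * sp[i])
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Hommel via exhaustive closed testing with Simes combination (small m):
# adjusted p_i = max over all subsets containing i of the Simes p-value.
oracle_hommel <- function(p) {
  m <- length(p)
  simes <- function(pv) min(length(pv) * sort(pv) / seq_along(pv))
  adj <- numeric(m)
  for (mask in seq_len(2^m - 1)) {
    members <- which(bitwAnd(mask, 2^(seq_len(m) - 1)) > 0)
    sp <- simes(p[members])
    adj[members] <- pmax(adj[members], sp)
  }
  pmin(1, adj)
}
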