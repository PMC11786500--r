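test_that("UMI collapse keeps unanimous groups and discards conflicts", {
  r <- make_records(pos = 100, haplotype = c("H1", "H1", "H1"),
                    umi = "U1")
  obs <- collapse_umis(r)
  expect_identical(nrow(obs), 1L)
  expect_identical(obs$read_support, 3L)
  expect_identical(obs$haplotype, "H1")
  expect_identical(attr(obs, "n_conflicts"), 0L)

  r <- make_records(pos = 100, haplotype = c("H1", "H2"), umi = "U1")
  obs <- collapse_umis(r)
  expect_identical(nrow(obs), 0L)
  expect_identical(attr(obs, "n_conflicts"), 1L)

  expect_identical(nrow(collapse_umis(r[0, ])), 0L)
})

test_that("UMI collapse equals brute-force grouping on random records", {
  set.seed(3)
  n <- 100
  r <- make_records(pos = sample(1:4, n, replace = TRUE),
                    haplotype = sample(c("H1", "H2"), n, replace = TRUE),
                    cell_barcode = sample(c("BC1", "BC2"), n, replace = TRUE),
                    umi = sample(sprintf("U%d", 1:10), n, replace = TRUE))
  obs <- collapse_umis(r)

  key <- paste(r$pos, r$cell_barcode, r$umi, sep = "|")
  groups <- split(r$haplotype, key)
  unanimous <- vapply(groups, function(h) length(unique(h)) == 1L, logical(1))
  expect_identical(nrow(obs), sum(unanimous))
  expect_identical(attr(obs, "n_conflicts"), sum(!unanimous))
  got_support <- setNames(obs$read_support,
                          paste(obs$pos, obs$cell_barcode, obs$umi, sep = "|"))
  expect_identical(got_support[names(groups)[unanimous]],
                   vapply(groups[unanimous], length, integer(1)))
})

test_that("position summaries separate reads, UMIs and barcodes", {
  # 12 reads at one position: 4 UMIs H1 (2 reads each), 2 UMIs H2
  # (2 reads each), across 3 barcodes
  r <- rbind(
    make_records(100, "H1", "BC1", rep(c("U1", "U2"), each = 2)),
    make_records(100, "H1", "BC2", rep(c("U3", "U4"), each = 2)),
    make_records(100, "H2", "BC3", rep(c("U5", "U6"), each = 2)))
  s <- summarize_positions(r)
  expect_identical(nrow(s), 1L)
  expect_identical(s$x1, 4L)
  expect_identical(s$x2, 2L)
  expect_identical(s$barcoding_frequency, 12L)
  expect_identical(s$n_barcodes, 3L)
  pb <- s$per_barcode[[1]]
  expect_identical(sum(pb$x1), s$x1)
  expect_identical(sum(pb$x2), s$x2)
  expect_identical(nrow(pb), s$n_barcodes)

  expect_identical(nrow(summarize_positions(r[0, ])), 0L)
})

test_that("conflicting UMIs count toward coverage but not allele support", {
  r <- rbind(
    make_records(100, c("H1", "H2"), "BC1", "U1"),   # conflicting UMI
    make_records(100, c("H1", "H1", "H2"), "BC2", c("U2", "U2", "U3")))
  s <- summarize_positions(r)
  expect_identical(s$barcoding_frequency, 5L)  # all reads counted
  expect_identical(s$x1, 1L)                   # U2 only
  expect_identical(s$x2, 1L)                   # U3 only
  expect_identical(s$n_barcodes, 2L)           # BC1 still observed
  pb <- s$per_barcode[[1]]
  expect_identical(pb$x1[pb$cell_barcode == "BC1"], 0L)
})

test_that("summaries match an independent tally on simulated data", {
  sim <- simulate_phased_reads(simulation_config(
    n_positions = 30, n_cells = 50, n_homozygous_decoys = 5, seed = 9))
  r <- sim$records
  s <- summarize_positions(r)

  expect_identical(s$pos, sort(unique(r$pos)))
  freq_oracle <- as.integer(table(r$pos)[as.character(s$pos)])
  expect_identical(s$barcoding_frequency, freq_oracle)
  nb_oracle <- vapply(s$pos, function(p)
    length(unique(r$cell_barcode[r$pos == p])), integer(1))
  expect_identical(s$n_barcodes, nb_oracle)
  x_oracle <- t(vapply(s$pos, function(p) {
    rr <- r[r$pos == p, ]
    key <- paste(rr$cell_barcode, rr$umi, sep = "|")
    haps <- vapply(split(rr$haplotype, key),
                   function(h) if (length(unique(h)) == 1L) h[1] else NA_character_,
                   character(1))
    c(sum(haps == "H1", na.rm = TRUE), sum(haps == "H2", na.rm = TRUE))
  }, integer(2)))
  expect_identical(s$x1, x_oracle[, 1])
  expect_identical(s$x2, x_oracle[, 2])

  # molecule counts never exceed read counts; equality iff 1 read per UMI
  expect_true(all(s$x1 + s$x2 <= s$barcoding_frequency))
})

test_that("skewing filter is inclusive at every boundary", {
  s <- make_summaries(pos = 1:6,
                      x1 = c(3, 2, 3, 3, 3, 3),
                      x2 = c(3, 10, 3, 3, 3, 3),
                      barcoding_frequency = c(10, 50, 1000, 9, 1001, 10),
                      n_barcodes = c(3, 5, 30, 3, 3, 31))
  kept <- filter_for_skewing(s)
  expect_identical(kept$pos, c(1L, 3L))  # boundary rows retained, rest fail
})

test_that("filtering equals brute-force predicate evaluation and is well-behaved", {
  set.seed(21)
  n <- 200
  s <- make_summaries(pos = seq_len(n),
                      x1 = sample(0:12, n, replace = TRUE),
                      x2 = sample(0:12, n, replace = TRUE),
                      barcoding_frequency = sample(1:1200, n, replace = TRUE),
                      n_barcodes = sample(1:40, n, replace = TRUE))
  t0 <- filter_thresholds()
  kept <- filter_for_skewing(s, t0)
  oracle <- s[s$barcoding_frequency >= 10 & s$barcoding_frequency <= 1000 &
                s$n_barcodes >= 3 & s$n_barcodes <= 30 &
                s$x1 >= 3 & s$x2 >= 3, ]
  expect_identical(kept$pos, oracle$pos)

  # idempotence and permutation-invariance of the retained set
  expect_identical(filter_for_skewing(kept, t0), kept)
  perm <- s[sample(n), ]
  expect_identical(sort(filter_for_skewing(perm, t0)$pos), sort(kept$pos))

  # tightening any single threshold never grows the retained count
  base_n <- nrow(kept)
  for (tt in list(filter_thresholds(freq_min = 20),
                  filter_thresholds(freq_max = 500),
                  filter_thresholds(barcode_min = 5),
                  filter_thresholds(barcode_max = 20),
                  filter_thresholds(allele_min = 5))) {
    expect_lte(nrow(filter_for_skewing(s, tt)), base_n)
  }
})

test_that("funnel report tallies the sample exactly", {
  no_records <- make_records(1, "H1")[0, ]
  empty_summaries <- summarize_positions(no_records)
  empty <- funnel_report(no_records, empty_summaries, empty_summaries)
  expect_identical(unlist(empty), c(total_reads = 0L, n_barcodes = 0L,
                                    candidate_positions = 0L,
                                    retained_positions = 0L))

  sim <- simulate_phased_reads(simulation_config(
    n_positions = 20, n_cells = 40, seed = 5))
  s <- summarize_positions(sim$records)
  f <- filter_for_skewing(s)
  rep <- funnel_report(sim$records, s, f)
  expect_identical(rep$total_reads, nrow(sim$records))
  expect_identical(rep$n_barcodes, length(unique(sim$records$cell_barcode)))
  expect_identical(rep$candidate_positions, length(unique(sim$records$pos)))
  expect_lte(rep$retained_positions, rep$candidate_positions)
})

test_that("threshold constructor rejects inconsistent bounds", {
  expect_error(filter_thresholds(freq_min = 100, freq_max = 10), "freq_min")
  expect_error(filter_thresholds(barcode_min = 31, barcode_max = 30), "barcode_min")
  expect_error(filter_thresholds(allele_min = 0), "allele_min")
})
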