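## Synthetic generator for phased, cell-barcoded, UMI-tagged reads at
## heterozygous chrX positions with known ground truth: per-cell XCI
## mosaicism, planted single-cell biallelic (escape) positions, and
## homozygous decoy positions. Everything downstream of the generator can
## be validated against the emitted truth table.

CHRX_LENGTH <- 155270560L

#' Simulation configuration
#'
#' Parameters of the synthetic read generator. Defaults emulate a desk-size
#' version of a CD4+ T-cell 10x experiment: ~500 cells, sparse per-cell
#' expression of any given chrX variant, roughly 3 molecules per expressing
#' cell and under 2 reads per molecule, with a population-level inactivation
#' bias of 0.7 (so positions skew to ~70% on average).
#'
#' @param n_positions number of heterozygous positions (including planted
#'   escape positions).
#' @param n_cells number of cells (distinct 16-nt barcodes).
#' @param mosaic_fraction probability that a cell inactivates haplotype H2,
#'   i.e. the expected population skew toward H1.
#' @param escape_rate fraction of `n_positions` planted as single-cell
#'   biallelic escape sites.
#' @param leak_rate probability that a UMI from a monoallelic cell carries
#'   the inactive haplotype (background noise).
#' @param expr_rate probability that a given cell expresses a given
#'   (non-escape) position.
#' @param umis_per_cell_position mean of the (zero-truncated Poisson) UMI
#'   count per expressing cell and position.
#' @param reads_per_umi mean of the (zero-truncated Poisson) read count per
#'   UMI.
#' @param n_homozygous_decoys number of homozygous decoy positions, which
#'   emit a single haplotype label in every expressing cell.
#' @param seed integer random seed; a fixed seed reproduces the output
#'   exactly.
#' @return an object of class `xci_sim_config` (a named list).
#' @export
simulation_config <- function(n_positions = 200L, n_cells = 500L,
                              mosaic_fraction = 0.7, escape_rate = 0.05,
                              leak_rate = 0.01, expr_rate = 0.02,
                              umis_per_cell_position = 3,
                              reads_per_umi = 1.8,
                              n_homozygous_decoys = 20L, seed = 1L) {
  cfg <- list(n_positions = as.integer(n_positions),
              n_cells = as.integer(n_cells),
              mosaic_fraction = mosaic_fraction,
              escape_rate = escape_rate, leak_rate = leak_rate,
              expr_rate = expr_rate,
              umis_per_cell_position = umis_per_cell_position,
              reads_per_umi = reads_per_umi,
              n_homozygous_decoys = as.integer(n_homozygous_decoys),
              seed = as.integer(seed))
  probs <- c(cfg$mosaic_fraction, cfg$escape_rate, cfg$leak_rate,
             cfg$expr_rate)
  if (any(probs < 0 | probs > 1)) {
    stop("mosaic_fraction, escape_rate, leak_rate and expr_rate must lie in [0, 1]",
         call. = FALSE)
  }
  if (cfg$n_positions < 0L || cfg$n_homozygous_decoys < 0L || cfg$n_cells < 1L) {
    stop("counts must be non-negative (n_cells >= 1)", call. = FALSE)
  }
  if (cfg$umis_per_cell_position <= 0 || cfg$reads_per_umi <= 0) {
    stop("count-distribution means must be positive", call. = FALSE)
  }
  structure(cfg, class = "xci_sim_config")
}

## distinct random DNA strings (retry collisions; deterministic under seed)
distinct_dna <- function(n, len) {
  s <- rand_dna(n, len)
  while (anyDuplicated(s)) {
    dup <- duplicated(s)
    s[dup] <- rand_dna(sum(dup), len)
  }
  s
}

#' Simulate phased read records with ground truth
#'
#' Generates per-read records of the phased-table dialect under a known
#' model:
#' * each non-escape heterozygous position is expressed by each cell with
#'   probability `expr_rate`; an expressing cell activates haplotype H1
#'   with probability `mosaic_fraction` and emits a zero-truncated Poisson
#'   number of UMIs, each carrying the active haplotype except with
#'   probability `leak_rate`;
#' * each planted escape position is expressed in exactly one cell, which
#'   emits at least 3 UMIs of *each* haplotype and enough reads to clear
#'   the default coverage floor of 10, so the site satisfies the
#'   operational escape criterion by construction;
#' * homozygous decoy positions emit only the H1 label in every expressing
#'   cell;
#' * every UMI carries a zero-truncated Poisson number of reads, giving the
#'   read > UMI > cell count hierarchy of real droplet data.
#'
#' @param config an [simulation_config()] object.
#' @return a list with `records` (phased read records, see
#'   [read_phased_table()]) and `truth`, a `data.frame` with one row per
#'   position: `pos`, `true_type` (`skewed`/`random`/`escape`/`homozygous`),
#'   `true_skew` (expected major-allele fraction) and `escape_barcode`.
#' @export
simulate_phased_reads <- function(config = simulation_config()) {
  stopifnot(inherits(config, "xci_sim_config"))
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(config$seed)

  n_escape <- as.integer(round(config$escape_rate * config$n_positions))
  n_het <- config$n_positions - n_escape
  n_total <- config$n_positions + config$n_homozygous_decoys
  if (n_total == 0L) {
    return(list(records = empty_phased_records(), truth = empty_truth()))
  }

  pos_all <- sort(sample.int(CHRX_LENGTH, n_total))
  type <- sample(c(rep("het", n_het), rep("escape", n_escape),
                   rep("homozygous", config$n_homozygous_decoys)))
  ## two distinct alleles per position: base carried by H1 / H2
  allele_idx <- t(vapply(seq_len(n_total), function(i) sample.int(4L, 2L),
                         integer(2)))
  bases <- c("A", "C", "G", "T")
  b1 <- bases[allele_idx[, 1L]]
  b2 <- bases[allele_idx[, 2L]]

  barcodes <- distinct_dna(config$n_cells, 16L)
  pi_h1 <- config$mosaic_fraction

  truth <- data.frame(
    pos = pos_all,
    true_type = ifelse(type == "het",
                       if (pi_h1 == 0.5) "random" else "skewed", type),
    true_skew = ifelse(type == "escape", 0.5,
                       ifelse(type == "homozygous", 1,
                              max(pi_h1, 1 - pi_h1))),
    escape_barcode = NA_character_, stringsAsFactors = FALSE)

  ## --- molecules (UMIs) at non-escape positions -------------------------
  non_escape <- which(type != "escape")
  mol <- NULL
  if (length(non_escape) > 0L) {
    grid <- data.table::CJ(pos_i = non_escape, cell_i = seq_len(config$n_cells))
    grid <- grid[runif(nrow(grid)) < config$expr_rate]
    if (nrow(grid) > 0L) {
      n_umis <- rztpois(nrow(grid), config$umis_per_cell_position)
      active_h1 <- ifelse(type[grid$pos_i] == "homozygous", TRUE,
                          runif(nrow(grid)) < pi_h1)
      mol <- data.table::data.table(
        pos_i = rep(grid$pos_i, n_umis),
        cell_i = rep(grid$cell_i, n_umis),
        active_h1 = rep(active_h1, n_umis))
      ## leak: monoallelic cells only; decoys have a single allele to emit
      leak <- runif(nrow(mol)) < config$leak_rate &
        type[mol$pos_i] != "homozygous"
      mol[, haplotype := ifelse(xor(active_h1, leak), "H1", "H2")]
      mol[, c("active_h1") := NULL]
      mol[, n_reads := rztpois(.N, config$reads_per_umi)]
    }
  }

  ## --- planted escape positions ----------------------------------------
  esc_rows <- which(type == "escape")
  esc_mol <- NULL
  if (length(esc_rows) > 0L) {
    esc_list <- vector("list", length(esc_rows))
    for (k in seq_along(esc_rows)) {
      i <- esc_rows[k]
      cell <- sample.int(config$n_cells, 1L)
      truth$escape_barcode[i] <- barcodes[cell]
      k1 <- 3L + rpois(1L, config$umis_per_cell_position)
      k2 <- 3L + rpois(1L, config$umis_per_cell_position)
      reads <- rztpois(k1 + k2, config$reads_per_umi)
      ## top up coverage so the planted site clears the default read floor
      j <- 0L
      while (sum(reads) < 10L) {
        j <- j %% length(reads) + 1L
        reads[j] <- reads[j] + 1L
      }
      esc_list[[k]] <- data.table::data.table(
        pos_i = i, cell_i = cell,
        haplotype = rep(c("H1", "H2"), c(k1, k2)), n_reads = reads)
    }
    esc_mol <- data.table::rbindlist(esc_list)
  }

  mol <- data.table::rbindlist(list(mol, esc_mol))
  if (is.null(mol) || nrow(mol) == 0L) {
    return(list(records = empty_phased_records(), truth = truth))
  }

  ## distinct UMIs within each (position, cell)
  mol[, umi := rand_dna(.N, 10L)]
  repeat {
    mol[, is_dup := duplicated(umi), by = .(pos_i, cell_i)]
    if (!any(mol$is_dup)) break
    mol[is_dup == TRUE, umi := rand_dna(.N, 10L)]
  }
  mol[, is_dup := NULL]

  ## --- expand molecules to reads ----------------------------------------
  reads <- mol[rep(seq_len(nrow(mol)), mol$n_reads)]
  records <- data.table::data.table(
    chrom = "chrX",
    pos = pos_all[reads$pos_i],
    base = ifelse(reads$haplotype == "H1", b1[reads$pos_i], b2[reads$pos_i]),
    haplotype = reads$haplotype,
    cell_barcode = barcodes[reads$cell_i],
    umi = reads$umi)
  data.table::setorder(records, pos, cell_barcode, umi)
  records[, read_id := sprintf("r%07d", seq_len(.N))]
  list(records = data.table::setDF(records), truth = truth)
}

empty_truth <- function() {
  data.frame(pos = integer(0), true_type = character(0),
             true_skew = numeric(0), escape_barcode = character(0),
             stringsAsFactors = FALSE)
}

#' Write a complete synthetic fixture to disk
#'
#' Runs [simulate_phased_reads()] and writes everything the pipeline needs:
#' the phased read table, a BED4 file of synthetic gene intervals tiling
#' the simulated positions (so gene mapping is exercised), a known-escape
#' gene list covering a deterministic half of the genes that contain a
#' planted escape site, the truth table, and the configuration as YAML.
#'
#' @param config an [simulation_config()] object.
#' @param out_dir output directory (created if needed).
#' @param genes_per_block number of consecutive positions grouped into one
#'   synthetic gene interval.
#' @return named character vector of the five file paths, invisibly.
#' @export
write_fixture <- function(config = simulation_config(), out_dir,
                          genes_per_block = 5L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_phased_reads(config)
  paths <- c(phased = file.path(out_dir, "phased_table.tsv"),
             bed = file.path(out_dir, "genes.bed"),
             known = file.path(out_dir, "known_escape.txt"),
             truth = file.path(out_dir, "truth.tsv"),
             config = file.path(out_dir, "config.yaml"))
  write_phased_table(sim$records, paths[["phased"]])

  ## synthetic genes: blocks of consecutive simulated positions, padded
  pos <- sim$truth$pos
  bed_lines <- character(0)
  gene_of_pos <- rep(NA_character_, length(pos))
  if (length(pos) > 0L) {
    block <- ceiling(seq_along(pos) / genes_per_block)
    for (bl in unique(block)) {
      p <- pos[block == bl]
      name <- sprintf("SIMG%04d", bl)
      gene_of_pos[block == bl] <- name
      bed_lines <- c(bed_lines, sprintf("chrX\t%d\t%d\t%s",
                                        max(0L, min(p) - 50L),
                                        max(p) + 50L, name))
    }
  }
  writeLines(bed_lines, paths[["bed"]])

  esc_genes <- sort(unique(gene_of_pos[sim$truth$true_type == "escape"]))
  known <- esc_genes[seq_along(esc_genes) %% 2L == 1L]
  writeLines(known, paths[["known"]])

  utils::write.table(sim$truth, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  yaml::write_yaml(unclass(config), paths[["config"]])
  invisible(paths)
}
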