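# Fixtures and independent oracles shared across test files. Oracles are
# deliberately naive (brute force / enumeration) and independent of the
# package's implementation paths.

toy_annotation <- function() {
  data.frame(
    gene_id = c("gA", "gB", "gC", "gD"),
    genome_id = "g1",
    start = c(200L, 1000L, 3000L, 6000L),
    end = c(800L, 2200L, 3600L, 7200L),
    strand = c("+", "-", "+", "-"),
    stringsAsFactors = FALSE
  )
}

bc <- function(i, width = 20L) {
  # deterministic distinct barcodes: base-4 encoding of i
  digits <- integer(width)
  x <- i
  for (p in seq_len(width)) {
    digits[p] <- x %% 4L
    x <- x %/% 4L
  }
  paste(c("A", "C", "G", "T")[digits + 1L], collapse = "")
}

toy_mapping <- function() {
  data.frame(
    barcode = vapply(1:3, bc, ""),
    genome_id = "g1",
    start = c(100L, 900L, 2800L),
    end = c(3100L, 2500L, 6000L),
    vector_orientation = c("+", "-", "+"),
    stringsAsFactors = FALSE
  )
}

toy_sheet <- function() {
  data.frame(
    sample_id = c("t0_1x", "sel_1x"),
    background = "dhisC", inducer = "1x",
    role = c("t0", "selected"), t0_pair = c("", "t0_1x"),
    library_label = "lib1", stringsAsFactors = FALSE
  )
}

# small simulated screen used by several files; returns everything downstream
# analyses need. A fragment pool over a 1 Mb genome with one complementing
# gene kept rare enough that winners clear the fitness cutoff.
small_screen <- function(seed = 11, n_comp = 1L, p_sense = 1, p_antisense = 0,
                         background_mass = 1e-4, t0_dropout = 0.13,
                         n_fragments = 10000L, depth = 1e6,
                         two_experiments = FALSE) {
  cfg <- sim_config(
    seed = seed, genome_length = 1000000L, n_genes = 60L,
    gene_length_range = c(900L, 1200L), n_fragments = n_fragments,
    depth_t0 = depth, depth_sel = depth, p_sense = p_sense,
    p_antisense = p_antisense, background_mass = background_mass,
    t0_dropout = t0_dropout
  )
  genome <- simulate_genome(cfg)
  cfg$complementing_genes <- genome$annotation$gene_id[
    seq(10, by = 17, length.out = n_comp)]
  lib <- shear_library(genome, cfg)
  ex1 <- simulate_experiment(lib, cfg, background = "aux", inducer = "1x",
                             rng_offset = 0L)
  if (two_experiments) {
    ex2 <- simulate_experiment(lib, cfg, background = "aux", inducer = "5x",
                               rng_offset = 1000L)
    ct <- combine_experiments(ex1, ex2)
  } else {
    ct <- ex1$counts
  }
  list(cfg = cfg, genome = genome, lib = lib, ct = ct,
       truth1 = ex1$truth, truth2 = if (two_experiments) ex2$truth else NULL)
}

# a screen sized for orientation-success parameter recovery: >= 500 expected
# carriers detected at t0 while winners stay rare enough to clear the
# fitness cutoff. One selected experiment so that per-insert success equals
# one colony-founding draw.
screen_for_recovery <- function(seed) {
  cfg <- sim_config(
    seed = seed, genome_length = 600000L, n_genes = 60L,
    gene_length_range = c(900L, 1200L), n_fragments = 40000L,
    depth_t0 = 1e6, depth_sel = 1e6
  )
  genome <- simulate_genome(cfg)
  cfg$complementing_genes <- genome$annotation$gene_id[seq(6, 60, by = 12)]
  lib <- shear_library(genome, cfg)
  ex <- simulate_experiment(lib, cfg, background = "aux", inducer = "1x")
  rec <- fitness_table(ex$counts)
  expected <- data.frame(
    protein_id = cfg$complementing_genes, genome_id = genome$genome_id,
    background = "aux", gene_id = cfg$complementing_genes,
    stringsAsFactors = FALSE
  )
  tbl <- covariate_table(expected, lib$mapping, ex$counts, rec,
                         genome$annotation)
  list(cfg = cfg, genome = genome, lib = lib, ct = ex$counts,
       truth = ex$truth, rec = rec, tbl = tbl)
}

random_barcodes_test <- function(n) {
  out <- unique(vapply(sample.int(2^30, 2L * n), bc, ""))
  stopifnot(length(out) >= n)
  out[seq_len(n)]
}

# O(n * m) containment scan
containment_oracle <- function(mapping, annotation) {
  hits <- list()
  for (i in seq_len(nrow(mapping))) {
    for (j in seq_len(nrow(annotation))) {
      if (mapping$genome_id[i] == annotation$genome_id[j] &&
          mapping$start[i] <= annotation$start[j] &&
          annotation$end[j] <= mapping$end[i]) {
        hits[[length(hits) + 1L]] <- c(mapping$barcode[i],
                                       annotation$gene_id[j])
      }
    }
  }
  if (!length(hits)) return(character(0))
  sort(vapply(hits, paste, "", collapse = "|"))
}

# all-pairs Hamming-distance-1 elimination
collapse_oracle <- function(barcodes, counts) {
  n <- length(barcodes)
  mat <- do.call(rbind, strsplit(barcodes, ""))
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (sum(mat[i, ] != mat[j, ]) == 1L && counts[j] > counts[i]) {
        keep[i] <- FALSE
        break
      }
    }
  }
  keep
}

# transitive closure of pairwise interval overlap -> component labels
merge_oracle <- function(start, end) {
  n <- length(start)
  adj <- outer(seq_len(n), seq_len(n), function(i, j) {
    start[i] <= end[j] & start[j] <= end[i]
  })
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (adj[i, j] && comp[j] != comp[i]) {
          m <- min(comp[i], comp[j])
          comp[comp == comp[i] | comp == comp[j]] <- m
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# brute-force triplet scan for rare codons
rare_oracle <- function(cds, rare) {
  n <- 0L
  tot <- 0L
  for (i in seq(1, nchar(cds), 3)) {
    codon <- substr(cds, i, i + 2)
    if (codon %in% c("TAA", "TAG", "TGA")) next
    tot <- tot + 1L
    if (codon %in% rare) n <- n + 1L
  }
  n / tot
}
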