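# Synthetic screens: genomes, sheared barcoded libraries, selection
# experiments and raw BarSeq reads with the statistical structure the
# analysis assumes.
#
# The generator emulates a pooled complementation selection: ~3 kb sheared
# fragments size-selected to a 1.5-5 kb gel window, random 20-nt barcodes,
# log-normal t0 abundances with transformation dropout, plate selection in
# which a fragment carrying a full-length complementing gene founds a colony
# with an orientation-dependent probability, and a small shared "faint
# colony" background mass that survives selection without complementing.

# Each generator draws from its own stream: set.seed(seed + offset).
SEED_OFFSET_GENOME <- 101L
SEED_OFFSET_SHEAR <- 202L
SEED_OFFSET_EXPERIMENT <- 303L
SEED_OFFSET_READS <- 404L

#' Simulation configuration
#'
#' Collects all generator parameters with the screen's study conditions as
#' defaults: a ~3 kb shear (sd 800 nt) gel-selected to 1.5-5 kb, log-normal
#' t0 abundances (sigma 1) with 13% transformation dropout, sense/antisense
#' colony-founding probabilities 0.66/0.35, a 2^10 winner enrichment, a 1e-4
#' background ("faint colony") mass fraction, and a 0.001 per-base read
#' error rate.
#'
#' @param seed integer seed; every generator derives its stream from it.
#' @param genome_length genome size in nt.
#' @param n_genes number of non-overlapping genes to place.
#' @param gene_length_range min/max gene length in nt (rounded to codons).
#' @param gc genome GC fraction.
#' @param n_fragments number of barcoded fragments in the library.
#' @param fragment_mean,fragment_sd fragment-length distribution (nt) before
#'   the gel window truncation.
#' @param fragment_window retained fragment-length window (nt), the gel cut.
#' @param t0_lognormal_sigma sd of log t0 abundances.
#' @param t0_dropout fraction of barcodes lost before t0 sampling.
#' @param depth_t0,depth_sel total reads per t0 / selected sample.
#' @param complementing_genes gene_ids whose full-length carriage can
#'   complement the selection.
#' @param p_sense,p_antisense probability that a carrier founds a colony
#'   when the gene is sense / antisense to the vector promoter.
#' @param enrichment_log2 log2 mass multiplier applied to winners.
#' @param background_mass fraction of post-selection mass shared by
#'   non-winners (faint colonies).
#' @param read_error_rate per-base substitution error rate in emitted reads.
#' @param low_quality_fraction fraction of read positions given a low (Q2)
#'   quality score; all other positions are Q40.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 200000L,
                       n_genes = 60L,
                       gene_length_range = c(600L, 1800L),
                       gc = 0.5,
                       n_fragments = 4000L,
                       fragment_mean = 3000,
                       fragment_sd = 800,
                       fragment_window = c(1500L, 5000L),
                       t0_lognormal_sigma = 1.0,
                       t0_dropout = 0.13,
                       depth_t0 = 1e6,
                       depth_sel = 1e6,
                       complementing_genes = character(0),
                       p_sense = 0.66,
                       p_antisense = 0.35,
                       enrichment_log2 = 10,
                       background_mass = 1e-4,
                       read_error_rate = 0.001,
                       low_quality_fraction = 0) {
  cfg <- list(seed = as.integer(seed), genome_length = as.integer(genome_length),
              n_genes = as.integer(n_genes),
              gene_length_range = as.integer(gene_length_range), gc = gc,
              n_fragments = as.integer(n_fragments),
              fragment_mean = fragment_mean, fragment_sd = fragment_sd,
              fragment_window = as.integer(fragment_window),
              t0_lognormal_sigma = t0_lognormal_sigma, t0_dropout = t0_dropout,
              depth_t0 = depth_t0, depth_sel = depth_sel,
              complementing_genes = complementing_genes,
              p_sense = p_sense, p_antisense = p_antisense,
              enrichment_log2 = enrichment_log2,
              background_mass = background_mass,
              read_error_rate = read_error_rate,
              low_quality_fraction = low_quality_fraction)
  probs <- c(cfg$t0_dropout, cfg$p_sense, cfg$p_antisense, cfg$background_mass,
             cfg$read_error_rate, cfg$low_quality_fraction, cfg$gc)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$depth_t0 <= 0 || cfg$depth_sel <= 0) stop("depths must be > 0")
  if (cfg$fragment_window[1] <= 0 ||
      cfg$fragment_window[2] > cfg$genome_length ||
      cfg$fragment_window[1] > cfg$fragment_window[2]) {
    stop("fragment_window must lie within (0, genome_length]")
  }
  structure(cfg, class = "sim_config")
}

#' Read a simulation configuration from a flat YAML file
#' @param path YAML file whose keys are [sim_config()] arguments.
#' @return a `sim_config`.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(sim_config)))
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  do.call(sim_config, vals)
}

#' Simulate a genome with non-overlapping genes
#'
#' Places `n_genes` non-overlapping genes with random strands on a random
#' ACGT background of the configured GC fraction. Gene bodies are written as
#' stop-free codon runs (ATG ... TAA) on their coding strand so that coding
#' sequence covariates (CAI, rare codons) are well defined.
#'
#' @param config a [sim_config()].
#' @param genome_id name for the simulated genome.
#' @return list with `genome_id`, `sequence` (character string) and
#'   `annotation` (data.frame).
#' @export
simulate_genome <- function(config, genome_id = "simg") {
  set.seed(config$seed + SEED_OFFSET_GENOME)
  L <- config$genome_length
  n <- config$n_genes
  seq <- random_dna(L, gc = config$gc)
  if (n == 0L) {
    ann <- data.frame(gene_id = character(0), genome_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE)
    return(list(genome_id = genome_id, sequence = seq, annotation = ann))
  }
  lens <- sample(seq(config$gene_length_range[1], config$gene_length_range[2]),
                 n, replace = TRUE)
  lens <- pmax(9L, (lens %/% 3L) * 3L)
  free <- L - sum(lens)
  if (free < n + 1L) {
    stop("cannot place ", n, " genes of up to ",
         config$gene_length_range[2], " nt in a ", L, " nt genome")
  }
  gaps <- as.integer(rmultinom(1, free, rep(1, n + 1L))[, 1])
  starts <- cumsum(gaps[seq_len(n)] + c(0L, lens[-n])) + 1L
  ends <- starts + lens - 1L
  strands <- sample(c("+", "-"), n, replace = TRUE)
  # write stop-free coding sequence into each gene body
  fams <- codon_families()
  sense_codons <- setdiff(unlist(fams, use.names = FALSE), "ATG")
  parts <- strsplit(seq, "")[[1]]
  for (i in seq_len(n)) {
    ncod <- lens[i] %/% 3L
    cds <- paste0("ATG",
                  paste(sample(sense_codons, ncod - 2L, replace = TRUE),
                        collapse = ""),
                  "TAA")
    if (strands[i] == "-") cds <- reverse_complement(cds)
    parts[starts[i]:ends[i]] <- strsplit(cds, "")[[1]]
  }
  seq <- paste(parts, collapse = "")
  ann <- data.frame(
    gene_id = sprintf("%s_g%03d", genome_id, seq_len(n)),
    genome_id = genome_id, start = starts, end = ends, strand = strands,
    stringsAsFactors = FALSE
  )
  list(genome_id = genome_id, sequence = seq, annotation = ann)
}

#' Shear a genome into a barcoded fragment library
#'
#' Fragment lengths follow a normal distribution truncated to the gel
#' window; starts are uniform; vector orientations are uniform +/-; barcodes
#' are unique random 20-mers. The returned ground truth records, per
#' barcode, which complementing gene (if any) is carried full length and
#' whether it is sense to the vector promoter.
#'
#' @param genome result of [simulate_genome()] (or a compatible list).
#' @param config a [sim_config()].
#' @return list with `mapping` (data.frame) and `truth` (data.frame with
#'   columns `barcode`, `carries_full_length`, `sense`, `selected_winner`).
#' @export
shear_library <- function(genome, config) {
  set.seed(config$seed + SEED_OFFSET_SHEAR)
  n <- config$n_fragments
  L <- config$genome_length
  win <- config$fragment_window
  lens <- integer(0)
  while (length(lens) < n) {
    cand <- round(rnorm(2L * (n - length(lens)), config$fragment_mean,
                        config$fragment_sd))
    lens <- c(lens, cand[cand >= win[1] & cand <= win[2]])
  }
  lens <- as.integer(lens[seq_len(n)])
  starts <- vapply(lens, function(l) sample.int(L - l + 1L, 1L), integer(1))
  mapping <- data.frame(
    barcode = random_barcodes(n),
    genome_id = genome$genome_id,
    start = starts,
    end = starts + lens - 1L,
    vector_orientation = sample(c("+", "-"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  truth <- data.frame(barcode = mapping$barcode,
                      carries_full_length = NA_character_,
                      sense = NA, selected_winner = NA,
                      stringsAsFactors = FALSE)
  comp <- genome$annotation[
    genome$annotation$gene_id %in% config$complementing_genes, , drop = FALSE]
  if (nrow(comp)) {
    pairs <- containment_pairs(mapping, comp)
    if (nrow(pairs)) {
      ann_strand <- stats::setNames(comp$strand, comp$gene_id)
      orient <- stats::setNames(mapping$vector_orientation, mapping$barcode)
      pairs$sense <- ann_strand[pairs$gene_id] == orient[pairs$barcode]
      # if a fragment carries several complementing genes, a sense copy wins
      pairs <- pairs[order(pairs$barcode, !pairs$sense), , drop = FALSE]
      pairs <- pairs[!duplicated(pairs$barcode), , drop = FALSE]
      idx <- match(pairs$barcode, truth$barcode)
      truth$carries_full_length[idx] <- pairs$gene_id
      truth$sense[idx] <- pairs$sense
    }
  }
  list(mapping = mapping, truth = truth)
}

#' Simulate one selection experiment (t0 + selected sample)
#'
#' t0 relative abundances are log-normal with a `t0_dropout` fraction zeroed
#' before multinomial sampling at `depth_t0`. For the selected sample each
#' barcode that carries a full-length complementing gene and has nonzero t0
#' abundance founds a colony ("wins") with probability `p_sense` or
#' `p_antisense` according to its orientation; winner mass is the t0
#' abundance times `2^enrichment_log2`, and all non-winners collectively
#' share `background_mass` of the post-selection mass (in proportion to t0
#' abundance). If no barcode wins, the post-selection composition is the t0
#' composition. Selected counts are multinomial at `depth_sel`.
#'
#' @param library result of [shear_library()]: list with `mapping`, `truth`.
#' @param config a [sim_config()].
#' @param background mutant background label for the sheet.
#' @param inducer inducer level label for the sheet (e.g. "1x", "5x").
#' @param library_label library label for the sheet.
#' @param rng_offset extra seed offset, so that repeated experiments on the
#'   same library draw independently.
#' @return list with `counts` (a [count_table()] of one t0 and one selected
#'   sample) and `truth` (ground truth with `selected_winner` filled in).
#' @export
simulate_experiment <- function(library, config, background = "aux",
                                inducer = "1x", library_label = "sim",
                                rng_offset = 0L) {
  mapping <- library$mapping
  truth <- library$truth
  if (nrow(mapping) == 0L) stop("mapping is empty")
  set.seed(config$seed + SEED_OFFSET_EXPERIMENT + as.integer(rng_offset))
  n <- nrow(mapping)
  abund <- rlnorm(n, meanlog = 0, sdlog = config$t0_lognormal_sigma)
  abund[runif(n) < config$t0_dropout] <- 0
  if (all(abund == 0)) stop("no barcodes detectable at t0")
  n_t0 <- rmultinom(1, config$depth_t0, abund)[, 1]

  carrier <- !is.na(truth$carries_full_length) & abund > 0
  p_win <- ifelse(truth$sense, config$p_sense, config$p_antisense)
  win <- carrier & runif(n) < ifelse(is.na(p_win), 0, p_win)
  mass <- numeric(n)
  if (any(win)) {
    mass[win] <- abund[win] * 2^config$enrichment_log2
    if (config$background_mass > 0) {
      nw <- !win & abund > 0
      if (any(nw)) {
        bg_total <- sum(mass[win]) * config$background_mass /
          (1 - config$background_mass)
        mass[nw] <- abund[nw] / sum(abund[nw]) * bg_total
      }
    }
  } else {
    mass <- abund
  }
  n_sel <- rmultinom(1, config$depth_sel, mass)[, 1]

  t0_id <- paste0("t0_", inducer)
  sel_id <- paste0("sel_", inducer)
  counts <- data.frame(barcode = mapping$barcode, stringsAsFactors = FALSE)
  counts[[t0_id]] <- as.integer(n_t0)
  counts[[sel_id]] <- as.integer(n_sel)
  sheet <- data.frame(
    sample_id = c(t0_id, sel_id), background = background, inducer = inducer,
    role = c("t0", "selected"), t0_pair = c("", t0_id),
    library_label = library_label, stringsAsFactors = FALSE
  )
  truth$selected_winner <- win
  list(counts = count_table(counts, sheet), truth = truth)
}

#' Combine experiments that share a library into one count table
#' @param ... results of [simulate_experiment()] on the same library.
#' @return a single [count_table()] with all samples.
#' @export
combine_experiments <- function(...) {
  xs <- list(...)
  counts <- xs[[1]]$counts$counts
  sheet <- xs[[1]]$counts$sheet
  for (x in xs[-1]) {
    add <- x$counts$counts
    if (!identical(add$barcode, counts$barcode)) {
      stop("experiments do not share a barcode universe")
    }
    counts <- cbind(counts, add[, -1, drop = FALSE])
    sheet <- rbind(sheet, x$counts$sheet)
  }
  count_table(counts, sheet)
}

# Fixed read layout: upstream flank + barcode + downstream flank, from the
# barcoding primer (...CGTACG <N20> AGAGACCTCGTGGACATC...).
READ_UPSTREAM <- "GTCGACCTGCAGCGTACG"
READ_DOWNSTREAM <- "AGAGACCTCGTGGACATC"

#' Emit raw BarSeq reads (FASTQ) from a count table
#'
#' Writes one read per counted unit: upstream flank + barcode + downstream
#' flank, with per-base substitution errors at `read_error_rate`. Qualities
#' are Q40 everywhere except a `low_quality_fraction` of positions set to
#' Q2.
#'
#' @param ct a [count_table()].
#' @param config a [sim_config()] (error model and seed).
#' @param dir output directory; one `<sample_id>.fastq` per sample.
#' @return named character vector of FASTQ paths.
#' @export
emit_barseq_reads <- function(ct, config, dir) {
  stopifnot(inherits(ct, "count_table"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set.seed(config$seed + SEED_OFFSET_READS)
  paths <- character(0)
  for (s in ct$sheet$sample_id) {
    cnt <- ct$counts[[s]]
    bc <- rep(ct$counts$barcode, cnt)
    reads <- paste0(READ_UPSTREAM, bc, READ_DOWNSTREAM)
    rl <- nchar(READ_UPSTREAM) + 20L + nchar(READ_DOWNSTREAM)
    nb <- length(reads) * rl
    if (config$read_error_rate > 0 && nb > 0) {
      k <- rbinom(1, nb, config$read_error_rate)
      if (k > 0) {
        pos <- sample.int(nb, k)
        ri <- (pos - 1L) %/% rl + 1L
        pi <- (pos - 1L) %% rl + 1L
        for (j in seq_len(k)) {
          old <- substr(reads[ri[j]], pi[j], pi[j])
          substr(reads[ri[j]], pi[j], pi[j]) <-
            sample(setdiff(DNA_BASES, old), 1L)
        }
      }
    }
    qual <- strrep("I", rl)  # Q40
    quals <- rep(qual, length(reads))
    if (config$low_quality_fraction > 0 && nb > 0) {
      k <- rbinom(1, nb, config$low_quality_fraction)
      if (k > 0) {
        pos <- sample.int(nb, k)
        ri <- (pos - 1L) %/% rl + 1L
        pi <- (pos - 1L) %% rl + 1L
        for (j in seq_len(k)) substr(quals[ri[j]], pi[j], pi[j]) <- "#"  # Q2
      }
    }
    path <- file.path(dir, paste0(s, ".fastq"))
    x <- Biostrings::DNAStringSet(reads)
    names(x) <- sprintf("%s_read%07d", s, seq_along(reads))
    Biostrings::writeXStringSet(x, path, format = "fastq",
                                qualities = Biostrings::BStringSet(quals))
    paths[s] <- path
  }
  paths
}

#' Write a complete simulated dataset to disk
#'
#' Convenience wrapper emitting the FASTA genome, GFF3 annotation, mapping
#' TSV, counts + sheet TSVs and the ground-truth TSV for one simulated
#' screen.
#'
#' @param dir output directory.
#' @param genome result of [simulate_genome()].
#' @param library result of [shear_library()].
#' @param ct a [count_table()].
#' @param truth ground-truth data.frame.
#' @return named vector of written paths.
#' @export
write_sim_dataset <- function(dir, genome, library, ct, truth) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    fasta = write_genome_fasta(
      stats::setNames(genome$sequence, genome$genome_id),
      file.path(dir, "genome.fasta")),
    gff3 = write_annotation_gff3(genome$annotation,
                                 file.path(dir, "annotation.gff3")),
    mapping = write_mapping_table(library$mapping,
                                  file.path(dir, "mapping.tsv")),
    counts = write_count_table(ct, file.path(dir, "counts.tsv"),
                               file.path(dir, "sheet.tsv"))
  )
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  c(paths, truth = file.path(dir, "truth.tsv"))
}
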