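# Expected-hit recovery: containment / t0-detection / orientation status per
# expected protein, success rates with exact binomial CIs, inducer
# concordance, and sequence covariates (GC, CAI, rare codons) with their
# tests.

#' Classify each expected hit by library containment, t0 detection,
#' orientation and recovery
#'
#' For every a-priori expected complementing protein the function computes,
#' never takes as input: whether any library fragment fully contains the
#' gene (`in_library_full_length`), whether any carrying barcode has > 0
#' reads in a t0 sample (`detected_t0`), whether any carrier is sense to the
#' vector promoter (`any_sense_insert`), and the recovery status
#' (`full_length` if a high-confidence hit's insert fully contains the gene,
#' `nearly_full_length` under the near-containment rule, otherwise
#' `not_recovered`).
#'
#' @param expected expected-hit table (see [read_expected_table()]).
#' @param mapping mapping data.frame.
#' @param ct a [count_table()] (t0 detection).
#' @param hits hits from [confirm_hits()].
#' @param annotation annotation data.frame.
#' @param nearly_threshold near-containment fraction (default 0.9).
#' @return `expected` with the four status columns added.
#' @export
classify_expected <- function(expected, mapping, ct, hits, annotation,
                              nearly_threshold = 0.9) {
  stopifnot(inherits(ct, "count_table"))
  ann_idx <- match(expected$gene_id, annotation$gene_id)
  if (anyNA(ann_idx)) {
    stop("expected gene(s) absent from annotation: ",
         paste(unique(expected$gene_id[is.na(ann_idx)]), collapse = ", "))
  }
  pairs <- containment_pairs(mapping, annotation[unique(ann_idx), , drop = FALSE])
  t0_samples <- ct$sheet$sample_id[ct$sheet$role == "t0"]
  t0_reads <- rowSums(ct$counts[, t0_samples, drop = FALSE])
  detected <- ct$counts$barcode[t0_reads > 0]
  orient <- stats::setNames(mapping$vector_orientation, mapping$barcode)

  n <- nrow(expected)
  in_lib <- logical(n); det <- logical(n); sense <- logical(n)
  for (i in seq_len(n)) {
    carriers <- pairs$barcode[pairs$gene_id == expected$gene_id[i]]
    in_lib[i] <- length(carriers) > 0
    det[i] <- any(carriers %in% detected)
    sense[i] <- any(orient[carriers] == annotation$strand[ann_idx[i]])
  }
  expected$in_library_full_length <- in_lib
  expected$detected_t0 <- det
  expected$any_sense_insert <- sense
  expected$recovered <- recovered_expected(expected, hits, annotation,
                                           nearly_threshold)
  expected
}

#' Per-insert covariate table for expected genes
#'
#' One row per (expected gene, carrying insert): the insert's orientation
#' relative to the gene (`sense` iff the gene's strand equals the insert's
#' vector orientation), whether the insert was detected at t0, whether it
#' showed a significant benefit in any experiment of the expected
#' background (`success`), the insert's GC fraction, and the gene's CAI and
#' rare-codon fraction. Per-insert rows are used because one gene may ride
#' several inserts.
#'
#' @param expected expected-hit table.
#' @param mapping mapping data.frame.
#' @param ct a [count_table()].
#' @param records fitness records from [fitness_table()].
#' @param annotation annotation data.frame.
#' @param genome_seqs named character vector of genome sequences, or `NULL`
#'   to skip the sequence covariates.
#' @param params a [fitness_params()] (significance thresholds).
#' @return data.frame with one row per (gene, insert) pair: `gene_id`,
#'   `background`, `barcode`, `genome_id`, `orientation`, `detected_t0`,
#'   `success`, and when sequences are given `gc_fraction`, `cai`,
#'   `rare_codon_fraction` (plus `rbs_strength` if present in `expected`).
#' @export
covariate_table <- function(expected, mapping, ct, records, annotation,
                            genome_seqs = NULL, params = fitness_params()) {
  ann_idx <- match(expected$gene_id, annotation$gene_id)
  if (anyNA(ann_idx)) {
    stop("expected gene(s) absent from annotation: ",
         paste(unique(expected$gene_id[is.na(ann_idx)]), collapse = ", "))
  }
  pairs <- containment_pairs(mapping, annotation[unique(ann_idx), , drop = FALSE])
  if (!nrow(pairs)) {
    return(data.frame(gene_id = character(0), background = character(0),
                      barcode = character(0), stringsAsFactors = FALSE))
  }
  t0_samples <- ct$sheet$sample_id[ct$sheet$role == "t0"]
  t0_reads <- rowSums(ct$counts[, t0_samples, drop = FALSE])
  detected <- ct$counts$barcode[t0_reads > 0]
  records$significant <- flag_significant(records, params)
  sig_key <- unique(paste(records$barcode[records$significant],
                          records$background[records$significant],
                          sep = "\r"))
  map_idx <- stats::setNames(seq_len(nrow(mapping)), mapping$barcode)

  rows <- list()
  for (i in seq_len(nrow(expected))) {
    gene <- annotation[ann_idx[i], ]
    carriers <- pairs$barcode[pairs$gene_id == expected$gene_id[i]]
    if (!length(carriers)) next
    mi <- map_idx[carriers]
    rows[[i]] <- data.frame(
      gene_id = expected$gene_id[i],
      background = expected$background[i],
      barcode = carriers,
      genome_id = mapping$genome_id[mi],
      orientation = ifelse(mapping$vector_orientation[mi] == gene$strand,
                           "sense", "antisense"),
      detected_t0 = carriers %in% detected,
      success = paste(carriers, expected$background[i], sep = "\r") %in% sig_key,
      stringsAsFactors = FALSE
    )
    if (!is.null(expected$rbs_strength)) {
      rows[[i]]$rbs_strength <- expected$rbs_strength[i]
    }
  }
  tbl <- do.call(rbind, rows)
  rownames(tbl) <- NULL
  if (!is.null(genome_seqs) && nrow(tbl)) {
    mi <- map_idx[tbl$barcode]
    ins_seq <- substr(genome_seqs[mapping$genome_id[mi]], mapping$start[mi],
                      mapping$end[mi])
    tbl$gc_fraction <- vapply(ins_seq, gc_content, numeric(1),
                              USE.NAMES = FALSE)
    genes <- unique(tbl$gene_id)
    gann <- annotation[match(genes, annotation$gene_id), , drop = FALSE]
    cds <- gene_cds(gann, genome_seqs)
    cai_by_gene <- vapply(cds, cai, numeric(1))
    rare_by_gene <- vapply(cds, rare_codon_fraction, numeric(1))
    tbl$cai <- unname(cai_by_gene[tbl$gene_id])
    tbl$rare_codon_fraction <- unname(rare_by_gene[tbl$gene_id])
  }
  tbl
}

#' Success rate with exact binomial confidence interval
#'
#' Rates are successes / n per group with a central Clopper-Pearson interval
#' (exact binomial; the conservative default when only "binomial test" is
#' specified).
#'
#' @param success logical vector.
#' @param group grouping vector (e.g. orientation).
#' @param conf_level confidence level (default 0.90).
#' @return data.frame per group: `group`, `n`, `successes`, `rate`, `lower`,
#'   `upper`. Empty groups are omitted with a warning.
#' @export
success_rate <- function(success, group, conf_level = 0.90) {
  stopifnot(length(success) == length(group))
  levels <- unique(as.character(group))
  alpha <- 1 - conf_level
  rows <- lapply(levels, function(g) {
    x <- success[group == g]
    x <- x[!is.na(x)]
    n <- length(x)
    if (n == 0L) {
      warning("group '", g, "' is empty; omitted")
      return(NULL)
    }
    k <- sum(x)
    data.frame(
      group = g, n = n, successes = k, rate = k / n,
      lower = if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1),
      upper = if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# rank inducer labels like "1x", "5x" by their numeric part
inducer_level <- function(x) {
  as.numeric(gsub("[^0-9.]", "", x))
}

#' Concordance of significance across inducer levels
#'
#' Among inserts significant at the lower inducer concentration, the
#' fraction also significant at the higher concentration -- overall and
#' restricted to inserts whose low-inducer benefit was confirmed by an
#' overlapping significant insert in the same experiment. Backgrounds
#' without two inducer levels are skipped with a warning.
#'
#' @param records fitness records (two inducer levels per background).
#' @param mapping mapping data.frame (for overlap confirmation).
#' @param params a [fitness_params()].
#' @return list with counts and proportions: `n_low`, `n_concordant`,
#'   `concordance`, `n_low_overlap`, `n_concordant_overlap`,
#'   `concordance_overlap`, and a `per_background` data.frame.
#' @export
inducer_concordance <- function(records, mapping, params = fitness_params()) {
  records$significant <- flag_significant(records, params)
  per_bg <- list()
  for (bg in unique(records$background)) {
    sub <- records[records$background == bg, , drop = FALSE]
    levs <- unique(sub$inducer)
    if (length(levs) < 2L) {
      warning("background '", bg, "' lacks two inducer levels; skipped")
      next
    }
    ranks <- inducer_level(levs)
    low <- levs[which.min(ranks)]
    high <- levs[which.max(ranks)]
    sig_low <- unique(sub$barcode[sub$significant & sub$inducer == low])
    sig_high <- unique(sub$barcode[sub$significant & sub$inducer == high])
    low_recs <- sub[sub$significant & sub$inducer == low, , drop = FALSE]
    ov_keys <- overlap_confirmed_barcodes(low_recs, mapping)
    ov_low <- intersect(sig_low,
                        vapply(strsplit(ov_keys, "\r", fixed = TRUE),
                               `[`, "", 1L))
    per_bg[[bg]] <- data.frame(
      background = bg,
      n_low = length(sig_low),
      n_concordant = sum(sig_low %in% sig_high),
      n_low_overlap = length(ov_low),
      n_concordant_overlap = sum(ov_low %in% sig_high),
      stringsAsFactors = FALSE
    )
  }
  tab <- do.call(rbind, per_bg)
  if (is.null(tab)) stop("no background has two inducer levels")
  n_low <- sum(tab$n_low)
  n_conc <- sum(tab$n_concordant)
  n_lo <- sum(tab$n_low_overlap)
  n_co <- sum(tab$n_concordant_overlap)
  list(
    n_low = n_low, n_concordant = n_conc,
    concordance = if (n_low > 0) n_conc / n_low else NA_real_,
    n_low_overlap = n_lo, n_concordant_overlap = n_co,
    concordance_overlap = if (n_lo > 0) n_co / n_lo else NA_real_,
    per_background = tab
  )
}

#' GC fraction of a nucleotide sequence
#' @param sequence ACGT string.
#' @return (G + C) / length.
#' @export
gc_content <- function(sequence) {
  if (is.na(sequence) || nchar(sequence) == 0L) stop("empty sequence")
  bases <- strsplit(toupper(sequence), "")[[1]]
  mean(bases %in% c("G", "C"))
}

# default relative-adaptiveness table: codon usage of highly expressed
# E. coli genes (Sharp & Li reference, as distributed with seqinr's caitab)
default_cai_w <- function() {
  env <- new.env()
  utils::data("caitab", package = "seqinr", envir = env)
  w <- env$caitab$ec
  stats::setNames(w, toupper(rownames(env$caitab)))
}

#' Codon adaptation index
#'
#' CAI is the geometric mean, over the codons of a coding sequence, of each
#' codon's relative adaptiveness `w = usage / max usage among synonyms` in a
#' reference set of highly expressed genes. Stop codons and the
#' single-codon families (ATG, TGG) are excluded; an internal stop codon is
#' skipped with a warning. Codons unused in the reference set (adaptiveness
#' below 1e-4) are assigned 0.01 so a single absent codon does not zero the
#' index.
#'
#' @param cds coding sequence (ACGT, length a multiple of 3).
#' @param usage named numeric vector over the 61 sense codons: either raw
#'   usage frequencies or already-normalized w values (normalization within
#'   synonym families is applied either way). Defaults to the highly
#'   expressed E. coli reference.
#' @return CAI in (0, 1].
#' @export
cai <- function(cds, usage = NULL) {
  cds <- toupper(cds)
  if (grepl("[^ACGT]", cds)) stop("CDS contains non-ACGT characters")
  if (nchar(cds) %% 3 != 0) stop("CDS length is not a multiple of 3")
  if (is.null(usage)) usage <- default_cai_w()
  names(usage) <- toupper(names(usage))
  fams <- codon_families()
  w <- usage
  for (fam in fams) {
    fam <- intersect(fam, names(usage))   # partial tables: known codons only
    if (!length(fam)) next
    w[fam] <- usage[fam] / max(usage[fam])
  }
  w[w < 1e-4] <- 0.01
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  stops <- c("TAA", "TAG", "TGA")
  is_stop <- codons %in% stops
  if (any(is_stop[-length(codons)])) {
    warning("internal stop codon(s) skipped")
  }
  codons <- codons[!is_stop & !codons %in% c("ATG", "TGG")]
  if (!length(codons)) stop("no codons usable for CAI")
  if (!all(codons %in% names(w))) {
    stop("reference usage does not cover codon(s): ",
         paste(unique(setdiff(codons, names(w))), collapse = ", "))
  }
  exp(mean(log(w[codons])))
}

RARE_CODONS <- c("ATA", "CGG", "CGA", "CTA", "AGA", "AGG", "GGA", "CCC")

#' Fraction of codons that are rare in the expression host
#'
#' Counts the eight codons rare in E. coli (ATA, CGG, CGA, CTA, AGA, AGG,
#' GGA, CCC) over all non-stop codons of the coding sequence.
#'
#' @param cds coding sequence (ACGT, length a multiple of 3).
#' @param rare set of rare codons.
#' @return fraction in [0, 1].
#' @export
rare_codon_fraction <- function(cds, rare = RARE_CODONS) {
  cds <- toupper(cds)
  if (grepl("[^ACGT]", cds)) stop("CDS contains non-ACGT characters")
  if (nchar(cds) %% 3 != 0) stop("CDS length is not a multiple of 3")
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  codons <- codons[!codons %in% c("TAA", "TAG", "TGA")]
  if (!length(codons)) return(0)
  mean(codons %in% rare)
}

#' Covariate tests between successful and unsuccessful cases
#'
#' Two-sided Wilcoxon rank-sum tests comparing each covariate between
#' successes and failures, with group sizes and medians. Covariates with a
#' group of fewer than 2 observations are skipped with a warning.
#'
#' @param tbl covariate table from [covariate_table()] (needs a logical
#'   `success` column).
#' @param covariates covariate columns to test (missing ones are ignored).
#' @return data.frame: `covariate`, `n_success`, `n_fail`, `median_success`,
#'   `median_fail`, `p_value`.
#' @export
covariate_tests <- function(tbl, covariates = c("gc_fraction", "cai",
                                                "rare_codon_fraction",
                                                "rbs_strength")) {
  covariates <- intersect(covariates, names(tbl))
  rows <- lapply(covariates, function(cv) {
    x <- tbl[[cv]][tbl$success]
    y <- tbl[[cv]][!tbl$success]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2L || length(y) < 2L) {
      warning("covariate '", cv, "': a group has < 2 observations; skipped")
      return(NULL)
    }
    p <- suppressWarnings(stats::wilcox.test(x, y)$p.value)
    data.frame(covariate = cv, n_success = length(x), n_fail = length(y),
               median_success = stats::median(x), median_fail = stats::median(y),
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-library RBS strength comparison
#'
#' For each library (source genome), a two-sided t test of that library's
#' RBS strengths against all other libraries', Bonferroni-corrected for the
#' number of libraries tested.
#'
#' @param tbl covariate table with `rbs_strength` and a library column.
#' @param library_col grouping column (default `genome_id`).
#' @return data.frame: `library`, `n`, `mean_rbs`, `mean_rbs_other`,
#'   `p_value`, `p_adjusted` (Bonferroni x number of libraries).
#' @export
rbs_library_tests <- function(tbl, library_col = "genome_id") {
  if (is.null(tbl$rbs_strength)) stop("no rbs_strength column")
  libs <- unique(tbl[[library_col]])
  rows <- lapply(libs, function(l) {
    x <- tbl$rbs_strength[tbl[[library_col]] == l]
    y <- tbl$rbs_strength[tbl[[library_col]] != l]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2L || length(y) < 2L) {
      warning("library '", l, "' has too few RBS values; skipped")
      return(NULL)
    }
    p <- stats::t.test(x, y)$p.value
    data.frame(library = l, n = length(x), mean_rbs = mean(x),
               mean_rbs_other = mean(y), p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(out)) out$p_adjusted <- pmin(1, out$p_value * length(libs))
  rownames(out) <- NULL
  out
}
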