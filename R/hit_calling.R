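# Hit calling: significance flags, confirmation (overlap / replicate),
# region merging, gene association, cutoff sensitivity.
#
# A fragment's benefit is "significant" when fitness > tau_f and z > tau_z
# (strict, thresholds 5 and 4 by default). A significant (barcode,
# background) is "high-confidence" when either an overlapping fragment was
# significant in the same experiment, or the fragment was significant in
# another experiment of the same background (any induction level).

#' Flag significant fitness records
#' @param records fitness records from [fitness_table()].
#' @param params a [fitness_params()] (thresholds).
#' @return logical vector, one per record: `f > tau_f & z > tau_z`.
#' @export
flag_significant <- function(records, params = fitness_params()) {
  records$f > params$tau_f & records$z > params$tau_z
}

#' Distinct (barcode, background) pairs significant in >= 1 experiment
#'
#' The pre-confirmation layer of hit counting: every fragment x mutant
#' background combination that provided a significant benefit in at least
#' one experiment.
#'
#' @inheritParams flag_significant
#' @return data.frame `barcode`, `background`.
#' @export
significant_instances <- function(records, params = fitness_params()) {
  sig <- records[flag_significant(records, params), c("barcode", "background")]
  unique(sig)
}

# barcodes that have an overlapping significant partner, per experiment
overlap_confirmed_barcodes <- function(sig_records, mapping) {
  out <- character(0)
  idx <- match(sig_records$barcode, mapping$barcode)
  sig_records$genome_id <- mapping$genome_id[idx]
  sig_records$start <- mapping$start[idx]
  sig_records$end <- mapping$end[idx]
  for (ex in unique(sig_records$experiment_id)) {
    for (g in unique(sig_records$genome_id)) {
      sub <- sig_records[sig_records$experiment_id == ex &
                           sig_records$genome_id == g, , drop = FALSE]
      if (nrow(sub) < 2L) next
      ir <- IRanges::IRanges(sub$start, sub$end)
      ov <- IRanges::findOverlaps(ir, ir)
      partnered <- unique(S4Vectors::queryHits(ov)[
        S4Vectors::queryHits(ov) != S4Vectors::subjectHits(ov)])
      out <- c(out, paste(sub$barcode[partnered], sub$background[partnered],
                          sep = "\r"))
    }
  }
  unique(out)
}

#' Confirm significant hits
#'
#' Classifies every significant (barcode, background) by its confirmation:
#' `overlap_same_experiment` (an overlapping fragment on the same genome was
#' significant in the same experiment), `replicate_other_experiment`
#' (significant in >= 2 distinct experiments of that background), `both`, or
#' `none`. High confidence requires confirmation other than `none`.
#' Significant barcodes absent from the mapping cannot be placed and are
#' excluded with a warning (returned in the `unmapped` attribute).
#'
#' @param records fitness records from [fitness_table()].
#' @param mapping mapping data.frame.
#' @param params a [fitness_params()].
#' @return data.frame of hits: `barcode`, `background`, `genome_id`,
#'   `start`, `end`, `n_experiments_significant`, `significant_in`
#'   (';'-joined experiment ids), `confirmation`, `high_confidence`,
#'   `mean_f` (mean fitness across that background's experiments).
#' @export
confirm_hits <- function(records, mapping, params = fitness_params()) {
  records$significant <- flag_significant(records, params)
  sig <- records[records$significant, , drop = FALSE]
  empty <- data.frame(
    barcode = character(0), background = character(0),
    genome_id = character(0), start = integer(0), end = integer(0),
    n_experiments_significant = integer(0), significant_in = character(0),
    confirmation = character(0), high_confidence = logical(0),
    mean_f = numeric(0), stringsAsFactors = FALSE
  )
  if (!nrow(sig)) return(empty)
  unmapped <- setdiff(sig$barcode, mapping$barcode)
  if (length(unmapped)) {
    warning(length(unmapped),
            " significant barcode(s) missing from mapping; excluded")
    sig <- sig[!sig$barcode %in% unmapped, , drop = FALSE]
    if (!nrow(sig)) {
      attr(empty, "unmapped") <- unmapped
      return(empty)
    }
  }
  overlap_keys <- overlap_confirmed_barcodes(sig, mapping)

  key <- paste(sig$barcode, sig$background, sep = "\r")
  groups <- split(sig$experiment_id, key)
  keys <- names(groups)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  barcode <- vapply(parts, `[`, "", 1L)
  background <- vapply(parts, `[`, "", 2L)
  n_exp <- vapply(groups, function(x) length(unique(x)), integer(1))
  sig_in <- vapply(groups, function(x) paste(sort(unique(x)), collapse = ";"),
                   character(1))
  by_overlap <- keys %in% overlap_keys
  by_replicate <- n_exp >= 2L
  confirmation <- ifelse(by_overlap & by_replicate, "both",
                  ifelse(by_overlap, "overlap_same_experiment",
                  ifelse(by_replicate, "replicate_other_experiment", "none")))
  mf <- background_mean_fitness(records)
  mf_key <- paste(mf$barcode, mf$background, sep = "\r")
  idx <- match(barcode, mapping$barcode)
  hits <- data.frame(
    barcode = barcode, background = background,
    genome_id = mapping$genome_id[idx],
    start = mapping$start[idx], end = mapping$end[idx],
    n_experiments_significant = n_exp, significant_in = sig_in,
    confirmation = confirmation, high_confidence = confirmation != "none",
    mean_f = mf$mean_f[match(keys, mf_key)],
    stringsAsFactors = FALSE
  )
  hits <- hits[order(hits$background, hits$genome_id, hits$start, hits$barcode), ,
               drop = FALSE]
  rownames(hits) <- NULL
  if (length(unmapped)) attr(hits, "unmapped") <- unmapped
  hits
}

#' Merge overlapping high-confidence hits into regions
#'
#' Within each (background, genome), high-confidence inserts are grouped
#' into connected components of the interval-overlap graph (overlap = >= 1
#' shared bp; components are transitive, so a chain A-B-C forms one region
#' even if A and C do not touch). The region interval is the union span of
#' its members.
#'
#' @param hits hits data.frame from [confirm_hits()].
#' @return data.frame of regions: `region_id`, `background`, `genome_id`,
#'   `start`, `end`, `n_members`, `member_barcodes` (';'-joined), ordered by
#'   background, genome, start.
#' @export
merge_regions <- function(hits) {
  hc <- hits[hits$high_confidence, , drop = FALSE]
  out <- list()
  if (nrow(hc)) {
    grp <- split(hc, paste(hc$background, hc$genome_id, sep = "\r"))
    for (sub in grp) {
      sub <- sub[order(sub$start, sub$end, sub$barcode), , drop = FALSE]
      reg <- integer(nrow(sub))
      cur <- 1L
      max_end <- sub$end[1]
      reg[1] <- 1L
      for (i in seq_len(nrow(sub))[-1]) {
        if (sub$start[i] > max_end) cur <- cur + 1L  # no shared bp: new region
        reg[i] <- cur
        max_end <- max(max_end, sub$end[i])
      }
      pieces <- split(sub, reg)
      out[[length(out) + 1L]] <- do.call(rbind, lapply(pieces, function(p) {
        data.frame(background = p$background[1], genome_id = p$genome_id[1],
                   start = min(p$start), end = max(p$end),
                   n_members = nrow(p),
                   member_barcodes = paste(p$barcode, collapse = ";"),
                   stringsAsFactors = FALSE)
      }))
    }
  }
  if (!length(out)) {
    return(data.frame(region_id = character(0), background = character(0),
                      genome_id = character(0), start = integer(0),
                      end = integer(0), n_members = integer(0),
                      member_barcodes = character(0), stringsAsFactors = FALSE))
  }
  regions <- do.call(rbind, out)
  regions <- regions[order(regions$background, regions$genome_id,
                           regions$start), , drop = FALSE]
  regions <- cbind(region_id = sprintf("R%04d", seq_len(nrow(regions))),
                   regions)
  rownames(regions) <- NULL
  regions
}

# does the insert cover >= threshold of the gene including its start codon?
nearly_contains <- function(ins_start, ins_end, gene_start, gene_end, strand,
                            threshold = 0.9) {
  ov <- pmin(ins_end, gene_end) - pmax(ins_start, gene_start) + 1
  frac <- pmax(ov, 0) / (gene_end - gene_start + 1)
  start_cov <- ifelse(strand == "+",
                      ins_start <= gene_start & ins_end >= gene_start + 2,
                      ins_end >= gene_end & ins_start <= gene_end - 2)
  frac >= threshold & start_cov
}

#' Associate regions with causative genes
#'
#' For each region, the insert with the highest mean fitness (across that
#' background's experiments) is selected -- ties broken by longer insert,
#' then lexicographic barcode -- and the region is associated with all genes
#' fully contained in that insert. Regions are classified by ORF content:
#' `one_orf`, `multi_orf`, or `no_full_orf`. Genes that are nearly full
#' length on the best insert (>= `nearly_threshold` of the gene covered,
#' including the start codon, but not fully contained) are reported
#' separately and do not count toward the ORF class.
#'
#' @param regions regions from [merge_regions()].
#' @param hits hits from [confirm_hits()] (provides member coordinates and
#'   mean fitness).
#' @param annotation annotation data.frame.
#' @param nearly_threshold covered fraction of the gene counted as "nearly
#'   full length" (default 0.9).
#' @return `regions` with columns `best_barcode`, `best_mean_f`,
#'   `associated_genes` (';'-joined), `n_orfs`, `orf_class`,
#'   `nearly_full_genes` added.
#' @export
associate_genes <- function(regions, hits, annotation, nearly_threshold = 0.9) {
  n <- nrow(regions)
  best_barcode <- character(n)
  best_mean_f <- numeric(n)
  associated <- character(n)
  n_orfs <- integer(n)
  nearly <- character(n)
  hit_key <- paste(hits$barcode, hits$background, sep = "\r")
  for (i in seq_len(n)) {
    members <- strsplit(regions$member_barcodes[i], ";", fixed = TRUE)[[1]]
    sub <- hits[match(paste(members, regions$background[i], sep = "\r"),
                      hit_key), , drop = FALSE]
    len <- sub$end - sub$start + 1L
    ord <- order(-sub$mean_f, -len, sub$barcode)
    best <- sub[ord[1], , drop = FALSE]
    best_barcode[i] <- best$barcode
    best_mean_f[i] <- best$mean_f
    ann <- annotation[annotation$genome_id == best$genome_id, , drop = FALSE]
    full <- ann$start >= best$start & ann$end <= best$end
    genes <- ann$gene_id[full][order(ann$start[full])]
    associated[i] <- paste(genes, collapse = ";")
    n_orfs[i] <- length(genes)
    near <- !full & nearly_contains(best$start, best$end, ann$start, ann$end,
                                    ann$strand, nearly_threshold)
    nearly[i] <- paste(ann$gene_id[near][order(ann$start[near])],
                       collapse = ";")
  }
  regions$best_barcode <- best_barcode
  regions$best_mean_f <- best_mean_f
  regions$associated_genes <- associated
  regions$n_orfs <- n_orfs
  regions$orf_class <- ifelse(n_orfs == 0L, "no_full_orf",
                              ifelse(n_orfs == 1L, "one_orf", "multi_orf"))
  regions$nearly_full_genes <- nearly
  regions
}

#' Scan sensitivity of the pipeline to the fitness cutoff
#'
#' Re-runs significance flagging, confirmation, region merging and expected
#' hit recovery at each fitness cutoff in `tau_f_grid` (the z cutoff is held
#' at `params$tau_z`), reporting how the number of recovered expected hits
#' and unexpected regions trade off as the cutoff rises.
#'
#' @param records fitness records.
#' @param mapping mapping data.frame.
#' @param annotation annotation data.frame.
#' @param expected expected-hit table (see [read_expected_table()]).
#' @param tau_f_grid fitness cutoffs to evaluate.
#' @param params baseline [fitness_params()].
#' @param nearly_threshold passed to recovery classification.
#' @return data.frame with one row per cutoff: `tau_f`,
#'   `n_significant_instances`, `n_high_confidence`, `n_regions`,
#'   `n_expected_recovered`, `n_unexpected_regions`.
#' @export
cutoff_scan <- function(records, mapping, annotation, expected,
                        tau_f_grid = c(5, 6, 7), params = fitness_params(),
                        nearly_threshold = 0.9) {
  rows <- lapply(tau_f_grid, function(tf) {
    p <- fitness_params(pseudocount = params$pseudocount, tau_f = tf,
                        tau_z = params$tau_z)
    inst <- significant_instances(records, p)
    hits <- suppressWarnings(confirm_hits(records, mapping, p))
    regions <- merge_regions(hits)
    if (nrow(regions)) {
      regions <- associate_genes(regions, hits, annotation, nearly_threshold)
    }
    rec <- recovered_expected(expected, hits, annotation, nearly_threshold)
    n_unexp <- 0L
    if (nrow(regions)) {
      for (i in seq_len(nrow(regions))) {
        genes <- strsplit(paste(regions$associated_genes[i],
                                regions$nearly_full_genes[i], sep = ";"),
                          ";", fixed = TRUE)[[1]]
        genes <- genes[nzchar(genes)]
        exp_genes <- expected$gene_id[expected$background ==
                                        regions$background[i]]
        if (!any(genes %in% exp_genes)) n_unexp <- n_unexp + 1L
      }
    }
    data.frame(tau_f = tf, n_significant_instances = nrow(inst),
               n_high_confidence = sum(hits$high_confidence),
               n_regions = nrow(regions),
               n_expected_recovered = sum(rec != "not_recovered"),
               n_unexpected_regions = n_unexp)
  })
  do.call(rbind, rows)
}

# recovery status of each expected row given high-confidence hits
recovered_expected <- function(expected, hits, annotation,
                               nearly_threshold = 0.9) {
  if (!nrow(expected)) return(character(0))
  hc <- hits[hits$high_confidence, , drop = FALSE]
  status <- rep("not_recovered", nrow(expected))
  ann_idx <- match(expected$gene_id, annotation$gene_id)
  if (anyNA(ann_idx)) {
    stop("expected gene(s) absent from annotation: ",
         paste(unique(expected$gene_id[is.na(ann_idx)]), collapse = ", "))
  }
  for (i in seq_len(nrow(expected))) {
    g <- annotation[ann_idx[i], ]
    sub <- hc[hc$background == expected$background[i] &
                hc$genome_id == g$genome_id, , drop = FALSE]
    if (!nrow(sub)) next
    if (any(sub$start <= g$start & sub$end >= g$end)) {
      status[i] <- "full_length"
    } else if (any(nearly_contains(sub$start, sub$end, g$start, g$end,
                                   g$strand, nearly_threshold))) {
      status[i] <- "nearly_full_length"
    }
  }
  status
}
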