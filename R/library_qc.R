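# Fragment library QC: gene containment, genes-per-fragment /
# fragments-per-gene distributions, insert-size moments, gene coverage.

#' All (fragment, fully contained gene) pairs
#'
#' A gene is contained in a fragment when the insert interval covers the
#' whole gene on the same genome; strand is ignored (containment, not
#' expression).
#'
#' @param mapping mapping data.frame.
#' @param annotation annotation data.frame.
#' @return data.frame with columns `barcode`, `gene_id`.
#' @export
containment_pairs <- function(mapping, annotation) {
  out <- list()
  for (g in unique(mapping$genome_id)) {
    ann <- annotation[annotation$genome_id == g, , drop = FALSE]
    frg <- mapping[mapping$genome_id == g, , drop = FALSE]
    if (!nrow(ann) || !nrow(frg)) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(ann$start, ann$end),
      IRanges::IRanges(frg$start, frg$end),
      type = "within"
    )
    if (length(hits)) {
      out[[g]] <- data.frame(
        barcode = frg$barcode[S4Vectors::subjectHits(hits)],
        gene_id = ann$gene_id[S4Vectors::queryHits(hits)],
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(barcode = character(0), gene_id = character(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Genes fully contained in one fragment
#'
#' @param insert single-row mapping data.frame (or list with `barcode`,
#'   `genome_id`, `start`, `end`).
#' @param annotation annotation data.frame.
#' @return character vector of contained gene_ids, in genomic order.
#' @export
genes_in_fragment <- function(insert, annotation) {
  insert <- as.data.frame(insert, stringsAsFactors = FALSE)
  stopifnot(nrow(insert) == 1L)
  if (!insert$genome_id %in% annotation$genome_id) {
    stop("genome_id not present in annotation: ", insert$genome_id)
  }
  ann <- annotation[annotation$genome_id == insert$genome_id, , drop = FALSE]
  hit <- ann$start >= insert$start & ann$end <= insert$end
  ann$gene_id[hit][order(ann$start[hit])]
}

bin_0123 <- function(x) {
  # fractions of counts equal to 0, 1, 2 and >= 3
  n <- length(x)
  out <- c(`0` = sum(x == 0), `1` = sum(x == 1), `2` = sum(x == 2),
           `>=3` = sum(x >= 3)) / n
  out
}

#' Library QC statistics
#'
#' Computes, per library, the number of mapped fragments, insert-size mean
#' and sd, the distribution (0 / 1 / 2 / >=3 and mean) of fully contained
#' genes per fragment and of containing fragments per gene, and the gene
#' coverage (fraction of genes fully contained in at least one fragment,
#' which equals one minus the zero class of fragments-per-gene).
#'
#' @param mapping mapping data.frame (one library).
#' @param annotation annotation data.frame for the mapped genome(s).
#' @return list of class `library_stats`.
#' @export
library_stats <- function(mapping, annotation) {
  if (!nrow(mapping)) stop("mapping is empty")
  pairs <- containment_pairs(mapping, annotation)
  gpf <- table(factor(pairs$barcode, levels = mapping$barcode))
  n_genes <- nrow(annotation)
  if (n_genes == 0L) {
    warning("annotation has no genes; gene coverage reported as 0")
    fpg <- integer(0)
    coverage <- 0
    fpg_frac <- c(`0` = NA_real_, `1` = NA_real_, `2` = NA_real_,
                  `>=3` = NA_real_)
    fpg_mean <- NA_real_
  } else {
    fpg <- table(factor(pairs$gene_id, levels = annotation$gene_id))
    coverage <- mean(fpg > 0)
    fpg_frac <- bin_0123(as.integer(fpg))
    fpg_mean <- mean(as.integer(fpg))
  }
  len <- mapping$end - mapping$start + 1L
  structure(list(
    n_mapped_fragments = nrow(mapping),
    insert_mean = mean(len),
    insert_sd = stats::sd(len),
    genes_per_fragment = bin_0123(as.integer(gpf)),
    genes_per_fragment_mean = mean(as.integer(gpf)),
    fragments_per_gene = fpg_frac,
    fragments_per_gene_mean = fpg_mean,
    gene_coverage = coverage,
    n_containment_pairs = nrow(pairs)
  ), class = "library_stats")
}

#' @export
print.library_stats <- function(x, ...) {
  cat(sprintf(
    "library_stats: %d fragments, insert %.0f +/- %.0f nt, %.2f genes/fragment, gene coverage %.1f%%\n",
    x$n_mapped_fragments, x$insert_mean, x$insert_sd,
    x$genes_per_fragment_mean, 100 * x$gene_coverage))
  invisible(x)
}

#' Write library QC statistics as a one-row TSV
#' @param stats a `library_stats` (or list of them, one row each).
#' @param path output file.
#' @param labels optional row labels.
#' @return `path`, invisibly.
#' @export
write_library_stats <- function(stats, path, labels = NULL) {
  if (inherits(stats, "library_stats")) stats <- list(stats)
  rows <- lapply(stats, function(s) {
    data.frame(
      n_mapped_fragments = s$n_mapped_fragments,
      insert_mean = s$insert_mean, insert_sd = s$insert_sd,
      gpf_mean = s$genes_per_fragment_mean,
      gpf_0 = s$genes_per_fragment[["0"]], gpf_1 = s$genes_per_fragment[["1"]],
      gpf_2 = s$genes_per_fragment[["2"]],
      gpf_3plus = s$genes_per_fragment[[">=3"]],
      fpg_mean = s$fragments_per_gene_mean,
      fpg_0 = s$fragments_per_gene[["0"]], fpg_1 = s$fragments_per_gene[["1"]],
      fpg_2 = s$fragments_per_gene[["2"]],
      fpg_3plus = s$fragments_per_gene[[">=3"]],
      gene_coverage = s$gene_coverage
    )
  })
  out <- do.call(rbind, rows)
  if (!is.null(labels)) out <- cbind(library = labels, out)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
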