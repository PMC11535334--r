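# On-disk formats and shared domain containers.
#
# Domain types are plain data.frames with fixed columns:
#   annotation: gene_id, genome_id, start, end, strand
#   mapping:    barcode, genome_id, start, end, vector_orientation
#   sheet:      sample_id, background, inducer, role, t0_pair, library_label
#   expected:   protein_id, genome_id, background, gene_id [, rbs_strength]
# Counts live in a "count_table": a list of a dense wide counts data.frame
# (barcode + one integer column per sample) plus the sample sheet.
# All coordinates are 1-based inclusive.

MAPPING_COLUMNS <- c("barcode", "genome_id", "start", "end", "vector_orientation")
SHEET_COLUMNS <- c("sample_id", "background", "inducer", "role", "t0_pair",
                   "library_label")

#' Read a gene annotation from a GFF3 file
#'
#' Imports protein-coding gene features from a GFF3 file into the package's
#' annotation data.frame. Coordinates are copied as-is (GFF3 is 1-based
#' inclusive, the convention used throughout this package). If the file has
#' `gene` features those are used; otherwise `CDS` features are taken.
#'
#' @param path path to a GFF3 file.
#' @return data.frame with columns `gene_id`, `genome_id`, `start`, `end`,
#'   `strand`, ordered by genome then start.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) stop("malformed GFF3 in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  type <- as.character(gr$type)
  keep <- if (any(type == "gene")) type == "gene" else type == "CDS"
  gr <- gr[keep]
  if (length(gr) == 0L) {
    return(data.frame(gene_id = character(0), genome_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  ids <- gr$ID
  if (is.null(ids) || anyNA(ids)) {
    alt <- gr$locus_tag %||% gr$Name
    if (!is.null(alt)) ids <- ifelse(is.na(ids) | is.null(ids), alt, ids)
  }
  if (is.null(ids)) ids <- paste0("gene", seq_along(gr))
  ann <- data.frame(
    gene_id = as.character(ids),
    genome_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  validate_annotation(ann)
  ann[order(ann$genome_id, ann$start, ann$end, ann$gene_id), , drop = FALSE]
}

#' Write an annotation data.frame as GFF3
#' @param annotation annotation data.frame (see [read_annotation()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_annotation_gff3 <- function(annotation, path) {
  validate_annotation(annotation)
  gr <- GenomicRanges::GRanges(
    seqnames = annotation$genome_id,
    ranges = IRanges::IRanges(annotation$start, annotation$end),
    strand = annotation$strand
  )
  gr$type <- "gene"
  gr$ID <- annotation$gene_id
  gr$source <- "auxseq"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

validate_annotation <- function(annotation) {
  req <- c("gene_id", "genome_id", "start", "end", "strand")
  miss <- setdiff(req, names(annotation))
  if (length(miss)) stop("annotation is missing columns: ",
                         paste(miss, collapse = ", "))
  bad <- annotation$end < annotation$start | annotation$start < 1
  if (any(bad)) {
    stop("invalid gene interval (end < start or start < 1) for: ",
         paste(utils::head(annotation$gene_id[bad], 5), collapse = ", "))
  }
  if (!all(annotation$strand %in% c("+", "-"))) {
    stop("gene strand must be '+' or '-'")
  }
  invisible(annotation)
}

#' Validate a barcode-to-fragment mapping table
#'
#' @param mapping data.frame with columns `barcode`, `genome_id`, `start`,
#'   `end`, `vector_orientation`.
#' @param strict if `TRUE` (default) duplicate barcodes are an error; if
#'   `FALSE` the last occurrence wins with a warning.
#' @param window allowed insert-length window in nt (inclusive), or `NULL`
#'   to skip the length check.
#' @return the validated (possibly deduplicated) mapping.
#' @export
validate_mapping <- function(mapping, strict = TRUE, window = c(1000, 6000)) {
  miss <- setdiff(MAPPING_COLUMNS, names(mapping))
  if (length(miss)) stop("mapping is missing columns: ",
                         paste(miss, collapse = ", "))
  ok_bc <- grepl("^[ACGT]{20}$", mapping$barcode)
  if (!all(ok_bc)) {
    stop("barcodes must be 20-nt ACGT strings; offending: ",
         paste(utils::head(mapping$barcode[!ok_bc], 5), collapse = ", "))
  }
  if (anyDuplicated(mapping$barcode)) {
    dups <- unique(mapping$barcode[duplicated(mapping$barcode)])
    if (strict) {
      stop("duplicate barcodes in mapping: ",
           paste(utils::head(dups, 5), collapse = ", "))
    }
    warning(length(dups), " duplicated barcode(s); keeping last occurrence")
    mapping <- mapping[!duplicated(mapping$barcode, fromLast = TRUE), ,
                       drop = FALSE]
  }
  if (any(mapping$end < mapping$start)) stop("mapping has end < start")
  if (!all(mapping$vector_orientation %in% c("+", "-"))) {
    stop("vector_orientation must be '+' or '-'")
  }
  if (!is.null(window)) {
    len <- mapping$end - mapping$start + 1L
    out <- len < window[1] | len > window[2]
    if (any(out)) {
      msg <- paste0(sum(out), " insert(s) outside the length window [",
                    window[1], ", ", window[2], "]")
      if (strict) stop(msg) else warning(msg)
    }
  }
  rownames(mapping) <- NULL
  mapping
}

#' Read a barcode-to-fragment mapping table (TSV)
#' @inheritParams validate_mapping
#' @param path TSV with header `barcode`, `genome_id`, `start`, `end`,
#'   `vector_orientation`.
#' @return validated mapping data.frame.
#' @export
read_mapping_table <- function(path, strict = TRUE, window = c(1000, 6000)) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_mapping(df, strict = strict, window = window)
}

#' Write a mapping table as TSV
#' @param mapping mapping data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mapping_table <- function(mapping, path) {
  utils::write.table(mapping[, MAPPING_COLUMNS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and validate an experiment sheet (TSV)
#'
#' The sheet has one row per BarSeq sample with columns `sample_id`,
#' `background`, `inducer`, `role` (`t0` or `selected`), `t0_pair` (the
#' sample_id of the paired t0 sample; empty for t0 rows) and `library_label`.
#'
#' @param path TSV path.
#' @return validated sheet data.frame.
#' @export
read_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  validate_sheet(df)
}

validate_sheet <- function(sheet) {
  miss <- setdiff(SHEET_COLUMNS, names(sheet))
  if (length(miss)) stop("sheet is missing columns: ",
                         paste(miss, collapse = ", "))
  if (!all(sheet$role %in% c("t0", "selected"))) {
    stop("sheet role must be 't0' or 'selected'")
  }
  if (anyDuplicated(sheet$sample_id)) stop("duplicate sample_id in sheet")
  sel <- sheet[sheet$role == "selected", , drop = FALSE]
  t0_ids <- sheet$sample_id[sheet$role == "t0"]
  bad <- is.na(sel$t0_pair) | sel$t0_pair == "" | !(sel$t0_pair %in% t0_ids)
  if (any(bad)) {
    stop("selected sample(s) without a valid t0 pair: ",
         paste(sel$sample_id[bad], collapse = ", "))
  }
  sheet
}

#' Construct a count table
#'
#' Bundles a dense wide count matrix (as a data.frame: `barcode` plus one
#' non-negative integer column per sample) with its experiment sheet. Every
#' sample named in the sheet must have a column; missing cells are 0 reads
#' (a barcode not seen in a sample was not detected there).
#'
#' @param counts wide counts data.frame.
#' @param sheet experiment sheet data.frame (see [read_sheet()]).
#' @return object of class `count_table` with elements `counts` and `sheet`.
#' @export
count_table <- function(counts, sheet) {
  sheet <- validate_sheet(sheet)
  if (!"barcode" %in% names(counts)) stop("counts must have a barcode column")
  extra <- setdiff(names(counts), c("barcode", sheet$sample_id))
  if (length(extra)) {
    stop("sample(s) in counts but absent from sheet: ",
         paste(extra, collapse = ", "))
  }
  miss <- setdiff(sheet$sample_id, names(counts))
  for (s in miss) counts[[s]] <- 0L
  counts <- counts[, c("barcode", sheet$sample_id), drop = FALSE]
  if (anyDuplicated(counts$barcode)) stop("duplicate barcodes in counts")
  for (s in sheet$sample_id) {
    x <- counts[[s]]
    x[is.na(x)] <- 0L
    if (any(x < 0)) stop("negative count in sample ", s)
    counts[[s]] <- as.integer(x)
  }
  structure(list(counts = counts, sheet = sheet), class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("count_table:", nrow(x$counts), "barcodes x", nrow(x$sheet),
      "samples (", sum(x$sheet$role == "selected"), "selected )\n")
  invisible(x)
}

#' Read a BarSeq count table and its experiment sheet
#' @param path counts TSV: column `barcode` plus one column per sample_id.
#' @param sheet_path experiment sheet TSV (see [read_sheet()]), or an
#'   already-validated sheet data.frame.
#' @return a [count_table()].
#' @export
read_count_table <- function(path, sheet_path) {
  counts <- utils::read.delim(path, stringsAsFactors = FALSE,
                              check.names = FALSE)
  sheet <- if (is.character(sheet_path)) read_sheet(sheet_path) else sheet_path
  count_table(counts, sheet)
}

#' Write a count table (counts TSV + sheet TSV)
#' @param ct a [count_table()].
#' @param counts_path,sheet_path output files.
#' @return `counts_path`, invisibly.
#' @export
write_count_table <- function(ct, counts_path, sheet_path) {
  stopifnot(inherits(ct, "count_table"))
  utils::write.table(ct$counts, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(ct$sheet, sheet_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(counts_path)
}

#' Read an expected-hit table (TSV)
#'
#' One row per protein expected a priori to complement a given mutant
#' background: columns `protein_id`, `genome_id`, `background`, `gene_id`,
#' and optionally `rbs_strength` (an externally computed covariate).
#'
#' @param path TSV path.
#' @return expected-hit data.frame.
#' @export
read_expected_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("protein_id", "genome_id", "background", "gene_id")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("expected table is missing columns: ",
                         paste(miss, collapse = ", "))
  df
}

#' Read genome sequences from FASTA
#' @param path FASTA file.
#' @return named character vector of genome sequences.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write genome sequences to FASTA
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Extract coding sequences for annotated genes
#'
#' Pulls each gene's CDS out of its genome sequence, reverse-complementing
#' minus-strand genes.
#'
#' @param annotation annotation data.frame.
#' @param genome_seqs named character vector of genome sequences (names are
#'   genome_ids).
#' @return named character vector of CDS, one per gene.
#' @export
gene_cds <- function(annotation, genome_seqs) {
  validate_annotation(annotation)
  miss <- setdiff(unique(annotation$genome_id), names(genome_seqs))
  if (length(miss)) stop("no sequence for genome(s): ",
                         paste(miss, collapse = ", "))
  cds <- substr(genome_seqs[annotation$genome_id], annotation$start,
                annotation$end)
  neg <- annotation$strand == "-"
  if (any(neg)) cds[neg] <- reverse_complement(cds[neg])
  stats::setNames(unname(cds), annotation$gene_id)
}
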