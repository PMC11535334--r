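# BarSeq reads -> per-barcode counts: flank-anchored barcode extraction,
# quality filtering, off-by-one barcode elimination, diversity estimation.

#' Barcode extraction specification
#'
#' Flanks come from the barcoding primer layout (a 6-mer upstream anchor
#' directly 5' of the barcode and the full downstream anchor). Flank matching
#' is exact. `min_quality` is 0 for fitness counting and 30 for diversity
#' estimation: with Q >= 30 everywhere the chance of any error in a 20-nt
#' barcode is bounded by 20 x 0.001 = 2%.
#'
#' @param upstream_flank exact sequence expected immediately 5' of the
#'   barcode.
#' @param downstream_flank exact sequence expected immediately 3' of it.
#' @param barcode_length barcode length (20).
#' @param min_quality minimum Phred quality required at every barcode base.
#' @return list of class `extraction_spec`.
#' @export
extraction_spec <- function(upstream_flank = "CGTACG",
                            downstream_flank = "AGAGACCTCGTGGACATC",
                            barcode_length = 20L,
                            min_quality = 0L) {
  if (!nzchar(upstream_flank) || !nzchar(downstream_flank)) {
    stop("flanks must be non-empty")
  }
  structure(list(upstream_flank = upstream_flank,
                 downstream_flank = downstream_flank,
                 barcode_length = as.integer(barcode_length),
                 min_quality = as.integer(min_quality)),
            class = "extraction_spec")
}

#' Extract barcodes from reads
#'
#' Finds the barcode between exact flank matches. A read is rejected (with a
#' reason, not an error) if the upstream or downstream flank is absent
#' (`no_flank`), the extracted barcode is shorter than expected because the
#' read is truncated (`bad_length`), the barcode contains an ambiguous base
#' (`ambiguous_base`), or any barcode base is below `min_quality`
#' (`low_quality`).
#'
#' @param seqs character vector of read sequences (ACGTN).
#' @param quals character vector of Phred+33 quality strings (same lengths
#'   as `seqs`), or `NULL` when `min_quality` is 0.
#' @param spec an [extraction_spec()].
#' @return data.frame with columns `barcode` (NA when rejected) and `reason`
#'   (`ok`, `no_flank`, `bad_length`, `ambiguous_base`, `low_quality`).
#' @export
extract_barcodes <- function(seqs, quals = NULL, spec = extraction_spec()) {
  if (spec$min_quality > 0 && is.null(quals)) {
    stop("quality strings are required when min_quality > 0")
  }
  if (!is.null(quals)) stopifnot(length(quals) == length(seqs))
  up <- spec$upstream_flank
  bl <- spec$barcode_length
  pos <- regexpr(up, seqs, fixed = TRUE)
  bstart <- pos + nchar(up)
  bc <- substr(seqs, bstart, bstart + bl - 1L)
  down <- substr(seqs, bstart + bl, bstart + bl + nchar(spec$downstream_flank) - 1L)

  reason <- rep("ok", length(seqs))
  reason[pos < 0L] <- "no_flank"
  found <- pos > 0L
  short <- found & nchar(bc) < bl
  reason[short] <- "bad_length"
  nodown <- found & !short & down != spec$downstream_flank
  reason[nodown] <- "no_flank"
  ambig <- reason == "ok" & grepl("[^ACGT]", bc)
  reason[ambig] <- "ambiguous_base"
  if (spec$min_quality > 0L) {
    chk <- which(reason == "ok")
    if (length(chk)) {
      qbc <- substr(quals[chk], bstart[chk], bstart[chk] + bl - 1L)
      lowq <- min_phred(qbc) < spec$min_quality
      reason[chk[lowq]] <- "low_quality"
    }
  }
  data.frame(barcode = ifelse(reason == "ok", bc, NA_character_),
             reason = reason, stringsAsFactors = FALSE)
}

#' Count barcodes in a BarSeq FASTQ file
#'
#' Re-implements flank-anchored barcode counting: every read either yields
#' an accepted barcode or a tallied rejection reason, so that accepted +
#' rejected = total reads.
#'
#' @param fastq path to a FASTQ file, or a list with elements `seqs` and
#'   `quals` (character vectors) for reads already in memory.
#' @param spec an [extraction_spec()].
#' @return list of class `barcode_counts`: `counts` (data.frame `barcode`,
#'   `count`, sorted by decreasing count), `rejections` (named integer
#'   vector) and `total_reads`.
#' @export
count_barcodes <- function(fastq, spec = extraction_spec()) {
  if (is.character(fastq)) {
    x <- tryCatch(
      Biostrings::readDNAStringSet(fastq, format = "fastq",
                                   with.qualities = TRUE),
      error = function(e) stop("failed to parse FASTQ ", fastq, ": ",
                               conditionMessage(e), call. = FALSE)
    )
    seqs <- as.character(x)
    quals <- as.character(S4Vectors::mcols(x)$qualities)
  } else {
    seqs <- fastq$seqs
    quals <- fastq$quals
  }
  ex <- extract_barcodes(seqs, quals, spec)
  acc <- ex$barcode[ex$reason == "ok"]
  tab <- table(acc)
  counts <- data.frame(barcode = as.character(names(tab) %||% character(0)),
                       count = as.integer(tab), stringsAsFactors = FALSE)
  counts <- counts[order(-counts$count, counts$barcode), , drop = FALSE]
  rownames(counts) <- NULL
  rej <- table(ex$reason[ex$reason != "ok"])
  structure(list(counts = counts,
                 rejections = stats::setNames(as.integer(rej), names(rej)),
                 total_reads = length(seqs)),
            class = "barcode_counts")
}

#' @export
print.barcode_counts <- function(x, ...) {
  cat("barcode_counts:", nrow(x$counts), "barcodes,",
      sum(x$counts$count), "accepted /", x$total_reads, "reads\n")
  invisible(x)
}

as_counts_df <- function(counts) {
  if (inherits(counts, "barcode_counts")) return(counts$counts)
  if (is.data.frame(counts)) {
    stopifnot(all(c("barcode", "count") %in% names(counts)))
    return(counts)
  }
  if (is.numeric(counts) && !is.null(names(counts))) {
    return(data.frame(barcode = names(counts), count = as.integer(counts),
                      stringsAsFactors = FALSE))
  }
  stop("counts must be a barcode_counts, a data.frame or a named vector")
}

#' Eliminate off-by-one barcode errors
#'
#' Removes every barcode that lies at Hamming distance 1 from a strictly
#' more common barcode. The removed barcodes' reads are discarded, not
#' reassigned; ties are kept (neither of two equally common neighbours is
#' "more common"). The operation is idempotent and order-independent.
#'
#' @param counts a `barcode_counts`, a data.frame (`barcode`, `count`) or a
#'   named count vector. All barcodes must have equal length.
#' @return filtered counts, in the same representation.
#' @export
collapse_offby1 <- function(counts) {
  df <- as_counts_df(counts)
  if (nrow(df) <= 1L) return(counts)
  widths <- nchar(df$barcode)
  if (length(unique(widths)) > 1L) stop("mixed barcode lengths")
  bc <- df$barcode
  cnt <- df$count
  max_neighbour <- rep(0L, length(bc))
  for (p in seq_len(widths[1])) {
    orig <- substr(bc, p, p)
    for (b in DNA_BASES) {
      variant <- bc
      substr(variant, p, p) <- b
      m <- match(variant, bc)
      hit <- which(orig != b & !is.na(m))
      if (length(hit)) {
        max_neighbour[hit] <- pmax(max_neighbour[hit], cnt[m[hit]])
      }
    }
  }
  keep <- max_neighbour <= cnt
  if (inherits(counts, "barcode_counts")) {
    counts$counts <- df[keep, , drop = FALSE]
    rownames(counts$counts) <- NULL
    return(counts)
  }
  if (is.data.frame(counts)) {
    out <- df[keep, , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  stats::setNames(cnt[keep], bc[keep])
}

#' Estimate library diversity
#'
#' The diversity of a barcoded library is the number of distinct barcodes
#' surviving a strict quality filter (Q >= 30 at every barcode base) and
#' off-by-one elimination.
#'
#' @param counts counts produced under `min_quality = 30` and already passed
#'   through [collapse_offby1()].
#' @return integer barcode count.
#' @export
estimate_diversity <- function(counts) {
  nrow(as_counts_df(counts))
}
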