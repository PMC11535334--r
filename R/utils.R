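# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' Generate unique random barcodes
#'
#' @param n number of barcodes.
#' @param width barcode length in nucleotides.
#' @param max_tries retry budget for resolving duplicate draws.
#' @return character vector of `n` distinct ACGT strings.
#' @keywords internal
random_barcodes <- function(n, width = 20L, max_tries = 20L) {
  out <- character(0)
  tries <- 0L
  while (length(out) < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop("could not generate ", n, " unique barcodes after ", max_tries,
           " attempts")
    }
    need <- n - length(out)
    m <- matrix(sample(DNA_BASES, need * width, replace = TRUE), nrow = need)
    out <- unique(c(out, do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))))
  }
  out[seq_len(n)]
}

#' Minimum Phred quality across a substring, vectorised over reads
#' @keywords internal
min_phred <- function(qual_strings) {
  vapply(qual_strings, function(s) {
    if (nchar(s) == 0L) return(NA_integer_)
    min(utf8ToInt(s)) - 33L
  }, integer(1), USE.NAMES = FALSE)
}

random_dna <- function(n, gc = 0.5) {
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = probs), collapse = "")
}

# Sense codons grouped by amino acid, from the standard genetic code.
codon_families <- function() {
  gc <- Biostrings::GENETIC_CODE
  sense <- gc[gc != "*"]
  split(names(sense), unname(sense))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
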