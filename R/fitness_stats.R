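# Per-barcode fitness (normalized log2 ratio) and count-noise z statistics
# for selected / t0 sample pairs.

#' Fitness parameters
#'
#' @param pseudocount reads added to each barcode count (and `pseudocount`
#'   times the number of barcodes to each sample total) so that fitness is
#'   finite at zero counts. Must be > 0 unless all counts are positive.
#' @param tau_f fitness threshold for significance (strict `>`).
#' @param tau_z z threshold for significance (strict `>`).
#' @return list of class `fitness_params`.
#' @export
fitness_params <- function(pseudocount = 0.5, tau_f = 5, tau_z = 4) {
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  if (tau_f <= 0 || tau_z <= 0) stop("thresholds must be > 0")
  structure(list(pseudocount = pseudocount, tau_f = tau_f, tau_z = tau_z),
            class = "fitness_params")
}

#' Per-barcode fitness: normalized log2 ratio
#'
#' Fitness is the log2 change in a barcode's relative abundance between the
#' selected sample and the t0 (control) sample:
#' \deqn{f = \log_2\frac{n_{sel} + p}{N_{sel} + pB} -
#'       \log_2\frac{n_{t0} + p}{N_{t0} + pB}}
#' where `p` is the pseudocount and `B` the number of barcodes in the table.
#' With `p = 0`, multiplying all counts of one sample by a constant leaves
#' `f` unchanged (pure relative-abundance normalization).
#'
#' @param n_t0,n_sel barcode read counts in the t0 / selected sample.
#' @param total_t0,total_sel total reads in each sample.
#' @param n_barcodes number of barcodes `B` in the table.
#' @param pseudocount pseudocount `p` (default 0.5).
#' @return numeric vector of fitness values, log2 units.
#' @export
compute_fitness <- function(n_t0, total_t0, n_sel, total_sel, n_barcodes,
                            pseudocount = 0.5) {
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  if (pseudocount == 0 && any(n_t0 == 0 | n_sel == 0)) {
    stop("fitness is undefined at zero counts when pseudocount = 0")
  }
  p <- pseudocount
  log2((n_sel + p) / (total_sel + p * n_barcodes)) -
    log2((n_t0 + p) / (total_t0 + p * n_barcodes))
}

#' Count-noise z statistic for a fitness value
#'
#' Scales fitness by its delta-method standard error under Poisson count
#' noise on the log2 scale:
#' \deqn{z = f \big/ \left[\tfrac{1}{\ln 2}
#'   \sqrt{\tfrac{1}{n_{sel}+p} + \tfrac{1}{n_{t0}+p}}\right]}
#' so that `sign(z) = sign(f)` and low-count barcodes need a larger fold
#' change to reach the same z.
#'
#' @param n_t0,n_sel barcode read counts.
#' @param f fitness from [compute_fitness()].
#' @param pseudocount pseudocount `p`.
#' @return numeric vector of z values.
#' @export
compute_z <- function(n_t0, n_sel, f, pseudocount = 0.5) {
  p <- pseudocount
  se <- (1 / log(2)) * sqrt(1 / (n_sel + p) + 1 / (n_t0 + p))
  f / se
}

#' Fitness and z for every (barcode, selected sample) pair
#'
#' @param ct a [count_table()]; every selected sample must name its t0 pair
#'   in the sheet.
#' @param params a [fitness_params()].
#' @return data.frame of fitness records: `barcode`, `experiment_id`,
#'   `background`, `inducer`, `n_t0`, `n_sel`, `f`, `z`.
#' @export
fitness_table <- function(ct, params = fitness_params()) {
  stopifnot(inherits(ct, "count_table"))
  sheet <- ct$sheet
  sel <- sheet[sheet$role == "selected", , drop = FALSE]
  if (!nrow(sel)) stop("no selected samples in sheet")
  B <- nrow(ct$counts)
  totals <- vapply(sheet$sample_id, function(s) sum(ct$counts[[s]]),
                   numeric(1))
  out <- vector("list", nrow(sel))
  for (i in seq_len(nrow(sel))) {
    s <- sel$sample_id[i]
    t0 <- sel$t0_pair[i]
    n_sel <- ct$counts[[s]]
    n_t0 <- ct$counts[[t0]]
    f <- compute_fitness(n_t0, totals[[t0]], n_sel, totals[[s]], B,
                         params$pseudocount)
    z <- compute_z(n_t0, n_sel, f, params$pseudocount)
    out[[i]] <- data.frame(
      barcode = ct$counts$barcode, experiment_id = s,
      background = sel$background[i], inducer = sel$inducer[i],
      n_t0 = n_t0, n_sel = n_sel, f = f, z = z, stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Mean fitness per barcode across a background's experiments
#'
#' @param records fitness records from [fitness_table()].
#' @return data.frame `barcode`, `background`, `mean_f`.
#' @export
background_mean_fitness <- function(records) {
  agg <- stats::aggregate(f ~ barcode + background, data = records, FUN = mean)
  names(agg)[names(agg) == "f"] <- "mean_f"
  agg
}

#' Write fitness records as TSV
#' @param records fitness records.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fitness_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
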