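# Significance flags, confirmation rules, region merging, gene association,
# cutoff scan.

fake_record <- function(barcode, experiment, f, z, background = "bg",
                        inducer = "1x") {
  data.frame(barcode = barcode, experiment_id = experiment,
             background = background, inducer = inducer,
             n_t0 = 10, n_sel = 10, f = f, z = z, stringsAsFactors = FALSE)
}

fake_mapping <- function(barcodes, starts, ends, genome = "g1", orient = "+") {
  data.frame(barcode = barcodes, genome_id = genome, start = starts,
             end = ends, vector_orientation = orient, stringsAsFactors = FALSE)
}

test_that("significance thresholds are strict", {
  rec <- fake_record(vapply(1:3, bc, ""), "e1",
                     f = c(5.1, 5.0, 6.0), z = c(4.2, 10, 3.9))
  expect_equal(flag_significant(rec), c(TRUE, FALSE, FALSE))
})

test_that("overlap in the same experiment confirms both fragments", {
  rec <- rbind(fake_record(bc(1), "e1", 8, 9), fake_record(bc(2), "e1", 7, 8))
  map <- fake_mapping(c(bc(1), bc(2)), c(1L, 2500L), c(3000L, 5500L))
  hits <- confirm_hits(rec, map)
  expect_equal(nrow(hits), 2L)
  expect_true(all(hits$high_confidence))
  expect_true(all(hits$confirmation == "overlap_same_experiment"))
})

test_that("significance at both inducer levels confirms by replication", {
  rec <- rbind(fake_record(bc(1), "e_1x", 8, 9, inducer = "1x"),
               fake_record(bc(1), "e_5x", 7, 8, inducer = "5x"))
  map <- fake_mapping(bc(1), 100L, 3100L)
  hits <- confirm_hits(rec, map)
  expect_equal(hits$confirmation, "replicate_other_experiment")
  expect_true(hits$high_confidence)
  expect_equal(hits$n_experiments_significant, 2L)
  # mean fitness averages that background's experiments
  expect_equal(hits$mean_f, 7.5)
})

test_that("a lone unconfirmed significant fragment is not high confidence", {
  rec <- rbind(fake_record(bc(1), "e1", 8, 9),
               fake_record(bc(2), "e1", 7, 8))
  # the two inserts do not overlap
  map <- fake_mapping(c(bc(1), bc(2)), c(1L, 10000L), c(3000L, 13000L))
  hits <- confirm_hits(rec, map)
  expect_false(any(hits$high_confidence))
  expect_true(all(hits$confirmation == "none"))
})

test_that("different backgrounds and genomes never confirm each other", {
  rec <- rbind(fake_record(bc(1), "e1", 8, 9, background = "bg1"),
               fake_record(bc(2), "e2", 8, 9, background = "bg2"))
  map <- fake_mapping(c(bc(1), bc(2)), c(1L, 1L), c(3000L, 3000L))
  hits <- confirm_hits(rec, map)
  expect_false(any(hits$high_confidence))

  # same experiment, overlapping coordinates but different genomes
  rec2 <- rbind(fake_record(bc(1), "e1", 8, 9), fake_record(bc(2), "e1", 8, 9))
  map2 <- fake_mapping(c(bc(1), bc(2)), c(1L, 1L), c(3000L, 3000L),
                       genome = c("g1", "g2"))
  hits2 <- confirm_hits(rec2, map2)
  expect_false(any(hits2$high_confidence))
})

test_that("significant barcodes missing from the mapping are excluded with a report", {
  rec <- rbind(fake_record(bc(1), "e1", 8, 9), fake_record(bc(2), "e1", 8, 9))
  map <- fake_mapping(bc(1), 1L, 3000L)
  expect_warning(hits <- confirm_hits(rec, map), "missing from mapping")
  expect_equal(hits$barcode, bc(1))
  expect_equal(attr(hits, "unmapped"), bc(2))
})

test_that("regions merge overlapping inserts transitively", {
  rec <- do.call(rbind, lapply(1:3, function(i) fake_record(bc(i), "e1", 8, 9)))
  # chain: A [1,3000], B [2500,5500], C [5400,8000]; A and C do not touch
  map <- fake_mapping(vapply(1:3, bc, ""), c(1L, 2500L, 5400L),
                      c(3000L, 5500L, 8000L))
  hits <- confirm_hits(rec, map)
  reg <- merge_regions(hits)
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$start, 1L)
  expect_equal(reg$end, 8000L)
  expect_equal(reg$n_members, 3L)
})

test_that("adjacent but non-overlapping inserts stay separate", {
  rec <- rbind(fake_record(bc(1), "e_1x", 8, 9, inducer = "1x"),
               fake_record(bc(1), "e_5x", 8, 9, inducer = "5x"),
               fake_record(bc(2), "e_1x", 8, 9, inducer = "1x"),
               fake_record(bc(2), "e_5x", 8, 9, inducer = "5x"))
  map <- fake_mapping(c(bc(1), bc(2)), c(1L, 3001L), c(3000L, 6000L))
  hits <- confirm_hits(rec, map)   # replicate-confirmed, no overlap
  reg <- merge_regions(hits)
  expect_equal(nrow(reg), 2L)
  expect_equal(sum(reg$n_members), sum(hits$high_confidence))
})

test_that("region merging equals the transitive-closure oracle on random instances", {
  set.seed(321)
  for (iter in 1:25) {
    n <- sample(5:60, 1)
    starts <- sample.int(40000L, n)
    ends <- starts + sample(500:6000, n, replace = TRUE)
    barcodes <- vapply(seq_len(n), bc, "")
    rec <- do.call(rbind, lapply(seq_len(n), function(i) {
      rbind(fake_record(barcodes[i], "e_1x", 8, 9, inducer = "1x"),
            fake_record(barcodes[i], "e_5x", 8, 9, inducer = "5x"))
    }))
    map <- fake_mapping(barcodes, starts, ends)
    hits <- confirm_hits(rec, map)
    reg <- merge_regions(hits)
    comp <- merge_oracle(starts, ends)
    expect_equal(nrow(reg), length(unique(comp)))
    # every member set matches an oracle component
    got <- lapply(strsplit(reg$member_barcodes, ";"), sort)
    want <- lapply(split(barcodes, comp), sort)
    expect_setequal(vapply(got, paste, "", collapse = ","),
                    vapply(want, paste, "", collapse = ","))
  }
})

test_that("every high-confidence hit belongs to exactly one region", {
  scr <- small_screen(seed = 101, n_comp = 2L, two_experiments = TRUE)
  rec <- fitness_table(scr$ct)
  hits <- confirm_hits(rec, scr$lib$mapping)
  reg <- merge_regions(hits)
  members <- unlist(strsplit(reg$member_barcodes, ";"))
  expect_equal(sort(members), sort(hits$barcode[hits$high_confidence]))
})

test_that("gene association follows the highest-fitness insert", {
  ann <- toy_annotation()
  # two members: the stronger insert contains gA fully, the weaker gB
  rec <- rbind(fake_record(bc(1), "e_1x", 9, 9, inducer = "1x"),
               fake_record(bc(1), "e_5x", 9, 9, inducer = "5x"),
               fake_record(bc(2), "e_1x", 7, 9, inducer = "1x"),
               fake_record(bc(2), "e_5x", 7, 9, inducer = "5x"))
  map <- fake_mapping(c(bc(1), bc(2)), c(100L, 900L), c(900L, 2500L))
  hits <- confirm_hits(rec, map)
  reg <- associate_genes(merge_regions(hits), hits, ann)
  expect_equal(reg$best_barcode, bc(1))
  expect_equal(reg$associated_genes, "gA")
  expect_equal(reg$orf_class, "one_orf")

  # no full ORF in the best insert
  map2 <- fake_mapping(c(bc(1), bc(2)), c(300L, 900L), c(900L, 2500L))
  hits2 <- confirm_hits(rec, map2)
  reg2 <- associate_genes(merge_regions(hits2), hits2, ann)
  expect_equal(reg2$orf_class, "no_full_orf")
  expect_equal(reg2$associated_genes, "")

  # multi-ORF class
  rec3 <- rbind(fake_record(bc(1), "e_1x", 9, 9, inducer = "1x"),
                fake_record(bc(1), "e_5x", 9, 9, inducer = "5x"))
  map3 <- fake_mapping(bc(1), 100L, 2500L)
  hits3 <- confirm_hits(rec3, map3)
  reg3 <- associate_genes(merge_regions(hits3), hits3, ann)
  expect_equal(reg3$orf_class, "multi_orf")
  expect_equal(reg3$associated_genes, "gA;gB")
})

test_that("best-insert ties break by length then barcode", {
  ann <- toy_annotation()
  b1 <- bc(1); b2 <- bc(2)
  rec <- do.call(rbind, lapply(c(b1, b2), function(b) {
    rbind(fake_record(b, "e_1x", 8, 9, inducer = "1x"),
          fake_record(b, "e_5x", 8, 9, inducer = "5x"))
  }))
  # equal mean fitness; bc(2)'s insert is longer
  map <- fake_mapping(c(b1, b2), c(100L, 100L), c(900L, 2500L))
  hits <- confirm_hits(rec, map)
  reg <- associate_genes(merge_regions(hits), hits, ann)
  expect_equal(reg$best_barcode, b2)

  # equal fitness and equal length: lexicographically smaller barcode
  map2 <- fake_mapping(c(b1, b2), c(100L, 100L), c(2500L, 2500L))
  hits2 <- confirm_hits(rec, map2)
  reg2 <- associate_genes(merge_regions(hits2), hits2, ann)
  expect_equal(reg2$best_barcode, min(b1, b2))
})

test_that("nearly full-length genes are reported separately from the ORF class", {
  ann <- toy_annotation()  # gB: [1000, 2200], strand -
  rec <- rbind(fake_record(bc(1), "e_1x", 8, 9, inducer = "1x"),
               fake_record(bc(1), "e_5x", 8, 9, inducer = "5x"))
  # covers gB from 1090 (91% of 1201 nt) through its minus-strand start at 2200
  map <- fake_mapping(bc(1), 1090L, 3200L)
  hits <- confirm_hits(rec, map)
  reg <- associate_genes(merge_regions(hits), hits, ann)
  expect_equal(reg$nearly_full_genes, "gB")
  expect_equal(reg$orf_class, "no_full_orf")

  # same coverage fraction on a plus-strand gene missing its start codon
  # does not count as nearly full length
  annP <- ann
  annP$strand[2] <- "+"
  regP <- associate_genes(merge_regions(hits), hits, annP)
  expect_equal(regP$nearly_full_genes, "")
})

test_that("raising thresholds never increases hit or region counts", {
  scr <- small_screen(seed = 111, n_comp = 2L, p_sense = 0.66,
                      p_antisense = 0.35, two_experiments = TRUE)
  rec <- fitness_table(scr$ct)
  grid <- c(3, 5, 7, 9)
  n_inst <- n_hc <- n_reg <- integer(length(grid))
  for (i in seq_along(grid)) {
    p <- fitness_params(tau_f = grid[i])
    n_inst[i] <- nrow(significant_instances(rec, p))
    hits <- suppressWarnings(confirm_hits(rec, scr$lib$mapping, p))
    n_hc[i] <- sum(hits$high_confidence)
    n_reg[i] <- nrow(merge_regions(hits))
  }
  expect_true(all(diff(n_inst) <= 0))
  expect_true(all(diff(n_hc) <= 0))
  expect_true(all(diff(n_reg) <= 0))
})

test_that("cutoff scan counts drop only when borderline hits exist", {
  ann <- toy_annotation()
  expected <- data.frame(protein_id = "P1", genome_id = "g1",
                         background = "bg", gene_id = "gA",
                         stringsAsFactors = FALSE)
  # two overlapping true hits at f ~ 10 containing gA; two overlapping
  # borderline false positives at f ~ 5.5 elsewhere
  rec <- rbind(fake_record(bc(1), "e1", 10, 9), fake_record(bc(2), "e1", 10.5, 9),
               fake_record(bc(3), "e1", 5.5, 9), fake_record(bc(4), "e1", 5.6, 9))
  map <- fake_mapping(vapply(1:4, bc, ""), c(100L, 150L, 5800L, 5900L),
                      c(900L, 950L, 7900L, 8000L))
  scan <- cutoff_scan(rec, map, ann, expected, tau_f_grid = c(5, 6, 7))
  expect_equal(scan$n_expected_recovered, c(1L, 1L, 1L))
  expect_equal(scan$n_unexpected_regions, c(1L, 0L, 0L))

  # only strong true hits: counts constant across the grid
  rec2 <- rec[1:2, ]
  scan2 <- cutoff_scan(rec2, map[1:2, ], ann, expected, tau_f_grid = c(5, 6, 7))
  expect_true(all(scan2$n_expected_recovered == 1L))
  expect_true(all(scan2$n_unexpected_regions == 0L))

  # empty record set: zeros everywhere
  scan3 <- cutoff_scan(rec[0, ], map, ann, expected, tau_f_grid = c(5, 6, 7))
  expect_true(all(scan3$n_high_confidence == 0L))
  expect_true(all(scan3$n_regions == 0L))
  expect_true(all(scan3$n_expected_recovered == 0L))
})
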