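# a small but structurally complete design for fast generator tests
mini_design <- function(seed = 7L) {
  grid <- rbind(
    data.frame(cell_type = "CT01", tf_name = sprintf("TF%02d", 1:4)),
    data.frame(cell_type = "CT02", tf_name = sprintf("TF%02d", 1:4)),
    data.frame(cell_type = "CT03", tf_name = c("TF01", "TF03")))
  compendium_design(grid = grid, peaks_per_exp = 40L, peak_len = 120L,
                    n_background_motifs = 3L, hot_region_count = 1L,
                    seed = seed)
}

test_that("generate_genome is seeded, GC-calibrated, and validates gc", {
  g1 <- generate_genome(5000, gc = 0.5, seed = 3)
  g2 <- generate_genome(5000, gc = 0.5, seed = 3)
  expect_identical(g1, g2)
  expect_false(identical(g1, generate_genome(5000, 0.5, seed = 4)))
  g <- generate_genome(1e5, gc = 0.5, seed = 9)
  n_gc <- sum(strsplit(g, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(n_gc / 1e5 - 0.5), 3 * sqrt(0.25 / 1e5))
  expect_error(generate_genome(100, gc = 1), "gc")
})

test_that("motif library: decoys perturb one column, drawing is seeded", {
  lib1 <- generate_motif_library(sprintf("TF%02d", 1:4),
                                 n_background_motifs = 3, seed = 5)
  lib2 <- generate_motif_library(sprintf("TF%02d", 1:4),
                                 n_background_motifs = 3, seed = 5)
  expect_identical(lapply(lib1$pwms, `[[`, "probs"),
                   lapply(lib2$pwms, `[[`, "probs"))
  expect_equal(lib1$canonical_map$TF01, c("CAN_TF01a", "CAN_TF01b"))
  decoy <- lib1$pwms$COF_DECOY_TF03
  canonical <- lib1$pwms[[lib1$canonical_map$TF03[1]]]
  diff_cols <- which(colSums(abs(decoy$probs - canonical$probs)) > 1e-12)
  expect_equal(length(diff_cols), 1L)
  # planted cofactors are guaranteed dissimilar from every canonical
  cans <- lib1$pwms[grep("^CAN_", names(lib1$pwms))]
  for (cof in c("COF_CT01", "COF_TF01", "COF_UBIQ", "COF_HOT")) {
    for (can in cans)
      expect_gte(similarity_pvalue(lib1$pwms[[cof]], can, n_null = 199,
                                   seed = 7)$p_value, 0.2)
  }
})

test_that("compendium structure: non-overlap, planted HOT, plant rates", {
  comp <- generate_compendium(mini_design())
  exps <- comp$experiments
  expect_equal(nrow(exps), 10L)
  expect_true(all(table(paste(exps$cell_type, exps$tf_name)) == 1))

  # non-HOT peaks never overlap, across experiments included
  hot_lo <- min(comp$hot_regions$start)
  pk <- comp$peaks[comp$peaks$end <= hot_lo, ]
  pk <- pk[order(pk$start), ]
  expect_true(all(diff(pk$start) >= (pk$end - pk$start)[-nrow(pk)]))

  # every HOT region is overlapped by peaks from > 50% of experiments
  for (h in seq_len(nrow(comp$hot_regions))) {
    ov <- comp$peaks$start < comp$hot_regions$end[h] &
      comp$peaks$end > comp$hot_regions$start[h]
    expect_gt(length(unique(comp$peaks$exp_id[ov])),
              0.5 * nrow(exps))
  }

  # realized per-experiment plant fractions within binomial 99.9% bounds
  pc <- comp$plant_counts
  expect_true(is.data.frame(pc) && nrow(pc) > 0)
  lo <- qbinom(5e-4, pc$n_class, pc$plant_rate)
  hi <- qbinom(1 - 5e-4, pc$n_class, pc$plant_rate)
  expect_true(all(pc$n_planted >= lo & pc$n_planted <= hi))

  # peak sequences match their genome slices
  idx <- sample(nrow(comp$peaks), 25)
  expect_equal(substring(comp$genome, comp$peaks$start[idx] + 1,
                         comp$peaks$end[idx]),
               unname(comp$peak_sequences[comp$peaks$peak_id[idx]]))

  # one truth row per scenario, all five kinds present
  expect_setequal(comp$truth$kind,
                  c("cell_type_specific", "tf_specific", "ubiquitous",
                    "decoy_similar_to_canonical", "hot_only"))
})

test_that("generation is a pure function of the design", {
  c1 <- generate_compendium(mini_design(seed = 11))
  c2 <- generate_compendium(mini_design(seed = 11))
  expect_identical(c1$genome, c2$genome)
  expect_identical(c1$peaks, c2$peaks)
  expect_identical(c1$peak_sequences, c2$peak_sequences)
  c3 <- generate_compendium(mini_design(seed = 12))
  expect_false(identical(c1$genome, c3$genome))
})

test_that("written compendium is readable by the curation loaders", {
  d <- tempfile()
  on.exit(unlink(d, recursive = TRUE))
  comp <- generate_compendium(mini_design(), out_dir = d)
  exps <- load_experiments(file.path(d, "experiments.tsv"))
  expect_equal(nrow(exps), nrow(comp$experiments))
  cm <- load_canonical_map(file.path(d, "canonical_map.tsv"))
  expect_equal(cm[order(names(cm))],
               comp$canonical_map[order(names(comp$canonical_map))],
               ignore_attr = TRUE)
  pwms <- parse_jaspar(readLines(file.path(d, "motifs.jaspar")),
                       pseudocount = 0)
  expect_equal(length(pwms), length(comp$pwms))
  expect_lt(max(abs(pwms[[1]]$probs - comp$pwms[[1]]$probs)), 5e-3)
  pk <- load_peaks(file.path(d, "peaks", paste0(exps$exp_id[1], ".bed")),
                   exps$exp_id[1])
  withseq <- extract_sequences(pk, file.path(d, "genome.fa"))
  expect_equal(withseq$sequence,
               unname(comp$peak_sequences[withseq$peak_id]))
})

test_that("evaluate_against_truth computes forced precision/recall", {
  truth <- data.frame(
    motif_id = c("A", "B", "C"),
    kind = c("cell_type_specific", "tf_specific", "ubiquitous"),
    key = c("CT1", "TF1", ""), cls = "proximal",
    expected_call = c(TRUE, TRUE, FALSE), stringsAsFactors = FALSE)
  call_row <- function(mid, scope, key)
    data.frame(motif_id = mid, scope = scope, key = key, cls = "proximal",
               stringsAsFactors = FALSE)
  perfect <- rbind(call_row("A", "cell_type", "CT1"),
                   call_row("B", "tf", "TF1"))
  ev <- evaluate_against_truth(perfect, truth)
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 1)

  empty <- evaluate_against_truth(perfect[0, ], truth)
  expect_equal(empty$recall, 0)

  with_fp <- rbind(perfect, call_row("BG01", "tf", "TF1"))
  ev2 <- evaluate_against_truth(with_fp, truth)
  expect_equal(ev2$precision, 2 / 3)
  expect_equal(ev2$recall, 1)
  # a call for the ubiquitous motif is a false positive
  with_ubiq <- rbind(perfect, call_row("C", "tf", "TF1"))
  ev3 <- evaluate_against_truth(with_ubiq, truth)
  expect_lt(ev3$precision, 1)
  expect_false(ev3$outcome$ok[3])
})
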