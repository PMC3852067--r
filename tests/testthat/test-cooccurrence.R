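# screens operate on flag tables; these builders make crafted ones
flag_row <- function(exp_id, motif_id, cls, abundance, flagged = TRUE) {
  data.frame(exp_id = exp_id, motif_id = motif_id, cls = cls,
             n_peaks = 100L, n_present = round(abundance * 100),
             abundance = abundance, q95 = NA_real_, flagged = flagged,
             stringsAsFactors = FALSE)
}

ct_experiments <- function() {
  # CT1: 12 experiments over 6 TFs (2 treatments); CT2/CT3: singles
  rbind(
    data.frame(exp_id = sprintf("E%02d", 1:12),
               tf_name = rep(sprintf("TF%d", 1:6), each = 2),
               cell_type = "CT1", treatment = rep(c("", "tr2"), 6)),
    data.frame(exp_id = sprintf("E%02d", 13:18),
               tf_name = sprintf("TF%d", 1:6), cell_type = "CT2",
               treatment = ""),
    data.frame(exp_id = sprintf("E%02d", 19:24),
               tf_name = sprintf("TF%d", 1:6), cell_type = "CT3",
               treatment = ""))
}

test_that("peak partition unions multiple canonical motifs", {
  canon_a <- rand_pwm(801, width = 9, id = "canA")
  canon_b <- rand_pwm(802, width = 9, id = "canB")
  ctx <- scan_context(list(canon_a, canon_b), background())
  set.seed(31)
  seqs <- vapply(1:10, function(i) rand_dna(4000 + i, 150), "")
  # plant canA in peaks 1-3, canB in peak 4 only
  for (i in 1:3) substr(seqs[i], 60, 68) <- consensus_of(canon_a)
  substr(seqs[4], 60, 68) <- consensus_of(canon_b)
  peaks <- data.frame(peak_id = paste0("E1:", 1:10), exp_id = "E1",
                      chrom = "chr1", start = 0L, end = 150L,
                      sequence = seqs, stringsAsFactors = FALSE)
  exp_row <- data.frame(exp_id = "E1", tf_name = "TFA", cell_type = "CT1",
                        treatment = "")
  part <- partition_peaks(exp_row, peaks, list(TFA = c("canA", "canB")),
                          ctx, presence_p = 1e-4)
  expect_true(all(paste0("E1:", 1:4) %in% part$positive_peak_ids))
  expect_equal(length(part$positive_peak_ids) +
               length(part$negative_peak_ids), 10L)
  expect_error(partition_peaks(exp_row, peaks, list(TFB = "canA"), ctx),
               "canonical")
  empty <- partition_peaks(exp_row, peaks[0, ],
                           list(TFA = "canA"), ctx)
  expect_equal(length(empty$positive_peak_ids), 0L)
})

test_that("abundance table excludes own canonical motifs and omits empty classes", {
  canon_a <- rand_pwm(811, width = 9, id = "canA")
  cof <- rand_pwm(812, width = 9, id = "cof1")
  ctx <- scan_context(list(canon_a, cof), background())
  seqs <- vapply(1:10, function(i) rand_dna(4100 + i, 150), "")
  for (i in 1:4) substr(seqs[i], 30, 38) <- consensus_of(canon_a)
  for (i in c(1, 2, 3)) substr(seqs[i], 80, 88) <- consensus_of(cof)
  peaks <- data.frame(peak_id = paste0("E1:", 1:10), exp_id = "E1",
                      chrom = "chr1", start = 0L, end = 150L,
                      sequence = seqs, stringsAsFactors = FALSE)
  exps <- data.frame(exp_id = "E1", tf_name = "TFA", cell_type = "CT1",
                     treatment = "")
  canon <- list(TFA = "canA")
  part <- partition_peaks(exps[1, ], peaks, canon, ctx, 1e-4)
  rec <- abundance_table(list(part), peaks, exps, canon, ctx, 1e-4)
  expect_false("canA" %in% rec$motif_id)
  prox <- rec[rec$cls == "proximal" & rec$motif_id == "cof1", ]
  expect_equal(prox$n_peaks, length(part$positive_peak_ids))
  expect_gte(prox$n_present, 3L)  # the three planted co-occurrences
  expect_true(all(rec$n_present <= rec$n_peaks))
  # all peaks positive -> no distal class emitted
  allpos <- part
  allpos$positive_peak_ids <- peaks$peak_id
  allpos$negative_peak_ids <- character(0)
  rec2 <- abundance_table(list(allpos), peaks, exps, canon, ctx, 1e-4)
  expect_false("distal" %in% rec2$cls)
})

test_that("percentile flagging matches the interpolated order-statistic formula", {
  ab <- (1:20) / 40
  rec <- flag_row(sprintf("E%02d", 1), sprintf("M%02d", 1:20), "proximal",
                  ab)[, 1:6]
  rec$exp_id <- "E1"
  flags <- suppressWarnings(enrichment_flags(rec, pct = 95))
  # type-7: h = 19 * 0.95 = 18.05, q = x[19] + 0.05 (x[20] - x[19])
  expect_equal(unique(flags$q95), 19 / 40 + 0.05 * (1 / 40))
  expect_equal(flags$motif_id[flags$flagged], "M20")
  # all-equal abundances: nothing exceeds the percentile
  rec$abundance <- 0.2
  flags2 <- suppressWarnings(enrichment_flags(rec, pct = 95))
  expect_false(any(flags2$flagged))
})

test_that("ubiquity filter applies class ceilings to flag fractions", {
  n_exps <- 20L
  flags <- rbind(
    flag_row(sprintf("E%02d", 1:5), "M_prox_ubiq", "proximal", 0.5),  # 25%
    flag_row(sprintf("E%02d", 1:3), "M_prox_ok", "proximal", 0.5),    # 15%
    flag_row(sprintf("E%02d", 1), "M_dist_ok", "distal", 0.5),        # 5%
    flag_row(sprintf("E%02d", 1:3), "M_dist_ubiq", "distal", 0.5),    # 15%
    flag_row(sprintf("E%02d", 6:9), "M_never", "proximal", 0.01,
             flagged = FALSE))
  kept <- ubiquity_filter(flags, n_exps)
  expect_setequal(paste(kept$motif_id, kept$cls),
                  c("M_prox_ok proximal", "M_dist_ok distal"))
})

test_that("cell-type screen enforces experiment, TF and abundance minima", {
  exps <- ct_experiments()
  retained <- data.frame(motif_id = "M1", cls = "proximal")
  # 12 supporting experiments over 6 TFs at 0.6 -> call
  f12 <- flag_row(sprintf("E%02d", 1:12), "M1", "proximal", 0.6)
  calls <- cell_type_specific_screen(f12, retained, exps)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$key, "CT1")
  expect_equal(calls$n_support, 12L)
  # 9 supporting experiments -> below the >=10 rule, no call
  f9 <- flag_row(sprintf("E%02d", 1:9), "M1", "proximal", 0.6)
  expect_equal(nrow(cell_type_specific_screen(f9, retained, exps)), 0L)
  # 12 experiments but all of one TF: TF diversity fails
  exps1tf <- exps
  exps1tf$tf_name[1:12] <- "TF1"
  expect_equal(nrow(cell_type_specific_screen(f12, retained, exps1tf)), 0L)
  # abundance at or below 0.15 does not support
  f_low <- flag_row(sprintf("E%02d", 1:12), "M1", "proximal", 0.15)
  expect_equal(nrow(cell_type_specific_screen(f_low, retained, exps)), 0L)
})

test_that("TF screen demands >0.2 abundance in all flagged sisters", {
  exps <- rbind(ct_experiments(),
                data.frame(exp_id = "E25", tf_name = "TF1",
                           cell_type = "CT4", treatment = ""))
  retained <- data.frame(motif_id = "M1", cls = "proximal")
  # TF1 flagged in CT2, CT3, CT4 at 0.25 -> call
  ok <- flag_row(c("E13", "E19", "E25"), "M1", "proximal", 0.25)
  calls <- tf_specific_screen(ok, retained, exps)
  expect_equal(calls$key, "TF1")
  expect_equal(calls$n_distinct, 3L)
  # one sister at 0.19 -> "above 20% in all experiments" fails
  bad <- ok
  bad$abundance[3] <- 0.19
  expect_equal(nrow(tf_specific_screen(bad, retained, exps)), 0L)
  # only two sisters -> fails
  expect_equal(nrow(tf_specific_screen(ok[1:2, ], retained, exps)), 0L)
  # two sisters in the SAME cell type count once
  same_ct <- flag_row(c("E01", "E02", "E13"), "M1", "proximal", 0.25)
  expect_equal(nrow(tf_specific_screen(same_ct, retained, exps)), 0L)
})

test_that("raising abundance thresholds never adds calls", {
  exps <- ct_experiments()
  set.seed(55)
  for (rep in 1:10) {
    n <- 30L
    flags <- flag_row(sample(exps$exp_id, n, replace = TRUE),
                      sample(paste0("M", 1:4), n, replace = TRUE),
                      sample(c("proximal", "distal"), n, replace = TRUE),
                      runif(n, 0.05, 0.6))
    flags <- flags[!duplicated(flags[c("exp_id", "motif_id", "cls")]), ]
    retained <- unique(flags[c("motif_id", "cls")])
    base_th <- screen_thresholds(ct_min_exps = 2, ct_min_tfs = 2,
                                 tf_min_sisters = 2)
    hi_th <- screen_thresholds(ct_min_abund = 0.3, tf_min_abund = 0.4,
                               ct_min_exps = 2, ct_min_tfs = 2,
                               tf_min_sisters = 2)
    key <- function(x) paste(x$motif_id, x$scope, x$key, x$cls)
    lo_calls <- rbind(cell_type_specific_screen(flags, retained, exps,
                                                base_th),
                      tf_specific_screen(flags, retained, exps, base_th))
    hi_calls <- rbind(cell_type_specific_screen(flags, retained, exps,
                                                hi_th),
                      tf_specific_screen(flags, retained, exps, hi_th))
    expect_true(all(key(hi_calls) %in% key(lo_calls)))
  }
})

test_that("remove_similar drops decoys and keeps unrelated cofactors", {
  target <- rand_pwm(901, width = 10, id = "CAN_TFA")
  cof <- rand_pwm(902, width = 9, id = "COF1")
  # resample the cofactor until genuinely dissimilar from the target,
  # mirroring the generator's guarantee
  s <- 903
  while (similarity_pvalue(cof, target, n_null = 199,
                           seed = 7)$p_value < 0.2) {
    s <- s + 1
    cof <- rand_pwm(s, width = 9, id = "COF1")
  }
  decoy_probs <- target$probs
  tmp <- decoy_probs[, 5]
  decoy_probs[, 5] <- tmp[c(2, 1, 3, 4)]
  decoy <- new_pwm("DECOY", decoy_probs)
  pwms <- list(CAN_TFA = target, COF1 = cof, DECOY = decoy)
  exps <- data.frame(exp_id = c("E1", "E2", "E3"), tf_name = "TFA",
                     cell_type = c("CT1", "CT2", "CT3"), treatment = "")
  calls <- data.frame(motif_id = c("COF1", "DECOY"), scope = "tf",
                      key = "TFA", cls = "proximal", n_support = 3L,
                      n_distinct = 3L, min_abundance = 0.3,
                      supporting_exp_ids = "E1,E2,E3",
                      stringsAsFactors = FALSE)
  out <- remove_similar(calls, list(TFA = "CAN_TFA"), pwms, exps,
                        n_null = 999, seed = 1)
  expect_equal(out$motif_id, "COF1")
  expect_equal(nrow(remove_similar(calls[0, ], list(TFA = "CAN_TFA"),
                                   pwms, exps)), 0L)
})

test_that("report writing is deterministic and summary totals count motifs", {
  calls <- data.frame(motif_id = c("M1", "M2", "M1"),
                      scope = c("tf", "tf", "cell_type"),
                      key = c("TFA", "TFA", "CT1"),
                      cls = c("proximal", "proximal", "distal"),
                      n_support = 3L, n_distinct = 3L,
                      min_abundance = 0.3, supporting_exp_ids = "E1",
                      stringsAsFactors = FALSE)
  flags <- flag_row("E1", c("M1", "M2"), "proximal", c(0.3, 0.4))
  d1 <- tempfile(); d2 <- tempfile()
  on.exit(unlink(c(d1, d2), recursive = TRUE))
  write_reports(calls, flags, d1)
  write_reports(calls, flags, d2)
  summ <- read.csv(file.path(d1, "summary_tf.csv"))
  expect_equal(summ$total[summ$key == "TFA"], 2L)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  # zero calls -> header-only files
  d3 <- tempfile(); on.exit(unlink(d3, recursive = TRUE), add = TRUE)
  write_reports(calls[0, ], flags, d3)
  expect_equal(nrow(read.csv(file.path(d3, "tf_specific.csv"))), 0L)
})
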