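test_that("score distribution matches forced width-1 case and conserves mass", {
  lom <- structure(list(motif_id = "w1", width = 1L,
                        scores = matrix(c(3L, 0L, 0L, 0L), 4,
                                        dimnames = list(c("A", "C", "G", "T"),
                                                        NULL)),
                        scale = 1, offset = 0, background = background()),
                   class = "log_odds_matrix")
  d <- score_distribution(lom, background())
  expect_equal(d$pmf[4], 0.25)          # P(score == 3)
  expect_equal(d$pmf[1], 0.75)          # P(score == 0)
  expect_equal(sum(d$pmf), 1, tolerance = 1e-12)
  expect_equal(score_pvalue(d, 0), 1)
})

test_that("DP tail equals brute-force enumeration (widths <= 6)", {
  bgs <- list(background(), background(c(0.4, 0.1, 0.1, 0.4)),
              background(c(0.2, 0.3, 0.3, 0.2)))
  for (seed in 1:6) {
    p <- rand_flat_pwm(seed, width = sample(3:6, 1))
    for (bg in bgs) {
      lom <- pwm_to_logodds(p, bg, pseudocount = 0.01)
      d <- score_distribution(lom)
      s_grid <- unique(round(seq(0, d$max_score, length.out = 15)))
      expect_lt(max(abs(score_pvalue(d, s_grid) -
                        brute_force_tails(lom, bg, s_grid))), 1e-12)
    }
  }
})

test_that("score_pvalue boundaries and monotonicity", {
  p <- rand_pwm(3, width = 6)
  lom <- pwm_to_logodds(p, background(), 0.01)
  d <- score_distribution(lom)
  expect_equal(score_pvalue(d, 0), 1)
  # consensus-unique maximum: P = (1/4)^width when argmax is unique
  expect_equal(score_pvalue(d, d$max_score), (1 / 4)^6, tolerance = 1e-12)
  ps <- score_pvalue(d, 0:d$max_score)
  expect_true(all(diff(ps) <= 1e-15))
})

test_that("scanning finds planted consensus on both strands", {
  p <- rand_pwm(11, width = 10)
  lom <- pwm_to_logodds(p, background(), 0.01)
  d <- score_distribution(lom)
  cons <- consensus_of(p)
  seq <- rand_dna(99, 100)
  substr(seq, 41, 50) <- cons
  hits <- scan_sequence(seq, lom, d, p_threshold = 1e-4)
  expect_true(any(hits$position == 40 & hits$strand == "+"))
  best <- hits[which.min(hits$p_value), ]
  expect_equal(best$position, 40L)

  seq2 <- rand_dna(99, 100)
  substr(seq2, 41, 50) <- revcomp_str(cons)
  hits2 <- scan_sequence(seq2, lom, d, p_threshold = 1e-4)
  expect_true(any(hits2$position == 40 & hits2$strand == "-"))

  expect_equal(nrow(scan_sequence(strrep("N", 50), lom, d, 1)), 0L)
  expect_equal(nrow(scan_sequence("ACGT", lom, d, 1)), 0L)
})

test_that("strand symmetry: seq/motif vs revcomp-seq/revcomp-motif", {
  # complement-symmetric background, as assumed by shared-distribution
  # double-strand scanning
  p <- rand_pwm(21, width = 8)
  lom <- pwm_to_logodds(p, background(), 0.01)
  d <- score_distribution(lom)
  rc_lom <- pwm_to_logodds(reverse_complement_pwm(p), background(), 0.01)
  rc_d <- score_distribution(rc_lom)
  expect_equal(d$pmf, rc_d$pmf)
  for (seed in 1:10) {
    seq <- rand_dna(seed + 500, 80)
    h1 <- scan_sequence(seq, lom, d, p_threshold = 0.01)
    h2 <- scan_sequence(revcomp_str(seq), rc_lom, rc_d, p_threshold = 0.01)
    expect_equal(nrow(h1), nrow(h2))
    if (nrow(h1)) {
      # mirrored coordinates: start' = L - w - start; a forward match of
      # the motif becomes a forward match of its reverse complement
      key1 <- paste(h1$position, h1$strand, signif(h1$p_value, 12))
      key2 <- paste(80 - 8 - h2$position, h2$strand,
                    signif(h2$p_value, 12))
      expect_setequal(key1, key2)
    }
  }
})

test_that("BH q-values implement the step-up rule", {
  expect_equal(bh_qvalues(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_qvalues(0.5), 0.5)
  expect_equal(bh_qvalues(numeric(0)), numeric(0))
  set.seed(9)
  for (i in 1:5) {
    p <- runif(20)
    q <- bh_qvalues(p)
    expect_true(all(q >= p - 1e-15))
    expect_true(all(q <= 1))
    # step-up equals the stats::p.adjust reference
    expect_equal(q, stats::p.adjust(p, "BH"))
  }
})

test_that("motif_present applies the best-hit presence rule", {
  p <- rand_pwm(31, width = 10)
  lom <- pwm_to_logodds(p, background(), 0.01)
  d <- score_distribution(lom)
  seq <- rand_dna(7, 200)
  substr(seq, 101, 110) <- consensus_of(p)
  call <- motif_present(seq, lom, d, presence_p = 1e-4, peak_id = "pk1")
  expect_true(call$present)
  expect_lte(call$best_p, 1e-4)

  gc_rich <- new_pwm("gc", matrix(rep(c(0.01, 0.54, 0.44, 0.01), 12), 4))
  lom2 <- pwm_to_logodds(gc_rich, background(), 0.01)
  d2 <- score_distribution(lom2)
  aaaa <- strrep("A", 200)
  call2 <- motif_present(aaaa, lom2, d2, presence_p = 1e-4)
  expect_false(call2$present)

  short <- motif_present("ACG", lom, d, 1e-4)
  expect_false(short$present)
  expect_true(is.na(short$best_p))
})

test_that("vectorized presence calls agree with per-peak scanning", {
  p <- rand_pwm(41, width = 9)
  lom <- pwm_to_logodds(p, background(), 0.01)
  d <- score_distribution(lom)
  set.seed(77)
  seqs <- vapply(1:40, function(i) rand_dna(i + 900, 120), "")
  planted <- sample(40, 12)
  for (i in planted) substr(seqs[i], 50, 58) <- consensus_of(p)
  names(seqs) <- paste0("pk", 1:40)
  fast <- presence_calls(seqs, lom, d, 1e-4)
  slow <- vapply(seqs, function(s)
    motif_present(s, lom, d, 1e-4)$present, TRUE)
  expect_equal(fast, slow)
  expect_true(all(fast[planted]))
})

test_that("hit export writes 1-based inclusive coordinates", {
  p <- rand_pwm(51, width = 8)
  lom <- pwm_to_logodds(p, background(), 0.01)
  d <- score_distribution(lom)
  seq <- rand_dna(13, 60)
  substr(seq, 21, 28) <- consensus_of(p)
  hits <- scan_sequence(seq, lom, d, p_threshold = 1e-3, seq_id = "s1")
  f <- tempfile(fileext = ".tsv")
  on.exit(unlink(f))
  out <- write_hits_tsv(hits, width = 8, path = f)
  expect_equal(out$start[out$p.value == min(out$p.value)][1], 21L)
  expect_equal(out$stop - out$start, rep(7L, nrow(out)))
  expect_true(all(out$q.value >= out$p.value - 1e-15))
})
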