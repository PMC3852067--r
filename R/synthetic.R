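#' Default experiment grid of the synthetic compendium
#'
#' One row per experiment: repeated (cell type, TF) pairs stand for
#' treatment replicates, as in real compendia where one TF is assayed in
#' one cell line under several treatments or with several antibodies.
#' The grid is sized so that the screens' own thresholds are satisfiable:
#' a cell-type-specific call needs >= 10 supporting experiments in one
#' cell type while staying under the 20% proximal ubiquity ceiling, which
#' requires well over 60 experiments in total (the real compendium the
#' method was designed for had 81).  Besides the 133 curated experiments
#' it contains a CTCF experiment, an orphan TF and a TF without canonical
#' motif so that every curation filter is exercised end to end.
#'
#' @return data.frame: cell_type, tf_name (one row per experiment).
#' @export
default_experiment_grid <- function() {
  g <- function(ct, tfs, times) data.frame(cell_type = ct,
                                           tf_name = rep(tfs, times),
                                           stringsAsFactors = FALSE)
  rbind(
    g("CT01", paste0("TF", sprintf("%02d", 1:6)), 2),
    g("CT02", c("TF01", "TF03", "TF02", "TF07", "TF08", "TF09"),
      c(1, 1, 5, 6, 6, 5)),
    g("CT03", c("TF01", "TF04", "TF07", "TF10", "TF11"),
      c(1, 5, 6, 6, 6)),
    g("CT04", c("TF01", "TF05", "TF08", "TF10", "TF12"),
      c(1, 5, 6, 6, 6)),
    g("CT05", c("TF03", "TF06", "TF09", "TF11", "TF12"),
      c(1, 5, 6, 6, 6)),
    g("CT06", c("TF03", "TF07", "TF08", "TF10", "TF11", "TF12"),
      c(1, 5, 5, 4, 5, 5)),
    # exercised by curation, removed before screening:
    g("CT02", "CTCF", 1),          # excluded TF
    g("CT03", "TF13", 1),          # orphan (single cell type)
    g(c("CT02", "CT04"), "TF14", 1)  # no canonical motif in the map
  )
}

#' Default cofactor scenarios
#'
#' One scenario per planted-pattern kind.  All plants are proximal
#' (inserted into canonical-positive peaks): with the structural ~5%
#' chance-flag rate of the 95th-percentile rule, the 10% distal ubiquity
#' ceiling would require a compendium of several hundred experiments for
#' robust distal recovery, so distal screen logic is validated on
#' constructed tables instead.  Plant rates are >= 1.5x the abundance
#' thresholds they must clear, leaving margin for scanner misses on
#' PWM-sampled (non-consensus) planted words.
#'
#' @return data.frame: motif_id, kind, key, cls, plant_rate, expected_call.
#' @export
default_scenarios <- function() {
  data.frame(
    motif_id = c("COF_CT01", "COF_TF01", "COF_UBIQ", "COF_DECOY_TF03",
                 "COF_HOT"),
    kind = c("cell_type_specific", "tf_specific", "ubiquitous",
             "decoy_similar_to_canonical", "hot_only"),
    key = c("CT01", "TF01", "", "TF03", ""),
    cls = "proximal",
    plant_rate = c(0.6, 0.4, 0.5, 0.4, 0.9),
    expected_call = c(TRUE, TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

#' Synthetic compendium design
#'
#' Collects every knob of the generator.  The defaults ARE the stated
#' world of the end-to-end recovery tests: change them only to explore.
#'
#' @param grid Experiment grid (cell_type, tf_name per experiment).
#' @param scenarios Scenario table as in [default_scenarios()].
#' @param peaks_per_exp Regular (non-HOT) peaks per experiment.
#' @param peak_len Peak width in nt.
#' @param gc Genome GC fraction in (0,1).
#' @param canonical_plant_rate Fraction of each experiment's peaks that
#'   receive a word sampled from the target TF's canonical PWM (the
#'   compendium the method was built for had ~31% canonical-positive
#'   peaks).
#' @param ubiquitous_exp_fraction Fraction of curated experiments in
#'   which an `ubiquitous` scenario motif is planted (>= 0.3).
#' @param n_background_motifs Decoy-free random library motifs.
#' @param widths Candidate motif widths (within 6..15).
#' @param ic_range Range of the per-column dominant-base probability.
#' @param hot_region_count Planted HOT regions.
#' @param hot_exp_fraction Fraction of curated experiments given a peak
#'   in each HOT region (must exceed 0.5 for the region to be HOT).
#' @param seed Integer seed; all outputs are pure functions of the design.
#' @return list of class `compendium_design`.
#' @export
compendium_design <- function(grid = default_experiment_grid(),
                              scenarios = default_scenarios(),
                              peaks_per_exp = 300L, peak_len = 200L,
                              gc = 0.5, canonical_plant_rate = 0.35,
                              ubiquitous_exp_fraction = 0.4,
                              n_background_motifs = 15L,
                              widths = 8:12, ic_range = c(0.80, 0.97),
                              hot_region_count = 2L,
                              hot_exp_fraction = 0.75, seed = 42L) {
  stopifnot(gc > 0, gc < 1, canonical_plant_rate > 0,
            canonical_plant_rate < 1, all(widths >= 6), all(widths <= 15),
            peak_len >= max(widths), hot_exp_fraction > 0.5)
  structure(list(grid = grid, scenarios = scenarios,
                 peaks_per_exp = as.integer(peaks_per_exp),
                 peak_len = as.integer(peak_len), gc = gc,
                 canonical_plant_rate = canonical_plant_rate,
                 ubiquitous_exp_fraction = ubiquitous_exp_fraction,
                 n_background_motifs = as.integer(n_background_motifs),
                 widths = widths, ic_range = ic_range,
                 hot_region_count = as.integer(hot_region_count),
                 hot_exp_fraction = hot_exp_fraction,
                 seed = as.integer(seed)),
            class = "compendium_design")
}

.random_dna <- function(n, gc = 0.5) {
  if (n <= 0L) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(BASES, n, replace = TRUE, prob = p), collapse = "")
}

#' Generate a random genome sequence
#'
#' I.i.d. bases with P(G) = P(C) = gc/2; seeded and reproducible.
#'
#' @param genome_len Length in nt.
#' @param gc GC fraction, strictly inside (0,1).
#' @param seed Integer seed.
#' @param chrom Chromosome name.
#' @return Named character vector of length 1 (chromosome -> sequence).
#' @export
generate_genome <- function(genome_len, gc = 0.5, seed = 1,
                            chrom = "chr1") {
  if (gc <= 0 || gc >= 1) stop("gc must be strictly inside (0,1)")
  withr_seed(seed, setNames(.random_dna(genome_len, gc), chrom))
}

.random_pwm_probs <- function(width, ic_range) {
  # dominant base with probability drawn from ic_range; the remaining
  # mass is split UNEVENLY over the minor bases (equal minors would make
  # all same-dominant columns exactly collinear, degenerate for the
  # correlation-based similarity metric)
  dom <- sample.int(4L, width, replace = TRUE)
  p <- runif(width, ic_range[1L], ic_range[2L])
  probs <- matrix(0, 4, width)
  for (i in seq_len(width)) {
    m <- runif(3L, 0.2, 1)
    probs[-dom[i], i] <- (1 - p[i]) * m / sum(m)
    probs[dom[i], i] <- p[i]
  }
  rownames(probs) <- BASES
  probs
}

.perturb_one_column <- function(probs) {
  # decoy construction: rotate the dominant base of the middle column
  i <- ceiling(ncol(probs) / 2)
  col <- probs[, i]
  dom <- which.max(col)
  new_dom <- dom %% 4L + 1L
  col2 <- col
  col2[new_dom] <- col[dom]
  col2[dom] <- col[new_dom]
  probs[, i] <- col2
  probs
}

.near_duplicate <- function(pwm, others, max_score = 0.8) {
  # cheap guard against accidental near-copies; the empirical similarity
  # p-value of UNRELATED pairs is uniform by construction, so demanding
  # p >= 0.2 for every pair of a whole library is not attainable by
  # rejection -- the exact check is reserved for the pairs that the
  # false-positive removal will actually test (scenario cofactor vs
  # canonical motifs)
  for (o in others) {
    if (best_ungapped_alignment(pwm, o)$mean_column_score >= max_score)
      return(TRUE)
  }
  FALSE
}

.similar_to_any <- function(pwm, targets, p_min = 0.2, n_null = 199,
                            seed = 7) {
  for (t in targets) {
    if (similarity_pvalue(pwm, t, n_null = n_null, seed = seed)$p_value <
        p_min)
      return(TRUE)
  }
  FALSE
}

#' Generate the synthetic motif library
#'
#' Canonical motifs (two for any TF listed in `multi_canonical_tfs`, one
#' otherwise), one cofactor motif per scenario (decoys are a one-column
#' perturbation of the key TF's first canonical motif), and background
#' motifs.  Dissimilarity at generation is two-tier: every draw is
#' rejected if it is a near-duplicate (best alignment mean column score
#' >= 0.8) of an existing non-decoy motif, and non-decoy scenario
#' cofactors are additionally resampled until their empirical similarity
#' p-value against every canonical motif is >= 0.2, which guarantees the
#' downstream false-positive removal (alpha 0.05) keeps them.
#'
#' @param tf_names TFs needing canonical motifs.
#' @param scenarios Scenario table.
#' @param n_background_motifs Number of background motifs.
#' @param widths,ic_range As in [compendium_design()].
#' @param multi_canonical_tfs TFs given two canonical motifs.
#' @param seed Integer seed.
#' @return list(pwms = named list of `pwm`, canonical_map = tf -> motif ids).
#' @export
generate_motif_library <- function(tf_names, scenarios = default_scenarios(),
                                   n_background_motifs = 15L,
                                   widths = 8:12, ic_range = c(0.80, 0.97),
                                   multi_canonical_tfs = tf_names[1L],
                                   seed = 1) {
  stopifnot(all(widths >= 6), all(widths <= 15))
  withr_seed(seed, {
    pwms <- list()
    canon <- list()
    draw <- function(id, avoid_similar_to = list(), max_try = 500L) {
      for (try in seq_len(max_try)) {
        probs <- .random_pwm_probs(sample(widths, 1L), ic_range)
        cand <- new_pwm(id, probs, source = "synthetic")
        if (.near_duplicate(cand, pwms)) next
        if (length(avoid_similar_to) &&
            .similar_to_any(cand, avoid_similar_to)) next
        return(cand)
      }
      stop("could not draw a dissimilar motif for '", id, "' after ",
           max_try, " retries")
    }
    for (tf in tf_names) {
      ids <- if (tf %in% multi_canonical_tfs)
        paste0("CAN_", tf, c("a", "b")) else paste0("CAN_", tf)
      for (id in ids) pwms[[id]] <- draw(id)
      canon[[tf]] <- ids
    }
    canonical_pwms <- pwms
    for (i in seq_len(nrow(scenarios))) {
      id <- scenarios$motif_id[i]
      if (scenarios$kind[i] == "decoy_similar_to_canonical") {
        base <- pwms[[canon[[scenarios$key[i]]][1L]]]
        pwms[[id]] <- new_pwm(id, .perturb_one_column(base$probs),
                              source = "synthetic")
      } else {
        pwms[[id]] <- draw(id, avoid_similar_to = canonical_pwms)
      }
    }
    for (i in seq_len(n_background_motifs))
      pwms[[sprintf("BG%02d", i)]] <- draw(sprintf("BG%02d", i))
    list(pwms = pwms, canonical_map = canon)
  })
}

.sample_word <- function(pwm) {
  paste(vapply(seq_len(pwm$width), function(i)
    sample(BASES, 1L, prob = pwm$probs[, i]), ""), collapse = "")
}

.revcomp_str <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1L]]), collapse = "")
}

.plant_words <- function(seq, words) {
  # insert words at non-overlapping uniform offsets, random strand
  len <- nchar(seq)
  taken <- integer(0)
  for (w in words) {
    wl <- nchar(w)
    for (try in 1:50) {
      pos <- sample.int(len - wl + 1L, 1L)
      if (!any(abs(pos - taken) < wl + 2L)) break
    }
    taken <- c(taken, pos)
    word <- if (runif(1) < 0.5) w else .revcomp_str(w)
    substr(seq, pos, pos + wl - 1L) <- word
  }
  seq
}

#' Generate a full synthetic compendium with planted ground truth
#'
#' Builds the genome, motif library, experiment metadata, per-experiment
#' peaks with planted canonical and scenario motif words, planted HOT
#' regions, and the truth table.  Peaks of different experiments never
#' overlap except inside the planted HOT regions, so co-occurrence
#' abundances are not contaminated across experiments.  Planted words are
#' sampled from the PWM (not the consensus) on a random strand, so the
#' screens exercise the scanner rather than string matching.
#'
#' @param design A [compendium_design()].
#' @param out_dir If non-NULL, writes genome.fa, peaks/<exp_id>.bed,
#'   experiments.tsv, canonical_map.tsv, motifs.jaspar and truth.csv
#'   there.
#' @return list(genome, experiments, peaks, pwms, canonical_map, truth,
#'   hot_regions).
#' @export
generate_compendium <- function(design = compendium_design(),
                                out_dir = NULL) {
  stopifnot(inherits(design, "compendium_design"))
  withr_seed(design$seed, {
    grid <- design$grid
    n_exp <- nrow(grid)
    exps <- data.frame(exp_id = sprintf("E%03d", seq_len(n_exp)),
                       tf_name = grid$tf_name, cell_type = grid$cell_type,
                       stringsAsFactors = FALSE)
    key <- paste(exps$cell_type, exps$tf_name)
    exps$treatment <- ""
    for (k in unique(key)) {
      ix <- which(key == k)
      if (length(ix) > 1L)
        exps$treatment[ix] <- paste0("tr", seq_along(ix))
    }

    lib <- generate_motif_library(
      setdiff(unique(grid$tf_name), "TF14"), design$scenarios,
      design$n_background_motifs, design$widths, design$ic_range,
      multi_canonical_tfs = "TF01", seed = design$seed + 1L)
    pwms <- lib$pwms
    canon <- lib$canonical_map

    # experiments that survive curation (the generator mirrors the
    # filters so HOT planting and scenario fractions use the right set)
    curated <- !(exps$tf_name %in% c("CTCF", "TF13", "TF14"))
    curated_ids <- exps$exp_id[curated]

    sc <- design$scenarios
    ubiq_rows <- which(sc$kind == "ubiquitous")
    ubiq_exps <- lapply(ubiq_rows, function(i)
      sample(curated_ids,
             max(ceiling(design$ubiquitous_exp_fraction *
                         length(curated_ids)), 1L)))
    names(ubiq_exps) <- sc$motif_id[ubiq_rows]

    # which scenario motifs are planted in a given experiment's peaks
    plants_for <- function(exp_row) {
      out <- list()
      for (i in seq_len(nrow(sc))) {
        hit <- switch(sc$kind[i],
          cell_type_specific = exp_row$cell_type == sc$key[i],
          tf_specific = exp_row$tf_name == sc$key[i],
          decoy_similar_to_canonical = exp_row$tf_name == sc$key[i],
          ubiquitous = exp_row$exp_id %in% ubiq_exps[[sc$motif_id[i]]],
          hot_only = FALSE)
        if (hit) out[[length(out) + 1L]] <- sc[i, ]
      }
      out
    }

    # ---- genome layout: non-overlapping peak slots + HOT blocks ----
    plen <- design$peak_len
    gap <- 12L
    n_slots <- n_exp * design$peaks_per_exp
    slot_span <- plen + gap
    hot_span <- plen + 100L + 200L
    genome_len <- n_slots * slot_span +
      design$hot_region_count * hot_span + 1000L

    slot_starts <- (seq_len(n_slots) - 1L) * slot_span +
      sample.int(gap, n_slots, replace = TRUE)
    # random interleaving of experiments along the genome
    slot_exp <- sample(rep(seq_len(n_exp), design$peaks_per_exp))

    hot_base <- n_slots * slot_span + 500L
    hot_starts <- hot_base + (seq_len(design$hot_region_count) - 1L) *
      hot_span
    hot_regions <- data.frame(chrom = "chr1", start = hot_starts,
                              end = hot_starts + plen + 100L,
                              stringsAsFactors = FALSE)

    # ---- per-experiment peak construction ----
    peak_rows <- vector("list", n_exp)
    plant_counts <- list()
    pieces <- character(0)        # (start, seq) fragments of the genome
    piece_starts <- integer(0)

    hot_motifs <- sc$motif_id[sc$kind == "hot_only"]
    n_hot_exps <- ceiling(design$hot_exp_fraction * length(curated_ids))
    hot_members <- lapply(seq_len(design$hot_region_count), function(i)
      sample(curated_ids, n_hot_exps))

    for (e in seq_len(n_exp)) {
      exp_row <- exps[e, ]
      my_slots <- which(slot_exp == e)
      starts <- sort(slot_starts[my_slots])
      n_pk <- length(starts)
      n_pos <- round(design$canonical_plant_rate * n_pk)
      pos_idx <- sort(sample.int(n_pk, n_pos))
      can_ids <- if (exp_row$tf_name %in% names(canon))
        canon[[exp_row$tf_name]] else character(0)
      plant_list <- plants_for(exp_row)
      planted <- setNames(integer(length(plant_list)),
                          vapply(plant_list, function(p) p$motif_id, ""))
      seqs <- character(n_pk)
      for (k in seq_len(n_pk)) {
        words <- character(0)
        if (k %in% pos_idx && length(can_ids)) {
          cid <- can_ids[(match(k, pos_idx) - 1L) %% length(can_ids) + 1L]
          words <- .sample_word(pwms[[cid]])
        }
        for (p in plant_list) {
          in_class <- if (p$cls == "proximal") k %in% pos_idx
                      else !(k %in% pos_idx)
          if (in_class && runif(1) < p$plant_rate) {
            words <- c(words, .sample_word(pwms[[p$motif_id]]))
            planted[p$motif_id] <- planted[p$motif_id] + 1L
          }
        }
        seqs[k] <- .plant_words(.random_dna(plen, design$gc), words)
      }
      if (length(plant_list))
        plant_counts[[length(plant_counts) + 1L]] <- data.frame(
          exp_id = exp_row$exp_id, motif_id = names(planted),
          n_planted = unname(planted),
          n_class = vapply(plant_list, function(p)
            if (p$cls == "proximal") length(pos_idx)
            else n_pk - length(pos_idx), 0L),
          plant_rate = vapply(plant_list, function(p) p$plant_rate, 0),
          stringsAsFactors = FALSE)
      # HOT peaks: one per HOT region the experiment belongs to
      hstarts <- integer(0); hseqs <- character(0)
      for (h in seq_len(design$hot_region_count)) {
        if (!exp_row$exp_id %in% hot_members[[h]]) next
        off <- sample.int(100L, 1L)
        hs <- hot_regions$start[h] + off
        words <- unlist(lapply(hot_motifs, function(m)
          if (runif(1) < sc$plant_rate[sc$motif_id == m])
            .sample_word(pwms[[m]]) else NULL))
        hstarts <- c(hstarts, hs)
        hseqs <- c(hseqs, .plant_words(.random_dna(plen, design$gc),
                                       words))
      }
      all_starts <- c(starts, hstarts)
      all_seqs <- c(seqs, hseqs)
      o <- order(all_starts)
      peak_rows[[e]] <- data.frame(exp_id = exp_row$exp_id, chrom = "chr1",
                                   start = all_starts[o],
                                   end = all_starts[o] + plen,
                                   sequence = all_seqs[o],
                                   stringsAsFactors = FALSE)
      pieces <- c(pieces, all_seqs[o])
      piece_starts <- c(piece_starts, all_starts[o])
    }

    peaks <- do.call(rbind, peak_rows)
    peaks$peak_id <- paste0(peaks$exp_id, ":",
                            ave(seq_len(nrow(peaks)), peaks$exp_id,
                                FUN = seq_along))
    peaks <- peaks[, c("peak_id", "exp_id", "chrom", "start", "end",
                       "sequence")]

    # ---- assemble the genome from fragments ----
    # HOT peaks of different experiments overlap; later fragments win on
    # the overlapped bases, which is irrelevant because every HOT peak of
    # a region shares the same planted content class and is removed by
    # curation anyway.  Regular slots never overlap.
    o <- order(piece_starts)
    pieces <- pieces[o]; piece_starts <- piece_starts[o]
    frag <- character(2L * length(pieces) + 1L)
    nf <- 0L
    cursor <- 0L
    for (i in seq_along(pieces)) {
      s <- piece_starts[i]
      if (s < cursor) {  # overlap (HOT): keep only the non-overlapped tail
        cut <- cursor - s
        if (cut >= nchar(pieces[i])) next
        pieces[i] <- substring(pieces[i], cut + 1L)
        s <- cursor
      }
      if (s > cursor) {
        nf <- nf + 1L
        frag[nf] <- .random_dna(s - cursor, design$gc)
      }
      nf <- nf + 1L
      frag[nf] <- pieces[i]
      cursor <- s + nchar(pieces[i])
    }
    if (cursor < genome_len) {
      nf <- nf + 1L
      frag[nf] <- .random_dna(genome_len - cursor, design$gc)
    }
    genome <- setNames(paste(frag[seq_len(nf)], collapse = ""), "chr1")
    # overlapping HOT peaks are trimmed during assembly (first writer
    # wins on overlapped bases); re-slice so stored sequences always
    # match the final genome
    peaks$sequence <- substring(genome, peaks$start + 1L, peaks$end)

    truth <- data.frame(motif_id = sc$motif_id, kind = sc$kind,
                        key = sc$key, cls = sc$cls,
                        expected_call = sc$expected_call,
                        stringsAsFactors = FALSE)

    res <- list(genome = genome, experiments = exps,
                peaks = peaks[, names(peaks) != "sequence"],
                peak_sequences = setNames(peaks$sequence, peaks$peak_id),
                pwms = pwms, canonical_map = canon, truth = truth,
                hot_regions = hot_regions,
                plant_counts = if (length(plant_counts))
                  do.call(rbind, plant_counts) else NULL)
    if (!is.null(out_dir)) write_compendium(res, out_dir)
    res
  })
}

#' Write a generated compendium to disk
#'
#' Emits exactly the formats the curation stage reads: genome.fa,
#' peaks/<exp_id>.bed (BED3), experiments.tsv, canonical_map.tsv,
#' motifs.jaspar (counts scaled from probabilities) and truth.csv.
#'
#' @param comp Result of [generate_compendium()].
#' @param out_dir Output directory.
#' @return Invisibly, `out_dir`.
#' @export
write_compendium <- function(comp, out_dir) {
  dir.create(file.path(out_dir, "peaks"), showWarnings = FALSE,
             recursive = TRUE)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(comp$genome), file.path(out_dir, "genome.fa"))
  for (ex in unique(comp$peaks$exp_id)) {
    pk <- comp$peaks[comp$peaks$exp_id == ex, , drop = FALSE]
    writeLines(paste(pk$chrom, pk$start, pk$end, sep = "\t"),
               file.path(out_dir, "peaks", paste0(ex, ".bed")))
  }
  write.table(comp$experiments, file.path(out_dir, "experiments.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cm <- data.frame(
    tf_name = rep(names(comp$canonical_map),
                  lengths(comp$canonical_map)),
    motif_id = unlist(comp$canonical_map, use.names = FALSE))
  write.table(cm, file.path(out_dir, "canonical_map.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(unlist(lapply(comp$pwms, function(p) {
    counts <- round(p$probs * 1000)
    c(paste0(">", p$motif_id, " ", p$name),
      vapply(BASES, function(b)
        paste0(b, " [", paste(counts[b, ], collapse = " "), "]"), ""))
  })), file.path(out_dir, "motifs.jaspar"))
  write.csv(comp$truth, file.path(out_dir, "truth.csv"),
            row.names = FALSE, quote = FALSE)
  invisible(out_dir)
}

#' Score specificity calls against the planted truth
#'
#' A truth row with expected_call = TRUE is recovered iff some call
#' matches its (motif_id, scope kind, key).  Precision counts any call
#' for a motif outside the expected set (including background motifs) as
#' a false positive; duplicate-class calls for one expected (motif, key)
#' count once.
#'
#' @param calls Call table from the screens.
#' @param truth Truth table from [generate_compendium()].
#' @return list(precision, recall, outcome = per-truth-row table,
#'   false_positives = offending calls).
#' @export
evaluate_against_truth <- function(calls, truth) {
  stopifnot(nrow(truth) > 0L)
  scope_of <- c(cell_type_specific = "cell_type", tf_specific = "tf")
  expected <- truth[truth$expected_call, , drop = FALSE]
  exp_keys <- paste(expected$motif_id, scope_of[expected$kind],
                    expected$key)
  call_keys <- unique(paste(calls$motif_id, calls$scope, calls$key))
  recovered <- exp_keys %in% call_keys
  fp <- setdiff(call_keys, exp_keys)
  tp <- sum(recovered)
  precision <- if (length(call_keys) == 0L) 1 else
    tp / (tp + length(fp))
  recall <- if (length(exp_keys) == 0L) 1 else tp / length(exp_keys)
  outcome <- truth
  outcome$called <- paste(truth$motif_id, scope_of[truth$kind],
                          truth$key) %in% call_keys |
    truth$motif_id %in% calls$motif_id
  outcome$ok <- ifelse(truth$expected_call,
                       paste(truth$motif_id, scope_of[truth$kind],
                             truth$key) %in% call_keys,
                       !truth$motif_id %in% calls$motif_id)
  list(precision = precision, recall = recall, outcome = outcome,
       false_positives = fp)
}
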