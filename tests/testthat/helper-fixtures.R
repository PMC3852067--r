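# Fixture builders and independent oracles shared across test files.

# random informative PWM with uneven minor-base mass
rand_pwm <- function(seed, width = 8L, id = paste0("P", seed),
                     ic = c(0.8, 0.97)) {
  set.seed(seed)
  probs <- matrix(0, 4, width)
  dom <- sample.int(4L, width, replace = TRUE)
  p <- runif(width, ic[1], ic[2])
  for (i in seq_len(width)) {
    m <- runif(3, 0.2, 1)
    probs[-dom[i], i] <- (1 - p[i]) * m / sum(m)
    probs[dom[i], i] <- p[i]
  }
  new_pwm(id, probs)
}

rand_flat_pwm <- function(seed, width = 5L, id = paste0("F", seed)) {
  set.seed(seed)
  probs <- matrix(runif(4 * width), 4, width)
  new_pwm(id, sweep(probs, 2, colSums(probs), "/"))
}

consensus_of <- function(pwm) {
  paste(c("A", "C", "G", "T")[apply(pwm$probs, 2, which.max)],
        collapse = "")
}

revcomp_str <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

rand_dna <- function(seed, n) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# ORACLE: exact tail probabilities by enumeration over all 4^width words
brute_force_tails <- function(lom, bg, scores) {
  w <- lom$width
  words <- as.matrix(expand.grid(rep(list(1:4), w)))
  tot <- vapply(seq_len(nrow(words)), function(i)
    sum(lom$scores[cbind(words[i, ], seq_len(w))]), 0)
  pr <- vapply(seq_len(nrow(words)), function(i)
    prod(bg[words[i, ]]), 0)
  vapply(scores, function(s) sum(pr[tot >= s]), 0)
}

# ORACLE: HOT intervals by per-base counting of distinct experiments
brute_force_hot <- function(peaks, n_experiments, hot_fraction,
                            max_coord = 1000L) {
  out <- list()
  for (chr in sort(unique(peaks$chrom))) {
    pk <- peaks[peaks$chrom == chr, , drop = FALSE]
    cov <- matrix(FALSE, max_coord, length(unique(pk$exp_id)),
                  dimnames = list(NULL, unique(pk$exp_id)))
    for (i in seq_len(nrow(pk))) {
      cov[(pk$start[i] + 1):pk$end[i], pk$exp_id[i]] <- TRUE
    }
    hot_base <- rowSums(cov) > hot_fraction * n_experiments
    r <- rle(hot_base)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    if (length(keep))
      out[[chr]] <- data.frame(chrom = chr, start = starts[keep] - 1L,
                               end = ends[keep],
                               stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# a tiny curated-experiment table for screen-logic tests
toy_experiments <- function(n_ct = 3L, tfs_per_ct = 4L) {
  ct <- rep(sprintf("CT%d", seq_len(n_ct)), each = tfs_per_ct)
  tf <- sprintf("TF%d", rep(seq_len(tfs_per_ct), n_ct))
  data.frame(exp_id = sprintf("E%02d", seq_along(ct)), tf_name = tf,
             cell_type = ct, treatment = "", stringsAsFactors = FALSE)
}

# cache for the expensive default-design end-to-end fixture; built once
# per test run, shared by the acceptance criteria
.e2e_cache <- new.env(parent = emptyenv())

default_e2e <- function() {
  if (is.null(.e2e_cache$res)) {
    dir <- file.path(tempdir(), "cofactorscreen-e2e")
    comp_dir <- file.path(dir, "comp")
    out_dir <- file.path(dir, "run1")
    comp <- generate_compendium(compendium_design(seed = 42L),
                                out_dir = comp_dir)
    cfg <- pipeline_config(
      genome = file.path(comp_dir, "genome.fa"),
      peaks_dir = file.path(comp_dir, "peaks"),
      metadata = file.path(comp_dir, "experiments.tsv"),
      motifs = file.path(comp_dir, "motifs.jaspar"),
      canonical_map = file.path(comp_dir, "canonical_map.tsv"),
      out_dir = out_dir, seed = 1L)
    res <- suppressMessages(run_pipeline(cfg))
    .e2e_cache$res <- list(comp = comp, comp_dir = comp_dir,
                           out_dir = out_dir, result = res)
  }
  .e2e_cache$res
}
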