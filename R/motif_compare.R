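#' Similarity of two PWM columns
#'
#' Pearson correlation of the two probability 4-vectors (one of the
#' published TOMTOM column metrics): bounded in [-1, 1], symmetric and
#' scale-free.  A zero-variance (exactly uniform) column returns 0 by
#' convention.
#'
#' @param col_a,col_b Numeric length-4 probability vectors summing to 1.
#' @return Similarity in [-1, 1].
#' @export
column_similarity <- function(col_a, col_b) {
  va <- stats::var(col_a)
  vb <- stats::var(col_b)
  if (va < 1e-18 || vb < 1e-18) return(0)
  stats::cor(col_a, col_b)
}

# standardized columns such that t(.zcols(a)) %*% .zcols(b) is the matrix
# of column Pearson correlations; uniform columns become zero vectors,
# realizing the cor = 0 convention
.zcols <- function(probs) {
  mu <- colMeans(probs)
  ctr <- sweep(probs, 2, mu)
  ss <- sqrt(colSums(ctr^2))
  ss[ss < 1e-12] <- Inf
  sweep(ctr, 2, ss, "/")
}

# C_fwd[i, j] = cor(query col i, target col j)
# D[i, j]     = cor(query col i, reverse-complemented target col j)
# (complementing a column reverses its 4-vector in A,C,G,T order)
.cor_matrices <- function(query_probs, target_probs) {
  zq <- .zcols(query_probs)
  zt <- .zcols(target_probs)
  list(fwd = crossprod(zq, zt), swap = crossprod(zq, zt[4:1, , drop = FALSE]))
}

# best ungapped alignment given the correlation matrix of one target
# orientation; returns score/offset/overlap (ties: larger overlap, then
# smaller |offset|)
.best_diag <- function(C, min_overlap) {
  wa <- nrow(C); wb <- ncol(C)
  best <- list(score = -Inf, offset = 0L, overlap = 0L)
  for (o in (-(wa - min_overlap)):(wb - min_overlap)) {
    i <- max(1L, 1L - o):min(wa, wb - o)
    sc <- mean(C[cbind(i, i + o)])
    ov <- length(i)
    if (sc > best$score + 1e-12 ||
        (abs(sc - best$score) <= 1e-12 &&
         (ov > best$overlap ||
          (ov == best$overlap && abs(o) < abs(best$offset)))))
      best <- list(score = sc, offset = o, overlap = ov)
  }
  best
}

#' Best ungapped alignment between two motifs
#'
#' Maximizes the mean column similarity over all offsets with overlap at
#' least `min_overlap`, considering the target in both orientations.
#' Ties are broken by larger overlap, then smaller absolute offset, then
#' forward orientation.  `offset` is the query start minus the target
#' start in the coordinates of the chosen target orientation.
#'
#' @param query,target `pwm` objects.
#' @param min_overlap Minimum aligned columns (default `min(4, widths)`).
#' @return list(query_id, target_id, offset, orientation,
#'   mean_column_score, overlap).
#' @export
best_ungapped_alignment <- function(query, target,
                                    min_overlap = min(4L, query$width,
                                                      target$width)) {
  stopifnot(inherits(query, "pwm"), inherits(target, "pwm"))
  if (min_overlap > min(query$width, target$width))
    stop("min_overlap exceeds the smaller motif width")
  cm <- .cor_matrices(query$probs, target$probs)
  wb <- target$width
  # reverse orientation: col j of rc(target) is the complemented col
  # wb+1-j of the target, so its correlation row is D[, wb+1-j]
  C_rev <- cm$swap[, rev(seq_len(wb)), drop = FALSE]
  bf <- .best_diag(cm$fwd, min_overlap)
  br <- .best_diag(C_rev, min_overlap)
  pick_rev <- br$score > bf$score + 1e-12 ||
    (abs(br$score - bf$score) <= 1e-12 &&
     (br$overlap > bf$overlap ||
      (br$overlap == bf$overlap && abs(br$offset) < abs(bf$offset))))
  b <- if (pick_rev) br else bf
  list(query_id = query$motif_id, target_id = target$motif_id,
       offset = b$offset, orientation = if (pick_rev) "reverse" else "forward",
       mean_column_score = b$score, overlap = b$overlap)
}

#' Empirical similarity p-value by column-order shuffling
#'
#' Null distribution: best ungapped alignment scores (both orientations)
#' of the query against `n_null` copies of the target with independently
#' permuted column order.  p = (1 + #\{null >= observed\}) / (n_null + 1);
#' seeded and reproducible.  Permuting the target's columns only permutes
#' the columns of the precomputed correlation matrices, so the null
#' costs indexing, not realignment.
#'
#' @inheritParams best_ungapped_alignment
#' @param n_null Number of shuffled targets (>= 100; default 999).
#' @param seed Integer seed for the permutations.
#' @return The [best_ungapped_alignment()] result with `p_value` added.
#' @export
similarity_pvalue <- function(query, target, n_null = 999, seed = 1,
                              min_overlap = min(4L, query$width,
                                                target$width)) {
  if (n_null < 100) stop("n_null must be >= 100")
  obs <- best_ungapped_alignment(query, target, min_overlap)
  cm <- .cor_matrices(query$probs, target$probs)
  wb <- target$width
  rev_idx <- rev(seq_len(wb))
  null_scores <- withr_seed(seed, {
    vapply(seq_len(n_null), function(i) {
      perm <- sample.int(wb)
      f <- .best_diag(cm$fwd[, perm, drop = FALSE], min_overlap)$score
      r <- .best_diag(cm$swap[, perm, drop = FALSE][, rev_idx,
                                                    drop = FALSE],
                      min_overlap)$score
      max(f, r)
    }, 0)
  })
  obs$p_value <- (1 + sum(null_scores >= obs$mean_column_score - 1e-12)) /
    (n_null + 1)
  obs
}

# run code under a local RNG state seeded deterministically
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Flag a candidate cofactor motif as a similarity false positive
#'
#' A candidate too similar to any of the ChIP target's canonical motifs
#' (empirical p below `alpha`, default 0.05) may simply be the target
#' motif itself and is discarded.
#'
#' @param candidate `pwm` under test.
#' @param target_motifs Non-empty list of the target TF's canonical `pwm`s.
#' @param alpha Significance cutoff (default 0.05).
#' @inheritParams similarity_pvalue
#' @return TRUE iff the similarity p-value is < alpha for ANY target motif.
#' @export
is_false_positive <- function(candidate, target_motifs, alpha = 0.05,
                              n_null = 999, seed = 1) {
  if (length(target_motifs) == 0L) stop("target_motifs must be non-empty")
  for (t in target_motifs) {
    if (similarity_pvalue(candidate, t, n_null, seed)$p_value < alpha)
      return(TRUE)
  }
  FALSE
}

#' Pairwise similarity report
#'
#' @param queries,targets Lists of `pwm`s.
#' @inheritParams is_false_positive
#' @return data.frame: query_id, target_id, offset, orientation,
#'   mean_column_score, p_value, flagged.
#' @export
similarity_report <- function(queries, targets, alpha = 0.05, n_null = 999,
                              seed = 1) {
  rows <- list()
  for (q in queries) for (t in targets) {
    r <- similarity_pvalue(q, t, n_null, seed)
    rows[[length(rows) + 1L]] <-
      data.frame(query_id = r$query_id, target_id = r$target_id,
                 offset = r$offset, orientation = r$orientation,
                 mean_column_score = r$mean_column_score,
                 p_value = r$p_value, flagged = r$p_value < alpha,
                 stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(query_id = character(), target_id = character(),
                      offset = integer(), orientation = character(),
                      mean_column_score = numeric(), p_value = numeric(),
                      flagged = logical(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
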