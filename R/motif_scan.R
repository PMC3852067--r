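#' Exact score distribution of a log-odds matrix under a background
#'
#' Distribution of the total integer score of a random word of the motif's
#' width drawn i.i.d. from the background, computed by positional
#' convolution over columns (the standard dynamic program over achievable
#' integer scores).  Because integer scores are non-negative by the offset
#' convention, the probability vector is indexed 0..max achievable score.
#'
#' @param lom A `log_odds_matrix` from [pwm_to_logodds()].
#' @param bg Background to convolve under; defaults to the one stored in
#'   the matrix.
#' @return Object of class `score_distribution` with `pmf` (named numeric,
#'   names are achievable integer scores), `tail` (P(score >= s) at every
#'   integer 0..max+1) and `max_score`.
#' @export
score_distribution <- function(lom, bg = NULL) {
  stopifnot(inherits(lom, "log_odds_matrix"))
  if (is.null(bg)) bg <- lom$background
  s <- lom$scores
  if (any(s < 0)) stop("integer scores must be non-negative")
  max_total <- sum(apply(s, 2, max))
  p <- numeric(max_total + 1L)   # index i+1 holds P(total == i)
  p[1L] <- 1
  cur_max <- 0L
  for (j in seq_len(ncol(s))) {
    nxt <- numeric(max_total + 1L)
    for (b in 1:4) {
      sh <- s[b, j]
      idx <- seq_len(cur_max + 1L)
      nxt[idx + sh] <- nxt[idx + sh] + bg[b] * p[idx]
    }
    p <- nxt
    cur_max <- cur_max + max(s[, j])
  }
  # tail[i+1] = P(score >= i); tail at max+2 is 0
  tail_vec <- rev(cumsum(rev(p)))
  structure(list(motif_id = lom$motif_id, pmf = p, tail = tail_vec,
                 max_score = max_total),
            class = "score_distribution")
}

#' Exact p-value of an integer score
#'
#' P(random-word score >= score) under the distribution's background.
#' Scores at or below the minimum achievable return 1; scores above the
#' maximum return the point mass at the maximum only if equal, else 0 —
#' but such scores cannot arise from scanning, so the practical range is
#' [0, max].
#'
#' @param dist A `score_distribution`.
#' @param score Integer score (vectorized).
#' @return Numeric p-values, non-increasing in `score`.
#' @export
score_pvalue <- function(dist, score) {
  stopifnot(inherits(dist, "score_distribution"))
  score <- pmax(as.integer(score), 0L)
  ifelse(score > dist$max_score, 0, dist$tail[score + 1L])
}

#' Smallest integer score whose exact p-value is at or below a threshold
#'
#' Used to turn a p-value presence cutoff into a score cutoff before
#' vectorized scanning.  Returns `max_score + 1` when no achievable score
#' is significant.
#'
#' @inheritParams score_pvalue
#' @param p_threshold Probability in (0, 1].
#' @return Integer score threshold.
#' @export
score_threshold <- function(dist, p_threshold) {
  hit <- which(dist$tail <= p_threshold)
  if (length(hit) == 0L) dist$max_score + 1L else hit[1L] - 1L
}

.encode_dna <- function(seq) {
  # A=1 C=2 G=3 T=4, anything else NA
  x <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  match(x, BASES)
}

.window_scores <- function(code, scores) {
  # code: integer vector (NA for non-ACGT); scores: 4 x w integer matrix.
  # Returns integer vector of total scores per window start (NA where the
  # window touches a non-ACGT letter).
  w <- ncol(scores)
  n <- length(code) - w + 1L
  if (n < 1L) return(integer(0))
  tot <- numeric(n)
  for (j in seq_len(w)) {
    tot <- tot + scores[, j][code[j:(j + n - 1L)]]
  }
  tot
}

#' Scan one sequence with a log-odds matrix
#'
#' Scores every window on the requested strand(s), converts scores to
#' exact p-values and returns hits at or below `p_threshold`.  Windows
#' containing any non-ACGT letter are skipped.  Minus-strand hits are
#' reported at the forward-strand coordinate of the window start.
#'
#' @param seq DNA string over A,C,G,T,N (case-insensitive).
#' @param lom A `log_odds_matrix`.
#' @param dist Matching `score_distribution`.
#' @param p_threshold Report hits with p <= this (default 1e-4).
#' @param both_strands Scan the reverse strand too (default TRUE).
#' @param seq_id Identifier recorded in the hits.
#' @return data.frame with columns motif_id, seq_id, position (0-based),
#'   strand, score, p_value; sorted by position then strand ('+' first).
#' @export
scan_sequence <- function(seq, lom, dist, p_threshold = 1e-4,
                          both_strands = TRUE, seq_id = "seq") {
  stopifnot(p_threshold > 0, p_threshold <= 1)
  code <- .encode_dna(seq)
  w <- lom$width
  empty <- data.frame(motif_id = character(), seq_id = character(),
                      position = integer(), strand = character(),
                      score = integer(), p_value = numeric(),
                      stringsAsFactors = FALSE)
  if (length(code) < w) return(empty)
  thr <- score_threshold(dist, p_threshold)
  res <- list()
  fwd <- .window_scores(code, lom$scores)
  keep <- which(!is.na(fwd) & fwd >= thr)
  if (length(keep))
    res[[1L]] <- data.frame(motif_id = lom$motif_id, seq_id = seq_id,
                            position = keep - 1L, strand = "+",
                            score = as.integer(fwd[keep]),
                            p_value = score_pvalue(dist, fwd[keep]),
                            stringsAsFactors = FALSE)
  if (both_strands) {
    # score the reverse strand by scanning with row/column-reversed scores
    rc_scores <- lom$scores[4:1, rev(seq_len(w)), drop = FALSE]
    rev_sc <- .window_scores(code, rc_scores)
    keep <- which(!is.na(rev_sc) & rev_sc >= thr)
    if (length(keep))
      res[[length(res) + 1L]] <-
        data.frame(motif_id = lom$motif_id, seq_id = seq_id,
                   position = keep - 1L, strand = "-",
                   score = as.integer(rev_sc[keep]),
                   p_value = score_pvalue(dist, rev_sc[keep]),
                   stringsAsFactors = FALSE)
  }
  if (length(res) == 0L) return(empty)
  out <- do.call(rbind, res)
  out[order(out$position, out$strand != "+"), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg step-up q-values
#'
#' q(i) = min over j >= i (in ascending p order) of m * p(j) / j, mapped
#' back to the input order and capped at 1.  Deterministic replacement for
#' bootstrap FDR procedures; reported alongside hits but not used for
#' presence calls.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return q-values in input order, elementwise >= p.
#' @export
bh_qvalues <- function(p_values) {
  m <- length(p_values)
  if (m == 0L) return(numeric(0))
  if (any(p_values <= 0 | p_values > 1)) stop("p-values must be in (0,1]")
  o <- order(p_values)
  q <- rev(cummin(rev(p_values[o] * m / seq_len(m))))
  q <- pmin(q, 1)
  q[order(o)]
}

#' Per-peak motif presence call
#'
#' A peak contains the motif iff its best window on either strand has
#' exact p-value at or below `presence_p` (FIMO-style best-hit rule).
#' Ties in the best hit are broken by smallest position, then '+' strand.
#'
#' @param peak_seq Peak DNA string.
#' @inheritParams scan_sequence
#' @param presence_p Presence cutoff (default 1e-4).
#' @param peak_id Identifier recorded in the call.
#' @return list(peak_id, motif_id, present, best_p) with best_p NA when no
#'   window was scorable.
#' @export
motif_present <- function(peak_seq, lom, dist, presence_p = 1e-4,
                          peak_id = "peak") {
  hits <- scan_sequence(peak_seq, lom, dist, p_threshold = 1,
                        both_strands = TRUE, peak_id)
  if (nrow(hits) == 0L)
    return(list(peak_id = peak_id, motif_id = lom$motif_id,
                present = FALSE, best_p = NA_real_))
  best <- hits[order(hits$p_value, hits$position, hits$strand != "+"), ][1L, ]
  list(peak_id = peak_id, motif_id = lom$motif_id,
       present = best$p_value <= presence_p, best_p = best$p_value)
}

#' Vectorized presence calls over a set of peaks
#'
#' Scans the concatenation of all peak sequences (separated by sentinels)
#' once per strand, then reduces to a per-peak best score.  Equivalent to
#' calling [motif_present()] per peak but orders of magnitude faster on
#' compendium-scale inputs.
#'
#' @param seqs Named character vector of peak sequences.
#' @inheritParams motif_present
#' @return Logical vector named by peak, TRUE where the best hit has
#'   p <= presence_p.
#' @export
presence_calls <- function(seqs, lom, dist, presence_p = 1e-4) {
  enc <- .encode_peakset(seqs, max(lom$width, 2L))
  .presence_from_enc(enc, lom, dist, presence_p)
}

# concatenate peak sequences with N sentinels of width wsep (>= any motif
# width scanned against this encoding) so no window spans two peaks
.encode_peakset <- function(seqs, wsep) {
  lens <- nchar(seqs)
  list(code = .encode_dna(paste(seqs, collapse = strrep("N", wsep))),
       starts = cumsum(c(1L, head(lens, -1L) + wsep)),
       names = names(seqs), n = length(seqs))
}

.presence_from_enc <- function(enc, lom, dist, presence_p) {
  out <- setNames(logical(enc$n), enc$names)
  if (enc$n == 0L) return(out)
  thr <- score_threshold(dist, presence_p)
  if (thr > dist$max_score) return(out)
  w <- lom$width
  fwd <- .window_scores(enc$code, lom$scores)
  hit_pos <- which(fwd >= thr)                      # which() drops NAs
  rev_sc <- .window_scores(enc$code,
                           lom$scores[4:1, rev(seq_len(w)), drop = FALSE])
  hit_pos <- c(hit_pos, which(rev_sc >= thr))
  if (length(hit_pos) == 0L) return(out)
  out[unique(findInterval(hit_pos, enc$starts))] <- TRUE
  out
}

#' Export hits in a FIMO-like tab-separated table
#'
#' Columns: motif_id, sequence_name, start, stop, strand, score, p-value,
#' q-value.  Start/stop are 1-based inclusive in the export (internal
#' coordinates are 0-based half-open).
#'
#' @param hits data.frame from [scan_sequence()] (rows may span motifs).
#' @param width Motif width used to compute stop coordinates; taken per
#'   row from `hits$width` when present.
#' @param path File to write.
#' @return The exported data.frame, invisibly.
#' @export
write_hits_tsv <- function(hits, width, path) {
  w <- if ("width" %in% names(hits)) hits$width else rep(width, nrow(hits))
  out <- data.frame(motif_id = hits$motif_id, sequence_name = hits$seq_id,
                    start = hits$position + 1L,
                    stop = hits$position + w,
                    strand = hits$strand, score = hits$score,
                    p.value = hits$p_value,
                    q.value = if (nrow(hits)) bh_qvalues(hits$p_value)
                              else numeric(0),
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
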