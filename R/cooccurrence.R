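#' Screening thresholds
#'
#' All tunable thresholds of the co-occurrence screens in one place.
#'
#' @param hot_fraction HOT-region occupancy fraction (strict >; default 0.5).
#' @param pct Within-experiment abundance percentile defining an
#'   experiment-level co-occurrence flag (default 95).
#' @param prox_ubiq,dist_ubiq Cross-experiment ubiquity ceilings on the
#'   flagged-experiment fraction for the proximal / distal class (strict <;
#'   defaults 0.20 and 0.10).
#' @param ct_min_abund Minimum abundance in supporting experiments for a
#'   cell-type-specific call (strict >; default 0.15).
#' @param ct_min_exps Minimum supporting experiments in one cell type
#'   (default 10).
#' @param ct_min_tfs Minimum distinct TFs among them (default 4).
#' @param tf_min_abund Minimum abundance in ALL sister experiments for a
#'   TF-specific call (strict >; default 0.20).
#' @param tf_min_sisters Minimum sister experiments in distinct cell types
#'   (default 3).
#' @param sim_alpha Similarity false-positive cutoff (default 0.05).
#' @param presence_p Per-peak presence p-value cutoff (default 1e-4).
#' @return Named list of class `screen_thresholds`.
#' @export
screen_thresholds <- function(hot_fraction = 0.5, pct = 95,
                              prox_ubiq = 0.20, dist_ubiq = 0.10,
                              ct_min_abund = 0.15, ct_min_exps = 10L,
                              ct_min_tfs = 4L, tf_min_abund = 0.20,
                              tf_min_sisters = 3L, sim_alpha = 0.05,
                              presence_p = 1e-4) {
  th <- list(hot_fraction = hot_fraction, pct = pct, prox_ubiq = prox_ubiq,
             dist_ubiq = dist_ubiq, ct_min_abund = ct_min_abund,
             ct_min_exps = as.integer(ct_min_exps),
             ct_min_tfs = as.integer(ct_min_tfs),
             tf_min_abund = tf_min_abund,
             tf_min_sisters = as.integer(tf_min_sisters),
             sim_alpha = sim_alpha, presence_p = presence_p)
  fracs <- c(th$hot_fraction, th$prox_ubiq, th$dist_ubiq, th$ct_min_abund,
             th$tf_min_abund, th$sim_alpha, th$presence_p)
  if (any(fracs <= 0) || any(fracs >= 1))
    stop("fractional thresholds must be in (0,1)")
  if (th$pct <= 0 || th$pct >= 100) stop("pct must be in (0,100)")
  if (any(c(th$ct_min_exps, th$ct_min_tfs, th$tf_min_sisters) < 1L))
    stop("integer minima must be >= 1")
  structure(th, class = "screen_thresholds")
}

#' Build a scan context: log-odds matrices and score distributions
#'
#' Precomputes the per-motif `log_odds_matrix` and `score_distribution`
#' for a motif library under one background — the expensive part of the
#' scan set-up, shared across experiments.
#'
#' @param pwms List of `pwm`s.
#' @param bg A `motif_background`.
#' @param pseudocount,scale Passed to [pwm_to_logodds()].
#' @return Named list (by motif_id) of list(lom, dist).
#' @export
scan_context <- function(pwms, bg = background(), pseudocount = 0.01,
                         scale = 1000) {
  ctx <- lapply(pwms, function(p) {
    lom <- pwm_to_logodds(p, bg, pseudocount, scale)
    list(lom = lom, dist = score_distribution(lom))
  })
  names(ctx) <- vapply(pwms, `[[`, "", "motif_id")
  ctx
}

#' Partition one experiment's COLD peaks by canonical-motif presence
#'
#' A peak is positive iff ANY canonical motif of the experiment's TF is
#' present (union over multiple canonical motifs); otherwise negative.
#'
#' @param exp_row One row of the experiment table.
#' @param peaks The experiment's COLD peaks with sequences attached.
#' @param canon Canonical map (tf_name -> motif ids).
#' @param ctx Scan context from [scan_context()].
#' @param presence_p Presence cutoff.
#' @return list(exp_id, positive_peak_ids, negative_peak_ids).
#' @export
partition_peaks <- function(exp_row, peaks, canon, ctx, presence_p = 1e-4) {
  tf <- exp_row$tf_name
  if (!tf %in% names(canon))
    stop("TF '", tf, "' has no canonical motif (should have been filtered)")
  ids <- canon[[tf]]
  miss <- setdiff(ids, names(ctx))
  if (length(miss))
    stop("canonical motif(s) not in the scan context: ",
         paste(miss, collapse = ", "))
  if (nrow(peaks) == 0L)
    return(list(exp_id = exp_row$exp_id, positive_peak_ids = character(),
                negative_peak_ids = character()))
  seqs <- setNames(peaks$sequence, peaks$peak_id)
  pos <- rep(FALSE, nrow(peaks))
  for (mid in ids) {
    pos <- pos | presence_calls(seqs, ctx[[mid]]$lom, ctx[[mid]]$dist,
                                presence_p)
  }
  list(exp_id = exp_row$exp_id,
       positive_peak_ids = peaks$peak_id[pos],
       negative_peak_ids = peaks$peak_id[!pos])
}

#' Proximal/distal abundance of every library motif in every experiment
#'
#' For each experiment and each library motif other than that experiment's
#' own canonical motifs, the abundance is the fraction of peaks of the
#' class (proximal: canonical-positive peaks, distal: canonical-negative
#' peaks) containing the motif.  Classes with zero peaks are omitted.
#'
#' @param partitions List of partitions from [partition_peaks()].
#' @param peaks All COLD peaks with sequences.
#' @param exps Curated experiment table.
#' @param canon Canonical map.
#' @param ctx Scan context (the full motif library).
#' @param presence_p Presence cutoff.
#' @return data.frame: exp_id, motif_id, cls, n_peaks, n_present, abundance.
#' @export
abundance_table <- function(partitions, peaks, exps, canon, ctx,
                            presence_p = 1e-4) {
  stopifnot(length(partitions) > 0L)
  seq_by_peak <- setNames(peaks$sequence, peaks$peak_id)
  w_max <- max(vapply(ctx, function(m) m$lom$width, 0L))
  rows <- vector("list", 0L)
  for (part in partitions) {
    exp_row <- exps[exps$exp_id == part$exp_id, , drop = FALSE]
    own <- canon[[exp_row$tf_name]]
    classes <- list(proximal = part$positive_peak_ids,
                    distal = part$negative_peak_ids)
    for (cls in names(classes)) {
      pids <- classes[[cls]]
      if (length(pids) == 0L) next
      enc <- .encode_peakset(seq_by_peak[pids], w_max)
      for (mid in setdiff(names(ctx), own)) {
        pres <- .presence_from_enc(enc, ctx[[mid]]$lom, ctx[[mid]]$dist,
                                   presence_p)
        rows[[length(rows) + 1L]] <-
          data.frame(exp_id = part$exp_id, motif_id = mid, cls = cls,
                     n_peaks = length(pids), n_present = sum(pres),
                     abundance = sum(pres) / length(pids),
                     stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(exp_id = character(), motif_id = character(),
                      cls = character(), n_peaks = integer(),
                      n_present = integer(), abundance = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Flag motifs co-occurring abundantly within an experiment
#'
#' Within each (experiment, class) group, the abundance distribution over
#' all library motifs is summarized by its `pct`-th percentile (type-7
#' linear interpolation between order statistics: with n sorted values x,
#' h = (n-1)*pct/100, q = x[floor(h)+1] + (h-floor(h))*(x[floor(h)+2]-x[floor(h)+1])).
#' A motif is flagged iff its abundance is strictly above that percentile.
#'
#' @param records Abundance table from [abundance_table()].
#' @param pct Percentile (default 95).
#' @return data.frame: exp_id, motif_id, cls, abundance, q95, flagged.
#' @export
enrichment_flags <- function(records, pct = 95) {
  stopifnot(pct > 0, pct < 100)
  if (nrow(records) == 0L)
    return(cbind(records, q95 = numeric(0), flagged = logical(0)))
  key <- paste(records$exp_id, records$cls, sep = "\r")
  q95 <- ave(records$abundance, key, FUN = function(x) {
    if (length(x) < 20L)
      warning("percentile computed over a group of only ", length(x),
              " motifs", call. = FALSE)
    quantile(x, pct / 100, type = 7, names = FALSE)
  })
  out <- records
  out$q95 <- q95
  out$flagged <- out$abundance > out$q95
  out
}

#' Ubiquity filter on flagged-experiment fractions
#'
#' For each (motif, class), f = (#experiments where flagged) / n_exps.
#' The motif is retained in that class iff 0 < f < the class ceiling
#' (proximal < `prox_ubiq`, distal < `dist_ubiq`): never-flagged motifs
#' carry no co-occurrence signal, while too-ubiquitous ones are
#' non-specific.
#'
#' @param flags Flag table from [enrichment_flags()].
#' @param n_exps Number of curated experiments (the denominator).
#' @param thresholds A `screen_thresholds`.
#' @return data.frame of retained (motif_id, cls) pairs with their flag
#'   fraction.
#' @export
ubiquity_filter <- function(flags, n_exps, thresholds = screen_thresholds()) {
  stopifnot(n_exps >= 1L)
  if (nrow(flags) == 0L)
    return(data.frame(motif_id = character(), cls = character(),
                      flag_fraction = numeric(), stringsAsFactors = FALSE))
  agg <- aggregate(flagged ~ motif_id + cls, data = flags, FUN = sum)
  agg$flag_fraction <- agg$flagged / n_exps
  ceiling_of <- ifelse(agg$cls == "proximal", thresholds$prox_ubiq,
                       thresholds$dist_ubiq)
  keep <- agg$flag_fraction > 0 & agg$flag_fraction < ceiling_of
  out <- agg[keep, c("motif_id", "cls", "flag_fraction"), drop = FALSE]
  rownames(out) <- NULL
  out
}

.empty_calls <- function() {
  data.frame(motif_id = character(), scope = character(), key = character(),
             cls = character(), n_support = integer(),
             n_distinct = integer(), min_abundance = numeric(),
             supporting_exp_ids = character(), stringsAsFactors = FALSE)
}

#' Cell-type-specific co-occurrence screen
#'
#' A motif is called cell-type specific for cell type C and class cls iff
#' the set S of experiments of cell type C where the motif is flagged AND
#' its abundance exceeds `ct_min_abund` satisfies |S| >= `ct_min_exps`
#' and the experiments in S target at least `ct_min_tfs` distinct TFs.
#' Candidate motifs must already have passed [ubiquity_filter()].
#'
#' @param flags Flag table.
#' @param retained Ubiquity-retained (motif, cls) pairs.
#' @param exps Curated experiment table.
#' @param thresholds A `screen_thresholds`.
#' @return data.frame of calls: motif_id, scope ("cell_type"), key, cls,
#'   n_support, n_distinct (TFs), min_abundance, supporting_exp_ids
#'   (comma-joined).
#' @export
cell_type_specific_screen <- function(flags, retained, exps,
                                      thresholds = screen_thresholds()) {
  calls <- list()
  tf_of <- setNames(exps$tf_name, exps$exp_id)
  ct_of <- setNames(exps$cell_type, exps$exp_id)
  for (i in seq_len(nrow(retained))) {
    mid <- retained$motif_id[i]; cls <- retained$cls[i]
    sub <- flags[flags$motif_id == mid & flags$cls == cls & flags$flagged &
                 flags$abundance > thresholds$ct_min_abund, , drop = FALSE]
    if (nrow(sub) == 0L) next
    for (ct in unique(ct_of[sub$exp_id])) {
      S <- sub$exp_id[ct_of[sub$exp_id] == ct]
      if (length(S) >= thresholds$ct_min_exps &&
          length(unique(tf_of[S])) >= thresholds$ct_min_tfs) {
        calls[[length(calls) + 1L]] <-
          data.frame(motif_id = mid, scope = "cell_type", key = ct,
                     cls = cls, n_support = length(S),
                     n_distinct = length(unique(tf_of[S])),
                     min_abundance = min(sub$abundance[sub$exp_id %in% S]),
                     supporting_exp_ids = paste(sort(S), collapse = ","),
                     stringsAsFactors = FALSE)
      }
    }
  }
  if (length(calls) == 0L) return(.empty_calls())
  out <- do.call(rbind, calls)
  out[order(out$key, out$motif_id, out$cls), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' TF-specific co-occurrence screen
#'
#' A motif is called TF specific for TF T and class cls iff among the
#' experiments targeting T there are at least `tf_min_sisters` flagged
#' experiments in distinct cell types AND the motif's abundance exceeds
#' `tf_min_abund` in ALL of those flagged sister experiments.
#'
#' @inheritParams cell_type_specific_screen
#' @return data.frame of calls with scope "tf"; n_distinct counts cell
#'   types.
#' @export
tf_specific_screen <- function(flags, retained, exps,
                               thresholds = screen_thresholds()) {
  calls <- list()
  tf_of <- setNames(exps$tf_name, exps$exp_id)
  ct_of <- setNames(exps$cell_type, exps$exp_id)
  for (i in seq_len(nrow(retained))) {
    mid <- retained$motif_id[i]; cls <- retained$cls[i]
    sub <- flags[flags$motif_id == mid & flags$cls == cls & flags$flagged, ,
                 drop = FALSE]
    if (nrow(sub) == 0L) next
    for (tf in unique(tf_of[sub$exp_id])) {
      S <- sub$exp_id[tf_of[sub$exp_id] == tf]
      n_ct <- length(unique(ct_of[S]))
      ab <- sub$abundance[sub$exp_id %in% S]
      if (n_ct >= thresholds$tf_min_sisters &&
          all(ab > thresholds$tf_min_abund)) {
        calls[[length(calls) + 1L]] <-
          data.frame(motif_id = mid, scope = "tf", key = tf, cls = cls,
                     n_support = length(S), n_distinct = n_ct,
                     min_abundance = min(ab),
                     supporting_exp_ids = paste(sort(S), collapse = ","),
                     stringsAsFactors = FALSE)
      }
    }
  }
  if (length(calls) == 0L) return(.empty_calls())
  out <- do.call(rbind, calls)
  out[order(out$key, out$motif_id, out$cls), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Remove similarity false positives from specificity calls
#'
#' Drops every call whose motif is too similar (empirical similarity
#' p-value < `sim_alpha`) to any relevant canonical motif: for TF-scope
#' calls the canonical motifs of the called TF; for cell-type-scope calls
#' the union of canonical motifs of the TFs in the supporting
#' experiments.
#'
#' @param calls Call table from the screens.
#' @param canon Canonical map.
#' @param library_pwms Named list of `pwm`s (by motif_id).
#' @param exps Curated experiment table.
#' @param thresholds A `screen_thresholds`.
#' @param n_null,seed Passed to [similarity_pvalue()].
#' @return The call table with false-positive rows removed.
#' @export
remove_similar <- function(calls, canon, library_pwms, exps,
                           thresholds = screen_thresholds(), n_null = 999,
                           seed = 1) {
  if (nrow(calls) == 0L) return(calls)
  tf_of <- setNames(exps$tf_name, exps$exp_id)
  keep <- logical(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    tfs <- if (calls$scope[i] == "tf") calls$key[i]
           else unique(tf_of[strsplit(calls$supporting_exp_ids[i],
                                      ",")[[1L]]])
    target_ids <- unique(unlist(canon[tfs]))
    targets <- library_pwms[intersect(target_ids, names(library_pwms))]
    keep[i] <- !is_false_positive(library_pwms[[calls$motif_id[i]]],
                                  targets, alpha = thresholds$sim_alpha,
                                  n_null = n_null, seed = seed)
  }
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write screening reports
#'
#' Emits `proximal.csv` / `distal.csv` (per-experiment, per-motif
#' abundances with flags), `cell_type_specific.csv` / `tf_specific.csv`
#' (one row per call) and `summary_cell_type.csv` / `summary_tf.csv`
#' (key, comma-joined motif ids, total — the shape of a results table).
#'
#' @param calls Final call table (after [remove_similar()]).
#' @param flags Flag table.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_reports <- function(calls, flags, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (cls in c("proximal", "distal")) {
    f <- file.path(out_dir, paste0(cls, ".csv"))
    sub <- flags[flags$cls == cls, , drop = FALSE]
    sub <- sub[order(sub$exp_id, sub$motif_id), , drop = FALSE]
    write.csv(sub, f, row.names = FALSE, quote = FALSE)
    files <- c(files, f)
  }
  for (scope in c("cell_type", "tf")) {
    f <- file.path(out_dir, paste0(scope, "_specific.csv"))
    sub <- calls[calls$scope == scope, , drop = FALSE]
    write.csv(sub, f, row.names = FALSE, quote = FALSE)
    files <- c(files, f)
    fs <- file.path(out_dir, paste0("summary_", scope, ".csv"))
    if (nrow(sub)) {
      summ <- aggregate(motif_id ~ key, data = sub, FUN = function(x)
        paste(sort(unique(x)), collapse = ";"))
      summ$total <- aggregate(motif_id ~ key, data = sub,
                              FUN = function(x) length(unique(x)))$motif_id
      names(summ) <- c("key", "motifs", "total")
    } else {
      summ <- data.frame(key = character(), motifs = character(),
                         total = integer(), stringsAsFactors = FALSE)
    }
    write.csv(summ, fs, row.names = FALSE, quote = FALSE)
    files <- c(files, fs)
  }
  invisible(files)
}
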