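#' Load an experiment metadata table
#'
#' @param path TSV with columns exp_id, tf_name, cell_type, treatment
#'   (treatment may be empty), or the text itself.
#' @return data.frame of experiments; duplicate exp_id is an error.
#' @export
load_experiments <- function(path) {
  df <- .read_tsv(path)
  need <- c("exp_id", "tf_name", "cell_type", "treatment")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("experiment metadata missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$exp_id))
    stop("duplicate exp_id: ",
         paste(unique(df$exp_id[duplicated(df$exp_id)]), collapse = ", "))
  df$treatment[is.na(df$treatment)] <- ""
  df[need]
}

#' Load peaks for one experiment from BED text
#'
#' BED3+ with 0-based half-open coordinates; columns beyond the third are
#' ignored.  Peak ids are `exp_id:lineno`.
#'
#' @param path BED file path or its text.
#' @param exp_id Experiment the peaks belong to.
#' @return data.frame: peak_id, exp_id, chrom, start, end.
#' @export
load_peaks <- function(path, exp_id) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path)
           else .as_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(data.frame(peak_id = character(), exp_id = character(),
                      chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  chrom <- vapply(fields, `[`, "", 1L)
  s <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
  e <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
  bad <- which(is.na(s) | is.na(e))
  if (length(bad))
    stop("BED for '", exp_id, "': non-integer coordinate at line ", bad[1L])
  bad <- which(s >= e)
  if (length(bad))
    stop("BED for '", exp_id, "': start >= end at line ", bad[1L])
  if (any(s < 0)) stop("BED for '", exp_id, "': negative start")
  data.frame(peak_id = paste0(exp_id, ":", seq_along(lines)),
             exp_id = exp_id, chrom = chrom, start = s, end = e,
             stringsAsFactors = FALSE)
}

#' Load a TF -> canonical motif map
#'
#' @param path TSV with columns tf_name, motif_id; one pair per row.  TFs
#'   matched to multiple canonical motifs occupy multiple rows.
#' @return Named list: tf_name -> character vector of motif ids.
#' @export
load_canonical_map <- function(path) {
  df <- .read_tsv(path)
  miss <- setdiff(c("tf_name", "motif_id"), names(df))
  if (length(miss))
    stop("canonical map missing column(s): ", paste(miss, collapse = ", "))
  split(df$motif_id, df$tf_name)
}

#' Curate the experiment table
#'
#' Applies, in order: (1) removal of excluded TFs (general transcription
#' machinery and CTCF by default); (2) removal of orphan experiments —
#' TFs assayed in only one cell type among the remaining experiments, for
#' which co-occurrence specificity cannot be assessed; (3) removal of
#' experiments whose TF has no canonical motif in the map.
#'
#' @param exps Experiment data.frame from [load_experiments()].
#' @param canon Canonical map from [load_canonical_map()].
#' @param excluded_tfs TF names to drop outright.
#' @return list(retained = data.frame, report = data.frame of per-stage
#'   experiment counts).
#' @export
filter_experiments <- function(exps, canon,
                               excluded_tfs = c("POLR2A", "POLR3A", "POL2",
                                                "POL3", "TBP", "CTCF")) {
  report <- data.frame(stage = "input", experiments = nrow(exps),
                       stringsAsFactors = FALSE)
  keep <- !(toupper(exps$tf_name) %in% toupper(excluded_tfs))
  exps <- exps[keep, , drop = FALSE]
  report <- rbind(report, data.frame(stage = "excluded_tfs",
                                     experiments = nrow(exps)))
  n_ct <- tapply(exps$cell_type, exps$tf_name,
                 function(x) length(unique(x)))
  exps <- exps[n_ct[exps$tf_name] >= 2L, , drop = FALSE]
  report <- rbind(report, data.frame(stage = "orphans",
                                     experiments = nrow(exps)))
  exps <- exps[exps$tf_name %in% names(canon), , drop = FALSE]
  report <- rbind(report, data.frame(stage = "missing_pwm",
                                     experiments = nrow(exps)))
  rownames(exps) <- NULL
  list(retained = exps, report = report)
}

#' Detect HOT (high-occupancy target) regions
#'
#' A genomic base is HOT when it is covered by peaks from strictly more
#' than `hot_fraction` of all experiments, counting each experiment once
#' per base regardless of how many of its peaks overlap it.  Maximal runs
#' of HOT bases are merged into intervals by a sweep line over interval
#' endpoints.
#'
#' @param peaks data.frame of all peaks (peak_id, exp_id, chrom, start, end).
#' @param n_experiments Denominator for the occupancy fraction.
#' @param hot_fraction Strict threshold fraction (default 0.5).
#' @return data.frame: chrom, start, end (0-based half-open), sorted.
#' @export
find_hot_regions <- function(peaks, n_experiments, hot_fraction = 0.5) {
  stopifnot(hot_fraction > 0, hot_fraction <= 1)
  need <- hot_fraction * n_experiments   # HOT iff coverage > need
  out <- list()
  for (chr in sort(unique(peaks$chrom))) {
    pk <- peaks[peaks$chrom == chr, , drop = FALSE]
    # per-experiment union so multiple peaks of one experiment count once
    evs <- list()
    for (ex in unique(pk$exp_id)) {
      ir <- IRanges::reduce(IRanges::IRanges(start = pk$start[pk$exp_id == ex] + 1L,
                                             end = pk$end[pk$exp_id == ex]))
      evs[[ex]] <- ir
    }
    all_ir <- do.call(c, unname(evs))
    cov <- IRanges::coverage(all_ir)
    v <- S4Vectors::runValue(cov)
    l <- S4Vectors::runLength(cov)
    ends <- cumsum(l)
    starts <- ends - l + 1L
    hot <- which(v > need)
    if (length(hot) == 0L) next
    ir <- IRanges::reduce(IRanges::IRanges(starts[hot], ends[hot]))
    out[[chr]] <- data.frame(chrom = chr,
                             start = IRanges::start(ir) - 1L,
                             end = IRanges::end(ir),
                             stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Remove peaks overlapping HOT regions
#'
#' A peak is removed iff it overlaps any HOT interval by at least one base
#' (half-open overlap test).  The retained peaks are the "COLD" peaks.
#'
#' @param peaks Peak data.frame.
#' @param hot HOT intervals from [find_hot_regions()].
#' @return list(cold = data.frame, n_removed = integer).
#' @export
remove_hot_peaks <- function(peaks, hot) {
  if (nrow(hot) == 0L || nrow(peaks) == 0L)
    return(list(cold = peaks, n_removed = 0L))
  removed <- logical(nrow(peaks))
  for (chr in unique(hot$chrom)) {
    hi <- hot[hot$chrom == chr, , drop = FALSE]
    sel <- which(peaks$chrom == chr)
    if (length(sel) == 0L) next
    q <- IRanges::IRanges(peaks$start[sel] + 1L, peaks$end[sel])
    s <- IRanges::IRanges(hi$start + 1L, hi$end)
    removed[sel] <- IRanges::overlapsAny(q, s)
  }
  list(cold = peaks[!removed, , drop = FALSE], n_removed = sum(removed))
}

#' Attach peak sequences from a genome FASTA
#'
#' Peaks are strandless; the forward-strand genome slice [start, end) is
#' attached, uppercased (soft-masked lowercase regions are unmasked).
#'
#' @param peaks Peak data.frame.
#' @param genome A named character vector of chromosome sequences, a
#'   `Biostrings::DNAStringSet`, or a FASTA file path.
#' @return The peak data.frame with a `sequence` column added.
#' @export
extract_sequences <- function(peaks, genome) {
  genome <- .as_genome(genome)
  seqs <- character(nrow(peaks))
  for (chr in unique(peaks$chrom)) {
    if (!chr %in% names(genome))
      stop("chromosome '", chr, "' not present in the genome")
    sel <- which(peaks$chrom == chr)
    chrom_len <- nchar(genome[[chr]])
    bad <- sel[peaks$end[sel] > chrom_len]
    if (length(bad))
      stop("peak '", peaks$peak_id[bad[1L]], "' extends beyond chromosome '",
           chr, "' (length ", chrom_len, ")")
    seqs[sel] <- toupper(substring(genome[[chr]], peaks$start[sel] + 1L,
                                   peaks$end[sel]))
  }
  peaks$sequence <- seqs
  peaks
}

.as_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    ss <- Biostrings::readDNAStringSet(genome)
    genome <- setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  } else if (methods::is(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), sub("\\s.*$", "", names(genome)))
  }
  if (is.null(names(genome)) || any(!nzchar(names(genome))))
    stop("genome sequences must be named by chromosome")
  as.list(genome)
}

.read_tsv <- function(path) {
  if (length(path) == 1L && !grepl("\n", path, fixed = TRUE) &&
      file.exists(path)) {
    read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  } else {
    read.delim(text = paste(.as_lines(path), collapse = "\n"),
               stringsAsFactors = FALSE, colClasses = "character")
  }
}
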