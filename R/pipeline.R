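#' Pipeline configuration
#'
#' @param genome Path to the genome FASTA.
#' @param peaks_dir Directory of per-experiment BED files named
#'   `<exp_id>.bed`.
#' @param metadata Path to the experiment metadata TSV.
#' @param motifs Path to the motif library (JASPAR dialect, UniPROBE
#'   dialect, or the internal probability format; chosen by content).
#' @param canonical_map Path to the tf_name/motif_id TSV.
#' @param out_dir Output directory.
#' @param thresholds A [screen_thresholds()].
#' @param pseudocount,scale Log-odds construction parameters.
#' @param bg_mode Background estimation: "per_experiment" (zero-order
#'   frequencies of the experiment's COLD peak sequences, floored at
#'   0.01), "global", or "uniform".
#' @param n_null,seed Similarity-null parameters for false-positive
#'   removal.
#' @param stages "all" or "curation" (stop after the curation report).
#' @param hot_count_set Experiment set whose size is the HOT denominator:
#'   "post_tf_filter" (after the excluded-TF filter) or "curated".
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(genome, peaks_dir, metadata, motifs,
                            canonical_map, out_dir,
                            thresholds = screen_thresholds(),
                            pseudocount = 0.01, scale = 1000,
                            bg_mode = c("per_experiment", "global",
                                        "uniform"),
                            n_null = 999, seed = 1,
                            stages = c("all", "curation"),
                            hot_count_set = c("post_tf_filter",
                                              "curated")) {
  cfg <- list(genome = genome, peaks_dir = peaks_dir, metadata = metadata,
              motifs = motifs, canonical_map = canonical_map,
              out_dir = out_dir, thresholds = thresholds,
              pseudocount = pseudocount, scale = scale,
              bg_mode = match.arg(bg_mode), n_null = n_null,
              seed = as.integer(seed), stages = match.arg(stages),
              hot_count_set = match.arg(hot_count_set))
  for (p in c("genome", "peaks_dir", "metadata", "motifs",
              "canonical_map")) {
    if (!file.exists(cfg[[p]]))
      stop("config path '", p, "' does not exist: ", cfg[[p]])
  }
  structure(cfg, class = "pipeline_config")
}

.log_stage <- function(...) message(format(Sys.time(), "%H:%M:%S"), " | ", ...)

.read_motif_file <- function(path) {
  lines <- readLines(path)
  if (any(grepl("^#id ", lines))) read_pwms(lines)
  else if (any(grepl("^>", lines))) parse_jaspar(lines)
  else parse_uniprobe(lines)
}

#' Run the full screening pipeline
#'
#' Curation -> HOT removal -> sequence extraction -> canonical-motif peak
#' partition -> library scan and abundance -> percentile flags ->
#' ubiquity filter -> cell-type and TF specificity screens -> similarity
#' false-positive removal -> reports.  Per-stage counts are logged to
#' stderr; a machine-readable manifest and the curation report are
#' written to `out_dir`.
#'
#' @param config A [pipeline_config()].
#' @return list(curation_report, calls, flags, retained, abundance,
#'   evaluation-ready tables), invisibly the same written to `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  th <- config$thresholds
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  .log_stage("loading inputs")
  exps <- load_experiments(config$metadata)
  canon <- load_canonical_map(config$canonical_map)
  pwms <- .read_motif_file(config$motifs)
  names(pwms) <- vapply(pwms, `[[`, "", "motif_id")
  missing_ids <- setdiff(unlist(canon), names(pwms))
  if (length(missing_ids))
    stop("canonical map references unknown motif(s): ",
         paste(missing_ids, collapse = ", "))

  filt <- filter_experiments(exps, canon)
  curated <- filt$retained
  .log_stage("curation: ", nrow(exps), " -> ", nrow(curated),
             " experiments")

  # experiment set over which HOT occupancy is counted
  hot_exps <- if (config$hot_count_set == "curated") curated else {
    excl <- c("POLR2A", "POLR3A", "POL2", "POL3", "TBP", "CTCF")
    exps[!(toupper(exps$tf_name) %in% excl), , drop = FALSE]
  }

  peak_list <- lapply(hot_exps$exp_id, function(ex) {
    f <- file.path(config$peaks_dir, paste0(ex, ".bed"))
    if (!file.exists(f)) stop("no BED file for experiment '", ex, "': ", f)
    load_peaks(f, ex)
  })
  hot_peaks_all <- do.call(rbind, peak_list)
  hot <- find_hot_regions(hot_peaks_all, nrow(hot_exps), th$hot_fraction)
  .log_stage("HOT regions: ", nrow(hot))

  peaks <- hot_peaks_all[hot_peaks_all$exp_id %in% curated$exp_id, ,
                         drop = FALSE]
  n_before <- nrow(peaks)
  rh <- remove_hot_peaks(peaks, hot)
  peaks <- rh$cold
  .log_stage("peaks: ", n_before, " -> ", nrow(peaks), " after HOT removal")

  report <- data.frame(
    stage = c(filt$report$stage, "hot_removal"),
    experiments = c(filt$report$experiments, nrow(curated)),
    peaks = c(rep(NA_integer_, nrow(filt$report)), nrow(peaks)),
    peaks_removed = c(rep(NA_integer_, nrow(filt$report)), rh$n_removed))
  write.table(report, file.path(config$out_dir, "curation_report.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(paste(hot$chrom, hot$start, hot$end, sep = "\t"),
             file.path(config$out_dir, "hot_regions.bed"))

  if (config$stages == "curation") {
    .log_stage("stopping after curation as requested")
    return(invisible(list(curation_report = report, hot_regions = hot)))
  }

  .log_stage("extracting sequences")
  genome <- .as_genome(config$genome)
  peaks <- extract_sequences(peaks, genome)

  global_bg <- switch(config$bg_mode,
    uniform = background(),
    background_from_sequences(peaks$sequence))

  .log_stage("scanning ", nrow(curated), " experiments x ",
             length(pwms), " motifs")
  partitions <- list()
  ab_rows <- list()
  for (e in seq_len(nrow(curated))) {
    exp_row <- curated[e, ]
    pk <- peaks[peaks$exp_id == exp_row$exp_id, , drop = FALSE]
    bg <- if (config$bg_mode == "per_experiment")
      background_from_sequences(pk$sequence) else global_bg
    ctx <- scan_context(pwms, bg, config$pseudocount, config$scale)
    part <- partition_peaks(exp_row, pk, canon, ctx, th$presence_p)
    partitions[[exp_row$exp_id]] <- part
    ab_rows[[exp_row$exp_id]] <-
      abundance_table(list(part), pk, curated, canon, ctx, th$presence_p)
  }
  records <- do.call(rbind, ab_rows)
  rownames(records) <- NULL
  write.table(records, file.path(config$out_dir, "abundance.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  flags <- enrichment_flags(records, th$pct)
  retained <- ubiquity_filter(flags, nrow(curated), th)
  .log_stage("ubiquity-retained motif/class pairs: ", nrow(retained))

  calls <- rbind(cell_type_specific_screen(flags, retained, curated, th),
                 tf_specific_screen(flags, retained, curated, th))
  .log_stage("specificity calls before similarity removal: ", nrow(calls))

  calls <- remove_similar(calls, canon, pwms, curated, th,
                          n_null = config$n_null, seed = config$seed)
  .log_stage("final calls: ", nrow(calls))

  write_reports(calls, flags, config$out_dir)
  manifest <- list(package = "cofactorscreen",
                   version = as.character(utils::packageVersion("cofactorscreen")),
                   seed = config$seed, n_null = config$n_null,
                   bg_mode = config$bg_mode,
                   thresholds = unclass(config$thresholds),
                   n_experiments = nrow(curated), n_peaks = nrow(peaks),
                   n_motifs = length(pwms))
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(curation_report = report, hot_regions = hot,
                 records = records, flags = flags, retained = retained,
                 calls = calls, partitions = partitions))
}

## ---- command-line interface ----------------------------------------------

.cli_args <- function(argv, spec) {
  # spec: named list default values; flags are --name value
  out <- spec
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a, call. = FALSE)
    key <- sub("^--", "", a)
    if (!key %in% names(spec)) stop("unknown flag --", key, call. = FALSE)
    if (i == length(argv)) stop("flag --", key, " needs a value",
                                call. = FALSE)
    val <- argv[i + 1L]
    out[[key]] <- if (is.numeric(spec[[key]])) as.numeric(val) else val
    i <- i + 2L
  }
  out
}

#' Command-line entry point
#'
#' Subcommands: `simulate --seed S --out DIR` (write a synthetic
#' compendium), `screen --dir DIR --out DIR [--seed S] [--stages all|curation]`
#' (run the pipeline on a compendium directory), `evaluate --calls-dir DIR
#' --truth FILE` (precision/recall against a truth table), `--version`.
#' Intended to be invoked as
#' `Rscript -e 'cofactorscreen::cli_main()' <subcommand> ...`.
#'
#' @param argv Character vector of arguments (default: the command line).
#' @return Exit code, invisibly (0 ok, 1 input error).
#' @export
cli_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  code <- tryCatch({
    if (length(argv) == 0L)
      stop("usage: simulate|screen|evaluate ... (or --version)",
           call. = FALSE)
    cmd <- argv[1L]
    rest <- argv[-1L]
    if (cmd == "--version") {
      cat("cofactorscreen",
          as.character(utils::packageVersion("cofactorscreen")), "\n")
    } else if (cmd == "simulate") {
      a <- .cli_args(rest, list(seed = 42, out = "compendium"))
      generate_compendium(compendium_design(seed = as.integer(a$seed)),
                          out_dir = a$out)
      .log_stage("compendium written to ", a$out)
    } else if (cmd == "screen") {
      a <- .cli_args(rest, list(dir = "compendium", out = "results",
                                seed = 1, stages = "all"))
      cfg <- pipeline_config(
        genome = file.path(a$dir, "genome.fa"),
        peaks_dir = file.path(a$dir, "peaks"),
        metadata = file.path(a$dir, "experiments.tsv"),
        motifs = file.path(a$dir, "motifs.jaspar"),
        canonical_map = file.path(a$dir, "canonical_map.tsv"),
        out_dir = a$out, seed = as.integer(a$seed),
        stages = a$stages)
      run_pipeline(cfg)
    } else if (cmd == "evaluate") {
      a <- .cli_args(rest, list(`calls-dir` = "results",
                                truth = "compendium/truth.csv"))
      calls <- rbind(
        utils::read.csv(file.path(a$`calls-dir`, "cell_type_specific.csv"),
                        stringsAsFactors = FALSE),
        utils::read.csv(file.path(a$`calls-dir`, "tf_specific.csv"),
                        stringsAsFactors = FALSE))
      truth <- utils::read.csv(a$truth, stringsAsFactors = FALSE)
      ev <- evaluate_against_truth(calls, truth)
      cat(sprintf("precision\t%g\nrecall\t%g\n", ev$precision, ev$recall))
    } else {
      stop("unknown subcommand '", cmd, "'", call. = FALSE)
    }
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(code)
}
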