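#' @importFrom stats runif rbinom quantile cor var setNames aggregate ave
#' @importFrom utils read.delim write.table write.csv head tail
NULL

BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix (PWM) object
#'
#' A PWM is the standard per-position nucleotide probability model of a
#' transcription factor binding site.  Columns are positions, rows are the
#' bases A, C, G, T (in that fixed order); every column sums to one.
#'
#' @param motif_id Identifier string (e.g. a JASPAR accession).
#' @param probs 4 x width numeric matrix of probabilities, rows A,C,G,T.
#' @param name Human-readable motif name.
#' @param source One of "jaspar", "uniprobe", "synthetic".
#' @return An object of class `pwm`.
#' @export
new_pwm <- function(motif_id, probs, name = motif_id,
                    source = c("synthetic", "jaspar", "uniprobe")) {
  source <- match.arg(source)
  probs <- as.matrix(probs)
  if (nrow(probs) != 4L)
    stop("PWM '", motif_id, "': probability matrix must have 4 rows (A,C,G,T)")
  if (ncol(probs) < 2L)
    stop("PWM '", motif_id, "': width must be >= 2")
  if (any(probs < -1e-12) || any(probs > 1 + 1e-12))
    stop("PWM '", motif_id, "': probabilities outside [0,1]")
  cs <- colSums(probs)
  if (any(abs(cs - 1) > 1e-9))
    stop("PWM '", motif_id, "': columns must sum to 1 (max deviation ",
         format(max(abs(cs - 1))), ")")
  rownames(probs) <- BASES
  structure(list(motif_id = motif_id, name = name, source = source,
                 width = ncol(probs), probs = probs),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM %s (%s, %s) width %d\n", x$motif_id, x$name, x$source,
              x$width))
  print(round(x$probs, 3))
  invisible(x)
}

#' Convert a count matrix to probabilities with a pseudocount
#'
#' prob(b, i) = (count(b, i) + pseudocount) / (colsum(i) + 4 * pseudocount).
#'
#' @param counts 4 x width non-negative numeric matrix, rows A,C,G,T.
#' @param pseudocount Non-negative pseudocount added per cell (default 0.25,
#'   the usual convention for JASPAR count matrices).
#' @inheritParams new_pwm
#' @return A `pwm`.
#' @export
counts_to_probabilities <- function(counts, pseudocount = 0.25,
                                    motif_id = "motif", name = motif_id,
                                    source = "synthetic") {
  counts <- as.matrix(counts)
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  if (any(counts < 0)) stop("negative counts")
  cs <- colSums(counts)
  if (pseudocount == 0 && any(cs == 0))
    stop("all-zero count column with pseudocount 0 in '", motif_id, "'")
  probs <- sweep(counts + pseudocount, 2, cs + 4 * pseudocount, "/")
  new_pwm(motif_id, probs, name = name, source = source)
}

#' Parse motifs in the JASPAR count-matrix dialect
#'
#' Records look like:
#' \preformatted{>MA0001.1 NAME
#' A [ 1  3 ]
#' C [ 1  0 ]
#' G [ 1  0 ]
#' T [ 1  1 ]}
#' Brackets are optional; the four base rows may appear in any order but all
#' four must be present with equal lengths.
#'
#' @param text Character scalar (file contents) or character vector of lines.
#' @param pseudocount Per-cell pseudocount for count-to-probability
#'   conversion.
#' @return List of `pwm` objects.
#' @export
parse_jaspar <- function(text, pseudocount = 0.25) {
  lines <- .as_lines(text)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) stop("no JASPAR records found (no '>' header)")
  bounds <- c(hdr, length(lines) + 1L)
  out <- vector("list", length(hdr))
  for (k in seq_along(hdr)) {
    block <- lines[bounds[k]:(bounds[k + 1L] - 1L)]
    head_tok <- strsplit(sub("^>\\s*", "", block[1L]), "\\s+")[[1L]]
    id <- head_tok[1L]
    nm <- if (length(head_tok) > 1L) paste(head_tok[-1L], collapse = " ") else id
    body <- block[-1L]
    if (length(body) < 4L)
      stop("JASPAR record '", id, "': expected 4 base rows, found ",
           length(body))
    rows <- list()
    for (ln in body[1:4]) {
      base <- toupper(sub("^\\s*([ACGTacgt]).*", "\\1", ln))
      if (!base %in% BASES)
        stop("JASPAR record '", id, "': malformed base row: ", ln)
      nums <- .parse_numbers(gsub("[][]", " ", sub("^\\s*[ACGTacgt]\\s*", "", ln)),
                             where = paste0("record '", id, "'"))
      rows[[base]] <- nums
    }
    if (length(rows) != 4L)
      stop("JASPAR record '", id, "': missing base row(s): ",
           paste(setdiff(BASES, names(rows)), collapse = ","))
    lens <- vapply(rows, length, 1L)
    if (length(unique(lens)) != 1L)
      stop("JASPAR record '", id, "': base rows have unequal lengths")
    counts <- do.call(rbind, rows[BASES])
    out[[k]] <- counts_to_probabilities(counts, pseudocount,
                                        motif_id = id, name = nm,
                                        source = "jaspar")
  }
  out
}

#' Parse motifs in the UniPROBE probability-matrix dialect
#'
#' Records are a name line (e.g. "Zic1 secondary") followed by four
#' tab-separated probability rows prefixed "A:", "C:", "G:", "T:".  Columns
#' are renormalized to sum exactly to one; a column sum deviating from 1 by
#' more than 0.05 is a parse error.
#'
#' @inheritParams parse_jaspar
#' @return List of `pwm` objects.
#' @export
parse_uniprobe <- function(text) {
  lines <- .as_lines(text)
  lines <- lines[nzchar(trimws(lines))]
  is_row <- grepl("^\\s*[ACGTacgt]\\s*:", lines)
  starts <- which(!is_row)
  if (length(starts) == 0L) stop("no UniPROBE records found (no name line)")
  out <- list()
  for (k in seq_along(starts)) {
    i0 <- starts[k]
    i1 <- if (k < length(starts)) starts[k + 1L] - 1L else length(lines)
    id <- trimws(lines[i0])
    body <- lines[(i0 + 1L):i1]
    if (i1 <= i0 || length(body) != 4L)
      stop("UniPROBE record '", id, "': expected 4 base rows, found ",
           max(0L, i1 - i0))
    rows <- list()
    for (ln in body) {
      base <- toupper(sub("^\\s*([ACGTacgt]):.*", "\\1", ln))
      nums <- .parse_numbers(sub("^\\s*[ACGTacgt]:\\s*", "", ln),
                             where = paste0("record '", id, "'"))
      rows[[base]] <- nums
    }
    lens <- vapply(rows, length, 1L)
    if (length(rows) != 4L || length(unique(lens)) != 1L)
      stop("UniPROBE record '", id, "': malformed base rows")
    probs <- do.call(rbind, rows[BASES])
    cs <- colSums(probs)
    if (any(abs(cs - 1) > 0.05))
      stop("UniPROBE record '", id, "': column sums deviate from 1 by > 0.05")
    probs <- sweep(probs, 2, cs, "/")
    out[[length(out) + 1L]] <- new_pwm(id, probs, name = id,
                                       source = "uniprobe")
  }
  out
}

#' Serialize PWMs as a tab-separated probability matrix
#'
#' Internal interchange format: per record a "#id <id>" line, a
#' "#source <source>" line, then four tab-separated probability rows
#' prefixed with the base letter.
#'
#' @param pwms List of `pwm` objects.
#' @param path Optional file to write; if `NULL` the text is returned.
#' @return Character vector of lines (invisibly when `path` given).
#' @export
write_pwms <- function(pwms, path = NULL) {
  lines <- unlist(lapply(pwms, function(p) {
    c(paste0("#id ", p$motif_id),
      paste0("#source ", p$source),
      vapply(BASES, function(b)
        paste(c(b, format(p$probs[b, ], digits = 17)), collapse = "\t"), ""))
  }))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Read PWMs written by [write_pwms()]
#' @param text Character scalar or lines, or a file path.
#' @return List of `pwm` objects.
#' @export
read_pwms <- function(text) {
  if (length(text) == 1L && file.exists(text)) text <- readLines(text)
  lines <- .as_lines(text)
  lines <- lines[nzchar(trimws(lines))]
  ids <- grep("^#id ", lines)
  out <- vector("list", length(ids))
  bounds <- c(ids, length(lines) + 1L)
  for (k in seq_along(ids)) {
    block <- lines[bounds[k]:(bounds[k + 1L] - 1L)]
    id <- sub("^#id ", "", block[1L])
    src <- sub("^#source ", "", block[2L])
    rows <- lapply(block[3:6], function(ln) {
      tok <- strsplit(ln, "\t")[[1L]]
      as.numeric(tok[-1L])
    })
    probs <- do.call(rbind, rows)
    probs <- sweep(probs, 2, colSums(probs), "/")
    out[[k]] <- new_pwm(id, probs, source = src)
  }
  out
}

#' Background nucleotide frequencies
#'
#' Zero-order background model used for log-odds scores and the score
#' distribution.  All four frequencies must be strictly positive.
#'
#' @param freqs Numeric length-4 vector (A, C, G, T), normalized internally.
#' @return Named numeric vector of class `motif_background`.
#' @export
background <- function(freqs = c(0.25, 0.25, 0.25, 0.25)) {
  if (length(freqs) != 4L) stop("background needs 4 frequencies")
  if (any(freqs <= 0)) stop("background frequencies must be > 0")
  freqs <- freqs / sum(freqs)
  structure(setNames(as.numeric(freqs), BASES), class = "motif_background")
}

#' Estimate a background from DNA sequences
#'
#' Zero-order frequencies over A,C,G,T (other letters ignored), floored at
#' `floor_freq` per base and renormalized, so the log-odds denominator never
#' vanishes on skewed peak sets.
#'
#' @param seqs Character vector of DNA sequences.
#' @param floor_freq Minimum per-base frequency (default 0.01).
#' @return A `motif_background`.
#' @export
background_from_sequences <- function(seqs, floor_freq = 0.01) {
  tab <- table(factor(strsplit(paste(toupper(seqs), collapse = ""), "")[[1L]],
                      levels = BASES))
  n <- sum(tab)
  f <- if (n == 0) rep(0.25, 4) else as.numeric(tab) / n
  f <- pmax(f, floor_freq)
  background(f)
}

#' Convert a PWM to an integer-scaled log-odds matrix
#'
#' Real score of base b at position i is log2(p'(b,i) / bg(b)) where p' is
#' the pseudocount-smoothed probability (p + pc*bg(b)) / (1 + pc).  Integer
#' scores are round(scale * (real - offset)) with offset the minimum real
#' score over the whole matrix, so all integer entries are non-negative —
#' the convention required by the score-distribution dynamic program.
#'
#' @param pwm A `pwm`.
#' @param bg A `motif_background`.
#' @param pseudocount Smoothing mass (must be > 0 when the PWM has zeros).
#' @param scale Integer scaling factor (default 1000): the de-scaled integer
#'   scores recover the real log-odds within 1/scale per position.
#' @return Object of class `log_odds_matrix` with fields `scores`
#'   (4 x width integer), `scale`, `offset`, `background`.
#' @export
pwm_to_logodds <- function(pwm, bg = background(), pseudocount = 0.01,
                           scale = 1000) {
  stopifnot(inherits(pwm, "pwm"))
  if (any(bg <= 0)) stop("zero background frequency")
  if (pseudocount <= 0 && any(pwm$probs == 0))
    stop("pseudocount must be > 0 when the PWM contains zero probabilities")
  smoothed <- (pwm$probs + pseudocount * matrix(bg, 4, pwm$width)) /
    (1 + pseudocount)
  real <- log2(smoothed / matrix(bg, 4, pwm$width))
  offset <- min(real)
  scores <- matrix(as.integer(round(scale * (real - offset))), 4, pwm$width,
                   dimnames = list(BASES, NULL))
  structure(list(motif_id = pwm$motif_id, width = pwm$width,
                 scores = scores, real = real, scale = scale,
                 offset = offset, background = bg),
            class = "log_odds_matrix")
}

#' Reverse complement of a PWM
#'
#' Columns reversed and base rows swapped A<->T, C<->G.  An involution:
#' applying it twice returns the original PWM.
#'
#' @param pwm A `pwm`.
#' @return A `pwm` for the opposite strand.
#' @export
reverse_complement_pwm <- function(pwm) {
  stopifnot(inherits(pwm, "pwm"))
  probs <- pwm$probs[c("T", "G", "C", "A"), rev(seq_len(pwm$width)),
                     drop = FALSE]
  rownames(probs) <- BASES
  new_pwm(pwm$motif_id, probs, name = pwm$name, source = pwm$source)
}

## ---- internal helpers -----------------------------------------------------

.as_lines <- function(text) {
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE))
    text <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  text
}

.parse_numbers <- function(s, where = "") {
  tok <- strsplit(trimws(s), "[\\s\t]+", perl = TRUE)[[1L]]
  tok <- tok[nzchar(tok)]
  if (length(tok) == 0L) stop("no numeric values in ", where)
  vals <- suppressWarnings(as.numeric(tok))
  if (anyNA(vals)) stop("non-numeric value '", tok[which(is.na(vals))[1L]],
                        "' in ", where)
  vals
}
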