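# Approximate substring screen: does a labeled transcript fragment share
# enough sequence with a mature miRNA to explain its array signal by
# cross-hybridization? Matching is sense-strand identity over one contiguous
# block with substitutions only (no indels); coordinates are 0-based,
# half-open.

#' Longest near-identical window between a miRNA and a transcript
#'
#' Finds the longest contiguous substring of the mature miRNA that matches a
#' transcript window of the same length with Hamming distance at most
#' \code{max_mismatch}. All relative alignments are scanned; within each, the
#' longest run containing at most \code{max_mismatch} mismatches is found by
#' a two-pointer sweep. Ties are resolved to the leftmost transcript
#' position, then the fewest mismatches.
#'
#' @param mirna_seq Mature miRNA sequence (U/T interchangeable).
#' @param transcript_seq Transcript sequence.
#' @param max_mismatch Mismatches allowed inside the window (default 1).
#' @return List with \code{length} (best window length), \code{tstart}
#'   (0-based transcript offset), \code{mstart} (0-based miRNA offset) and
#'   \code{mismatches} (count inside the reported window).
#' @export
best_window <- function(mirna_seq, transcript_seq, max_mismatch = 1L) {
  if (nchar(mirna_seq) == 0L || nchar(transcript_seq) == 0L) {
    fail("sequences must be non-empty")
  }
  p <- utf8ToInt(normalize_sequence(mirna_seq, "miRNA"))
  s <- utf8ToInt(normalize_sequence(transcript_seq, "transcript"))
  L <- length(p); Ls <- length(s)
  best <- list(length = 0L, tstart = NA_integer_, mstart = NA_integer_,
               mismatches = NA_integer_)
  for (d in seq.int(-(L - 1L), Ls - 1L)) {   # d = tstart - mstart (0-based)
    i_lo <- max(1L, 1L - d)
    i_hi <- min(L, Ls - d)
    if (i_hi < i_lo) next
    mism <- p[i_lo:i_hi] != s[(i_lo + d):(i_hi + d)]
    w <- longest_window_leq(mism, max_mismatch)
    if (w$length > best$length ||
        (w$length == best$length && w$length > 0L &&
         (i_lo + w$start - 1L + d) < best$tstart + 1L)) {
      mstart0 <- i_lo + w$start - 2L         # 0-based miRNA offset
      best <- list(length = w$length, tstart = mstart0 + d,
                   mstart = mstart0, mismatches = w$mismatches)
    }
  }
  best
}

# longest run of a logical mismatch vector containing at most k TRUEs;
# leftmost on ties, and minimal mismatch count for that leftmost run
longest_window_leq <- function(mism, k) {
  n <- length(mism)
  best_len <- 0L; best_start <- NA_integer_; best_mm <- NA_integer_
  lo <- 1L; mm <- 0L
  for (hi in seq_len(n)) {
    mm <- mm + mism[hi]
    while (mm > k) {
      mm <- mm - mism[lo]
      lo <- lo + 1L
    }
    len <- hi - lo + 1L
    if (len > best_len) {
      best_len <- len; best_start <- lo; best_mm <- mm
    }
  }
  # trim trailing mismatches out of the reported count? No: report the count
  # inside the chosen window as-is.
  list(length = best_len, start = best_start, mismatches = as.integer(best_mm))
}

#' Screen annotated miRNAs against a transcript set
#'
#' A miRNA of length L is flagged homologous when some transcript carries a
#' window of length at least \code{ceiling(min_frac * L)} matching a
#' contiguous block of the miRNA with at most \code{max_mismatch}
#' substitutions. Candidate transcripts are located with a fast exact-width
#' scan (\code{Biostrings::vcountPattern} over the miRNA's length-w
#' substrings, which is equivalent to the window criterion); the best window
#' is then refined per candidate. Matching is sense-strand by default; set
#' \code{both_strands = TRUE} to also scan the reverse complement.
#'
#' @param annotation Annotation table (\code{mirna_id},
#'   \code{mature_sequence}).
#' @param transcripts Named character vector of transcript sequences, or a
#'   FASTA path.
#' @param min_frac Minimum matched fraction of the miRNA length
#'   (default 0.9).
#' @param max_mismatch Allowed mismatches (default 1).
#' @param both_strands Also scan reverse complements (default FALSE).
#' @return Object of class \code{homology_screen}: list with \code{flags}
#'   (named logical per miRNA) and \code{hits} (data.frame of best hits:
#'   \code{mirna_id}, \code{transcript_id}, \code{window_start},
#'   \code{window_length}, \code{mismatches}, \code{overlap_frac}).
#' @export
homology_screen <- function(annotation, transcripts, min_frac = 0.9,
                            max_mismatch = 1L, both_strands = FALSE) {
  annotation <- validate_mirbase_annotation(annotation)
  if (is.character(transcripts) && length(transcripts) == 1L &&
      file.exists(transcripts)) {
    transcripts <- read_transcripts(transcripts)
  }
  if (!(min_frac > 0 && min_frac <= 1)) fail("min_frac must be in (0, 1]")
  flags <- stats::setNames(logical(nrow(annotation)), annotation$mirna_id)
  hits <- list()
  if (length(transcripts) == 0L) {
    return(structure(list(flags = flags, hits = empty_hits()),
                     class = "homology_screen"))
  }
  tx_names <- names(transcripts)
  subjects <- Biostrings::DNAStringSet(normalize_sequence(unname(transcripts),
                                                          "transcript"))
  if (both_strands) {
    subjects <- c(subjects, Biostrings::reverseComplement(subjects))
    tx_names <- c(tx_names, tx_names)
  }
  for (i in seq_len(nrow(annotation))) {
    mir <- annotation$mature_sequence[i]
    L <- nchar(mir)
    w <- as.integer(ceiling(min_frac * L))
    cand <- logical(length(subjects))
    for (start in seq_len(L - w + 1L)) {
      pat <- substr(mir, start, start + w - 1L)
      cand <- cand | Biostrings::vcountPattern(pat, subjects,
                                               max.mismatch = max_mismatch) > 0
    }
    if (!any(cand)) next
    flags[i] <- TRUE
    best <- NULL; best_tx <- NA_character_
    for (j in which(cand)) {
      bw <- best_window(mir, as.character(subjects[[j]]), max_mismatch)
      if (is.null(best) || bw$length > best$length) {
        best <- bw; best_tx <- tx_names[j]
      }
    }
    hits[[length(hits) + 1L]] <- data.frame(
      mirna_id = annotation$mirna_id[i], transcript_id = best_tx,
      window_start = best$tstart, window_length = best$length,
      mismatches = best$mismatches, overlap_frac = best$length / L,
      stringsAsFactors = FALSE)
  }
  hits <- if (length(hits)) do.call(rbind, hits) else empty_hits()
  structure(list(flags = flags, hits = hits), class = "homology_screen")
}

empty_hits <- function() {
  data.frame(mirna_id = character(0), transcript_id = character(0),
             window_start = integer(0), window_length = integer(0),
             mismatches = integer(0), overlap_frac = numeric(0),
             stringsAsFactors = FALSE)
}

#' @export
print.homology_screen <- function(x, ...) {
  cat(sprintf("Homology screen: %d / %d miRNAs flagged\n",
              sum(x$flags), length(x$flags)))
  invisible(x)
}

#' Homology fraction per group
#'
#' @param flags Named logical vector of per-miRNA homology flags.
#' @param grouping Named group labels (cluster assignment or classification
#'   labels) over the same miRNAs.
#' @return Named numeric vector: flagged fraction per group (NA for an
#'   empty group level).
#' @export
group_homology_fraction <- function(flags, grouping) {
  missing_f <- setdiff(names(grouping), names(flags))
  if (length(missing_f)) {
    fail("no homology flag for: %s", paste(utils::head(missing_f, 5), collapse = ", "))
  }
  g <- if (is.factor(grouping)) grouping else factor(grouping)
  out <- tapply(flags[names(grouping)], g, mean)
  out[is.nan(out)] <- NA_real_
  stats::setNames(as.numeric(out), levels(g))
}
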