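# Readers and writers for the tab-delimited interchange formats.
#
# Expression matrices: first column = miRNA ID, header row = sample IDs, "."
# decimal, UTF-8. A leading comment line "# state: normalized" marks
# normalized matrices. Detection flags travel in a companion "<path>.flags"
# file with identical layout (0/1); when absent, a quantile fallback rule is
# applied and logged.

#' Read an expression matrix from disk
#'
#' @param path Path to the matrix file.
#' @param format \code{"tsv"} (default) or \code{"geo_series_matrix"} for the
#'   table section of a GEO series-matrix file.
#' @param flags_path Optional path to a companion detection-flag table. For
#'   TSV input, \code{"<path>.flags"} is picked up automatically when present.
#' @param detect_quantile Optional fallback detection rule when no flags are
#'   available: a cell is flagged detected when its value exceeds this
#'   quantile of the whole matrix (e.g. 0.25); the fallback is reported via
#'   \code{message()}. With the default \code{NULL}, a flag-less matrix is
#'   treated as all-detected.
#' @return A validated \code{\link{expression_matrix}}; state is taken from
#'   the header comment (\code{raw} when absent). Row/column order is
#'   preserved from the file.
#' @export
read_expression_matrix <- function(path, format = c("tsv", "geo_series_matrix"),
                                   flags_path = NULL, detect_quantile = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) fail("file not found: %s", path)
  if (format == "tsv") {
    parsed <- parse_matrix_tsv(path)
  } else {
    parsed <- parse_geo_series_matrix(path)
  }
  values <- parsed$values
  state <- parsed$state
  if (is.null(flags_path) && format == "tsv" && file.exists(paste0(path, ".flags"))) {
    flags_path <- paste0(path, ".flags")
  }
  if (!is.null(flags_path)) {
    fparsed <- parse_matrix_tsv(flags_path)
    fv <- fparsed$values
    if (!identical(dimnames(fv), dimnames(values))) {
      fail("flag table layout does not match the matrix: %s", flags_path)
    }
    detected <- fv != 0
  } else if (state == "raw" && !is.null(detect_quantile)) {
    thr <- stats::quantile(values, detect_quantile, names = FALSE)
    detected <- values > thr
    dimnames(detected) <- dimnames(values)
    message(sprintf(
      "no detection flags for %s; fallback rule: value > %.3g (quantile %.2f)",
      basename(path), thr, detect_quantile))
  } else {
    detected <- matrix(TRUE, nrow(values), ncol(values), dimnames = dimnames(values))
  }
  expression_matrix(values, detected, state = state)
}

parse_matrix_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  state <- "raw"
  if (length(lines) && grepl("^#", lines[1])) {
    if (grepl("state:\\s*normalized", lines[1])) state <- "normalized"
    lines <- lines[-1]
  }
  if (length(lines) < 2L) fail("matrix file has no data rows: %s", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  sample_ids <- header[-1]
  body <- fields[-1]
  ncol_expected <- length(header)
  ids <- character(length(body))
  vals <- matrix(NA_real_, length(body), length(sample_ids))
  for (i in seq_along(body)) {
    row <- body[[i]]
    if (length(row) != ncol_expected) {
      fail("row %d has %d fields, expected %d (%s)", i, length(row), ncol_expected, path)
    }
    ids[i] <- row[1]
    num <- suppressWarnings(as.numeric(row[-1]))
    bad <- which(is.na(num) & !(row[-1] %in% c("NA", "")))
    if (length(bad)) {
      fail("non-numeric cell at row '%s', column '%s': '%s'",
           row[1], sample_ids[bad[1]], row[-1][bad[1]])
    }
    vals[i, ] <- num
  }
  dup <- ids[duplicated(ids)]
  if (length(dup)) fail("duplicate miRNA IDs in %s: %s", path, paste(unique(dup), collapse = ", "))
  if (anyDuplicated(sample_ids)) {
    fail("duplicate sample IDs in %s: %s", path,
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  dimnames(vals) <- list(ids, sample_ids)
  list(values = vals, state = state)
}

parse_geo_series_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  beg <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(beg) != 1L || length(end) != 1L || end <= beg + 1L) {
    fail("no series-matrix table found in %s", path)
  }
  tab <- lines[(beg + 1L):(end - 1L)]
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(gsub('"', "", tab, fixed = TRUE), tmp)
  parse_matrix_tsv(tmp)
}

#' Write an expression matrix (and its flags) to disk
#'
#' Emits the matrix as TSV with a \code{# state:} header comment and the
#' detection flags as \code{<path>.flags} (0/1, same layout), so that
#' \code{\link{read_expression_matrix}} round-trips the object.
#'
#' @param m An \code{ExpressionMatrix}.
#' @param path Output path.
#' @param flags Write the companion flag file (default \code{TRUE}).
#' @return \code{path}, invisibly.
#' @export
write_expression_matrix <- function(m, path, flags = TRUE) {
  validate_expression_matrix(m)
  con <- file(path, "w", encoding = "UTF-8")
  writeLines(sprintf("# state: %s", m$state), con)
  write_tsv_matrix(m$values, "mirna_id", con)
  close(con)
  if (flags) {
    con <- file(paste0(path, ".flags"), "w", encoding = "UTF-8")
    writeLines(sprintf("# state: %s", m$state), con)
    write_tsv_matrix(m$detected + 0L, "mirna_id", con)
    close(con)
  }
  invisible(path)
}

write_tsv_matrix <- function(v, id_col, con) {
  writeLines(paste(c(id_col, colnames(v)), collapse = "\t"), con)
  body <- apply(v, 1, function(r) paste(format(r, trim = TRUE, digits = 15,
                                               scientific = FALSE), collapse = "\t"))
  writeLines(paste(rownames(v), body, sep = "\t"), con)
}

sample_meta_columns <- c("sample_id", "tissue", "temperature", "time_h", "rin",
                         "replicate", "arm", "rna_fraction", "dnase", "rnase_units")

#' Validate a sample metadata table
#'
#' Checks field domains (tissue, temperature, canonical storage times, RIN in
#' [1,10], experiment arm, RNA fraction, DNase, RNase dose) and the
#' cross-field invariants: time-course samples carry the small-RNA fraction
#' and no RNase dose; small-RNA-depleted samples always carry an RNase dose.
#'
#' @param meta A data.frame with the columns listed in the details.
#' @return \code{meta}, with canonical column types, after validation.
#' @export
validate_sample_meta <- function(meta) {
  missing_cols <- setdiff(sample_meta_columns, names(meta))
  if (length(missing_cols)) {
    fail("metadata is missing columns: %s", paste(missing_cols, collapse = ", "))
  }
  meta <- meta[, sample_meta_columns]
  meta$sample_id <- as.character(meta$sample_id)
  if (anyDuplicated(meta$sample_id)) {
    fail("duplicate sample IDs: %s",
         paste(unique(meta$sample_id[duplicated(meta$sample_id)]), collapse = ", "))
  }
  chk <- function(col, choices) {
    bad <- !meta[[col]] %in% choices
    if (any(bad)) {
      fail("invalid %s for sample %s: '%s'", col,
           meta$sample_id[bad][1], meta[[col]][bad][1])
    }
  }
  chk("tissue", c("liver", "heart", "brain"))
  chk("temperature", c("4C", "RT"))
  meta$time_h <- as.numeric(meta$time_h)
  chk("time_h", c(0, 1, 3, 6, 14, 24, 48, 96))
  meta$rin <- as.numeric(meta$rin)
  bad <- is.na(meta$rin) | meta$rin < 1 | meta$rin > 10
  if (any(bad)) {
    fail("rin outside [1,10] for sample %s: %s", meta$sample_id[bad][1],
         meta$rin[bad][1])
  }
  meta$replicate <- as.integer(meta$replicate)
  if (any(is.na(meta$replicate) | meta$replicate < 1)) fail("replicate must be a positive integer")
  chk("arm", c("timecourse", "control"))
  chk("rna_fraction", c("with_small_rna", "depleted"))
  meta$dnase <- as.character(meta$dnase)
  chk("dnase", c("yes", "no", "na"))
  meta$rnase_units <- as.character(meta$rnase_units)
  chk("rnase_units", c("0", "0.027", "0.67", "na"))
  tc <- meta$arm == "timecourse"
  bad <- tc & (meta$rna_fraction != "with_small_rna" | meta$rnase_units != "na")
  if (any(bad)) {
    fail("time-course sample %s must have rna_fraction=with_small_rna and rnase_units=na",
         meta$sample_id[bad][1])
  }
  bad <- meta$rna_fraction == "depleted" & meta$rnase_units == "na"
  if (any(bad)) {
    fail("depleted sample %s must carry an RNase dose", meta$sample_id[bad][1])
  }
  rownames(meta) <- NULL
  meta
}

#' Read sample metadata
#'
#' @param path Tab-delimited file whose header matches the metadata fields
#'   (sample_id, tissue, temperature, time_h, rin, replicate, arm,
#'   rna_fraction, dnase, rnase_units; missing categorical values spelled
#'   \code{na}).
#' @return A validated data.frame, one row per sample.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) fail("file not found: %s", path)
  meta <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  validate_sample_meta(meta)
}

#' Write sample metadata
#'
#' @param meta A validated metadata data.frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_sample_metadata <- function(meta, path) {
  meta <- validate_sample_meta(meta)
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a miRBase annotation table
#'
#' Expects columns \code{mirna_id}, \code{mature_sequence},
#' \code{first_version}. Sequences are upper-cased and U is normalized to T
#' (recorded in the \code{"had_rna_alphabet"} attribute); versions must lie in
#' 1..21 and mature sequences must be 16-30 nt over \{A,C,G,T,U\}.
#'
#' @param path Tab-delimited annotation file.
#' @return A validated annotation data.frame.
#' @export
read_mirbase_annotation <- function(path) {
  if (!file.exists(path)) fail("file not found: %s", path)
  ann <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  validate_mirbase_annotation(ann)
}

#' Validate a miRBase annotation table
#'
#' @param ann Data.frame with columns \code{mirna_id}, \code{mature_sequence},
#'   \code{first_version}.
#' @return The validated table with normalized (DNA-alphabet) sequences.
#' @export
validate_mirbase_annotation <- function(ann) {
  need <- c("mirna_id", "mature_sequence", "first_version")
  missing_cols <- setdiff(need, names(ann))
  if (length(missing_cols)) {
    fail("annotation is missing columns: %s", paste(missing_cols, collapse = ", "))
  }
  ann <- ann[, need]
  ann$mirna_id <- as.character(ann$mirna_id)
  if (anyDuplicated(ann$mirna_id)) {
    fail("duplicate miRNA IDs in annotation: %s",
         paste(unique(ann$mirna_id[duplicated(ann$mirna_id)]), collapse = ", "))
  }
  had_rna <- any(grepl("U", toupper(ann$mature_sequence), fixed = TRUE))
  ann$mature_sequence <- normalize_sequence(as.character(ann$mature_sequence),
                                            "mature_sequence")
  len <- nchar(ann$mature_sequence)
  bad <- len < 16L | len > 30L
  if (any(bad)) {
    fail("mature sequence length outside [16,30] for %s", ann$mirna_id[bad][1])
  }
  ann$first_version <- suppressWarnings(as.integer(ann$first_version))
  bad <- is.na(ann$first_version) | ann$first_version < 1L | ann$first_version > 21L
  if (any(bad)) {
    fail("first_version outside [1,21] for %s", ann$mirna_id[bad][1])
  }
  attr(ann, "had_rna_alphabet") <- had_rna
  rownames(ann) <- NULL
  ann
}

#' Write a miRBase annotation table
#'
#' @param ann A validated annotation data.frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_mirbase_annotation <- function(ann, path) {
  ann <- validate_mirbase_annotation(ann)
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read transcript sequences from FASTA
#'
#' @param path FASTA file; RNA alphabets are normalized to DNA.
#' @return Named character vector of sequences.
#' @export
read_transcripts <- function(path) {
  if (!file.exists(path)) fail("file not found: %s", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) fail("FASTA parse failure in %s: %s", path,
                                           conditionMessage(e)))
  seqs <- as.character(set)
  nm <- sub("\\s.*$", "", names(seqs))
  if (any(nm == "")) fail("FASTA record without a name in %s", path)
  stats::setNames(normalize_sequence(seqs, "transcript"), nm)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of DNA sequences.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_transcripts <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
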