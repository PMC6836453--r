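# Delimited text I/O for recordings, event tables, labeled matrices, and
# the packaged subject-description table.
#
# sEMG format: UTF-8 CSV; line 1 is `# fs_hz=<rate>`; line 2 a header of
# muscle labels; each following row is one time sample across channels.

#' Write an sEMG recording to the delimited format
#'
#' @param rec an [emg_recording()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_emg <- function(rec, path) {
  stopifnot(inherits(rec, "emg_recording"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# fs_hz=%g", rec$fs), con)
  writeLines(paste(rec$muscle_labels, collapse = ","), con)
  utils::write.table(format(t(rec$samples), digits = 15, trim = TRUE,
                            scientific = FALSE),
                     con, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read an sEMG recording from the delimited format
#'
#' @param path input file.
#' @param expected_channels if not `NULL`, the file must have exactly this
#'   many channels.
#' @return an [emg_recording()].
#' @export
read_emg <- function(path, expected_channels = NULL) {
  abort_if(!file.exists(path), "file not found: %s", path)
  hdr <- readLines(path, n = 2)
  abort_if(length(hdr) < 2 || !grepl("^# *fs_hz=", hdr[1]),
           "%s: line 1 must be '# fs_hz=<rate>'", path)
  fs <- as.numeric(sub("^# *fs_hz=", "", hdr[1]))
  abort_if(is.na(fs) || fs <= 0, "%s: invalid sampling rate in header", path)
  labels <- trimws(strsplit(hdr[2], ",")[[1]])
  abort_if(anyDuplicated(labels) > 0, "%s: duplicated muscle labels", path)
  if (!is.null(expected_channels)) {
    abort_if(length(labels) != expected_channels,
             "%s: found %d channels, expected %d",
             path, length(labels), expected_channels)
  }
  nf <- utils::count.fields(path, sep = ",", skip = 2, comment.char = "")
  bad <- which(nf != length(labels))
  abort_if(length(bad) > 0, "%s: line %d has %d fields, expected %d",
           path, bad[1] + 2L, nf[bad[1]], length(labels))
  df <- utils::read.csv(path, skip = 2, header = FALSE,
                        colClasses = NA, comment.char = "")
  for (j in seq_along(df)) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    nonnum <- which(is.na(v) & !is.na(df[[j]]))
    abort_if(length(nonnum) > 0, "%s: non-numeric value '%s' at line %d",
             path, df[nonnum[1], j], nonnum[1] + 2L)
    df[[j]] <- v
  }
  abort_if(anyNA(df), "%s: missing values in sample rows", path)
  emg_recording(t(as.matrix(df)), muscle_labels = labels, fs = fs)
}

#' Write a gait event table
#'
#' @param events a [gait_events()] table.
#' @param path output file; times are written with 6 decimal places.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  stopifnot(inherits(events, "gait_events"))
  df <- as.data.frame(events)
  for (cl in c("HS_ref", "TO_contra", "HS_contra", "TO_ref", "HS_ref_next")) {
    df[[cl]] <- sprintf("%.6f", df[[cl]])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a gait event table
#'
#' @param path input CSV with columns `stride_id`, `HS_ref`, `TO_contra`,
#'   `HS_contra`, `TO_ref`, `HS_ref_next` (seconds).
#' @return a [gait_events()] table (monotonicity validated).
#' @export
read_events <- function(path) {
  abort_if(!file.exists(path), "file not found: %s", path)
  df <- utils::read.csv(path)
  abort_if(nrow(df) == 0, "%s: empty event table", path)
  gait_events(df)
}

#' Write a labeled numeric matrix as delimited text
#'
#' @param m matrix with row and/or column names.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_matrix_labeled <- function(m, path) {
  df <- data.frame(row = rownames(m) %||% paste0("r", seq_len(nrow(m))),
                   as.data.frame(m), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a labeled numeric matrix written by [write_matrix_labeled()]
#'
#' @param path input file.
#' @return numeric matrix with dimnames.
#' @export
read_matrix_labeled <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Path to a packaged example data file
#'
#' @param file file name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return a file path (or a vector of file names).
#' @export
gaitsynergy_example <- function(file = NULL) {
  base <- system.file("extdata", package = "gaitsynergy")
  if (is.null(file)) return(list.files(base))
  path <- file.path(base, file)
  abort_if(!file.exists(path), "no packaged file '%s'", file)
  path
}

#' Descriptive statistics for a subject-description table
#'
#' Computes per-column mean and standard deviation (rounded half-up to one
#' decimal, the usual presentation convention) for every numeric column of
#' a subject table such as the packaged participant fixtures
#' (`table1_patients.csv`, `table1_controls.csv`).
#'
#' @param path CSV file with one row per subject.
#' @param columns optional character vector restricting the summarized
#'   columns; by default all numeric columns except `subject`.
#' @return data.frame with `column`, `n`, `mean`, `sd` (SD is `NA`, not 0,
#'   for a single-row table).
#' @export
summarize_table1 <- function(path, columns = NULL) {
  abort_if(!file.exists(path), "file not found: %s", path)
  df <- utils::read.csv(path)
  num_cols <- names(df)[vapply(df, is.numeric, logical(1))]
  num_cols <- setdiff(num_cols, "subject")
  if (!is.null(columns)) {
    missing <- setdiff(columns, names(df))
    abort_if(length(missing) > 0, "missing column(s): %s",
             paste(missing, collapse = ", "))
    num_cols <- intersect(columns, num_cols)
  }
  out <- lapply(num_cols, function(cl) {
    v <- df[[cl]]
    data.frame(column = cl, n = length(v),
               mean = round_half_up(mean(v), 1),
               sd = if (length(v) > 1) round_half_up(stats::sd(v), 1) else NA_real_)
  })
  do.call(rbind, out)
}
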