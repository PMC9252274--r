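#' Read a regional time-series file
#'
#' Reads a delimited text file of T rows x N regions with a header of region
#' labels, validating that all cells are numeric and, when an atlas label
#' order is supplied, reordering columns to it (with a warning if the file
#' order differed).
#'
#' @param path File path (tab- or comma-delimited; auto-detected).
#' @param atlas_labels Optional character vector giving the expected region
#'   order.
#' @return Numeric matrix with region labels as column names.
#' @export
read_timeseries <- function(path, atlas_labels = NULL) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE)
  bad <- !vapply(df, is.numeric, logical(1))
  if (any(bad))
    stop("non-numeric column(s) in ", path, ": ",
         paste(names(df)[bad], collapse = ", "), call. = FALSE)
  X <- as.matrix(df)
  if (anyNA(X)) stop("missing values in ", path, call. = FALSE)
  if (!is.null(atlas_labels)) {
    if (!setequal(colnames(X), atlas_labels))
      stop("region labels in ", path, " do not match the atlas table",
           call. = FALSE)
    if (!identical(colnames(X), atlas_labels)) {
      warning("region columns reordered to atlas order")
      X <- X[, atlas_labels, drop = FALSE]
    }
  }
  X
}

#' Write a regional time-series file
#'
#' @param ts `T x N` matrix with region labels as column names.
#' @param path Output path (tab-delimited).
#' @export
write_timeseries <- function(ts, path) {
  write.table(ts, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an FC matrix as labelled delimited text
#'
#' @param fc An `fc_matrix`.
#' @param path Output path (CSV with a label header row and column).
#' @export
write_fc_matrix <- function(fc, path) {
  write.csv(fc$z, path, quote = FALSE)
  invisible(path)
}

#' Read an FC matrix written by [write_fc_matrix()]
#'
#' @param path File path.
#' @param session_id Optional session identifier.
#' @return An `fc_matrix`.
#' @export
read_fc_matrix <- function(path, session_id = NULL) {
  df <- read.csv(path, row.names = 1, check.names = FALSE)
  z <- as.matrix(df)
  if (nrow(z) != ncol(z) || max(abs(z - t(z))) > 1e-10)
    stop("not a symmetric FC matrix: ", path, call. = FALSE)
  z <- (z + t(z)) / 2
  diag(z) <- 0
  structure(list(z = z, region_labels = colnames(z),
                 session_id = session_id), class = "fc_matrix")
}

#' Write a simulated study to disk
#'
#' Writes the participants/sessions table (CSV), one tab-delimited time-series
#' file per session, and a ground-truth JSON of implanted parameters.
#'
#' @param study Result of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(study$cohort$sessions, file.path(dir, "participants.csv"),
            row.names = FALSE)
  ts_dir <- file.path(dir, "timeseries")
  dir.create(ts_dir, showWarnings = FALSE)
  for (sid in names(study$timeseries))
    write_timeseries(study$timeseries[[sid]],
                     file.path(ts_dir, paste0(sid, ".tsv")))
  truth <- study$truth
  truth$subject_scale <- as.list(truth$subject_scale)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

# tiny FNV-1a hash of a string (provenance manifests; no external digest dep)
fnv1a <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
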