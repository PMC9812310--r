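## Delimited-text I/O for matrices, labels and experiment configurations.
## Files ending in .gz are read and written through a gzip connection;
## field separator is inferred from the extension (.csv -> comma, else tab).

infer_sep <- function(path) {
  base <- sub("\\.gz$", "", path)
  if (grepl("\\.csv$", base, ignore.case = TRUE)) "," else "\t"
}

open_read <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

open_write <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
}

#' Read a square dissimilarity matrix from delimited text
#'
#' Expects a square numeric matrix, tab- or comma-separated (inferred from
#' the extension), optionally gzip-compressed, with an optional first row of
#' sample ids (detected automatically: a first line whose fields are not all
#' numeric is taken as a header). Ragged rows and non-numeric cells raise
#' errors naming the offending location. The matrix is validated through
#' [as_dist_matrix()].
#'
#' @param path File path (`.tsv`, `.csv`, optionally `.gz`).
#' @param metric Metric tag to record on the returned matrix.
#' @param tol Symmetry tolerance passed to [as_dist_matrix()].
#' @return A `dist_matrix`; sample ids, if present, are kept in attribute
#'   `"ids"`.
#' @export
read_dist_matrix <- function(path, metric = "precomputed", tol = 1e-8) {
  con <- open_read(path)
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop(sprintf("empty file: %s", path),
                                call. = FALSE)
  sep <- infer_sep(path)
  fields <- strsplit(lines, sep, fixed = TRUE)
  first <- suppressWarnings(as.numeric(fields[[1L]]))
  ids <- NULL
  if (anyNA(first)) {                   # header row of ids
    ids <- trimws(fields[[1L]])
    if (anyDuplicated(ids)) {
      stop(sprintf("duplicate sample id '%s' in header of %s",
                   ids[duplicated(ids)][1L], path), call. = FALSE)
    }
    fields <- fields[-1L]
  }
  n <- length(fields)
  widths <- lengths(fields)
  if (any(widths != widths[1L])) {
    bad <- which(widths != widths[1L])[1L]
    stop(sprintf("ragged row %d in %s: %d fields, expected %d",
                 bad, path, widths[bad], widths[1L]), call. = FALSE)
  }
  vals <- suppressWarnings(vapply(fields, as.numeric, numeric(widths[1L])))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell at row %d, column %d of %s",
                 bad[2L], bad[1L], path), call. = FALSE)
  }
  m <- t(matrix(vals, nrow = widths[1L]))
  if (nrow(m) != ncol(m)) {
    stop(sprintf("matrix in %s is %d x %d, not square", path, nrow(m),
                 ncol(m)), call. = FALSE)
  }
  if (!is.null(ids) && length(ids) != nrow(m)) {
    stop(sprintf("header of %s has %d ids but matrix has %d rows",
                 path, length(ids), nrow(m)), call. = FALSE)
  }
  out <- as_dist_matrix(m, metric = metric, tol = tol)
  attr(out, "ids") <- ids
  out
}

#' Write a dissimilarity matrix as delimited text
#'
#' Values are printed with 9 significant digits, which round-trips typical
#' dissimilarities within diff-friendly file sizes.
#'
#' @param dmatrix A `dist_matrix` or `dod_matrix`.
#' @param path Output path (`.tsv`/`.csv`, optionally `.gz`).
#' @param ids Optional character vector of sample ids written as a header
#'   row; defaults to the ids stored on the matrix, if any.
#' @param digits Significant digits for printing.
#' @return `path`, invisibly.
#' @export
write_dist_matrix <- function(dmatrix, path, ids = attr(dmatrix, "ids"),
                              digits = 9) {
  v <- if (inherits(dmatrix, "dod_matrix")) dmatrix$values
       else as_dist_matrix(dmatrix)$values
  sep <- infer_sep(path)
  con <- open_write(path)
  on.exit(close(con))
  if (!is.null(ids)) {
    if (length(ids) != nrow(v)) {
      stop("length of 'ids' does not match the matrix size", call. = FALSE)
    }
    writeLines(paste(ids, collapse = sep), con)
  }
  writeLines(apply(signif(v, digits), 1L, paste, collapse = sep), con)
  invisible(path)
}

#' Read per-sample labels from a two-column delimited file
#'
#' Column 1 is the sample id, column 2 the label ([NOISE_LABEL] reserved for
#' noise). Duplicate ids are an error. When `ids` is supplied (e.g. from the
#' header of a matrix file), labels are checked and returned in that order.
#'
#' @param path File path (two columns, tab- or comma-separated, optional
#'   `.gz`).
#' @param ids Optional sample ids to align the labels against; an id missing
#'   from the file, or a file id missing from `ids`, is an error.
#' @return Named character vector of labels.
#' @export
read_labels <- function(path, ids = NULL) {
  con <- open_read(path)
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop(sprintf("empty file: %s", path),
                                call. = FALSE)
  sep <- infer_sep(path)
  fields <- strsplit(lines, sep, fixed = TRUE)
  if (any(lengths(fields) != 2L)) {
    bad <- which(lengths(fields) != 2L)[1L]
    stop(sprintf("row %d of %s has %d fields, expected 2 (id, label)",
                 bad, path, lengths(fields)[bad]), call. = FALSE)
  }
  lab <- vapply(fields, `[`, character(1), 2L)
  names(lab) <- vapply(fields, `[`, character(1), 1L)
  if (anyDuplicated(names(lab))) {
    stop(sprintf("duplicate sample id '%s' in %s",
                 names(lab)[duplicated(names(lab))][1L], path),
         call. = FALSE)
  }
  if (!is.null(ids)) {
    missing <- setdiff(ids, names(lab))
    if (length(missing)) {
      stop(sprintf("no label for sample id '%s' in %s", missing[1L], path),
           call. = FALSE)
    }
    extra <- setdiff(names(lab), ids)
    if (length(extra)) {
      stop(sprintf("label file %s has id '%s' absent from the matrix",
                   path, extra[1L]), call. = FALSE)
    }
    lab <- lab[ids]
  }
  lab
}

#' Write per-sample labels
#'
#' @param labels Character vector of labels; names are used as sample ids
#'   (defaulting to `s1, s2, ...`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  ids <- names(labels)
  if (is.null(ids)) ids <- paste0("s", seq_along(labels))
  sep <- infer_sep(path)
  con <- open_write(path)
  on.exit(close(con))
  writeLines(paste(ids, as.character(labels), sep = sep), con)
  invisible(path)
}

#' Read an experiment configuration from key = value text
#'
#' One `key = value` pair per line; `#` starts a comment. Values that parse
#' as numbers are returned numeric; comma-separated values become vectors
#' (so `seeds = 1, 2, 3` is `c(1, 2, 3)`). A configuration written by
#' [write_config()] reads back identically.
#'
#' @param path File path.
#' @return Named list of values.
#' @export
read_config <- function(path) {
  con <- open_read(path)
  on.exit(close(con))
  lines <- readLines(con)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (i in seq_along(lines)) {
    if (!grepl("=", lines[i], fixed = TRUE)) {
      stop(sprintf("line %d of %s is not 'key = value': %s", i, path,
                   lines[i]), call. = FALSE)
    }
    key <- trimws(sub("=.*$", "", lines[i]))
    val <- trimws(sub("^[^=]*=", "", lines[i]))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1L]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (anyNA(num)) parts else num
  }
  out
}

#' Write an experiment configuration as key = value text
#'
#' @param config Named list of scalars or vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  if (is.null(names(config)) || any(!nzchar(names(config)))) {
    stop("'config' must be a fully named list", call. = FALSE)
  }
  con <- open_write(path)
  on.exit(close(con))
  writeLines(vapply(names(config), function(key) {
    sprintf("%s = %s", key, paste(format(config[[key]], trim = TRUE,
                                         scientific = FALSE),
                                  collapse = ", "))
  }, character(1)), con)
  invisible(path)
}

## structured stage log line on stderr; results never go to stderr
log_stage <- function(stage, ...) {
  info <- c(...)
  msg <- if (length(info)) {
    paste0(sprintf("[%s] ", stage),
           paste(names(info), unname(info), sep = "=", collapse = " "))
  } else sprintf("[%s]", stage)
  message(msg)
}
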