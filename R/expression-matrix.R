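#' Validate an expression matrix
#'
#' Expression data travel through the package as a plain numeric matrix with
#' features as rows and samples as columns, both axes carrying unique
#' identifiers. Values are assumed to be on the log2 scale throughout.
#'
#' @param x numeric matrix, features x samples, with rownames (feature ids)
#'   and colnames (sample ids).
#' @return `x`, invisibly, after validation.
#' @export
validate_expression <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression must be a numeric matrix (features x samples)")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix must have feature ids (rownames) and sample ids (colnames)")
  dup_f <- unique(rownames(x)[duplicated(rownames(x))])
  if (length(dup_f))
    stop("duplicate feature id(s): ", paste(dup_f, collapse = ", "))
  dup_s <- unique(colnames(x)[duplicated(colnames(x))])
  if (length(dup_s))
    stop("duplicate sample id(s): ", paste(dup_s, collapse = ", "))
  if (any(!is.finite(x)))
    stop("expression matrix contains non-finite values")
  invisible(x)
}

#' Read an expression matrix from delimited text
#'
#' Reads a features-by-samples table. Two dialects are supported:
#' `"tsv"`, a plain tab-separated table whose first column holds feature ids
#' and whose header row holds sample ids; and `"geo"`, the GEO series-matrix
#' dialect in which metadata lines start with `!` and the expression table is
#' bracketed by `!series_matrix_table_begin` / `!series_matrix_table_end`.
#'
#' @param path file to read.
#' @param dialect `"tsv"` (default) or `"geo"`.
#' @param transpose set `TRUE` if the file stores samples as rows.
#' @return numeric matrix, features x samples.
#' @export
read_expression <- function(path, dialect = c("tsv", "geo"), transpose = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (dialect == "geo") {
    beg <- grep("^!series_matrix_table_begin", lines, ignore.case = TRUE)
    end <- grep("^!series_matrix_table_end", lines, ignore.case = TRUE)
    if (length(beg) == 1L && length(end) == 1L && end > beg + 1L) {
      lines <- lines[(beg + 1L):(end - 1L)]
    } else {
      lines <- lines[!startsWith(lines, "!")]
    }
    lines <- gsub("\"", "", lines, fixed = TRUE)
  }
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("empty or header-only expression file: ", path)

  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  sample_ids <- trimws(header[-1L])
  body <- fields[-1L]
  feature_ids <- trimws(vapply(body, `[`, character(1), 1L))
  ncol_expect <- length(sample_ids)
  vals <- matrix(NA_real_, nrow = length(body), ncol = ncol_expect)
  for (i in seq_along(body)) {
    row <- body[[i]][-1L]
    if (length(row) != ncol_expect)
      stop("row for feature '", feature_ids[i], "' has ", length(row),
           " values; expected ", ncol_expect)
    v <- suppressWarnings(as.numeric(row))
    if (any(is.na(v))) {
      j <- which(is.na(v))[1L]
      stop("unparseable value at feature '", feature_ids[i],
           "', sample '", sample_ids[j], "': '", row[j], "'")
    }
    vals[i, ] <- v
  }
  dimnames(vals) <- list(feature_ids, sample_ids)
  if (transpose) vals <- t(vals)
  validate_expression(vals)
  vals
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression()] for the plain dialect: first column is the
#' feature id, header row carries the sample ids.
#'
#' @param x validated expression matrix.
#' @param path output file.
#' @export
write_expression <- function(x, path) {
  validate_expression(x)
  df <- data.frame(feature_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical table
#'
#' CSV with required columns `sample_id`, `time`, `event`, `endpoint`
#' (one of OS, DFS, DMFS); extra covariate columns (age, sex, stage, batch,
#' ...) are preserved verbatim. Time is in the cohort's own units (months in
#' the cohorts this package emulates), `event` is 0/1.
#'
#' @param path CSV file.
#' @return data.frame.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_clinical(df)
  df
}

#' @rdname read_clinical
#' @param df clinical data.frame to validate.
#' @export
validate_clinical <- function(df) {
  need <- c("sample_id", "time", "event", "endpoint")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("clinical table missing column(s): ", paste(miss, collapse = ", "))
  if (any(df$time < 0)) stop("clinical times must be non-negative")
  if (!all(df$event %in% c(0, 1))) stop("clinical event must be 0/1")
  if (!all(df$endpoint %in% c("OS", "DFS", "DMFS")))
    stop("endpoint must be one of OS, DFS, DMFS")
  key <- paste(df$sample_id, df$endpoint)
  if (anyDuplicated(key))
    stop("duplicate sample_id within an endpoint")
  invisible(df)
}

#' @rdname read_clinical
#' @export
write_clinical <- function(df, path) {
  validate_clinical(df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
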