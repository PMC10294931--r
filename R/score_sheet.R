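#' Score sheets
#'
#' A score sheet holds one 0-5 score per tertiary index (rows) and
#' subject (columns) — the same layout as the published scoring tables,
#' so sheets can be pasted straight from a report. Internally it is a
#' numeric matrix with index ids as row names and subject names as
#' column names.
#'
#' @param scores numeric matrix (or data frame) with tertiary index ids
#'   as row names and subject identifiers as column names.
#' @return An object of class `score_sheet`.
#' @seealso [read_score_sheet()], [validate_score_sheet()], [assess()]
#' @export
score_sheet <- function(scores) {
  m <- as.matrix(scores)
  if (is.null(rownames(m)))
    stop("score sheet needs tertiary index ids as row names",
         call. = FALSE)
  if (is.null(colnames(m)))
    colnames(m) <- paste0("subject", seq_len(ncol(m)))
  storage.mode(m) <- "numeric"
  structure(m, class = c("score_sheet", "matrix", "array"))
}

#' @export
print.score_sheet <- function(x, ...) {
  cat("<score_sheet> ", nrow(x), " indices x ", ncol(x), " subject(s): ",
      paste(colnames(x), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Subjects of a score sheet
#' @param sheet a [score_sheet].
#' @return Character vector of subject identifiers.
#' @export
subjects <- function(sheet) colnames(sheet)

.sheet_sep <- function(path, sep) {
  if (!is.null(sep)) {
    return(switch(sep, comma = ",", tab = "\t", sep))
  }
  if (grepl("\\.tsv$|\\.tab$|\\.txt$", path, ignore.case = TRUE)) "\t"
  else ","
}

#' Read / write score sheets as delimited tables
#'
#' The file layout mirrors the published scoring tables: first column
#' `index` holds the tertiary ids, every further column one subject.
#' Comma and tab dialects are both understood; the delimiter is inferred
#' from the extension (`.csv` vs `.tsv`/`.tab`/`.txt`) unless declared
#' via `sep` (`"comma"`, `"tab"`, or a literal separator).
#'
#' @param path file path.
#' @param sep delimiter override, `NULL` to infer from the extension.
#' @return `read_score_sheet()` returns a [score_sheet];
#'   `write_score_sheet()` returns `path` invisibly.
#' @export
read_score_sheet <- function(path, sep = NULL) {
  if (!file.exists(path))
    stop("score sheet file not found: ", path, call. = FALSE)
  d <- .sheet_sep(path, sep)
  df <- utils::read.table(path, header = TRUE, sep = d,
                          check.names = FALSE, strip.white = TRUE,
                          colClasses = NA, stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop("score sheet '", path, "' needs an 'index' column plus at ",
         "least one subject column", call. = FALSE)
  if (tolower(names(df)[1]) != "index")
    stop("first column of a score sheet must be named 'index', found '",
         names(df)[1], "'", call. = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- ids
  score_sheet(m)
}

#' @rdname read_score_sheet
#' @param sheet a [score_sheet].
#' @export
write_score_sheet <- function(sheet, path, sep = NULL) {
  d <- .sheet_sep(path, sep)
  df <- data.frame(index = rownames(sheet), unclass(sheet),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = d, row.names = FALSE, quote = TRUE)
  invisible(path)
}
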