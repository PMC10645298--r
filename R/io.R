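#' Read a single-column lifetime sample
#'
#' Reads positive-valued lifetimes from a plain-text or CSV file holding
#' one value per line (a single column; an optional header row is skipped
#' when `header = TRUE`).
#'
#' @param path file to read.
#' @param header logical; does the file start with a header line?
#' @return Numeric vector of the parsed values, in file order.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' export_dataset(load_dataset("bearings23"), tf)
#' all.equal(read_lifetimes(tf), load_dataset("bearings23")$values)
#' @export
read_lifetimes <- function(path, header = FALSE) {
  if (!file.exists(path))
    stop("input file not found: ", path, call. = FALSE)
  d <- read.table(path, header = header, sep = "",
                  colClasses = "character", comment.char = "")
  if (ncol(d) != 1L)
    stop("expected a single column in ", path, call. = FALSE)
  v <- suppressWarnings(as.numeric(d[[1]]))
  if (anyNA(v)) {
    bad <- which(is.na(v))[1] + as.integer(header)
    stop("unparseable value at line ", bad, " of ", path, call. = FALSE)
  }
  v
}

#' Export a bundled dataset to a single-column text file
#'
#' @param dataset a `"lifetime_dataset"` from [load_dataset()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
export_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "lifetime_dataset"))
  writeLines(format(dataset$values, trim = TRUE, scientific = FALSE),
             path)
  invisible(path)
}

#' Write a model-comparison table as TSV or JSON
#'
#' @param comparison a `data.frame` from [compare_models()].
#' @param path destination file.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @examples
#' tbl <- compare_models(load_dataset("bearings23")$values)
#' export_comparison(tbl, tempfile(fileext = ".json"), format = "json")
#' @export
export_comparison <- function(comparison, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    write.table(comparison, path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  } else {
    jsonlite::write_json(comparison, path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(path)
}
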