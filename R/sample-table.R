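#' Construct a sample table
#'
#' A sample table holds one record per collected sample: an identifier plus
#' one or more categorical covariates (the biological groups of interest and
#' any confounders that should be balanced across batches). Covariate levels
#' are kept verbatim as strings and compared case-sensitively, so that the
#' strata built from them are reproducible bit for bit.
#'
#' @param data a data.frame with one row per sample.
#' @param id_column name of the column holding unique sample identifiers.
#' @param variables character vector of covariate column names to consider in
#'   the allocation. Defaults to every column except `id_column`.
#' @param na_as_level if `TRUE`, missing covariate values are recoded as the
#'   literal level `"NA"` instead of being rejected.
#' @return an object of class `sample_table`: a data.frame restricted to the
#'   identifier and covariate columns (all character), with attributes
#'   `id_column` and `variables`.
#' @examples
#' x <- data.frame(ID = c("a", "b"), Group = c("case", "control"))
#' st <- sample_table(x, "ID")
#' @export
sample_table <- function(data, id_column = "ID", variables = NULL,
                         na_as_level = FALSE) {
  if (!is.data.frame(data)) stop("`data` must be a data.frame", call. = FALSE)
  if (nrow(data) == 0L)
    stop("sample table is empty: at least one sample record is required",
         call. = FALSE)
  if (is.null(variables))
    variables <- setdiff(names(data), id_column)
  missing_cols <- setdiff(c(id_column, variables), names(data))
  if (length(missing_cols) > 0L)
    stop("column(s) not found in sample data: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (length(variables) == 0L)
    stop("at least one covariate column is required", call. = FALSE)

  ids <- as.character(data[[id_column]])
  if (anyNA(ids) || any(!nzchar(ids)))
    stop("sample identifiers must be non-missing and non-empty", call. = FALSE)
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicated sample identifier(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }

  cols <- list(ids)
  names(cols) <- id_column
  for (v in variables) {
    lev <- as.character(data[[v]])
    bad <- is.na(lev) | !nzchar(lev)
    if (any(bad)) {
      if (!na_as_level)
        stop("missing value(s) in covariate '", v, "' for sample(s): ",
             paste(utils::head(ids[bad], 5L), collapse = ", "),
             "; use na_as_level = TRUE to treat missing as a level",
             call. = FALSE)
      lev[bad] <- "NA"
    }
    cols[[v]] <- lev
  }
  out <- data.frame(cols, stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  structure(out, id_column = id_column, variables = variables,
            class = c("sample_table", "data.frame"))
}

#' Read sample metadata from a CSV file
#'
#' Reads a header-equipped CSV (one row per sample) and validates it into a
#' [sample_table()]. Levels are taken verbatim as strings: a column of `1/2`
#' codes stays the strings `"1"`, `"2"`.
#'
#' @param path path to a CSV file with a header row.
#' @param id_column name of the identifier column.
#' @param variables covariate columns to use; default all non-id columns.
#' @param na_as_level treat missing covariate values as the level `"NA"`.
#' @return a `sample_table`.
#' @export
load_samples <- function(path, id_column = "ID", variables = NULL,
                         na_as_level = FALSE) {
  if (!file.exists(path))
    stop("sample file not found: ", path, call. = FALSE)
  x <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                       fileEncoding = "UTF-8")
  if (nrow(x) == 0L)
    stop("sample file has no data rows: ", path, call. = FALSE)
  sample_table(x, id_column = id_column, variables = variables,
               na_as_level = na_as_level)
}

#' @export
print.sample_table <- function(x, ...) {
  cat("Sample table: ", nrow(x), " samples, ",
      length(attr(x, "variables")), " covariate(s) [",
      paste(attr(x, "variables"), collapse = ", "), "]\n", sep = "")
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("... (", nrow(x) - 6L, " more rows)\n", sep = "")
  invisible(x)
}

sample_ids <- function(samples) as.character(samples[[attr(samples, "id_column")]])
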