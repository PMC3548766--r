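#' Build optimization strata from categorical covariates
#'
#' Crossing the covariates under consideration yields a single unified
#' variable whose levels are the observed combinations of covariate levels;
#' these combinations are the optimization strata over which batch balance is
#' scored. Only combinations that actually occur in the data form strata, so
#' every stratum size is at least one.
#'
#' Stratum order is deterministic: combinations are sorted lexicographically
#' by the declared variable order, then by sorted level strings within each
#' variable — never by order of first appearance.
#'
#' @param samples a [sample_table()].
#' @param variables covariates to cross; defaults to all declared variables.
#' @return an object of class `strata_index`: a list with elements
#'   `variables`, `levels` (data.frame, one row per stratum), `s` (number of
#'   strata), `stratum_of` (integer vector mapping each sample, named by
#'   sample id, to its stratum), and `S` (stratum sizes).
#' @examples
#' x <- data.frame(ID = paste0("s", 1:4),
#'                 g = c("a", "a", "b", "b"), h = c("x", "y", "x", "x"))
#' sx <- build_strata(sample_table(x, "ID"))
#' sx$S
#' @export
build_strata <- function(samples, variables = NULL) {
  stopifnot(inherits(samples, "sample_table"))
  if (is.null(variables)) variables <- attr(samples, "variables")
  if (length(variables) == 0L)
    stop("at least one optimization variable is required", call. = FALSE)
  unknown <- setdiff(variables, attr(samples, "variables"))
  if (length(unknown) > 0L)
    stop("unknown optimization variable(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)

  # key per sample: levels joined in variable declaration order
  cols <- lapply(variables, function(v) samples[[v]])
  key <- do.call(paste, c(cols, sep = "\r"))
  observed <- sort(unique(key), method = "radix")
  j <- match(key, observed)
  names(j) <- sample_ids(samples)

  parts <- strsplit(observed, "\r", fixed = TRUE)
  levels_df <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(levels_df) <- variables

  S <- as.integer(tabulate(j, nbins = length(observed)))
  structure(list(variables = variables, levels = levels_df,
                 s = length(observed), stratum_of = j, S = S),
            class = "strata_index")
}

#' @export
print.strata_index <- function(x, ...) {
  cat("Strata index: ", x$s, " strata over [",
      paste(x$variables, collapse = ", "), "], n = ", sum(x$S), "\n", sep = "")
  df <- cbind(x$levels, S = x$S)
  print(utils::head(df, 10L))
  if (x$s > 10L) cat("... (", x$s - 10L, " more strata)\n", sep = "")
  invisible(x)
}
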