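#' Batch-by-level contingency table for one covariate
#'
#' Tallies, for each batch, how many placed samples carry each level of the
#' given covariate. Empty wells are never counted. All batches appear as
#' rows (including empty ones); [chi_square_test()] drops empty rows before
#' testing.
#'
#' @param assignment an `assignment`.
#' @param samples the [sample_table()] the assignment places.
#' @param variable covariate name.
#' @param container the container the assignment refers to.
#' @return an m x L integer matrix with batch rows and level columns.
#' @export
contingency <- function(assignment, samples, variable, container) {
  if (!variable %in% attr(samples, "variables"))
    stop("unknown variable '", variable, "'; declared variables: ",
         paste(attr(samples, "variables"), collapse = ", "), call. = FALSE)
  ids <- sample_ids(samples)
  lev <- samples[[variable]][match(names(assignment$placement), ids)]
  b <- container$wells$batch[assignment$placement]
  levels_present <- sort(unique(lev), method = "radix")
  tab <- table(factor(b, levels = seq_len(container$m)),
               factor(lev, levels = levels_present))
  mat <- matrix(as.integer(tab), nrow = container$m,
                dimnames = list(batch = seq_len(container$m),
                                level = levels_present))
  mat
}

#' Pearson chi-square test of batch association
#'
#' Tests independence between batch membership and a covariate via the plain
#' Pearson statistic \eqn{\sum (O-E)^2/E} with no continuity correction,
#' using df = (m' - 1)(L - 1) where m' counts batches holding at least one
#' sample and L the levels present. Small expected cell counts (< 5) trigger
#' a warning but the test is still reported.
#'
#' @param table batch x level count matrix, e.g. from [contingency()].
#' @param variable optional covariate name carried into the result.
#' @return an object of class `batch_association`: list with `variable`,
#'   `table`, `chi_square`, `df`, `p_value`.
#' @export
chi_square_test <- function(table, variable = NA_character_) {
  tab <- as.matrix(table)
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]   # drop empty batches
  tab <- tab[, colSums(tab) > 0, drop = FALSE]   # levels present only
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    warning("degenerate table (single batch or single level); ",
            "reporting df = 0, p = 1", call. = FALSE)
    return(structure(list(variable = variable, table = tab,
                          chi_square = 0, df = 0L, p_value = 1),
                     class = "batch_association"))
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5))
    warning("expected cell count(s) below 5; the chi-square approximation ",
            "may be inaccurate", call. = FALSE)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  structure(list(variable = variable, table = tab,
                 chi_square = unname(ct$statistic),
                 df = as.integer(unname(ct$parameter)),
                 p_value = unname(ct$p.value)),
            class = "batch_association")
}

#' @export
print.batch_association <- function(x, ...) {
  cat(if (!is.na(x$variable)) paste0(x$variable, ": "),
      "chi-square = ", signif(x$chi_square, 7L),
      ", df = ", x$df,
      ", p = ", signif(x$p_value, 7L), "\n", sep = "")
  invisible(x)
}

#' Diagnostic report of an assignment
#'
#' For each covariate, builds the batch-by-level count table and the Pearson
#' chi-square test of batch association. Printing the report gives a Table-
#' style summary (DF, chi-square, p-value per variable, 7 significant
#' digits); `plot()` draws grouped barplots of the per-batch counts.
#'
#' @param assignment an `assignment`.
#' @param samples the [sample_table()] placed by the assignment.
#' @param container the container.
#' @param variables covariates to report on; default all declared.
#' @return an object of class `allocation_report`: list of
#'   [chi_square_test()] results, one per variable.
#' @export
diagnose <- function(assignment, samples, container, variables = NULL) {
  if (is.null(variables)) variables <- attr(samples, "variables")
  results <- lapply(variables, function(v)
    chi_square_test(contingency(assignment, samples, v, container),
                    variable = v))
  names(results) <- variables
  structure(list(results = results, V = assignment$V),
            class = "allocation_report")
}

#' @export
print.allocation_report <- function(x, ...) {
  df <- as.data.frame(x)
  cat("Batch association diagnostics (objective V = ", format(x$V), ")\n",
      sep = "")
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.allocation_report <- function(x, ...) {
  data.frame(
    Variable = vapply(x$results, function(r) r$variable, ""),
    DF = vapply(x$results, function(r) as.integer(r$df), 0L),
    Chi.square = vapply(x$results, function(r) signif(r$chi_square, 7L), 0),
    P.value = vapply(x$results, function(r) signif(r$p_value, 7L), 0),
    row.names = NULL
  )
}

#' @export
#' @importFrom graphics barplot legend par
plot.allocation_report <- function(x, ...) {
  nr <- length(x$results)
  old <- par(mfrow = c(1, nr))
  on.exit(par(old))
  for (r in x$results) {
    barplot(t(r$table), beside = TRUE, legend.text = colnames(r$table),
            xlab = "batch", ylab = "samples", main = r$variable, ...)
  }
  invisible(x)
}
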