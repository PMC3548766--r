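#' Write a plate-map sample sheet
#'
#' Emits one row per well in container traversal order — so the CSV reads
#' like the physical plate map — with columns plate, chip, row, column,
#' batch, sample_id and the sample covariates. Wells left empty (spare
#' capacity) appear as blank rows.
#'
#' @param assignment an `assignment`.
#' @param samples the placed [sample_table()].
#' @param container the container.
#' @param path output CSV path.
#' @return the sheet data.frame, invisibly.
#' @export
write_assignment <- function(assignment, samples, container, path) {
  sheet <- container$wells
  sheet$sample_id <- NA_character_
  sheet$sample_id[assignment$placement] <- names(assignment$placement)
  ids <- sample_ids(samples)
  for (v in attr(samples, "variables"))
    sheet[[v]] <- samples[[v]][match(sheet$sample_id, ids)]
  utils::write.csv(sheet, path, row.names = FALSE, na = "")
  invisible(sheet)
}

#' Rebuild an assignment from an emitted sample sheet
#'
#' Reads a CSV written by [write_assignment()] and reconstructs the
#' placement (and, with strata, the count matrix and objective) so an
#' existing allocation can be re-diagnosed.
#'
#' @param path sample-sheet CSV.
#' @param container the container the sheet was written for.
#' @return list with `assignment` (placement only; `n` and `V` unset) and
#'   `samples` (a [sample_table()] rebuilt from the sheet's covariates).
#' @export
read_assignment_sheet <- function(path, container) {
  sheet <- utils::read.csv(path, colClasses = "character",
                           check.names = FALSE)
  need <- c("plate", "chip", "row", "column", "sample_id")
  if (!all(need %in% names(sheet)))
    stop("sample sheet lacks column(s): ",
         paste(setdiff(need, names(sheet)), collapse = ", "), call. = FALSE)
  key <- function(p, c_, r, col) paste(p, c_, r, col, sep = "/")
  well_key <- key(container$wells$plate, container$wells$chip,
                  container$wells$row, container$wells$column)
  filled <- !is.na(sheet$sample_id) & nzchar(sheet$sample_id)
  pos <- match(key(sheet$plate[filled], sheet$chip[filled],
                   sheet$row[filled], sheet$column[filled]), well_key)
  if (anyNA(pos))
    stop("sample sheet refers to wells outside the container", call. = FALSE)
  placement <- pos
  names(placement) <- sheet$sample_id[filled]
  vars <- setdiff(names(sheet), c(need, "batch"))
  samples <- sample_table(
    data.frame(ID = sheet$sample_id[filled],
               sheet[filled, vars, drop = FALSE],
               stringsAsFactors = FALSE, check.names = FALSE),
    id_column = "ID", variables = vars)
  list(assignment = new_assignment(placement, NULL, NA_real_,
                                   meta = list(method = "sheet")),
       samples = samples)
}

#' Run the full allocation pipeline
#'
#' Reads the sample CSV, builds the container, runs the requested
#' allocation method, and writes three artifacts to `output_dir`:
#' `assignment.csv` (the plate-map sample sheet), `diagnostics.csv`
#' (per-variable chi-square tests) plus `counts_<variable>.csv` tables,
#' and `metadata.json` (seed, method, tuning parameters, initial and final
#' objective, package version) — enough to reproduce the run exactly.
#' Nothing is written until the whole computation has succeeded.
#'
#' @param config a named list (or path to a YAML file) with fields `input`
#'   (sample CSV), `id_column`, `variables`, `container` (see
#'   [container_from_config()]), `method` (`"shuffle"`, `"block"` or
#'   `"random"`), `seed`, `output_dir`, and method tuning: `n_attempts`,
#'   `k` (shuffle), `blocking_variables`, `pool_size` (block).
#' @return invisibly, a list with `assignment`, `trace` (if any), `report`.
#' @export
run_allocation <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (f in c("input", "container", "method", "output_dir"))
    if (is.null(config[[f]]))
      stop("run config is missing field '", f, "'", call. = FALSE)
  method <- config$method
  if (!method %in% c("shuffle", "block", "random"))
    stop("unknown method '", method,
         "'; valid methods: shuffle, block, random", call. = FALSE)

  samples <- load_samples(config$input,
                          id_column = config$id_column %||% "ID",
                          variables = config$variables)
  container <- if (inherits(config$container, "container")) config$container
               else container_from_config(config$container)
  seed <- config$seed %||% 1L

  trace <- NULL
  if (method == "shuffle") {
    cfg <- shuffle_config(n_attempts = config$n_attempts %||% 5000L,
                          k = config$k %||% 2L, seed = seed)
    res <- optimal_shuffle(samples, container, cfg)
    assignment <- res$assignment; trace <- res$trace
  } else if (method == "block") {
    if (is.null(config$blocking_variables))
      stop("method 'block' requires field 'blocking_variables'",
           call. = FALSE)
    cfg <- block_pool_config(config$blocking_variables,
                             pool_size = config$pool_size %||% 1000L,
                             seed = seed)
    res <- optimal_block(samples, container, cfg)
    assignment <- res$assignment; trace <- res$trace
  } else {
    assignment <- complete_randomization(samples, container, seed = seed)
  }
  report <- diagnose(assignment, samples, container)

  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  write_assignment(assignment, samples, container,
                   file.path(out, "assignment.csv"))
  utils::write.csv(as.data.frame(report),
                   file.path(out, "diagnostics.csv"), row.names = FALSE)
  for (r in report$results)
    utils::write.csv(as.data.frame.matrix(r$table),
                     file.path(out, paste0("counts_", r$variable, ".csv")))
  meta <- list(method = method, seed = seed,
               n_samples = nrow(samples),
               batches = container$m,
               initial_V = if (!is.null(trace)) trace$initial_V else
                 assignment$V,
               final_V = assignment$V,
               n_attempts = config$n_attempts %||%
                 if (method == "shuffle") 5000L else NULL,
               pool_size = config$pool_size %||%
                 if (method == "block") 1000L else NULL,
               k = if (method == "shuffle") config$k %||% 2L else NULL,
               blocking_variables = config$blocking_variables,
               version = as.character(utils::packageVersion("batchalloc")))
  jsonlite::write_json(meta[!vapply(meta, is.null, TRUE)],
                       file.path(out, "metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(assignment = assignment, trace = trace, report = report))
}
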