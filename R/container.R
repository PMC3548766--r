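#' Plate layout geometry
#'
#' Describes one plate type: how many chips it carries and the grid of wells
#' on each chip. Well traversal order within a chip is column-major by
#' default (down each column, then the next column), matching the scan order
#' of common bead-array platforms.
#'
#' @param name layout name (informational).
#' @param chips_per_plate,chip_rows,chip_columns positive integers.
#' @param well_order `"column-major"` or `"row-major"` traversal within a chip.
#' @return an object of class `plate_layout`.
#' @seealso [predefined_layout()] for registered platform layouts.
#' @export
plate_layout <- function(name, chips_per_plate, chip_rows, chip_columns,
                         well_order = c("column-major", "row-major")) {
  well_order <- match.arg(well_order)
  for (v in c(chips_per_plate, chip_rows, chip_columns))
    if (length(v) != 1L || is.na(v) || v < 1L || v != round(v))
      stop("layout dimensions must be positive integers", call. = FALSE)
  structure(list(name = as.character(name),
                 chips_per_plate = as.integer(chips_per_plate),
                 chip_rows = as.integer(chip_rows),
                 chip_columns = as.integer(chip_columns),
                 well_order = well_order),
            class = "plate_layout")
}

wells_per_plate <- function(layout)
  layout$chips_per_plate * layout$chip_rows * layout$chip_columns

# registry of common platform geometries
.layout_registry <- function() list(
  # bead-array style plate: 8 chips of 6 rows x 2 columns = 96 wells
  "illumina-beadchip-96" = plate_layout("illumina-beadchip-96", 8L, 6L, 2L),
  # generic microtitre plates modeled as a single "chip"
  "plate-96"  = plate_layout("plate-96", 1L, 8L, 12L),
  "plate-384" = plate_layout("plate-384", 1L, 16L, 24L)
)

#' Look up a predefined plate layout
#'
#' @param name registered layout key, e.g. `"illumina-beadchip-96"`.
#' @return the registered [plate_layout()].
#' @export
predefined_layout <- function(name) {
  reg <- .layout_registry()
  if (!name %in% names(reg))
    stop("unknown layout '", name, "'; available layouts: ",
         paste(names(reg), collapse = ", "), call. = FALSE)
  reg[[name]]
}

#' @export
print.plate_layout <- function(x, ...) {
  cat("Plate layout '", x$name, "': ", x$chips_per_plate, " chip(s) x ",
      x$chip_rows, " rows x ", x$chip_columns, " columns = ",
      wells_per_plate(x), " wells/plate (", x$well_order, ")\n", sep = "")
  invisible(x)
}

#' Build the batch container
#'
#' Enumerates every well of `n_plates` plates in a deterministic traversal
#' order (plates in index order, chips in index order within a plate, wells
#' per the layout's `well_order`), removes excluded wells, and groups the
#' usable wells into batches at plate or chip granularity. All coordinates
#' are 1-based.
#'
#' @param layout a [plate_layout()] or the name of a predefined layout.
#' @param n_plates number of plates available.
#' @param batch_level `"plate"` (default) to treat each plate as one batch,
#'   `"chip"` for chip-level batches.
#' @param excluded optional data.frame of wells to leave empty, with columns
#'   `plate`, `chip` and optionally `row`, `column`; omitting row/column
#'   excludes the whole chip.
#' @return an object of class `container`: a list with the usable `wells`
#'   (data.frame of plate/chip/row/column plus a `batch` index), the number
#'   of batches `m`, batch capacities `B`, and the excluded set.
#' @examples
#' cont <- make_container("illumina-beadchip-96", 6)
#' cont$m      # 6 plate-level batches
#' cont$B      # 96 usable wells each
#' @export
make_container <- function(layout, n_plates, batch_level = c("plate", "chip"),
                           excluded = NULL) {
  if (is.character(layout)) layout <- predefined_layout(layout)
  stopifnot(inherits(layout, "plate_layout"))
  batch_level <- match.arg(batch_level)
  if (length(n_plates) != 1L || is.na(n_plates) || n_plates < 1L)
    stop("n_plates must be a positive integer", call. = FALSE)
  n_plates <- as.integer(n_plates)

  # deterministic traversal: plate, chip, then wells within chip
  if (layout$well_order == "column-major") {
    rows <- rep(seq_len(layout$chip_rows), times = layout$chip_columns)
    cols <- rep(seq_len(layout$chip_columns), each = layout$chip_rows)
  } else {
    rows <- rep(seq_len(layout$chip_rows), each = layout$chip_columns)
    cols <- rep(seq_len(layout$chip_columns), times = layout$chip_rows)
  }
  per_chip <- length(rows)
  wells <- data.frame(
    plate  = rep(seq_len(n_plates), each = layout$chips_per_plate * per_chip),
    chip   = rep(rep(seq_len(layout$chips_per_plate), each = per_chip),
                 times = n_plates),
    row    = rep(rows, times = n_plates * layout$chips_per_plate),
    column = rep(cols, times = n_plates * layout$chips_per_plate)
  )

  excl_mask <- rep(FALSE, nrow(wells))
  if (!is.null(excluded) && NROW(excluded) > 0L) {
    excluded <- as.data.frame(excluded)
    if (!all(c("plate", "chip") %in% names(excluded)))
      stop("excluded wells need at least 'plate' and 'chip' columns",
           call. = FALSE)
    has_rc <- all(c("row", "column") %in% names(excluded))
    for (k in seq_len(nrow(excluded))) {
      e <- excluded[k, ]
      whole_chip <- !has_rc || is.na(e$row) || is.na(e$column)
      hit <- wells$plate == e$plate & wells$chip == e$chip
      if (!whole_chip)
        hit <- hit & wells$row == e$row & wells$column == e$column
      if (!any(hit))
        stop("excluded well out of bounds: plate ", e$plate, ", chip ",
             e$chip,
             if (!whole_chip) paste0(", row ", e$row, ", column ", e$column),
             call. = FALSE)
      excl_mask <- excl_mask | hit
    }
  }
  excluded_wells <- wells[excl_mask, , drop = FALSE]
  usable <- wells[!excl_mask, , drop = FALSE]
  rownames(usable) <- NULL

  if (batch_level == "plate") {
    m <- n_plates
    usable$batch <- usable$plate
  } else {
    m <- n_plates * layout$chips_per_plate
    usable$batch <- (usable$plate - 1L) * layout$chips_per_plate + usable$chip
  }
  B <- as.integer(tabulate(usable$batch, nbins = m))
  if (any(B == 0L))
    warning("batch(es) with zero usable wells: ",
            paste(which(B == 0L), collapse = ", "), call. = FALSE)

  structure(list(layout = layout, n_plates = n_plates,
                 batch_level = batch_level, wells = usable,
                 excluded = excluded_wells, m = m, B = B),
            class = "container")
}

#' @export
print.container <- function(x, ...) {
  cat("Container: ", x$n_plates, " plate(s) of layout '", x$layout$name,
      "', batch level = ", x$batch_level, "\n", sep = "")
  cat("  ", x$m, " batch(es); usable wells ", sum(x$B),
      if (nrow(x$excluded) > 0L) paste0(" (", nrow(x$excluded), " excluded)"),
      "\n", sep = "")
  invisible(x)
}

#' Build a container from a YAML or JSON config
#'
#' The config supplies `layout` (either a predefined `name`, or `custom` with
#' `name`, `chips_per_plate`, `chip_rows`, `chip_columns` and optional
#' `well_order`), `n_plates`, optional `batch_level`, and an optional list of
#' `excluded` wells, each with `plate`, `chip` and optional `row`/`column`
#' (whole chips may be excluded by omitting row/column).
#'
#' @param config path to a YAML/JSON file, or an equivalent named list.
#' @return a [make_container()] container.
#' @export
container_from_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$layout))
    stop("container config needs a 'layout' entry", call. = FALSE)
  lay <- config$layout
  layout <- if (!is.null(lay$custom)) {
    cu <- lay$custom
    plate_layout(cu$name %||% "custom", cu$chips_per_plate, cu$chip_rows,
                 cu$chip_columns, cu$well_order %||% "column-major")
  } else if (!is.null(lay$name)) {
    predefined_layout(lay$name)
  } else if (is.character(lay)) {
    predefined_layout(lay)
  } else stop("layout config needs 'name' or 'custom'", call. = FALSE)
  excl <- NULL
  if (!is.null(config$excluded) && length(config$excluded) > 0L) {
    excl <- do.call(rbind, lapply(config$excluded, function(e)
      data.frame(plate = e$plate, chip = e$chip,
                 row = e$row %||% NA_integer_,
                 column = e$column %||% NA_integer_)))
  }
  make_container(layout, config$n_plates,
                 batch_level = config$batch_level %||% "plate",
                 excluded = excl)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
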