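#' @importFrom rlang .data %||% abort
#' @importFrom dplyr filter mutate group_by summarise ungroup arrange select
#'   left_join bind_rows distinct n across all_of
#' @importFrom tibble tibble as_tibble
NULL

# Condition tokens accepted in measurement tables. MONOCULTURE/COCULTURE are
# the physical co-culture screen arms; CM/TSM the conditioned-media secondary
# arms; BACKGROUND wells carry reagent-only absorbance.
CONDITIONS <- c("MONOCULTURE", "COCULTURE", "CM", "TSM", "BACKGROUND")
READOUT_KINDS <- c("BLI", "ABSORBANCE")

#' Sentinel compound id for solvent-only control wells
#' @export
VEHICLE <- "VEHICLE"

MEASUREMENT_COLS <- c("plate_id", "well_id", "condition", "compound_id",
                      "dose_uM", "replicate", "readout", "readout_kind")

#' Convert a well identifier to zero-based (row, col) indices
#'
#' Well identifiers follow the standard microplate convention: a row letter
#' (A-H for a 96-well plate) followed by a 1-based column number (1-12).
#' Parsing is case-insensitive.
#'
#' @param well_id Character vector of well ids, e.g. `"A1"`, `"h12"`.
#' @param nrow,ncol Plate dimensions; default 8 x 12 (96-well).
#' @return A tibble with columns `well_id` (normalized to upper case),
#'   `row` and `col` (both 0-based).
#' @export
#' @examples
#' parse_well_id(c("A1", "h12"))
parse_well_id <- function(well_id, nrow = 8L, ncol = 12L) {
  wid <- toupper(trimws(as.character(well_id)))
  ok <- grepl("^[A-Z][0-9]+$", wid)
  if (any(!ok)) {
    abort(paste0("malformed well id(s): ",
                 paste(unique(well_id[!ok]), collapse = ", ")))
  }
  row <- match(substr(wid, 1, 1), LETTERS) - 1L
  col <- as.integer(substring(wid, 2)) - 1L
  bad <- row >= nrow | col < 0L | col >= ncol
  if (any(bad)) {
    abort(paste0("well id(s) outside a ", nrow, "x", ncol, " plate: ",
                 paste(unique(wid[bad]), collapse = ", ")))
  }
  tibble(well_id = wid, row = row, col = col)
}

#' Build a well identifier from zero-based (row, col) indices
#'
#' @param row,col 0-based indices.
#' @param nrow,ncol Plate dimensions; default 96-well.
#' @return Character vector of well ids (upper case).
#' @export
make_well_id <- function(row, col, nrow = 8L, ncol = 12L) {
  if (any(row < 0L | row >= nrow | col < 0L | col >= ncol)) {
    abort("row/col indices outside plate dimensions")
  }
  paste0(LETTERS[row + 1L], col + 1L)
}

#' Read a long-format well-measurement table
#'
#' Reads a CSV with one row per well measurement (columns `plate_id`,
#' `well_id`, `condition`, `compound_id`, `dose_uM`, `replicate`, `readout`,
#' `readout_kind`) and validates it: conditions must be one of MONOCULTURE,
#' COCULTURE, CM, TSM or BACKGROUND; readouts must be non-negative; vehicle
#' wells must have dose 0; background wells carry no compound.
#'
#' @param path Path to a CSV file.
#' @param readout_kind Optional; if given ("BLI" or "ABSORBANCE") every row
#'   must carry that readout kind.
#' @return A tibble of validated well measurements.
#' @export
read_measurements <- function(path, readout_kind = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  missing <- setdiff(MEASUREMENT_COLS, names(raw))
  if (length(missing) > 0) {
    abort(paste0("measurement table is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  m <- tibble(
    plate_id = raw$plate_id,
    well_id = toupper(trimws(raw$well_id)),
    condition = toupper(trimws(raw$condition)),
    compound_id = raw$compound_id,
    dose_uM = suppressWarnings(as.numeric(raw$dose_uM)),
    replicate = suppressWarnings(as.integer(raw$replicate)),
    readout = suppressWarnings(as.numeric(raw$readout)),
    readout_kind = toupper(trimws(raw$readout_kind))
  )
  validate_measurements(m, readout_kind = readout_kind)
}

#' Validate an in-memory measurement table
#'
#' Same contract as [read_measurements()] for tables built in code.
#'
#' @param m A data frame with the measurement columns.
#' @param readout_kind Optional required readout kind.
#' @return The validated tibble (invisibly unchanged).
#' @export
validate_measurements <- function(m, readout_kind = NULL) {
  m <- as_tibble(m)
  missing <- setdiff(MEASUREMENT_COLS, names(m))
  if (length(missing) > 0) {
    abort(paste0("measurement table is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  bad_cond <- unique(m$condition[!m$condition %in% CONDITIONS])
  if (length(bad_cond) > 0) {
    abort(paste0("unknown condition token(s): ",
                 paste(bad_cond, collapse = ", ")))
  }
  bad_kind <- unique(m$readout_kind[!m$readout_kind %in% READOUT_KINDS])
  if (length(bad_kind) > 0) {
    abort(paste0("unknown readout kind(s): ", paste(bad_kind, collapse = ", ")))
  }
  if (!is.null(readout_kind)) {
    readout_kind <- match.arg(toupper(readout_kind), READOUT_KINDS)
    if (any(m$readout_kind != readout_kind)) {
      abort(paste0("expected readout_kind ", readout_kind, " throughout"))
    }
  }
  if (any(is.na(m$readout))) {
    abort(paste0("non-numeric readout in well(s): ",
                 paste(head(m$well_id[is.na(m$readout)], 5), collapse = ", ")))
  }
  neg <- m$readout < 0
  if (any(neg)) {
    abort(paste0("negative readout in well(s): ",
                 paste(unique(m$well_id[neg]), collapse = ", ")))
  }
  if (any(is.na(m$dose_uM) | m$dose_uM < 0)) {
    bad <- is.na(m$dose_uM) | m$dose_uM < 0
    abort(paste0("missing or negative dose in well(s): ",
                 paste(unique(m$well_id[bad]), collapse = ", ")))
  }
  veh_bad <- m$compound_id == VEHICLE & m$dose_uM != 0
  if (any(veh_bad, na.rm = TRUE)) {
    abort(paste0("vehicle wells must have dose 0; offending well(s): ",
                 paste(unique(m$well_id[veh_bad]), collapse = ", ")))
  }
  bg_bad <- m$condition == "BACKGROUND" & !is.na(m$compound_id) &
    m$compound_id != "" & m$compound_id != "NONE"
  if (any(bg_bad)) {
    abort(paste0("background wells must not carry a compound; well(s): ",
                 paste(unique(m$well_id[bg_bad]), collapse = ", ")))
  }
  # well ids must parse for the default plate geometry
  parse_well_id(unique(m$well_id))
  m
}

#' Read a compound annotation table
#'
#' Columns: `compound_id`, `name`, `annotation`, `screen_dose_uM`.
#'
#' @param path Path to a CSV file.
#' @return A tibble, one row per compound.
#' @export
read_compounds <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  x <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("compound_id", "name", "annotation", "screen_dose_uM")
  missing <- setdiff(need, names(x))
  if (length(missing) > 0) {
    abort(paste0("compound table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(x$compound_id)) {
    abort("compound_id values must be unique within a library")
  }
  as_tibble(x)
}

#' Check that every plate has vehicle controls for each condition it contains
#'
#' Plate-local vehicle (DMSO) wells define the no-drug baseline used for all
#' normalization, so a plate missing them cannot be analyzed. The report
#' flags, per plate and experimental condition, whether at least one vehicle
#' well is present (background wells are exempt). Downstream operations
#' refuse flagged plates.
#'
#' @param measurements A measurement tibble (see [read_measurements()]).
#' @return A tibble with columns `plate_id`, `condition`, `n_vehicle`, `ok`;
#'   attribute `"pass"` is TRUE when no plate is flagged.
#' @export
validate_plate_controls <- function(measurements) {
  m <- as_tibble(measurements)
  rep <- m |>
    filter(.data$condition != "BACKGROUND") |>
    group_by(.data$plate_id, .data$condition) |>
    summarise(n_vehicle = sum(.data$compound_id == VEHICLE), .groups = "drop") |>
    mutate(ok = .data$n_vehicle >= 1L) |>
    arrange(.data$plate_id, .data$condition)
  attr(rep, "pass") <- all(rep$ok)
  rep
}

#' Write a result table to CSV
#'
#' Column order is preserved; numeric values are written with enough digits
#' to round-trip (15 significant digits).
#'
#' @param results A non-empty data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_results <- function(results, path) {
  if (is.null(results) || nrow(as.data.frame(results)) == 0) {
    abort("refusing to write an empty result table")
  }
  out <- as_tibble(results)
  # format reals explicitly so read-back agrees to >= 12 significant digits
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], \(x) formatC(x, digits = 15, format = "g"))
  readr::write_csv(out, path)
  invisible(path)
}

#' Read a result table written by [write_results()]
#'
#' @param path Path to a CSV file.
#' @return A tibble with numeric columns restored.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  x <- readr::read_csv(path, show_col_types = FALSE, guess_max = 100000)
  as_tibble(x)
}
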