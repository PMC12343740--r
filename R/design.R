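#' Design constants for a vial emergence experiment
#'
#' Bundles the fixed quantities of a single-generation host--parasitoid
#' emergence experiment: eggs seeded per vial (`H0`), the day emergence is
#' totalled (`T`), the number of foraging female wasps (`P`), the day wasps
#' are introduced, the calendar day of each heat-timing level, and the
#' replicate count per treatment cell. Defaults reproduce the standard
#' design: 50 eggs, emergence totalled at day 8, 3 female wasps introduced
#' on day 3, heat on day 1 ("before"), 3 ("during") or 7 ("after"), six
#' replicates.
#'
#' @param eggs_per_vial Number of host eggs seeded per vial (H0).
#' @param end_day Day at which emergence is totalled (T).
#' @param wasp_count Number of foraging female parasitoids per vial (P).
#' @param attack_day Day the parasitoids are introduced.
#' @param heat_days Named numeric vector mapping each heat-timing level to
#'   the day its 24-h exposure starts. The ambient (no heat) level is
#'   implicit and carries no day.
#' @param replicates_per_cell Replicate vials per treatment combination.
#'
#' @return An object of class `design_constants` (a named list).
#' @examples
#' const <- design_constants()
#' const$eggs_per_vial
#' @export
design_constants <- function(eggs_per_vial = 50,
                             end_day = 8,
                             wasp_count = 3,
                             attack_day = 3,
                             heat_days = c(before = 1, during = 3, after = 7),
                             replicates_per_cell = 6) {
  if (!is_count_vector(eggs_per_vial) || eggs_per_vial <= 0) {
    abort_validation("`eggs_per_vial` must be a positive integer.")
  }
  if (!is_count_vector(wasp_count)) {
    abort_validation("`wasp_count` must be a non-negative integer.")
  }
  if (!is.numeric(end_day) || end_day <= 0) {
    abort_validation("`end_day` must be positive.")
  }
  if (!is.numeric(attack_day) || attack_day <= 0 || attack_day >= end_day) {
    abort_validation("`attack_day` must satisfy 0 < attack_day < end_day.")
  }
  if (length(heat_days) > 0) {
    if (is.null(names(heat_days)) || anyDuplicated(names(heat_days)) ||
        any(!nzchar(names(heat_days)))) {
      abort_validation("`heat_days` must map each timing level to exactly one day.")
    }
    if (!is.numeric(heat_days) || any(heat_days < 1) || any(heat_days > end_day)) {
      abort_validation("`heat_days` entries must be days within [1, end_day].")
    }
  }
  if (!is_count_vector(replicates_per_cell) || replicates_per_cell <= 0) {
    abort_validation("`replicates_per_cell` must be a positive integer.")
  }
  structure(
    list(
      eggs_per_vial = as.integer(eggs_per_vial),
      end_day = as.numeric(end_day),
      wasp_count = as.integer(wasp_count),
      attack_day = as.numeric(attack_day),
      heat_days = heat_days,
      replicates_per_cell = as.integer(replicates_per_cell)
    ),
    class = "design_constants"
  )
}

#' @export
print.design_constants <- function(x, ...) {
  cat("<design_constants>\n")
  cat("  eggs per vial (H0):   ", x$eggs_per_vial, "\n")
  cat("  end day (T):          ", x$end_day, "\n")
  cat("  female wasps (P):     ", x$wasp_count, "\n")
  cat("  attack day:           ", x$attack_day, "\n")
  cat("  heat days:            ",
      paste(names(x$heat_days), x$heat_days, sep = "=", collapse = ", "), "\n")
  cat("  replicates per cell:  ", x$replicates_per_cell, "\n")
  invisible(x)
}

#' Read design constants from a JSON or YAML file
#'
#' The file holds a flat mapping with any subset of the `design_constants()`
#' argument names; absent keys keep their defaults. `heat_days` is a nested
#' mapping from timing level to day.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A `design_constants` object.
#' @export
read_design_constants <- function(path) {
  if (!file.exists(path)) {
    abort_validation(paste0("Constants file not found: ", path))
  }
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(design_constants))
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0) {
    abort_validation(paste0("Unknown design constant keys: ", comma(extra)))
  }
  if (!is.null(raw$heat_days)) raw$heat_days <- unlist(raw$heat_days)
  do.call(design_constants, raw)
}

#' Enumerate the fully crossed treatment design
#'
#' Forms the Cartesian product of host species, parasitoid treatment and
#' heat-timing levels, in deterministic order: host varies slowest, then
#' parasitoid, then timing. The default levels reproduce the standard
#' 3 x 4 x 4 = 48-cell design (three Drosophila hosts; three parasitoid
#' species plus a no-parasitoid control; ambient plus three heat timings).
#'
#' @param host_levels Character vector of host species labels.
#' @param parasitoid_levels Character vector of parasitoid treatment labels;
#'   use `"none"` for the no-parasitoid control.
#' @param timing_levels Character vector of heat-timing labels; use
#'   `"ambient"` for the no-heat control.
#'
#' @return A tibble with columns `host`, `parasitoid`, `heat_timing`, one
#'   row per treatment cell.
#' @examples
#' nrow(enumerate_design()) # 48
#' @export
enumerate_design <- function(host_levels = c("birchii", "bipectinata", "simulans"),
                             parasitoid_levels = c("none", "asobara", "ganaspis", "leptopilina"),
                             timing_levels = c("ambient", "before", "during", "after")) {
  for (nm in c("host_levels", "parasitoid_levels", "timing_levels")) {
    lv <- get(nm)
    if (length(lv) == 0) abort_validation(paste0("`", nm, "` must be non-empty."))
    if (anyDuplicated(lv)) {
      abort_validation(paste0("`", nm, "` contains duplicate labels: ",
                              comma(unique(lv[duplicated(lv)]))))
    }
  }
  expand_grid(host = host_levels, parasitoid = parasitoid_levels,
              heat_timing = timing_levels)
}

vial_columns <- c("host", "parasitoid", "heat_timing", "replicate",
                  "eggs", "flies", "wasps")

#' Validate a vial-level emergence count table
#'
#' Checks the structural invariants of a vial table: all canonical columns
#' present, counts are non-negative integers, emerged flies plus wasps never
#' exceed the eggs seeded, and no wasps emerge from no-parasitoid controls.
#' Violations are reported with their row numbers.
#'
#' @param vials Data frame with columns `host`, `parasitoid`, `heat_timing`,
#'   `replicate`, `eggs`, `flies`, `wasps`.
#' @return The input, invisibly, as a tibble.
#' @export
validate_vials <- function(vials) {
  missing_cols <- setdiff(vial_columns, names(vials))
  if (length(missing_cols) > 0) {
    abort_validation(paste0("Vial table is missing columns: ", comma(missing_cols)))
  }
  vials <- as_tibble(vials)
  for (col in c("eggs", "flies", "wasps")) {
    x <- vials[[col]]
    bad <- which(!is.finite(x) | x < 0 | x != floor(x))
    if (length(bad) > 0) {
      abort_validation(paste0(
        "Column `", col, "` must hold non-negative integer counts; ",
        "invalid in row(s): ", comma(head(bad, 10))))
    }
  }
  over <- which(vials$flies + vials$wasps > vials$eggs)
  if (length(over) > 0) {
    abort_validation(paste0(
      "flies + wasps exceeds eggs in row(s): ", comma(head(over, 10))))
  }
  stray <- which(vials$parasitoid == "none" & vials$wasps > 0)
  if (length(stray) > 0) {
    abort_validation(paste0(
      "Wasps recorded in no-parasitoid vials in row(s): ", comma(head(stray, 10))))
  }
  invisible(vials)
}

#' Read a vial count table from CSV
#'
#' Reads the canonical vial CSV (`host,parasitoid,heat_timing,replicate,`
#' `eggs,flies,wasps`), validates every row and preserves row order. A file
#' holding only the header yields an empty tibble with a warning.
#'
#' @param path Path to a CSV file.
#' @return A validated tibble of vial records.
#' @export
read_vials <- function(path) {
  if (!file.exists(path)) {
    abort_validation(paste0("Vial file not found: ", path))
  }
  # a missing column is reported below as a validation error, not as
  # readr's spec-mismatch warning
  vials <- suppressWarnings(readr::read_csv(
    path,
    col_types = readr::cols(
      host = readr::col_character(),
      parasitoid = readr::col_character(),
      heat_timing = readr::col_character(),
      replicate = readr::col_character(),
      eggs = readr::col_double(),
      flies = readr::col_double(),
      wasps = readr::col_double()
    ),
    progress = FALSE
  ))
  missing_cols <- setdiff(vial_columns, names(vials))
  if (length(missing_cols) > 0) {
    abort_validation(paste0("Vial CSV is missing columns: ", comma(missing_cols)))
  }
  vials <- select(vials, all_of(vial_columns))
  if (nrow(vials) == 0) {
    warn("Vial file contains a header but no records.")
    return(vials)
  }
  validate_vials(vials)
  vials
}

#' Write a vial count table to CSV
#'
#' Validates the records, then writes the canonical CSV so that
#' `read_vials(write_vials(x, path))` returns `x` field-for-field.
#'
#' @param vials A vial tibble (see [validate_vials()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_vials <- function(vials, path) {
  if (nrow(vials) > 0) validate_vials(vials)
  missing_cols <- setdiff(vial_columns, names(vials))
  if (length(missing_cols) > 0) {
    abort_validation(paste0("Vial table is missing columns: ", comma(missing_cols)))
  }
  out <- select(as_tibble(vials), all_of(vial_columns))
  out <- mutate(out, across(all_of(c("eggs", "flies", "wasps")), as.integer))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
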