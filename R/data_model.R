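#' Sorption datasets
#'
#' A sorption dataset is a data frame with one row per equilibrium point and
#' columns `branch` ("adsorption" or "desorption"), `T` (temperature, Kelvin),
#' `aw` (water activity, dimensionless in `[0, 1)`) and `xe` (equilibrium
#' moisture content, g water / g dry matter). Replicate observations at the
#' same `(branch, T, aw)` are kept as separate rows, mirroring duplicate
#' instrument runs.
#'
#' @param branch character vector, each "adsorption" or "desorption"
#' @param temperature numeric temperatures
#' @param aw numeric water activities in `[0, 1)`
#' @param xe numeric equilibrium moisture contents (g/g dry basis, `>= 0`)
#' @param temperature_unit `"C"` or `"K"`; temperatures are stored in Kelvin
#' @param label free-text label attached to the dataset
#' @return an object of class `sorption_dataset` (a data frame)
#' @export
#' @examples
#' sorption_dataset("adsorption", 25, 0.5, 0.015, temperature_unit = "C")
sorption_dataset <- function(branch, temperature, aw, xe,
                             temperature_unit = c("K", "C"),
                             label = "") {
  temperature_unit <- match.arg(temperature_unit)
  n <- length(aw)
  branch <- rep_len(as.character(branch), n)
  temperature <- rep_len(as.numeric(temperature), n)
  T_K <- if (temperature_unit == "C") celsius_to_kelvin(temperature) else temperature
  ds <- data.frame(
    branch = branch, T = T_K, aw = as.numeric(aw), xe = as.numeric(xe),
    stringsAsFactors = FALSE
  )
  class(ds) <- c("sorption_dataset", "data.frame")
  attr(ds, "label") <- label
  validate_sorption_dataset(ds)
  ds
}

#' Validate a sorption dataset
#'
#' Checks branch values, water-activity bounds, non-negative moisture and
#' positive absolute temperature; errors name the offending row.
#'
#' @param ds a `sorption_dataset`
#' @return `ds`, invisibly, if valid
#' @export
validate_sorption_dataset <- function(ds) {
  req <- c("branch", "T", "aw", "xe")
  missing_cols <- setdiff(req, names(ds))
  if (length(missing_cols) > 0) {
    st_stop("sorptherm_format_error", "missing column(s): %s",
            paste(missing_cols, collapse = ", "))
  }
  bad <- which(!ds$branch %in% c("adsorption", "desorption"))
  if (length(bad) > 0) {
    st_stop("sorptherm_validation_error",
            "row %d: branch must be 'adsorption' or 'desorption' (got '%s')",
            bad[1], ds$branch[bad[1]])
  }
  bad <- which(!is.finite(ds$aw) | ds$aw < 0 | ds$aw >= 1)
  if (length(bad) > 0) {
    st_stop("sorptherm_validation_error",
            "row %d: aw must satisfy 0 <= aw < 1 (got %s)", bad[1],
            format(ds$aw[bad[1]]))
  }
  bad <- which(!is.finite(ds$xe) | ds$xe < 0)
  if (length(bad) > 0) {
    st_stop("sorptherm_validation_error",
            "row %d: xe must be >= 0 (got %s)", bad[1], format(ds$xe[bad[1]]))
  }
  bad <- which(!is.finite(ds$T) | ds$T <= 0)
  if (length(bad) > 0) {
    st_stop("sorptherm_validation_error",
            "row %d: temperature must be > 0 K (got %s)", bad[1],
            format(ds$T[bad[1]]))
  }
  invisible(ds)
}

#' Read a sorption CSV file
#'
#' Expected header: `branch,temperature,aw,xe`. Lines starting with `#` are
#' comments. Temperatures are converted to Kelvin on read.
#'
#' @param path path to a CSV file
#' @param temperature_unit unit of the `temperature` column, `"C"` or `"K"`
#' @return a `sorption_dataset`
#' @export
read_sorption_csv <- function(path, temperature_unit = c("C", "K")) {
  temperature_unit <- match.arg(temperature_unit)
  if (!file.exists(path)) {
    st_stop("sorptherm_format_error", "file not found: %s", path)
  }
  raw <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  req <- c("branch", "temperature", "aw", "xe")
  missing_cols <- setdiff(req, names(raw))
  if (length(missing_cols) > 0) {
    st_stop("sorptherm_format_error", "%s: missing column(s): %s", path,
            paste(missing_cols, collapse = ", "))
  }
  for (col in c("temperature", "aw", "xe")) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]))
    if (length(bad) > 0) {
      st_stop("sorptherm_format_error",
              "%s: row %d: column '%s' is not numeric ('%s')",
              path, bad[1], col, raw[[col]][bad[1]])
    }
    raw[[col]] <- v
  }
  sorption_dataset(raw$branch, raw$temperature, raw$aw, raw$xe,
                   temperature_unit = temperature_unit,
                   label = basename(path))
}

#' Write a sorption dataset to CSV
#'
#' Writes the `branch,temperature,aw,xe` layout read by [read_sorption_csv()].
#' Numeric fields keep 15 significant digits so a write/read round trip is
#' lossless well past 12 significant digits.
#'
#' @param ds a `sorption_dataset`
#' @param path output path
#' @param temperature_unit unit for the written `temperature` column
#' @return `path`, invisibly
#' @export
write_sorption_csv <- function(ds, path, temperature_unit = c("C", "K")) {
  temperature_unit <- match.arg(temperature_unit)
  validate_sorption_dataset(ds)
  temp <- if (temperature_unit == "C") kelvin_to_celsius(ds$T) else ds$T
  out <- data.frame(
    branch = ds$branch,
    temperature = format(temp, digits = 15, trim = TRUE, scientific = FALSE),
    aw = format(ds$aw, digits = 15, trim = TRUE),
    xe = format(ds$xe, digits = 15, trim = TRUE),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Split a sorption dataset into (branch, temperature) groups
#'
#' @param ds a `sorption_dataset`
#' @return a named list of `sorption_dataset` slices; names are
#'   `"<branch>@<T>K"`
#' @export
sorption_groups <- function(ds) {
  validate_sorption_dataset(ds)
  key <- paste0(ds$branch, "@", format(ds$T, digits = 10, trim = TRUE), "K")
  out <- split(as.data.frame(ds), key)
  lapply(out, function(g) {
    class(g) <- c("sorption_dataset", "data.frame")
    g
  })
}

#' Extract one (branch, temperature) slice
#'
#' @param ds a `sorption_dataset`
#' @param branch `"adsorption"` or `"desorption"`
#' @param T_K temperature in Kelvin (matched within 1e-6 K)
#' @return a `sorption_dataset` slice
#' @export
sorption_group <- function(ds, branch, T_K) {
  sel <- ds$branch == branch & abs(ds$T - T_K) < 1e-6
  if (!any(sel)) {
    st_stop("sorptherm_validation_error",
            "no points for branch '%s' at T = %s K", branch, format(T_K))
  }
  g <- as.data.frame(ds)[sel, , drop = FALSE]
  class(g) <- c("sorption_dataset", "data.frame")
  g
}

#' Temperatures present in a dataset
#' @param ds a `sorption_dataset`
#' @param branch optional branch filter
#' @return sorted unique temperatures (K)
#' @export
sorption_temperatures <- function(ds, branch = NULL) {
  if (!is.null(branch)) ds <- ds[ds$branch == branch, , drop = FALSE]
  sort(unique(round(ds$T, 6)))
}

#' Convert dry-basis moisture to wet-basis water mass fraction
#'
#' Dry-basis moisture `x_db` (g water / g dry matter) relates to the wet-basis
#' mass fraction `xw` (g water / g total) by `xw = x_db / (1 + x_db)`;
#' [wet_to_db_fraction()] is the inverse.
#'
#' @param x_db dry-basis moisture content(s), `>= 0`
#' @return water mass fraction(s) in `[0, 1)`
#' @export
#' @examples
#' db_to_wet_fraction(0.08)         # 0.0740740...
#' wet_to_db_fraction(db_to_wet_fraction(0.08))
db_to_wet_fraction <- function(x_db) {
  if (any(!is.finite(x_db) | x_db < 0)) {
    st_stop("sorptherm_validation_error", "dry-basis moisture must be >= 0")
  }
  x_db / (1 + x_db)
}

#' @rdname db_to_wet_fraction
#' @param xw wet-basis water mass fraction(s) in `[0, 1)`
#' @export
wet_to_db_fraction <- function(xw) {
  if (any(!is.finite(xw) | xw < 0 | xw >= 1)) {
    st_stop("sorptherm_validation_error",
            "water mass fraction must be in [0, 1)")
  }
  xw / (1 - xw)
}

#' Read a glass-transition CSV file
#'
#' Expected header: `xw,tg_c` — wet-basis water mass fraction and
#' glass-transition midpoint temperature in degrees Celsius. Lines starting
#' with `#` are comments. A `# basis: dry` comment line declares that the
#' `xw` column is dry-basis moisture (g/g); it is then converted to a wet
#' mass fraction on read.
#'
#' @param path path to a CSV file
#' @return a data frame of class `tg_dataset` with columns `xw`, `tg_c`
#' @export
read_tg_csv <- function(path) {
  if (!file.exists(path)) {
    st_stop("sorptherm_format_error", "file not found: %s", path)
  }
  lines <- readLines(path)
  dry_basis <- any(grepl("^#\\s*basis:\\s*dry", lines))
  raw <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("xw", "tg_c") %in% names(raw))) {
    st_stop("sorptherm_format_error", "%s: expected columns xw, tg_c", path)
  }
  xw <- as.numeric(raw$xw)
  if (dry_basis) xw <- db_to_wet_fraction(xw)
  bad <- which(!is.finite(xw) | xw < 0 | xw > 1)
  if (length(bad) > 0) {
    st_stop("sorptherm_validation_error",
            "%s: row %d: xw must be in [0, 1]", path, bad[1])
  }
  out <- data.frame(xw = xw, tg_c = as.numeric(raw$tg_c))
  class(out) <- c("tg_dataset", "data.frame")
  out
}

#' Write a glass-transition dataset to CSV
#' @param tg a data frame with columns `xw`, `tg_c`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_tg_csv <- function(tg, path) {
  out <- data.frame(
    xw = format(tg$xw, digits = 15, trim = TRUE),
    tg_c = format(tg$tg_c, digits = 15, trim = TRUE)
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
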