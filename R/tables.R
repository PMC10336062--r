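.SURVIVAL_COLS <- c("cell_line", "modality_1", "dose_1_Gy", "modality_2",
                    "dose_2_Gy", "interval_min", "delivery_min_1",
                    "delivery_min_2", "replicate", "surviving_fraction")

.FOCI_COLS <- c("cell_line", "modality", "dose_Gy", "time_h", "mean_foci",
                "sd_foci", "n_cells")

.validate_survival <- function(df) {
  for (i in seq_len(nrow(df))) {
    sf <- df$surviving_fraction[i]
    if (!is.finite(sf) || sf <= 0 || sf > 1)
      stop("row ", i, ": surviving_fraction must lie in (0, 1], got ", sf)
    if (df$dose_1_Gy[i] < 0 || df$dose_2_Gy[i] < 0)
      stop("row ", i, ": doses must be non-negative")
    if (df$interval_min[i] < 0)
      stop("row ", i, ": interval_min must be non-negative")
    if (is.na(df$modality_2[i]) || df$modality_2[i] == "") {
      if (df$dose_2_Gy[i] != 0 || df$interval_min[i] != 0)
        stop("row ", i, ": single-fraction rows must have dose_2_Gy = 0 ",
             "and interval_min = 0")
    }
  }
  invisible(df)
}

.validate_foci <- function(df) {
  for (i in seq_len(nrow(df))) {
    if (!is.finite(df$mean_foci[i]) || df$mean_foci[i] < 0)
      stop("row ", i, ": mean_foci must be non-negative")
    if (df$dose_Gy[i] <= 0) stop("row ", i, ": dose_Gy must be positive")
    if (df$time_h[i] < 0) stop("row ", i, ": time_h must be non-negative")
    if (df$sd_foci[i] < 0) stop("row ", i, ": sd_foci must be non-negative")
    if (df$n_cells[i] < 1 || df$n_cells[i] != round(df$n_cells[i]))
      stop("row ", i, ": n_cells must be a positive integer")
  }
  invisible(df)
}

.read_table <- function(path, cols, numeric_cols) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0)
    stop("missing column(s): ", paste(missing, collapse = ", "))
  df <- df[cols]
  for (k in numeric_cols) {
    v <- suppressWarnings(as.numeric(df[[k]]))
    if (nrow(df) > 0 && anyNA(v))
      stop("column '", k, "' contains non-numeric values")
    df[[k]] <- v
  }
  tibble::as_tibble(df)
}

#' Read a clonogenic-survival table
#'
#' Reads the CSV interchange format for survival data. One row is one
#' replicate measurement of one exposure: a single fraction
#' (`modality_2` empty, `dose_2_Gy = 0`, `interval_min = 0`) or a
#' two-fraction schedule with the stated inter-fraction interval. Doses are
#' in Gy, times in minutes. Every row is validated: surviving fractions must
#' lie in (0, 1].
#'
#' @param path CSV path with header
#'   `cell_line,modality_1,dose_1_Gy,modality_2,dose_2_Gy,interval_min,delivery_min_1,delivery_min_2,replicate,surviving_fraction`
#' @return a tibble with one validated row per record, in file order
#' @export
read_survival_table <- function(path) {
  num <- c("dose_1_Gy", "dose_2_Gy", "interval_min", "delivery_min_1",
           "delivery_min_2", "replicate", "surviving_fraction")
  df <- .read_table(path, .SURVIVAL_COLS, num)
  .validate_survival(df)
  df
}

#' Write a clonogenic-survival table
#'
#' Deterministic column order; floats are written with 15 significant digits
#' so a write/read round-trip is lossless at double precision.
#'
#' @param records a survival tibble (see [read_survival_table()])
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_survival_table <- function(records, path) {
  .validate_survival(records)
  .write_table(records[.SURVIVAL_COLS], path)
}

#' Read a foci time-course table
#'
#' One row per (condition, time point, experiment): mean background-corrected
#' foci per cell across `n_cells` scored cells, with the per-cell standard
#' deviation. Times are in hours.
#'
#' @param path CSV path with header
#'   `cell_line,modality,dose_Gy,time_h,mean_foci,sd_foci,n_cells`
#' @return a validated tibble in file order
#' @export
read_foci_table <- function(path) {
  num <- c("dose_Gy", "time_h", "mean_foci", "sd_foci", "n_cells")
  df <- .read_table(path, .FOCI_COLS, num)
  .validate_foci(df)
  df
}

#' Write a foci time-course table
#'
#' @param records a foci tibble (see [read_foci_table()])
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_foci_table <- function(records, path) {
  .validate_foci(records)
  .write_table(records[.FOCI_COLS], path)
}

.write_table <- function(df, path) {
  out <- df
  for (k in names(out)) {
    if (is.numeric(out[[k]])) out[[k]] <- sprintf("%.15g", out[[k]])
  }
  tryCatch(
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE),
    error = function(e) stop("cannot write table to '", path, "': ",
                             conditionMessage(e))
  )
  invisible(path)
}
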