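# CSV dialect is fixed (UTF-8, comma separator, period decimal, header
# required) so round trips are bit-exact in tests.

release_csv_columns <- c("sample_id", "time_h", "release_ug_cm2")

#' Write release profiles to the standard CSV layout
#'
#' Columns: `sample_id`, optional `condition` and `size`, `time_h` (hours
#' since delivery start) and `release_ug_cm2`.
#'
#' @param x A `release_dataset`, a `release_profile`, or any data frame with
#'   at least the standard columns.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_release_csv <- function(x, path) {
  if (inherits(x, "release_dataset")) x <- x$profiles
  if (!is.data.frame(x)) stop("x must be a data frame or release_dataset")
  missing <- setdiff(release_csv_columns, names(x))
  if (length(missing))
    stop("missing required columns: ", paste(missing, collapse = ", "))
  keep <- intersect(c("sample_id", "condition", "size", "time_h",
                      "release_ug_cm2"), names(x))
  write.csv(x[, keep, drop = FALSE], path, row.names = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' Read release profiles from the standard CSV layout
#'
#' Validates the header, cell types, duplicate (sample, time) pairs and the
#' per-sample time ordering; any violation is rejected with the offending
#' file row numbers.  Rows are grouped by `sample_id` in file order.
#'
#' @param path CSV file path.
#' @return A named list of `release_profile` data frames (possibly empty,
#'   with a warning, for a header-only file).
#' @export
read_release_csv <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                  fileEncoding = "UTF-8")
  missing <- setdiff(release_csv_columns, names(raw))
  if (length(missing))
    stop("missing required columns: ", paste(missing, collapse = ", "))
  if (nrow(raw) == 0) {
    warning("release CSV has a header but no data rows: ", path, call. = FALSE)
    return(list())
  }
  file_row <- seq_len(nrow(raw)) + 1L  # +1 for the header line
  for (col in c("time_h", "release_ug_cm2")) {
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(vals))
    if (length(bad))
      stop(sprintf("non-numeric value(s) in column '%s' at file row(s) %s",
                   col, paste(file_row[bad], collapse = ", ")))
    raw[[col]] <- vals
  }
  dup <- duplicated(raw[, c("sample_id", "time_h")])
  if (any(dup))
    stop("duplicate (sample_id, time_h) pair(s) at file row(s) ",
         paste(file_row[dup], collapse = ", "))
  out <- list()
  for (sid in unique(raw$sample_id)) {
    idx <- which(raw$sample_id == sid)
    tt <- raw$time_h[idx]
    bad <- which(diff(tt) <= 0)
    if (length(bad))
      stop(sprintf(
        "times for sample '%s' are not strictly increasing at file row %d",
        sid, file_row[idx[bad[1] + 1L]]))
    prof <- raw[idx, , drop = FALSE]
    rownames(prof) <- NULL
    class(prof) <- c("release_profile", "data.frame")
    out[[sid]] <- prof
  }
  out
}

#' Export a simulation as tidy CSV files
#'
#' Writes the wall field as long-format `stage, time_h, r_cm,
#' concentration_ug_cm3` (thinned to at most `max_times_per_stage` snapshot
#' times per stage) and the delivery reservoir as `stage, time_h, cd_ug_cm3,
#' release_ug_cm2`.
#'
#' @param result A `catheter_simulation`.
#' @param wall_path,reservoir_path Output file paths (`NULL` to skip one).
#' @param max_times_per_stage Snapshot times kept per stage in the wall file.
#' @return Invisible character vector of the files written.
#' @export
export_simulation_csv <- function(result, wall_path = NULL,
                                  reservoir_path = NULL,
                                  max_times_per_stage = 25) {
  stopifnot(inherits(result, "catheter_simulation"))
  written <- character(0)
  if (!is.null(wall_path)) {
    rows <- lapply(names(result$stages), function(stage) {
      st <- result$stages[[stage]]
      nt <- length(st$times)
      pick <- unique(round(seq(1, nt, length.out = min(nt,
                                                       max_times_per_stage))))
      do.call(rbind, lapply(pick, function(i) data.frame(
        stage = stage, time_h = st$times[i], r_cm = result$grid$r,
        concentration_ug_cm3 = st$states[i, ])))
    })
    write.csv(do.call(rbind, rows), wall_path, row.names = FALSE,
              fileEncoding = "UTF-8")
    written <- c(written, wall_path)
  }
  if (!is.null(reservoir_path)) {
    d <- result$stages$delivery
    write.csv(data.frame(stage = "delivery", time_h = d$times,
                         cd_ug_cm3 = d$cd, release_ug_cm2 = d$release),
              reservoir_path, row.names = FALSE, fileEncoding = "UTF-8")
    written <- c(written, reservoir_path)
  }
  invisible(written)
}
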