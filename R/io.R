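#' Read / write list-mode event CSV files
#'
#' The on-disk format is a CSV with header
#' `event_id,crystal_a,crystal_b,energy_a_kev,energy_b_kev,t_a_ns,t_b_ns,truth_class`
#' and deterministic row order (by `t_a_ns`, then `event_id`).
#'
#' @param events an `event_list`.
#' @param path output CSV path.
#' @return `write_events()`: `path` invisibly; `read_events()`: an
#'   `event_list`.
#' @export
write_events <- function(events, path) {
  data.table::fwrite(as.data.frame(events)[, event_columns], path)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- as.data.frame(data.table::fread(path))
  missing <- setdiff(event_columns, names(df))
  if (length(missing))
    stop("event CSV is missing columns: ", paste(missing, collapse = ", "))
  df$truth_class <- as.character(df$truth_class)
  as_event_list(df, resort = FALSE)
}

#' Read / write image arrays as raw float32 + JSON sidecar
#'
#' Images (and other gridded arrays) are stored as flat little-endian
#' 32-bit float binaries in column-major order with a JSON sidecar
#' `{shape, spacing_mm, origin_mm}` at `<path>.json`.
#'
#' @param image a `pet_image`.
#' @param path binary output path (sidecar written at `<path>.json`).
#' @return `write_image()`: `path` invisibly; `read_image()`: a
#'   `pet_image`.
#' @export
write_image <- function(image, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(image$intensity), con, size = 4, endian = "little")
  jsonlite::write_json(
    list(shape = c(image$grid_n, image$grid_n),
         spacing_mm = image$pixel_size_mm,
         origin_mm = c(0, 0)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- as.integer(meta$shape[1])
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- readBin(con, "numeric", n = prod(meta$shape), size = 4,
                  endian = "little")
  new_image(matrix(vals, n, meta$shape[2]), meta$spacing_mm)
}

#' Read / write profile CSV files
#'
#' Two-column CSV (`position_mm`, `intensity`).
#'
#' @param profile a `pet_profile`.
#' @param path CSV path.
#' @return `write_profile()`: `path` invisibly; `read_profile()`: a
#'   `pet_profile`.
#' @export
write_profile <- function(profile, path) {
  data.table::fwrite(as.data.frame(profile), path)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  df <- as.data.frame(data.table::fread(path))
  new_profile(df$position_mm, df$intensity)
}
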