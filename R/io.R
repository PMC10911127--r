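#' Read a per-nucleus detection table
#'
#' Reads a delimited text export of detected nuclei (one row per nucleus or
#' per nucleus-timepoint). Required columns are `id`, `t`, `x`, `y`, `z`;
#' any further columns (channel intensities, QC flags, labels) are kept as
#' given. Coordinates are converted from pixel units to um through the
#' calibration unless they are already in um.
#'
#' @param path CSV file with a header row.
#' @param calibration A [pixel_calibration()]; `z` spacing is required when
#'   `units = "pixel"` and the table has non-zero z values.
#' @param units Units of the stored x/y/z columns: `"pixel"` (default,
#'   converted on read) or `"um"` (passed through).
#' @return A `nucleus_table`: a data.frame with coordinates in um and the
#'   calibration attached as an attribute. Missing optional columns are not
#'   invented; row count equals the file's data rows.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' write.csv(data.frame(id = 1:3, t = 0, x = c(2, 4, 6), y = 0, z = 0),
#'           tf, row.names = FALSE)
#' nt <- read_nucleus_table(tf, pixel_calibration(0.5, 1))
#' nt$x  # 1 2 3 um
#' @export
read_nucleus_table <- function(path, calibration, units = c("pixel", "um")) {
  units <- match.arg(units)
  stopifnot(inherits(calibration, "pixel_calibration"))
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("id", "t", "x", "y", "z")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("nucleus table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  for (col in c("t", "x", "y", "z")) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      vn <- suppressWarnings(as.numeric(v))
      if (anyNA(vn) & !anyNA(v))
        stop(sprintf("non-numeric value in column '%s' at row %d",
                     col, which(is.na(vn))[1]))
      df[[col]] <- vn
    }
  }
  if (units == "pixel") {
    df$x <- df$x * calibration$xy
    df$y <- df$y * calibration$xy
    zs <- calibration$z
    if (is.null(zs)) {
      if (any(df$z != 0, na.rm = TRUE))
        stop("table has non-zero z but calibration lacks pixel_size_z")
      zs <- 1
    }
    df$z <- df$z * zs
  }
  as_nucleus_table(df, calibration)
}

#' Coerce a data.frame (coordinates already in um) to a nucleus table
#'
#' @param df data.frame with columns id, t, x, y, z (um) and extras.
#' @param calibration optional [pixel_calibration()] to attach.
#' @return A `nucleus_table`.
#' @export
as_nucleus_table <- function(df, calibration = NULL) {
  required <- c("id", "t", "x", "y", "z")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("nucleus table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  attr(df, "calibration") <- calibration
  attr(df, "units") <- "um"
  class(df) <- c("nucleus_table", "data.frame")
  df
}

#' Write a nucleus table (um coordinates) to CSV
#'
#' @param table A `nucleus_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_nucleus_table <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Read a binary silhouette mask
#'
#' Reads a single-channel PNG or TIFF raster; any non-zero pixel is
#' foreground. Explant-level analyses expect a single connected foreground
#' component; if more are present the mask is still returned and a warning
#' is raised.
#'
#' @param path PNG or TIFF file.
#' @param calibration A [pixel_calibration()] attached to the mask.
#' @return An `explant_mask` (see [explant_mask()]).
#' @export
read_mask <- function(path, calibration) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = , tiff = tiff::readTIFF(path),
                stop("unsupported raster format: .", ext))
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  m <- img != 0
  if (!any(m)) stop("empty mask: ", path)
  explant_mask(m, calibration)
}

#' Write a binary mask as PNG
#'
#' @param mask An `explant_mask` or logical matrix.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  m <- if (inherits(mask, "explant_mask")) mask$mask else mask
  png::writePNG(m * 1, path)
  invisible(path)
}

#' Write a result artifact with a reproducibility sidecar
#'
#' Writes any tabular result (gradient profile, dispersal curves, alignment
#' or morphometrics records, plain data.frames) as CSV, plus a JSON sidecar
#' `<path>.meta.json` recording the run configuration, seed, software
#' version and artifact class. Re-reading with [read_results()] reproduces
#' integer values bit-identically and reals within 1e-9.
#'
#' @param artifact Result object; anything with an `as.data.frame` method.
#' @param path Output CSV path.
#' @param config Optional [run_config()] recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_results <- function(artifact, path, config = NULL) {
  df <- as.data.frame(artifact)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("cannot write results: no such directory ", dir)
  write.csv(df, path, row.names = FALSE)
  meta <- list(
    artifact_class = class(artifact)[1],
    software = "explantr",
    version = as.character(utils::packageVersion("explantr")),
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    n_rows = nrow(df)
  )
  if (!is.null(config)) {
    meta$config <- unclass(config)
    meta$seed <- config$seed
  }
  extra <- attr(artifact, "meta")
  if (!is.null(extra)) meta$artifact_meta <- extra
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a result artifact written by [write_results()]
#'
#' @param path CSV path previously written by [write_results()].
#' @return A data.frame with the sidecar metadata in `attr(, "meta")`.
#' @export
read_results <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  side <- paste0(path, ".meta.json")
  if (file.exists(side))
    attr(df, "meta") <- jsonlite::read_json(side, simplifyVector = TRUE)
  df
}
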