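#' Read and write CT volumes and masks as NIfTI
#'
#' Volumes are written as 64-bit floats and masks as 8-bit integers;
#' voxel spacing travels in the NIfTI `pixdim` field, so a round-trip
#' preserves shape, spacing and voxel values exactly.
#'
#' @param x a [ct_volume()] or [label_mask()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `write_volume`/`write_mask` return `path` invisibly;
#'   `read_volume` returns a [ct_volume()]; `read_mask` a [label_mask()].
#' @name nifti_io
NULL

#' @rdname nifti_io
#' @export
write_volume <- function(x, path) {
  if (!inherits(x, "ct_volume")) stop("'x' must be a ct_volume")
  arr <- x$data
  attr(arr, "pixdim") <- x$spacing
  img <- RNifti::asNifti(arr, datatype = "double")
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' @rdname nifti_io
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  ct_volume(arr, sp)
}

#' @rdname nifti_io
#' @export
write_mask <- function(x, path) {
  if (!inherits(x, "label_mask")) stop("'x' must be a label_mask")
  arr <- x$data
  storage.mode(arr) <- "integer"
  attr(arr, "pixdim") <- x$spacing
  img <- RNifti::asNifti(arr, datatype = "uint8")
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' @rdname nifti_io
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  label_mask(arr != 0, sp)
}

#' Read and write CSV tables with a provenance header
#'
#' Tables are plain CSV preceded by `#`-prefixed provenance comment lines
#' (tool version, seed, config hash when run through the pipeline).
#' Round-trips preserve column order and values to full double precision.
#'
#' @param x data frame to write.
#' @param path file path.
#' @param provenance optional named character vector written as
#'   `# key: value` comment lines.
#' @param required optional character vector of column names that must be
#'   present; a missing column raises an error naming it.
#' @name table_io
NULL

#' @rdname table_io
#' @export
write_table <- function(x, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance))
    writeLines(sprintf("# %s: %s", names(provenance),
                       as.character(provenance)), con)
  x <- as.data.frame(x)
  # doubles serialized with %.17g so a round-trip is bit-exact
  x[] <- lapply(x, function(col)
    if (is.double(col)) sprintf("%.17g", col) else col)
  write.csv(x, con, row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_table <- function(path, required = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!is.null(required)) {
    missing <- setdiff(required, names(df))
    if (length(missing))
      stop("table ", path, " is missing required column(s): ",
           paste(missing, collapse = ", "))
  }
  df
}

#' Landmark table CSV round-trip
#'
#' CSV format: columns `level_label,z_mm`, one row per landmark.
#'
#' @param landmarks a [landmark_table()].
#' @param path file path.
#' @name landmark_io
NULL

#' @rdname landmark_io
#' @export
write_landmarks <- function(landmarks, path) {
  write_table(as.data.frame(landmarks), path)
}

#' @rdname landmark_io
#' @export
read_landmarks <- function(path) {
  landmark_table(read_table(path, required = c("level_label", "z_mm")))
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON config path.
#' @return A named list (class `run_config`) with defaults filled in; see
#'   [run_pipeline()] for the recognized fields.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_run_config(cfg)
}
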