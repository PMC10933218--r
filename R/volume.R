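#' CT volume container
#'
#' A `ct_volume` is a 3-D numeric array of Hounsfield units (HU) together
#' with its voxel spacing. Array dimensions are `(nx, ny, nz)` where the
#' third axis is the craniocaudal (slice) axis; slice `i` spans the axial
#' slab `[(i-1) * spacing[3], i * spacing[3])` mm, so slice 1 is the most
#' caudal slice and z increases towards the head.
#'
#' @param data 3-D numeric array of HU values.
#' @param spacing numeric length-3 voxel spacing in mm `(dx, dy, dz)`;
#'   `dz` is the slice thickness.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(data, spacing = c(1, 1, 3)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("'data' must be a 3-D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be three positive voxel sizes in mm")
  structure(list(data = data, spacing = spacing), class = "ct_volume")
}

#' Binary label mask aligned to a CT volume
#'
#' @param data 3-D logical (or coercible) array.
#' @param spacing voxel spacing in mm, as in [ct_volume()].
#' @return An object of class `label_mask`.
#' @export
label_mask <- function(data, spacing = c(1, 1, 3)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("'data' must be a 3-D array")
  storage.mode(data) <- "logical"
  data[is.na(data)] <- FALSE
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be three positive voxel sizes in mm")
  structure(list(data = data, spacing = spacing), class = "label_mask")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ct_volume> %d x %d x %d voxels, spacing %s mm, HU range [%.0f, %.0f]\n",
              d[1], d[2], d[3], paste(format(x$spacing), collapse = " x "),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.label_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<label_mask> %d x %d x %d voxels, spacing %s mm, %d foreground voxels\n",
              d[1], d[2], d[3], paste(format(x$spacing), collapse = " x "),
              sum(x$data)))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$data)

#' @export
dim.label_mask <- function(x) dim(x$data)

voxel_volume_mm3 <- function(x) prod(x$spacing)

as_mask_array <- function(mask) {
  if (inherits(mask, "label_mask")) mask$data else {
    m <- as.array(mask)
    storage.mode(m) <- "logical"
    m
  }
}

stop_if_shape_mismatch <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("masks have mismatched shapes: ", paste(dim(a), collapse = "x"),
         " vs ", paste(dim(b), collapse = "x"))
}

# Run an expression with the RNG seeded, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}
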