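#' Fat attenuation window
#'
#' The Hounsfield-unit window that defines adipose tissue. The default,
#' -190 to -30 HU, is the de-facto standard body-composition fat window.
#'
#' @param low,high window bounds in HU, `low < high`, both within
#'   `[-1024, 1024]`.
#' @return A `fat_window` object.
#' @export
fat_window <- function(low = -190, high = -30) {
  low <- as.numeric(low); high <- as.numeric(high)
  if (!is.finite(low) || !is.finite(high) || low >= high)
    stop("fat window requires low < high")
  if (low < -1024 || high > 1024)
    stop("fat window bounds must lie within [-1024, 1024] HU")
  structure(list(low = low, high = high), class = "fat_window")
}

#' Threshold a CT volume to its fat voxels
#'
#' Marks every voxel whose attenuation lies inside the fat window
#' (inclusive at both ends). Idempotent in the sense that re-thresholding
#' changes nothing, and independent of voxel traversal order.
#'
#' @param volume a [ct_volume()] in HU.
#' @param window a [fat_window()].
#' @return A [label_mask()] of fat voxels.
#' @export
threshold_fat <- function(volume, window = fat_window()) {
  if (!inherits(volume, "ct_volume")) stop("'volume' must be a ct_volume")
  rng <- range(volume$data)
  if (rng[1] < -2000 || rng[2] > 4000)
    warning("volume values outside [-2000, 4000]: input may not be HU-scaled")
  label_mask(volume$data >= window$low & volume$data <= window$high,
             volume$spacing)
}

#' Extract the body mask
#'
#' The body is the largest 26-connected component of voxels above
#' `air_threshold` HU, with internal cavities filled. On a phantom it
#' contains every subcutaneous and visceral fat voxel.
#'
#' @param volume a [ct_volume()].
#' @param air_threshold HU value separating body tissue from air
#'   (default -500).
#' @return A [label_mask()].
#' @export
body_mask <- function(volume, air_threshold = -500) {
  if (!inherits(volume, "ct_volume")) stop("'volume' must be a ct_volume")
  fg <- volume$data > air_threshold
  if (!any(fg)) stop("no body found: volume is entirely air")
  labels <- .cc_label_3d(fg, dim(fg))
  tab <- tabulate(labels[labels > 0L])
  biggest <- which.max(tab)
  body <- .fill_holes_3d(labels == biggest, dim(fg))
  label_mask(body, volume$spacing)
}

#' Separate fat into visceral and subcutaneous compartments
#'
#' Subcutaneous fat (SAT) is the set of 26-connected fat components that
#' touch the body boundary shell (the outermost `shell_voxels` of the body
#' mask, obtained by 6-neighbourhood erosion); visceral fat (VAT) is the
#' remaining fat inside the cavity. Components touching both the shell and
#' the cavity through a bridge are assigned to SAT, which makes the split
#' deterministic and order-independent. The two outputs partition the fat
#' mask.
#'
#' @param fat fat [label_mask()] (e.g. from [threshold_fat()]); must be a
#'   subset of `body`.
#' @param body body [label_mask()] (e.g. from [body_mask()]).
#' @param shell_voxels thickness of the boundary shell in voxels
#'   (default 2).
#' @return A list with [label_mask()] elements `vat` and `sat`.
#' @export
separate_compartments <- function(fat, body, shell_voxels = 2L) {
  fm <- as_mask_array(fat); bm <- as_mask_array(body)
  stop_if_shape_mismatch(fm, bm)
  if (any(fm & !bm)) stop("fat mask is not contained in the body mask")
  spacing <- if (inherits(fat, "label_mask")) fat$spacing else c(1, 1, 1)
  if (!any(fm))
    return(list(vat = label_mask(fm, spacing), sat = label_mask(fm, spacing)))
  shell <- bm & !.erode_3d(bm, dim(bm), as.integer(shell_voxels))
  labels <- .cc_label_3d(fm, dim(fm))
  n_comp <- max(labels)
  in_shell <- unique(labels[shell & labels > 0L])
  sat_comp <- logical(n_comp)
  sat_comp[in_shell] <- TRUE
  sat <- fm & array(sat_comp[pmax(labels, 1L)] & labels > 0L, dim = dim(fm))
  vat <- fm & !sat
  list(vat = label_mask(vat, spacing), sat = label_mask(sat, spacing))
}

#' Dice and Jaccard overlap of two masks
#'
#' `dice = 2|A∩B| / (|A| + |B|)`, `jaccard = |A∩B| / |A∪B|`. Two empty
#' masks agree perfectly (both scores 1); an empty versus a non-empty mask
#' scores 0.
#'
#' @param a,b aligned [label_mask()]s (or logical arrays) of equal shape.
#' @return An `overlap_scores` list with elements `dice` and `jaccard`.
#' @export
overlap_scores <- function(a, b) {
  am <- as_mask_array(a); bm <- as_mask_array(b)
  stop_if_shape_mismatch(am, bm)
  na <- sum(am); nb <- sum(bm)
  if (na == 0 && nb == 0)
    return(structure(list(dice = 1, jaccard = 1), class = "overlap_scores"))
  inter <- sum(am & bm)
  structure(list(dice = 2 * inter / (na + nb),
                 jaccard = inter / (na + nb - inter)),
            class = "overlap_scores")
}

#' @export
print.overlap_scores <- function(x, ...) {
  cat(sprintf("Dice %.4f, Jaccard %.4f\n", x$dice, x$jaccard))
  invisible(x)
}

#' Run the full rule-based VAT segmentation
#'
#' Convenience wrapper: [threshold_fat()], [body_mask()], then
#' [separate_compartments()].
#'
#' @inheritParams threshold_fat
#' @inheritParams separate_compartments
#' @param air_threshold passed to [body_mask()].
#' @return A list with `vat`, `sat`, `body` and `fat` [label_mask()]s.
#' @export
segment_vat <- function(volume, window = fat_window(), shell_voxels = 2L,
                        air_threshold = -500) {
  fat <- threshold_fat(volume, window)
  body <- body_mask(volume, air_threshold)
  comp <- separate_compartments(fat, body, shell_voxels)
  c(comp, list(body = body, fat = fat))
}
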