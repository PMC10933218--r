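#' Visceral fat area of one axial slice
#'
#' @param mask_slice 2-D logical matrix (one axial slice of a VAT mask).
#' @param pixel_area_mm2 area of one pixel, mm^2.
#' @return Area in cm^2 (empty slice gives 0).
#' @export
vfa <- function(mask_slice, pixel_area_mm2 = 1) {
  m <- as.matrix(mask_slice)
  storage.mode(m) <- "logical"
  sum(m, na.rm = TRUE) * pixel_area_mm2 / 100
}

#' Per-slice visceral fat areas of a 3-D mask
#'
#' @param mask a [label_mask()] (or logical array; then `spacing` is used).
#' @param spacing voxel spacing, mm; defaults to the mask's own.
#' @return Numeric vector of VFA in cm^2, one per slice (caudal to
#'   cranial).
#' @export
slice_vfas <- function(mask, spacing = NULL) {
  m <- as_mask_array(mask)
  if (is.null(spacing))
    spacing <- if (inherits(mask, "label_mask")) mask$spacing else c(1, 1, 1)
  apply(m, 3, sum) * spacing[1] * spacing[2] / 100
}

#' Total VAT volume of a mask
#'
#' @param mask a [label_mask()] or 3-D logical array.
#' @param voxel_volume_mm3 volume of one voxel, mm^3; defaults to the
#'   product of the mask's spacing.
#' @return Volume in cm^3. Equals the sum over slices of
#'   `vfa * thickness` when the slices tile the mask.
#' @export
vat_volume <- function(mask, voxel_volume_mm3 = NULL) {
  m <- as_mask_array(mask)
  if (is.null(voxel_volume_mm3))
    voxel_volume_mm3 <- if (inherits(mask, "label_mask"))
      voxel_volume_mm3(mask) else 1
  sum(m) * voxel_volume_mm3 / 1000
}

#' Visceral adipose index (VAI)
#'
#' The visceral fat area standardized by the squared lumbar height:
#' `VAI = VFA / height^2` in cm^2/m^2.
#'
#' @param vfa_cm2 visceral fat area, cm^2.
#' @param height_m lumbar height (L1-1 to L5-5), m; must be > 0.
#' @return VAI in cm^2/m^2.
#' @export
vai <- function(vfa_cm2, height_m) {
  if (any(!is.finite(height_m)) || any(height_m <= 0))
    stop("lumbar height must be > 0")
  vfa_cm2 / height_m^2
}

#' VAT ratio of a slice
#'
#' A slice's share of the total VAT volume:
#' `VAT ratio (%) = (VFA x layer thickness) / VAT volume x 100`, with the
#' thickness converted mm -> cm so the ratio is dimensionless. Over a set
#' of slices that tile the whole mask the ratios sum to exactly 100%.
#'
#' @param vfa_cm2 slice visceral fat area, cm^2.
#' @param thickness_mm layer thickness, mm.
#' @param volume_cm3 total VAT volume, cm^3; must be > 0.
#' @return Ratio in percent.
#' @export
vat_ratio <- function(vfa_cm2, thickness_mm, volume_cm3) {
  if (any(!is.finite(volume_cm3)) || any(volume_cm3 <= 0))
    stop("VAT volume must be > 0")
  vfa_cm2 * (thickness_mm / 10) / volume_cm3 * 100
}

#' Mean, SD and coefficient of variation of a set of areas
#'
#' The distribution summary used over per-slice visceral fat areas:
#' arithmetic mean, sample SD (n - 1 denominator) and CV = SD/mean x 100.
#'
#' @param areas numeric vector of areas (>= 2 values).
#' @return List with `mean`, `sd` (same units as `areas`) and `cv`
#'   (percent; `NA` with a warning when the mean is not positive).
#' @export
distribution_stats <- function(areas) {
  areas <- as.numeric(areas)
  if (length(areas) < 2) stop("need at least 2 areas")
  if (any(!is.finite(areas))) stop("areas must be finite")
  m <- mean(areas)
  s <- sd(areas)
  cv <- if (m > 0) s / m * 100 else {
    warning("mean area is not positive; CV undefined")
    NA_real_
  }
  list(mean = m, sd = s, cv = cv)
}

#' Inter-subject CV of VFA at one level
#'
#' Sample coefficient of variation of one slice level's visceral fat area
#' across subjects.
#'
#' @param vfas numeric vector, one VFA per subject (>= 2 subjects).
#' @return CV in percent.
#' @export
inter_subject_cv <- function(vfas) {
  distribution_stats(vfas)$cv
}

#' Correlation between per-level VFA and total VAT volume
#'
#' @param vfas numeric vector of one level's VFA across subjects.
#' @param volumes numeric vector of total VAT volumes, same subjects.
#' @param method `"pearson"` or `"spearman"`.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
level_volume_correlation <- function(vfas, volumes,
                                     method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(vfas) != length(volumes)) stop("inputs must be paired")
  if (length(vfas) < 3) stop("need at least 3 subjects")
  if (sd(vfas) == 0 || sd(volumes) == 0)
    stop("zero variance: correlation undefined")
  cor(vfas, volumes, method = method)
}

#' Full indicator set for one subject
#'
#' Computes every distribution indicator from a VAT mask and its vertebral
#' landmarks: total VAT volume; per-slice VFA, VAI and VAT ratio at the
#' representative slice plan; the lumbar mean/SD/CV over *all* acquired
#' slices between L1-1 and L5-5; and `cv_35`, the CV over the
#' representative slices only (the two CV variants are reported
#' separately because they summarize different slice sets).
#'
#' @param vat_mask a [label_mask()] of visceral fat.
#' @param landmarks a [landmark_table()].
#' @param n_per_vertebra,n_pelvic slice plan counts, see [select_slices()].
#' @return A `subject_metrics` list: `vat_volume`, `lumbar_mean`,
#'   `lumbar_sd`, `lumbar_cv`, `cv_35`, `lumbar_height`, and `slices`
#'   (data frame: `level_label`, `slice`, `thickness_mm`, `vfa`, `vai`,
#'   `vat_ratio`, `lumbar`).
#' @export
subject_metrics <- function(vat_mask, landmarks, n_per_vertebra = 5,
                            n_pelvic = 10) {
  if (!inherits(vat_mask, "label_mask")) stop("'vat_mask' must be a label_mask")
  spacing <- vat_mask$spacing
  n_slices <- dim(vat_mask$data)[3]
  plan <- select_slices(landmarks, spacing[3], n_per_vertebra, n_pelvic,
                        n_slices = n_slices)
  vfas_all <- slice_vfas(vat_mask)
  vol <- vat_volume(vat_mask)
  height <- lumbar_height(landmarks)

  plan_vfa <- vfas_all[plan$slice]
  slices <- data.frame(level_label = plan$level_label,
                       slice = plan$slice,
                       thickness_mm = plan$thickness_mm,
                       vfa = plan_vfa,
                       vai = vai(plan_vfa, height),
                       vat_ratio = if (vol > 0)
                         vat_ratio(plan_vfa, plan$thickness_mm, vol)
                       else NA_real_,
                       lumbar = plan$lumbar,
                       stringsAsFactors = FALSE)

  lumbar_idx <- lumbar_slice_indices(landmarks, spacing[3], n_slices)
  lumbar <- distribution_stats(vfas_all[lumbar_idx])
  cv35 <- distribution_stats(plan_vfa)$cv

  structure(list(vat_volume = vol,
                 lumbar_mean = lumbar$mean,
                 lumbar_sd = lumbar$sd,
                 lumbar_cv = lumbar$cv,
                 cv_35 = cv35,
                 lumbar_height = height,
                 slices = slices),
            class = "subject_metrics")
}

#' @export
print.subject_metrics <- function(x, ...) {
  cat(sprintf(paste0("<subject_metrics> VAT volume %.1f cm^3, lumbar mean ",
                     "%.2f cm^2, SD %.2f cm^2, CV %.2f%% (CV over %d ",
                     "representative slices: %.2f%%)\n"),
              x$vat_volume, x$lumbar_mean, x$lumbar_sd, x$lumbar_cv,
              nrow(x$slices), x$cv_35))
  invisible(x)
}
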