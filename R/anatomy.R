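#' Vertebral landmark table
#'
#' Craniocaudal positions of the landmarks bounding the analysis range:
#' the superior borders of L1..L5 (labels `L1-1` .. `L5-1`, adjacent
#' vertebrae sharing borders), the inferior border of L5 (`L5-5`), and the
#' pubic symphysis. z is measured in mm along the scanner axis and
#' increases towards the head, so the landmark sequence is strictly
#' decreasing in z.
#'
#' @param z_mm named numeric vector of landmark positions in mm. Names must
#'   be exactly the seven labels above (any order).
#' @return A `landmark_table` data frame with columns `level_label`, `z_mm`,
#'   ordered craniocaudally.
#' @export
landmark_table <- function(z_mm) {
  labels <- landmark_labels()
  if (is.data.frame(z_mm)) {
    df <- z_mm
    if (!all(c("level_label", "z_mm") %in% names(df)))
      stop("landmark data frame needs columns 'level_label' and 'z_mm'")
    z_mm <- stats::setNames(as.numeric(df$z_mm), as.character(df$level_label))
  }
  if (is.null(names(z_mm)) || !setequal(names(z_mm), labels))
    stop("landmarks must be named exactly: ", paste(labels, collapse = ", "))
  z <- as.numeric(z_mm[labels])
  if (any(!is.finite(z))) stop("landmark positions must be finite")
  if (any(diff(z) >= 0))
    stop("landmark z-positions must be strictly decreasing craniocaudally ",
         "(L1-1 above L5-5 above pubic symphysis)")
  structure(data.frame(level_label = labels, z_mm = z,
                       stringsAsFactors = FALSE),
            class = c("landmark_table", "data.frame"))
}

landmark_labels <- function() {
  c("L1-1", "L2-1", "L3-1", "L4-1", "L5-1", "L5-5", "pubic_symphysis")
}

landmark_z <- function(landmarks, label) {
  i <- match(label, landmarks$level_label)
  if (is.na(i)) stop("missing landmark: ", label)
  landmarks$z_mm[i]
}

#' Lumbar height
#'
#' Vertical height between the superior border of L1 (`L1-1`) and the
#' inferior border of L5 (`L5-5`), used to standardize the visceral fat
#' area into the visceral adipose index (VAI).
#'
#' @param landmarks a [landmark_table()].
#' @return Height in metres (strictly positive).
#' @export
lumbar_height <- function(landmarks) {
  h <- abs(landmark_z(landmarks, "L1-1") - landmark_z(landmarks, "L5-5")) / 1000
  if (h <= 0) stop("lumbar height must be strictly positive")
  h
}

#' Plan the representative analysis slices
#'
#' Selects the representative axial slices used for per-level reporting:
#' `n_per_vertebra` slices evenly spaced within each lumbar vertebra
#' (between its superior and inferior borders) and `n_pelvic` slices evenly
#' spaced between the inferior border of L5 and the pubic symphysis. The
#' defaults give the conventional 5 x 5 + 10 = 35 slices, labelled
#' `L1-1` .. `L5-5` and `Pelvis-1` .. `Pelvis-10` craniocaudally.
#'
#' Target positions are the midpoints of equal sub-bands of each span and
#' are mapped to the nearest acquired slice (slice `i`, 1-based, spans
#' `[(i-1) * spacing, i * spacing)` mm); midpoint ties round towards the
#' cranial side.
#'
#' @param landmarks a [landmark_table()].
#' @param spacing slice thickness in mm.
#' @param n_per_vertebra slices per lumbar vertebra (default 5).
#' @param n_pelvic slices in the pelvic span (default 10).
#' @param n_slices total number of acquired slices, used to verify that
#'   the landmarks lie inside the volume; `NULL` skips the check.
#' @return A `slice_plan` data frame with columns `level_label`, `z_mm`
#'   (target position), `slice` (1-based index), `thickness_mm`, `lumbar`
#'   (logical flag).
#' @export
select_slices <- function(landmarks, spacing, n_per_vertebra = 5,
                          n_pelvic = 10, n_slices = NULL) {
  landmarks <- landmark_table(stats::setNames(landmarks$z_mm,
                                              landmarks$level_label))
  if (spacing <= 0) stop("'spacing' must be positive")
  n_per_vertebra <- as.integer(n_per_vertebra)
  n_pelvic <- as.integer(n_pelvic)
  if (n_per_vertebra < 1) stop("'n_per_vertebra' must be >= 1")
  if (n_pelvic < 0) stop("'n_pelvic' must be >= 0")

  z_sup <- c(landmark_z(landmarks, "L1-1"), landmark_z(landmarks, "L2-1"),
             landmark_z(landmarks, "L3-1"), landmark_z(landmarks, "L4-1"),
             landmark_z(landmarks, "L5-1"))
  z_inf <- c(z_sup[-1], landmark_z(landmarks, "L5-5"))

  band_midpoints <- function(z_top, z_bot, n) {
    # midpoints of n equal sub-bands, ordered craniocaudally
    z_top - (seq_len(n) - 0.5) / n * (z_top - z_bot)
  }
  rows <- list()
  for (v in 1:5) {
    z <- band_midpoints(z_sup[v], z_inf[v], n_per_vertebra)
    rows[[v]] <- data.frame(
      level_label = sprintf("L%d-%d", v, seq_len(n_per_vertebra)),
      z_mm = z, lumbar = TRUE, stringsAsFactors = FALSE)
  }
  if (n_pelvic > 0) {
    z <- band_midpoints(landmark_z(landmarks, "L5-5"),
                        landmark_z(landmarks, "pubic_symphysis"), n_pelvic)
    rows[[6]] <- data.frame(
      level_label = sprintf("Pelvis-%d", seq_len(n_pelvic)),
      z_mm = z, lumbar = FALSE, stringsAsFactors = FALSE)
  }
  plan <- do.call(rbind, rows)
  plan$slice <- z_to_slice(plan$z_mm, spacing)
  plan$thickness_mm <- spacing
  if (any(plan$slice < 1) ||
      (!is.null(n_slices) && any(plan$slice > n_slices)))
    stop("landmarks place slices outside the volume")
  plan <- plan[, c("level_label", "z_mm", "slice", "thickness_mm", "lumbar")]
  structure(plan, class = c("slice_plan", "data.frame"))
}

# Map z (mm) to the 1-based index of the slice whose slab contains it.
# A z exactly on a slab boundary belongs to the more cranial (upper) slab
# by the half-open convention; the +0.5-slab shift never occurs because
# targets are band midpoints, but floor() handles boundaries consistently.
z_to_slice <- function(z_mm, spacing) {
  as.integer(floor(z_mm / spacing)) + 1L
}

# Indices of every acquired slice whose slab midpoint falls in the lumbar
# range [z(L5-5), z(L1-1)].
lumbar_slice_indices <- function(landmarks, spacing, n_slices) {
  z_top <- landmark_z(landmarks, "L1-1")
  z_bot <- landmark_z(landmarks, "L5-5")
  mids <- (seq_len(n_slices) - 0.5) * spacing
  which(mids >= z_bot & mids <= z_top)
}
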