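#' Cross-sectional area of one segmentation mask
#'
#' The contour interior is represented by the foreground pixels of a binary
#' mask; the area is the foreground count times the pixel area.
#'
#' @param mask binary (0/1) matrix.
#' @param pixel_size pixel edge length, cm.
#' @return Area in cm^2.
#' @export
slice_area <- function(mask, pixel_size) {
  if (!is.matrix(mask) && !is.array(mask)) stop("'mask' must be a matrix")
  if (!all(mask %in% c(0, 1))) stop("mask must be binary (values 0/1)")
  if (pixel_size <= 0) stop("'pixel_size' must be > 0")
  sum(mask) * pixel_size^2
}

#' Disk-summation volume of a short-axis mask stack
#'
#' The standard volumetric method: the volume is the sum over slices of
#' cross-sectional area times slice thickness.  Slices whose mid-plane lies
#' beyond the apex are empty and contribute zero (the resulting at-most
#' half-slice apical error is documented, not corrected).
#'
#' @param stack an [mask_stack()] object.
#' @return An object of class `rv_volume_estimate`: `volume_ml`, `n_slices`,
#'   `per_slice_areas_cm2`, `slice_thickness_cm`, `method`.
#' @export
#' @examples
#' g <- phantom_geometry(calibrate_shape(0.3, 0.9, 1.21), 4.2, 7.7)
#' st <- rasterize_short_axis(g, slice_thickness = 0.8, pixel_size = 0.1)
#' disk_summation_volume(st)
disk_summation_volume <- function(stack) {
  if (!inherits(stack, "rv_mask_stack")) stop("'stack' must be an rv_mask_stack")
  areas <- vapply(stack$masks, slice_area, numeric(1),
                  pixel_size = stack$pixel_size)
  structure(list(volume_ml = sum(areas) * stack$slice_thickness,
                 n_slices = length(areas),
                 per_slice_areas_cm2 = areas,
                 slice_thickness_cm = stack$slice_thickness,
                 method = "disk_summation"),
            class = "rv_volume_estimate")
}

#' @export
print.rv_volume_estimate <- function(x, ...) {
  cat(sprintf("%s volume: %.2f mL over %d slices (t = %.2f cm)\n",
              x$method, x$volume_ml, x$n_slices, x$slice_thickness_cm))
  invisible(x)
}

#' Linear measurements from a four-chamber section mask
#'
#' Reads the two linear measurements off a rasterized long-axis section: the
#' basal diameter as the foreground extent of the basal row (row 1, tricuspid
#' plane by convention) and the baso-apical length as the row span from the
#' basal row to the last non-empty row.
#'
#' @param long_axis_mask binary matrix from [rasterize_long_axis()].
#' @param pixel_size pixel size in cm; defaults to the mask's `pixel_size`
#'   attribute.
#' @return A list: `diameter_cm`, `length_cm`.
#' @export
measure_four_chamber <- function(long_axis_mask,
                                 pixel_size = attr(long_axis_mask, "pixel_size")) {
  if (is.null(pixel_size)) stop("'pixel_size' missing and not an attribute")
  if (!all(long_axis_mask %in% c(0, 1))) stop("mask must be binary (values 0/1)")
  nonempty <- which(rowSums(long_axis_mask) > 0)
  if (length(nonempty) == 0) stop("empty mask: no measurement possible")
  basal <- nonempty[1]
  diameter <- sum(long_axis_mask[basal, ]) * pixel_size
  len <- (nonempty[length(nonempty)] - basal + 1) * pixel_size
  list(diameter_cm = diameter, length_cm = len)
}
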