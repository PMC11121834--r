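#' Shape parameters of the truncated cone minus rhomboid pyramid family
#'
#' The simplified right-ventricular solid is a generalized cone: every
#' cross-section perpendicular to the long axis is a scaled copy of the base
#' section, which is a disc of radius `(1 + p0) * D / 2` minus a rhombus with
#' diagonals `p0 * D` (along x) and `q0 * D` (along y).  The rhombus is placed
#' so that its +x vertex touches the circle; as a consequence the cavity chord
#' along the x axis has length exactly `D` — the basal diameter a reader
#' measures in a four-chamber view.
#'
#' @param alpha apical taper ratio in (0, 1]: the scale factor of the apical
#'   cross-section relative to the base (1 = cylinder/prism, small values =
#'   sharply tapered).
#' @param p0 rhombus long diagonal as a fraction of the measured basal
#'   diameter `D` (>= 0).
#' @param q0 rhombus short diagonal as a fraction of `D` (>= 0).
#'
#' @return An object of class `rv_shape` with fields `alpha`, `p0`, `q0` and
#'   the derived `beta = 1 + p0` (frustum basal diameter as a multiple of `D`).
#'
#' @details The rhombus must stay inscribed in the circle at every level,
#'   which requires `1 + q0^2 <= (1 + p0)^2`; violating inputs are rejected.
#'
#' @seealso [shape_coefficient()], [calibrate_shape()], [phantom_geometry()]
#' @export
#' @examples
#' shape_params(alpha = 0.3, p0 = 1.0, q0 = 0.9)
shape_params <- function(alpha, p0, q0) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L,
            is.numeric(p0), length(p0) == 1L,
            is.numeric(q0), length(q0) == 1L)
  if (!is.finite(alpha) || alpha <= 0 || alpha > 1)
    stop("'alpha' must satisfy 0 < alpha <= 1 (apical taper ratio)")
  if (!is.finite(p0) || p0 < 0)
    stop("'p0' must be >= 0 (rhombus long diagonal / D)")
  if (!is.finite(q0) || q0 < 0)
    stop("'q0' must be >= 0 (rhombus short diagonal / D)")
  if (1 + q0^2 > (1 + p0)^2 + 1e-12)
    stop("rhombus not inscribed in the circle: need 1 + q0^2 <= (1 + p0)^2")
  structure(list(alpha = alpha, p0 = p0, q0 = q0, beta = 1 + p0),
            class = "rv_shape")
}

#' @export
print.rv_shape <- function(x, ...) {
  cat(sprintf(
    "RV shape: alpha = %.4f, p0 = %.4f, q0 = %.4f (k = %.4f)\n",
    x$alpha, x$p0, x$q0, shape_coefficient(x)))
  invisible(x)
}

#' Closed-form volume coefficient of a shape
#'
#' For a phantom with basal diameter `D` and length `L` the cavity volume is
#' `k * D^2 * L` where
#' `k = (1 + alpha + alpha^2) * (pi * (1 + p0)^2 / 12 - p0 * q0 / 6)`.
#' `k` is the geometric counterpart of the constant 1.21 in the cone-pyramid
#' formula `V = 1.21 * D^2 * L`.
#'
#' @param shape an [shape_params()] object.
#' @return The dimensionless coefficient `k` (> 0).
#' @export
#' @examples
#' shape_coefficient(shape_params(1, 0, 0))       # cylinder: pi/4
#' shape_coefficient(shape_params(0.3, 1, 0.9))   # ~1.247
shape_coefficient <- function(shape) {
  if (!inherits(shape, "rv_shape")) stop("'shape' must be an rv_shape object")
  k <- (1 + shape$alpha + shape$alpha^2) *
    (pi * shape$beta^2 / 12 - shape$p0 * shape$q0 / 6)
  if (!is.finite(k) || k <= 0) stop("shape coefficient is not positive")
  k
}

#' Calibrate the rhombus long diagonal to a target volume coefficient
#'
#' Solves for `p0` such that the closed-form coefficient of
#' `shape_params(alpha, p0, q0)` equals `target_k`.  With the defaults
#' `alpha = 0.3`, `q0 = 0.9` this recovers a shape whose coefficient is the
#' cone-pyramid constant 1.21 exactly (`p0` close to 0.970).  The coefficient
#' is strictly increasing in `p0`, so the root (when bracketed in [0, 3]) is
#' unique.
#'
#' @param alpha apical taper ratio.
#' @param q0 rhombus short diagonal fraction.
#' @param target_k target coefficient (default 1.21).
#' @return A calibrated `rv_shape`; `shape_coefficient()` of the result equals
#'   `target_k` to better than 1e-9.
#' @export
#' @examples
#' calibrate_shape(0.3, 0.9, 1.21)
calibrate_shape <- function(alpha, q0, target_k = 1.21) {
  f <- function(p0) {
    (1 + alpha + alpha^2) * (pi * (1 + p0)^2 / 12 - p0 * q0 / 6) - target_k
  }
  lo <- 0; hi <- 3
  if (f(lo) > 0 || f(hi) < 0)
    stop("target coefficient unreachable for these parameters ",
         "(no sign change for p0 in [0, 3])")
  root <- stats::uniroot(f, c(lo, hi), tol = .Machine$double.eps^0.75)$root
  # Newton polish to machine precision (f is smooth and strictly increasing)
  for (it in 1:3) {
    fp <- (1 + alpha + alpha^2) * (pi * (1 + root) / 6 - q0 / 6)
    root <- root - f(root) / fp
  }
  shape <- shape_params(alpha, root, q0)
  if (abs(shape_coefficient(shape) - target_k) >= 1e-9)
    stop("calibration failed to reach the target coefficient")
  shape
}

#' Outflow-tract appendage specification
#'
#' The right ventricular outflow tract (RVOT) is invisible to four-chamber
#' linear measurements but contributes to true RV volume (up to ~19%).  It is
#' modeled as a half-cylinder patch attached on the +y side of the base over
#' the axial range `[0, h_frac * L]`, sized so that it contributes fraction
#' `f` of the total cavity volume.  The patch touches the main solid only at a
#' single tangent point and never intersects the x-axis measurement line, so
#' the four-chamber basal chord is unaffected.
#'
#' @param f fraction of total RV volume in the appendage, in [0, 0.3].
#' @param h_frac appendage axial extent as a fraction of the baso-apical
#'   length `L` (default 0.3).
#' @return An object of class `rv_rvot`.
#' @export
rvot_spec <- function(f, h_frac = 0.3) {
  stopifnot(is.numeric(f), length(f) == 1L,
            is.numeric(h_frac), length(h_frac) == 1L)
  if (!is.finite(f) || f < 0 || f > 0.3)
    stop("'f' (RVOT volume fraction) must be in [0, 0.3]")
  if (!is.finite(h_frac) || h_frac <= 0 || h_frac > 1)
    stop("'h_frac' must be in (0, 1]")
  structure(list(f = f, h_frac = h_frac), class = "rv_rvot")
}

#' One right-ventricular phantom instance
#'
#' Couples a shape family member with the two measurable linear dimensions:
#' the basal diameter `D` (tricuspid-valve level, four-chamber view) and the
#' baso-apical length `L` (tricuspid-valve center to apex).  The long axis
#' runs along z with the base plane at z = 0 and the apex plane at z = `L`;
#' the cross-section at height z is the base section scaled by
#' `s(z) = 1 - (1 - alpha) * z / L`.
#'
#' @param shape an `rv_shape`.
#' @param D basal diameter in cm (> 0).
#' @param L baso-apical length in cm (> 0).
#' @param rvot optional [rvot_spec()] appendage.
#' @return An object of class `rv_phantom`.
#' @export
#' @examples
#' phantom_geometry(calibrate_shape(0.3, 0.9, 1.21), D = 4.2, L = 7.7)
phantom_geometry <- function(shape, D, L, rvot = NULL) {
  if (!inherits(shape, "rv_shape")) stop("'shape' must be an rv_shape object")
  stopifnot(is.numeric(D), length(D) == 1L, is.numeric(L), length(L) == 1L)
  if (!is.finite(D) || D <= 0) stop("'D' must be a positive diameter in cm")
  if (!is.finite(L) || L <= 0) stop("'L' must be a positive length in cm")
  if (!is.null(rvot) && !inherits(rvot, "rv_rvot"))
    stop("'rvot' must be an rvot_spec() object or NULL")
  if (!is.null(rvot) && rvot$f == 0) rvot <- NULL
  structure(list(shape = shape, D = D, L = L, rvot = rvot),
            class = "rv_phantom")
}

#' @export
print.rv_phantom <- function(x, ...) {
  cat(sprintf("RV phantom: D = %.3f cm, L = %.3f cm, k = %.4f, volume = %.2f mL\n",
              x$D, x$L, shape_coefficient(x$shape), analytic_volume(x)))
  if (!is.null(x$rvot))
    cat(sprintf("  RVOT appendage: f = %.3f of total volume, h = %.2f L\n",
                x$rvot$f, x$rvot$h_frac))
  invisible(x)
}

# Internal: appendage half-cylinder (radius, center y offset, axial extent).
# Sized so the appendage is fraction f of TOTAL volume: Va = f/(1-f) * k D^2 L.
rvot_patch <- function(geom) {
  if (is.null(geom$rvot)) return(NULL)
  k <- shape_coefficient(geom$shape)
  body <- k * geom$D^2 * geom$L
  va <- geom$rvot$f / (1 - geom$rvot$f) * body
  h <- geom$rvot$h_frac * geom$L
  list(radius = sqrt(2 * va / (pi * h)),
       yc = geom$shape$beta * geom$D / 2,
       h = h, volume = va)
}

#' Closed-form phantom volume
#'
#' Returns `k * D^2 * L` (in mL; 1 cm^3 = 1 mL) plus, when an RVOT appendage
#' is present, the appendage volume `f / (1 - f) * k * D^2 * L`, so that the
#' appendage makes up fraction `f` of the returned total.
#'
#' @param geom an [phantom_geometry()] object.
#' @return Volume in mL.
#' @export
#' @examples
#' g <- phantom_geometry(calibrate_shape(0.3, 0.9, 1.21), 4.2, 7.7)
#' analytic_volume(g)  # 1.21 * 4.2^2 * 7.7 = 164.35 mL
analytic_volume <- function(geom) {
  if (!inherits(geom, "rv_phantom")) stop("'geom' must be an rv_phantom")
  v <- shape_coefficient(geom$shape) * geom$D^2 * geom$L
  patch <- rvot_patch(geom)
  if (!is.null(patch)) v <- v + patch$volume
  v
}

#' Cross-sectional cavity area at an axial position
#'
#' @param geom an `rv_phantom`.
#' @param z axial position in cm (base at 0, apex at `L`); vectorized.
#'   Positions outside `[0, L]` return zero area.
#' @return Area in cm^2 (base section area times `s(z)^2`, plus the constant
#'   appendage patch area over its axial extent).
#' @export
cross_section_area <- function(geom, z) {
  if (!inherits(geom, "rv_phantom")) stop("'geom' must be an rv_phantom")
  sh <- geom$shape
  a0 <- (pi * sh$beta^2 / 4 - sh$p0 * sh$q0 / 2) * geom$D^2
  s <- 1 - (1 - sh$alpha) * z / geom$L
  area <- ifelse(z >= 0 & z <= geom$L, s^2 * a0, 0)
  patch <- rvot_patch(geom)
  if (!is.null(patch))
    area <- area + ifelse(z >= 0 & z <= patch$h, pi * patch$radius^2 / 2, 0)
  area
}

#' Point membership in the phantom cavity
#'
#' Closed-solid convention: points on the disc boundary or the rhombus
#' boundary belong to the cavity; the open rhombus interior is the "bite"
#' removed from the disc.  Vectorized over coordinates (recycled).
#'
#' @param geom an `rv_phantom`.
#' @param x,y,z coordinates in cm.
#' @return Logical vector.
#' @export
contains_point <- function(geom, x, y, z) {
  if (!inherits(geom, "rv_phantom")) stop("'geom' must be an rv_phantom")
  n <- max(length(x), length(y), length(z))
  x <- rep_len(x, n); y <- rep_len(y, n); z <- rep_len(z, n)
  sh <- geom$shape; D <- geom$D; L <- geom$L
  s <- 1 - (1 - sh$alpha) * z / L
  in_z <- z >= 0 & z <= L
  # scale back to the base plane (s >= alpha > 0 whenever in_z)
  u <- ifelse(in_z, x / s, Inf)
  v <- ifelse(in_z, y / s, Inf)
  r2 <- (sh$beta * D / 2)^2
  in_disc <- u^2 + v^2 <= r2
  # rhombus centered at (D/2, 0) with half-diagonals p0*D/2 (x), q0*D/2 (y);
  # open interior; degenerate (p0 or q0 = 0) removes nothing
  if (sh$p0 > 0 && sh$q0 > 0) {
    in_rhomb <- abs(u - D / 2) / (sh$p0 * D / 2) +
      abs(v) / (sh$q0 * D / 2) < 1
  } else {
    in_rhomb <- rep(FALSE, n)
  }
  inside <- in_z & in_disc & !in_rhomb
  patch <- rvot_patch(geom)
  if (!is.null(patch)) {
    in_app <- z >= 0 & z <= patch$h & y >= patch$yc &
      x^2 + (y - patch$yc)^2 <= patch$radius^2
    inside <- inside | in_app
  }
  inside
}

#' Monte-Carlo volume estimate
#'
#' Uniform rejection sampling over the bounding box of the solid; an unbiased
#' estimator reported with its binomial standard error.  Reproducible for a
#' fixed seed (the caller's random-number state is preserved).
#'
#' @param geom an `rv_phantom`.
#' @param n number of sample points (>= 1).
#' @param seed integer seed.
#' @return A list of class `rv_mc_volume`: `volume` (mL), `se` (mL), `n`.
#' @export
monte_carlo_volume <- function(geom, n, seed) {
  if (!inherits(geom, "rv_phantom")) stop("'geom' must be an rv_phantom")
  stopifnot(n >= 1)
  r <- geom$shape$beta * geom$D / 2
  ymax <- r
  xmax <- r
  patch <- rvot_patch(geom)
  if (!is.null(patch)) {
    ymax <- max(ymax, patch$yc + patch$radius)
    xmax <- max(xmax, patch$radius)
  }
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  x <- stats::runif(n, -xmax, xmax)
  y <- stats::runif(n, -r, ymax)
  z <- stats::runif(n, 0, geom$L)
  box <- (2 * xmax) * (ymax + r) * geom$L
  p <- mean(contains_point(geom, x, y, z))
  structure(list(volume = box * p,
                 se = box * sqrt(p * (1 - p) / n),
                 n = n),
            class = "rv_mc_volume")
}

#' @export
print.rv_mc_volume <- function(x, ...) {
  cat(sprintf("Monte-Carlo volume: %.3f mL (SE %.3f, n = %d)\n",
              x$volume, x$se, x$n))
  invisible(x)
}

#' Long-axis (four-chamber analog) section of the phantom
#'
#' The section of the cavity by the x-z plane is a trapezoid whose basal
#' width is exactly `D` by construction: the disc chord of length
#' `(1 + p0) * D` loses the rhombus extent `p0 * D`, leaving `D` regardless
#' of `p0` and `q0`.  The widths are computed from the geometry, not assumed.
#'
#' @param geom an `rv_phantom`.
#' @return A list: `basal_width`, `apical_width`, `height` (cm).
#' @export
long_axis_section <- function(geom) {
  if (!inherits(geom, "rv_phantom")) stop("'geom' must be an rv_phantom")
  sh <- geom$shape
  # chord through the cavity along the x axis at z = 0:
  # [-beta*D/2, beta*D/2] minus the open rhombus interval
  # (beta*D/2 - p0*D, beta*D/2)
  chord <- (sh$beta - sh$p0) * geom$D
  list(basal_width = chord,
       apical_width = sh$alpha * chord,
       height = geom$L)
}

#' Serialize a phantom to a flat record
#'
#' @param geom an `rv_phantom`.
#' @return A named list `{alpha, p0, q0, D_cm, L_cm, rvot_f, rvot_hfrac}`
#'   (JSON-compatible; `rvot_f = 0` when no appendage is present).
#' @export
geom_to_record <- function(geom) {
  if (!inherits(geom, "rv_phantom")) stop("'geom' must be an rv_phantom")
  list(alpha = geom$shape$alpha, p0 = geom$shape$p0, q0 = geom$shape$q0,
       D_cm = geom$D, L_cm = geom$L,
       rvot_f = if (is.null(geom$rvot)) 0 else geom$rvot$f,
       rvot_hfrac = if (is.null(geom$rvot)) 0.3 else geom$rvot$h_frac)
}

#' Deserialize a phantom from a flat record
#'
#' @param record a named list as produced by [geom_to_record()].
#' @return An `rv_phantom`.
#' @export
record_to_geom <- function(record) {
  need <- c("alpha", "p0", "q0", "D_cm", "L_cm", "rvot_f", "rvot_hfrac")
  if (!all(need %in% names(record)))
    stop("record must contain fields: ", paste(need, collapse = ", "))
  rvot <- if (record$rvot_f > 0)
    rvot_spec(record$rvot_f, record$rvot_hfrac) else NULL
  phantom_geometry(shape_params(record$alpha, record$p0, record$q0),
                   D = record$D_cm, L = record$L_cm, rvot = rvot)
}
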