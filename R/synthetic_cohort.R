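#' Configuration of a virtual patient cohort
#'
#' Default distributions follow the published cohort statistics of a typical
#' adult CMR referral population: basal diameter Dd ~ N(4.2, 0.6) cm,
#' baso-apical length Ld ~ N(7.7, 1.1) cm, 70% male, BSA ~ N(1.99, 0.2) m^2
#' (mean implied by the indexed/non-indexed volume pair 162.6 mL and
#' 81.7 mL/m^2).  Contraction is modeled by fractional shortenings `fD`, `fL`
#' (so that `Ds = Dd * (1 - fD)`, `Ls = Ld * (1 - fL)`), centered on the
#' values implied by the cohort means Ds = 3.5 cm and Ls = 6.5 cm; modeling
#' the shortenings rather than the systolic dimensions themselves induces the
#' physiologic correlation between the two cardiac phases.
#'
#' Phase-specific base shapes default to a diastolic shape calibrated to a
#' true volume coefficient of 1.05 and a more crescent-like systolic shape
#' calibrated to 0.95 — both below the assumed formula constant 1.21 — and
#' the outflow-tract fraction defaults to 0.10 of total volume.  Together
#' these make the cone-pyramid formula overestimate volumes (systolic more
#' than diastolic) and underestimate ejection fraction, the bias pattern the
#' method shows against disk-summation volumetry in practice.
#'
#' @param n number of subjects (>= 1).
#' @param seed integer seed (mandatory; all cohort randomness derives from it).
#' @param Dd_mean,Dd_sd diastolic basal diameter distribution, cm.
#' @param Ld_mean,Ld_sd diastolic baso-apical length distribution, cm.
#' @param fD_mean,fD_sd fractional basal-diameter shortening distribution.
#' @param fL_mean,fL_sd fractional longitudinal shortening distribution.
#' @param bsa_mean,bsa_sd body surface area distribution, m^2.
#' @param male_frac fraction of male subjects.
#' @param shape_ed,shape_es base [shape_params()] for end-diastole and
#'   end-systole.
#' @param jitter_alpha_sd,jitter_q0_sd per-subject Gaussian jitter SDs applied
#'   to `alpha` and `q0` of both phase shapes (`p0` is kept at the base value,
#'   so jitter perturbs the true volume coefficient).
#' @param rvot_f_mean,rvot_f_sd distribution of the outflow-tract volume
#'   fraction (truncated to [0, 0.3]).
#' @param rvot_hfrac axial extent of the outflow-tract appendage as a
#'   fraction of `L`.
#' @param noise_sd observer measurement noise SD per linear measurement, cm.
#' @param observer2_bias additive bias of the second observer on every linear
#'   measurement, cm (inter-observer systematic difference).
#' @param slice_thickness short-axis slice thickness, cm (default 0.8).
#' @param pixel_size in-plane pixel size, cm (default 0.1).
#' @return An object of class `rv_cohort_config`.
#' @seealso [sample_cohort()], [ideal_config()]
#' @export
cohort_config <- function(n,
                          seed,
                          Dd_mean = 4.2, Dd_sd = 0.6,
                          Ld_mean = 7.7, Ld_sd = 1.1,
                          fD_mean = 1 - 3.5 / 4.2, fD_sd = 0.05,
                          fL_mean = 1 - 6.5 / 7.7, fL_sd = 0.05,
                          bsa_mean = 1.99, bsa_sd = 0.2,
                          male_frac = 0.70,
                          shape_ed = calibrate_shape(0.30, 0.90, 1.05),
                          shape_es = calibrate_shape(0.25, 0.95, 0.95),
                          jitter_alpha_sd = 0.03,
                          jitter_q0_sd = 0.03,
                          rvot_f_mean = 0.10, rvot_f_sd = 0.03,
                          rvot_hfrac = 0.3,
                          noise_sd = 0.1,
                          observer2_bias = 0.15,
                          slice_thickness = 0.8,
                          pixel_size = 0.1) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1,
            is.numeric(seed), length(seed) == 1L)
  sds <- c(Dd_sd, Ld_sd, fD_sd, fL_sd, bsa_sd, jitter_alpha_sd,
           jitter_q0_sd, rvot_f_sd, noise_sd)
  if (any(!is.finite(sds)) || any(sds < 0))
    stop("all standard deviations must be finite and >= 0")
  if (slice_thickness <= 0 || pixel_size <= 0)
    stop("'slice_thickness' and 'pixel_size' must be > 0")
  if (male_frac < 0 || male_frac > 1) stop("'male_frac' must be in [0, 1]")
  stopifnot(inherits(shape_ed, "rv_shape"), inherits(shape_es, "rv_shape"))
  structure(list(
    n = as.integer(n), seed = as.integer(seed),
    Dd_mean = Dd_mean, Dd_sd = Dd_sd, Ld_mean = Ld_mean, Ld_sd = Ld_sd,
    fD_mean = fD_mean, fD_sd = fD_sd, fL_mean = fL_mean, fL_sd = fL_sd,
    bsa_mean = bsa_mean, bsa_sd = bsa_sd, male_frac = male_frac,
    shape_ed = shape_ed, shape_es = shape_es,
    jitter_alpha_sd = jitter_alpha_sd, jitter_q0_sd = jitter_q0_sd,
    rvot_f_mean = rvot_f_mean, rvot_f_sd = rvot_f_sd,
    rvot_hfrac = rvot_hfrac,
    noise_sd = noise_sd, observer2_bias = observer2_bias,
    slice_thickness = slice_thickness, pixel_size = pixel_size),
    class = "rv_cohort_config")
}

#' Idealized cohort configuration
#'
#' Same between-subject variability in size as the default cohort but no
#' observer noise, no shape jitter, no outflow-tract appendage, and both
#' phase shapes calibrated exactly to the formula constant 1.21.  Under this
#' configuration the cone-pyramid formula is exact by construction, so any
#' residual disagreement with disk summation isolates the rasterization /
#' slicing error of the standard method.
#'
#' @param n number of subjects.
#' @param seed integer seed.
#' @param ... further overrides passed to [cohort_config()].
#' @return An `rv_cohort_config`.
#' @export
ideal_config <- function(n, seed, ...) {
  k121 <- calibrate_shape(0.30, 0.90, 1.21)
  cohort_config(n = n, seed = seed,
                shape_ed = k121, shape_es = k121,
                jitter_alpha_sd = 0, jitter_q0_sd = 0,
                rvot_f_mean = 0, rvot_f_sd = 0,
                noise_sd = 0, observer2_bias = 0, ...)
}

# Internal: clamp draws to a physical range, warning once per column.
clamp_warn <- function(x, lo, hi, what) {
  bad <- x < lo | x > hi
  if (any(bad)) {
    warning(sprintf("%d %s draw(s) truncated to [%g, %g]",
                    sum(bad), what, lo, hi), call. = FALSE)
    x <- pmin(pmax(x, lo), hi)
  }
  x
}

#' Sample a virtual cohort
#'
#' Draws per-subject linear dimensions, shortenings, BSA, sex, per-subject
#' shape jitter and outflow-tract fraction from the configured distributions.
#' Non-physical draws are truncated to fixed floors with a warning (never
#' silently resampled, preserving seed reproducibility).  True end-diastolic
#' and end-systolic volumes are the closed-form volumes of the subject's
#' phantom pair.
#'
#' @param config an [cohort_config()] object.
#' @return A data.frame of class `rv_cohort`, one row per subject, with
#'   columns `id`, `sex`, `bsa_m2`, `Dd_cm`, `Ds_cm`, `Ld_cm`, `Ls_cm`,
#'   `fD`, `fL`, per-phase shape parameters, `rvot_f`, `true_edv_ml`,
#'   `true_esv_ml`.  The configuration is attached as attribute `config`.
#' @export
sample_cohort <- function(config) {
  if (!inherits(config, "rv_cohort_config"))
    stop("'config' must be an rv_cohort_config")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)
  n <- config$n
  Dd <- clamp_warn(stats::rnorm(n, config$Dd_mean, config$Dd_sd),
                   0.5, Inf, "Dd")
  Ld <- clamp_warn(stats::rnorm(n, config$Ld_mean, config$Ld_sd),
                   1.0, Inf, "Ld")
  fD <- clamp_warn(stats::rnorm(n, config$fD_mean, config$fD_sd),
                   0, 0.9, "fD")
  fL <- clamp_warn(stats::rnorm(n, config$fL_mean, config$fL_sd),
                   0, 0.9, "fL")
  bsa <- clamp_warn(stats::rnorm(n, config$bsa_mean, config$bsa_sd),
                    0.5, Inf, "BSA")
  sex <- ifelse(stats::runif(n) < config$male_frac, "male", "female")
  jitter_shape <- function(base) {
    alpha <- clamp_warn(base$alpha + stats::rnorm(n, 0, config$jitter_alpha_sd),
                        0.05, 1, "alpha jitter")
    qmax <- sqrt((1 + base$p0)^2 - 1)
    q0 <- clamp_warn(base$q0 + stats::rnorm(n, 0, config$jitter_q0_sd),
                     0, qmax, "q0 jitter")
    list(alpha = alpha, p0 = rep(base$p0, n), q0 = q0)
  }
  ed <- jitter_shape(config$shape_ed)
  es <- jitter_shape(config$shape_es)
  rvot_f <- if (config$rvot_f_mean == 0 && config$rvot_f_sd == 0) {
    rep(0, n)
  } else {
    clamp_warn(stats::rnorm(n, config$rvot_f_mean, config$rvot_f_sd),
               0, 0.3, "rvot_f")
  }
  out <- data.frame(
    id = sprintf("S%03d", seq_len(n)),
    sex = sex, bsa_m2 = bsa,
    Dd_cm = Dd, Ds_cm = Dd * (1 - fD),
    Ld_cm = Ld, Ls_cm = Ld * (1 - fL),
    fD = fD, fL = fL,
    alpha_ed = ed$alpha, p0_ed = ed$p0, q0_ed = ed$q0,
    alpha_es = es$alpha, p0_es = es$p0, q0_es = es$q0,
    rvot_f = rvot_f,
    stringsAsFactors = FALSE)
  vols <- vapply(seq_len(n), function(i) {
    pair <- phantom_pair(out[i, ])
    c(analytic_volume(pair$ed), analytic_volume(pair$es))
  }, numeric(2))
  out$true_edv_ml <- vols[1, ]
  out$true_esv_ml <- vols[2, ]
  attr(out, "config") <- config
  class(out) <- c("rv_cohort", "data.frame")
  out
}

#' Build the end-diastolic and end-systolic phantoms of one subject
#'
#' @param subject one row of an [sample_cohort()] table (or any list with the
#'   same fields).
#' @return A list with elements `ed` and `es`, both [phantom_geometry()]
#'   objects sharing the subject's outflow-tract fraction.  When both phases
#'   share the same shape and there is no appendage, the true ejection
#'   fraction is exactly `100 * (1 - (1 - fD)^2 * (1 - fL))`.
#' @export
phantom_pair <- function(subject) {
  s <- as.list(subject)
  rvot <- if (!is.null(s$rvot_f) && s$rvot_f > 0) {
    hf <- if (!is.null(s$rvot_hfrac)) s$rvot_hfrac else 0.3
    rvot_spec(s$rvot_f, hf)
  } else NULL
  list(
    ed = phantom_geometry(shape_params(s$alpha_ed, s$p0_ed, s$q0_ed),
                          D = s$Dd_cm, L = s$Ld_cm, rvot = rvot),
    es = phantom_geometry(shape_params(s$alpha_es, s$p0_es, s$q0_es),
                          D = s$Ds_cm, L = s$Ls_cm, rvot = rvot))
}

#' Simulate noisy observer measurements of one subject
#'
#' Observed value = true value + independent Gaussian noise per observer and
#' replicate, plus an optional per-observer additive bias.  Draws below the
#' 0.1 cm floor are truncated there with a warning.
#'
#' @param subject one cohort row.
#' @param noise_sd Gaussian noise SD per measurement, cm.
#' @param n_observers number of observers.
#' @param n_replicates replicates per observer.
#' @param seed integer seed.
#' @param observer_bias numeric vector (recycled to `n_observers`) of additive
#'   biases in cm applied to all four measurements of each observer.
#' @return A data.frame with columns `observer`, `replicate`, `Dd_cm`,
#'   `Ds_cm`, `Ld_cm`, `Ls_cm`.
#' @export
simulate_measurements <- function(subject, noise_sd, n_observers = 1,
                                  n_replicates = 1, seed,
                                  observer_bias = 0) {
  stopifnot(noise_sd >= 0, n_observers >= 1, n_replicates >= 1)
  s <- as.list(subject)
  bias <- rep_len(observer_bias, n_observers)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  grid <- expand.grid(replicate = seq_len(n_replicates),
                      observer = seq_len(n_observers))
  m <- nrow(grid)
  truth <- c(s$Dd_cm, s$Ds_cm, s$Ld_cm, s$Ls_cm)
  obs <- matrix(stats::rnorm(4 * m, sd = noise_sd), nrow = m, ncol = 4,
                byrow = FALSE)
  obs <- sweep(obs, 2, truth, `+`) + bias[grid$observer]
  if (any(obs < 0.1)) {
    warning(sprintf("%d measurement(s) truncated at the 0.1 cm floor",
                    sum(obs < 0.1)), call. = FALSE)
    obs[obs < 0.1] <- 0.1
  }
  data.frame(observer = grid$observer, replicate = grid$replicate,
             Dd_cm = obs[, 1], Ds_cm = obs[, 2],
             Ld_cm = obs[, 3], Ls_cm = obs[, 4])
}

#' Construct a short-axis mask stack container
#'
#' @param masks list of binary (0/1) matrices on a common grid, ordered from
#'   base to apex.
#' @param pixel_size in-plane pixel size, cm.
#' @param slice_thickness slice thickness, cm.
#' @param phase `"ED"` or `"ES"`.
#' @return An object of class `rv_mask_stack`.
#' @export
mask_stack <- function(masks, pixel_size, slice_thickness, phase = "ED") {
  if (!is.list(masks) || length(masks) < 1)
    stop("'masks' must be a non-empty list of matrices")
  dims <- vapply(masks, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all masks must share the same grid")
  vals <- unlist(masks, use.names = FALSE)
  if (!all(vals %in% c(0, 1))) stop("mask values must be 0 or 1")
  if (pixel_size <= 0 || slice_thickness <= 0)
    stop("'pixel_size' and 'slice_thickness' must be > 0")
  phase <- match.arg(phase, c("ED", "ES"))
  structure(list(masks = masks, pixel_size = pixel_size,
                 slice_thickness = slice_thickness, phase = phase),
            class = "rv_mask_stack")
}

#' @export
print.rv_mask_stack <- function(x, ...) {
  cat(sprintf("Short-axis mask stack (%s): %d slices of %dx%d, pixel %.2f cm, thickness %.2f cm\n",
              x$phase, length(x$masks), nrow(x$masks[[1]]),
              ncol(x$masks[[1]]), x$pixel_size, x$slice_thickness))
  invisible(x)
}

#' Rasterize a phantom into a short-axis mask stack
#'
#' Emulates a contiguous stack of segmented short-axis slices.  Slice `i`
#' (i = 1..ceiling(L / t)) is the membership mask sampled at pixel centers on
#' the mid-plane `z = (i - 0.5) * t`; a mid-plane beyond the apex yields an
#' empty mask.  The grid is sized to the solid's bounding box plus `margin`.
#'
#' @param geom an `rv_phantom`.
#' @param slice_thickness slice thickness `t`, cm.
#' @param pixel_size pixel size, cm.
#' @param phase phase tag for the stack.
#' @param margin grid margin around the bounding box, cm.
#' @param grid_half_width optional fixed grid half-width, cm; rejected if it
#'   does not cover the solid.
#' @return An [mask_stack()] object.
#' @export
rasterize_short_axis <- function(geom, slice_thickness = 0.8,
                                 pixel_size = 0.1, phase = "ED",
                                 margin = 0.2, grid_half_width = NULL) {
  if (!inherits(geom, "rv_phantom")) stop("'geom' must be an rv_phantom")
  if (slice_thickness <= 0 || pixel_size <= 0)
    stop("'slice_thickness' and 'pixel_size' must be > 0")
  r <- geom$shape$beta * geom$D / 2
  ymax <- r; xmax <- r
  patch <- rvot_patch(geom)
  if (!is.null(patch)) {
    ymax <- max(ymax, patch$yc + patch$radius)
    xmax <- max(xmax, patch$radius)
  }
  half <- max(xmax, ymax, r) + margin
  if (!is.null(grid_half_width)) {
    if (grid_half_width < max(xmax, ymax, r))
      stop("grid too small: half-width ", grid_half_width,
           " cm does not cover the solid (needs >= ",
           signif(max(xmax, ymax, r), 4), " cm)")
    half <- grid_half_width
  }
  npx <- ceiling(2 * half / pixel_size)
  centers <- -half + (seq_len(npx) - 0.5) * pixel_size
  xg <- rep(centers, times = npx)          # x varies over rows
  yg <- rep(centers, each = npx)           # y varies over columns
  n_slices <- ceiling(geom$L / slice_thickness)
  masks <- lapply(seq_len(n_slices), function(i) {
    z <- (i - 0.5) * slice_thickness
    matrix(as.integer(contains_point(geom, xg, yg, z)),
           nrow = npx, ncol = npx)
  })
  mask_stack(masks, pixel_size, slice_thickness, phase)
}

#' Rasterize the four-chamber (x-z plane) section of a phantom
#'
#' Rows run from the base (row 1, tricuspid plane) toward the apex; columns
#' span x.  The basal-row chord of the result equals the true basal diameter
#' `D` to within one pixel.
#'
#' @param geom an `rv_phantom`.
#' @param pixel_size pixel size, cm.
#' @param margin grid margin beyond the basal half-width, cm.
#' @return A binary integer matrix with attributes `pixel_size` and
#'   `x_origin` (x coordinate of the first column's pixel center).
#' @export
rasterize_long_axis <- function(geom, pixel_size = 0.05, margin = 0.2) {
  if (!inherits(geom, "rv_phantom")) stop("'geom' must be an rv_phantom")
  if (pixel_size <= 0) stop("'pixel_size' must be > 0")
  half <- geom$shape$beta * geom$D / 2 + margin
  npx <- ceiling(2 * half / pixel_size)
  xs <- -half + (seq_len(npx) - 0.5) * pixel_size
  nz <- ceiling(geom$L / pixel_size)
  zs <- (seq_len(nz) - 0.5) * pixel_size
  mask <- matrix(0L, nrow = nz, ncol = npx)
  for (i in seq_len(nz))
    mask[i, ] <- as.integer(contains_point(geom, xs, 0, zs[i]))
  attr(mask, "pixel_size") <- pixel_size
  attr(mask, "x_origin") <- xs[1]
  mask
}
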