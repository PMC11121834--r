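# Shared fixtures and independent oracles.

# Shape whose closed-form coefficient is the formula constant 1.21.
shape_121 <- calibrate_shape(0.3, 0.9, 1.21)

phantom_at <- function(D = 4.2, L = 7.7, rvot = NULL, shape = shape_121) {
  phantom_geometry(shape, D, L, rvot = rvot)
}

# Independent route to the volume coefficient: difference of two classical
# frustum volumes (cone frustum minus rhomboid-pyramid frustum), rather than
# the factored closed form used by the implementation.
frustum_coefficient <- function(alpha, p0, q0) {
  R <- (1 + p0) / 2                       # cone base radius / D
  v_cone <- pi * R^2 * (1 + alpha + alpha^2) / 3
  A <- p0 * q0 / 2                        # pyramid base area / D^2
  v_pyr <- (A + sqrt(A * alpha^2 * A) + alpha^2 * A) / 3
  v_cone - v_pyr
}

# Bisection oracle for the calibrated rhombus diagonal.
bisect_p0 <- function(alpha, q0, target, tol = 1e-12) {
  f <- function(p0) frustum_coefficient(alpha, p0, q0) - target
  lo <- 0; hi <- 3
  stopifnot(f(lo) <= 0, f(hi) >= 0)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Brute-force AUC: concordance over all positive/negative pairs, ties 1/2.
brute_auc <- function(scores, labels, direction = "higher") {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  if (direction == "lower") {
    pos <- -pos
    neg <- -neg
  }
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Random valid shape parameters (rhombus inscribed by construction).
random_shape <- function() {
  alpha <- runif(1, 0.1, 1)
  p0 <- runif(1, 0, 1.5)
  qmax <- sqrt((1 + p0)^2 - 1)
  q0 <- runif(1, 0, min(qmax, 1.5))
  shape_params(alpha, p0, q0)
}
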