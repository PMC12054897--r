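#' Parametric tuning-curve model
#'
#' Constructs a tuning-curve family shared by all neurons of a population.
#' Two families are supported:
#' \describe{
#'   \item{\code{"rectified_cosine"}}{\eqn{f(\phi,\theta) = A/(1-c)\,
#'     [\cos(\phi-\theta) - c]_+}. The threshold \eqn{c \in [-1, 1)} sets the
#'     tuning width: the curve is positive on an arc of width
#'     \eqn{2\cos^{-1}(c)} around the preferred angle \eqn{\phi}, and the
#'     peak value is exactly \eqn{A}. Large \eqn{c} gives narrow tuning;
#'     \eqn{c = -1} gives a full (non-rectified) cosine.}
#'   \item{\code{"von_mises"}}{\eqn{f(\phi,\theta) = A\,
#'     \exp[(\cos(\phi-\theta)-1)/w]}, a smooth circular bell of width
#'     \eqn{w > 0}, normalized so the peak equals \eqn{A}.}
#' }
#' An optional constant \code{baseline} is added to the rate (default 0).
#'
#' @param family \code{"rectified_cosine"} or \code{"von_mises"}.
#' @param A peak response amplitude (rate units), > 0.
#' @param c rectification threshold, \eqn{-1 \le c < 1}
#'   (rectified cosine only).
#' @param w tuning width, > 0 (von Mises only).
#' @param baseline constant background rate added to the tuning curve.
#' @return an object of class \code{"tuning_model"}.
#' @examples
#' tm <- tuning_model("rectified_cosine", A = 1, c = -0.1)
#' tuning_rate(tm, phi = pi / 2, theta = pi / 2)  # peak = A
#' @export
tuning_model <- function(family = c("rectified_cosine", "von_mises"),
                         A = 1, c = -0.1, w = NULL, baseline = 0) {
  family <- match.arg(family)
  if (!is.numeric(A) || length(A) != 1L || !is.finite(A) || A <= 0)
    stop("'A' must be a single positive number", call. = FALSE)
  if (!is.numeric(baseline) || length(baseline) != 1L || !is.finite(baseline))
    stop("'baseline' must be a single finite number", call. = FALSE)
  if (family == "rectified_cosine") {
    if (!is.numeric(c) || length(c) != 1L || !is.finite(c) ||
        c < -1 || c >= 1)
      stop("threshold 'c' must satisfy -1 <= c < 1", call. = FALSE)
    w <- NULL
  } else {
    if (is.null(w) || !is.numeric(w) || length(w) != 1L ||
        !is.finite(w) || w <= 0)
      stop("width 'w' must be a single number > 0", call. = FALSE)
    c <- NULL
  }
  structure(list(family = family, A = A, c = c, w = w, baseline = baseline),
            class = "tuning_model")
}

#' @export
print.tuning_model <- function(x, ...) {
  if (x$family == "rectified_cosine")
    cat(sprintf("Rectified cosine tuning: A = %g, c = %g", x$A, x$c))
  else
    cat(sprintf("Von Mises tuning: A = %g, w = %g", x$A, x$w))
  if (x$baseline != 0) cat(sprintf(", baseline = %g", x$baseline))
  cat("\n")
  invisible(x)
}

# rate as a function of the (possibly rescaled) angular offset delta
.rate_from_delta <- function(model, delta) {
  if (model$family == "rectified_cosine")
    model$A / (1 - model$c) * pmax(cos(delta) - model$c, 0) + model$baseline
  else
    model$A * exp((cos(delta) - 1) / model$w) + model$baseline
}

# derivative of the rate w.r.t. theta, delta = phi - theta.
# At the rectification kink (cos(delta) == c) the derivative is defined as 0,
# the limit from the inactive side; inactive neurons have exactly zero slope.
.deriv_from_delta <- function(model, delta) {
  if (model$family == "rectified_cosine") {
    d <- model$A / (1 - model$c) * sin(delta)
    d[cos(delta) <= model$c] <- 0
    d
  } else {
    model$A * exp((cos(delta) - 1) / model$w) * sin(delta) / model$w
  }
}

#' Evaluate a tuning curve
#'
#' Mean response of a neuron with preferred angle \code{phi} to stimulus
#' \code{theta}. Vectorized over \code{theta} (and \code{phi}, recycled);
#' 2\eqn{\pi}-periodic in both arguments.
#'
#' @param model a \code{\link{tuning_model}}.
#' @param phi preferred angle(s), radians.
#' @param theta stimulus angle(s), radians.
#' @return mean rate(s), same length as the recycled arguments.
#' @export
tuning_rate <- function(model, phi, theta) {
  stopifnot(inherits(model, "tuning_model"))
  if (!all(is.finite(phi)) || !all(is.finite(theta)))
    stop("angles must be finite", call. = FALSE)
  .rate_from_delta(model, phi - theta)
}

#' Derivative of a tuning curve with respect to the stimulus
#'
#' Analytic derivative \eqn{f'(\theta)} used in the Fisher information. For
#' rectified-cosine tuning the derivative is 0 wherever
#' \eqn{\cos(\phi-\theta) \le c}; at the rectification kink the inactive-side
#' limit (0) is used, so inactive neurons contribute no information.
#'
#' @inheritParams tuning_rate
#' @return rate change per radian, vectorized like \code{\link{tuning_rate}}.
#' @export
tuning_derivative <- function(model, phi, theta) {
  stopifnot(inherits(model, "tuning_model"))
  .deriv_from_delta(model, phi - theta)
}

#' Build a neuron population
#'
#' A population is an ordered set of neurons with equally spaced preferred
#' angles sharing one tuning model. Circular geometry places preferred angles
#' at \eqn{\phi_k = 2\pi k / N} (for \eqn{N = 4}: 90 degrees apart,
#' \eqn{\phi_k = k\pi/2}, as in the four-neuron cricket wind-direction
#' system). Linear geometry places neurons at \eqn{\phi_k = k d} on an
#' unbounded line; linear populations are only evaluated far from the array
#' ends.
#'
#' @param N number of neurons, >= 1.
#' @param geometry \code{"circular"} or \code{"linear"}.
#' @param tuning a \code{\link{tuning_model}}.
#' @param spacing inter-neuron spacing \eqn{d} (required for linear
#'   geometry).
#' @param tuning_scale for linear geometry, the spatial scale \eqn{s} of the
#'   tuning curve: the rate is evaluated at offset \eqn{(\phi - x)/s}, so a
#'   rectified cosine has support width \eqn{2 s \cos^{-1}(c)} on the
#'   stimulus axis. Defaults to \code{spacing}, which makes the tuning width
#'   proportional to the inter-neuron distance.
#' @return an object of class \code{"population"}.
#' @examples
#' pop <- build_population(4, tuning = tuning_model())
#' pop$phi  # pi/2, pi, 3*pi/2, 2*pi
#' @export
build_population <- function(N, geometry = c("circular", "linear"),
                             tuning = tuning_model(), spacing = NULL,
                             tuning_scale = NULL) {
  geometry <- match.arg(geometry)
  if (!is.numeric(N) || length(N) != 1L || N < 1 || N != round(N))
    stop("'N' must be a positive integer", call. = FALSE)
  stopifnot(inherits(tuning, "tuning_model"))
  N <- as.integer(N)
  if (geometry == "circular") {
    phi <- 2 * pi * seq_len(N) / N
    spacing <- 2 * pi / N
    tuning_scale <- 1
  } else {
    if (is.null(spacing) || !is.numeric(spacing) || spacing <= 0)
      stop("linear geometry requires a positive 'spacing'", call. = FALSE)
    phi <- spacing * seq_len(N)
    if (is.null(tuning_scale)) tuning_scale <- spacing
  }
  structure(list(N = N, phi = phi, geometry = geometry, spacing = spacing,
                 tuning = tuning, tuning_scale = tuning_scale),
            class = "population")
}

#' @export
print.population <- function(x, ...) {
  cat(sprintf("Population of %d neurons (%s geometry, spacing %.4g)\n",
              x$N, x$geometry, x$spacing))
  print(x$tuning)
  invisible(x)
}

#' Tuning-curve matrix of a population
#'
#' Evaluates every neuron's tuning curve at every stimulus.
#'
#' @param pop a \code{\link{build_population}} object.
#' @param theta stimulus angles (circular) or positions (linear).
#' @return an \code{N x length(theta)} matrix of mean rates.
#' @export
tuning_matrix <- function(pop, theta) {
  stopifnot(inherits(pop, "population"))
  .rate_from_delta(pop$tuning,
                   outer(pop$phi, theta, "-") / pop$tuning_scale)
}

#' Tuning-derivative matrix of a population
#'
#' @inheritParams tuning_matrix
#' @return an \code{N x length(theta)} matrix of derivatives w.r.t. the
#'   stimulus.
#' @export
tuning_deriv_matrix <- function(pop, theta) {
  stopifnot(inherits(pop, "population"))
  .deriv_from_delta(pop$tuning,
                    outer(pop$phi, theta, "-") / pop$tuning_scale) /
    pop$tuning_scale
}

#' Rescale a population to a new size
#'
#' Grows a circular population from \code{base$N} to \code{N_new} neurons
#' under one of three scaling rules:
#' \describe{
#'   \item{\code{"none"}}{only the density of preferred angles increases;
#'     the tuning model is untouched.}
#'   \item{\code{"amplitude"}}{the amplitude is multiplied by
#'     \code{base$N / N_new}, so the mean population activity
#'     \eqn{\int \sum_k f_k \, d\theta} is conserved exactly.}
#'   \item{\code{"width"}}{the tuning width shrinks so that the expected
#'     number of simultaneously active neurons stays constant. For the
#'     rectified cosine the active arc \eqn{2\cos^{-1}(c)} is scaled by
#'     \code{base$N / N_new} and solved for the new threshold. For von Mises
#'     tuning the width \eqn{w} is solved numerically (tolerance 1e-8) so
#'     that the summed tuning mass \eqn{\int \sum_k f_k \, d\theta} is
#'     conserved.}
#' }
#'
#' @param base a circular \code{\link{build_population}}.
#' @param N_new new neuron count, >= \code{base$N}.
#' @param mode \code{"none"}, \code{"amplitude"} or \code{"width"}.
#' @return a new \code{"population"} with \code{N_new} neurons.
#' @export
scale_population <- function(base, N_new,
                             mode = c("none", "amplitude", "width")) {
  mode <- match.arg(mode)
  stopifnot(inherits(base, "population"))
  if (base$geometry != "circular")
    stop("population scaling is defined for circular geometry", call. = FALSE)
  if (N_new < base$N)
    stop("'N_new' must be >= base$N", call. = FALSE)
  tun <- base$tuning
  if (N_new != base$N && mode == "amplitude") {
    tun$A <- tun$A * base$N / N_new
  } else if (N_new != base$N && mode == "width") {
    if (tun$family == "rectified_cosine") {
      arc_new <- acos(tun$c) * base$N / N_new
      c_new <- cos(arc_new)
      if (c_new >= 1)
        stop("width scaling infeasible: required threshold c >= 1",
             call. = FALSE)
      tun$c <- c_new
    } else {
      # conserve N * exp(-1/w) * I0(1/w), the per-period tuning mass / (2 pi A)
      g <- function(w) besselI(1 / w, 0, expon.scaled = TRUE)  # = e^{-1/w} I0(1/w)
      target <- g(tun$w) * base$N / N_new
      sol <- stats::uniroot(function(w) g(w) - target,
                            lower = tun$w * 1e-6, upper = tun$w,
                            tol = 1e-12)
      tun$w <- sol$root
    }
  }
  build_population(N_new, geometry = "circular", tuning = tun)
}

#' Observation-noise specification
#'
#' \code{"gaussian"}: each neuron's single-trial response is
#' \eqn{r_k = f_k(\theta) + \sigma\nu} with \eqn{\nu} i.i.d. standard
#' normal. \code{"poisson"}: responses are spike counts
#' \eqn{n_k \sim \mathrm{Poisson}(T f_k(\theta))}, where \eqn{T} is the
#' counting-window duration in the tuning curve's inverse-rate units;
#' decoders consume the counts together with \eqn{T}.
#'
#' @param kind \code{"gaussian"} or \code{"poisson"}.
#' @param sigma noise standard deviation, >= 0 (Gaussian).
#' @param window counting-window duration \eqn{T > 0} (Poisson).
#' @return an object of class \code{"noise_spec"}.
#' @export
noise_spec <- function(kind = c("gaussian", "poisson"), sigma = 0.1,
                       window = 1) {
  kind <- match.arg(kind)
  if (kind == "gaussian") {
    if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
        sigma < 0)
      stop("'sigma' must be a single number >= 0", call. = FALSE)
    window <- NULL
  } else {
    if (!is.numeric(window) || length(window) != 1L || !is.finite(window) ||
        window <= 0)
      stop("'window' must be a single number > 0", call. = FALSE)
    sigma <- NULL
  }
  structure(list(kind = kind, sigma = sigma, window = window),
            class = "noise_spec")
}

#' @export
print.noise_spec <- function(x, ...) {
  if (x$kind == "gaussian")
    cat(sprintf("Gaussian additive noise, sigma = %g\n", x$sigma))
  else
    cat(sprintf("Poisson spike-count noise, window T = %g\n", x$window))
  invisible(x)
}

#' Sample noisy population responses
#'
#' Draws \code{n_trials} independent single-trial response vectors to a
#' fixed stimulus. Gaussian noise returns rates
#' \eqn{r_k = f_k(\theta) + \sigma\nu}; Poisson noise returns spike counts
#' drawn from \eqn{\mathrm{Poisson}(T f_k(\theta))} (the counting window
#' \eqn{T} travels with the \code{noise} object into the decoders).
#' A given \code{seed} makes the output exactly reproducible.
#'
#' @param pop a \code{\link{build_population}}.
#' @param noise a \code{\link{noise_spec}}.
#' @param theta stimulus angle (radians).
#' @param n_trials number of trials, >= 1.
#' @param seed optional integer seed.
#' @return an \code{n_trials x N} numeric matrix (rates or counts).
#' @export
sample_responses <- function(pop, noise, theta, n_trials, seed = NULL) {
  stopifnot(inherits(pop, "population"), inherits(noise, "noise_spec"))
  if (n_trials < 1) stop("'n_trials' must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  f <- drop(tuning_matrix(pop, theta))
  if (noise$kind == "gaussian") {
    matrix(rep(f, each = n_trials), ncol = pop$N) +
      noise$sigma * matrix(stats::rnorm(n_trials * pop$N), ncol = pop$N)
  } else {
    if (any(f < 0))
      stop("Poisson noise requires nonnegative tuning values", call. = FALSE)
    matrix(stats::rpois(n_trials * pop$N, rep(noise$window * f,
                                              each = n_trials)),
           ncol = pop$N)
  }
}
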