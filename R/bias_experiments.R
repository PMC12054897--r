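#' Derive a per-condition seed from a root seed
#'
#' Each stimulus angle (or condition) of an experiment gets its own
#' deterministic RNG stream so that full bias curves are reproducible and
#' individual angles can be recomputed in isolation.
#'
#' @param root root integer seed of the experiment.
#' @param i condition index, >= 0.
#' @return a derived integer seed in \code{[1, 2^31 - 2]}.
#' @export
derive_seed <- function(root, i) {
  as.integer((abs(root) + 7919 * i) %% 2147483646L + 1L)
}

.config_fingerprint <- function(pop, noise, decoder, grid = NULL) {
  tun <- pop$tuning
  paste0(tun$family, "(A=", tun$A,
         if (!is.null(tun$c)) paste0(",c=", tun$c),
         if (!is.null(tun$w)) paste0(",w=", tun$w),
         if (tun$baseline != 0) paste0(",b0=", tun$baseline),
         ") N=", pop$N, " ", pop$geometry, " ",
         noise$kind,
         if (!is.null(noise$sigma)) paste0("(sigma=", noise$sigma, ")"),
         if (!is.null(noise$window)) paste0("(T=", noise$window, ")"),
         " decoder=", decoder,
         if (!is.null(grid)) paste0(" grid=", length(grid$theta)))
}

#' Monte-Carlo bias and variance of a decoder at one stimulus
#'
#' Samples \code{n_trials} noisy responses to the fixed stimulus, decodes
#' every trial, and returns the bias \eqn{b(\Theta) =
#' \langle\hat\theta\rangle - \Theta} together with the trial-to-trial
#' variance. All deviations \eqn{\hat\theta - \Theta} are wrapped into
#' \eqn{(-\pi, \pi]} before averaging, which coincides with ordinary
#' statistics for stimuli away from the circular discontinuity.
#'
#' @param pop a \code{\link{build_population}}.
#' @param noise a \code{\link{noise_spec}}.
#' @param theta true stimulus angle, radians.
#' @param decoder \code{"pv"}, \code{"ml"} or \code{"bayes"}.
#' @param n_trials number of Monte-Carlo trials (>= 100).
#' @param seed integer seed for this condition.
#' @param grid a \code{\link{decode_grid}} for the grid-based decoders.
#' @return list with \code{bias} (radians), \code{variance} (radians^2),
#'   \code{sem} (Monte-Carlo standard error of the bias,
#'   \eqn{\sqrt{\mathrm{var}/n}}) and \code{n_trials}.
#' @examples
#' pop <- build_population(4, tuning = tuning_model())
#' estimate_bias_variance(pop, noise_spec("gaussian", sigma = 0.1),
#'                        theta = pi / 2 - 0.1, decoder = "bayes",
#'                        n_trials = 500, seed = 1,
#'                        grid = decode_grid(1000))
#' @export
estimate_bias_variance <- function(pop, noise, theta,
                                   decoder = c("bayes", "ml", "pv"),
                                   n_trials = 10000, seed = 1,
                                   grid = decode_grid()) {
  decoder <- match.arg(decoder)
  if (n_trials < 100) stop("'n_trials' must be >= 100", call. = FALSE)
  R <- sample_responses(pop, noise, theta, n_trials, seed = seed)
  est <- decode_trials(R, pop, noise, grid, decoder)
  d <- wrap_angle(est - theta)
  v <- stats::var(d)
  list(bias = mean(d), variance = v, sem = sqrt(v / n_trials),
       n_trials = n_trials)
}

#' Bias curve across stimulus angles
#'
#' Runs \code{\link{estimate_bias_variance}} at every angle of a stimulus
#' grid (Monte-Carlo backend, per-angle seeds derived from \code{seed}), or
#' evaluates the deterministic analytical approximation
#' (\code{backend = "approx"}, Bayesian decoder only).
#'
#' @inheritParams estimate_bias_variance
#' @param thetas stimulus angles; keep them away from the \eqn{0/2\pi}
#'   discontinuity.
#' @param backend \code{"mc"} (Monte Carlo) or \code{"approx"}
#'   (\code{\link{approx_bias}} quadrature; \code{bias_sem} is then 0).
#' @param n_quad quadrature points for the approximation backend.
#' @param approx_with_variance if \code{TRUE}, the approximation backend
#'   also fills the variance column via \code{\link{approx_variance}}
#'   (a double quadrature per angle, considerably slower).
#' @return a data frame of class \code{"bias_curve"} with columns
#'   \code{theta}, \code{bias}, \code{variance}, \code{n_trials},
#'   \code{bias_sem}; attributes \code{decoder} and \code{config}.
#' @export
bias_curve <- function(pop, noise, thetas, decoder = c("bayes", "ml", "pv"),
                       n_trials = 10000, seed = 1, grid = decode_grid(),
                       backend = c("mc", "approx"), n_quad = 2001,
                       approx_with_variance = FALSE) {
  decoder <- match.arg(decoder)
  backend <- match.arg(backend)
  if (backend == "approx") {
    if (decoder != "bayes")
      stop("the approximation backend is defined for the Bayesian decoder",
           call. = FALSE)
    bias <- vapply(thetas, function(t)
      approx_bias(pop, noise, t, n_quad)$bias, numeric(1))
    variance <- if (approx_with_variance)
      vapply(thetas, function(t)
        approx_variance(pop, noise, t, n_quad)$variance, numeric(1))
    else rep(NA_real_, length(thetas))
    out <- data.frame(theta = thetas, bias = bias, variance = variance,
                      n_trials = Inf, bias_sem = 0)
  } else {
    rows <- lapply(seq_along(thetas), function(i)
      estimate_bias_variance(pop, noise, thetas[i], decoder, n_trials,
                             seed = derive_seed(seed, i), grid = grid))
    out <- data.frame(theta = thetas,
                      bias = vapply(rows, `[[`, numeric(1), "bias"),
                      variance = vapply(rows, `[[`, numeric(1), "variance"),
                      n_trials = n_trials,
                      bias_sem = vapply(rows, `[[`, numeric(1), "sem"))
  }
  attr(out, "decoder") <- decoder
  attr(out, "backend") <- backend
  attr(out, "config") <- .config_fingerprint(pop, noise, decoder,
                                             if (backend == "mc") grid)
  attr(out, "seed") <- if (backend == "mc") seed else NA_integer_
  class(out) <- c("bias_curve", "data.frame")
  out
}

#' Minimum and maximum bias over a window left of a preferred angle
#'
#' Summarizes a bias curve by its extreme values over the half-interval to
#' the left of a preferred angle (default \eqn{-\pi/4 \le \Theta - \phi
#' \le 0} for the four-neuron population). On this side, a positive bias
#' corresponds to attraction toward the preferred stimulus and a negative
#' bias to repulsion, so \code{min_bias >= 0} means a purely attractive
#' profile, \code{max_bias <= 0} purely repulsive, and
#' \code{min_bias < 0 < max_bias} a bi-phasic one.
#'
#' @param curve a \code{\link{bias_curve}}.
#' @param preferred the reference preferred angle \eqn{\phi}, radians.
#' @param window angle window relative to \code{preferred}
#'   (default \code{c(-pi/4, 0)}).
#' @return list of class \code{"bias_summary"} with \code{min_bias},
#'   \code{max_bias}, \code{window}, \code{preferred}.
#' @export
min_max_bias <- function(curve, preferred, window = c(-pi / 4, 0)) {
  stopifnot(inherits(curve, "bias_curve"), length(window) == 2)
  rel <- wrap_angle(curve$theta - preferred)
  sel <- rel >= window[1] - 1e-12 & rel <= window[2] + 1e-12
  if (!any(sel)) stop("no curve points fall in the window", call. = FALSE)
  b <- curve$bias[sel]
  structure(list(min_bias = min(b), max_bias = max(b),
                 window = window, preferred = preferred),
            class = "bias_summary")
}

#' @export
print.bias_summary <- function(x, ...) {
  cat(sprintf(
    "Bias over [%.4f, %.4f] rel. to phi = %.4f: min %.5f, max %.5f\n",
    x$window[1], x$window[2], x$preferred, x$min_bias, x$max_bias))
  invisible(x)
}

# preferred angle nearest pi/2 and the interval to its left: the default
# measurement window, far from the circular discontinuity at 0/2pi
.reference_interval <- function(pop) {
  j <- which.min(abs(pop$phi - pi / 2))
  c(pop$phi[j] - pop$spacing / 2, pop$phi[j])
}

#' Maximum absolute bias as the population grows
#'
#' For each population size in \code{N_list}, rescales the base population
#' under the given scaling rule (\code{\link{scale_population}}) and
#' measures the maximum absolute bias over one half-interval between two
#' adjacent preferred angles (symmetry makes one interval sufficient).
#'
#' @inheritParams bias_curve
#' @param base_pop circular base population (its tuning defines the
#'   starting point of the scaling).
#' @param N_list ascending population sizes, starting at
#'   \code{base_pop$N}.
#' @param mode scaling rule: \code{"none"}, \code{"amplitude"} or
#'   \code{"width"}.
#' @param n_theta stimulus angles per interval (default 21).
#' @return data frame with columns \code{N}, \code{mode},
#'   \code{max_abs_bias}.
#' @export
scaling_experiment <- function(base_pop, noise,
                               decoder = c("bayes", "ml", "pv"), N_list,
                               mode = c("none", "amplitude", "width"),
                               n_trials = 10000, seed = 1,
                               grid = decode_grid(),
                               backend = c("mc", "approx"), n_theta = 21,
                               n_quad = 2001) {
  decoder <- match.arg(decoder)
  mode <- match.arg(mode)
  backend <- match.arg(backend)
  if (is.unsorted(N_list)) stop("'N_list' must be ascending", call. = FALSE)
  rows <- lapply(seq_along(N_list), function(j) {
    pop_j <- scale_population(base_pop, N_list[j], mode)
    iv <- .reference_interval(pop_j)
    thetas <- seq(iv[1], iv[2], length.out = n_theta)
    cv <- bias_curve(pop_j, noise, thetas, decoder, n_trials,
                     seed = derive_seed(seed, j), grid = grid,
                     backend = backend, n_quad = n_quad)
    data.frame(N = N_list[j], mode = mode,
               max_abs_bias = max(abs(cv$bias)))
  })
  do.call(rbind, rows)
}

#' Bias in a long linear sensor array
#'
#' Evaluates the Bayesian-decoder bias on an unbounded linear array of
#' equally spaced neurons (spacing \eqn{d}) with rectified-cosine tuning
#' whose spatial scale is proportional to \eqn{d}, so the tuning width
#' (where \eqn{f > 0}) equals \eqn{2 d \cos^{-1}(c) \cdot}
#' \code{width_factor}. Stimuli span the half-interval left of a central
#' neuron, far from the array ends. The whole configuration is scale
#' invariant in \eqn{d}, so the bias is proportional to \eqn{d}. If the
#' tuning width falls below one spacing, some stimuli activate no neuron
#' at all and the bias is ill-defined; such configurations are rejected.
#'
#' By default the bias is computed with the analytical approximation
#' (a single quadrature per stimulus); \code{backend = "mc"} runs a full
#' Monte-Carlo simulation instead.
#'
#' @param tuning a rectified-cosine \code{\link{tuning_model}}.
#' @param spacing_list inter-neuron distances \eqn{d} to evaluate.
#' @param sigma Gaussian noise standard deviation.
#' @param width_factor tuning spatial scale in units of \eqn{d}
#'   (default 1, the canonical parametrization).
#' @param n_theta stimuli per interval (default 21).
#' @param n_quad quadrature (or decoding-grid) points.
#' @param backend \code{"approx"} or \code{"mc"}.
#' @param n_trials,seed Monte-Carlo settings (\code{backend = "mc"}).
#' @return data frame with columns \code{d}, \code{min_bias},
#'   \code{max_bias} (sign convention as in \code{\link{min_max_bias}}).
#' @export
linear_array_bias <- function(tuning, spacing_list, sigma,
                              width_factor = 1, n_theta = 21,
                              n_quad = 2001, backend = c("approx", "mc"),
                              n_trials = 10000, seed = 1) {
  backend <- match.arg(backend)
  stopifnot(inherits(tuning, "tuning_model"))
  if (tuning$family != "rectified_cosine")
    stop("linear arrays are defined for rectified-cosine tuning",
         call. = FALSE)
  width_in_d <- 2 * width_factor * acos(tuning$c)
  if (width_in_d < 1)
    stop(sprintf(paste0("ill-defined bias: tuning width (%.3f d) is below ",
                        "one inter-neuron spacing, some stimuli activate ",
                        "no neuron"), width_in_d), call. = FALSE)
  rows <- lapply(seq_along(spacing_list), function(j) {
    d <- spacing_list[j]
    s <- width_factor * d
    support <- s * acos(tuning$c)            # tuning half-width on the axis
    win <- support + 2 * d                   # integration half-window
    n_side <- ceiling((win + support) / d) + 2
    n_arr <- 2 * n_side + 1
    pop <- build_population(n_arr, "linear", tuning, spacing = d,
                            tuning_scale = s)
    centre <- pop$phi[n_side + 1]            # a neuron far from both ends
    xs <- seq(centre - d / 2, centre, length.out = n_theta)
    bias <- vapply(xs, function(x) {
      th <- x + seq(-win, win, length.out = n_quad)
      if (backend == "approx") {
        lk <- .log_bias_kernel(pop, noise_spec("gaussian", sigma), th, x)
        K <- exp(lk - max(lk))
        sum(K * th) / sum(K) - x             # linear (non-circular) mean
      } else {
        F <- tuning_matrix(pop, th)
        fx <- drop(tuning_matrix(pop, x))
        set.seed(derive_seed(seed, j * 1000 + round(1e6 * (x - centre))))
        R <- matrix(rep(fx, each = n_trials), ncol = pop$N) +
          sigma * matrix(stats::rnorm(n_trials * pop$N), ncol = pop$N)
        G <- (R %*% F - rep(colSums(F^2) / 2, each = n_trials)) / sigma^2
        W <- exp(G - G[cbind(seq_len(n_trials), max.col(G))])
        mean(drop(W %*% th) / rowSums(W)) - x
      }
    }, numeric(1))
    data.frame(d = d, min_bias = min(bias), max_bias = max(bias))
  })
  do.call(rbind, rows)
}
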