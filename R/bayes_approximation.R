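#' Generalized hypergeometric function 0F2(;1,1;x)
#'
#' Evaluates \eqn{{}_0F_2(;1,1;x) = \sum_{k\ge 0} x^k/(k!)^3} by direct
#' series summation to a relative tolerance of 1e-12. This function arises
#' in the Poisson variance kernel as the closed form of
#' \eqn{\sum_n \lambda_1^n \lambda_2^n \lambda_3^n / (n!)^3}.
#'
#' @param x argument(s); the series converges for every finite \code{x}.
#' @return function value(s); may overflow to \code{Inf} for very large
#'   \code{x} (use \code{log = TRUE} to stay in log space).
#' @param log if \code{TRUE}, return the log of the function value
#'   (requires \code{x >= 0}), accumulated in log space so it never
#'   overflows.
#' @export
hyp0f2 <- function(x, log = FALSE) {
  if (log) return(.lhyp0f2(x))
  out <- numeric(length(x))
  term <- rep(1, length(x))
  s <- rep(1, length(x))
  for (k in 1:10000) {
    term <- term * x / k^3
    s <- s + term
    if (all(abs(term) <= 1e-15 * abs(s))) return(s)
  }
  if (any(abs(term) > 1e-12 * abs(s)) && all(is.finite(s)))
    stop("hyp0f2 series did not converge", call. = FALSE)
  s
}

# log of 0F2(;1,1;x) for x >= 0, via log-space accumulation; vectorized.
.lhyp0f2 <- function(x) {
  if (any(x < 0)) stop("log-space hyp0f2 requires x >= 0", call. = FALSE)
  lx <- log(x)                          # -Inf at x == 0 is fine
  ls <- numeric(length(x))              # log of running sum, term k=0 is 1
  # terms peak near k = x^(1/3); iterate past the peak until negligible
  kmax <- max(20, ceiling(3 * max(x)^(1/3)) + 20)
  for (k in seq_len(kmax)) {
    lt <- k * lx - 3 * lgamma(k + 1)
    m <- pmax(ls, lt)
    ls <- m + log(exp(ls - m) + exp(lt - m))
    if (k > max(x)^(1/3) && all(lt - ls < -36)) break
  }
  ls
}

.approx_quad_grid <- function(theta_true, n_quad) {
  # uniform half-open grid over one period centred on the true stimulus;
  # on a periodic domain the rectangle rule is the trapezoidal rule
  theta_true - pi + 2 * pi * (seq_len(n_quad) - 1) / n_quad
}

# per-candidate log kernel of the trial-averaged estimate integrand:
# Gaussian: -sum_k (f_k(theta) - f_k(Theta))^2 / (4 sigma^2)
# Poisson:  sum_k [ -T(f_k(theta) + f_k(Theta)) + log I0(2T sqrt(f f_Theta)) ]
.log_bias_kernel <- function(pop, noise, th, theta_true) {
  f <- tuning_matrix(pop, th)
  fT <- drop(tuning_matrix(pop, theta_true))
  if (noise$kind == "gaussian") {
    -colSums((f - fT)^2) / (4 * noise$sigma^2)
  } else {
    Tt <- noise$window
    x <- 2 * Tt * sqrt(f * fT)
    # log I0 via the exponentially scaled Bessel: log I0(x) = log(I0(x)e^-x) + x
    li0 <- log(besselI(x, 0, expon.scaled = TRUE)) + x
    colSums(-Tt * (f + fT) + li0)
  }
}

#' Analytical approximation of the Bayesian decoder's mean and bias
#'
#' Approximates the trial-averaged Bayesian least-squares estimate by a
#' single quadrature over candidate stimuli,
#' \deqn{\langle\hat\theta_{BA}\rangle(\Theta) \approx \frac{1}{Z_1}
#'   \int d\theta\,\theta\, \exp\Big\{-\frac{1}{4\sigma^2}\sum_k
#'   [f_k(\theta) - f_k(\Theta)]^2\Big\}}
#' (Gaussian noise), obtained by integrating the product
#' \eqn{\int dr\,P(r|\theta)P(r|\Theta)} over response space while dropping
#' the \eqn{1/P(r)} normalizer. For Poisson spike-count noise the
#' per-neuron response integral becomes a count sum with closed form
#' \eqn{e^{-T(f_k(\theta)+f_k(\Theta))} I_0(2T\sqrt{f_k(\theta)
#' f_k(\Theta)})}. The mean is taken in circular (resultant-vector) form,
#' and the kernel is rescaled by its maximum before exponentiation so it
#' never underflows. The approximation tends to moderately overestimate
#' the Monte-Carlo bias while following all of its qualitative structure.
#'
#' @param pop a \code{\link{build_population}}.
#' @param noise a \code{\link{noise_spec}}; Gaussian requires
#'   \code{sigma > 0}.
#' @param theta_true true stimulus angle \eqn{\Theta}, radians.
#' @param n_quad quadrature points over one period (default 2001).
#' @return an object of class \code{"approx_result"} with fields
#'   \code{theta_true}, \code{mean_estimate}, \code{bias}, \code{Z1} and
#'   \code{resolution}.
#' @export
approx_bias <- function(pop, noise, theta_true, n_quad = 2001) {
  stopifnot(inherits(pop, "population"), inherits(noise, "noise_spec"))
  if (noise$kind == "gaussian" && noise$sigma <= 0)
    stop("the approximation requires sigma > 0", call. = FALSE)
  th <- .approx_quad_grid(theta_true, n_quad)
  lk <- .log_bias_kernel(pop, noise, th, theta_true)
  K <- exp(lk - max(lk))
  res <- 2 * pi / n_quad
  mean_est <- .wrap_to(atan2(sum(K * sin(th)), sum(K * cos(th))))
  structure(list(theta_true = theta_true,
                 mean_estimate = mean_est,
                 bias = wrap_angle(mean_est - theta_true),
                 Z1 = sum(K) * res,
                 resolution = res),
            class = "approx_result")
}

#' Analytical approximation of the Bayesian decoder's variance
#'
#' Approximates the trial-to-trial variance of the Bayesian least-squares
#' estimate by a double quadrature
#' \deqn{\sigma^2_{\hat\theta}(\Theta) \approx \frac{1}{Z_2}\int
#'   d\theta_1 d\theta_2\, (\theta_1 - \langle\hat\theta\rangle)
#'   (\theta_2 - \langle\hat\theta\rangle)\, Q(\theta_1, \theta_2)}
#' with, for Gaussian noise,
#' \deqn{Q = \exp\Big\{-\frac{1}{6\sigma^2}\sum_k
#'   [f_k(\theta_1)-f_k(\Theta)]^2 + [f_k(\theta_2)-f_k(\Theta)]^2 +
#'   [f_k(\theta_1)-f_k(\theta_2)]^2\Big\}}
#' and \eqn{Z_2 = \int Q}. For Poisson noise the per-neuron kernel is
#' \eqn{{}_0F_2(;1,1;T^3 f_k(\theta_1) f_k(\theta_2) f_k(\Theta))\,
#' e^{-T(f_k(\theta_1)+f_k(\theta_2)+f_k(\Theta))}}, accumulated in log
#' space. The mean \eqn{\langle\hat\theta\rangle} inside the integrand is
#' the approximation's own mean from \code{\link{approx_bias}}; deviations
#' from it are wrapped into \eqn{(-\pi, \pi]}.
#'
#' @inheritParams approx_bias
#' @param n_quad quadrature points per dimension (default 2001; the kernel
#'   matrix has \code{n_quad^2} entries).
#' @return an \code{"approx_result"} with additional fields
#'   \code{variance} and \code{Z2}.
#' @export
approx_variance <- function(pop, noise, theta_true, n_quad = 2001) {
  stopifnot(inherits(pop, "population"), inherits(noise, "noise_spec"))
  if (noise$kind == "gaussian" && noise$sigma <= 0)
    stop("the approximation requires sigma > 0", call. = FALSE)
  ab <- approx_bias(pop, noise, theta_true, n_quad)
  th <- .approx_quad_grid(theta_true, n_quad)
  f <- tuning_matrix(pop, th)                       # N x n
  fT <- drop(tuning_matrix(pop, theta_true))
  if (noise$kind == "gaussian") {
    s1 <- colSums((f - fT)^2)
    lq <- matrix(0, n_quad, n_quad)
    for (k in seq_len(pop$N)) {
      d <- outer(f[k, ], f[k, ], "-")
      lq <- lq - d * d
    }
    lq <- (lq - outer(s1, s1, "+")) / (6 * noise$sigma^2)
  } else {
    Tt <- noise$window
    lq <- matrix(0, n_quad, n_quad)
    for (k in seq_len(pop$N)) {
      x <- Tt^3 * fT[k] * outer(f[k, ], f[k, ])
      lq <- lq + .lhyp0f2(x) - Tt * (outer(f[k, ], f[k, ], "+") + fT[k])
    }
  }
  Q <- exp(lq - max(lq))
  u <- wrap_angle(th - ab$mean_estimate)
  z2 <- sum(Q)
  res <- ab$resolution
  out <- ab
  out$variance <- drop(u %*% Q %*% u) / z2
  out$Z2 <- z2 * res^2
  out
}

#' @export
print.approx_result <- function(x, ...) {
  cat(sprintf("Bayesian-decoder approximation at Theta = %.4f\n",
              x$theta_true))
  cat(sprintf("  mean estimate %.6f, bias %.6f", x$mean_estimate, x$bias))
  if (!is.null(x$variance)) cat(sprintf(", variance %.6g", x$variance))
  cat("\n")
  invisible(x)
}
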