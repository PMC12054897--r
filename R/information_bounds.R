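#' Fisher information of a population code (Gaussian noise)
#'
#' \eqn{I_F(\Theta) = \sigma^{-2} \sum_k [f_k'(\Theta)]^2}. Inactive
#' rectified-cosine neurons have exactly zero slope and contribute
#' nothing. For a pure cosine population (\eqn{c = -1}, equally spaced
#' preferred angles) the information is stimulus independent,
#' \eqn{N A^2 / (8\sigma^2)}.
#'
#' Only the Gaussian observation model is supported; requesting the
#' Poisson form raises an error rather than guessing a formula.
#'
#' @param pop a \code{\link{build_population}}.
#' @param sigma Gaussian noise standard deviation, > 0.
#' @param theta stimulus angle(s), radians.
#' @return Fisher information (radians^-2), one value per \code{theta}.
#' @export
fisher_information <- function(pop, sigma, theta) {
  stopifnot(inherits(pop, "population"))
  if (inherits(sigma, "noise_spec")) {
    if (sigma$kind != "gaussian")
      stop("Fisher information is implemented for Gaussian noise only",
           call. = FALSE)
    sigma <- sigma$sigma
  }
  if (sigma <= 0)
    stop("sigma = 0 gives infinite Fisher information", call. = FALSE)
  colSums(tuning_deriv_matrix(pop, theta)^2) / sigma^2
}

#' Bias-corrected Cramer-Rao bound
#'
#' Lower bound on the variance of a biased estimator,
#' \eqn{\sigma^2_{\hat\theta}(\Theta) \ge [1 + b'(\Theta)]^2 /
#' I_F(\Theta)}, where \eqn{b'} is the derivative of the bias with respect
#' to the stimulus. With \eqn{b' = 0} this is the usual unbiased bound
#' \eqn{1/I_F}; with complete attraction (\eqn{b' = -1}) the bound
#' vanishes.
#'
#' @param fisher Fisher information value(s), > 0.
#' @param bias_derivative \eqn{b'(\Theta)} value(s), dimensionless.
#' @return bound value(s), radians^2.
#' @export
corrected_cr_bound <- function(fisher, bias_derivative) {
  if (any(fisher <= 0)) stop("'fisher' must be > 0", call. = FALSE)
  (1 + bias_derivative)^2 / fisher
}

#' Derivative of a bias curve
#'
#' Central finite differences of the (optionally smoothed) bias curve,
#' with one-sided differences at the curve boundaries (a warning is
#' issued when those are used via \code{theta}).
#'
#' @param curve a \code{\link{bias_curve}} sampled densely enough that
#'   central differences are stable.
#' @param theta optional angle(s) at which to return the derivative
#'   (nearest curve point); default: the whole curve.
#' @param smooth moving-average window applied to the bias before
#'   differencing (0 or 1 = none; 3 is a typical choice for Monte-Carlo
#'   curves).
#' @return dimensionless derivative value(s).
#' @export
bias_derivative <- function(curve, theta = NULL, smooth = 0) {
  stopifnot(inherits(curve, "bias_curve"))
  th <- curve$theta
  b <- curve$bias
  n <- length(th)
  if (n < 3) stop("need at least 3 curve points", call. = FALSE)
  if (smooth > 1) {
    k <- rep(1 / smooth, smooth)
    sm <- stats::filter(b, k, sides = 2)
    b <- ifelse(is.na(sm), b, as.numeric(sm))
  }
  dv <- numeric(n)
  dv[2:(n - 1)] <- (b[3:n] - b[1:(n - 2)]) / (th[3:n] - th[1:(n - 2)])
  dv[1] <- (b[2] - b[1]) / (th[2] - th[1])
  dv[n] <- (b[n] - b[n - 1]) / (th[n] - th[n - 1])
  if (is.null(theta)) return(dv)
  idx <- vapply(theta, function(t) which.min(abs(th - t)), integer(1))
  if (any(idx == 1L | idx == n))
    warning("derivative at a curve boundary uses a one-sided difference")
  dv[idx]
}

#' Decoder variance, Cramer-Rao bounds and efficiency across stimuli
#'
#' Assembles, for every stimulus angle: the Fisher information, the
#' uncorrected bound \eqn{1/I_F}, the bias derivative \eqn{b'} (central
#' differences of a Monte-Carlo bias curve, moving-average smoothed), the
#' bias-corrected bound \eqn{[1+b']^2/I_F}, the Monte-Carlo decoder
#' variance, and the efficiency (corrected bound / variance; 1 means the
#' decoder attains the bound). The column \code{var_sem} carries the
#' Monte-Carlo standard error of the variance estimate,
#' \eqn{\mathrm{var}\sqrt{2/(n-1)}}.
#'
#' @inheritParams bias_curve
#' @param smooth moving-average window for the bias derivative
#'   (default 3).
#' @return a data frame of class \code{"bound_curve"} with columns
#'   \code{theta}, \code{fisher_info}, \code{bound_uncorrected},
#'   \code{bias_deriv}, \code{bound_corrected}, \code{variance},
#'   \code{var_sem}, \code{efficiency}.
#' @export
efficiency_curve <- function(pop, noise, decoder = "bayes", thetas,
                             n_trials = 10000, seed = 1,
                             grid = decode_grid(), smooth = 3) {
  stopifnot(inherits(noise, "noise_spec"))
  if (noise$kind != "gaussian")
    stop("efficiency analysis is implemented for Gaussian noise only",
         call. = FALSE)
  cv <- bias_curve(pop, noise, thetas, decoder, n_trials, seed, grid)
  fi <- fisher_information(pop, noise$sigma, thetas)
  bd <- bias_derivative(cv, smooth = smooth)
  bc <- corrected_cr_bound(fi, bd)
  out <- data.frame(theta = thetas,
                    fisher_info = fi,
                    bound_uncorrected = 1 / fi,
                    bias_deriv = bd,
                    bound_corrected = bc,
                    variance = cv$variance,
                    var_sem = cv$variance * sqrt(2 / (n_trials - 1)),
                    efficiency = bc / cv$variance)
  attr(out, "decoder") <- attr(cv, "decoder")
  attr(out, "config") <- attr(cv, "config")
  class(out) <- c("bound_curve", "data.frame")
  out
}
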