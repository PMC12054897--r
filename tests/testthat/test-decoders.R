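test_that("population-vector decoder returns the resultant angle", {
  pop <- default_pop()
  # single contributing neuron at pi/2
  expect_equal(pv_decode(c(1, 0, 0, 0), pop), pi / 2)
  # equal weight on neurons at pi/2 and pi: symmetry midpoint
  expect_equal(pv_decode(c(1, 1, 0, 0), pop), 3 * pi / 4)
  # zero resultant is a degenerate estimate
  expect_error(pv_decode(c(1, 1, 1, 1), pop), "degenerate")
})

test_that("population vector is exact for noiseless pure-cosine tuning", {
  pop <- build_population(4, tuning = tuning_model(c = -1))
  for (th in c(0.37, 1.9, 4.41)) {
    r <- drop(tuning_matrix(pop, th))
    expect_equal(pv_decode(r, pop), th, tolerance = 1e-10)
  }
})

test_that("Gaussian log-likelihood peaks at the generating stimulus", {
  pop <- default_pop()
  nz <- gauss(0.1)
  th_star <- 1.3
  r <- drop(tuning_matrix(pop, th_star))
  cand <- seq(0.1, 2 * pi, length.out = 500)
  ll <- log_likelihood(r, pop, nz, cand)
  expect_equal(log_likelihood(r, pop, nz, th_star), 0)
  expect_true(all(ll <= 0))
})

test_that("Poisson log-likelihood matches the Poisson pmf up to a constant", {
  pop1 <- build_population(1, tuning = tuning_model(c = -1))
  nzp <- noise_spec("poisson", window = 1.5)
  cand <- c(0.2, 0.9, 1.7, 3.0)
  n_obs <- 2
  ll <- log_likelihood(n_obs, pop1, nzp, cand)
  lam <- 1.5 * drop(tuning_matrix(pop1, cand))
  ref <- dpois(n_obs, lam, log = TRUE)
  expect_equal(diff(ll), diff(ref), tolerance = 1e-12)
})

test_that("Poisson log-likelihood handles zero rates by convention", {
  pop <- default_pop(c = 0.9)  # narrow: gaps with no active neuron
  nzp <- noise_spec("poisson", window = 2)
  theta_off <- pi / 2 + pi / 4  # midpoint: every rate is exactly zero
  # a spike in a neuron with zero rate makes the candidate impossible
  r <- c(3, 0, 0, 0)
  expect_identical(log_likelihood(r, pop, nzp, theta_off), -Inf)
  # all-zero counts with zero rates contribute 0, not NaN
  expect_identical(log_likelihood(c(0, 0, 0, 0), pop, nzp, theta_off), 0)
})

test_that("ML decoding recovers on-grid noiseless stimuli exactly and ties break low", {
  pop <- default_pop()
  nz <- gauss(0.1)
  th_star <- small_grid$theta[1000]
  r <- drop(tuning_matrix(pop, th_star))
  expect_equal(ml_decode(r, pop, nz, small_grid), th_star)
  # narrow tuning, one active neuron: Theta and its mirror are both maxima;
  # the lowest-index candidate must be returned deterministically
  popn <- default_pop(c = 0.1)
  th_amb <- pi / 2 + 0.08
  ramb <- drop(tuning_matrix(popn, th_amb))
  est <- ml_decode(ramb, popn, nz, small_grid)
  mirror <- pi / 2 - 0.08
  expect_true(min(abs(wrap_angle(est - c(th_amb, mirror)))) <
                2 * small_grid$resolution)
  expect_lt(est, pi / 2)  # lower-index (smaller-angle) tie wins
})

test_that("posteriors are normalized densities that concentrate as noise vanishes", {
  pop <- default_pop()
  r <- drop(tuning_matrix(pop, 1.3))
  for (sig in c(0.01, 0.1, 2)) {
    post <- posterior_on_grid(r, pop, gauss(sig), small_grid)
    expect_true(all(post$values >= 0))
    expect_equal(sum(post$values) * post$grid$resolution, 1,
                 tolerance = 1e-10)
  }
  # huge noise: posterior approaches uniform
  flat <- posterior_on_grid(r, pop, gauss(50), small_grid)
  expect_equal(max(flat$values) / min(flat$values), 1, tolerance = 1e-3)
  # small noise: mass concentrates at the generating stimulus
  sharp <- posterior_on_grid(r, pop, gauss(0.01), small_grid)
  expect_equal(bayes_decode(sharp), 1.3, tolerance = small_grid$resolution)
})

test_that("the Bayesian decoder returns the symmetry point of symmetric posteriors", {
  pop <- default_pop(c = 0.1)
  nz <- gauss(0.1)
  # single active neuron: the posterior is symmetric about its preferred
  # angle, so the mean estimate sits at phi regardless of the offset
  r <- drop(tuning_matrix(pop, pi / 2 + 0.05))
  post <- posterior_on_grid(r, pop, nz, small_grid)
  expect_equal(bayes_decode(post), pi / 2, tolerance = small_grid$resolution)
  # hand-built bimodal posterior with equal peaks at phi +/- delta
  th <- small_grid$theta
  v <- dnorm(wrap_angle(th - (pi - 0.4)), sd = 0.05) +
       dnorm(wrap_angle(th - (pi + 0.4)), sd = 0.05)
  post2 <- structure(list(grid = small_grid, log_values = log(v),
                          values = v / (sum(v) * small_grid$resolution)),
                     class = "posterior")
  expect_equal(bayes_decode(post2), pi, tolerance = small_grid$resolution)
})

test_that("decode_trials agrees with the single-trial decoders", {
  pop <- default_pop()
  nz <- gauss(0.1)
  R <- sample_responses(pop, nz, 1.4, 50, seed = 9)
  est <- sapply(c("pv", "ml", "bayes"), function(d)
    decode_trials(R, pop, nz, small_grid, d))
  for (i in c(1, 17, 50)) {
    expect_equal(unname(est[i, "pv"]), pv_decode(R[i, ], pop))
    expect_equal(unname(est[i, "ml"]), ml_decode(R[i, ], pop, nz, small_grid))
    expect_equal(unname(est[i, "bayes"]),
                 bayes_decode(posterior_on_grid(R[i, ], pop, nz,
                                                small_grid)),
                 tolerance = 1e-9)
  }
  nzp <- noise_spec("poisson", window = 10)
  Rp <- sample_responses(pop, nzp, 1.4, 30, seed = 10)
  estp <- decode_trials(Rp, pop, nzp, small_grid, "ml")
  for (i in c(2, 30))
    expect_equal(estp[i], ml_decode(Rp[i, ], pop, nzp, small_grid))
})

test_that("decoders are equivariant under a common rotation", {
  pop <- default_pop()
  nz <- gauss(0.1)
  delta <- 64 * small_grid$resolution  # grid-commensurate rotation
  rot <- pop
  rot$phi <- pop$phi + delta
  th <- 1.2
  set.seed(5)
  noise_draw <- 0.1 * matrix(rnorm(20 * 4), ncol = 4)
  R <- matrix(rep(drop(tuning_matrix(pop, th)), each = 20), ncol = 4) +
    noise_draw
  Rr <- matrix(rep(drop(tuning_matrix(rot, th + delta)), each = 20),
               ncol = 4) + noise_draw
  for (d in c("pv", "ml", "bayes")) {
    e1 <- decode_trials(R, pop, nz, small_grid, d)
    e2 <- decode_trials(Rr, rot, nz, small_grid, d)
    expect_equal(wrap_angle(e2 - e1 - delta), rep(0, 20),
                 tolerance = 2 * small_grid$resolution)
  }
})

test_that("ML equals the Bayes estimate in the dense low-noise Gaussian limit", {
  pop <- build_population(64, tuning = tuning_model(c = -0.5))
  nz <- gauss(0.01)
  R <- sample_responses(pop, nz, 1.37, 200, seed = 21)
  ml <- decode_trials(R, pop, nz, small_grid, "ml")
  ba <- decode_trials(R, pop, nz, small_grid, "bayes")
  frac <- mean(abs(wrap_angle(ml - ba)) < 2 * small_grid$resolution)
  expect_gte(frac, 0.99)
})

test_that("the population vector has larger variance than ML at defaults", {
  pop <- default_pop()
  nz <- gauss(0.1)
  for (th in c(pi / 2 - 0.3, pi / 2 - 0.7)) {
    R <- sample_responses(pop, nz, th, 4000, seed = 31)
    vpv <- var(wrap_angle(decode_trials(R, pop, nz, small_grid, "pv") - th))
    vml <- var(wrap_angle(decode_trials(R, pop, nz, small_grid, "ml") - th))
    expect_gt(vpv, vml)
  }
})
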