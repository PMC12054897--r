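# popbias

Estimation bias and variance of neural population-code decoders when few
neurons are active.

## The problem

Population codes represent a stimulus — an orientation, a direction, a
position — in the joint activity of many tuned neurons. Read-outs such
as the population vector, the maximum-likelihood (ML) estimator and the
Bayesian least-squares (posterior-mean) estimator are unbiased when many
neurons respond. When only a *few* neurons are active — small
populations like the four-neuron cricket wind-direction system, or large
arrays with narrow tuning — a systematic error appears: even after
averaging over trials, the decoded stimulus differs from the true one.
With estimate θ̂ and true stimulus Θ, the bias is

    b(Θ) = ⟨θ̂⟩ − Θ

This package is for computational and systems neuroscientists who want
to quantify that bias, its dependence on tuning-curve shape (rectified
cosine with threshold c, or von Mises with width w), noise (Gaussian σ
or Poisson counting window T), and population size, and its interaction
with the Cramér–Rao bound: a biased estimator obeys
σ²(Θ) ≥ [1 + b′(Θ)]² / I_F(Θ), and near preferred angles the decoder
variance genuinely drops below the *uncorrected* bound 1/I_F.

Besides Monte-Carlo simulation, the package implements a fast analytical
approximation to the Bayesian decoder's bias and variance: dropping the
1/P(r) normalizer turns the trial average into a single quadrature
against the kernel exp{−Σ_k [f_k(θ) − f_k(Θ)]² / 4σ²} (Gaussian), with
Poisson counterparts built from I₀ and the generalized hypergeometric
series ₀F₂(;1,1;x) = Σ x^k/(k!)³.

## Worked example

```r
library(popbias)
pop   <- build_population(4, tuning = tuning_model("rectified_cosine",
                                                   A = 1, c = -0.1))
noise <- noise_spec("gaussian", sigma = 0.1)

# Monte-Carlo bias of the Bayesian decoder at Theta = pi/2 - 0.1
estimate_bias_variance(pop, noise, theta = pi/2 - 0.1,
                       decoder = "bayes", n_trials = 20000, seed = 1)
#> $bias      -0.0226
#> $variance   0.00946
#> $sem        0.000688
#> $n_trials   20000

# the analytical approximation at the same stimulus
approx_variance(pop, noise, pi/2 - 0.1)
#> Bayesian-decoder approximation at Theta = 1.4708
#>   mean estimate 1.441857, bias -0.028940, variance 0.0101491

# summary over the half-interval left of the preferred angle
cv <- bias_curve(pop, noise, seq(pi/4, pi/2, length.out = 21),
                 backend = "approx")
min_max_bias(cv, preferred = pi/2)
#> Bias over [-0.7854, 0.0000] rel. to phi = 1.5708: min -0.02541, max 0.00000
```

Reading: 0.1 rad left of the preferred angle, the Bayesian estimate is
on average pushed a further 0.023 rad away from the preferred angle
(repulsive bias; the Monte-Carlo standard error is 0.0007, so the effect
is ~30σ). The quadrature approximation reproduces the sign and shape
while moderately overestimating the magnitude (−0.029 vs −0.023), and
puts the decoder's trial-to-trial variance at 0.0101 vs the simulated
0.0095. Over the whole half-interval the bias at this tuning width is
repulsive everywhere (max = 0); narrow tuning (c > 0) flips it to
attractive, with slope −1 right at the preferred angle, where only one
neuron is active and the sign of the offset is fundamentally ambiguous.

Further entry points: `bias_curve()` (bias/variance across stimuli, MC
or approximation backend), `efficiency_curve()` (Fisher information,
corrected/uncorrected bounds, efficiency), `scaling_experiment()`
(density/amplitude/width scaling with N), `linear_array_bias()`
(unbounded 1-D arrays, bias ∝ spacing), `run_experiment()` (config-file
driven runs with reproducible seeds and tab-delimited/JSON output).
The methods vignette (`vignettes/decoder-bias-methods.Rmd`) documents
the model, all numerical choices and their rationale.

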