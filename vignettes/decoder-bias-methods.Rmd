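---
title: "Decoder bias in sparse population codes: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoder bias in sparse population codes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popbias)
```

## The problem

A population code represents a stimulus value in the joint activity of
many neurons. When many neurons respond, standard read-outs — the
population vector, the maximum-likelihood (ML) estimate, the Bayesian
least-squares (posterior-mean) estimate — are unbiased: averaged over
trials, the decoded value equals the encoded one. When only a few neurons
are active, either because the population is small (the four-neuron
cricket wind-direction system is the canonical example) or because tuning
is narrow, a *systematic* error appears. Writing $\hat\theta$ for the
single-trial estimate and $\Theta$ for the true stimulus, the bias is

$$ b(\Theta) = \langle\hat\theta\rangle - \Theta, $$

the trial average of the estimation error. This package simulates the
emergence of that bias, characterizes its dependence on tuning shape,
noise and population size, relates it to the bias-corrected Cramér–Rao
bound, and implements a fast analytical approximation to the Bayesian
decoder's bias and variance.

## Encoding model

Neurons $k = 1 \ldots N$ have preferred angles $\phi_k = 2\pi k/N$
(for $N = 4$: $\phi_k = k\pi/2$, 90° apart). Two tuning families are
provided:

* **Rectified cosine** $f_k(\Theta) = \frac{A}{1-c}\,
  [\cos(\phi_k - \Theta) - c]_+$. The threshold $c \in [-1, 1)$ sets the
  width: the active arc (where $f > 0$) has width $2\cos^{-1}(c)$, and
  the peak equals $A$ exactly. $c = -1$ is a full cosine; large $c$ gives
  narrow tuning. At the default $c = -0.1$ (close to the $c = -0.14$
  fitted to cricket interneurons) two neurons are active for most
  stimuli, three very close to a preferred angle.
* **Von Mises** $f_k(\Theta) = A \exp[(\cos(\phi_k - \Theta) - 1)/w]$,
  a smooth circular bell of width $w > 0$. The family is usually written
  only up to proportionality; we fix the constant so the peak equals
  $A$, making the two families directly comparable.

Observation noise is either Gaussian additive,
$r_k = f_k(\Theta) + \sigma\nu$ with $\nu \sim \mathcal N(0,1)$ i.i.d.,
or Poisson: spike counts $n_k \sim \text{Poisson}(T f_k(\Theta))$ with
counting window $T$. Poisson responses are returned as counts and
decoders consume the pair (counts, $T$); this avoids any ambiguity
between rate- and count-based likelihoods. Defaults throughout are
$A = 1$, $c = -0.1$, $\sigma = 0.1$, chosen as the reference operating
point of the four-neuron system.

All angles are radians on $[0, 2\pi)$. Experiment stimulus grids are kept
away from $0/2\pi$; deviations $\hat\theta - \Theta$ are always wrapped
into $(-\pi, \pi]$, which coincides with ordinary statistics away from
the discontinuity.

## Decoders

* **Population vector**: the angle of
  $p = \left(\sum_k r_k\cos\phi_k, \sum_k r_k\sin\phi_k\right)$.
  Cheap, but with the largest variance and bias.
* **Maximum likelihood**: the arg-max of $\log P(r \mid \theta)$ over a
  uniform candidate grid covering one period. The default grid has
  $10^4$ points ($2\pi/10^4 \approx 6\times10^{-4}$ rad resolution),
  so the quantization error (at most half a step) is two orders of
  magnitude below the biases of interest ($\sim 10^{-2}$ rad). Ties are
  broken toward the lowest-index candidate — deterministic and
  seed-independent, which matters in noiseless ambiguity demonstrations
  where two candidates are exactly equally likely.
* **Bayesian least squares**: the posterior mean under a flat prior,
  computed on the same grid after max-subtraction (so the posterior
  never underflows). The mean is always taken in circular
  (resultant-vector) form,
  $\hat\theta = \mathrm{atan2}\!\left(\int\sin\theta' P\,d\theta',
  \int\cos\theta' P\,d\theta'\right)$: one uniform code path that equals
  the linear mean for concentrated posteriors and remains correct at the
  period boundary.

For narrow tuning ($c > 0$) a stimulus near a preferred angle activates
a single neuron. The response of that neuron is symmetric in
$\pm(\Theta - \phi_k)$, so the posterior is symmetric about $\phi_k$ and
*any* reasonable estimator averages to $\phi_k$: the bias is complete and
attractive, $b(\Theta) = -(\Theta - \phi_k)$, giving a bias slope of
exactly $-1$ near the preferred angle for all three decoders. This limit
is the one regime where the sign and size of the bias are intuitive; the
package's acceptance suite verifies it by simulation.

## Monte-Carlo experiments

`estimate_bias_variance()` samples `n_trials` responses at one stimulus,
decodes them in a single blocked matrix pass (`decode_trials()`), and
returns bias, variance and the Monte-Carlo standard error
$\sqrt{\mathrm{var}/n}$. `bias_curve()` repeats this over a stimulus
grid; each angle gets its own deterministically derived seed
(`derive_seed()`), so a full curve is reproducible and any single angle
can be recomputed in isolation.

Default trial counts are $10^4$ per angle, matching typical usage;
headline checks that must resolve $10^{-3}$-level differences use
$10^5$. Stimulus grids default to 21–41 points per interval between
adjacent preferred angles; by symmetry the bias is odd and periodic with
zeros at preferred angles and at midpoints, so one interval suffices.
The summary `min_max_bias()` reports extremes over the half-interval
*left* of a preferred angle ($-\pi/4 \le \Theta - \phi \le 0$ for
$N = 4$), where positive bias means attraction; a purely attractive
profile has `min_bias >= 0`, a purely repulsive one `max_bias <= 0`, and
a bi-phasic one changes sign.

A practical note on the bi-phasic regime: at the default noise
$\sigma = 0.1$ the $c = -0.1$ curve is overwhelmingly repulsive — a
$4\times10^5$-trial run bounds any attractive lobe below $5\times10^{-4}$
rad, and the analytical approximation puts its maximum at exactly zero.
The clear bi-phasic shape (both signs well resolved) appears at higher
noise; the test suite therefore demonstrates it at $\sigma = 0.2$, the
upper end of the standard noise sweep
$\sigma \in \{0.01, 0.05, 0.1, 0.15, 0.2\}$.

## Scaling rules and the linear array

`scale_population()` grows a population three ways: **none** (only the
density of preferred angles increases), **amplitude** ($A \mapsto
A\,N_\text{old}/N_\text{new}$, conserving mean population activity
exactly), and **width**. Width scaling holds the expected number of
simultaneously active neurons fixed: for the rectified cosine the active
arc is scaled by $N_\text{old}/N_\text{new}$ and solved for the new
threshold; for von Mises tuning no closed form exists, so $w$ is solved
numerically (tolerance $10^{-8}$ in the root) to conserve the summed
tuning mass $\int \sum_k f_k\,d\theta = 2\pi N A\, e^{-1/w} I_0(1/w)$.
Note the two families conserve different invariants — arc length versus
mass — because those are the natural notions of "same number of active
neurons" for a hard-edged and a soft-edged curve respectively.

`linear_array_bias()` treats an unbounded one-dimensional array with
inter-neuron distance $d$ and rectified-cosine tuning whose spatial
scale is proportional to $d$, so the tuning width (where $f > 0$) is
$2d\cos^{-1}(c)$. The configuration is then scale invariant and the bias
is exactly proportional to $d$. If the width falls below one spacing,
some stimuli activate no neuron and the bias is ill-defined; such
configurations raise an error. Stimuli are evaluated in a central
interval far from the array ends, and the integration window is
$\pm(\text{tuning half-width} + 2d)$ around the stimulus — wide enough
to contain all likelihood mass from overlapping neurons while scaling
with $d$, which preserves the exact proportionality. By default this
driver uses the analytical approximation backend (one quadrature per
stimulus); a Monte-Carlo backend is available behind a flag.

## Fisher information and the bias-corrected bound

For Gaussian noise,
$I_F(\Theta) = \sigma^{-2}\sum_k [f_k'(\Theta)]^2$. The derivative of
the rectified cosine is defined as zero at the rectification kink (the
limit from the inactive side), so inactive neurons contribute exactly
nothing and the information stays finite. For the pure cosine
($c = -1$) the closed form $N A^2/(8\sigma^2)$ is stimulus independent
and serves as an exact oracle in the tests. The Poisson Fisher
information is deliberately not implemented: requesting it raises an
error rather than silently using a guessed formula.

A biased estimator obeys
$\sigma^2_{\hat\theta}(\Theta) \ge [1 + b'(\Theta)]^2 / I_F(\Theta)$.
`efficiency_curve()` assembles the information, the uncorrected bound
$1/I_F$, the bias derivative $b'$ (central differences of the
Monte-Carlo bias curve with an optional moving-average smoothing of
window 3 — Monte-Carlo noise differentiates badly without it), the
corrected bound, the decoder variance, and the efficiency
(corrected bound / variance). Near a preferred angle the decoder
variance can drop *below* the uncorrected bound — only the
bias-corrected form is actually a bound there — which is why knowing the
bias matters even when one only cares about variance.

## The analytical approximation

The trial-averaged Bayes estimate involves an integral over response
space of $P(r\mid\Theta)\,P(\theta\mid r)$; dropping the $1/P(r)$
normalizer makes the response integral tractable and yields, for
Gaussian noise,

$$ \langle\hat\theta_{BA}\rangle(\Theta) \approx \frac{1}{Z_1}
   \int d\theta\,\theta\,
   \exp\!\Big\{-\tfrac{1}{4\sigma^2}\textstyle\sum_k
   [f_k(\theta) - f_k(\Theta)]^2\Big\}, $$

a single one-dimensional quadrature per stimulus, and for the variance a
double quadrature against the kernel

$$ Q(\theta_1,\theta_2) = \exp\!\Big\{-\tfrac{1}{6\sigma^2}
   \textstyle\sum_k [f_k(\theta_1)-f_k(\Theta)]^2 +
   [f_k(\theta_2)-f_k(\Theta)]^2 +
   [f_k(\theta_1)-f_k(\theta_2)]^2\Big\}. $$

The $1/(4\sigma^2)$ and $1/(6\sigma^2)$ factors come from completing
the square in the two- and three-factor Gaussian products; both are
verified in the test suite against brute-force response-space
quadrature. The mean inside the variance integrand is the
approximation's own mean estimate (not the true $\Theta$), and
deviations are wrapped.

For Poisson noise the response integral becomes a count sum with closed
forms: the bias kernel per neuron is
$e^{-T(f_k(\theta) + f_k(\Theta))}\, I_0\!\big(2T\sqrt{f_k(\theta)
f_k(\Theta)}\big)$ and the variance kernel is
${}_0F_2\!\big(;1,1; T^3 f_k(\theta_1) f_k(\theta_2) f_k(\Theta)\big)\,
e^{-T(f_k(\theta_1)+f_k(\theta_2)+f_k(\Theta))}$, where
${}_0F_2(;1,1;x) = \sum_k x^k/(k!)^3$. These closed forms are
*identities* for the count sums
$\sum_n \prod_i \text{Pois}(n; T f_i)$ — the tests check them to
$10^{-10}$ — which pins down both the square root inside $I_0$ and the
exponential prefactors unambiguously. $I_0$ is evaluated in
exponentially scaled form and ${}_0F_2$ in log space, so neither can
overflow.

### Numerical choices

* Quadrature: uniform grids over one period centred on $\Theta$,
  2001 points per dimension by default. The kernels are smooth and
  periodic, so the rectangle rule (= trapezoid on a periodic domain)
  converges fast: halving the step changes the default-configuration
  bias by under $10^{-6}$ rad.
* The kernel is rescaled by its maximum before exponentiation
  (mandatory, not cosmetic: at small $\sigma$ the raw kernel underflows
  everywhere except near $\theta = \Theta$).
* The approximation's mean uses the same circular resultant form as the
  Monte-Carlo decoder.

### What the approximation does and does not capture

It reproduces every qualitative feature of the simulations — the sign
flip of the bias with $c$, the bi-phasic band near $c \in (-0.2, 0)$ at
sufficient noise, the always-attractive von Mises bias, the decrease of
bias with population size under all three scaling rules — while
moderately *overestimating* the magnitude at the extrema. It is the
default backend for the scaling and linear-array drivers, where
Monte-Carlo resolution of sub-$10^{-3}$ biases would need millions of
trials. One caveat observed in this implementation: at small $N$ the
approximation compresses the difference between amplitude-scaled and
unscaled populations to a few percent and can even reverse their order,
whereas paired Monte-Carlo runs show the amplitude-scaled population
clearly retaining more bias; comparisons *between* scaling modes at the
same $N$ are therefore done with the Monte-Carlo backend.

## Synthetic data and external validity

All inputs are generated internally from the encoding model; nothing is
fitted to recorded data. The generator emulates independent
trial-to-trial noise (Gaussian or Poisson), exact knowledge of the
tuning curves by the decoder, and perfectly equidistant preferred
angles. Real populations violate all three — correlated noise,
encoder/decoder mismatch and heterogeneous tuning each produce
additional biases of their own — so passing tests here demonstrate that
biases arise *even in the idealized case*, not that the magnitudes
transfer to any particular circuit.

## Problem sizes

The shipped test-suite and acceptance runs use: $10^5$ trials for the
reference four-neuron bias values, $10^4$ trials per angle for slope,
spread-ratio and bound checks, 4 000–6 000 trials per angle for sign-level
phenomenology, a $10^4$-point decoding grid, and 2001-point quadrature.
These sizes put Monte-Carlo standard errors a factor of three to ten
below every asserted effect.

## Known limitations

* The ML decoder is grid-based; no continuous refinement is attempted
  (the grid is fine enough that refinement would change nothing at the
  reported precision).
* Poisson Fisher information and non-uniform priors are out of scope.
* The exact orthant-integral machinery for ML bias is not implemented;
  the analytical route here covers the Bayesian decoder only.
* Correlated noise and heterogeneous preferred-angle layouts are not
  modelled.
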