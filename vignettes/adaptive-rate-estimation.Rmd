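---
title: "Estimating the adaptive amino-acid substitution rate from polymorphism and divergence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the adaptive amino-acid substitution rate from polymorphism and divergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

`adaptiveMK` implements a maximum-likelihood McDonald–Kreitman framework.
The data for one focal species / outgroup pair are the unfolded (or
folded) synonymous and non-synonymous site frequency spectra, $P_S[i]$
and $P_N[i]$, the counts of fixed synonymous and non-synonymous
differences $D_S$ and $D_N$, and the numbers of sites behind each count
($L_S$, $L_N$ and their divergence-alignment counterparts). Synonymous
mutations are taken as neutral; each new non-synonymous mutation carries
a scaled selection coefficient $S = 4 N_e s$ drawn from a distribution of
fitness effects (DFE) $\Phi(S)$, with semidominant selection and free
recombination.

Under the Poisson random field approximation the expected data are

$$\hat P_S[i] = \theta L_S \, r_i / i, \qquad
  \hat P_N[i] = \tfrac{\theta}{2} L_N \, r_i
  \left[\textstyle\sum_m \mathrm{mass}_m G(S_m, i, n) +
  \int \Phi(S)\, G(S, i, n)\, dS\right],$$

$$\hat D_S = L^{div}_S T, \qquad
  \hat D_N = L^{div}_N T \left[\textstyle\sum_m \mathrm{mass}_m F(S_m) +
  \int \Phi(S) F(S)\, dS\right] + A,$$

where $\theta = 4 N_e \mu$ per site, $T = \mu t$, and

$$G(S, i, n) = \int_0^1 H(S, x)\, q(i, n, x)\, dx, \qquad
  H(S, x) = \frac{2\,(1 - e^{-S(1-x)})}{x(1-x)(1 - e^{-S})}, \qquad
  F(S) = \frac{S}{1 - e^{-S}}.$$

$H$ is the diffusion sojourn-time density of a semidominant mutation
(neutral limit $2/x$), $q$ the binomial sampling probability in $2n$
chromosomes, and $F$ the scaled fixation probability ($F(0) = 1$). The
scaling of $H$ is chosen so that $G(0, i, n) = 2/i$ exactly, which makes
the fully neutral spectrum equal $\theta L/i$ — the classical
constant-size result. With this convention $S > 0$ is advantageous.
Only three degrees of freedom of $(N_e, \mu, s, t)$ are identifiable;
$\theta$, $T$ and $\Phi(S)$ are exactly that reparametrization.

Two devices absorb what the demographic-equilibrium model cannot fit.
The nuisance multipliers $r_i$ (one per frequency class, $r_1 = 1$)
rescale both spectra class by class and soak up demography, population
structure, linked selection and orientation error — anything that
distorts synonymous and non-synonymous classes alike. The divergence
excess $A \ge 0$ represents strongly advantageous substitutions that fix
too fast to leave a polymorphism signature; the `minus_A` variant pins
$A = 0$ to ask whether the continuous DFE alone explains divergence.

## DFE families

| family | parameters | support |
|---|---|---|
| `neutral` | `f_neutral` | mass at $S=0$, rest strongly deleterious |
| `gamma` | `shape`, `mean_del` | $-S \sim$ Gamma (all deleterious) |
| `gammaexpo` | + `p_pos`, `mean_adv` | adds an exponential positive tail |
| `scaledbeta` | `a`, `b`, `w_mild` | Beta on $[-S_{max}, S_{max}]$ + lethal mass |
| `displgamma` | `shape`, `mean_del`, `displacement` | Gamma shifted to allow $S \le d$ |

Gamma branches are parametrized by (shape, mean), the natural scale for
reporting the mean scaled deleterious effect. "Strongly deleterious" is
an absorbing class contributing neither polymorphism nor divergence — no
numeric $S$ is attached to it, which avoids an arbitrary large-$|S|$
cutoff. $S_{max} = 25$ by default for `scaledbeta`; the Gamma shape is
capped at 100 during fitting (beyond that the family is
indistinguishable from a point mass at its mean).

## Likelihood and estimation

All $4n$ data cells are independent Poisson draws around their
expectations; factorials are generalized through $\log \Gamma$ so the
fractional counts produced by hypergeometric projection are handled
smoothly. Maximization runs in an unconstrained transformed space (log
for $\theta$, $T$, $A$ and positive DFE parameters, logit for
proportions, a logit map onto $(0, 100)$ for Gamma shapes) with
multi-start BFGS: one start combines method-of-moments initialization
with a coarse DFE grid, the rest are seeded random perturbations, and
nested fits can be warm-started from their null's optimum. Conditional
on the other parameters the Poisson score gives the $r_i$ ($i \ge 2$) in
closed form, $\hat r_i = (P_S[i] + P_N[i]) / (\hat P_S^{base}[i] + \hat
P_N^{base}[i])$, so they are profiled out analytically and the numeric
optimizer only sees $\theta$, $T$, $A$ and the DFE parameters. This is
both much faster and much more robust than optimizing the full vector.

From a fitted model the expected *non-adaptive* non-synonymous
divergence counts only the DFE mass below a threshold $S_{adv}$
(default 5):
$\hat D_N^{na} = L^{div}_N T \int_{-\infty}^{S_{adv}} \Phi(S) F(S)\,dS$,
excluding $A$. The reported estimators deliberately mix this fitted
expectation with *observed* rates:

$$\omega_{na} = \frac{\hat d_N^{na}}{d_S}, \qquad
  \omega_a = \frac{d_N - \hat d_N^{na}}{d_S}, \qquad
  \alpha = \frac{d_N - \hat d_N^{na}}{d_N},$$

so $\omega_a = d_N/d_S - \omega_{na}$ and $\alpha = \omega_a/(d_N/d_S)$
hold exactly, and $\alpha < 0$ (observed divergence below the
nearly-neutral expectation) is reported as such, never clipped.

Model comparison uses AIC (ties broken toward fewer parameters) and
likelihood-ratio tests along the nested chains neutral → gamma →
gammaexpo and minus_A → standard. For boundary nulls ($p_{pos} = 0$,
$A = 0$) the plain $\chi^2$ reference is used, which is conservative —
simulation under a Gamma truth shows rejection well below the nominal
level. Confidence intervals for $\alpha$ are profile-likelihood
intervals ("two units of support"): the constraint is imposed by solving
$L^{div}_N T \, I_{na}(\Phi) = (1 - \alpha) D_N$ for $T$ and
re-maximizing over everything else, stepping outward from
$\hat \alpha$ with warm starts and bisecting each bound. Such intervals
condition on the model being true and are expected to be narrow relative
to real between-dataset variability.

# Numerical choices

* Frequency integral: 256-node Gauss–Legendre on $(0,1)$ (configurable);
  doubling the nodes changes $G$ by $< 10^{-9}$ in the tested range.
* DFE integrals: each continuous branch is integrated through its own
  quantile function with 64 Gauss–Legendre nodes on $(0,1)$, so the
  nodes follow the distribution mass wherever the parameters move.
  The scalar divergence integrand gets a 4-fold node budget because
  $F$ through the exponential quantile has a logarithmic endpoint.
* Truncation at $S_{adv}$ restricts the $u$-interval through the branch
  CDF rather than clipping the integrand, keeping the quadrature smooth.
* Inside the optimizer, $G(S, i, n)$ is evaluated from per-shape cached
  monotone cubic splines in $\log|S|$ (built once from exact quadrature
  on a dense grid spanning $|S| \in [10^{-6}, 10^{10}]$); the reported
  log-likelihood at the optimum is always recomputed with exact
  quadrature. The interpolation error is below $10^{-2}$ log-likelihood
  units in the tested range and cancels in likelihood differences.
* $H$ and $F$ switch to asymptotic branches beyond $|S| = 650$ to avoid
  overflow; $S = 0$ uses the analytic limits $2/x$ and $1$.
* Invalid parameter regions return a large finite penalty rather than
  `-Inf`, keeping finite-difference gradients defined.

# The simulator and what it does (not) show

`SimScenario` + `sampleDataset` draw every SFS class and divergence
count Poisson around its model expectation — the estimator's own
sampling distribution — optionally moving each SNP to its mirror
frequency class with a given misorientation probability (binomial
thinning), and offer fixed $r$-vector presets (`flat`,
`expansion-like`, `bottleneck-like`) as documented shapes. The default
generating conditions (`referenceParams()`) are $\theta = 0.01$,
$T = 0.1$, $2n = 8$, $A = 0$, and per-family DFE defaults built around a
Gamma(0.4) deleterious branch of mean scaled effect 1000 with, for
`gammaexpo`, 1% of advantageous mutations of mean scaled effect 10 —
values typical of the animal population-genomic literature; validation
runs use $L_N = 10^6$ and $L_S = 3 \times 10^5$ sites (roughly the 3:1
non-synonymous to synonymous site ratio of coding sequence), with
scaled-down sizes ($L_N = 5 \times 10^4$) for replicate-heavy
calibration studies.

Because simulation happens at the level of the model's own Poisson
field, passing recovery tests demonstrates that the estimator is
consistent and approximately unbiased *at its assumptions*. It says
nothing about linkage, selective sweeps, background selection,
fluctuating population size over the divergence period, or non-equilibrium
demography beyond what $r_i$ can absorb — on real data those enter as
model misspecification. Folding is the exception that can be exercised
directly: misorientation moves counts only between mirror classes, so
the folded spectrum is exactly invariant to it, and folded fits are
immune by construction (at the price of weaker identifiability of the
positive DFE tail).

# Design decisions taken where the design was open

* The sojourn density is the standard diffusion form with numerator
  $1 - e^{-S(1-x)}$; the sign convention is fixed by requiring the
  neutral limit $2/x$ and the $\theta L / i$ neutral spectrum.
* The divergence excess $A$ enters additively on the count scale and is
  constrained $\ge 0$: a negative excess is indistinguishable from model
  misfit and would trade against the DFE.
* Projected fractional SFS counts are kept as-is (no rounding); weight
  projected onto the monomorphic classes is dropped, not renormalized,
  mirroring the loss of observable polymorphism.
* SNPs, not sites, are projected; monomorphic sites never enter the SFS.
* "Derivative-based local optimization" is realized as quasi-Newton BFGS
  in transformed space rather than a literal Newton–Raphson — more
  robust with dense Hessians of this size, and invariant to the choice
  once multi-started.
* The neutral family is only a limiting case of the gamma family
  (shape $\to 0$ splits mass between a near-neutral spike and an
  effectively lethal tail), so the neutral-vs-gamma LRT df follows the
  parameter-count difference; this is the conventional, slightly
  conservative reading.
* Profile intervals profile $\alpha$ directly (constrained refits) rather
  than transforming parameter-wise intervals.
* The flat-file format carries separate polymorphism and divergence site
  counts (`L` vs `Ldiv`), since the two alignments need not coincide;
  when a single count is available the fields simply repeat it, and the
  non-adaptive divergence uses the divergence-alignment count.
* The per-replicate random stream is `seed + 104729 (replicate - 1)`,
  keeping replicates independent and reproducible from one integer.

# Limitations

* $\alpha$ aggregates over the genome fraction supplied; gene-level
  estimates and asymptotic-MK extrapolation are out of scope.
* The proportion and mean strength of positive effects are strongly
  confounded (only their product is well constrained by SFS data of
  realistic size); $\alpha$ itself remains estimable, which is why
  validation targets $\alpha$, $\theta$ and $T$ rather than individual
  positive-tail parameters.
* Profile-likelihood intervals inherit every model assumption;
  between-replicate scatter on real data is typically wider.
* Comparative regressions reuse $\pi_S$ on both axes when rate
  estimates are correlated against diversity; the package reports raw
  Pearson statistics and leaves causal interpretation to the user.
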