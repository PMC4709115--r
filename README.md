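# adaptiveMK

Maximum-likelihood McDonald–Kreitman estimation of the adaptive
amino-acid substitution rate from coding-sequence polymorphism and
divergence.

## What it does and for whom

Population geneticists comparing a focal species with a close outgroup
routinely ask what fraction of amino-acid substitutions was driven by
positive selection. The naive McDonald–Kreitman contrast of
*d*<sub>N</sub>/*d*<sub>S</sub> against *p*<sub>N</sub>/*p*<sub>S</sub>
is biased by segregating slightly deleterious mutations and by
demography. `adaptiveMK` addresses both by fitting an explicit
population-genetic model to the synonymous and non-synonymous site
frequency spectra (SFS) together with the divergence counts:

* synonymous class *i* has Poisson expectation θ L<sub>S</sub> r<sub>i</sub>/i;
* non-synonymous class *i* has expectation
  (θ/2) L<sub>N</sub> r<sub>i</sub> ∫ Φ(S) G(S, i, n) dS, where Φ(S) is a
  parametric distribution of fitness effects (DFE) over scaled selection
  coefficients S = 4N<sub>e</sub>s and G is the diffusion
  sojourn-and-sampling factor (G(0, i, n) = 2/i);
* expected divergence is L<sup>div</sup><sub>S</sub> T and
  L<sup>div</sup><sub>N</sub> T ∫ Φ(S) F(S) dS + A, with
  F(S) = S/(1 − e<sup>−S</sup>) the scaled fixation probability and A an
  optional excess from strongly advantageous substitutions.

The nuisance multipliers r<sub>i</sub> (r<sub>1</sub> = 1) absorb
demography, structure and orientation error shared by both spectra. DFE
families: `neutral`, `gamma`, `gammaexpo`, `scaledbeta`, `displgamma`,
compared by AIC and likelihood-ratio tests, each optionally in a
`minus_A` variant (A pinned to 0). From a fit the package derives

* ω<sub>na</sub> — non-adaptive non-synonymous rate relative to neutral
  (DFE mass below S<sub>adv</sub> = 5),
* ω<sub>a</sub> = d<sub>N</sub>/d<sub>S</sub> − ω<sub>na</sub> — adaptive rate,
* α = ω<sub>a</sub>/(d<sub>N</sub>/d<sub>S</sub>) — proportion of adaptive
  amino-acid substitutions,

with profile-likelihood confidence intervals for α. Utilities cover SFS
construction from SNP records (outgroup orientation, tri-/tetra-allelic
filtering, hypergeometric projection, folding), a Poisson simulator for
validation, and a small comparative layer (Pearson regressions of rates
on log π<sub>S</sub>, the π<sub>N</sub>–π<sub>S</sub> log-log slope whose
complement estimates the Gamma DFE shape).

## Worked example

Simulate one species pair under the reference conditions (θ = 0.01,
T = 0.1, 2n = 8, a Gamma(0.4, 1000) deleterious DFE with 1% of
advantageous mutations of mean scaled effect 10, A = 0) and re-estimate
the adaptive rate:

```r
library(adaptiveMK)
truth <- referenceParams("gammaexpo")
scenario <- SimScenario(truth, nChrom = 8, LN = 1e6, LS = 3e5)
trueAlpha(scenario)
#> [1] 0.5863315

d <- sampleDataset(scenario, replicate = 1, seed = 7)
d
#> PolyDivData 'sim_r001': 2n = 8 (unfolded)
#>   P_N = 3269 SNPs over L_N = 1e+06 sites
#>   P_S = 8056 SNPs over L_S = 300000 sites
#>   D_N = 15578 (Ldiv_N = 1e+06), D_S = 29845 (Ldiv_S = 300000)

fit <- fitMinusA(d, "gammaexpo", restarts = 2, seed = 1)
fit
#> FitResult [gammaexpo, minus_A]: loglik = -71.8246, AIC = 167.6492, k = 12
#> ModelParams: theta = 0.01007, T = 0.09949, A = 0, 7 r-classes
#> DFEModel 'gammaexpo': shape = 0.4534, mean_del = 584.4, p_pos = 0.008952, mean_adv = 11.88

adaptiveRates(d, fit@params)
#> AdaptiveRateEstimate (S_adv = 5):
#>   dN/dS = 0.1566, omega_na = 0.0574, omega_a = 0.09919, alpha = 0.6334
```

The fit recovers θ and T to well under 1%, the DFE shape (0.45 vs 0.4),
and an α̂ of 0.63 against a generating value of 0.59 on this single
replicate; averaging over replicates removes most of the residual
scatter (see `tests/testthat/test-acceptance.R`). d<sub>N</sub>/d<sub>S</sub>
= 0.157 decomposes into a non-adaptive part ω<sub>na</sub> = 0.057 —
weakly deleterious mutations that drifted to fixation — and an adaptive
part ω<sub>a</sub> = 0.099.

A command-line wrapper is installed as `exec/adaptiveMK` with
subcommands `simulate`, `fit`, `sfs` and `meta`, e.g.

```sh
adaptiveMK simulate --family gammaexpo --replicates 10 --seed 1 --out-dir sim/
adaptiveMK fit --input sim/datasets.tsv --model scan --out-dir fits/
adaptiveMK meta --summary fits/summary.tsv --out-dir meta/
```

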