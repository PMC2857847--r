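# gsprior

Bayesian whole-genome regression for genomic selection: how sensitive is
the accuracy of genomic breeding values (GEBV) to the prior placed on
marker effects?

The package is for quantitative geneticists and animal breeders who want to
compare, on a common footing and with known ground truth, the four classical
whole-genome regression methods:

* **Bayes BLUP** — all SNP effects share one normal variance
  (infinitesimal-model analogue), the variance itself sampled by Gibbs;
* **Bayes A** — per-SNP variances with scaled inverse-χ²(ν, S) priors,
  giving a marginal *t* distribution on effects;
* **Bayes A/B hybrid** — a mixture prior in which a proportion 1−π of
  effects is exactly zero, implemented as reversible-jump in/out moves run
  every *k* Gibbs iterations (excluded SNPs held at zero in between);
* **Bayes C / SSVS** — a Bernoulli(π) indicator assigns each effect to a
  "large" or "near-zero" (ratio *c*) variance component, all by Gibbs.

All methods fit, per time point,

    y = 1μ + Σ_j X_j β_j + Z u + e,   u ~ N(0, A σ²_u),   e ~ N(0, I σ²_e)

with flat χ⁻²(−2, 0) priors on the variance components and A the
pedigree-derived additive relationship matrix (tabular method; sparse A⁻¹ by
Henderson's rules with exact inbreeding). GEBV_i = Σ_j x_ij β̂_j per time
point, and the GEBV at the unobserved day 600 is a per-animal least-squares
line through days 265/397/530 evaluated at 600.

Because the benchmark dataset the design emulates is not redistributable,
the package includes a gene-drop simulator (`sim_dataset()`) producing a
pedigreed population with 435 SNPs, 21 QTL (the largest explaining 10.5% of
genetic variance), phenotypes on the linear part of a growth curve at days
265/397/530 for ~2,050 training animals, and 50 unphenotyped full-sib
validation families — with true breeding values (TBV) recorded at all four
days, so accuracy is measured exactly.

## Worked example

```r
library(gsprior)
ex <- run_experiment(sim_config(), seed = 1, chain = chain_config(5000, 1000))
print(ex)
```

takes about a minute (12 chains) and prints:

```
gs_experiment (seed 1)

Validation-set accuracy at the extrapolation point:
  method correlation   mse rank regression
    blup       0.895 3.912 0.75      0.972
  bayesA       0.947 2.720 0.79      0.899
 bayesAB       0.992 0.193 0.93      0.956
  bayesC       0.979 1.042 0.86      0.936

Between-method GEBV correlations:
         blup bayesA bayesAB bayesC
blup    1.000  0.981   0.902  0.947
bayesA  0.981  1.000   0.955  0.987
bayesAB 0.902  0.955   1.000  0.987
bayesC  0.947  0.987   0.987  1.000
```

Reading the first table: `correlation` is Pearson r between each method's
day-600 GEBV and the true breeding values of the 650 unphenotyped validation
animals — every method exceeds 0.85, i.e. all four priors produce highly
accurate predictions on this architecture, with the mixture priors
(Bayes A/B, Bayes C) ahead of BLUP. `mse` is the mean squared error in
squared trait units, `rank` the fraction of the 100 truly best animals
recovered in the predicted top 100, and `regression` the slope of true on
predicted (1 = unbiased). The second table shows the methods largely agree
with one another, BLUP least so — the signature of equal- versus
unequal-variance priors.

The numbered scripts under `analysis/` run the same study as separate
stages (simulate → fit → predict → evaluate → π sweep), writing plain-text
tables under `results/`; `analysis/05_pi_sweep.R` maps Bayes C accuracy over
π ∈ {0.05, 0.1, 0.2, 0.3, 0.4, 0.6, 1} and checks that the
accuracy-maximizing π tracks the simulated nonzero fraction.

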