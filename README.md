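# imcoal

Two-deme isolation–migration demographic inference from the joint site
frequency spectrum (JSFS), with the supporting population-genetic
statistics of a phylogeographic study: diversity, hierarchical AMOVA,
Mantel tests, and a ddRAD-like synthetic data generator.

## The problem

A species split into a western and an eastern lineage leaves a signature
in the JSFS — the matrix counting SNPs by their joint derived-allele
counts in the two populations. `imcoal` asks which of ten
isolation–migration histories best explains an observed spectrum:
isolation only (M1), continuous symmetric or unidirectional gene flow
(M2–M4), or gene flow restricted to an ancient or a recent epoch
(M5–M10), including the secondary-contact history (M6) in which two
long-isolated lineages recently resumed exchanging migrants.

The machinery is the one used by simulation-based SFS fitters:

* the expected JSFS under a candidate history is approximated by
  structured-coalescent simulation, accumulating branch length per
  descendant-count class (no mutation noise);
* the fit criterion is the multinomial composite log-likelihood
  `sum m_ij log p_ij` over polymorphic cells, compared against the
  saturated bound `sum m_ij log(m_ij / M)`; the replicate optimization
  minimizing the gap between the two wins;
* candidate models are ranked by `AIC = 2k - 2 lnL` and Akaike weights
  `w_m = exp(-dAIC_m/2) / sum exp(-dAIC/2)`;
* uncertainty comes from a parametric bootstrap: re-simulate spectra from
  the fitted history, refit, and take percentile 95% intervals.

Default conventions: mutation rate 3.5e-9 per site per generation,
generation time 0.5 years, and (at full scale) 50 replicate
optimizations × 50,000 coalescent simulations per likelihood evaluation ×
40 cycles. See the methods vignette (`vignettes/imcoal-methods.Rmd`) for
the model ledger, the optimizer, the scale-anchoring step that makes
absolute sizes and times identifiable from a pure-SNP spectrum, and known
limitations.

## A worked example

Simulate 20,000 unlinked SNPs (10 + 10 haploid samples) under the
package's reference secondary-contact history — a large western deme
(N_W ≈ 7.0M), a much smaller eastern deme (N_E ≈ 550k), an old split
(≈384 kya) and recent asymmetric contact — then refit the generating
model:

```r
library(imcoal)
truth <- reference_history()
obs <- generate_jsfs("M6", truth, sample_config(10, 10), 20000,
                     inference_settings(seed = 1), seed = 1001)
fit <- fit_model(obs, "M6",
                 inference_settings(n_sims = 5000, n_cycles = 20,
                                    n_reps = 5, seed = 1))
fit
```

```
Model M6 fit: lnL_est = -29069.657, lnL_obs = -29023.846, delta = 45.811, AIC = 58153.315
       N_anc       N_west       N_east        T_div    T_contact         m_EW
5.923106e+03 6.781234e+06 5.385383e+05 3.860408e+05 2.689971e+04 1.300000e-07
        m_WE
4.000000e-08
```

The three effective sizes and the divergence time come back within a few
percent of the generating values, and the migration asymmetry keeps its
direction (`m_EW > m_WE`). The contact time and the migration rates
individually sit on a ridge — a short contact epoch constrains mainly
their product `m * T_contact` — so only their combination (and ordering)
is meaningful at this scale; the methods vignette discusses this
identifiability limit and why model selection among nested gene-flow
variants is far harder than parameter recovery on such data.
`select_models(obs, model_ids(), ...)` fits all ten variants and returns
the AIC/weight table, and `parametric_bootstrap(fit)` attaches percentile
95% CIs.

A command-line wrapper covers the same pipeline
(`inst/exec/imcoal simulate | sfs | fit | select | bootstrap | stats |
mantel`), writing a YAML log with settings and seeds next to every
output.

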