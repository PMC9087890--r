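---
title: "Methods: two-deme isolation-migration inference from the joint SFS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-deme isolation-migration inference from the joint SFS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model family

`imcoal` fits two-population isolation-migration (IM) histories to a joint
site frequency spectrum (JSFS). A history is described by seven quantities:
three diploid effective sizes ($N_0$ ancestral, $N_W$ western, $N_E$
eastern), a divergence time $T_0$ and a migration-regime change time $T_1$
(both in years, converted internally to generations with the generation
time), and two per-generation migration probabilities $m_{EW}$ (eastern
lineage into western) and $m_{WE}$ (the reverse). Ten model variants place
gene flow differently in time:

| id  | gene flow | direction |
|-----|------------------------|---------------------|
| M1  | none | — |
| M2  | continuous over $[0, T_0)$ | symmetric |
| M3  | continuous | west→east only |
| M4  | continuous | east→west only |
| M5  | ancient only, $[T_1, T_0)$ | symmetric |
| M6  | recent only, $[0, T_1)$ (secondary contact) | bidirectional, asymmetric |
| M7  | recent only | west→east only |
| M8  | recent only | east→west only |
| M9  | ancient only | west→east only |
| M10 | ancient only | east→west only |

The assignment of topologies to the labels M2–M5 and M7–M10 is a documented
package convention (an explicit, overridable table in `R/models.R`); only
M6 — recent bidirectional secondary contact — is pinned by the empirical
result it reproduces. The enumeration covers each combination of timing
(continuous / ancient-only / recent-only) and direction at most once.

Migration parameters are interpreted as *backward* per-lineage
per-generation probabilities, with labels matching the forward description:
$m_{EW}$, "migration of the eastern lineage into the western lineage",
is the rate at which a lineage sampled in the west traces back into the
east. This label-to-rate mapping lives in exactly one place
(`build_model()`); whether a published rate is forward or backward is
rarely stated, so the convention is explicit and swappable.

## Expected spectra by structured-coalescent simulation

The expected JSFS under a history is approximated by simulating `n_sims`
genealogies of the sampled lineages under the structured coalescent with
piecewise-constant sizes and rates (coalescence at rate $k(k-1)/(4N)$ per
deme, migration per lineage, epoch boundaries and the merge into the
ancestral deme as deterministic barriers), and accumulating *branch length*
per descendant-count class $(i, j)$. Under infinite sites, the probability
that a polymorphic SNP falls in cell $(i,j)$ is the expected branch length
of that class over the expected total; accumulating length rather than
dropping Poisson mutations (Rao-Blackwellization) removes the mutational
noise layer entirely, giving strictly lower variance per simulated
genealogy. The monomorphic corners $(0,0)$ and $(n_W, n_E)$ are masked.
Empty cells are floored at `min_cell_prob`, by default
$1 / (10\, n_\mathrm{sims}\, C)$ with $C$ the number of unmasked cells, and
the spectrum renormalized; the floor vanishes as `n_sims` grows.

One numerical device matters for robustness: when migration within an epoch
is much faster than coalescence (by default, more than 200 expected
migration events per lineage per expected pair-coalescence time, with
enough epoch length to equilibrate), the two demes are simulated as a
single effective pool in the strong-migration limit, with pair coalescence
rate $\pi_W^2/(2N_W) + \pi_E^2/(2N_E)$ at the stationary location
distribution $\pi$, and locations redrawn from $\pi$ at the epoch boundary.
This is the standard strong-migration limit of the structured coalescent;
without it, optimizer excursions into (large $N$, large $m$) corners cost
billions of migration events per likelihood evaluation. The approximation
error is $O(1/200)$ in a regime where the spectrum is insensitive to the
exact rates, and the engine as a whole reproduces an independent
coalescent simulator (msprime, branch-mode joint AFS) to total variation
distance below $10^{-3}$ at the reference history — the test suite asserts
$< 0.02$ at 50,000 genealogies per side.

Genealogies use exponential waiting times (continuous-time approximation of
the discrete-generation model, error $O(1/N)$); lineage pairs coalesce
uniformly at random; the RNG is R's seeded stream, so identical seeds give
identical spectra. The engine never simulates recombination within loci,
sequence evolution beyond infinite sites, or selection.

## Composite likelihood, optimization and model selection

With observed counts $m_{ij}$ (monomorphic corners excluded throughout) and
floored expected probabilities $p_{ij}$, the composite log-likelihood is
the multinomial form $\sum m_{ij} \log p_{ij}$; the saturated bound
$\sum m_{ij} \log (m_{ij}/M)$ plays the role of the "maximum observed
likelihood", and the fit quality measure is
$\delta = \ln L_\mathrm{obs} - \ln L_\mathrm{est} \ge 0$. Natural
logarithms are used everywhere; AIC is $2k - 2\ln L_\mathrm{est}$ with $k$
the number of parameters the model estimates. Since a fixed dataset
rescales all models' likelihoods identically under a change of log base,
Akaike weights are unaffected by this convention.

Each of `n_reps` replicate optimizations starts from an independent uniform
draw in the log10 search box (sizes $10^2$–$10^8$ diploid individuals,
times $10^2$–$10^7$ years, migration $10^{-9}$–$10^{-3}$; brackets the
reference estimates by at least two orders of magnitude) and performs
`n_cycles` conditional-maximization cycles: one bounded golden-section 1-D
search per free parameter per cycle, on the log10 scale, within a bracket
around the current value whose half-width shrinks across cycles
(`max(0.2, 4 * 0.75^cycle)` decades), respecting $T_1 < T_0$. Within a
replicate the simulation seed of every likelihood evaluation is fixed
(common random numbers), so the Monte Carlo surface is deterministic and
1-D searches are well-posed. The replicate with the smallest $\delta$ wins;
ties resolve to the lower replicate index.

### Anchoring the absolute scale

A polymorphism-conditioned JSFS is *exactly* invariant under the rescaling
$N \to aN$, $T \to aT$, $m \to m/a$: a pure-SNP spectrum identifies only
the shape of the history, not its scale. Real ddRAD datasets carry the
missing information in their total assembled length, and the fitter uses it
the way SFS tools conventionally do with a known mutation rate: when the
observed spectrum records `n_sites` (total surveyed sites), the parameter
vector is rescaled along the invariance ridge after every cycle so that the
expected SNP yield, $\mu \times n_\mathrm{sites} \times E[\text{total tree
length}]$, equals the observed SNP count. The rescaling leaves the
composite likelihood unchanged (the ridge is exact) and pins sizes and
times in absolute units. Spectra generated by `generate_jsfs()` record the
implied `n_sites` of their generating history for this purpose. Without
`n_sites` and without a user-fixed parameter, `fit_model()` warns that
absolute values are only weakly identified.

A related, weaker ridge is intrinsic to secondary-contact histories: when
the contact epoch is much shorter than within-deme coalescence times, the
spectrum constrains mainly the *flux* $m \times T_1$, not $m$ and $T_1$
separately (the likelihood does bound $T_1$ above, because old migrants
would carry multi-lineage clades across). The contact-time estimate
therefore has wide, asymmetric uncertainty at desk scale, which is why the
package's recovery checks hold $T_1$ only to ±50% while sizes and the
divergence time are held to ±15%.

### What AIC selection can and cannot resolve here

The ten candidate models are heavily nested: the secondary-contact model
reproduces continuous migration as $T_1 \to T_0$, and any weak-flux
history is approximated by several neighbors that match its total migrant
flux. When the generating history's flux is small (of order $10^{-3}$
migrant lineages per genealogy, as in the reference parameterization), the
Kullback–Leibler separation between the true model's spectrum and the best
competitor's can amount to only a few log-likelihood units across tens of
thousands of SNPs — the same order as the sampling noise of the dataset —
while AIC's complexity penalty (2 units per extra parameter) works against
the richer true model. In that regime the Akaike weight of the generating
model over replicate datasets is widely dispersed, and no optimizer
settings change this: it is an information limit of the data design, not a
numerical one. Sharp selection (weight near 1) is expected only when the
data separate the candidates by much more than the parameter penalty —
e.g. strong migration, more samples, or spectra that no simpler candidate
can mimic. The package therefore reports the full weight table rather
than only a winner, and the recovery checks treat parameter recovery
(which is well-conditioned here) separately from model identity.

## Parametric bootstrap

Confidence intervals use the parametric bootstrap: `n_boot` spectra of the
observed SNP count are drawn multinomially from the fitted model's expected
spectrum and refitted (by default at a reduced replicate count, 5 instead
of 50; a flag restores full scale). The per-parameter mean and the 2.5%
and 97.5% percentiles are reported — the percentile method, since no
interval construction is prescribed by convention beyond "95% CI". All
refits share one optimization seed, so replicate-to-replicate variation
reflects multinomial resampling rather than refit noise. The test suite
includes a reduced-scale calibration study (20 generating histories ×
50 replicates, two free parameters) checking that nominal 95% intervals
cover the truth at a rate binomially consistent with 95%.

## Supporting statistics

* `diversity()`: observed heterozygosity, unbiased expected heterozygosity
  $\frac{2n}{2n-1} 2\hat p (1-\hat p)$, and per-SNP nucleotide diversity
  (mean pairwise allele-difference proportion). The per-*SNP* denominator
  is stated explicitly in the documentation because per-site values would
  require the monomorphic site count.
* `amova()`: hierarchical analysis of molecular variance on squared
  Euclidean dosage distances (equivalent to the locus-by-locus formulation
  summed over loci), with unequal-sample-size coefficients, $\Phi$
  statistics, and permutation p-values (populations among groups for
  $\Phi_{CT}$, individuals among populations within groups for
  $\Phi_{SC}$, individuals among all populations for $\Phi_{ST}$; add-one
  convention, so p is never 0). Missing dosages are imputed at the locus
  mean. The permutation scheme follows the conventional hierarchy but may
  differ in detail from specific legacy software.
* `mantel()`: Pearson correlation over upper-triangle entries with
  simultaneous row/column permutation of the second matrix, one-tailed for
  positive association; exact enumeration available for small matrices.
* `geo_distances()`: haversine great-circle distances, Earth radius
  6371 km.

## The synthetic data generator

`generate_dataset()` emulates the structure the inference assumes, at the
scale of the empirical dataset the package was modeled on: 1,179 unlinked
biallelic loci, one SNP per locus, ~3% missing genotypes, ten pure
populations of 10 diploids split across two diverged lineages plus two
admixed populations. For each locus one genealogy is simulated for all
sampled haplotypes and a single mutation is placed on a branch chosen
proportionally to length — exactly the "one random SNP per locus" sampling
under infinite sites, and automatically conditioned on polymorphism.
Admixture is haplotype-level: each haplotype of an admixed individual
descends from the western pool with probability $\alpha$, independently
per locus. This produces the mixed-ancestry heterozygosity signal of a
hybrid population with a single controllable knob, without simulating the
contact demography per individual. Coordinates lie on a jittered west-east
longitudinal gradient and environment variables are linear in longitude
plus noise, so isolation-by-distance and isolation-by-environment tests
have known positive effects.

What the generator does *not* emulate: read-level error, RAD-locus
dropout beyond uniform missingness, linked sites within loci,
mitochondrial-nuclear discordance, and selection. Passing tests on these
data therefore validate the estimator machinery, not robustness to those
real-data pathologies.

## Problem sizes and numerical choices

The package's own recovery checks run at a deliberate desk scale: expected
spectra from 5,000 genealogies per likelihood evaluation, 20 cycles, 5
replicates per model, 20,000 SNPs at 10+10 haploid samples (the full-scale
convention of the workflow it mirrors is 50,000 simulations, 40 cycles and
50 replicates — `inference_settings()` defaults). Engine oracle checks use
50,000 genealogies; the bootstrap calibration uses 20 × 50 refits of a
two-parameter model. Degenerate inputs are handled explicitly: zero-length
epochs are dropped and identical adjacent epochs merged (so a contact model
with zero rates is *identical*, stream-for-stream, to isolation-only);
constant distance matrices flag `r = NaN`; fully monomorphic genotype
tables flag AMOVA $\Phi$ as `NaN`; empty expected cells are floored before
logs.

## Known limitations

* Composite (not full) likelihood: SNPs are treated as independent;
  parameter uncertainty must come from the bootstrap, not the curvature.
* The contact-time / migration-rate flux ridge discussed above.
* A small ancestral population behind an old split contributes little
  branch length, so $N_0$ is held only to a factor of 2 at desk scale.
* No three-population models, growth epochs, or within-locus
  recombination; unpolarized data are handled by folding, not by outgroup
  inference.
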