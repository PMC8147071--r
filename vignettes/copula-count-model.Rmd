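---
title: "The copula count model behind sccopula"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The copula count model behind sccopula}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sccopula)
```

## The model

sccopula treats a labelled scRNA-seq experiment as a collection of cell
types, each with its own joint distribution of gene counts. Within one cell
type, gene $i$'s counts follow a zero-inflated negative binomial
$\mathrm{ZINB}(p_i, \psi_i, \mu_i)$: with probability $p_i$ the gene drops
out (a structural zero), otherwise the count is negative binomial with mean
$\mu_i$ and dispersion $\psi_i$ (variance $\mu_i + \mu_i^2/\psi_i$).
Poisson, zero-inflated Poisson (ZIP) and plain NB are the $p_i = 0$ and/or
$\psi_i = \infty$ special cases, and the fitter picks among the four
automatically:

* if the gene's sample mean is at least its unbiased sample variance (no
  over-dispersion), Poisson and ZIP are fitted by maximum likelihood and a
  likelihood-ratio test with a $\chi^2_1$ null decides whether the
  zero-inflation weight is worth keeping;
* otherwise NB and ZINB are fitted and tested the same way.

The default test level is $\alpha = 0.05$. Because the null value
$p_i = 0$ sits on the boundary of the parameter space, the $\chi^2_1$
reference makes the test conservative — the realised false-selection rate
under a true Poisson gene stays below $\alpha$ — and we keep that reference
rather than substituting the $\tfrac12\chi^2_0 + \tfrac12\chi^2_1$
mixture, so that selection behaves exactly as documented. Ties in the
dispersion branch (mean exactly equal to variance) go to the
no-over-dispersion side, reading the inequality literally.

Dependence between genes is modelled with a Gaussian copula. Counts are
discrete, so the copula of the joint law is not identifiable from the
marginals alone; the *distributional transform* resolves this. With
$V_{ij} \sim \mathrm{Uniform}[0,1]$ drawn independently,

$$U_{ij} = V_{ij} F_i(X_{ij} - 1) + (1 - V_{ij}) F_i(X_{ij})$$

is exactly uniform when $F_i$ is the true marginal CDF, spreading each
atom of the discrete distribution uniformly over a unit interval. The
fitted copula correlation $\widehat{R}$ is the sample covariance of the
standard-normal quantiles of these scores. The latent correlation relates
to Kendall's tau of the underlying variables through
$R_{hl} = \sin(\pi \tau_{hl} / 2)$, which both interprets $\widehat{R}$
and provides an alternative plug-in estimator from sample tau values
(`corr_estimator = "tau"`); the plug-in is faster and free of the
auxiliary randomisation but not guaranteed positive semidefinite, so the
Gaussian-scores route is the default and either result is repaired by
eigenvalue clipping if floating-point drift produces a negative
eigenvalue.

Genes are partitioned before fitting. Group 1 — zero proportion below a
cutoff (default 0.8) — is modelled jointly with the copula; group 2 —
sparser genes still seen in at least three cells — gets independent
marginals; group 3 — genes expressed in fewer than three cells — is
generated as all zeros. Correlations of very sparse genes are neither
interesting nor estimable, which is what the cutoff encodes; lowering it
shrinks the copula block monotonically. A gene meeting both the group-1
and group-3 definitions (possible only for tiny cohorts) goes to group 3:
a gene seen in under three cells is never copula-modelled.

## Generation and depth rescaling

Synthetic data are drawn at a user-chosen cell number $n'$ and expected
total count $N'$. Cell-type counts $n^{(k)\prime}$ come from
$\mathrm{Multinomial}(n', \hat\pi)$ with $\hat\pi^{(k)} = n^{(k)}/n$
estimated from the training labels. Each type's unscaled depth is
$N^{(k)0} = (N^{(k)}/n^{(k)})\, n^{(k)\prime}$ and the common scaling
factor $r = N' / \sum_s N^{(s)0}$ multiplies **every modelled gene's mean**
(zero-inflation weight and dispersion untouched), so the expected grand
total equals $N'$ while the realised total fluctuates, as in a real
sequencing run. Because only $\mu$ is rescaled, the NB variance function
changes shape with depth; that is the model's stated behaviour, not an
artefact. The model notation does not distinguish group-1 from group-2
genes when rescaling, so we apply $r$ uniformly to both.

Group-1 cells are generated by drawing latent vectors from
$N(0, \widehat{R})$, mapping coordinates through $\Phi$ and then through
each gene's rescaled marginal quantile; group-2 genes are independent
draws; group-3 genes are zeros. The latent draw uses an eigen
decomposition with negative eigenvalues clipped at zero, which covers the
rank-deficient case of more copula genes than training cells. The draw
order is fixed (latent Gaussian block first, then independent genes in
gene order), and the RNG algorithm (Mersenne-Twister) is recorded in model
archives, so a seed reproduces a matrix bit for bit, before or after a
save/load cycle. The `use_copula = FALSE` variant keeps the marginals and
drops the dependence — useful for quantifying what correlation modelling
adds.

## Numerical choices

* NB/ZINB likelihoods are maximised by quasi-Newton search (with a
  Nelder–Mead retry) in unconstrained $(\mathrm{logit}\, p, \log\psi,
  \log\mu)$ coordinates, started from the sample mean, a
  method-of-moments dispersion clipped to $[10^{-2}, 10^4]$, and the
  observed excess-zero fraction. These starts make the nested-likelihood
  inequalities (ZINB ≥ NB ≥ Poisson, ZIP ≥ Poisson) hold in practice, and
  each fitter enforces them by falling back to the nested optimum if the
  optimiser returns anything worse.
* A fitted dispersion above $10^8$ is treated as the Poisson/ZIP limit:
  the fit degrades to the closed-form nested fit, flagged `degraded`, with
  $\psi = \infty$ as the stored sentinel.
* Fit failures degrade along ZINB → NB → Poisson and ZIP → Poisson with a
  warning naming the gene; a simulator should not abort on one
  pathological gene.
* All-zero genes are recorded as $p = 1, \mu = 0$ (they land in group 3
  anyway and always generate zeros).
* Transform scores are clipped into $[10^{-10}, 1 - 10^{-10}]$ before the
  normal quantile so $\Phi^{-1}$ stays finite.
* The sample covariance of the normal scores has diagonal near, but not
  exactly, one; it is standardised to a correlation matrix because
  generation assumes standard-normal latent components.
* Kendall's tau is the tie-corrected tau-b, computed from the pair's joint
  contingency table (concordant/discordant counts via 2-D cumulative
  sums). For counts, whose distinct values are few, this is exact and far
  faster than generic $O(n^2)$-per-pair scanning; tests verify it against
  both a brute-force pair count and `stats::cor`.

## What the fixtures emulate — and what they do not

`ground_truth_spec()` / `make_ground_truth_model()` build fully synthetic
cell-type models (chosen families, parameter ranges, and an identity,
exchangeable or block correlation), so every pipeline stage can be tested
against known truth with no downloads. They emulate the *model's* view of
data: ZINB-family marginals coupled by a Gaussian copula. They do not
emulate what real scRNA-seq adds on top — batch effects, cell-cycle and
pseudotime structure, cross-type doublets, or spatial coordinates — so a
passing round-trip shows the implementation is faithful to the model, not
that the model captures everything in a real experiment.

Two fixture choices deserve a note:

* **Family-recovery checks use over-dispersed fixtures (NB + ZINB).** The
  selection procedure branches on the sample mean/variance comparison and
  only ever tests for zero inflation, so a true Poisson gene is labelled
  NB (with a very large fitted dispersion) whenever its sample variance
  happens to exceed its mean — roughly half the time at any sample size.
  The Poisson/NB *label* is thus unidentifiable at the boundary even
  though the fitted *distribution* is essentially identical. Family
  recovery is therefore measured where labels are identifiable, which is
  also the realistic regime: real scRNA-seq genes are predominantly
  over-dispersed.
* **The correlation-recovery study is run at desk scale.** The full-size
  study uses 1000 replicates and gene panels up to 2000 drawn from models
  fitted to real data; the in-package experiment uses 50 replicates,
  a 50-gene panel and cohorts of 20–500 cells, which reproduces the
  qualitative behaviour (error falling with $n$, rising as sparser genes
  enter the panel, crossing the 0.09 / 0.04 / 0.01 quality levels) at a
  few minutes' cost. `correlation_recovery_experiment()` accepts any
  fitted `cell_type_model`, including one fitted from real accessions,
  for a full-scale rerun.

## Known limitations

* Correlation estimation needs enough cells: below roughly 20 cells the
  copula matrix is dominated by sampling noise (the recovery curve
  quantifies this), and with one cell the fit falls back to independent
  marginals with a warning.
* The marginal family is selected per gene without shrinkage across genes;
  very low counts can make ZINB parameters weakly identified, in which
  case the likelihood-ratio test simply keeps the simpler family.
* Rescaling depth changes only the means; extreme scaling factors
  extrapolate the mean–variance relationship outside the fitted range.
* Pair-statistic evaluation is quadratic in the number of genes kept by
  the zero-proportion filter; use `top_k` to bound it for large panels.
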