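---
title: "Local regulatory networks: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local regulatory networks: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lrnkit)
```

## The inference problem

A local regulatory network (LRN) describes the regulatory neighborhood of a
single gene as a directed acyclic graph over typed nodes: a phenotype `p`,
the gene's mRNA level `e`, cis DNA-methylation sites `m`, cis histone-
acetylation peaks `h`, the best-associated SNP for each molecular trait
(`g_e`, `g_m`, `g_h`), and one composite hidden covariate per molecular
feature (`C_e`, `C_m`, `C_h`). Cross-omic correlations alone cannot orient
edges among molecular traits, but genotype can: a SNP's value is fixed at
conception, so any dependence between a SNP and a molecular trait must run
from the SNP outward. `lrnkit` encodes this as a hard structural constraint
— SNP nodes may have outgoing edges only — and lets the data resolve the
remaining orientations.

## Structure model and score

For observations `X` and DAG `G` with parent sets `G_j`, the likelihood
factorizes into per-family terms, and structures are sampled from the
posterior `P(G | X) ∝ P(X | G) P(G)`. Two modeling choices are genuinely
open and are made explicitly here:

* **Conditional distributions.** Families are scored with the BGe metric:
  the closed-form marginal likelihood of a Gaussian child given Gaussian
  parents under a conjugate normal–Wishart prior. We choose it because (i)
  all non-genetic node values are quantile-normalized to standard-normal
  margins before scoring, so Gaussian families are exactly the working
  scale; (ii) BGe is decomposable, making single-edge MCMC cheap; and (iii)
  it is score-equivalent — Markov-equivalent DAGs receive identical scores
  — so orientation information comes only from the anchors and from
  v-structures, never from scoring artifacts. Hyperparameters are
  `alpha_mu = 1`, `alpha_w = p + 2`, prior scale `T = t I` with
  `t = alpha_mu (alpha_w − p − 1) / (alpha_mu + 1)` on column-standardized
  data, i.e., a unit-variance-scaled identity prior. A Gaussian BIC family
  score is available via `score = "bic"` for sensitivity checks.
* **Structure prior.** `P(G)` is uniform over mask-respecting DAGs. The
  mask already carries all prior knowledge we are willing to assert (parent
  menus per node class, SNP and covariate nodes as roots, anchors tied to
  their own mark, no self-edges); beyond it we see no defensible reason to
  prefer sparser or denser structures a priori.

Dosage values enter the score as they are (0/1/2, standardized internally);
treating a three-level variable as Gaussian is a pragmatic approximation
shared by most systems-genetics scoring schemes.

## Sampler

`structure_mcmc()` runs Metropolis–Hastings over mask-respecting DAGs,
starting from the empty graph. Proposals mix:

* single-edge addition / deletion / reversal, drawn uniformly from the
  current valid neighborhood, with the neighborhood-size ratio in the
  acceptance probability (14/15 of proposals);
* the new-edge-reversal (REV) move (1/15 of proposals, `rev_prob`
  configurable): an existing edge `i → j` is reversed and the parent sets
  of both endpoints are resampled from their score-weighted conditional
  distributions. Both proposal densities are computed explicitly from the
  partition sums over valid parent subsets, so the acceptance ratio is
  exact by construction; algebraically the sampled-set weights cancel and
  the ratio reduces to the familiar partition-sum form. REV moves matter
  because plain edge reversal of a well-supported edge is almost always
  rejected, trapping chains in one orientation basin.

Defaults are 75,000 steps with the first 10% discarded as burn-in and
**every** post-burn-in iteration tallied (no thinning); edge frequencies
are the tallied proportions. Family scores over all allowed parent subsets
are precomputed once per node set (bounded at 12 allowed parents per node,
i.e., 4,096 subsets), so each MCMC step is a table lookup plus an
incremental acyclicity check; the loop is compiled (Rcpp) and a 75,000-step
run on a 4–7-node LRN takes tens of milliseconds. Acceptance rate and a
log-score trace are returned as diagnostics; a run with zero accepted moves
on a non-trivial mask warns and dumps the trace.

`exhaustive_posterior()` enumerates every mask-respecting DAG (refusing
networks with more than six constrained nodes) and marginalizes edge
probabilities exactly with a streaming log-sum-exp. It exists as the
independent oracle: the test suite requires MCMC edge frequencies at the
default settings to match enumeration within ±0.05 per edge on random
small networks.

## Consensus and relation labels

Per unordered pair the most frequent of `i → j`, `j → i`, and independent
(frequency `1 − f_ij − f_ji`) is kept; exact ties resolve to independence
(the conservative state). Because pairs are voted independently the
consensus digraph can, in principle, contain a cycle; when that happens the
lowest-frequency edge inside each strongly connected component is dropped
until acyclicity holds, with a warning. Relation labels use directed-path
reachability (`classify_relation()`), with one deliberate asymmetry:
a gene is called upstream of a phenotype only on a **direct** `e → p`
edge, while downstream uses any path `p ⇝ e`. The direct-edge rule for
upstream calls is the stricter reading of the classification used for
gene–phenotype relations; path-based downstream/independent is the only
reading that yields a three-way partition. Labels supported by at least 3
of 4 phenotype contexts (`consensus_across_phenotypes()`) form the
cross-phenotype consensus; a support tie between labels drops the pair so
an ordered pair never carries two labels.

## Association mapping

Cis windows are symmetric about the feature anchor — the TSS for genes, the
peak center for marks — truncated at position 1; conventional half-widths
are 50 kb (eQTL, haQTL), 5 kb (mQTL) and 1 Mb (eQTM/eQTH). Feature-level
significance uses the permutation minimum-p scheme: shuffle the feature's
values, take the best candidate statistic per shuffle, and report
`(1 + #{better}) / (n_perm + 1)` with 1,000 permutations by default (the
direct empirical estimate; no Beta-tail approximation is applied at these
desk scales). FDR control is Benjamini–Hochberg on the permutation
p-values. eQTM/eQTH mapping applies two layers — peak-level BH across all
gene–peak pairs and gene-level BH across gene permutation p-values — and a
pair is significant only if both pass, which controls the error-rate bias
from genes with many cis peaks. Missing dosages are mean-imputed per SNP;
best-SNP ties resolve to the lowest genomic position then lexicographic id,
so results are deterministic. Storey's π1 estimates the alternative
fraction from a p-value set; the default point estimate is the median of
`pi0(lambda)` over the 0.05–0.95 grid, chosen over the spline-at-0.95
smoother because the smoother's tail extrapolation has null-case sampling
noise of the same order as the quantity itself at `m ≈ 10^4`, while the
median is stable and unbiased when alternative p-values concentrate near
zero (the replication-rate use case). The smoother remains available via
`method = "smoother"`.

## What the generator emulates — and what it does not

`simulate_lrn_cascade()` draws linear-Gaussian structural equations over a
user-specified template DAG: every non-root node is the effect-weighted sum
of its standardized parents plus `N(0, noise_sd²)` noise; SNP roots are
Hardy–Weinberg dosages with MAF uniform on `maf_range`; molecular nodes
additionally load on shared hidden factors. Defaults define the reference
study conditions and were fixed a priori:

| parameter | default | rationale |
|---|---|---|
| `n_samples` | 400 | a realistic multi-omic cohort size |
| `effect_sizes` | 0.7 | a strong but not deterministic standardized effect |
| `noise_sd` | 0.5 | node variance dominated by, but not reduced to, its parents |
| `maf_range` | (0.05, 0.5] | common variants only, matching the usual MAF filter |
| `n_hidden_factors`, `factor_strength` | 1, 0.2 | ~4% of molecular variance from residual confounding, the scale that survives covariate removal |
| `n_decoy_snps` | 3 | effect-free cis candidates so windows contain decoys |

The choice of `factor_strength` deserves a note: a factor shared by `m` and
`e` opens the collider at `m` when conditioning on it, inducing a spurious
`g – e` partial correlation of roughly −0.11 at loading 0.2. This is
intentional — it makes single-context errors possible at a realistic rate —
but it is weak enough not to overwhelm the anchored chain.

Linear-Gaussian equations were chosen to match the Gaussian scoring
assumption, which makes exact posteriors computable for the oracle tests.
DNAm is generated on a latent Gaussian (M-like) scale and exported both as
latent values and as `Beta = logistic(latent)`, so the Beta→M transform is
exercised. What the generator does **not** emulate: linkage disequilibrium
among SNPs, genome-scale feature counts, non-Gaussian or nonlinear
regulation, count noise in sequencing data, missing values, and population
structure. Passing tests therefore certify the inference machinery under
its own model assumptions — identifiability through anchors, calibration of
permutation tests, correctness of the sampler — not robustness to the full
messiness of cohort data.

## Numerical choices and degenerate inputs

* Beta values are clipped to `[eps, 1 − eps]` (`eps = 1e-6`) before the
  M transform; values outside `[0, 1]` are errors.
* Quantile normalization uses normal quantiles of `(rank − 0.5) / n` with
  average ranks on ties; a constant feature maps to zeros with a warning.
  The normal target (rather than an empirical average distribution) is used
  because downstream scoring assumes Gaussian margins.
* Residualization rejects rank-deficient covariate sets by name rather than
  silently dropping columns.
* The hidden-covariate model is a truncated SVD of the feature-standardized
  matrix. Any variance-capturing factorization satisfies the composite
  contract `C_j = Σ_i w_ij F_i`; the test surface is recovery of planted
  confounding, which SVD meets. `k = 0` yields zero composites.
* The per-sample outlier statistic is `d_i = 1 −` (mean Spearman
  correlation of sample `i` with all others), flagged outside 1.5 × IQR
  beyond the quartiles of `d` — a standard connectivity statistic paired
  with the usual IQR fence.
* BGe determinants are computed per cached node subset; a singular parent
  covariance cannot occur because the Wishart prior adds `t I`.
* Permutation p-values respect the `(1 + c) / (n_perm + 1)` floor
  everywhere, so zero p-values never occur.
* Promoter (TSS ± 3 kb, strand-symmetric), gene body (TSS–TED span,
  non-promoter), downstream (3 kb past TED, strand-oriented) and intergenic
  categories overlap across gene models; assignment uses the precedence
  promoter > gene body > downstream, promoter being the focal category of
  the mark-location analyses. Positions are 1-based inclusive; interval
  sets in 0-based half-open conventions must be shifted on ingestion.

## Problem sizes used in the checks

The property checks shipped with the package use: 20 random ≤5-node
networks at n = 300 for oracle equivalence; 50 replicate genes at n = 400
(effects 0.7) for structure recovery and, with four phenotype contexts,
for relation labels; a 500-feature null at n = 200 with 1,000 permutations
for calibration plus a 50-gene signal block for empirical FDR; and 10,000
p-values for π1. These sizes make the full suite run in about a minute
while keeping Monte-Carlo noise well inside the stated tolerances.

## Known limitations

* One gene per network: influences from other genes' expression are absent,
  so some inferred edges stand in for indirect paths through unmodeled
  regulators.
* The Gaussian/BGe assumption treats dosages and any non-normalized inputs
  as Gaussian; heavy deviations should be normalized first.
* The consensus step is a per-pair majority vote; it does not propagate
  uncertainty, and its cycle-breaking (rare) is a heuristic.
* Hidden-factor composites estimated from few features absorb real signal
  along with batch structure; with very small feature panels the `C` nodes
  can shadow genuine regulators.
* π1, FDR and permutation calibration statements hold under exchangeable
  nulls; strong dependence across features weakens them.
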