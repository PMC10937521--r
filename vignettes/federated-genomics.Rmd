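---
title: "Federated learning on distributed genomic cohorts: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Federated learning on distributed genomic cohorts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

fedgeno studies a practical question in statistical genetics: when
individual-level genotype data is locked inside separate silos (hospitals,
biobanks, testing companies) that cannot pool records, how close can a
*federated* model — trained by exchanging only model parameters — come to the
centralized model that pooling would allow, and how far ahead of the purely
local models is it? The package provides the full pipeline needed to pose
that question on synthetic data: a multi-node genotype/phenotype generator
with a population-structure dial, per-node quality control, GWAS with
random-effects meta-analysis for feature selection, exact federated PCA, two
trainable models (a parallel-penalty LASSO bank for quantitative traits and a
multilayer perceptron for ancestry), a federated-averaging engine, and a
cross-validation harness that compares local, federated and centralized
training on identical test data.

```{r, eval = FALSE}
library(fedgeno)
reg <- simulate_regime("biobank", n_nodes = 19, samples_per_node = 300,
                       n_variants = 500, n_causal = 50, heritability = 0.5,
                       seed = 1)
res <- run_phenotype_experiment(reg$nodes, seed = 1)
tidy(res)
autoplot(res)
```

## The synthetic cohorts

Real multi-silo genotype cohorts are access-restricted, so the generator is a
first-class, tested component rather than a fixture. It emulates two study
regimes.

**Population structure.** Allele frequencies follow the Balding–Nichols
model: each variant draws an ancestral frequency `p` uniformly from a
configurable interval, and population `k` draws its own frequency from
`Beta(p(1-F_k)/F_k, (1-p)(1-F_k)/F_k)`. `F_k` is an interpretable divergence
dial: the Hudson FST between two populations simulated at `F` concentrates
at `F` (a property test checks this against an independent FST estimator).
`F = 0` returns the ancestral frequency exactly. Genotypes are
`Binomial(2, freq)` minor-allele dosages; calls are masked missing completely
at random at a configurable rate — QC only needs a rate to act on, so no
informative missingness is modelled.

**The many-node, low-heterogeneity regime** (`"biobank"`): 19 nodes, one
near-identical population per node with `F` in `[0.001, 0.01]`, and a shared
additive quantitative trait. A trait draws `n_causal` standard-normal effect
sizes once, shared by every node; the phenotype is
`y = G beta + b_age * age + b_sex * sex + e` with `age ~ U{40..70}`,
`sex ~ Bernoulli(0.5)`, small fixed covariate effects (defaults 0.01 and
0.1), and Gaussian noise scaled so the genetic score explains a target
heritability of the phenotypic variance. The noise SD is calibrated once
from the *pooled* genetic-score variance (`calibrate_noise_sd()`), so all
nodes share one true model. At `heritability = 0` the genetic term is
dropped entirely, giving an exact null. The regime's standard scale is 19
nodes of 2,000 samples; the packaged experiments run a desk-scale version
(19 × 300 samples, 500 variants, 50 causal, h² = 0.5) chosen so a full
10-fold comparison completes in minutes on one CPU while preserving the
node-count asymmetry and the local/federated performance gap.

**The few-node, high-heterogeneity regime** (`"continental"`): 5 nodes equal
to 5 disjoint superpopulations, 26 population labels nested in them
(balanced round-robin), `F` in `[0.05, 0.15]`, no quantitative trait. Each
of the 26 populations diverges independently from the common ancestral pool;
populations within a superpopulation are therefore no more similar to each
other than to outside populations. That is sufficient for the experiments —
superpopulation structure is carried by the node boundaries and all 26
classes are separable in PC space — but it does not reproduce the nested
hierarchy of real continental cohorts. Because variants carry no chromosome
map, LD pruning would otherwise have nothing to act on; the generator
rewrites 30% of variants as stochastic copies of their left neighbour
(per-pair copy probability drawn from `[0.5, 0.98]`, shared across nodes),
giving pruning thresholds a real frequency–correlation spectrum to bite on.

**What passing tests do and do not show.** The generator has exchangeable
variants (no LD maps beyond the injected proxy pairs), no realistic
minor-allele-frequency spectrum, no sex chromosomes, and MCAR missingness.
Results on it establish the *relative* behavior of local, federated and
centralized training under controlled heterogeneity; they say nothing about
absolute predictive performance on real cohorts.

## Quality control

Per-node QC mirrors standard array practice, with the usual printed
thresholds as defaults: sample missingness ≤ 6%, KING-robust kinship
< 0.0884 (second-degree relatives), MAF ≥ 5%, variant missingness ≤ 2%,
HWE p ≥ 1e-6. Two orderings are supported because the two study designs
historically differ: `samples_first` (sample missingness → relatedness →
variant QC) for the biobank flow and `variants_first` for the continental
flow; both are config keys.

Hardy–Weinberg is tested with the 1-df chi-square goodness-of-fit rather
than the exact test: it is closed-form and adequate at simulated genotype
counts (hundreds per node); this is a deliberate deviation from the exact
test a production PLINK run would use. Relatedness uses the KING-robust
between-family estimator
`phi = (N_AaAa - 2 N_AAaa) / (N_Aa(i) + N_Aa(j))` on pairwise-complete
sites; the greedy removal rule drops the member of each flagged pair with
the higher missingness (ties drop the later sample), which approximates
PLINK's behavior without reproducing it exactly. Note KING's sampling SD at
`m` independent variants is roughly `1/sqrt(m het)`; below a few thousand
variants, unrelated pairs can cross the 0.0884 cutoff by chance, which is a
property of the estimator, not a bug.

LD pruning slides a window (default 50 variants, step 5, r² ceiling 0.1 —
common practice; no values are prescribed by the designs) and removes the
lower-MAF member of each over-correlated pair (ties drop the later variant).
The cross-node harmonization step is a plain id union in catalog order —
only variant identifiers travel between nodes.

## Feature selection: GWAS and meta-analysis

Each node fits, per variant, OLS of the phenotype on dosage, age, sex and
its own top-20 training-fold PCs. The implementation residualizes the
phenotype and all dosage columns against the covariates once (Frisch–Waugh),
which is exactly the per-variant regression but runs as a handful of matrix
operations. Two degenerate cases get explicit handling: a phenotype fully
explained by covariates reports `beta = 0, p = 1`, and an exact linear fit
reports the smallest representable double rather than an unstable t tail.

Cross-node pooling is DerSimonian–Laird random effects — the standard
closed-form choice when "random-effects meta-analysis" is delegated to
PLINK. The implementation is hand-coded from the moment equations and
cross-checked in the test suite against `metafor::rma(method = "DL")` on
random study sets to 1e-8. Feature selection takes the `m` smallest pooled
p-values (ties: larger |pooled beta|, then catalog order). Selection, like
every other training statistic, happens inside the CV loop on training folds
only; a leakage test perturbs validation/test rows and asserts bit-identical
training outputs.

## Exact federated PCA

The shared low-dimensional feature space for ancestry prediction comes from
a stacked-eigenvector scheme. One aggregation round establishes the global
per-variant means from per-client (sum, count). Each client then
eigendecomposes its *locally centered* dosage matrix — rank at most
`n_k - 1`, so `n_k - 1` components are the full local rank — and uploads
eigenvalues and eigenvectors. The server stacks the rows
`sqrt((n_k - 1) lambda_i) v_i` together with one mean-correction row
`sqrt(n_k) (mu_k - mu)` per client (it already knows `mu_k` from the
centering round) and takes a single SVD. The stacked Gram matrix then equals
the pooled globally-centered scatter *exactly*, so the federated and
centralized top-`q` loading spans agree to numerical precision whenever the
`q`-th and `(q+1)`-th pooled singular values are separated. The mean
correction matters: without it, truncating a globally-centered client matrix
(rank `n_k`, not `n_k - 1`) to `n_k - 1` components loses a direction and
the "exact" scheme is off by a visible angle.

Genotypes are centered but not variance-standardized before PCA (a
`1/sqrt(2p(1-p))` scaling is a documented alternative the caller can apply;
centered-only is the default because nothing in the studied designs requires
the scaling and it keeps the exactness statement clean). Loading signs are
fixed (largest-magnitude entry positive) so runs are deterministic; all
subspace comparisons in tests use principal angles, never per-vector
equality. Note `acos()` cannot resolve angles below about `sqrt(eps)` ≈
1.5e-8, which sets the floor for "exact" in the assertions.

Communication is linear in the variant count: each client uploads
`d_k * m + d_k` values and receives `n_pcs * m` back.

## Models

**LASSO bank.** The quantitative-trait model minimizes, for each penalty on
a log-spaced grid, `mean((y - X b - b0)^2) + lambda * ||b||_1` with an
unpenalized intercept, features standardized by training-fold mean/SD (in
the federated arm, from one (sum, sum-of-squares, count) aggregation round).
With that objective the zero solution is optimal exactly at
`lambda_max = 2 max|X^T (y - mean(y))| / n`, which anchors the grid (32
values down to `lambda_max / 1000` by default). Optimization is proximal
mini-batch SGD: a gradient step on the squared error followed by
soft-thresholding at `eta * lambda` — chosen over naive subgradient descent
because it produces exact zeros, preserving LASSO's selection semantics.
All penalties train in one pass over each mini-batch, but each column is
updated with the *same sequence of floating-point operations* a standalone
single-penalty model would execute, so bank and standalone trainings are
bit-identical — the bank is purely an efficiency device, and the suite
asserts this. Penalty selection takes the argmin of size-weighted aggregated
validation loss over (round, penalty), ties to the larger penalty then the
earlier round.

**MLP.** The ancestry classifier is a fully connected network (reference
architecture 20 → 800 → 200 → 26 with selu activations, 182,226 parameters)
over the shared PCs, trained on mean cross-entropy with hand-rolled
backpropagation (verified against numerical gradients) and seeded mini-batch
SGD. Initialization is LeCun-style `N(0, 1/fan_in)` — the variance-scaling
scheme paired with selu — with zero biases, seeded. The scaled-down
communication sweep uses hidden sizes (64, 32) at the same input/output
widths: the sweep's subject is the schedule, not capacity, and the reference
architecture is separately instantiated and counted in the tests.

**Optimizer conventions.** Plain SGD with per-local-epoch multiplicative
decay (0.99 for the bank, 0.9999 for the MLP). The decay follows a *global*
epoch counter that continues across communication rounds, so schedules that
split a fixed total epoch budget differently consume identical learning-rate
sequences — the (R, E) split changes only the communication pattern. The
decay cadence (per epoch, not per step) is a stated assumption.

## Federated averaging

The engine implements cross-silo FedAvg: all clients participate in every
round; a round is broadcast → E local epochs per client → sample-size
weighted average `omega = sum_k (n_k/n) omega_k`. Federation is simulated
sequentially in one process; "parallel" is a semantic contract (no
cross-client state), not concurrency. Each epoch's batch shuffle is seeded
by `mix_seed(seed, client, global_epoch)`, making trajectory-equality tests
exact: a one-client federation is bit-identical to plain training, and
homogeneous clients doing full-batch single-epoch rounds match centralized
full-batch descent to 1e-10 per round.

After each aggregation the engine evaluates validation loss per client and
aggregates it weighted by validation counts (mirroring the training-side
weighting; plain averaging is the undocumented alternative). The returned
model is the best-validation checkpoint over rounds, not the last round.
Per-round logs record each client's training loss at the received
(aggregated) parameters and after local fitting — the difference is the
client-drift "spike" that heterogeneous silos produce — plus cumulative
communication (`2 K size(params)` values per round).

## The three study designs

All designs share 10-fold cross-validation with the rotation: test = fold
`t`, validation = fold `(t+1) mod 10`, train = the rest (the rotation rule
for the validation fold is our concrete choice; only the 8/1/1 split is
given). Every compared model is evaluated on the byte-identical merged test
set of its fold. Fold summaries report the median and the 0.1–0.9 quantile
interval under linear CDF interpolation (R type 7), with a "drop the extreme
pair" alternative mode.

1. **Phenotype comparison** (`run_phenotype_experiment()`): per-node variant
   QC and GWAS on training folds, DL meta-analysis, top-m selection; local
   banks on own-GWAS and on meta features, a federated bank on meta
   features, a centralized bank on centralized-GWAS features, and
   covariates-only baselines. The qualitative target: every local model
   below the federated model, federated within a hair of centralized.
2. **Communication sweep** (`run_ancestry_experiment()`): per-node pruning +
   union, federated PCA, FedAvg MLPs at epochs-per-round in {1, 2, 4, 8,
   16, 32} with the total budget fixed at 512 local epochs (a desk-scale
   stand-in for cluster-scale budgets), plus a centralized MLP. Expected
   pattern: more communication (smaller E) converges to lower validation
   loss, and post-aggregation loss spikes appear at large E.
3. **PCA input sweep** (`run_pca_sweep()`): pruning relaxed across a grid of
   r² ceilings to produce growing variant sets; federated and centralized
   PCA feed the same centrally-trained classifier; their accuracies should
   be indistinguishable (exactness) and rise to a plateau with input size.

## Numerical choices and known limitations

* Missing dosages are mean-imputed everywhere they enter linear algebra
  (GWAS, PCA, model features); QC statistics use non-missing calls only.
* Monomorphic variants: HWE p = 1 by convention; MAF 0 removes them with
  reason `maf`; an all-monomorphic block filters to an empty block, not an
  error.
* At exactly `lambda = lambda_max` the proximal update can leave a last-ulp
  coefficient; assertions about "exact zeros" use a 1e-12 tolerance.
* The KING estimator is undefined (reported `NA`) when neither sample has a
  heterozygous call.
* `fedavg_aggregate` requires conformable tensors and positive sizes;
  client failure is fatal by design (no straggler handling, no client
  sampling, no secure aggregation or differential privacy).
* Real distributed deployment, VCF/BGEN input, PLINK 2 formats, dosage
  genotypes, logistic GWAS and alternative federated strategies (control
  variates, dynamic regularization) are out of scope.

## Reproducibility

Every stochastic step derives its stream from one integer seed via a
31-bit mixing function (`mix_seed`), so whole experiments re-run
bit-identically; the suite asserts this end to end. `scripts/acceptance.R`
re-runs the main computations from scratch at the desk scales above and
writes the resulting quantities as JSON.
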