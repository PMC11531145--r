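---
title: "Models and methods for root-associated fungal community assembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for root-associated fungal community assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(rootfungi)
```

This vignette explains the statistical machinery in `rootfungi`: the models,
their assumptions, the tunable parameters, what the synthetic-data generator
does and does not emulate, and the numerical choices made where the design
was genuinely open.

## The sampling design and data model

The pipeline targets a root-tip / bulk-soil survey: a forest plot with on
the order of a hundred sampling positions at least 4 m apart; at each
position several ~1 cm root-tip samples, each assigned to a host-plant
genus, and one bulk-soil sample. Data enter as integer count matrices
(samples × OTUs), a metadata table (`sample_id`, `kind`, `position_id`,
`x`, `y`, `host_plant`) and an OTU → guild map using the controlled
vocabulary EcMF, AMF, Endophyte, Pathogen, Mycoparasite, Nematophagous,
Other_RAF, Unassigned, Unidentified.

### Coverage-based rarefaction

Samples are standardized to a common *coverage* (the probability that the
next read belongs to an already-seen OTU) rather than a common depth. The
coverage of a sample with read total $n$, $f_1$ singleton and $f_2$
doubleton OTUs is estimated as

$$\hat C = 1 - \frac{f_1}{n}\cdot\frac{(n-1)f_1}{(n-1)f_1 + 2 f_2}.$$

`coverage_rarefy()` chooses, per sample, the smallest depth whose *expected*
coverage (plugging hypergeometric expectations of $f_1$, $f_2$ into the
estimator) reaches the target — by default the minimum coverage across
samples, so the shallowest-coverage sample is kept unchanged — and draws one
without-replacement subsample at that depth. A single draw (not an average
over draws) keeps counts integer-valued; the realised coverage of the draw
therefore fluctuates tightly around the target, while the chosen depth's
expected coverage meets it exactly. Root and soil tables are rarefied
separately, with depth pre-filters (1,000 reads for roots, 5,000 for soil)
applied first via `filter_low_depth()`.

## The joint species distribution model

Occurrences are binary. OTU $s$ in root sample $i$ follows a multivariate
probit with latent factors:

$$P(y_{is}=1 \mid u_i) = \Phi(x_i'\beta_s + u_i'\lambda_s),
\qquad u_i \sim N(0, I_r).$$

The candidate design blocks are

* **P** — host-plant dummies (treatment coding against the most frequent
  genus); hosts with fewer than 30 root samples (15 in the reduced variant)
  are excluded beforehand;
* **S** — principal coordinates of Bray–Curtis dissimilarities between soil
  communities, axes retained until the cumulative contribution among
  positive eigenvalues reaches 90 % (negative eigenvalues are dropped, no
  Cailliez/Lingoes correction — the contribution denominator is the sum of
  positive eigenvalues only);
* **Sp** — spatial eigenvectors: principal coordinates of the inter-position
  Euclidean distance matrix (no truncation). For 2-D coordinates this yields
  exactly the two centred coordinate axes; broad-scale spatial trend is what
  this block can capture;
* **Cov** — the latent factors ($r$ per sample, OTU-specific loadings
  $\lambda_s$), carrying residual fungus–fungus covariance: both direct
  interactions and shared unmeasured niches.

S and Sp columns are standardized; root samples whose position lacks soil
data are dropped; OTUs with no occurrence variation cannot inform a probit
likelihood and are dropped with a message.

### Estimation

Without Cov the likelihood factorises into independent probit regressions,
fitted exactly by IRLS with an optional ridge penalty (`jsdm_control(ridge)`,
default 1 on non-intercept coefficients) that guards against separation when
design blocks are wide. With Cov, the marginal likelihood

$$\ell = \sum_i \log \frac{1}{K}\sum_{k=1}^{K}
  \prod_s \mathrm{Bern}\!\left(y_{is} \mid \Phi(x_i'\beta_s + u_{ik}'\lambda_s)\right)$$

is estimated with $K$ fixed standard-normal draws per sample (common random
numbers, so the objective is deterministic) and maximised by L-BFGS with
analytic gradients, warm-started from the factor-only IRLS fit. Defaults:
$r = 8$, $K = 100$ for fitting and $1{,}000$ for the reported
log-likelihood; the desk-scale analyses in the tests and the acceptance
script use $r = 2$ (matching the generative rank of the synthetic preset),
$K = 30$/$300$ and 60 optimiser iterations, which profiling showed to be
within Monte-Carlo noise of the converged values at these problem sizes.
Probabilities are clipped at $10^{-12}$ for log-likelihood stability.

### Two kinds of predicted probability

For latent-factor models the package distinguishes, exactly as mixed-model
software does:

* **conditional** fitted values — draw-level probabilities averaged under
  the posterior weights of $u_i$ given the observed community. The
  covariance factor expresses itself through these; they are the in-sample
  fitted values used for the reported ROC AUC;
* **marginal** predictions — latent factors integrated out; appropriate for
  prediction on new samples and for calibration checks (on null data the
  marginal in-sample AUC stays near 0.5–0.6, while conditional values add
  the latent-state optimism inherent to any in-sample fit).

### Per-OTU log-likelihood decomposition

The MC marginal log-likelihood couples OTUs through the shared draws, so a
per-OTU decomposition is defined as the posterior-weighted conditional
log-likelihood per OTU plus an equal per-OTU share of the log-mean-exp
mixing correction; the vector sums exactly to the total, and for factor-only
models the decomposition is the exact Bernoulli log-likelihood. Factor
attribution uses log-likelihood ratios of this decomposition between fixed
model pairs: Cov is judged against the full model (Full vs. P+S+Sp), while
P, S and Sp are judged within the covariance-free lattice (P+S+Sp vs. the
model dropping the factor) so that factor effects are not absorbed into
shared-niche covariance. Guild comparisons use Steel–Dwass all-pairs tests
(pairwise rank-sum statistics with tie-corrected variance, referred to the
studentized range; guilds need at least 5 OTUs), with no extra FDR layer —
the studentized-range calibration is the family correction.

## Host-preference statistics

`build_bipartite()` counts, for each OTU × plant pair, the root samples
carrying both labels, after discarding OTUs in fewer than 30 root samples
and hosts with fewer than 30 samples. Blüthgen's d′ for a row with
interactions $N_{ij}$, row total $A_i$ and availabilities $q_j = A_j/m$ is

$$d_i = \sum_j p'_{ij}\,\ln\frac{p'_{ij}}{q_j},\qquad
  d' = \frac{d - d_{min}}{d_{max} - d_{min}},$$

with the extremes taken over *integer* redistributions of $A_i$: $d_{max}$
concentrates the row on the rarest partner ($\ln(1/\min_j q_j)$, a vertex of
the simplex since KL is convex), $d_{min}$ is found greedily from the floor
of the proportional allocation, adding remaining units where the KL
increment is smallest — validated against exhaustive search for small
totals. Because the bounds refine as counts grow, d′ is scale-invariant only
up to the integer grid (KL and $d_{max}$ are exactly invariant).

The null model shuffles host labels *within sampling positions* (the
per-position label multiset is preserved exactly), which holds the spatial
and effort structure fixed and randomises only the fungus–host assignment.
Each permuted matrix is rescaled with its own redistribution bounds. The
standardized score is $z = (d'_{obs} - \overline{d'_{null}})/s(d'_{null})$;
two-tailed p-values come from the permutation ranks of d′ (exact at the
permutation resolution, rather than a normal approximation), BH q-values
follow. Pair-level ("two-dimensional") preference standardizes each cell
count $N(i,j)$ the same way, reusing the identical permutation stream for
equal seeds so the two statistics are coherent. Degenerate nulls (zero
permutation SD, e.g. all positions monocultures) are flagged and scored 0.

## Habitat preference and spatial autocorrelation

`habitat_surface()` reports occurrence counts and mean relative abundances
(log10 of the read proportion with half the smallest positive proportion as
offset, averaged over samples where the OTU is present) in roots and soil,
for OTUs in ≥ 30 root and ≥ 15 soil samples. `glm_soil_coupling()` fits, per
OTU, a Poisson GLM of the per-(position × host) count of occupied root
samples on the position's log soil relative abundance and host identity,
with log cell size as offset; the soil coefficient is standardized by the
predictor's SD and reported with its Wald p-value.

`mantel_correlogram()` pools root samples to position-level presence
(pooling is idempotent), computes Jaccard dissimilarities, and for each
distance class reports the (sign-flipped) correlation between the
dissimilarity vector and the class indicator, so positive r means nearby
positions are more similar. Classes follow Sturges' rule on the pairwise
distances unless breaks are given; significance is a two-tailed permutation
test shuffling position identities, with BH q-values across classes. Guild
subsets restrict the community to the guild's OTUs before pooling.

## Direct-association networks

Counts (un-rarefied) are CLR-transformed with pseudocount 1; the empirical
*correlation* matrix of the CLR data (correlation rather than covariance,
for scale stability) is the input $\hat\Sigma$ to the latent-variable
graphical lasso

$$\min_{S, L}\; -\log\det(S-L) + \mathrm{tr}(\hat\Sigma (S-L))
  + \lambda\|S\|_{1,\mathrm{off}} + \gamma\,\mathrm{tr}(L),
  \quad S-L \succ 0,\; L \succeq 0,$$

solved by ADMM (eigendecomposition updates for the log-det and PSD blocks,
soft-thresholding for $S$; step $\rho = 1$, tolerance $10^{-6}$ on scaled
residuals). The solver logs the objective at the feasible point
$\Theta = S - L$, which is non-increasing in practice even though raw ADMM
iterates are not monotone; at rank 0 the solution coincides with the plain
graphical lasso (verified against an independent coordinate-descent
implementation to $10^{-4}$). $\gamma$ is tuned by bisection so that
$\mathrm{rank}(L)$ hits the requested value, ties broken toward smaller
$\gamma$; warm starts make the bisection cheap. The latent rank is selected
by

$$BIC = n\left[-\log\det\hat\Theta + \mathrm{tr}(\hat\Sigma\hat\Theta)\right]
 + \ln(n)\left[|E(S)| + rp - r(r-1)/2\right]$$

over ranks 0–20. The sparsity penalty is *not* stability-selected: it is the
smallest $\lambda$ on a geometric path whose rank-0 edge density stays at or
below 5 % (configurable). Edges are the non-zero off-diagonals of $S$ with
partial-correlation weights $-S_{uv}/\sqrt{S_{uu}S_{vv}}$; positive and
negative sub-networks are analysed separately, AMF–AMF pairs are flagged
(multi-genome individuals can mimic associations), Louvain modules are
computed on the positive sub-network (igraph, fixed seed, resolution 1), and
Kendall $\tau_b$ (tie-corrected, normal-approximation p) links network
degree to the jSDM covariance attribution.

## The synthetic-data generator

`simulate_dataset()` emulates the study design with known ground truth:

* positions on a jittered grid with rejection so all pairs are ≥ 4 m apart
  (124 positions in a 280 m arena by default — about the density of an
  8-ha plot);
* host genera assigned with spatially clumped probabilities (10 genera,
  clump range 60 m) and per-position root-sample counts (Poisson, mean 12 —
  matching the study scale of roughly 1,500 root tips over 124 positions);
* per-OTU soil log-abundance fields from Gaussian processes with
  exponential covariance (range 10 m), exact Cholesky simulation;
  multinomial counts at negative-binomial depths (roots NB(2·10⁴, 2), soil
  NB(10⁵, 2) — plausible magnitudes, configurable);
* root occurrence from the generative probit
  $\Phi(\alpha_s + \beta_{s,host} + c_g z_s + \gamma_g w_s + \lambda_s'u_i)$
  with guild-archetype effect scales: EcMF-like (soil coupling 1.2, spatial
  1.0, plant 0, loadings 0.4), Endophyte-like (plant 0.8, soil 0.1, spatial
  0.2, loadings 1.5), AMF-like (plant 1.5, soil 0.3, spatial 0.5, loadings
  0.4). EcMF plant filtering is zero so host-effect recovery can be scored
  against a known no-effect group; the contrasts mirror the qualitative
  guild differences the pipeline is designed to detect.

The **assembly** preset (100 positions, ~300 root tips, 40 OTUs, 2 latent
factors) is the parameter-recovery surface; the **null** preset (124
positions, ~1,500 root tips, 60 OTUs, every effect zero, common intercept
at prevalence 0.3) is the calibration surface. The null preset fixes
per-position effort at exactly 12 samples: with variable effort,
position-pooled richness tracks effort, and chance spatial gradients in
effort masquerade as spatial community structure — constant effort restores
the exchangeability the calibration tests rely on.
`generate_network_dataset()` draws latent Gaussians with precision
$S_{true} - L_{true}$ (default 40 edges of magnitude 0.3 among 50 OTUs,
rank-3 confounder with leading eigenvalue 0.85 — factor variance several
times the idiosyncratic variance, i.e. a genuinely strong environmental
gradient, without which BIC rank selection would trivially return 0) and
maps them to counts by per-OTU negative-binomial quantile transforms.

What the generator does **not** emulate: PCR/sequencing bias, chimeras,
contamination, taxonomic mis-assignment, OTU-clustering artefacts, and
plant identification error. Passing tests therefore demonstrate statistical
correctness of the pipeline under the stated generative model, not
robustness to those upstream artefacts.

## Problem sizes used in tests and the acceptance script

Simulations are scaled for a single CPU: permutation tests run at 300–1,000
permutations (the field-standard 10,000 remains the function default),
latent-factor fits use $r = 2$, 30 Monte-Carlo draws and 60 optimiser
iterations, null calibrations use 50 preference replicates and 100
correlogram replicates, and sequencing depths in calibration replicates are
reduced (depth affects only the count layer, not the binary occurrences the
calibrated statistics use). The acceptance script replicates factor
attribution over 6 seeds and reports pooled quantities.

## Known limitations

* The spatial eigenvector block is the plain principal-coordinate embedding
  of the position coordinates — two columns for 2-D designs — so only
  broad-scale trend is captured; fine-scale spatial structure shows up in
  the correlogram instead.
* Training log-likelihoods compare models on the same data; they are not
  cross-validated, and their absolute magnitudes depend on the Monte-Carlo
  settings (orderings are stable).
* The d′ permutation z-scores of different OTUs share one permutation
  stream and are positively correlated within a dataset; their dispersion
  is calibrated across replicate datasets, not within one.
* The latent-variable graphical lasso separates direct associations from
  shared environmental responses only up to the adequacy of the low-rank
  representation; edge signs and weights inherit the usual compositional
  caveats of CLR analysis.
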