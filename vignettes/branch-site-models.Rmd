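---
title: "Codon models of positive selection: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon models of positive selection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

Protein-coding sequences evolve under a Markov process on the 61 sense
codons of the universal genetic code. The instantaneous rate from codon
$i$ to codon $j$ is

$$
q_{ij} \propto
\begin{cases}
0 & \text{more than one nucleotide difference} \\
\pi_j & \text{synonymous transversion} \\
\kappa \pi_j & \text{synonymous transition} \\
\omega \pi_j & \text{nonsynonymous transversion} \\
\kappa \omega \pi_j & \text{nonsynonymous transition,}
\end{cases}
$$

where $\pi$ are the codon equilibrium frequencies, $\kappa$ the
transition/transversion rate ratio, and $\omega = d_N/d_S$ the ratio of
nonsynonymous to synonymous substitution rates. Purifying selection gives
$\omega < 1$, neutrality $\omega = 1$, and positive selection $\omega > 1$.
The chain is time-reversible ($\pi_i q_{ij} = \pi_j q_{ji}$), so the
likelihood of an unrooted tree does not depend on where the pruning
recursion is rooted.

Heterogeneity in $\omega$ is expressed through *site-class mixtures*: each
class has a proportion and a background and foreground $\omega$. Every
model in the catalogue is an instance of this structure:

* **Site models** — M0 (one ratio), M1a (nearly neutral: $\omega_0 \le 1$,
  $\omega_1 = 1$), M2a (adds $\omega_2 \ge 1$), M7 (beta-distributed
  $\omega \le 1$, ten equal-probability categories), M8 (beta plus a class
  at $\omega_s \ge 1$), M8a (M8 with $\omega_s = 1$).
* **Branch models** — model 0 (one ratio for the tree), model 1 (a free
  ratio per branch), strict model 2 (the flagged foreground branch gets its
  own free ratio, the rest share a ratio $\le 1$) and relaxed model 2
  (foreground ratio fixed at 1).
* **Branch-site models A1/A2** — four classes (0, 1, 2a, 2b): class 0 is
  purifying everywhere, class 1 neutral everywhere, classes 2a/2b switch to
  $\omega_2$ on the foreground branch. A1 fixes $\omega_2 = 1$, A2 frees
  it; their likelihood-ratio test ("test 2") with one degree of freedom is
  the branch-site test of positive selection. The proportions of classes
  2a/2b split $1 - p_0 - p_1$ in the ratio $p_0 : p_1$.

Nested pairs are compared with $2\delta = 2[\ln L_{alt} - \ln L_{null}]$
referred to a plain $\chi^2$ with the difference in free parameter counts
as degrees of freedom (no boundary mixture correction, the convention of
the standard branch-site testing workflow; the plain $\chi^2$ is
conservative for the branch-site test). Small negative $2\delta$ from optimizer noise is
clamped to zero with a warning.

## Branch-length scaling across site classes

A branch length is the expected number of substitutions per codon
*averaged over site classes*. Each class's generator is normalized by the
common mixture-average rate, so a class with ratio $\omega$ evolves at
relative rate $(a + \omega b) / \sum_k p_k (a + \omega_k b)$, where $a$
and $b$ are the synonymous and neutral-nonsynonymous substitution flows of
the exchangeability. This is the convention of the standard ML codon
software and its simulator: positively selected classes accumulate
proportionally more substitutions on the foreground branch, which is where
most of the branch-site test's information comes from. The simulator, the
likelihood, and the BEB calculation all share this convention (in the BEB
grid the normalization stays fixed at the maximum-likelihood mixture so
branch lengths keep their fitted meaning).

## Fitting

`fit_model()` maximizes the likelihood jointly over branch lengths,
$\kappa$ and the model's mixture parameters with L-BFGS-B on transformed
coordinates: logarithms for rates and branch lengths, logit/stick-breaking
for proportions. Branch-length gradients are analytic (a post-order /
pre-order pass through the pruning graph); mixture-proportion gradients
are analytic through the class-posterior weights; the few remaining
scalars use forward differences. Bounds: $\omega \in [10^{-6}, 999]$
(999 matching the largest foreground estimate reported for the emulated
cluster),
$\kappa \in [10^{-3}, 100]$, branch lengths $\in [10^{-6}, 50]$.
Proportions may reach 0 and $\omega$ may sit exactly at 1, so boundary
solutions (e.g. M1a and M2a converging to the same optimum) are
representable. Three restarts from deterministically perturbed starting
points are the default; convergence is reported per restart and the best
solution returned.

M7/M8/M8a discretize the beta distribution into ten equal-probability
categories represented by their category means, computed exactly from
incomplete beta functions.

## Bayes Empirical Bayes site identification

After a significant A1-vs-A2 test, `beb_site_posteriors()` computes
per-site posteriors of the four site classes, integrating over a discrete
uniform prior on $(p_0, p_1, \omega_0, \omega_2)$: ten midpoint categories
per dimension, $\omega_0 \in (0,1)$, $\omega_2 \in (1,11)$, and the 45
midpoint pairs $(p_0, p_1)$ inside the simplex (a documented constant,
`BEB_GRID_N`). Branch lengths, $\kappa$ and codon frequencies stay fixed
at their MLEs. The reported evidence for positive selection at a site is
$P(2a) + P(2b)$, with the conventional reporting tiers $P > 0.95$ and
$P > 0.99$. The implementation is verified against a direct
grid-summation oracle written independently of the pruning core.

## The synthetic data

The generators emulate a divergent insect gene-family alignment (a
glutathione S-transferase cluster with paralogs and orthologs):

* `gambiae_like_codon_usage()` — a frozen synthetic codon usage table with
  the GC-rich third codon position characteristic of the *Anopheles
  gambiae* genome (GC3 just above 0.6). It is a stand-in built from fixed
  position-specific nucleotide frequencies, not genome-derived counts.
* `gstall_like_tree()` — a random gene-family topology: taxa are grouped
  into paralog clades (genes), each holding orthologs of one gene, with a
  random backbone over clades and random shapes within them. Branch
  lengths are calibrated by simulation at two levels until the mean
  pairwise synonymous divergence (NG86 $k_S$ with Jukes-Cantor
  correction) is within 0.25 of 1.6 for between-clade (paralog) pairs and
  1.1 for within-clade (ortholog) pairs — the saturation regime of the
  emulated cluster. One clade-subtending branch is flagged
  foreground and its length pinned so that, under the branch-site
  foreground mixture at the template's $\omega_2$, the branch shows a
  nonsynonymous divergence of $d_N \approx 0.11$
  ($t = 3\rho_N d_N \bar R / (b \sum_k p_k \omega_k)$, with $\rho_N$ the
  neutral nonsynonymous site fraction and $\bar R$ the foreground
  mixture-average rate) — emulating the long post-duplication lineage on
  which selection is tested. Leaving that length to the random draw makes
  the study's operating characteristics swing widely between tree seeds;
  the lineage's $d_N$ is a summary property of the emulated data, so it
  is treated as a condition, not a random variable.
* `make_dataset()` — branch-site data with class proportions
  $p_0 = 0.80$, $p_1 = 0.15$ (5% of sites in classes 2a/2b),
  $\omega_0 = 0.09$ and $\kappa = 2$. The proportions and $\omega_0$ are
  explicit assumptions: site-model analyses of the emulated cluster put
  more than 95% of
  sites under strong purifying selection with $\omega \le 0.09$; its
  fitted branch-site proportions are not published, so round defaults in
  that regime are shipped and every value is overridable.

What the generator does **not** emulate: alignment error, indels/gaps,
recombination, among-site rate variation beyond the $\omega$ classes, and
non-stationary codon usage. Passing tests therefore demonstrate the
estimator's behaviour under the model's own assumptions at a matched
divergence level — not robustness to real-data misalignment artifacts.

## The simulation study

`run_power_study()` measures, per condition: the fraction of replicates
with A1-vs-A2 LRT $p \le 0.05$ (power when generating under A2, false
positive rate under A1), and — pooling confusion counts over replicates
(micro-averaging, robust when single replicates flag nothing;
per-replicate means are reported alongside) — the BEB site-detection
power, accuracy and false-positive rate at $P > 0.95$ and $P > 0.99$.
Replicates whose fits fail to converge are excluded and counted.

`run_study_grid()` reproduces the six study conditions on one calibrated
tree: null at true and doubled branch lengths, and $\omega_2 \in
\{4, 9, 999\}$ at true lengths plus $\omega_2 = 9$ at halved lengths.

Two profiles are first-class configurations. The `fast` profile — 12
taxa, 257 codons, 50 replicates per condition — is the desk-scale setting
used by the test suite and the acceptance script; it keeps the full grid
around a quarter of an hour on one CPU while retaining the alignment
length of the emulated dataset. The `full` profile (31 taxa, 257 codons,
100 replicates) matches the original study scale and is a batch job of
several hours. With fewer taxa the test has somewhat less information per
site, so power and BEB detection rates at the fast profile sit slightly
below the full-scale values; the acceptance checks therefore judge
stochastic quantities within three standard errors at the executed
replicate count, using replicate-level (cluster-robust) standard errors
for pooled site metrics because sites within a replicate share one fitted
model.

Within the study profile the alternative fit reuses the null fit's branch
lengths and $\kappa$ and is warm-started from the null solution (with a
second $\omega_2$ start on the strong-selection side of the likelihood's
occasional bimodality) — the warm start enforces
$\ln L_{A2} \ge \ln L_{A1}$ by construction, making single-restart fits
robust. Joint re-optimization of everything under A2 remains available
(`reuse_null_lengths = FALSE`) and is the default for standalone
`fit_model()` calls.

Two systematic consequences of the desk scale are worth understanding
when reading study output. First, with a third of the taxa the ancestral
states at the foreground branch's endpoints are less resolved, so LRT
power sits below full-scale values — most visibly under weak selection
($\omega_2 = 4$) and under halved branch lengths, where the per-site
signal is smallest; the qualitative patterns (power monotone in
$\omega_2$, power loss on halving) persist. Second, the historical
observation that doubling branch lengths inflates the test's
false-positive rate does not reproduce here: that inflation arises when
null and alternative models are optimized independently on saturated
data, where a poorly converged null fit yields spuriously large
likelihood-ratio statistics. The nested warm-start scheme used here makes
such spurious statistics impossible by construction, and with exact
transition probabilities under a correctly specified model the plain
$\chi^2_1$ branch-site test remains conservative at doubled divergence
rather than anticonservative.

## Foreground branch choice

The branch-site test requires an a priori foreground lineage (`#1` labels
in Newick input). The supported workflow mirrors standard practice:
fit the free-ratio branch model, rank branches by their nonsynonymous rate
with `branch_dn_ds()` (high $\omega$ on a branch with very low $d_S$ is
typically estimation noise on a short branch), pick the candidate branch,
and then run strict/relaxed branch model 2 and the A1/A2 pair on that
flag. No automatic multiple-testing correction across candidate branches
is applied.

## Known limitations

* NG86 counting with Jukes-Cantor correction saturates at a synonymous
  difference proportion of 3/4; saturated pairs are flagged and excluded
  from calibration means, which slightly biases the achieved mean $k_S$
  downward in the saturation regime the generator targets.
* The free-ratio branch model (one $\omega$ per branch) is fit with
  numerical gradients and is intended for small trees / exploratory
  ranking, not the simulation harness.
* Real-data reproduction (GenBank alignments of the original cluster) is
  out of scope here; all quantitative checks run on the synthetic
  emulation.
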