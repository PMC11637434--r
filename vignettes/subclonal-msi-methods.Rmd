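---
title: "Methods: deconvolving subclonal microsatellite instability from length spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deconvolving subclonal microsatellite instability from length spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Microsatellite instability (MSI) is called from sequencing by comparing, at
each microsatellite locus, the distribution of repeat lengths carried by
tumor reads with the matched normal's distribution. Classical callers treat
the tumor as one population: they fit or test a single, unimodal length
distribution per locus. In heterogeneous tumors this assumption fails. When
only a subclone has lost mismatch repair, the tumor spectrum is a *mixture*
— a large component that matches the germline plus a smaller, shifted
component — and the mixture as a whole can resemble the normal closely
enough that unimodal callers report MSS. Such *partial MSI-positive*
samples are exactly the ones where the call changes treatment.

msiclone addresses this by deconvolving each locus's tumor spectrum into
per-subclone Gaussian components under an externally supplied clonal
structure, and then testing each component — not the pooled spectrum —
against the matched normal.

## Model

At one locus, read lengths (in repeat units) are modeled as a K-component
Gaussian mixture,

$$p(L) = \sum_{k=1}^{K} \pi_k\, \mathcal N(L \mid \mu_k, \Lambda_k^{-1}),
\qquad K \le G,$$

where G is the number of subclones and the mixing weights are not free:
each subclone g, with known fraction $B_g$, belongs to exactly one
component through a binary assignment matrix A (rows sum to one), so that
$\pi_k = Y_k = \sum_g B_g A_{gk}$. Two clones may share a component (a
shared instability event), which is why $K \le G$.

Inference alternates two optimizations:

1. **Variational Bayes for the component parameters.** Each component
   carries a conjugate Normal-Gamma prior — mean
   $\mu_k \sim \mathcal N(m_0, (\beta_0 \Lambda_k)^{-1})$ and precision
   $\Lambda_k \sim \mathrm{Gamma}(v_0/2,\, 1/(2w_0))$, written in the
   one-dimensional Wishart parameterization $(w, v)$ so that
   $\mathbb E[\Lambda_k] = v_k w_k$. Mean-field coordinate ascent updates
   responsibilities and posterior hyperparameters
   ($m_k, \beta_k, w_k, v_k$) until the evidence lower bound (ELBO)
   stabilizes. With the weights *pinned* to Y, the Dirichlet terms of the
   usual bound are replaced by the fixed-weight cross-entropy
   $\sum_k N_k \log Y_k$. For $K = 1$ the variational family contains the
   exact posterior and the converged ELBO equals the closed-form
   Normal-Gamma log marginal likelihood — the package tests this identity
   to $10^{-6}$.

2. **Integer assignment of clones to components.** Given fitted
   $(\mu_k, \sigma_k)$, A is chosen to minimize the squared deviation
   between the clone-fraction-implied mixture and the empirical length
   frequency $f(L)$, summed over reads. Lengths are integers, so the
   fitted density enters as the probability mass of the unit bin
   $[L-\tfrac12, L+\tfrac12)$, which puts both terms of the difference on
   the same probability scale. The minimization is exact: all $K^G$
   row-feasible binary matrices are enumerated ($\le 3125$ for the
   $G, K \le 5$ regime this method targets), replacing the commercial
   solver dependency of the original formulation. An optional MILP backend
   (`lpSolve`) implements the standard binary-product linearization; it is
   polished and self-verified because the available open solver's branch
   and bound proved unreliable on this dense objective.

The alternation refits the components with weights pinned to the current
Y, re-solves A, and stops when A is stable (or after `max_outer_iters`).
A-updates that would worsen the objective are rejected, which makes the
objective trace monotone and termination certain.

### Two necessary departures from the naive formulation

**Smallest adequate K, not smallest objective.** The squared-error
objective never prefers fewer components: sweeping K and keeping the
minimum would always split MSS loci at the clone fractions and call their
noise components unstable (in development this produced 50–70%
false-positive rates). The package instead sweeps K upward and stops at
the smallest K whose fit is *statistically adequate*: a Pearson
goodness-of-fit statistic over pooled unit bins is compared against its
own null distribution, obtained by redrawing spectra from the fitted
mixture (parametric bootstrap, level 0.05, 200 replicates). Only if no K
is adequate does the minimum-objective rule decide. The Pearson form
matters: the squared-error objective is dominated by the peak of the
spectrum and is nearly blind to a small shifted bump, which is precisely
the signal a minor MSI clone leaves.

**Assignment hypotheses are judged after refitting.** Multinomial sampling
makes a minor clone's realized read mass fluctuate around $B_g N$. When it
falls below, the squared error often prefers dropping the component
($Y_k = 0$) over carrying it at its nominal fraction — a systematic
false-negative mode. The alternation is therefore multi-started from the
top few distinct-weight assignments; each non-leading start is evaluated
as a fixed hypothesis (components refitted under its pinned weights), and
a statistically adequate state is preferred over a marginally
lower-squared-error state that fails to account for part of the spectrum.

### Discretization

Moments fitted on integer-rounded lengths include the rounding variance:
$\sigma^2_{\text{fit}} \approx \sigma^2 + 1/12$. Wherever a fitted
component is converted back to unit-bin masses (assignment objective,
adequacy test, clone test), Sheppard's correction
$\sigma^2_{\text{cont}} = \sigma^2_{\text{fit}} - 1/12$ is applied.
Without it, spectra simulated from binned Gaussians systematically fail
their own goodness of fit and the caller over-rejects.

## Calling MSI per clone

Each clone inherits its component's $(\mu_k, \sigma_k)$ and an effective
read count $n_{\text{eff}} = Y_k N$; clones sharing a component share one
test. The default test compares the clone's expected unit-bin counts
against the normal spectrum's proportions scaled to $n_{\text{eff}}$ with
a Pearson-type statistic. Both sides of that comparison are estimated from
finite reads, so the textbook $\chi^2_{B-1}$ reference is badly
miscalibrated (measured null rejection 0.19 at $\alpha = 0.05$). The
p-value is instead computed by a parametric bootstrap under the pooled
null: a single Gaussian is moment-fitted to the pooled reads, both sides
are redrawn from it, the clone Gaussian is refitted by moments on each
redraw, and the statistic is recomputed (400 replicates; measured null
rejection 0.041). A two-sided z-test on means is available as
`test = "ztest"` for users who want the classical mean-shift notion only.

A locus is MSI if any testable clone is MSI. The sample score is the
fraction of MSI loci; the sample verdict is MSS below a configurable
threshold (default 0.2, a conventional panel cutoff), *MSI* when every
testable clone call at the unstable loci is MSI, and *partial-MSI*
otherwise. The partial-MSI rule is a convention of this package — the
aggregation level is implied but not specified by the per-clone reports it
mirrors.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `beta0` | 1e-3 | — | weakly informative mean-precision scale |
| `m0`, `w0` | data mean, 1/variance | repeat units | center the prior on the locus |
| `v0` | 3 | — | proper but weak Gamma prior on precision |
| `alpha0` | 1 | — | flat Dirichlet in free-weight mode |
| `elbo_tol` | 1e-4 | relative | stopping rule of the inner VB loop |
| `max_outer_iters` | 20 | — | cap on VB/assignment alternations |
| `gof_level`, `gof_boot` | 0.05, 200 | — | adequacy test level and bootstrap size |
| `min_component_weight` | 0.01 | proportion | a thinner assigned component is treated as spurious |
| `min_reads` | 20 | reads | below this, mixture fitting is unstable; locus skipped |
| `alpha` | 0.05 | — | per-clone significance level |
| `nboot` (caller) | 400 | — | bootstrap size of the per-clone test |

## What the simulator emulates — and what it does not

`simulate_dataset()` draws, per locus, a germline mean in 12–25 repeat
units and standard deviation in 0.5–2.5 (the ranges seen in fitted
mono-repeat panel tables), gives every clone the germline distribution,
and, at MSI loci (half of the 60-locus panel by default), shifts a
uniformly chosen nonempty subset of clones by 3–8 units in a random
direction with a freshly drawn width. Tumor reads are a multinomial draw
of `depth` reads from the clone-fraction-weighted binned mixture; normal
reads are drawn from the germline Gaussian. Everything is seeded.

This is histogram-level simulation. It deliberately does not model
read-level effects — PCR stutter, alignment loss, flanking-sequence
ambiguity, sequencing error — that a read simulator feeding an aligner and
a spectrum extractor would introduce. Consequences worth knowing:

* a green benchmark here establishes that the deconvolution and calling
  machinery work on clean mixture spectra, not that the method survives
  stutter-heavy real data;
* published benchmark numbers that depend on read-level noise are not
  reproduced exactly. In particular, this implementation is *more*
  accurate at high depth and clone number than the tables it is compared
  against (precision ≈ 0.94 vs 0.857 at five clones, 800x), and its
  depth trend is flatter, because shifts of 3–8 units are already
  detectable at 100x in noiseless histograms. The generator's parameter
  ranges were fixed a priori and not tuned toward any printed value.

## Numerical choices

* All VB computations collapse reads to (distinct length, count) pairs;
  responsibilities live on distinct lengths, making a fit independent of
  depth in cost.
* The E-step is computed in log space with max subtraction; pinned zero
  weights yield exactly zero responsibility.
* Empty components revert to their prior; deletion only happens through
  model selection, never mid-run.
* k-means initialization is a deterministic weighted Lloyd run from
  quantile seeds (label order fixed by center order), so a seed fully
  determines a fit.
* Assignment ties (within 1e-12) break to the lexicographically smallest
  A; the K sweep breaks objective ties (1e-9) toward smaller K.
* Per-locus seeds are derived from the batch seed and the locus index, so
  serial and parallel execution give identical results.

## Known limitations

* Clone fractions are trusted inputs from an upstream subclone caller;
  errors in B propagate directly into the weight lattice the assignment
  can choose from.
* With strongly overlapping components (shifts below ~2 units at typical
  widths) the adequacy test loses power and minor-clone events are missed;
  this mirrors the degradation the overlap experiments describe.
* The bootstrap null of the per-clone test assumes the normal spectrum is
  adequately Gaussian after binning; heavy stutter tails would make the
  test anti-conservative.
* The MILP backend depends on an open solver whose branch and bound is
  unreliable on this objective; it is self-verified against enumeration
  within the enumeration cap and best-effort beyond it.

## A worked example

```{r, eval = FALSE}
library(msiclone)

tumor <- spectra_for_sample(
  read_spectrum_table(system.file("extdata", "example_tumor.tsv",
                                  package = "msiclone")), "tumor")
normal <- spectra_for_sample(
  read_spectrum_table(system.file("extdata", "example_normal.tsv",
                                  package = "msiclone")), "normal")
clones <- read_clonal_structure(
  system.file("extdata", "example_clones.json", package = "msiclone"))

res <- run_pipeline(tumor, normal, clones,
                    deconvolve_config(seed = 1))
res$report
```

The example data are synthetic (15-locus mono-repeat panel, two clones at
fractions 0.707/0.293, 200x), with ground truth in
`example_truth_synthetic.tsv`.
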