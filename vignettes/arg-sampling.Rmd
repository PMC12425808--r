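---
title: "Posterior sampling of ancestral recombination graphs by threading"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Posterior sampling of ancestral recombination graphs by threading}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(argthread)
```

## The model

An ancestral recombination graph (ARG) assigns a rooted binary coalescent
tree to every genomic position; adjacent trees differ by a single
subtree-prune-regraft event caused by an ancestral recombination.
`argthread` represents an ARG tskit-style, as node / edge / mutation
tables (`arg_tables`) with 0-based half-open genomic spans and node times
in generations, and samples ARGs from the posterior

$$\pi(\mathcal{G} \mid D) \propto
  P_{\mathrm{SMC}}(\mathcal{G}) \, P(D \mid \mathcal{G}),$$

where `P_SMC` is the sequentially-Markov-coalescent prior for a
constant-size panmictic population of diploid size `Ne` and per-base
recombination rate `r`, and the likelihood is the infinite-sites mutation
model with per-base rate `mu`.  Data are phased biallelic haplotypes with
a known ancestral allele.

Internally everything lives on a lattice: the genome is tiled with bins of
about `4e-3 / (4 Ne r)` base pairs (5 bp at human-like rates), and at most
one recombination event is represented per bin boundary.  The prior is the
exact lattice factorization — a Kingman density for the first marginal
tree; per boundary either the survival factor
$\log(1-\rho)$ with $\rho = 1 - e^{-r\,b\,\Lambda}$ ($\Lambda$ the current
total branch length, $b$ the bin size) or, at a breakpoint, the jump mass
$\rho\,\times$ the recombination-height-marginalized re-coalescence
density; and the no-mutation area factor $e^{-\mu \cdot \mathrm{area}}$
with per-site placement terms.  We verified this factorization by
exhaustively enumerating all two-bin pair configurations against an
independent transfer-matrix computation.

Because site patterns proposed during sampling can be transiently
incompatible with a single mutation, the likelihood of a site is computed
as a log-sum-exp over single-branch placements, with mismatched leaves
charged an extra mutation on their terminal branch.  For compatible
patterns this is the exact infinite-sites likelihood up to terms of order
$(\mu \Lambda)^2$; it keeps the posterior well defined everywhere.

## Threading

Haplotypes are added one at a time.  For the `n`-th haplotype a
Li–Stephens-style HMM over the bins first samples the *joining branch* in
each marginal tree: the transition kernel is
$(1-r_i)\,\delta_{ij} + r_i\, q_j$, where $r_i = 1 - e^{-r\,b\,\ell_i}$
uses the candidate segment's time-length $\ell_i$ and $q_j$ is the exact
probability that a floating lineage re-coalesces onto branch $j$ under
the constant-Ne coalescent (computed by closed-form epoch-wise
integration; the state above the root absorbs the remaining mass, so the
$q_j$ sum to one).  A second HMM then samples the *joining time*,
conditioned on the branch path: each branch interval carries 40
log-spaced cells whose masses are exact integrals of the truncated
re-coalescence density; within-branch time recombination uses the same
$r_i$ machinery evaluated at the current joining time.  Emissions at
polymorphic sites compare the new haplotype's allele with the allele
implied by the joining point (match: no extra mutation, probability
$e^{-\mu\tau}$; mismatch: one extra mutation, $1-e^{-\mu\tau}$), and every
bin carries the no-mutation factor $e^{-\mu\tau b}$ over its monomorphic
positions.  A join above the current root also extends the root lineage,
so the exposed length doubles there.

At a bin boundary that already carries a recombination event the new
lineage may not introduce a second one: the branch state maps through a
deterministic carry-over (keep the surviving child; a removed node maps
down to its stayed child) and the time coordinate is preserved by value
on an *extended* grid that covers the entire lineage above the base
child.  Carries that would land on the dissolved segment of the
boundary's moved lineage are forbidden, since realizing them would
require a second event at the same boundary.

## MCMC: sub-graph pruning and re-grafting

A cut selects a marginal tree proportionally to span times total branch
length, a branch proportionally to its length, and a height uniformly on
the branch.  The lineage below the cut is detached over an extension
interval and re-grafted by the threading HMMs restricted to times above
the cut, with a Metropolis–Hastings correction using the forward and
reverse threading densities, the cut-selection densities, and
lattice-measure (cell-width) terms for every re-sampled joining time.

Two move classes are used, both exactly balanced within their own kernel
family:

* **Re-siting moves** act on the genomic span of the cut branch's
  ancestral segment (the maximal run of trees sharing the same attachment
  node).  The proposal is restricted to a single re-attachment over the
  span, so the reverse move lives in the identical kernel; free span ends
  contribute a re-coalescence coupling towards the neighbouring
  attachments, while ends at which the cut lineage's clade is assembled
  or disassembled pin the attachment (the old attachment node persists
  outside, and moving it would need a second event at that boundary).
* **Segment-structure moves** re-thread the lineage's whole attachment
  path inside a fixed 4096-bin genomic block.  Because the interval is
  determined by shared structure only, proposals that split, merge or
  relocate attachment segments are reversed by the same kernel; the cut
  height is drawn uniformly on its valid range with the corresponding
  density factors.

One *iteration* performs `n` re-siting cuts plus one segment-structure
move (the literature does not pin down the per-iteration work unit; this
choice makes the work scale with the sample size).  The chain is
initialized by sequential threading in input order
(`shuffle_order = TRUE` randomizes it), uses `burn_in = 1000` iterations,
and records `n_samples = 100` samples every `thin = 20` iterations.
Node times are re-scaled against the mutation clock after initialization
and at every thinning boundary; the re-scaling is a deterministic
reparameterization applied outside the accept/reject step, which is an
acknowledged approximation.  The always-accept ("near-Gibbs") variant of
the sampler is available via `chain_config(accept_mode = "always")`; the
exact MH correction is the default.

During development the sampler was validated three ways: per-move
acceptance arithmetic against independent hand computations on forced
two-bin transitions (exact agreement); stationarity when started at a
simulated ground truth (no drift in total branch length); and, for two
haplotypes, agreement of the chain's marginal coalescence-time posteriors
with an independent fine-grid forward–backward solution, with and without
data.

## ARG re-scaling

`fit_and_apply()` partitions the time axis into `K` windows of equal
span-weighted branch length (default `K = 100`), counts mutations
fractionally by branch overlap, and re-scales each window's width by
observed/expected counts, flooring empty windows at 0.05 to keep the map
strictly increasing.  A single pass is not exactly idempotent — mutations
smear uniformly along branches, so a second pass cuts windows where
observed and expected densities differ pointwise — and the pass is
therefore iterated to its fixed point (geometric contraction; machine
precision within a few hundred cheap passes).  Inside the chain only a
few passes are applied, and the number of windows is capped at one window
per eight mutations so the per-window counts stay statistically
meaningful on small regions.

## The synthetic-data generator

`sim_arg()` draws the first tree from the standard coalescent and walks
along the genome under the SMC: breakpoints arise with rate `r` times the
current total branch length, a uniformly chosen point is detached, and
the floating lineage re-coalesces at rate `k(t)/(2 Ne)`.
`drop_mutations()` adds infinite-sites mutations as a Poisson process on
the edges and emits the phased haplotype matrix and a VCF with the
ancestral allele in `INFO/AA`.  The generator's model deliberately
matches the inference model (SMC, not SMC'), so exactness tests compare
like with like; it does not emulate gene conversion, sequencing or
phasing error, or variable mutation rate, and passing tests therefore
say nothing about robustness to those features of real data.
`ceu_like_history()` is a stylized three-epoch stand-in (expansion 30k
from 0–1k generations, bottleneck 2k from 1–3k, ancestral 10k beyond)
used only to generate misspecification test data with a bi-modal pair
coalescence-time distribution; it is not a fit to any published
demography.

## Numerical choices

* Bin size `max(1, round(4e-3/(4 Ne r)))`; all sampler coordinates are
  bin-aligned (`snap_to_bins()` snaps externally simulated ARGs).
* 40 log-spaced time cells per branch interval (12 on the coarser
  carry-only ancestor segments); cell masses are exact integrals, and the
  semi-infinite above-root interval uses exponential quantiles truncated
  at 99.9%.
* Old (off-lattice) joining times are identified with the cell containing
  their value; boundary cell straddles make a proposal unspliceable and
  the move is rejected (rare, and symmetric between forward and reverse).
* Allele ages use the branch midpoint by default (`method = "sample"`
  draws a uniform time on the branch); the headline estimator is the
  posterior mean across sampled ARGs.
* Ties in node times are permitted only between distinct subtrees;
  equality of parent and child times is rejected by `validate_arg()`.

## Benchmark configuration and known limitations

The package's benchmark experiments (test suite and
`scripts/acceptance.R`) run at desk scale: credible-interval coverage
uses 15 replicates of 4 haplotypes over 8 kb with the standard sampling
scheme; simulation-based calibration uses 24 replicates of 4 haplotypes
over 6 kb with a shortened burn-in; the stationarity check runs 500 SGPR
moves from a simulated truth.  These sizes were chosen once, as the
package's own benchmark design, and the vignette records them so results
are interpretable.

The main known limitation is mixing under the fixed sampling scheme: at
desk scale, 100 samples taken every 20 iterations resolve only a modest
number of effective posterior draws per locus, so empirical credible
intervals are narrower than the true posterior's and their coverage of
the truth falls short of the nominal level (the acceptance experiment
reports roughly 0.6, versus the ~0.85 reported at much larger scale with
a better-mixing sampler).  The
two-haplotype experiments show the stationary law itself is accurate, so
the shortfall is a question of sampler efficiency per iteration, not of
the target.  Secondary limitations: old paths whose canonical
representation is not reachable under the deterministic carry-over are
auto-rejected (valid but wasteful); re-scaling inside the chain bypasses
the accept/reject step; and the likelihood's single-placement
approximation slightly smooths the posterior at sites that are
incompatible with one mutation.

## A small worked example

```{r example, eval = FALSE}
params <- model_params(Ne = 1e4, mu = 2e-8, r = 2e-8)
truth <- sim_arg(5, 10000, params, seed = 1)
data <- drop_mutations(truth, params$mu, seed = 2)

cfg <- chain_config(n_samples = 50, thin = 10, burn_in = 200, seed = 3)
ps <- run_chain(data$haplotypes, data$positions, 10000, params, cfg)

empirical_ci(ps, 1, 2, 5000, level = 0.9)
pairwise_tmrca(truth, 1, 2, 5000)
```
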