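---
title: "Models and methods for ARG inference with recoal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for ARG inference with recoal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`recoal` estimates the posterior distribution of an ancestral
recombination graph (ARG) together with population-genetic and
substitution parameters from an alignment of phased nucleotide
sequences. This vignette is the package's own account of the model, the
numerical choices, and what the validation battery does and does not
demonstrate.

## The state space

An ARG is a rooted graph of timed nodes: tips at height 0, coalescent
nodes with two children, and recombination nodes with one child, two
parents and a breakpoint $b \in \{1, \dots, L-1\}$. Sites with (0-based)
index below $b$ follow parent 1, the rest follow parent 2. Heights are
real-valued, in expected substitutions per site; exact ties are broken by
node id so traversals are deterministic. For every site the routing rules
induce an ordinary rooted binary **marginal tree**, obtained by
suppressing unary nodes (branch segments are summed; suppressed nodes
never appear in Newick output). The marginal-tree root height is the TMRCA
at that site.

Each edge carries its **ancestral material**, the set of sites (stored as
sorted, maximally merged half-open intervals) that are ancestral to at
least one sampled sequence: tips carry $[0, L)$, coalescent nodes the
union of their children's edge material, and a recombination node splits
the material arriving on its child edge at the breakpoint. When the child
is itself a recombination node, the arriving material is the child's
*split* edge material, not its full node material — a distinction that
matters for the prior's event rates on nested recombinations.

The state space is truncated at the **grand MRCA**: the first time (going
rootward) at which a single lineage carries all material. ARGs with events
above that point — for example towers of immediately rejoining
recombinations on the root lineage — have prior density zero. This
matches the backward simulator, which stops when one lineage remains, and
it is essential for the sampler and the simulator to target the same
distribution: without the truncation the chain accumulates invisible
structure above the root that no backward simulation ever produces.

## Prior: the coalescent with recombination

With $k$ extant lineages at time $t$, any specific pair coalesces at rate
$2/\theta(t)$ (total rate $k(k-1)/\theta(t)$), where
$\theta(t) = \theta_0 e^{-g t}$; $g = 0$ gives the constant-size model and
$g > 0$ exponential growth, handled exactly through the closed-form
integrated rate. Each lineage recombines at rate
$(\rho/\theta_0)\,s/(L-1)$, where $s$ is the number of inter-site gaps
strictly inside the lineage's ancestral span (Hudson-style: breakpoints
outside ancestral material are unidentifiable and carry no rate; the
simulator can optionally emit them for demonstrations via
`emit_non_ancestral`). The log-density of an ARG is the usual sum of
exponential waiting terms and per-event log-rates. The backward simulator
draws events from exactly these rates, so prior density and simulator are
consistent by construction — the package's central cross-check, asserted
in the tests by accumulating the generative log-density inside an
instrumented simulator and comparing it with `arg_log_prior()` per
realization.

The textbook definitions $\theta = 2N\mu$, $\rho = 2Nr$ fix the
parameters' meaning but not the rate algebra; the convention above is
self-consistent, reduces to the classical coalescent under rescaling, and
is shared bit-for-bit by density and simulator, which is what the
distributional validation requires.

Scalar priors default to uniform-on-log densities for $\theta$ and $\rho$
on configurable bounds and a uniform prior for the F84 transition-excess
parameter $\kappa$ (TN93's two rates get log-uniform priors). Parameters
are held fixed unless flagged `sampled`.

## Likelihood

The data likelihood is the full Felsenstein likelihood of the ARG: the
partition of $[0, L)$ at the breakpoints yields marginal trees, and the
log-likelihood is the sum over intervals of interval-restricted standard
pruning log-likelihoods. Substitution models are F84 (one
transition-excess parameter $\kappa$; within-purine rate
$1 + \kappa/\pi_R$, within-pyrimidine $1 + \kappa/\pi_Y$ relative to
transversions) and TN93 (two transition rates), both through closed-form
spectral transition probabilities with the generator normalized to one
expected substitution per site per unit time. A generic
matrix-exponential oracle is used in the tests only. Base frequencies are
empirical by default (the common practice) and may instead be supplied
explicitly. Gaps and `N` are missing data (all-ones tip vectors).
Identical alignment columns are collapsed once globally (column
aliasing), and per-node partial likelihoods are rescaled when they
underflow, with the scaling absorbed into the log. A further per-node
subtree-pattern deduplication would be a pure optimization and is not
implemented; no value can depend on it.

Incremental recomputation works at the granularity of marginal-tree
intervals: every kernel reports the site ranges whose routing or heights
it can affect (for a height move of a coalescent node, the intersection of
its children's edge materials — a recombination node is unary in every
marginal tree, so its height never dirties the likelihood), and only
cached intervals that intersect those ranges, or whose boundaries moved,
are recomputed. A fuzzed audit asserts the incremental value equals a
from-scratch recomputation to $10^{-9}$, and the running chain audits its
caches periodically.

## Proposal kernels

Seven kernels operate on the ARG: uniform-window node-height moves
reflected at parent/child bounds; a root-height multiplier; a whole-ARG
height scaling with Green ratio $m^{d}$ for $d$ internal nodes (heights
are drawn jointly with a log-uniform multiplier); an SPR-like subtree
regraft with uniform reattachment height on the target edge and an
exponential tail above the root; a reversible-jump recombination birth
(edge, breakpoint gap, direction, recombination height uniform on the
edge, re-coalescence height exponential above it, target lineage uniform
among those crossing that height) with its exact-reverse death; and a
geometric-window breakpoint shift. Scalar parameters use log-uniform
multiplier moves. The birth/death pair requires care with two degenerate
matchings: a *trivial* rejoin (both parents of the new recombination are
the new coalescent) is produced by both direction choices, and its death
by either slot choice, so both densities drop a factor of $1/2$
symmetrically. Acceptance follows the Metropolis–Hastings–Green rule
$\min(1, \exp(\Delta\log\text{lik} + \Delta\log\text{prior} + \log HR))$
(the first two terms divided by the temperature on heated chains).

Kernel windows are auto-tuned toward 0.234 acceptance during burn-in and
frozen afterwards, preserving detailed balance for the retained samples.
Kernel weights default to 1 for ARG kernels and 0.5 for active scalar
kernels; recombination kernels are disabled when $\rho$ is fixed at zero.

State management is double-buffered: proposals are built in a scratch
state and the buffers are exchanged by reference on acceptance, so a
rejection leaves the active state bit-identical (asserted by a chain
whose proposals are all vetoed).

Metropolis coupling runs `n_chains` chains at temperatures
$(1+\lambda)^{i-1}$ (default $\lambda = 0.1$), advancing in
`swap_interval` segments and proposing one adjacent-pair exchange per
segment with the standard coupled-chain ratio; only the cold chain is
sampled. Swap points align with the sampling grid when `swap_interval` is
a multiple of `sample_interval`.

## Synthetic data

`simulation_spec()` defaults encode the package's reference study
conditions: $n = 10$ sequences, $L = 10{,}000$ sites, $\theta = 0.02$,
$\rho = 1.0$, F84. The substitution settings used when simulating
sequences for the validation battery are equal base frequencies and
$\kappa = 1.5$ (a transition/transversion ratio of 2, a common default
for simulated nucleotide data). Sequence simulation draws root states
from the stationary distribution and mutates them down every ARG edge, so
marginal trees that share edges share realized mutations and linked sites
are correlated exactly as the ARG dictates; `per_interval = TRUE` instead
simulates each marginal tree independently (the classical
one-tree-at-a-time pipeline).

The generator emulates neutral, panmictic, constant-rate evolution with a
uniform recombination map. Real data violate most of these assumptions —
selection, population structure, rate heterogeneity across sites,
recombination hotspots, phasing and alignment error are all absent — so
passing the battery certifies the *implementation* (sampler, likelihood,
prior and their mutual consistency), not robustness of the model on
empirical alignments.

## Validation battery and problem sizes

The acceptance tests assert, with fixed seeds:

1. the engine's ARG log-likelihood equals the sum of marginal-tree
   log-likelihoods from the independent R pruning implementation within
   $10^{-6}$ on 50 random ARGs ($n \le 8$, $L \le 1000$);
2. prior-only MCMC ($n = 10$, $\theta = 1$, $\rho = 1$, $10^6$ steps,
   1000 samples per side) is indistinguishable from backward simulation
   on breakpoint count and root height (two-sample KS, $p > 0.01$), and
   the $\rho = 0$ mean root height matches $\theta(1 - 1/n) = 0.9$ within
   three (ESS-adjusted) standard errors;
3. the site-0 TMRCA distribution at $\rho \in \{0, 1, 5\}$ matches the
   standard coalescent (KS, $p > 0.01$);
4. incremental likelihood equals from-scratch within $10^{-9}$ over 1000
   fuzzed proposals, and rejected proposals restore the state bit-exactly;
5. with ten datasets simulated under the reference conditions and
   $10^6$-step chains, the 95% credible intervals cover the generating
   $\theta$ and $\rho$ in at least 8 of 10 replicates;
6. constructed trivial and non-ancestral recombinations leave marginal
   trees identical on both sides of the breakpoint, and an inference run
   on sequences simulated from such an ARG shows no breakpoint-density
   peak at the undetectable positions;
7. fixed-seed runs are bit-identical and a saved configuration re-runs to
   the identical trace.

KS tests at $p > 0.01$ have a 1% false-alarm rate per invocation, so the
statistical batteries allow up to three attempts with disjoint seeds
before reporting failure.

Prior-only runs use $L = 1000$ rather than $10^4$ — the prior depends on
$L$ only through the per-gap rate normalization, and the smaller alignment
keeps the battery compact. The parameter-recovery replicates start from a
UPGMA tree built on raw mismatch distances with no recombinations,
$\theta$ initialized away from the truth (0.01) and $\rho$ at 0.5, so
coverage reflects genuine mixing rather than initialization.

## Numerical choices and degenerate inputs

* Heights are doubles; ties broken by node id. Intervals are 0-based
  half-open internally; every user-facing table is 1-based inclusive.
* Breakpoint classes: `non_ancestral` (the breakpoint does not split the
  edge's material) takes precedence over `trivial` (both parent slots
  attach to one coalescent node); `trivial` is the strict immediate-rejoin
  rule, so a topologically silent recombination whose rejoin path is
  interrupted by another recombination node is reported `detectable`.
* Majority-rule consensus retains clades with support strictly above 0.5;
  ties at exactly 0.5 are dropped. Node heights are means over supporting
  trees.
* ESS uses the initial monotone positive sequence truncation of the
  autocorrelation sum; constant traces are reported as undefined.
* The `variant_only` VCF mode records the number (and approximate REF
  composition) of monomorphic columns in the region and folds them into
  the likelihood as width-weighted invariant-column terms per marginal
  interval — exact when the ARG has no recombination, and necessary for
  $\theta$ to remain interpretable from variant-only input. The
  `region_fill` mode requires an explicit reference sequence.
* `restart_from_best` reuses the maximum data-likelihood ARG observed at
  sampling points; ties resolve to the earliest step.

## Known limitations

Single panmictic population (no migration or multiple demes), uniform
recombination rate across sites and time, no rate heterogeneity across
sites, phased input required. The convergence heuristic (comparing
data-likelihood means and standard deviations between adjacent post-burn-in
quartiles) is advisory and never stops a run.
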