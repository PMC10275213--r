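---
title: "Methods: connectivity-based classification and circuit analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: connectivity-based classification and circuit analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

`mesocircuit` infers a mesoscale circuit from a *weighted potential
connectome*: a directed matrix $A_c$ whose integer entry $a_{c,ij}$ counts
the axonal-dendritic segment overlaps between neuron $i$ and neuron $j$.
Overlap is only a proxy for synaptic connectivity, so the pipeline treats
every overlapping segment pair as an independent Bernoulli trial with
success probability $p_{\mathrm{conn}}$. The probability that the pair of
neurons is connected at all is then

$$a_{p,ij} = 1 - (1 - p_{\mathrm{conn}})^{a_{c,ij}},$$

which preserves the sparsity pattern and saturates quickly: at
$p_{\mathrm{conn}} = 0.15$ every strength above 30 yields a connection
probability above 0.99. `choose_p_conn()` selects $p_{\mathrm{conn}}$ on a
0.01-step grid so that the mean of the nonzero $a_{p,ij}$ is 0.5 -- the
convention that gives the binarized graphs roughly half of the potential
edges on average.

From $A_p$, `sample_binary_ensemble()` draws $G$ independent binary
connectomes $A^{(\ell)}$. Each is trimmed to the fixed point of "every
neuron keeps at least one incoming and one outgoing edge". The rule as
usually stated only demands no all-zero rows or columns; because a
removal can strip other neurons of their last edge, a fixed point is the
only self-consistent reading, and trimming is idempotent by construction.

Each binary graph is modelled as a directed stochastic block model (SBM):
neurons in class $i$ connect to neurons in class $j$ independently with a
class-pair probability $p_{ij}$. Classes are recovered per graph in two
steps:

1. **Adjacency spectral embedding.** The rank-$d$ SVD
   $A \approx U_d D_d V_d^t$ embeds each neuron as the row of
   $[U_d \sqrt{D_d} \mid V_d \sqrt{D_d}]$, concatenating out- and
   in-connectivity coordinates. $d$ is chosen by maximizing the two-group
   Gaussian profile likelihood of the singular values (the "elbow"), with
   a pooled variance floored at $10^{-12}$; all-equal values return
   $d = 1$ by convention. The elbow is read off the leading part of the
   spectrum (default: top 80 values). Feeding the entire bulk spectrum to
   the two-group likelihood makes it split the bulk instead of isolating
   the signal dimensions, which is why the restriction matters. A second
   elbow, computed recursively on the tail, is reported so users can pin
   the larger alternative dimension.
2. **Gaussian mixture modelling.** The $2d$-dimensional latent vectors
   are fitted with a full-covariance GMM by EM for each candidate number
   of components $k = 1..k_{\max}$, and $k$ is chosen by BIC
   ($2\log L - \nu \log n$). EM is initialised from a Ward-linkage
   agglomerative partition of the latent vectors, making the fit
   deterministic; tolerance is $10^{-6}$ relative log-likelihood with a
   500-iteration cap, and non-convergence is flagged rather than hidden.
   No external mixture-modelling engine is assumed: the EM, its
   initialisation and the BIC search are implemented in the package. A
   small covariance ridge ($10^{-6}$ of the average coordinate variance)
   guards the degenerate fits that perfectly separated blocks produce.

# Consensus

The $G$ clusterings $\pi_1, \dots, \pi_G$ disagree in label names, in
cluster counts, and on individual neurons. They are merged by a modified
iterative voting consensus: for each reference clustering, every cluster
gets a *center vector* (its majority label under each of the $G$
clusterings), and every neuron is reassigned to the cluster whose center
is nearest in Hamming distance to the neuron's own label vector, iterated
to a fixed point. Ties -- in majority labels and in distances -- break
toward the lowest numeric label, which makes the update deterministic and
independent of processing order; clusters emptied mid-iteration are
dropped. Neurons trimmed out of a graph carry a missing label there,
which counts as a mismatch against every center: absence is treated as
evidence against association.

The updated clusterings define a similarity matrix $s_{ij}$, the
proportion of clusterings placing $i$ and $j$ together (always a multiple
of $1/G$). Final classes are the connected components of the graph with
an edge wherever $s_{ij} \ge \tau$ — the transitive closure of the
$\tau$-chain rule. (The chain condition is sometimes printed against the
count scale $\tau G$; since $s$ is a proportion the only dimensionally
consistent reading is $s_{ij} \ge \tau$, equivalently a count of at least
$\tau G$.) Components smaller than $c_{\mathrm{size}}$ are moved to an
explicit *unassigned* pool; survivors are renumbered by decreasing size.
Raising $\tau$ can only refine the partition, never merge it.

# The circuit

Block probabilities are estimated by Eq.-style averaging: $\hat p_{ij}$
is the mean over graphs of (edges from class $i$ to class $j$) divided by
the number of ordered neuron pairs present in that graph. Two decisions
matter here. Within-class denominators exclude self-pairs
($|V_i|(|V_i|-1)$), because the graphs have no self-loops, so self-pairs
are structural zeros. And denominators are per graph, so neurons trimmed
from one realisation do not dilute the others.

The raw $\hat P$ is floored to make the circuit readable: entries are
removed from the smallest value upward, stopping at the largest threshold
that still leaves every class at least one incident (incoming or
outgoing) edge. Feasibility is monotone in the threshold, so the scan is
over distinct ascending values; the recorded threshold reproduces the
edge set exactly as "keep $\hat p_{ij} >$ threshold", which sidesteps the
strict-versus-weak inequality ambiguity of a verbal flooring rule.
Restricting the estimator to a neuron subset (a neurotransmitter, for
example) reuses the identical formula on masked neurons only, and equals
the unrestricted estimate when the mask is full. Pathway views keep the
top fraction of edges by weight, with ties at the cutoff all kept.

# Random walks: absorption and driftiness

On the circuit with scaled class sizes
$\tilde V_i = |V_i| / \min_k |V_k|$, a step from class $i$ to class $j$
costs $1 / (P_{ij} \tilde V_i \tilde V_j)$: the more neuron-level edges
expected between two classes, the cheaper the hop. Walks are simple
(no class revisited, self-loops ignored) and the target is terminal.
*Absorption* $A(s \to t)$ is the average total cost over **all** simple
paths from $s$ to $t$; *driftiness* is $D = A / \delta$ with $\delta$ the
Dijkstra shortest-path cost. $D \ge 1$ wherever defined, and both $A$ and
$\delta$ scale linearly under a uniform cost scaling, leaving $D$
invariant.

Enumeration is exhaustive up to $\kappa = 10$ classes (the path count
grows faster than $\kappa!$). Beyond that, absorption is estimated from
$m$ self-avoiding walks that pick the next class uniformly among
unvisited out-neighbours, resampling dead ends and non-arrivals. That
sampling law does not weight paths uniformly -- it favours paths through
sparse neighbourhoods -- so each sampled path carries an importance
weight equal to the product of its branching factors (the inverse of its
sampling probability), and the weighted average provably targets the
enumerated mean. The unweighted estimator is also available for
comparison, but the enumeration oracle defines correctness and the two
estimators are tested against it. Unreachable pairs are excluded from the
per-class averages (computed over the $\kappa - 1$ counterpart classes)
and their count is reported rather than silently absorbed as infinities.

Interpretation rules are exposed as percentile predicates: classes in the
bottom 20th percentile of average in-absorption are easily reached
(accessible), classes in the bottom 20th percentile of out-absorption
readily originate signals, and pairs in the top 10th percentile of
driftiness mark critical, non-redundant links. Percentiles are rank-based
with ties sharing rank.

# Biomarkers, growth, hubs and fit

Class-to-biomarker maps use the empirical posterior
$p(Y = j \mid X = i)$; a class is labelled with a category only when the
posterior strictly exceeds 0.67. Dependence between classification
schemes is quantified with entropy, mutual information and the
directional NMI $I(X;Y)/H(Y)$, all in bits -- NMI is scale-free, but a
fixed log base keeps entropies comparable across runs. NMI toward a
constant labeling divides by zero and is reported as 0 with a degeneracy
flag (1 only if both labelings are constant). Partition agreement uses
the permutation-adjusted Rand index, restricted to neurons classified by
both schemes; unassigned neurons are excluded from all pairwise
comparisons.

Growth statistics compare each class's cumulative daily size against
uniform growth: $g_k^i = 100\,(n_i\rho_k^i - n_i\rho_k^9) /
(n_i\rho_k^9)$, with day 9 its own reference ($g_k^9 = 0$). Critical
periods are the top quartile of day-over-day growth-rate differences,
computed per class (critical periods are reported per class); the
embryo day, which has no predecessor, contributes $g_k^0 - 0$, treating
the embryonic jump as growth from an empty circuit.

Hubs are classes above a quantile (default 0.9, configurable -- the
reference analysis identifies hubs by inspection rather than a printed
cutoff) on *both* size-weighted degree and betweenness centrality, the
latter computed on the unweighted digraph and normalized by
$(\kappa-1)(\kappa-2)$. Goodness-of-fit pools each neuron's out-connection
counts into a target class across all graphs and reports the fraction
within two binomial standard deviations of $|V_j|\hat p_{ij}$; on exactly
SBM data this fraction is the usual ~95% normal coverage, and
overdispersed (mixture) data pushes it down. Histogram intersection of
two samples uses integer-aligned unit bins for count data.

# The synthetic generator: what it emulates, and what it does not

`sbm_spec()` + `simulate_connectome()` produce the stated world for every
test: a directed SBM with membership probabilities $\rho$, block matrix
$P$, no self-connections, and integer strengths on present edges drawn
from a shifted geometric distribution with configurable mean (default
7.8, matching the long-tailed, mean-7.8 character of fly potential
connectomes; the true strength distribution is unpublished, so the
one-parameter geometric is an explicit stand-in exposed as a knob).
Biomarker columns are generated with tunable block concordance -- with
probability `concordance` a neuron's category is a fixed function of its
block, otherwise uniform -- and birthtimes follow per-block day profiles.
The default test scale is $n = 2000$, $\kappa = 6$, exercising
$\kappa \ll n$ at desk size.

The generator does **not** emulate spatial embedding, morphology, degree
heterogeneity within blocks, or any deviation from conditional edge
independence. A green test therefore establishes that the pipeline
recovers a *true* SBM planted at realistic sparsity and strength scales;
it does not establish that real connectomes are SBMs, nor does it
reproduce dataset-specific headline numbers (class counts, NMI values,
hub identities), which depend on data not distributable with a package.

# Numerical and design choices

- **Decompositions.** Exact LAPACK SVD up to 800 neurons; above that, a
  randomized range-finder SVD (3 power iterations, oversampling 10,
  seeded) computes the leading 80 singular pairs. The randomized path
  trades the exact best-rank-$d$ guarantee for an order-of-magnitude
  speedup; on SBM spectra with separated signal values the leading pairs
  agree with LAPACK to ~1e-6 (tested).
- **BIC search.** Exhaustive over $k = 1..k_{\max}$ by default. A finite
  `patience` stops the scan after the BIC has declined for that many
  consecutive candidates -- a runtime optimisation appropriate for the
  unimodal BIC landscapes of planted data, used by the acceptance-scale
  tests and documented wherever used.
- **Seeds.** One master seed spawns named substreams (one per sampled
  graph, one per pipeline stage), so any stage can be rerun in isolation
  and a rerun of the whole pipeline is bit-for-bit identical. The
  random-walk sampler uses R's RNG from C++, so it follows `set.seed()`.
- **Degenerate inputs.** All-zero probability matrices, empty consensus
  partitions, unreachable walk targets, constant labelings and zero
  expected growth sizes are all explicit flagged states, not errors or
  silent zeros, except where a contract makes emptiness impossible.

# Known limitations

- The per-graph clustering assumes $\kappa \ll n$; subsampling guards
  refuse fractions that leave too few neurons to support the search.
- Absorption by enumeration is exponential in $\kappa$; the sampling
  estimator's variance grows with branching, and for circuits much larger
  than the reference scale (~54 classes) the $m = 10^5$ default may need
  raising.
- The weighted-SBM generalisation (clustering the strength matrix
  directly, without binarization) is out of scope.
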