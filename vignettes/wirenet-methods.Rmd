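---
title: "Methods: models, parameters, and numerical choices in wirenet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters, and numerical choices in wirenet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the models it
implements, the assumptions behind them, the tunable parameters that
matter, what the synthetic-data generator does and does not emulate, and
the numerical and design decisions taken where the design was genuinely
open. It states no empirical result that the test suite does not itself
compute.

## The data model

A wiring diagram is two tables. The neuron table assigns each named
neuron a category (sensory, interneuron, motor), a GABAergic flag, a
body side (L/R/none), and an anatomical class (so bilateral pairs such
as AVAL/AVAR share the class AVA). The synapse table is a list of
records (pre, post, type, contacts, polyadic): `contacts` is the number
of parallel synaptic contacts (the multiplicity of the connection);
`polyadic` counts the contacts whose presynaptic terminal apposes more
than one candidate postsynaptic process, which creates a counting
ambiguity in electron-micrograph reconstruction.

Conventions adopted where the source conventions were open:

- **Polyadic quantitation.** Under `polyad_split`, each polyadic contact
  contributes weight 1/2 instead of 1 (configurable via
  `polyad_weight`). A dyad shared between two candidate postsynaptic
  processes is the minimal nontrivial split; nothing in the data
  supports a finer choice.
- **Paired gap records.** Gap junctions must be recorded from both
  sides. When the two stated counts disagree, the larger is used and a
  `gap count mismatch` violation is reported; disagreement is data
  worth surfacing, not an exception worth raising.
- **Neuromuscular records** are parsed and preserved but excluded from
  all neuron-to-neuron networks.
- **Zero-synapse neurons** are dropped by default (`drop_isolated`),
  mirroring the exclusion of non-synapsing cells from the reference
  dataset; a flag retains them, which is also how the gap and chemical
  networks are aligned onto a common index.
- **Self-records are rejected**: the networks have zero diagonal by
  construction.

## Tail fitting

All integer-valued data are fitted with discrete likelihoods. The power
law `p(k) = k^(-alpha) / zeta(alpha, xmin)` uses the Hurwitz zeta
function, computed by Euler–Maclaurin summation (64 explicit terms plus
correction terms; absolute accuracy far below the optimizer's 1e-8
tolerance). The exponential family on a discrete support is the
geometric law, whose MLE is closed-form. The stretched exponential is
fitted to the whole distribution — it is a body model, not a tail model
— with survival `P(M >= m) = exp(-((m-1)/lambda)^beta)` for `m >= 1`.

`xmin` is selected by minimizing the KS distance between the fitted and
empirical tail, over candidates that leave at least 10 *distinct* tail
values (and at least as many observations). Counting observations alone
lets the KS minimization drift into vanishing tails, where any family
fits anything.

**Family comparison.** Competing fits are compared by log-likelihood
after re-fitting both families on the tail starting at the *smaller* of
the two selected `xmin` values. The alternative (the larger `xmin`)
makes the comparison support the possibly tiny tail chosen by the
misspecified family — for a misspecified family the KS-optimal `xmin`
drifts deep into the tail precisely because small samples fit anything
— and in a 20-seed pilot that rule turned the preference into a coin
flip (15/20 and 17/20 correct), while the smaller-support rule is 20/20
in both directions. Both rules evaluate the two likelihoods on
identical observations, so commensurability is preserved.

**Goodness of fit** is a semiparametric bootstrap: each replicate draws
from the fitted tail model with probability `n_tail/n` and resamples the
observed body below `xmin` otherwise, is re-fitted from scratch
(including `xmin` re-selection), and the p-value is the fraction of
replicates with KS at least the observed. Plausibility threshold:
p > 0.1, the convention of the methodology this follows.

## Random-graph analytics

`er_giant_stats` uses mean degree `c = p (n - 1)` (the expected degree,
not `p n`). The giant fraction is `rho = 1 + W(-c e^(-c))/c` with the
principal Lambert branch, computed by Newton iteration. The asymptotic
variance is implemented as `n rho (1 - rho) / (1 - c(1 - rho))^2`; the
source's printed expression is not recoverable, so this form is held to
a Monte-Carlo acceptance test (ER simulation at c in {1.5, 2, 4},
agreement of the mean within 3 sigma and of the sd within 50%) rather
than asserted textually.

`gf_giant_component` iterates `u <- G1(u)` from 0, which converges to
the smallest non-negative fixed point because G1 is monotone on [0, 1].
The mean small-component size is `1 + z1 u^2 / ((1 - S)(1 - G1'(u)))`,
the generating-function expression for the expected size of the
component containing a randomly chosen *node* outside the giant
component (node-weighted, which is how the test suite validates it
against configuration-model simulation).

## Null models

Rewiring operates on binarized networks (the small-world and motif
analyses ignore multiplicity by design). Degree-preserving rewiring is
the double-edge swap; burn-in defaults to 100 attempted swaps per edge
(the source does not state its schedule; 100 sweeps is far beyond the
mixing observed on networks of this size). The triangle-preserving
variant rejects any swap that changes the *global* triangle count — the
simplest reading of "preserves the number of triangles"; a per-node
variant would be a different (stricter) ensemble and is not claimed.
The directed variant keeps unidirectional arcs and mutual pairs in
disjoint pools and never creates a connection on a pair connected in
either direction, so each node's in-degree, out-degree, and
unidirectional/bidirectional connection counts are exact invariants.

Motif significance uses one-sided (overrepresentation) plug-in
p-values, `(1 + #{samples >= observed}) / (R + 1)`, corrected by the
step-down min-P algorithm with full-ensemble reuse: each sample's
counts are converted to p-values against the same ensemble, and the
adjusted p of the currently most extreme class is the fraction of
samples whose minimum plug-in p over the classes still in play is at
most its raw p, with monotonicity enforced. Underrepresentation is the
same machinery on negated counts, behind a flag.

Isomorphism classes are built by enumerating all labelled patterns
(2^3, 2^6, or 2 bits per ordered pair) and grouping them under explicit
vertex permutations; classes are ordered by edge count, then degree
sequence, then pattern code. The census enumerates every subset in
compiled code; size-4 censuses cost C(n, 4) checks and stay practical
to a few hundred neurons, which covers the intended scale.

## Linear dynamics

The gap-junction network is a resistor network: with equal neuron
capacitances `C_m` and equal per-contact conductances `g`, charge
conservation gives `tau dV/dt = -L V`, `tau = C_m / g`, with L the
weighted Laplacian. Chemical synapses enter through the linearization
of tonic transmitter release around the operating point: the
postsynaptic current is proportional to the presynaptic voltage, so
chemical coupling appears purely off-diagonally,
`M[i,j] += s_j (g_c/g) m_chem(j -> i)`, with `s_j = -1` for GABAergic
presynaptic neurons. No chemical diagonal loss term is included — that
is the content of the linearized tonic-release model, and the membrane
leak (if enabled) is an explicit `-g_m/g` identity shift that moves
every eigenvalue by exactly that amount.

Default constants are `C_m` = 1 pF, `g = g_c` = 100 pS, `g_m` = 10 pS,
giving `tau` = 10 ms. They are order-of-magnitude electrophysiological
estimates, configurable; decay times scale linearly in `tau`, so all
structure in the spectrum is independent of them.

Eigenmodes are L2-normalized with the phase convention that the
largest-magnitude component is positive real (this pins the sign for
regression tests). Sparseness is the L1 norm of the unit-L2 mode,
between 1 (single neuron) and sqrt(n) (flat). `simulate_response`
solves by eigendecomposition when the eigenbasis condition number is
below 1e8 and by fixed-step RK4 otherwise, stepping at 0.01 of the
spectral-radius time; the two paths agree to 1e-6 relative in tests.

The signal-flow layout minimizes `sum w_ij (z_j - z_i - 1)^2`; the
stationarity system `L_sym z = d_in - d_out` is solved per weakly
connected component with a zero-mean gauge (one coordinate is fixed and
the solution recentred; L_sym is singular exactly by the gauge freedom).
The affinity layout uses the eigenvectors of the 2nd- and 3rd-smallest
Laplacian eigenvalues of the symmetrized weighted network on its giant
component. The unnormalized Laplacian is the default; the
degree-normalized variant is available behind `normalized = TRUE`,
since the source's supplementary drawing algorithm is not reproduced
here.

The pseudospectrum is computed densely — `sigma_min(zI - M)` by SVD at
each point of a default 51x51 grid. Networks here have at most a few
hundred nodes; no Krylov projection is warranted.

## The synthetic connectome

`synth_params()` defaults state the emulated world: 280 neurons
(30/30/40% sensory/inter/motor, bilateral L/R name pairs), ~500
gap-junction connections from a configuration model with discrete
power-law degrees (exponent 3), ~2000 chemical connections with
heavy-tailed Chung–Lu in/out propensities (exponent 2.5),
stretched-exponential multiplicities (lambda = 2, beta = 0.5), 40%
polyadic contacts, 10% of non-sensory neurons GABAergic. These match
the orders of magnitude of the hermaphrodite somatic nervous system and
the distribution families its published statistics follow.

Decisions inside the generator:

- **Conflict resolution in the configuration model.** Self-pairs and
  parallel pairs are resolved by rejection, applied locally: the
  conflicted stubs are re-shuffled together with an equal number of
  innocent edges (pure whole-matching rejection has vanishing
  acceptance for heavy-tailed degrees at n = 5000; re-shuffling only
  the conflicted stubs can deadlock). After 1000 rounds the generator
  errors, naming the parameters as the cause.
- **Gap density knob.** The power-law exponent fixes the degree
  distribution's shape, so `mean_gap_connections` is honoured by
  choosing the minimum degree (continuous-approximation inversion,
  rounded). The realized edge count therefore tracks the target only
  approximately, with visible jumps where the rounding switches — the
  exponent, not the count, is the calibrated quantity.
- **Association between the networks.** `overlap_odds` multiplies the
  odds of a chemical connection for pairs joined by a gap junction
  *and* couples neuron-level chemical propensities to gap degree via a
  Gaussian copula with weight `1 - 1/overlap_odds`. The pairwise boost
  alone cannot produce the degree-sequence correlations observed in
  real data: boosting a few hundred of ~78,000 pairs under a calibrated
  total leaves the degree sequences uncorrelated (measured: r ~ 0.00 ±
  0.03). Real connectomes show both effects because the same neurons
  are hubs of both networks; the copula weight vanishes exactly at
  `overlap_odds = 1`, so the independence control (all likelihood
  ratios = 1) is preserved.
- **Bilaterality is nominal**: name pairing only, no mirrored
  connectivity, because no quantitative left/right symmetry statistic
  is available to emulate.
- **Scaling convention.** When tests need a larger network "like" the
  default world, connection counts are scaled to hold per-pair density
  constant (the 280-neuron densities are the stated world; a 2000-neuron
  control with worm-level sparsity would have essentially no
  bidirectional pairs, making conditional state probabilities
  degenerate).

What a green test on synthetic data does **not** establish: anything
about spatial structure (there is none), about left/right symmetry
(nominal), about the identity of specific neurons or circuits, or about
the real dataset's numerical values (which require the external
download).

## Interaction statistics

Likelihood ratios condition on all unordered pairs of the common index.
Confidence intervals use a **neuron-resampling bootstrap** rather than
pair resampling: pair states sharing a neuron are strongly dependent
(one hub's propensity shifts thousands of pairs at once), and the pair
bootstrap understates the uncertainty enough that exact independence is
rejected through realization noise alone. Resampling neurons and taking
the induced pair multiset (computed sparsely, O(edges) per replicate)
captures the dominant variance component. A zero denominator yields an
infinite ratio with an `undefined` flag, not an error.

The GABA-restricted ratios use pairs containing at least one GABAergic
neuron, with the chemical state classified from the connections whose
presynaptic end is the GABAergic member; a connection into the
GABAergic member from a non-GABAergic partner does not count. This is
an interpretation — the source's exact pair universe is not
recoverable — and is documented as such.

Degree-correlation significance is by permutation: one sequence is
permuted `n_perm` times; the permuted correlations have mean ~0 and sd
~1/sqrt(n), and both the two-sided p-value and the 97.5th percentile
are reported.

## Robustness editing

Errors are simulated per *contact*, not per connection: each unit of
multiplicity independently moves with its type's probability to a
uniformly random ordered pair (chemical) or unordered pair (gap
junction, keeping the edited network symmetric), never a self-pair.
Total contacts per type are conserved exactly, polyadic flags travel
with their contacts, and relocated contacts may stack on
already-connected pairs (the alternative — forbidding stacking — would
bias the edit toward sparsification and is not what "assigning them to
a randomly chosen pair" says). Each ensemble member is a deterministic
function of (seed, draw index).

## Known limitations

- The real reference dataset is optional input; nothing is bundled, and
  the published numerical values for it are not asserted anywhere.
- Size-4 censuses above a few hundred nodes and dense pseudospectrum
  grids on large matrices are the two deliberately brute-force hot
  spots.
- The min-P correction reuses the full ensemble for the plug-in null
  distribution (no leave-one-out); with R >= 100 samples the
  discreteness is below the decision thresholds used here, and a
  warning is emitted below that.
- Nonlinear electrophysiology is out of scope; the linear model is the
  analysis tool, not a biophysical claim.
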