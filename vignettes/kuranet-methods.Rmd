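---
title: "Synchronization criticality on large networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synchronization criticality on large networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`kuranet` simulates the weighted Kuramoto model on large sparse networks,

$$\dot\theta_i(t) \;=\; \omega_{i,0} \;+\; K \sum_j W_{ij}\,
  \sin\!\bigl(\theta_j(t) - \theta_i(t)\bigr),$$

where the intrinsic frequencies $\omega_{i,0}$ are i.i.d. standard normal,
$W_{ij}$ is a weighted coupling matrix (row $i$ receives from column $j$),
and the global coupling $K$ is the control parameter.  The degree of
synchrony is measured by the order parameter

$$R(t) = \frac{1}{N}\Bigl|\sum_j e^{i\theta_j(t)}\Bigr| \in [0, 1].$$

On graphs whose topological dimension is below four no true synchronization
phase transition survives the thermodynamic limit; there is instead a smooth
crossover between desynchronized and partially synchronized states.  Near
this crossover the model develops the slow, heterogeneous dynamics the
package is built to quantify: power-law growth and decay of $R(t)$ and
power-law-tailed first-passage (desynchronization) durations, a
Griffiths-phase-like phenomenology sustained by quenched network
heterogeneity.

## Observables

Three quantitative outputs are extracted from ensembles of runs.

* **First-passage durations.**  A run started from random phases (or from
  full synchrony) is integrated until $R(t)$ first falls below the
  incoherent-phase noise level $R_T = 1/\sqrt N$.  Crossings are detected at
  the sampled instants; the crossing time is estimated by the midpoint rule
  $t_x = (t_k + t_{k-1})/2$ with $t_{-1} \equiv 0$.  The distribution
  $p(t_x)$ develops a power-law tail $p \sim t_x^{-\tau_t}$ near the
  transition.
* **Growth exponent.**  From incoherent starts, $\langle R(t)\rangle \sim
  t^{\eta}$ at the critical coupling.  The effective exponent
  $\eta_\mathrm{eff}(t_k) = \bigl[\ln\langle R(t_{k+3})\rangle -
  \ln\langle R(t_k)\rangle\bigr] / \bigl[\ln t_{k+3} - \ln t_k\bigr]$
  is plotted against $1/t$: flat at criticality, veering up
  (supercritical) or down (subcritical) otherwise.
* **Decay exponent.**  From coherent starts ($\theta_i(0) = 0$),
  $\langle R(t)\rangle \sim t^{-\delta}$ at criticality.  The two dynamical
  exponents are linked by the scaling relation $\tau_t = 1 + \delta$, which
  `scaling_relation_check()` evaluates against the combined fit
  uncertainties.

## Networks

* `make_2dll(L)` builds the small-world reference substrate: a periodic
  $L \times L$ lattice with unit-weight nearest-neighbour bonds plus
  $\lfloor N/2\rfloor$ distinct random long-range links, giving mean degree
  $\langle k\rangle \approx 5$.  Long-range links are *added* (not rewired),
  and all weights are 1; the lattice substrate is conventionally unweighted
  and the incoming-weight normalization step is reserved for connectome
  graphs.
* `make_full_graph(n)` is the mean-field fixture.  With normalized weights
  $W_{ij} = 1/(n-1)$ and standard normal frequencies the classical
  threshold $K_c = 2/(\pi g(0)) = 2\sqrt{2\pi}/\pi \approx 1.5958$ applies,
  which anchors the validation suite.
* `make_synthetic_connectome(n, ...)` generates a surrogate with the
  statistical features that drive the dynamics on real tractography
  connectomes: two hierarchy levels (modules inside module groups, with the
  intermediate coupling density taken as the geometric mean of the intra-
  and inter-module densities), log-normally dispersed module sizes,
  Pareto-tailed positive weights ($p(w) \sim w^{-3}$ by default, $w \ge 1$,
  standing in for fiber-count heavy tails), and a forced spanning backbone
  so the graph is connected.  It does **not** reproduce anatomical
  geometry, the empirical degree sequence, or the $d \approx 3$ topological
  dimension of a specific brain graph — conclusions that depend on those
  features require the real edge list, which `load_edge_list()` accepts in
  the plain `source target weight` format.
* `load_edge_list()` merges duplicate edges by weight summation (weights
  are fiber counts; counts add), remaps node ids densely and keeps the
  mapping.

Connectome preparation follows the fixed order *largest component →
incoming-weight normalization → inhibitory flips*.  `normalize_incoming()`
divides each node's received weights by their sum (homeostatic input
balance; every row of $W'$ sums to 1).  `flip_links()` makes a fraction of
links inhibitory, either symmetrically ($W''_{ij} = W''_{ji} = -W'_{ij}$) or
anisotropically ($W''_{ij} = -W'_{ij}$, $W''_{ji} = 0$); `flip_nodes()`
negates all out- or in-links of a node fraction.  Link selection operates
on undirected link positions so the symmetric mode is well defined, and
uses an RNG stream separate from the frequency/phase streams.

`topological_dimension()` estimates $d$ from $\langle N_r\rangle \sim r^d$
via breadth-first shells from random sources.  Both the shell and the
cumulative pair-count conventions are implemented; the cumulative form is
the default (its growth exponent is $d$ directly, and it is the reading
under which $\langle N_r \rangle \sim r^d$ is dimensionally consistent),
and the default fit window ends where the cumulative count reaches half the
graph, before finite-size saturation bends the curve.

## Integration and sampling

The equation is integrated with classical fixed-step RK4 at $\Delta t =
0.1$.  Smaller steps do not change ensemble statistics on these networks;
they only reshuffle individual chaotic trajectories.  A per-sample
finiteness guard aborts on numerical blow-up (with bounded phase
velocities, $|\dot\theta_i| \le |\omega_i| + K \sum_j |W_{ij}|$, this can
only fire for couplings far outside the stability region $K\,\Delta t
\lesssim 2.8$ of the explicit scheme — at such couplings reduce `dt`).
The compiled kernel expands $\sin(\theta_j - \theta_i)$ into two sparse
matrix-vector products over the stored links, so an evaluation costs
$O(N)$ trigonometric calls plus $O(\mathrm{nnz})$ multiply-adds; the
uniform complete graph short-circuits to the exact $O(N)$ global-phasor
form.  A pure-R reference implementation of the same right-hand side and
integrator is exported and cross-checked against the kernel in the tests.

$R$ is sampled at $t_k = 1 + 1.08^k$, equidistant in $\log(t-1)$, the
standard schedule for power-law asymptotics.  Duration ensembles terminate
each realization at its first crossing (cheap); curve ensembles integrate
every realization to `t_max` so $\langle R(t)\rangle$ is an unconditional
mean.  Both modes exist because the duration statistics and the
growth/decay curves are different measurements: the conditional late-time
mean over surviving runs differs from the unconditional mean.

Each realization draws fresh frequencies and phases from two independent,
deterministically derived seed streams, so ensembles are bit-reproducible
and embarrassingly parallel in principle.

## Histograms and fits

Durations are binned with widths growing as $\Delta t_x \propto
t_x^{1.12}$; the proportionality constant is chosen automatically to give
about 40 bins over the sample range (both the growth exponent and the bin
count are exposed).  Densities normalize over the uncensored sample;
censored (never-crossing) runs are counted and reported, and a warning is
raised when censoring exceeds 10%, since a depleted far tail flattens
least-squares slopes.  Tail exponents come from unweighted least squares of
$\log p$ on $\log t_x$ (geometric bin centers) above a threshold
$t_\mathrm{min}$ — 10 for lattice-style runs and 20 for connectome-style
runs by default.  The threshold choice replaces visual inspection;
`scan_tail_threshold()` reports the fit drift across thresholds so the
stability of a quoted exponent is explicit.  Maximum-likelihood power-law
estimators are deliberately not the primary route: the binned least-squares
slope is the estimator the reference measurements are defined by.

`locate_transition()` operationalizes the visual convex/concave criterion:
for each coupling the trend statistic is the negated slope of
$\eta_\mathrm{eff}$ versus $1/t$ over the last third of the series, so
up-veering is positive; $K_c$ is bracketed between the largest coupling
trending negative and the smallest trending positive, with linear
interpolation through zero as the point estimate.  The bracket, not the
interpolated point, is the honest uncertainty.  The trend criterion needs
smooth $\langle R(t)\rangle$ curves (thousands of realizations per
coupling); `locate_transition_steady()` offers an amplitude-free
alternative on the steady-state sweep — the coupling where $\log
R_\infty(K)$ rises fastest (the inflexion condition) — which self-averages
and works from tens of realizations, at grid-limited resolution.  `plateau_exponent()` and
the automatic window of `decay_exponent()` use the same stability idea: the
longest contiguous stretch of local slopes within a tolerance (0.1 by
default) of its own mean.

## Problem sizes and what desk-scale runs can show

The reference measurements for this class of dynamics were produced on
cluster/GPU-scale systems ($L = 6000$ lattices, $\simeq 10^4$ runs,
million-node connectomes).  The package's validation suite and acceptance
script run the same protocols at desk scale, a deliberate design choice
with known consequences:

* Lattice experiments use $L = 64$ ($N = 4096$): duration ensembles of
  400–500 runs to $t_\mathrm{max} = 600$, curve ensembles of 200–300 runs
  to $t_\mathrm{max} = 150$–300.
* At this size the scaling window is short and the three exponents degrade
  very differently.  The decay exponent is robust ($\approx 0.58$ against
  the large-system 0.6(1)).  The $\eta_\mathrm{eff}$ plateau spans only
  $t \in [5, 30]$ before finite-size saturation bends it down and reads
  0.49–0.60 across seeds against 0.55(10); the plateau picker deliberately
  takes the earliest stable stretch, since on these sizes a long stretch
  of post-breakdown bent-down slopes would otherwise win.  The first-passage tail is the fragile
  one: on lattices of $L = 64$–100 the fitted tail reads $\tau_t \approx
  1.0$–1.3 *at every coupling across and below the critical window*, far
  from the large-$L$ 1.6(1).  The mechanism is visible in single runs: at
  these sizes $R(t)$ fluctuates on the same scale as the threshold
  $1/\sqrt N$ throughout the run, so late crossings are ordinary
  fluctuation events with a near-$1/t$ first-passage tail, whereas on a
  $6000^2$-node lattice the order parameter self-averages over many
  correlation volumes and late crossings are genuinely rare.  The
  steep tail is therefore an asymptotic large-$L$ feature that desk-scale
  runs of this protocol cannot reproduce, and the package reports the
  desk-scale value as measured rather than emulating the asymptotic one.
* Mean-field validation uses the normalized complete graph at $N = 2000$,
  50 realizations per coupling, where the steady-state sweep must bracket
  $K_c = 2\sqrt{2\pi}/\pi$.
* Connectome-specific numbers ($\tau_t \simeq 1.2$, crossover couplings
  1.65–1.9) depend on the real KKI-18 graph and cannot be validated against
  the surrogate; the synthetic connectome checks construction invariants
  (modularity, connectivity, weight tails) and pipeline mechanics, not
  those exponent values.

## Numerical choices and degenerate inputs

* Default threshold: `threshold = NULL` resolves to $1/\sqrt N$ at run
  time, for the network actually simulated.
* A first sample already below threshold yields $t_x = t_0/2$, preserving
  the midpoint convention at the boundary.
* Histogram edges start at the smallest uncensored sample; an all-equal
  sample degenerates to a single bin of unit mass.
* Tie-break for equally large components: the one containing the smallest
  original node index.
* The effective-exponent stride is 3 sampling indices; series shorter than
  stride + 1 are rejected rather than padded.
* Transition bracketing requires at least three couplings and errors
  when all trends share a sign (the grid does not straddle the
  transition).
* Seeds derive from a single master seed via a fixed affine map into the
  32-bit range, with separate streams for frequencies, phases, link
  selection and per-coupling offsets.

## Limitations

* Fixed-step RK4 has no error control; the step size is a protocol
  constant, not an accuracy knob.  Couplings beyond the stability region
  require a smaller `dt` set explicitly.
* Censored runs are excluded from duration densities (with a warning above
  10% censoring); no survival-analysis correction is attempted, matching
  the reference protocol.
* The synthetic connectome is a statistical stand-in, not an anatomical
  model; results that depend on the real graph's geometry require loading
  it.
* Single-threaded: ensembles are run sequentially for determinism.
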