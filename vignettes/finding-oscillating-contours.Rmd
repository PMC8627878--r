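---
title: "Finding and verifying potentially oscillating feedback contours"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding and verifying potentially oscillating feedback contours}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oscontour)
```

## The problem

Many molecular-genetic systems oscillate: circadian clocks, the p53–Mdm2
couple, glycolytic flux, calcium spiking. The common structural ingredient
is negative feedback — an end product that inhibits an upstream step —
combined with enough delay and nonlinearity around the loop. `oscontour`
automates a two-stage screen for such systems in enzymatic networks:

1. **Structural stage.** In a typed bipartite graph of substances and
   reactions, enumerate *potentially oscillating contours*: directed
   mass-flow chains (substrate → reaction → product → …) closed by a
   single inhibitory regulator edge from the last substance back onto the
   reaction producing the first one, passing through more than 3 nodes.
2. **Dynamical stage.** For each candidate contour, reconstruct a kinetic
   model automatically, integrate it, and decide numerically whether the
   trajectory is a sustained oscillation; scan the inhibition parameters
   to map the oscillatory region.

A structural hit is only a *candidate*: negative feedback is necessary but
not sufficient, so the numerical stage is what confirms (or rejects) a
limit cycle.

## The typed graph and the contour criteria

Nodes are either substances or reactions; edges are typed `substrate`
(substance → reaction), `product` (reaction → substance) or `regulator`
(substance → reaction, signed `activation`/`inhibition`/`unknown`).
A contour with substances $s_1 \dots s_k$ and reactions $r_0 \dots
r_{k-1}$ is the cycle

$$r_0 \to s_1 \to r_1 \to s_2 \to \cdots \to r_{k-1} \to s_k
  \dashv r_0,$$

where every $s_i \to r_i$ is a substrate edge, every $r_i \to s_{i+1}$ a
product edge, and the single closing edge $s_k \dashv r_0$ is an
inhibitory regulation. Two conventions needed fixing where the criteria
alone underdetermine them; both are deliberate package choices:

* **Node counting.** The "more than 3 nodes" rule counts *all* nodes on
  the cycle, reactions included (`n_nodes` $= 2k$). With alternation this
  excludes the degenerate substance–reaction self-loop while admitting the
  smallest interesting loop ($k = 2$, 4 nodes).
* **Exactly one regulator edge.** A candidate cycle that traverses a
  second regulator edge is rejected; the contour is a pure mass-flow path
  with one regulatory closure. Regulator edges with `sign = "unknown"` do
  not close contours unless `assume_unknown_inhibitory = TRUE` — the
  conservative default, since the criterion demands inhibition
  specifically.

`enumerate_contours()` walks, for every inhibitory regulator edge, the
mass-flow chains from the regulated reaction's products by depth-first
search. Results are deduplicated and sorted by a canonical id (the node
sequence starting at the regulated reaction, which the closing edge makes
unique — no rotation ambiguity). `brute_force_contours()` is the
independent oracle: it enumerates *all* simple directed cycles of the
graph (anchored exhaustive DFS, parallel edges expanded) and filters by
the contour invariants; the equality of the two routes is asserted over
100 seeded random graphs in the test suite.

## The generated kinetic model

For a contour of $k$ substances the package builds a Goodwin-type chain:

$$v_0 = \frac{V \prod_b [b]}{K + [s_k]^h}, \qquad
  v_i = k_i\, [s_i] \prod_b [b] \quad (i \ge 1),$$

$$\frac{d[s_1]}{dt} = v_0 - v_1 - k_{D,1}[s_1], \quad \dots, \quad
  \frac{d[s_k]}{dt} = v_{k-1} - k_{D,k}[s_k].$$

The regulated entry reaction carries Hill inhibition with cooperativity
$h$ and half-saturation $K$; every other contour reaction is linear mass
action; each state has first-order degradation. Off-contour co-substrates
and co-products are *boundary species*, held constant; co-substrate
concentrations multiply the rates and default to 1, so they are absorbable
into $V$ and $k_i$. This is the minimal rate-law family consistent with a
feedback chain of enzymatic steps, and the lineage every Goodwin-type
oscillator shares. Intermediate reactions can be given saturating kinetics
only by overriding rate constants — saturable intermediate steps are a
known omission, chosen to keep the generated model reducible to the
canonical chain.

### Default parameters, and why

| parameter | default | units | role |
|---|---|---|---|
| $V$ | 1 | conc/time | entry-reaction scale |
| $K$ | 1 | conc$^h$ | half-saturation of inhibition |
| $h$ | 4 | — | Hill cooperativity |
| $k_i$ | 1 | 1/time | chain rate constants |
| $k_D$ | 0.5 | 1/time | degradation, every state |
| initials | 0.1 | conc | all states |
| boundary | 1 | conc | all boundary species |

The degradation default matters most. Linearizing the chain, the loop's
poles are $k_i + k_D$ at the intermediates and $k_D$ alone at the end
product (which no contour reaction consumes). If $k_D \ll k_i$ the end
product integrates slowly while the intermediates relax fast, the loop
phase margin collapses, and no Hill exponent of practical size
destabilizes the fixed point: with $k_D = 0.1$ the whole
$h \in \{1..8\} \times K \in \{0.1, 1, 10\}$ scan of the 5-stage
tryptophan chain is stable. $k_D = 0.5$ keeps the poles commensurate
(1.5, 1.5, 1.5, 1.5, 0.5); the secant-type bound then puts the Hopf
threshold within reach of moderate cooperativity, and the default scan
shows a sustained region ($h \ge 5$ at $K = 0.1$). This choice was made
once, from the linearized analysis, and is documented here rather than
tuned per example.

Parameter values of the published tryptophan model itself were sourced
from a kinetics database that is not redistributed here, so the package
treats all kinetic constants as user-supplied with the defaults above.

## The trajectory classifier

"Sustained oscillation" is operationalized on a finite trajectory. After
discarding the first half of the window as transient (fraction
configurable), local maxima with topographic prominence at least 5 % of
the post-transient range are located, peak times refined by parabolic
interpolation, and per variable:

* **sustained** — at least 5 peaks, inter-peak coefficient of variation
  $\le 0.05$, last/first peak-amplitude ratio in $[0.9, 1.1]$, overall
  envelope stable, and mean amplitude at least 1 % of the mean signal
  level (guards against numerical ripple);
* **damped** — amplitude ratio below 0.9, or the envelope (range of the
  second half-window over the first) below 0.9 — the second clause
  catches fast spirals whose later peaks fall under the prominence
  threshold;
* **growing** — amplitude ratio above 1.1, envelope growth, or a
  divergent integration;
* **irregular** — enough peaks but period CV above tolerance;
* **steady** — flat or peak-free traces; **inconclusive** otherwise
  (typically too few peaks to decide).

Peak prominences of the first and last detected peaks are truncated by
the window edges, so the amplitude trend uses interior peaks when four or
more are available. The overall label is sustained if *any* variable is
(configurable to *all*). Everything is deterministic: same trajectory and
settings, same report.

Two classifier caveats are intentional. Neutral, non-limit-cycle orbits
(the predator–prey system) satisfy every sustained criterion — the
classifier detects sustained periodicity, not structural stability.
And a trajectory that needs longer than the window to settle can be
labelled `inconclusive` or `growing`; the window is a user decision, with
model-specific default horizons shipped in the classical registry.

## Numerical choices

Integration uses a stiff-capable solver with automatic method switching
(`lsoda`), relative tolerance $10^{-8}$, absolute $10^{-10}$, 2000 output
points — tight because period estimates difference peak times. Divergence
(non-finite or $|x| > 10^8$) truncates and flags rather than fails.
Degenerate inputs are handled explicitly: empty graphs are valid and
contour-free; a contour search with `min_nodes < 4` is a parameter error
(the node-count rule is not relaxable); scan cells that fail record their
error in the cell rather than aborting the scan.

Calibration of the classifier rests on the classical oscillator registry,
each entry in its documented regime: the 1910 two-variable chemical
oscillator (damped control), the predator–prey system (neutral cycles),
the relaxation oscillator (limit cycle; harmonic limit $2\pi/\omega$ used
for period accuracy), the 3-stage repression loop (Hopf near $h \approx
9$–$10$ at the registry defaults $a = 1, K = 1, k_d = 0.5$ — stable at
$h \le 8$, sustained at $h = 12$, so the scan's sustained region is an
up-set in $h$), the reduced glycolytic oscillator ($a = 0.08, b = 0.6$)
and the minimal calcium-release model.

## The synthetic-data generator

`random_typed_graph()` emulates the *structure* of a metabolic network
screen: a random bipartite background of substrate/product edges at a
chosen density, with planted mass-flow chains closed by inhibitory
edges as ground truth. By default background regulator edges are never
inhibitory, so every inhibitory closure is planted; an adversarial flag
permits background inhibitions, in which case accidental contours are
legitimate findings and the brute-force oracle defines truth. Generation
is seeded and byte-reproducible, and the generator restores the caller's
RNG state.

What it does *not* emulate: realistic degree distributions, shared
currency metabolites (ATP-like hubs), reversible reactions, or kinetic
heterogeneity. Passing the planted-recovery and oracle-equivalence suites
therefore demonstrates correctness of the search semantics, not
performance on genome-scale networks.

The tryptophan fixture is the one real pathway shipped: five reactions
over 13 substances with end-product inhibition of anthranilate synthase,
unit stoichiometry (the fixture encodes participation, not
stoichiometric coefficients). Its generated model has exactly 5 state
variables (AN,
NPRAN, CPAD5P, IGP, TRP) and 8 boundary species.

## Gene-network fixtures and the one-link switch

`ring_repression_network()` builds protein-only Hill-repression rings:
$dp_j/dt = a \prod_r (1 + p_r^h)^{-1} - b\,p_j$. The 3-gene ring at
$a = 5, b = 1, h = 4$ oscillates (the repressilator regime); at $h = 1$
it cannot (per-stage gain below the secant bound).

For the qualitative result that *adding a single repressive link can
switch a stationary network to a cyclic one*, the package's fixture is
the open 4-gene repression chain (`ring_closed = FALSE`) — a directed
acyclic network, hence steady for every parameter set — plus the one
closing link $p_3 \dashv g_1$, which creates an odd negative circuit and
oscillates at the frozen set $a = 5, b = 1, h = 4$ with the downstream
gene following as a slave. We verified by grid search that the
alternative demonstration on the 4-gene *symmetric double-repression*
topology does not work in this protein-only reduction: its
mutual-repression pairs are positive circuits whose winner-take-all
stationary attractors persist after any single added link (and the
directed double-repression variant is either already cyclic or is
*stabilized* by a ninth link). Formulations with explicit mRNA/protein
stages and delays behave differently; that layer is out of scope here.

## Problem sizes in the shipped suites

The test and acceptance suites run: the 18-node tryptophan graph; random
graphs of 16 nodes (100 seeds) for oracle equivalence; 24-cell $(h, K)$
scans at 2000 output points over 500 time units; classifier calibration
runs of 40–400 time units per model. These sizes were chosen to exercise
every code path at full numerical tolerance while keeping the whole suite
interactive (tens of seconds).

## Known limitations

* Positive-feedback contours, multi-feedback motifs and double-negative
  closures are out of scope by design; the criteria define
  single-negative-closure contours only.
* The brute-force oracle is exponential and guarded at 20 nodes; the
  targeted search scales with the number of inhibitory edges times simple
  mass-flow paths, which is fine for pathway-scale graphs but has no
  polynomial guarantee on pathological inputs.
* No analytic bifurcation detection (eigenvalue/Hopf tests), Lyapunov
  diagnostics, delays, PDEs or stochastic kinetics.
* SBML support covers core constructs used by the exporter (species,
  reactions, modifiers, MathML kinetic laws, SBO-term signs); it is not a
  general SBML toolkit.
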