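---
title: "Logical modeling of the Caulobacter cell cycle: methods and design"
author: "CauloLogic authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Logical modeling of the Caulobacter cell cycle: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CauloLogic)
```

## The biological question and the modeling formalism

*Caulobacter crescentus* divides asymmetrically into a motile swarmer cell
and a sessile, replication-competent stalked cell. The decision is made by
a compact regulatory circuit around the master regulator CtrA: a
transcriptional core (CtrA, GcrA, DnaA, the methyl-transferase CcrM, and
the co-repressor SciP) that oscillates over the cell cycle, coupled to a
phosphorelay (PleC, DivJ, DivK, DivL, CckA, ChpT, CpdR) and the
ClpXP–RcdA protease that together set CtrA's phosphorylation and
degradation at each cell pole.

CauloLogic models this circuit as a **synchronous multi-valued logical
network** (Thomas formalism). Each node $i$ carries an integer level
$\sigma_i(t) \in \{0, \dots, L_i\}$ — here $L_i \in \{1, 2\}$, with 0 =
absent, 1 = present/unphosphorylated, 2 = phosphorylated (for PleC, 2 =
active phosphatase; for CpdR, 1 = the complex-promoting unphosphorylated
form). All nodes update simultaneously,

$$\sigma_i(t+1) = f_i\big(\sigma_{i_1}(t), \dots, \sigma_{i_k}(t)\big),$$

so the dynamics is a deterministic map on a finite state space of size
$\prod_i (L_i + 1)$. Every trajectory ends in an attractor — a fixed point
or a limit cycle — and the attractors are read as cell states: the
oscillation of the transcriptional core is the cell cycle, the two fixed
points of the phospho-proteolytic network are the two pole micro-domains
that become the two cell types.

## Rule representation

Update functions are stored as **ordered threshold-condition cases** with
an explicit default (`updateRule("DnaA", "CtrA_a & CcrM & !GcrA & !DnaA -> 1")`),
rather than raw truth tables. The first matching case wins, which encodes
multi-valued semantics such as "PleC at level 2 acts as a phosphatase and
overrides the DivJ kinase" directly as case order. Rules are total by
construction (the default catches everything), and `truthTable()` expands
any rule to its explicit table when a representation-independent
comparison is needed (file round trips, oracle checks). The same condition
syntax is used by the YAML/JSON model files, and the packaged model files
load `identical()` to the programmatic builders.

Clamping (used for knockouts, constitutive expression, and the switch
protocol) is applied in the successor map, not in rule evaluation, so a
clamped node's rule remains inspectable; level 0 uniformly means
absent/knocked out.

## The reference rule sets

The curated interaction catalogue (13 nodes, 27 signed, mechanism-annotated
interactions) ships as `inst/extdata/table1_g2.tsv` and loads with
`loadInteractions()`; `reduceToCore()` implements the reduction that prunes
non-regulatory nodes (out-degree 0, self-loops counting as out-edges) until
a fully regulatory core remains.

The logical functions themselves are reconstructed from the functional
descriptions of each interaction; the following choices were genuinely
open and were fixed as follows:

* **CtrA_a**: `GcrA OR (NOT CcrM AND NOT SciP)` — transcribed
  constitutively unless repressed by promoter methylation or SciP,
  OR-gated with GcrA activation. This is the only simple gate we found
  that both reproduces the observed 4-state cycle exactly and leaves no
  spurious all-zero fixed point (treating positive autoregulation as a
  hard conjunct creates one).
* **GcrA** omits its documented positive autoregulation: including
  `OR GcrA` prevents GcrA from switching off when CtrA rises while DnaA
  is absent, breaking the observed progression. This is a deliberate,
  documented deviation.
* **DivK's** transcriptional activation by CtrA is kept in the
  interaction catalogue but not in DivK's update rule: the stalked-pole
  fixed point has DivK phosphorylated while CtrA is absent, so DivK
  protein is treated as persistent on the signaling time scale.
* **PleC** level semantics (2 = phosphatase-active, 1 = inactivated by
  DivK~P) and the phosphatase-over-kinase case order are the unique
  assignment under which both pole fixed points are stable and the
  PleC-to-DivJ replacement drives the switch.

The combined 13-node model re-unifies CtrA as one ternary node:
transcriptional targets read activity as `CtrA == 2`, and CtrA's own rule
composes degradation (`ClpXP_RcdA == 1` wins), the transcriptional gate,
and phosphorylation by ChpT~P.

```{r attractors}
enumerateAttractors(buildG2a())
enumerateAttractors(buildG2b())
```

## Attractor enumeration: algorithm and numerical choices

States are encoded as mixed-radix integers (first node most significant,
so encoded order is lexicographic). `enumerateAttractors()` computes the
full successor table vectorised over the state space, then finds all cycle
states by pointer doubling (repeatedly squaring the successor map until
every state has been iterated past any possible transient), walks each
cycle explicitly, and tabulates basins. `bruteForceAttractors()` is the
independent oracle: it simulates a trajectory from every start state
through the scalar rule evaluator with visited-set cycle detection. The
two must agree exactly — same attractors, same basins — and the test suite
enforces this on hundreds of random networks.

Determinism and reproducibility choices:

* cycles are canonically rotated to start at their smallest encoded state,
  and attractors are ordered by that index, so reports are reproducible;
* exhaustive analyses refuse state spaces above a hard cap (default
  $10^7$) instead of silently sampling;
* ties cannot occur: the synchronous map is a function, so every state has
  exactly one successor.

## In-silico genetics

`applyPerturbation()` clamps a node to 0 (knockout, $\Delta$) or to its
maximal level (constitutive expression, +) for the whole run, matching the
steady-state language of mutant phenotyping; `knockoutScan()` and
`overexpressionScan()` recompute the full landscape per node.
Two mutant rows are **flagged inconsistent rather than asserted**: the
CtrA deletions in both subnetworks conflict with the explicit DnaA
function (which requires CtrA) and with the stalked fixed point, so no
rule set containing those printed components can reproduce them; the
pipeline reports them as `flagged-inconsistent`.

One documented surprise: deleting PleC preserves both pole fixed points
(bistability) but also frees a period-2 DivK/DivJ flip-flop — with the
phosphatase gone, the two kinases phosphorylate each other out of phase —
so the $\Delta$pleC landscape has three attractors, not two. The tests
assert the bistable pair and report the cycle honestly.

`switchExperiment()` implements the differentiation protocol: start at the
swarmer-pole fixed point, transiently clamp `PleC = 0, DivJ = 2`
(the polar replacement of the phosphatase by the kinase), iterate the
clamped dynamics to rest, release, and relax. The system lands in the
stalked-pole fixed point. The `holdSteps` argument distinguishes a
sustained replacement (hold to convergence) from a pulse: a one-step
DivK~P pulse with PleC still active relaxes back to the swarmer state,
whereas holding DivK~P long enough commits the cascade — the clamp
duration, not DivK phosphorylation per se, is what decides commitment.

## Derrida criticality analysis

The Derrida map quantifies perturbation propagation: draw a background
state $S_1$ uniformly, build $S_2$ at Hamming distance $h$ (number of
differing nodes — level gaps are not summed, the standard multi-valued
generalization), advance both one synchronous step, and record
$M(h) = E\,[\,|F(S_1) - F(S_2)|_H\,]$. The slope $m = dM/dh$ at $h = 0$
classifies the regime: ordered ($m < 1$), critical ($m = 1$), chaotic
($m > 1$), with a configurable critical band (default $|m - 1| \le 0.05$).

Estimator choices:

* $M(0) = 0$ exactly, and $h$ is discrete, so the default slope estimator
  is the finite difference through the origin, $m = M(1)$: the network's
  mean single-node perturbation sensitivity, averaged over background,
  perturbed node and replacement level. A weighted least-squares line
  through the origin over $h \le 3$ is available (`method = "fit"`) as a
  discretization sensitivity check.
* Backgrounds are uniform over the full state space, not restricted to
  attractors.
* On clamped networks, backgrounds carry the clamp levels and
  perturbations still pick among all $n$ nodes uniformly; a perturbation
  landing on a clamped node is erased by the clamp after one step. This
  convention makes a knockout of an unread constant node exactly neutral,
  as it should be, and is enforced by tests.
* `exactDerridaSlope()` enumerates every (state, node, replacement) triple
  and is the oracle for the sampled estimator on small state spaces.

```{r derrida}
derridaSlope(buildG2Combined(), samples = 5000, seed = 1)
```

With the reconstructed rules the combined network's exact slope is
$m = 0.740$, on the ordered side of criticality; deleting GcrA, DivJ or
SciP lowers it further (exact values 0.663, 0.663, 0.728), while the
protease knockout pushes the network toward criticality. The precise
value of $m$ is sensitive to the reconstructed rule set — the original
truth tables live in supplementary material unavailable here — so the
package treats $m$ as a quantity to be recomputed, not a constant.

Default sample counts: 20,000 pairs per $h$ class put the standard error
of $M(1)$ near 0.003 on a 13-node network, far below the ordered/critical
separation being tested; the test suite and the bundled analyses scale
down to 300–20,000 samples depending on the precision each check needs.

## The random-network ensemble generator

`randomNetwork()` draws from the N–K ensemble generalized to multi-valued
nodes: exact per-node in-degree $k$ (inputs distinct, self-inputs allowed,
as in the biological models), complete random truth tables with i.i.d.
outputs from a bias distribution, integer-seeded and reproducible. The
generator exists to validate the machinery, and its defaults mirror the
classical calibration: the unbiased Boolean $k = 2$ ensemble has expected
slope $k \cdot 2p(1-p) = 1$, and the test suite checks that the ensemble
mean of the exact slope is ~1 over 100 networks.

What the synthetic ensemble does *not* emulate: the curated models'
structured wiring (chains, phosphatase dominance, dual regulation),
correlated truth tables, or biological level semantics. Passing the
ensemble tests therefore validates the algorithms — enumeration, basins,
Derrida estimation — on arbitrary rule sets, but says nothing further
about the biological fidelity of the curated rules, which rests on the
attractor-pattern and mutant-phenotype checks instead.

## Interfaces

Everything is driven through R functions; `runPipeline()` strings the
stages together (bookkeeping, attractors, scans, switch, criticality) and
writes a CSV bundle plus a claim-by-claim summary marking each result
`match`, `mismatch`, or `flagged-inconsistent`. Models round-trip through
a declarative YAML/JSON format; transition graphs export to DOT/GraphML;
attractor reports to CSV/JSON with format-version headers. All
randomness flows from explicit integer seeds.

## Known limitations

* Only synchronous updating is implemented; asynchronous or
  priority-class semantics can reshape limit cycles (though not fixed
  points).
* The logical functions are reconstructions from functional descriptions,
  not the authors' original truth tables; all quantitative claims
  downstream of the rules (basin sizes, $m$) inherit that uncertainty.
* The full 153-node literature network is handled only as a graph
  (loading and reduction), not dynamically — no rules exist for it.
* The swarmer-vs-stalked variant of the transcriptional cycle (differing
  in SciP/DnaA expression) cannot coexist with the swarmer cycle in a
  single deterministic synchronous model; the package models the single
  4-state cycle and leaves the coupling to proteolysis context open.
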