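---
title: "Selective interventions in Boolean networks: models, encodings and design choices"
author: "BoolIntervene"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selective interventions in Boolean networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BoolIntervene)
```

# The modulation problem

A Boolean network assigns each node a binary state updated by a logical
function of its regulators.  An *intervention* clamps a support set
$S$ of nodes to enforced values $z$, overriding their rules.  The
package answers two questions:

* **single-network modulation** — what is the smallest $S$ whose
  clamping admits a steady state with a chosen target node at a desired
  value $d$?
* **selective modulation** — given two structurally similar networks
  $A$ (pathological) and $B$ (healthy), what is the smallest *shared*
  intervention that forces the target to $d_A$ in $A$ and the opposite
  value $d_B$ in $B$?

Both are encoded as mixed-integer linear programs.  Per node and
network, binary variables $x$ (final value), $\hat x$ (value computed by
the unperturbed logic), a shared perturbation flag $u$, and an enforced
value $z$ are linked by the exact linearisation of
$x = (1-u)\hat x + u z$ (four inequalities).  Each rule is compiled into
a circuit of $k$-ary AND, $k$-ary OR and NOT gates, and each gate is
linearised with the standard exact encodings, so for any fixed $(u, z)$
the feasible $x$ vectors coincide with the steady states of the clamped
network.  The objective is $\min \sum_i u_i$, the number of clamped
nodes.

## Steady-state (fixed-point) semantics

The gate system computes $\hat x_i$ from the parents' *final* values
$x$, not from a separate time layer.  This is the only reading under
which a static constraint system and the synchronous update dynamics
coexist: the feasible states are exactly the fixed points of the clamped
network, which are also precisely the states preserved under any
asynchronous update order.  Two consequences deserve emphasis:

* With feedback loops a clamped network can be multistable, and the
  solver may certify the target value with *any* consistent fixed point.
  This is deliberately permissive: a reported intervention guarantees a
  steady state with the desired target value exists, not that every
  trajectory reaches it.
* Periodic attractors are invisible to the encoding.  A network whose
  only behaviour at some clamping is an oscillation contributes no
  feasible state there.

## Input nodes

Source nodes (no rule) hold whatever value they are given.  In the
programs their $\hat x$ is fixed to a per-node default, 1 ("present")
unless declared otherwise, so the unperturbed reference state is the
"everything available" condition of the bundled case studies; rule files
may override any default (`input n = 0`), and a clamped input follows
its enforced value like any other node.  Names referenced but never
declared are auto-registered as inputs with default 1.

# Coupling the two networks: one intervention, not equal states

A selective instance must say what "the same intervention in both
networks" means.  The package ties the *intervention*: a single $u$
vector, and (by default, `tieZ = TRUE`) a single enforced value per
shared clamped node.  Downstream node states are then free to diverge
between the networks — that divergence *is* the selectivity one is
looking for.

The alternative — coupling the *states* of all shared unperturbed nodes
with $x^A_i - x^B_i \le u_i$, $x^B_i - x^A_i \le u_i$ — is implemented
(`encodeSharedCoupling()`, `coupleShared = TRUE`) but not the default,
for a structural reason: the target itself is shared and must end at
different values, so under a tied enforced value every coupled instance
is infeasible, and with network-specific enforced values the coupled
model's optimum is always the trivial single-node clamp of the target
($z_A = d_A$, $z_B = d_B$).  Neither behaviour describes a physical
intervention applied identically to two cell populations; the tied,
uncoupled default does, and it reproduces the bundled case study's
published behaviour (the one-node inhibitions of `C6`, `C7` or `r3`).
With `tieZ = FALSE` the full per-network variable set is available for
experimentation.

If the target exists in only one network, that network receives the only
target constraint and everything else is unchanged; nodes unique to one
network get a perturbation flag but, naturally, no tie.

# Solving and enumerating

The built-in solver is an exact depth-first branch-and-bound over the
binary variables:

* **Propagation.**  At every node of the search tree, interval
  arithmetic over the constraint rows tightens variable bounds and fixes
  forced binaries (unit propagation); on acyclic networks, fixing
  $(u, z)$ propagates to the entire state without branching.
* **Relaxation.**  When continuous variables are present (the flux
  programs), the LP relaxation — solved with a small dense two-phase
  simplex using Bland's rule — prunes infeasible and dominated subtrees.
  A near-integral relaxation is never accepted as an incumbent, because
  under big-M rows a relaxation can sit within integer tolerance of 0
  while rounding would be infeasible; incumbents arise only at leaves
  with all binaries fixed.
* **Determinism.**  Branching always selects the first unfixed binary in
  declaration order (perturbation flags are declared first) and tries
  the objective-cheaper value first.  The solver is therefore fully
  deterministic; the `seed` in `solverConfig()` is recorded in run logs
  for provenance but cannot change a result.  Enumeration output is
  additionally sorted, so results are reproducible byte for byte.

Alternative optima are enumerated by repeated solves with support-based
no-good cuts, $\sum_{i \in S} u_i - \sum_{i \notin S} u_i \le |S| - 1$,
which remove exactly one support pattern each.  Solutions differing only
in enforced values over the same support are collapsed into one
(carrying the first-found values): the scientific object of interest is
the support family, and keeping $(S, z)$ variants would multiply the
pool without adding clamping choices.  `enumerateRanked()` continues
past the optimum up to a caller-chosen objective cap, and
`subsetScan()` implements the ranked two-list workflow (first
network-A solution contained in a network-B solution).

Support minimality is re-verified by fixing $u_i = 1$ on the candidate
support, **clamping $u_i = 0$ everywhere else**, and re-solving with
each support member (or, with `depth > 1`, each small subset) removed;
any feasible reduced solve disqualifies the candidate.  The outside
clamp is essential — without it a re-solve could substitute fresh nodes
for the removed one and the test would certify nothing.  The empty
support is vacuously minimal.

# Elementary-mode validation

Two notions of "elementary mode" coexist deliberately:

* **Stoichiometric.**  On a species-by-reaction matrix $N$, a mode is a
  nonzero flux $v \ge 0$ with $Nv = 0$ (boundary species exempt) whose
  support is strictly minimal.  The implementation follows the big-M
  programs verbatim: feasibility inside a candidate support fixes the
  activity indicators and tests $Nv = 0$, $0 \le v_j \le M y_j$,
  $\sum v_j \ge \varepsilon_{tot}$; minimality solves
  $\min \sum y_j$ confined to the support and compares the optimum with
  $|S|$.  Defaults $M = 1000$ and $\varepsilon_{tot} = 10^{-3}$ follow
  the usual guidance ($M$ above any attainable flux,
  $\varepsilon_{tot}$ small but clearly nonzero) and are overridable.
  Reversible reactions are split into irreversible pairs before any
  program is built; a $y_f + y_b \le 1$ row excludes futile two-cycles
  whenever the indicators are free, and supports are reported on the
  original reaction names with direction annotations.
* **Boolean activation routes.**  On a Boolean network, the analogue of
  a mode is a support-minimal node set $T$ containing the target whose
  exclusive activation ("$T$ on, everything else off") is a fixed point.
  `booleanActivationRoutes()` enumerates these exhaustively (guarded to
  20 nodes) and always returns an antichain.

The selectivity check accepts a support that is a route of network A and
of no route of network B (set equality on supports).  A failed check
only demotes a solution's flag; it never deletes it, since the flux
formalism is a biological-plausibility lens, not a feasibility
condition.

A brute-force enumerator (`enumerateEMsBruteForce()`, guarded to 15
split reactions) provides the independent reference for the minimality
programs: it scans supports in order of increasing size, skips supersets
of modes already found and futile pairs, and certifies each mode with an
explicit flux witness balancing every non-boundary species to $10^{-9}$.
Scalable mode enumeration (double description, null-space methods) is
out of scope: the machinery here validates candidate supports post hoc,
it does not enumerate genome-scale mode sets.

# Synthetic fixtures

`makeMKMNPair()` returns the bundled reconstruction of the two-network
case study: thirteen shared nodes, network B with one 3-ary OR and three
binary AND gates, network A identical except for the `r3 → C2` feedback
link and the consequent `C2` dependency of `C4`.  The reconstruction is
committed as plain rule files, not code, so the published topology can
be substituted without touching the package; its structure (route
counts, gate census, intervention family) is asserted by computation in
the test suite, never by fiat.  One narrative property of the original —
an inhibition cascade reaching the source input `C6` — is not
reproducible in any rule set in which `C6` is a source node, and is
knowingly left out.

`randomPair()` generates acyclic random networks (random AND/OR gates
over earlier nodes, literals negated with probability 0.25) and derives
the second network by adding or removing an exact number of regulator
edges, one edge per modification, never stripping a node's last
regulator.  Defaults (6–10 nodes, 2–3 inputs, edge density 0.3–0.5, 1–3
edge differences) mirror the scale at which exhaustive state-space
search is still exact, which is what makes the oracle-equivalence suite
possible: across 200 generated pairs the ILP's optimal support families
are compared against exhaustive search over all interventions under
fixed-point semantics, in both single and selective modes.  These
fixtures emulate *structural* similarity (small edge edits between two
circuits sharing all nodes); they do not emulate scale-free topology,
canalising rule bias, node-set asymmetry, or noisy/probabilistic logic —
passing tests therefore certify the optimisation machinery, not
fidelity to any particular biological network class.  Toy
stoichiometric fixtures (chain, two parallel routes, a 3-cycle with
exchanges) carry analytically known mode sets; random 8-reaction models
stress the minimality programs against the brute-force enumerator.

# Numerical choices

* Integer feasibility tolerance $10^{-6}$; constraint propagation
  tolerance $10^{-7}$; simplex pivot tolerance $10^{-9}$; flux-balance
  witnesses verified to $10^{-9}$.
* Problem sizes in the shipped tests: exhaustive truth-table checks up
  to arity 4; oracle equivalence on 200 pairs of ≤ 10 nodes; flux
  minimality agreement on the toys plus 50 random 8-reaction models;
  route enumeration guarded at 20 nodes and $2^{n-1}$ states.  These
  sizes keep every check exact (full enumeration) rather than sampled.
* Ties everywhere are broken lexicographically (variable declaration
  order, sorted supports), so all outputs are stable across runs and
  platforms.

# Limitations

* Only fixed-point semantics: cyclic attractors, basins and transient
  dynamics are out of scope, and on multistable networks a certified
  intervention guarantees existence of the desired steady state, not
  global convergence.
* The objective counts clamped nodes uniformly.  Per-node weights
  (druggability, essentiality) have an obvious hook — objective
  coefficients — but no scoring is implemented.
* One target node per problem; multi-target trade-offs are not encoded.
* The branch-and-bound solver is exact but engineered for the tens-to-
  hundreds-of-binaries regime of the shipped analyses, not for
  genome-scale models; the LP export (`writeLP()`) exists precisely so
  large instances can be handed to an industrial solver.
* SBML-qual import is intentionally not provided; the rule-file dialect
  and JSON serialization are the exchange formats.
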