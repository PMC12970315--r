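# BoolIntervene

Minimal selective interventions in Boolean regulatory networks via
integer linear programming.

## The problem

Pathological cells — a tumour clone, an epileptic focus, a dysregulated
microbial strain — often run *almost* the same regulatory circuits as
their healthy counterparts, differing only in a few rewired links.  An
intervention that simply shuts a target gene down will shut it down
everywhere.  `BoolIntervene` searches for the smallest set of nodes to
clamp (inhibit or activate) so that a chosen target node is forced **off
in the pathological network while staying on in the healthy one** (or
vice versa), exploiting exactly those structural differences.  It is
aimed at computational/systems biologists working with logical models of
signalling or metabolic networks.

## The model

A Boolean network is a directed graph `G(V, F)` whose nodes carry states
`x_i ∈ {0, 1}` updated by rules `x_i(t+1) = f_i(x_i1(t), …, x_ik(t))`.
An intervention clamps a support set `S` of nodes to enforced values
`z`, overriding their logic; the remaining nodes settle into a fixed
point (steady state; fixed points are exactly the states stable under
both synchronous and asynchronous update).

Every rule is compiled to an AND/OR/NOT gate circuit and linearised with
the standard exact encodings over binaries

```
AND:  w = ∧ a_i   ⟹  w ≤ a_i (∀i),  w ≥ Σ a_i − (k−1)
OR:   w = ∨ a_i   ⟹  w ≥ a_i (∀i),  w ≤ Σ a_i
NOT:  w = ¬a      ⟹  w = 1 − a
```

Per node, binary variables `x` (final value), `x̂` (value computed by the
unperturbed logic), `u` (perturbation flag) and `z` (enforced value) are
linked through the exact linearisation of `x = (1−u)·x̂ + u·z`:

```
x − x̂ ≤ u,   x̂ − x ≤ u,   x − z ≤ 1 − u,   z − x ≤ 1 − u
```

For the selective task, one `u` vector (and, by default, one `z` value
per shared node) is shared between the two networks, the two target
constraints `x*_A = d_A`, `x*_B = d_B` with `d_A ≠ d_B` are added, and
the objective is `min Σ u_i` — the fewest clamped nodes.  All optimal
supports are enumerated with no-good exclusion cuts
`Σ_{i∈S} u_i − Σ_{i∉S} u_i ≤ |S| − 1`, each support is re-verified by
single-removal re-solves, and candidates can be validated post hoc
against elementary modes: support-minimal steady-state flux vectors
(`Nv = 0`, `0 ≤ v_j ≤ M·y_j`, `Σ v_j ≥ ε_tot`) of a stoichiometric
model, or their Boolean analogue, minimal activation routes.  An exact
branch-and-bound solver with a dense two-phase simplex for the
continuous flux subproblems is built in; no external solver is needed.

## Worked example

The bundled MKMN case study is a pair of 13-node circuits that share
every node; the pathological network A has one extra feedback link
(r3 → C2).  Target `C9` is on in both networks at rest.

```r
library(BoolIntervene)

pair <- makeMKMNPair()
length(booleanActivationRoutes(netB(pair), "C9"))  # 3 routes to C9 in B
length(booleanActivationRoutes(netA(pair), "C9"))  # 1 route in A

built <- buildSelectiveMILP(pair, selectiveProblem("C9", dA = 0, dB = 1))
sols  <- enumerateOptimalSupports(built$lp, built$index)
for (s in sols) show(s)
```

```
InterventionSolution |S|=1 S={C6} A:{C6=0} B:{C6=0} minimal=unchecked em=unchecked
InterventionSolution |S|=1 S={C7} A:{C7=0} B:{C7=0} minimal=unchecked em=unchecked
InterventionSolution |S|=1 S={r3} A:{r3=0} B:{r3=0} minimal=unchecked em=unchecked
```

Inhibiting any one of `C6`, `C7` or `r3` in *both* circuits kills the
only activation route of network A (C6–C7–r3–C9) while network B keeps
`C9` on through its two alternative routes — a one-node intervention
that is selective purely because of the structural difference.  Each
support passes `verifySupportMinimality()`, and simulating the clamped
networks (`applyIntervention()` + `simulateToFixedPoint()`) confirms
`C9 = 0` in A and `C9 = 1` in B.

The same workflows are scriptable from a shell via the thin wrapper
installed at `system.file("scripts", "bnintervene", package =
"BoolIntervene")` (commands `solve-single`, `solve-selective`,
`validate-em`, `fixtures`; exit codes 0 optimal / 2 input error /
3 infeasible / 4 limit).  Solutions are written as JSON lines
(`support`, `enforced`, `objective`, `verified_minimal`, `em_status`)
and/or a TSV summary with the same fields; models can be exported in the
LP file format with `writeLP()`.

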