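#' @include AllClasses.R linprog.R boolnet-io.R
NULL

#' Linearise a logic gate
#'
#' Emits the linear constraints whose 0/1 feasible set is exactly the
#' gate's truth table: a k-ary AND \eqn{w = \wedge_i a_i} becomes
#' \eqn{w \le a_i} for each input plus \eqn{w \ge \sum_i a_i - (k-1)};
#' a k-ary OR \eqn{w = \vee_i a_i} becomes \eqn{w \ge a_i} for each input
#' plus \eqn{w \le \sum_i a_i}; NOT becomes \eqn{w = 1 - a}; LITERAL is
#' the identity \eqn{w = a}.
#'
#' @param kind \code{"AND"}, \code{"OR"}, \code{"NOT"} or \code{"LITERAL"}.
#' @param outputVar id of the (binary) output variable.
#' @param inputVars character vector of input variable ids (k >= 1 for
#'   AND/OR, exactly 1 for NOT/LITERAL).
#' @return list of constraints, each \code{list(coefs, sense, rhs)}.
#' @export
encodeGate <- function(kind, outputVar, inputVars) {
  k <- length(inputVars)
  if (kind %in% c("NOT", "LITERAL") && k != 1L)
    stop(kind, " gate requires exactly one input", call. = FALSE)
  if (kind %in% c("AND", "OR") && k < 1L)
    stop(kind, " gate requires at least one input", call. = FALSE)
  w <- outputVar
  switch(kind,
    AND = c(
      lapply(inputVars, function(a)
        list(coefs = stats::setNames(c(1, -1), c(w, a)), sense = "<=", rhs = 0)),
      list(list(coefs = stats::setNames(c(1, rep(-1, k)), c(w, inputVars)),
                sense = ">=", rhs = -(k - 1)))),
    OR = c(
      lapply(inputVars, function(a)
        list(coefs = stats::setNames(c(1, -1), c(w, a)), sense = ">=", rhs = 0)),
      list(list(coefs = stats::setNames(c(1, rep(-1, k)), c(w, inputVars)),
                sense = "<=", rhs = 0))),
    NOT = list(list(coefs = stats::setNames(c(1, 1), c(w, inputVars)),
                    sense = "=", rhs = 1)),
    LITERAL = list(list(coefs = stats::setNames(c(1, -1), c(w, inputVars)),
                        sense = "=", rhs = 0)),
    stop("unknown gate kind: ", kind, call. = FALSE))
}

#' Linearise the perturbation linkage
#'
#' The exact linearisation of \eqn{x = (1-u)\hat x + u z} for binary
#' variables: four inequalities that force \eqn{x = \hat x} when
#' \eqn{u = 0} and \eqn{x = z} when \eqn{u = 1}.
#'
#' @param x,xhat,u,z variable ids (all binary): the final value, the value
#'   computed by the unperturbed logic, the perturbation flag, and the
#'   enforced value.
#' @return list of 4 constraints.
#' @export
encodePerturbationLinkage <- function(x, xhat, u, z) {
  sn <- stats::setNames
  list(
    list(coefs = sn(c(1, -1, -1), c(x, xhat, u)), sense = "<=", rhs = 0),
    list(coefs = sn(c(1, -1, -1), c(xhat, x, u)), sense = "<=", rhs = 0),
    list(coefs = sn(c(1, -1, 1), c(x, z, u)), sense = "<=", rhs = 1),
    list(coefs = sn(c(1, -1, 1), c(z, x, u)), sense = "<=", rhs = 1))
}

#' Linearise the shared-node coupling
#'
#' Two inequalities forcing a shared node's final values to coincide
#' across the two networks whenever it is not perturbed:
#' \eqn{x^A - x^B \le u} and \eqn{x^B - x^A \le u}.  With \eqn{u = 1}
#' they place no restriction beyond the variable bounds.  Note that
#' applying these rows to every shared node makes any selective instance
#' with a tied enforced value infeasible (the target itself must differ),
#' which is why [buildSelectiveMILP()] leaves them out unless asked.
#'
#' @param xA,xB,u variable ids (binary).
#' @return list of 2 constraints.
#' @export
encodeSharedCoupling <- function(xA, xB, u) {
  sn <- stats::setNames
  list(
    list(coefs = sn(c(1, -1, -1), c(xA, xB, u)), sense = "<=", rhs = 0),
    list(coefs = sn(c(1, -1, -1), c(xB, xA, u)), sense = "<=", rhs = 0))
}

## ---- problem specs -----------------------------------------------------

#' Specify a single-network modulation problem
#' @param target target node name.
#' @param d desired value (0 or 1).
#' @return a [ProblemSpec-class] with mode \code{"single"}.
#' @export
singleProblem <- function(target, d)
  new("ProblemSpec", target = target,
      desired = c(A = as.integer(d)), mode = "single", tieZ = TRUE)

#' Specify a selective (two-network) modulation problem
#' @param target target node name.
#' @param dA,dB desired values in networks A and B; must differ.
#' @param tieZ if TRUE (default), a perturbed shared node is clamped to the
#'   same enforced value in both networks — the intervention is one
#'   physical action.  FALSE reproduces the formulation with
#'   network-specific enforced values, under which clamping the target
#'   alone is always a (trivial) solution.
#' @return a [ProblemSpec-class] with mode \code{"selective"}.
#' @export
selectiveProblem <- function(target, dA, dB, tieZ = TRUE)
  new("ProblemSpec", target = target,
      desired = c(A = as.integer(dA), B = as.integer(dB)),
      mode = "selective", tieZ = tieZ)

## ---- network encoding --------------------------------------------------

## Variable naming is deterministic: {net}.{node}.{role} for per-network
## variables, u.{node} for the shared perturbation flags, {net}.{node}.g#
## for gate auxiliaries.  Models are therefore reproducible byte-for-byte.
varX <- function(tag, node) paste(tag, node, "x", sep = ".")
varXhat <- function(tag, node) paste(tag, node, "xhat", sep = ".")
varZ <- function(tag, node) paste(tag, node, "z", sep = ".")
varU <- function(node) paste("u", node, sep = ".")

## Encode one network's logic plus perturbation linkage onto a builder.
## The gate system computes xhat_i from the *final* x values of the
## parents, so for fixed (u, z) the feasible x vectors are exactly the
## fixed points of the perturbed network.
encodeNetwork <- function(b, net, tag) {
  nodes <- net@nodes
  gateMap <- character(0)
  for (nm in nodes) {
    lpAddVar(b, varX(tag, nm))
    lpAddVar(b, varZ(tag, nm))
    if (nm %in% net@inputs) {
      d <- net@inputDefaults[[nm]]
      lpAddVar(b, varXhat(tag, nm), lb = d, ub = d)
    } else {
      lpAddVar(b, varXhat(tag, nm))
    }
  }
  for (nm in names(net@rules)) {
    circ <- net@rules[[nm]]
    ref2var <- stats::setNames(varX(tag, nodes), nodes)
    for (g in circ$gates) {
      vid <- if (g$id == circ$output) varXhat(tag, nm)
             else paste(tag, nm, g$id, sep = ".")
      if (g$id != circ$output) {
        if (g$kind == "CONST") lpAddVar(b, vid, lb = g$value, ub = g$value)
        else lpAddVar(b, vid)
        gateMap[paste(nm, g$id, sep = ".")] <- vid
      }
      if (g$kind == "CONST") {
        if (g$id == circ$output)
          lpAddConstr(b, stats::setNames(1, vid), "=", g$value)
      } else {
        for (cn in encodeGate(g$kind, vid, unname(ref2var[g$inputs])))
          lpAddConstr(b, cn$coefs, cn$sense, cn$rhs)
      }
      ref2var[g$id] <- vid
    }
  }
  for (nm in nodes)
    for (cn in encodePerturbationLinkage(varX(tag, nm), varXhat(tag, nm),
                                         varU(nm), varZ(tag, nm)))
      lpAddConstr(b, cn$coefs, cn$sense, cn$rhs)
  gateMap
}

makeIndex <- function(tags, nets, gateMaps) {
  idx <- list(tags = tags,
              x = list(), xhat = list(), z = list(), gate = list(),
              u = character(0))
  allNodes <- character(0)
  for (i in seq_along(tags)) {
    tag <- tags[i]; net <- nets[[i]]
    idx$x[[tag]] <- stats::setNames(varX(tag, net@nodes), net@nodes)
    idx$xhat[[tag]] <- stats::setNames(varXhat(tag, net@nodes),
                                       setdiff(net@nodes, character(0)))
    idx$z[[tag]] <- stats::setNames(varZ(tag, net@nodes), net@nodes)
    idx$gate[[tag]] <- gateMaps[[i]]
    allNodes <- union(allNodes, net@nodes)
  }
  idx$u <- stats::setNames(varU(allNodes), allNodes)
  class(idx) <- "EncodingIndex"
  idx
}

#' Build the single-network modulation MILP
#'
#' Declares per-node final values x, unperturbed logic values \eqn{\hat x},
#' perturbation flags u, enforced values z and gate auxiliaries; encodes
#' every rule's gate circuit onto \eqn{\hat x} with gate inputs read from
#' the parents' final x values; links x, \eqn{\hat x}, u, z through the
#' perturbation linkage; fixes input nodes' \eqn{\hat x} to their defaults;
#' adds the target constraint \eqn{x_{target} = d}; and minimises
#' \eqn{\sum_i u_i}.  For any fixed (u, z) the feasible x vectors are
#' exactly the fixed points of the perturbed network, so with feedback
#' loops the solver may select any consistent steady state.
#'
#' @param net a [BooleanNetwork-class].
#' @param spec a [ProblemSpec-class] with mode \code{"single"} (see
#'   [singleProblem()]).
#' @return list with elements \code{lp} ([LinearProgram-class]) and
#'   \code{index} (the variable-name index).
#' @export
buildSingleTargetMILP <- function(net, spec) {
  stopifnot(is(spec, "ProblemSpec"))
  if (spec@mode != "single") stop("spec mode must be 'single'", call. = FALSE)
  if (!spec@target %in% net@nodes)
    stop("target node '", spec@target, "' not in network", call. = FALSE)
  b <- lpBuilder()
  for (nm in net@nodes) lpAddVar(b, varU(nm))     # u first: branch priority
  gm <- encodeNetwork(b, net, "A")
  lpAddConstr(b, stats::setNames(1, varX("A", spec@target)), "=",
              spec@desired[["A"]])
  lpSetObjective(b, stats::setNames(rep(1, length(net@nodes)),
                                    varU(net@nodes)), "min")
  list(lp = lpBuild(b), index = makeIndex("A", list(net), list(gm)))
}

#' Build the selective (two-network) modulation MILP
#'
#' One perturbation flag u per node of the union node set; per-network
#' final values, logic values, enforced values and gate systems; the
#' perturbation linkage in both networks; the two target constraints
#' \eqn{x^A_{target} = d_A}, \eqn{x^B_{target} = d_B}; and the objective
#' \eqn{\min \sum_i u_i}.  With \code{tieZ} (the default) the enforced
#' values of perturbed shared nodes are equated across networks, so one
#' physical intervention acts identically on both circuits and selectivity
#' can only arise from their structural difference.  If the target is
#' present in only one network, the other network simply receives no
#' target constraint.
#'
#' @param pair a [NetworkPair-class].
#' @param spec a [ProblemSpec-class] with mode \code{"selective"} (see
#'   [selectiveProblem()]).
#' @param coupleShared if TRUE, additionally add the shared-node coupling
#'   rows of [encodeSharedCoupling()] for every shared node.  Off by
#'   default: with a tied enforced value those rows make every instance
#'   infeasible (the target must differ while coupled), and with free
#'   enforced values they make clamping the target alone the trivial
#'   optimum.
#' @return list with elements \code{lp} and \code{index}.
#' @export
buildSelectiveMILP <- function(pair, spec, coupleShared = FALSE) {
  stopifnot(is(pair, "NetworkPair"), is(spec, "ProblemSpec"))
  if (spec@mode != "selective")
    stop("spec mode must be 'selective'", call. = FALSE)
  a <- pair@netA; bnet <- pair@netB
  inA <- spec@target %in% a@nodes
  inB <- spec@target %in% bnet@nodes
  if (!inA && !inB)
    stop("target node '", spec@target, "' absent from both networks",
         call. = FALSE)
  allNodes <- union(a@nodes, bnet@nodes)
  b <- lpBuilder()
  for (nm in allNodes) lpAddVar(b, varU(nm))
  gmA <- encodeNetwork(b, a, "A")
  gmB <- encodeNetwork(b, bnet, "B")
  if (spec@tieZ)
    for (nm in pair@shared)
      lpAddConstr(b, stats::setNames(c(1, -1), c(varZ("A", nm), varZ("B", nm))),
                  "=", 0)
  if (coupleShared)
    for (nm in pair@shared)
      for (cn in encodeSharedCoupling(varX("A", nm), varX("B", nm), varU(nm)))
        lpAddConstr(b, cn$coefs, cn$sense, cn$rhs)
  if (inA)
    lpAddConstr(b, stats::setNames(1, varX("A", spec@target)), "=",
                spec@desired[["A"]])
  if (inB)
    lpAddConstr(b, stats::setNames(1, varX("B", spec@target)), "=",
                spec@desired[["B"]])
  lpSetObjective(b, stats::setNames(rep(1, length(allNodes)),
                                    varU(allNodes)), "min")
  list(lp = lpBuild(b),
       index = makeIndex(c("A", "B"), list(a, bnet), list(gmA, gmB)))
}
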