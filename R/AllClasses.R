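#' @import methods
NULL

#' Boolean regulatory network
#'
#' An immutable container for a Boolean network: an ordered node set, one
#' gate circuit per regulated node, and a set of input (source) nodes with
#' default values.  Gate circuits are ordered lists of AND/OR/NOT/LITERAL
#' gates whose inputs refer to declared nodes or to earlier gates in the
#' same circuit, so every circuit is acyclic by construction; cycles in the
#' network itself (node-to-node feedback) are allowed.
#'
#' @slot nodes character vector of node names, in declaration order.
#' @slot rules named list (one entry per non-input node) of gate circuits;
#'   each circuit is a list with elements \code{gates} (list of
#'   \code{list(id, kind, inputs, value)}) and \code{output} (the id of the
#'   gate computing the node's next value).
#' @slot inputs character vector of input node names (nodes without rules).
#' @slot inputDefaults named integer vector (0/1) over \code{inputs}; the
#'   value an input takes when it is not perturbed.
#'
#' @seealso [parseRules()], [synchronousStep()], [sharedNodes()]
#' @export
setClass("BooleanNetwork",
  representation(
    nodes         = "character",
    rules         = "list",
    inputs        = "character",
    inputDefaults = "integer"
  )
)

setValidity("BooleanNetwork", function(object) {
  msgs <- character(0)
  nodes <- object@nodes
  if (length(nodes) == 0L) msgs <- c(msgs, "network has no nodes")
  if (anyDuplicated(nodes)) msgs <- c(msgs, "duplicated node names")
  regulated <- setdiff(nodes, object@inputs)
  if (!setequal(names(object@rules), regulated))
    msgs <- c(msgs, "every non-input node must have exactly one rule")
  if (!setequal(names(object@inputDefaults), object@inputs))
    msgs <- c(msgs, "inputDefaults must cover exactly the input nodes")
  if (length(object@inputDefaults) &&
      !all(object@inputDefaults %in% c(0L, 1L)))
    msgs <- c(msgs, "input defaults must be 0 or 1")
  for (nm in names(object@rules)) {
    circ <- object@rules[[nm]]
    seen <- character(0)
    for (g in circ$gates) {
      k <- length(g$inputs)
      if (g$kind == "NOT" && k != 1L)
        msgs <- c(msgs, sprintf("NOT gate in rule for '%s' must have 1 input", nm))
      if (g$kind %in% c("AND", "OR") && k < 1L)
        msgs <- c(msgs, sprintf("%s gate in rule for '%s' needs >= 1 input", g$kind, nm))
      if (g$kind == "LITERAL" && k != 1L)
        msgs <- c(msgs, sprintf("LITERAL gate in rule for '%s' must have 1 input", nm))
      bad <- setdiff(g$inputs, c(nodes, seen))
      if (length(bad))
        msgs <- c(msgs, sprintf("rule for '%s' references unknown '%s'", nm, bad[1]))
      seen <- c(seen, g$id)
    }
    if (!circ$output %in% seen)
      msgs <- c(msgs, sprintf("rule for '%s' has no output gate", nm))
  }
  if (length(msgs)) msgs else TRUE
})

#' A pair of structurally similar Boolean networks
#'
#' Bundles a "pathological" network A and a "healthy" network B together
#' with their shared node set.  The shared set is always recomputed as the
#' exact intersection of the two node name sets; it is never user-supplied.
#'
#' @slot netA,netB [BooleanNetwork-class] objects.
#' @slot shared character vector, the intersection of the node sets.
#' @export
setClass("NetworkPair",
  representation(netA = "BooleanNetwork", netB = "BooleanNetwork",
                 shared = "character")
)

setValidity("NetworkPair", function(object) {
  want <- intersect(object@netA@nodes, object@netB@nodes)
  if (!identical(sort(object@shared), sort(want)))
    "shared must equal the computed intersection of node sets" else TRUE
})

#' Solver-agnostic mixed-integer linear program
#'
#' The package's central intermediate representation: a list of bounded
#' variables (binary or continuous), linear constraints in sparse triplet
#' form, and a linear objective.  All Boolean-network encodings and the
#' stoichiometric steady-state programs are expressed as this class and
#' solved by [milpSolve()].
#'
#' @slot varIds character vector of variable identifiers.
#' @slot lb,ub numeric bounds per variable.
#' @slot isInt logical per variable; integer variables must be binary
#'   (bounds within \[0, 1\]).
#' @slot constrMat list of numeric coefficient vectors named by variable id,
#'   one per constraint.
#' @slot sense character per constraint, one of \code{"<="}, \code{"="},
#'   \code{">="}.
#' @slot rhs numeric per constraint.
#' @slot objective named numeric vector of objective coefficients (variables
#'   not named have coefficient zero).
#' @slot direction \code{"min"} or \code{"max"}.
#' @export
setClass("LinearProgram",
  representation(
    varIds    = "character",
    lb        = "numeric",
    ub        = "numeric",
    isInt     = "logical",
    constrMat = "list",
    sense     = "character",
    rhs       = "numeric",
    objective = "numeric",
    direction = "character"
  ),
  prototype(direction = "min", objective = numeric(0))
)

setValidity("LinearProgram", function(object) {
  msgs <- character(0)
  n <- length(object@varIds)
  if (anyDuplicated(object@varIds)) msgs <- c(msgs, "duplicated variable ids")
  if (length(object@lb) != n || length(object@ub) != n || length(object@isInt) != n)
    msgs <- c(msgs, "bounds and integrality must match the variable list")
  if (any(object@lb > object@ub + 1e-9)) msgs <- c(msgs, "lb > ub for some variable")
  if (any(object@isInt & (object@lb < -1e-9 | object@ub > 1 + 1e-9)))
    msgs <- c(msgs, "integer variables must be binary with bounds in [0,1]")
  m <- length(object@constrMat)
  if (length(object@sense) != m || length(object@rhs) != m)
    msgs <- c(msgs, "sense/rhs must match the constraint list")
  if (m && !all(object@sense %in% c("<=", "=", ">=")))
    msgs <- c(msgs, "constraint sense must be <=, = or >=")
  known <- object@varIds
  for (cf in object@constrMat)
    if (length(cf) && !all(names(cf) %in% known)) {
      msgs <- c(msgs, "constraint references an undeclared variable")
      break
    }
  if (length(object@objective) && !all(names(object@objective) %in% known))
    msgs <- c(msgs, "objective references an undeclared variable")
  if (!object@direction %in% c("min", "max"))
    msgs <- c(msgs, "direction must be 'min' or 'max'")
  if (length(msgs)) msgs else TRUE
})

#' Stoichiometric model
#'
#' Species-by-reaction stoichiometric matrix with per-reaction
#' irreversibility flags and an optional set of boundary (unbalanced)
#' species, used by the elementary-mode validation machinery.
#'
#' @slot species character, row names of \code{N}.
#' @slot reactions character, column names of \code{N}.
#' @slot N numeric matrix of stoichiometric coefficients (rows species,
#'   columns reactions).
#' @slot irreversible logical per reaction; reversible reactions are split
#'   into forward/backward irreversible pairs before any program is built.
#' @slot boundary character subset of \code{species} exempt from the
#'   steady-state balance.
#' @export
setClass("StoichiometricModel",
  representation(species = "character", reactions = "character",
                 N = "matrix", irreversible = "logical",
                 boundary = "character")
)

setValidity("StoichiometricModel", function(object) {
  msgs <- character(0)
  if (!identical(dim(object@N),
                 c(length(object@species), length(object@reactions))))
    msgs <- c(msgs, "N dimensions must match species x reactions")
  if (length(object@irreversible) != length(object@reactions))
    msgs <- c(msgs, "one irreversibility flag per reaction required")
  if (length(object@boundary) && !all(object@boundary %in% object@species))
    msgs <- c(msgs, "boundary species must be declared species")
  if (anyDuplicated(object@reactions)) msgs <- c(msgs, "duplicated reaction names")
  if (anyDuplicated(object@species)) msgs <- c(msgs, "duplicated species names")
  if (length(msgs)) msgs else TRUE
})

#' Intervention problem specification
#'
#' Names the target node and the desired post-intervention value(s).  In
#' \code{"selective"} mode the two desired values must differ; in
#' \code{"single"} mode only the value for network A is used.
#'
#' @slot target character(1), the target node.
#' @slot desired named integer vector with entries \code{A} and/or \code{B}
#'   in \{0, 1\}.
#' @slot mode \code{"single"} or \code{"selective"}.
#' @slot tieZ logical; if TRUE (default) a perturbed shared node is clamped
#'   to the same enforced value in both networks (one physical action).
#' @export
setClass("ProblemSpec",
  representation(target = "character", desired = "integer",
                 mode = "character", tieZ = "logical")
)

setValidity("ProblemSpec", function(object) {
  msgs <- character(0)
  if (length(object@target) != 1L) msgs <- c(msgs, "exactly one target node")
  if (!object@mode %in% c("single", "selective"))
    msgs <- c(msgs, "mode must be 'single' or 'selective'")
  if (!all(object@desired %in% c(0L, 1L)))
    msgs <- c(msgs, "desired values must be 0 or 1")
  if (object@mode == "selective") {
    if (!all(c("A", "B") %in% names(object@desired)))
      msgs <- c(msgs, "selective mode needs desired values for A and B")
    else if (object@desired[["A"]] == object@desired[["B"]])
      msgs <- c(msgs, "selective mode requires d_A != d_B")
  } else {
    if (!"A" %in% names(object@desired))
      msgs <- c(msgs, "single mode needs a desired value for A")
  }
  if (length(msgs)) msgs else TRUE
})

#' One intervention solution
#'
#' A candidate intervention: the support S (perturbed nodes), the enforced
#' values z per network on S, the objective |S|, and verification flags
#' filled in by the minimality and elementary-mode checks.
#'
#' @slot support character vector of perturbed node names (sorted).
#' @slot enforced named list with entries per network tag; each a named
#'   integer vector of enforced values over \code{support} (restricted to
#'   the nodes present in that network).
#' @slot objective integer, equals \code{length(support)}.
#' @slot verifiedMinimal logical(1) or NA (unchecked).
#' @slot emStatus character(1): \code{"em_in_A_only"}, \code{"other"} or
#'   \code{"unchecked"}.
#' @export
setClass("InterventionSolution",
  representation(support = "character", enforced = "list",
                 objective = "integer", verifiedMinimal = "logical",
                 emStatus = "character")
)

setValidity("InterventionSolution", function(object) {
  msgs <- character(0)
  if (object@objective != length(object@support))
    msgs <- c(msgs, "objective must equal |support|")
  for (tag in names(object@enforced)) {
    z <- object@enforced[[tag]]
    if (!all(names(z) %in% object@support))
      msgs <- c(msgs, "enforced values must be defined on support nodes only")
    if (length(z) && !all(z %in% c(0L, 1L)))
      msgs <- c(msgs, "enforced values must be 0 or 1")
  }
  if (!object@emStatus %in% c("em_in_A_only", "other", "unchecked"))
    msgs <- c(msgs, "invalid emStatus")
  if (length(msgs)) msgs else TRUE
})
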