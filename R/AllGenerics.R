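#' @include AllClasses.R
NULL

#' Node names of a network
#' @param x a [BooleanNetwork-class] or [NetworkPair-class].
#' @return character vector of node names.
#' @export
setGeneric("nodeNames", function(x) standardGeneric("nodeNames"))

#' Input (source) nodes of a network
#' @param x a [BooleanNetwork-class].
#' @return character vector of input node names.
#' @export
setGeneric("inputNodes", function(x) standardGeneric("inputNodes"))

#' Default values of the input nodes
#' @param x a [BooleanNetwork-class].
#' @return named integer vector of 0/1 defaults.
#' @export
setGeneric("inputDefaults", function(x) standardGeneric("inputDefaults"))

#' Update rules of a network
#' @param x a [BooleanNetwork-class].
#' @return named list of gate circuits, one per regulated node.
#' @export
setGeneric("networkRules", function(x) standardGeneric("networkRules"))

#' @rdname nodeNames
#' @export
setMethod("nodeNames", "BooleanNetwork", function(x) x@nodes)

#' @rdname nodeNames
#' @export
setMethod("nodeNames", "NetworkPair",
          function(x) union(x@netA@nodes, x@netB@nodes))

#' @rdname inputNodes
#' @export
setMethod("inputNodes", "BooleanNetwork", function(x) x@inputs)

#' @rdname inputDefaults
#' @export
setMethod("inputDefaults", "BooleanNetwork", function(x) x@inputDefaults)

#' @rdname networkRules
#' @export
setMethod("networkRules", "BooleanNetwork", function(x) x@rules)

#' Networks of a pair
#' @param x a [NetworkPair-class].
#' @return the requested [BooleanNetwork-class].
#' @export
setGeneric("netA", function(x) standardGeneric("netA"))

#' @rdname netA
#' @export
setGeneric("netB", function(x) standardGeneric("netB"))

#' @rdname netA
#' @export
setMethod("netA", "NetworkPair", function(x) x@netA)

#' @rdname netA
#' @export
setMethod("netB", "NetworkPair", function(x) x@netB)

setMethod("show", "BooleanNetwork", function(object) {
  cat("BooleanNetwork with", length(object@nodes), "nodes (",
      length(object@inputs), "inputs )\n")
  census <- gateCensus(object)
  cat("  gates:", paste(names(census), census, sep = "=", collapse = " "), "\n")
  cat("  nodes:", paste(utils::head(object@nodes, 10), collapse = ", "),
      if (length(object@nodes) > 10) "...", "\n")
})

setMethod("show", "NetworkPair", function(object) {
  cat("NetworkPair: A has", length(object@netA@nodes), "nodes, B has",
      length(object@netB@nodes), "nodes;", length(object@shared), "shared\n")
})

setMethod("show", "LinearProgram", function(object) {
  cat("LinearProgram:", length(object@varIds), "variables (",
      sum(object@isInt), "binary ),", length(object@constrMat),
      "constraints,", object@direction, "objective\n")
})

setMethod("show", "StoichiometricModel", function(object) {
  cat("StoichiometricModel:", length(object@species), "species x",
      length(object@reactions), "reactions;",
      sum(!object@irreversible), "reversible;",
      length(object@boundary), "boundary species\n")
})

setMethod("show", "InterventionSolution", function(object) {
  zTxt <- vapply(names(object@enforced), function(tag) {
    z <- object@enforced[[tag]]
    if (!length(z)) return(sprintf("%s:-", tag))
    sprintf("%s:{%s}", tag, paste(names(z), z, sep = "=", collapse = ","))
  }, character(1))
  cat(sprintf("InterventionSolution |S|=%d S={%s} %s minimal=%s em=%s\n",
              object@objective, paste(object@support, collapse = ","),
              paste(zTxt, collapse = " "),
              ifelse(is.na(object@verifiedMinimal), "unchecked",
                     object@verifiedMinimal),
              object@emStatus))
})

setMethod("show", "ProblemSpec", function(object) {
  cat(sprintf("ProblemSpec: mode=%s target=%s desired={%s} tieZ=%s\n",
              object@mode, object@target,
              paste(names(object@desired), object@desired,
                    sep = "=", collapse = ","),
              object@tieZ))
})
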