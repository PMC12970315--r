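#' @include AllClasses.R solver.R encode.R
NULL

## Extract an InterventionSolution from solver values.
solutionFromValues <- function(values, index, config) {
  uVals <- values[index$u]
  support <- sort(names(index$u)[uVals > 0.5])
  enforced <- list()
  for (tag in index$tags) {
    here <- intersect(support, names(index$z[[tag]]))
    enforced[[tag]] <- stats::setNames(
      as.integer(round(values[index$z[[tag]][here]])), here)
  }
  new("InterventionSolution", support = support, enforced = enforced,
      objective = length(support), verifiedMinimal = NA, emStatus = "unchecked")
}

## The support-based no-good cut: excludes exactly the support S
## (sum_{i in S} u_i - sum_{i not in S} u_i <= |S| - 1).
exclusionCut <- function(index, support) {
  uAll <- index$u
  coefs <- stats::setNames(ifelse(names(uAll) %in% support, 1, -1),
                           unname(uAll))
  list(coefs = coefs, sense = "<=", rhs = length(support) - 1)
}

#' Enumerate all optimal intervention supports
#'
#' Repeatedly solves the program; after each incumbent with support S adds
#' the exclusion cut \eqn{\sum_{i \in S} u_i - \sum_{i \notin S} u_i \le
#' |S| - 1}, which removes exactly that support, and stops as soon as the
#' objective rises above the first optimum (or the program becomes
#' infeasible).  Solutions that differ only in their enforced values over
#' the same support are collapsed into one, carrying the first-found
#' enforced values.
#'
#' @param lp a [LinearProgram-class] with the \eqn{\min \sum u} objective.
#' @param index the encoding index returned by the builder.
#' @param limit maximum number of solutions to collect (default 10000);
#'   when exceeded the partial list is returned with attribute
#'   \code{truncated = TRUE}.
#' @param config solver configuration, see [solverConfig()].
#' @return list of [InterventionSolution-class], sorted lexicographically
#'   by support.
#' @export
enumerateOptimalSupports <- function(lp, index, limit = 10000,
                                     config = solverConfig()) {
  out <- list()
  optimum <- NULL
  truncated <- FALSE
  repeat {
    res <- milpSolve(lp, config)
    if (res$status != "optimal") break
    if (is.null(optimum)) optimum <- round(res$objective)
    if (round(res$objective) > optimum) break
    sol <- solutionFromValues(res$values, index, config)
    out[[length(out) + 1L]] <- sol
    if (length(out) >= limit) { truncated <- TRUE; break }
    cut <- exclusionCut(index, sol@support)
    lp <- lpAddConstraint(lp, cut$coefs, cut$sense, cut$rhs)
  }
  out <- out[order(vapply(out, function(s)
    paste(s@support, collapse = "\r"), character(1)))]
  attr(out, "truncated") <- truncated
  attr(out, "optimum") <- optimum
  out
}

#' Enumerate ranked solutions up to a maximum objective
#'
#' Continues the exclusion-cut enumeration past the optimum, collecting
#' every support whose objective does not exceed \code{maxObjective}.
#'
#' @inheritParams enumerateOptimalSupports
#' @param maxObjective largest objective value (support size) to include.
#' @return list of [InterventionSolution-class], sorted by (objective,
#'   lexicographic support).
#' @export
enumerateRanked <- function(lp, index, maxObjective, limit = 10000,
                            config = solverConfig()) {
  out <- list()
  truncated <- FALSE
  repeat {
    res <- milpSolve(lp, config)
    if (res$status != "optimal") break
    if (round(res$objective) > maxObjective) break
    sol <- solutionFromValues(res$values, index, config)
    out[[length(out) + 1L]] <- sol
    if (length(out) >= limit) { truncated <- TRUE; break }
    cut <- exclusionCut(index, sol@support)
    lp <- lpAddConstraint(lp, cut$coefs, cut$sense, cut$rhs)
  }
  out <- out[order(vapply(out, function(s) s@objective, integer(1)),
                   vapply(out, function(s)
                     paste(s@support, collapse = "\r"), character(1)))]
  attr(out, "truncated") <- truncated
  out
}

#' Scan ranked solution lists for a subset pair
#'
#' The subset-scan workflow: walk the network-A solutions in order of
#' objective value and return the first whose support is contained in
#' (or equal to) the support of some network-B solution.
#'
#' @param solutionsA,solutionsB lists of [InterventionSolution-class],
#'   sorted by objective (as produced by [enumerateRanked()]).
#' @return the matching A-solution with attribute \code{matchedSupportB}
#'   (the containing B support), or NULL if no pair exists.
#' @export
subsetScan <- function(solutionsA, solutionsB) {
  ordA <- order(vapply(solutionsA, function(s) s@objective, integer(1)))
  for (i in ordA) {
    sa <- solutionsA[[i]]
    for (sb in solutionsB) {
      if (all(sa@support %in% sb@support)) {
        attr(sa, "matchedSupportB") <- sb@support
        return(sa)
      }
    }
  }
  NULL
}
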