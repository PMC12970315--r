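#' @include AllClasses.R solver.R enumerate.R
NULL

#' Verify that an intervention support is minimal
#'
#' The pure-Boolean minimality test: fix \eqn{u_i = 1} for every node of
#' the candidate support S and \eqn{u_i = 0} for every node outside S,
#' then for each removal subset R (single nodes by default) attempt to
#' re-solve with \eqn{u_j = 0} for \eqn{j \in R}.  If any reduced problem
#' is feasible the support is not minimal.  Clamping the flags outside S
#' to zero is essential: without it a re-solve could substitute fresh
#' nodes for the removed one and the test would never certify anything.
#' The empty support is vacuously minimal.
#'
#' @param lp the [LinearProgram-class] the support solves (without
#'   exclusion cuts).
#' @param index the encoding index of the program.
#' @param support character vector of perturbed node names.
#' @param depth largest removal-subset size to try (default 1, the
#'   single-element-removal test; larger values give stricter minimality).
#' @param config solver configuration, see [solverConfig()].
#' @return logical(1): TRUE iff no removal of up to \code{depth} elements
#'   leaves the target constraints satisfiable.
#' @export
verifySupportMinimality <- function(lp, index, support, depth = 1L,
                                    config = solverConfig()) {
  if (!length(support)) return(TRUE)
  stopifnot(all(support %in% names(index$u)))
  base <- lp
  for (nm in names(index$u))
    base <- lpFixVar(base, index$u[[nm]], as.numeric(nm %in% support))
  for (k in seq_len(min(depth, length(support)))) {
    removals <- utils::combn(support, k, simplify = FALSE)
    for (R in removals) {
      reduced <- base
      for (nm in R) reduced <- lpFixVar(reduced, index$u[[nm]], 0)
      res <- milpSolve(reduced, config)
      if (res$status == "optimal") return(FALSE)
      if (res$status == "feasible-limit")
        stop("solver node limit hit during minimality check", call. = FALSE)
    }
  }
  TRUE
}
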