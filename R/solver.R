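#' @include AllClasses.R linprog.R
NULL

#' Default solver configuration
#'
#' @param seed integer; recorded for reproducibility of the run log.  The
#'   bundled branch-and-bound solver is fully deterministic, so the seed
#'   never changes a result, but it is threaded through so that runs are
#'   reproducible byte-for-byte including their logs.
#' @param intTol integer feasibility tolerance (default 1e-6).
#' @param nodeLimit branch-and-bound node cap; when hit, the incumbent (if
#'   any) is returned with status \code{"feasible-limit"}.
#' @return a named list of solver settings.
#' @export
solverConfig <- function(seed = 0L, intTol = 1e-6, nodeLimit = 2e6) {
  list(seed = as.integer(seed), intTol = intTol, nodeLimit = nodeLimit)
}

## Normalise a LinearProgram into <=-only triplet form for the solver.
normalizeLP <- function(lp) {
  idx <- stats::setNames(seq_along(lp@varIds), lp@varIds)
  ci <- integer(0); vi <- integer(0); av <- numeric(0)
  rhs <- numeric(0)
  k <- 0L
  for (i in seq_along(lp@constrMat)) {
    cf <- lp@constrMat[[i]]
    v <- unname(idx[names(cf)])
    a <- unname(cf)
    s <- lp@sense[i]
    if (s %in% c("<=", "=")) {
      k <- k + 1L
      ci <- c(ci, rep(k, length(a))); vi <- c(vi, v); av <- c(av, a)
      rhs <- c(rhs, lp@rhs[i])
    }
    if (s %in% c(">=", "=")) {
      k <- k + 1L
      ci <- c(ci, rep(k, length(a))); vi <- c(vi, v); av <- c(av, -a)
      rhs <- c(rhs, -lp@rhs[i])
    }
  }
  obj <- numeric(length(lp@varIds))
  if (length(lp@objective)) obj[idx[names(lp@objective)]] <- lp@objective
  flip <- lp@direction == "max"
  if (flip) obj <- -obj
  list(ci = ci, vi = vi, av = av, rhs = rhs, m = k, obj = obj, flip = flip,
       nVar = length(lp@varIds))
}

## Interval-arithmetic constraint propagation on <=-form triplets.
## Returns list(lb, ub, feasible); tightens binary and continuous bounds.
propagateBounds <- function(nf, lb, ub, intMask, tol = 1e-7) {
  if (nf$m == 0L) return(list(lb = lb, ub = ub, feasible = TRUE))
  ci <- nf$ci; vi <- nf$vi; av <- nf$av
  pos <- av > 0
  repeat {
    contrib <- ifelse(pos, av * lb[vi], av * ub[vi])
    minLHS <- numeric(nf$m)
    sums <- rowsum(contrib, ci)
    minLHS[as.integer(rownames(sums))] <- sums[, 1]
    slack <- nf$rhs - minLHS
    if (any(slack < -tol)) return(list(lb = lb, ub = ub, feasible = FALSE))
    rng <- ub[vi] - lb[vi]
    amt <- abs(av) * rng
    tight <- amt > slack[ci] + tol & rng > tol
    if (!any(tight)) break
    changed <- FALSE
    ti <- which(tight)
    ## a > 0: x_j <= lb_j + slack / a
    tp <- ti[pos[ti]]
    if (length(tp)) {
      cand <- lb[vi[tp]] + slack[ci[tp]] / av[tp]
      cand[intMask[vi[tp]]] <- floor(cand[intMask[vi[tp]]] + tol)
      o <- order(vi[tp], cand)
      first <- !duplicated(vi[tp][o])
      js <- vi[tp][o][first]; vals <- cand[o][first]
      upd <- vals < ub[js] - tol
      if (any(upd)) { ub[js[upd]] <- vals[upd]; changed <- TRUE }
    }
    ## a < 0: x_j >= ub_j - slack / |a|
    tn <- ti[!pos[ti]]
    if (length(tn)) {
      cand <- ub[vi[tn]] - slack[ci[tn]] / (-av[tn])
      cand[intMask[vi[tn]]] <- ceiling(cand[intMask[vi[tn]]] - tol)
      o <- order(vi[tn], -cand)
      first <- !duplicated(vi[tn][o])
      js <- vi[tn][o][first]; vals <- cand[o][first]
      upd <- vals > lb[js] + tol
      if (any(upd)) { lb[js[upd]] <- vals[upd]; changed <- TRUE }
    }
    if (any(lb > ub + tol)) return(list(lb = lb, ub = ub, feasible = FALSE))
    if (!changed) break
  }
  list(lb = lb, ub = ub, feasible = TRUE)
}

## Solve the LP relaxation (all variables continuous within current
## bounds) with the dense simplex; used when the model has continuous
## variables.  Returns list(status, x, obj) in <=-form terms.
solveRelaxation <- function(nf, lb, ub) {
  n <- nf$nVar
  A <- matrix(0, nf$m, n)
  A[cbind(nf$ci, nf$vi)] <- nf$av
  ## shift variables to start at 0:  y = x - lb
  bShift <- nf$rhs - as.vector(A %*% lb)
  res <- simplexSolve(A, rep("<=", nf$m), bShift, nf$obj, ub = ub - lb)
  if (res$status != "optimal") return(res)
  x <- res$x + lb
  list(status = "optimal", x = x, obj = sum(nf$obj * x))
}

#' Solve a mixed-integer linear program
#'
#' An exact depth-first branch-and-bound solver for programs whose integer
#' variables are binary (the only kind this package generates).  At every
#' node, interval-arithmetic constraint propagation tightens bounds and
#' fixes forced binaries; when the model contains continuous variables the
#' LP relaxation (solved with a dense two-phase simplex) additionally
#' prunes infeasible or dominated subtrees.  Branching is deterministic:
#' the first unfixed binary in declaration order, trying the value with
#' the smaller objective contribution first.  Because the whole procedure
#' is deterministic, repeated solves of the same program return the same
#' solution.
#'
#' @param lp a [LinearProgram-class].
#' @param config a list from [solverConfig()].
#' @return a \code{SolveResult}: a list with elements \code{status}
#'   (\code{"optimal"}, \code{"infeasible"} or \code{"feasible-limit"}),
#'   \code{objective}, and \code{values} (named vector; binaries rounded to
#'   integers at the integer-feasibility tolerance).
#' @export
milpSolve <- function(lp, config = solverConfig()) {
  stopifnot(is(lp, "LinearProgram"))
  nf <- normalizeLP(lp)
  n <- nf$nVar
  intMask <- lp@isInt
  anyCont <- any(!intMask)
  best <- new.env(parent = emptyenv())
  best$obj <- Inf; best$x <- NULL
  nodes <- 0L
  hitLimit <- FALSE

  recurse <- function(lb, ub) {
    if (hitLimit) return()
    nodes <<- nodes + 1L
    if (nodes > config$nodeLimit) { hitLimit <<- TRUE; return() }
    pr <- propagateBounds(nf, lb, ub, intMask)
    if (!pr$feasible) return()
    lb <- pr$lb; ub <- pr$ub
    bound <- sum(ifelse(nf$obj >= 0, nf$obj * lb, nf$obj * ub))
    if (bound >= best$obj - 1e-9) return()
    freeInt <- which(intMask & ub - lb > 0.5)
    ## LP relaxation: prunes infeasible/dominated subtrees.  A
    ## near-integral relaxation is never promoted to an incumbent --
    ## with big-M rows a tiny fractional binary (v/M) sits inside the
    ## integer tolerance while rounding it would cut the flux off.
    if (anyCont && length(freeInt)) {
      rel <- solveRelaxation(nf, lb, ub)
      if (rel$status != "optimal") return()
      if (rel$obj >= best$obj - 1e-9) return()
    }
    if (!length(freeInt)) {
      if (anyCont) {
        ## continuous part: optimise it (or certify feasibility)
        rel <- solveRelaxation(nf, lb, ub)
        if (rel$status != "optimal") return()
        if (rel$obj < best$obj - 1e-9) { best$obj <- rel$obj; best$x <- rel$x }
      } else {
        obj <- sum(nf$obj * lb)
        if (obj < best$obj - 1e-9) { best$obj <- obj; best$x <- lb }
      }
      return()
    }
    j <- freeInt[1L]
    vals <- if (nf$obj[j] >= 0) c(lb[j], ub[j]) else c(ub[j], lb[j])
    for (v in vals) {
      lb2 <- lb; ub2 <- ub
      lb2[j] <- v; ub2[j] <- v
      recurse(lb2, ub2)
    }
  }

  recurse(lp@lb, lp@ub)

  if (is.null(best$x)) {
    status <- if (hitLimit) "feasible-limit" else "infeasible"
    return(structure(list(status = status, objective = NA_real_,
                          values = NULL, nodes = nodes),
                     class = "SolveResult"))
  }
  x <- best$x
  x[intMask] <- round(x[intMask])
  obj <- best$obj
  if (nf$flip) obj <- -obj
  structure(list(status = if (hitLimit) "feasible-limit" else "optimal",
                 objective = obj,
                 values = stats::setNames(x, lp@varIds),
                 nodes = nodes),
            class = "SolveResult")
}

#' @export
print.SolveResult <- function(x, ...) {
  cat(sprintf("SolveResult: %s, objective %s (%d nodes)\n", x$status,
              format(x$objective), x$nodes))
  invisible(x)
}
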