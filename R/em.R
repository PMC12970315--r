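#' @include AllClasses.R stoich.R solver.R boolnet-io.R
NULL

## Build the flux program of the steady-state machinery on a *split*
## (all-irreversible) model: binary activity indicators y_j, continuous
## fluxes v_j in [0, M], steady state N v = 0 on balanced species, big-M
## linking v_j <= M y_j, and total flux sum v >= eps_tot.  Futile
## forward/backward pairs are excluded with y_f + y_b <= 1 when the y are
## free (minimality search); when y are fixed the pair rows are omitted so
## that a fixed support may legitimately allow both directions.
buildFluxProgram <- function(split, freeY, fixedOne, bigM, epsTot,
                             futileRows = TRUE) {
  sm <- split$model
  rxns <- sm@reactions
  if (!length(rxns)) stop("degenerate model: no reactions", call. = FALSE)
  b <- lpBuilder()
  yId <- stats::setNames(paste0("y.", rxns), rxns)
  vId <- stats::setNames(paste0("v.", rxns), rxns)
  for (j in rxns) {
    if (j %in% freeY) lpAddVar(b, yId[[j]], 0, 1, TRUE)
    else {
      val <- as.numeric(j %in% fixedOne)
      lpAddVar(b, yId[[j]], val, val, TRUE)
    }
  }
  for (j in rxns) lpAddVar(b, vId[[j]], 0, bigM, FALSE)
  balanced <- setdiff(sm@species, sm@boundary)
  for (sp in balanced) {
    row <- sm@N[sp, ]
    nz <- which(row != 0)
    if (!length(nz)) next
    lpAddConstr(b, stats::setNames(row[nz], vId[rxns[nz]]), "=", 0)
  }
  for (j in rxns)
    lpAddConstr(b, stats::setNames(c(1, -bigM), c(vId[[j]], yId[[j]])),
                "<=", 0)
  lpAddConstr(b, stats::setNames(rep(1, length(rxns)), unname(vId)),
              ">=", epsTot)
  if (futileRows) {
    revOrig <- unique(split$map$orig[split$map$dir == "-"])
    for (r in revOrig) {
      pair <- split$map$split[split$map$orig == r]
      lpAddConstr(b, stats::setNames(rep(1, 2), yId[pair]), "<=", 1)
    }
  }
  list(builder = b, yId = yId, vId = vId)
}

## Map a support of original reaction names to split names (both
## directions for reversible members).
splitSupport <- function(split, S) {
  bad <- setdiff(S, unique(split$map$orig))
  if (length(bad))
    stop("unknown reaction name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  split$map$split[split$map$orig %in% S]
}

## Net flux on original reaction names from split values.
netFlux <- function(split, v) {
  out <- stats::setNames(numeric(length(unique(split$map$orig))),
                         unique(split$map$orig))
  for (i in seq_len(nrow(split$map))) {
    s <- split$map$split[i]; o <- split$map$orig[i]
    sgn <- if (split$map$dir[i] == "-") -1 else 1
    out[o] <- out[o] + sgn * v[[paste0("v.", s)]]
  }
  out
}

#' Test whether a nonzero steady flux exists inside a support
#'
#' Fixes the activity indicators to the candidate support S (\eqn{y_j = 1}
#' for \eqn{j \in S}, 0 otherwise) and tests feasibility of the
#' steady-state system \eqn{Nv = 0}, \eqn{0 \le v_j \le M y_j},
#' \eqn{\sum_j v_j \ge \varepsilon_{tot}} on the balanced species.
#' Feasibility certifies that a nonzero steady flux supported inside S
#' exists, but says nothing about minimality.
#'
#' @param model a [StoichiometricModel-class].
#' @param S character vector of reaction names (original names; a
#'   reversible member may run in either direction).
#' @param bigM upper flux bound M (default 1000), chosen larger than any
#'   attainable flux.
#' @param epsTot total-flux threshold \eqn{\varepsilon_{tot}} (default
#'   1e-3), small but numerically distinguishable from zero.
#' @param config solver configuration.
#' @return list with elements \code{feasible} (logical) and \code{flux}
#'   (named net-flux witness over the original reactions, or NULL).
#' @export
steadyFluxFeasible <- function(model, S, bigM = 1000, epsTot = 1e-3,
                               config = solverConfig()) {
  stopifnot(bigM > 0, epsTot > 0)
  split <- splitReversible(model)
  Ssplit <- splitSupport(split, S)
  fp <- buildFluxProgram(split, freeY = character(0), fixedOne = Ssplit,
                         bigM = bigM, epsTot = epsTot, futileRows = FALSE)
  res <- milpSolve(lpBuild(fp$builder), config)
  if (res$status != "optimal") return(list(feasible = FALSE, flux = NULL))
  list(feasible = TRUE, flux = netFlux(split, res$values))
}

#' MILP support-minimality test for a candidate flux support
#'
#' Solves \eqn{\min \sum_j y_j} subject to \eqn{Nv = 0},
#' \eqn{0 \le v_j \le M y_j}, \eqn{\sum_j v_j \ge \varepsilon_{tot}} and
#' \eqn{y_j = 0} for \eqn{j \notin S}.  If the optimum equals |S| no
#' strictly smaller-support steady flux exists inside S and S is
#' support-minimal (an elementary mode); an optimum below |S| shows S is
#' not minimal.
#'
#' @inheritParams steadyFluxFeasible
#' @return logical(1).
#' @export
supportMinimalityMILP <- function(model, S, bigM = 1000, epsTot = 1e-3,
                                  config = solverConfig()) {
  stopifnot(bigM > 0, epsTot > 0, length(S) >= 1)
  split <- splitReversible(model)
  Ssplit <- splitSupport(split, S)
  fp <- buildFluxProgram(split, freeY = Ssplit, fixedOne = character(0),
                         bigM = bigM, epsTot = epsTot, futileRows = TRUE)
  b <- fp$builder
  lpSetObjective(b, stats::setNames(rep(1, length(Ssplit)),
                                    unname(fp$yId[Ssplit])), "min")
  res <- milpSolve(lpBuild(b), config)
  if (res$status != "optimal")
    stop("no steady flux inside the candidate support; ",
         "steadyFluxFeasible() must hold before testing minimality",
         call. = FALSE)
  round(res$objective) == length(S)
}

#' Brute-force enumeration of elementary modes
#'
#' The independent oracle for the steady-state machinery: enumerates
#' candidate supports of the split (all-irreversible) network in order of
#' increasing size, skipping supersets of modes already found and futile
#' forward/backward pairs, and keeps every support-minimal feasible
#' support together with a flux witness.  Exponential in the reaction
#' count, so guarded to small models.
#'
#' @param model a [StoichiometricModel-class] with at most 15 (split)
#'   reactions.
#' @param maxSupport largest support size to enumerate (default: all).
#' @param bigM,epsTot as in [steadyFluxFeasible()].
#' @return list of EM candidates, each a list with elements
#'   \code{support} (original reaction names, sorted), \code{dir}
#'   (direction annotation per support member), \code{flux} (net-flux
#'   witness) and \code{is_em = TRUE}; sorted by (size, lexicographic).
#' @export
enumerateEMsBruteForce <- function(model, maxSupport = NULL, bigM = 1000,
                                   epsTot = 1e-3) {
  split <- splitReversible(model)
  rxns <- split$model@reactions
  r <- length(rxns)
  if (r == 0L) stop("degenerate model: no reactions", call. = FALSE)
  if (r > 15L)
    stop("brute-force enumeration is limited to 15 split reactions (got ",
         r, ")", call. = FALSE)
  if (is.null(maxSupport)) maxSupport <- r
  sm <- split$model
  balanced <- setdiff(sm@species, sm@boundary)
  Nb <- sm@N[balanced, , drop = FALSE]
  ## futile pair masks
  revOrig <- unique(split$map$orig[split$map$dir == "-"])
  pairIdx <- lapply(revOrig, function(o)
    which(rxns %in% split$map$split[split$map$orig == o]))
  ems <- list()
  emIdx <- list()
  feas <- function(idx) {
    A <- Nb[, idx, drop = FALSE]
    res <- simplexSolve(rbind(A, rep(1, length(idx))),
                        c(rep("=", nrow(A)), "="),
                        c(rep(0, nrow(A)), 1),
                        rep(0, length(idx)))
    if (res$status != "optimal") return(NULL)
    res$x
  }
  for (size in seq_len(maxSupport)) {
    for (combo in utils::combn(r, size, simplify = FALSE)) {
      if (any(vapply(pairIdx, function(p) all(p %in% combo), logical(1))))
        next
      if (any(vapply(emIdx, function(e) all(e %in% combo), logical(1))))
        next
      w <- feas(combo)
      if (is.null(w)) next
      ## minimal by construction (no found EM inside); the witness of a
      ## minimal support must use all of it
      v <- stats::setNames(numeric(r), rxns)
      v[combo] <- w * epsTot        # scale to the eps_tot threshold
      supSplit <- rxns[combo]
      origs <- split$map$orig[match(supSplit, split$map$split)]
      dirs <- split$map$dir[match(supSplit, split$map$split)]
      o <- order(origs)
      ems[[length(ems) + 1L]] <- list(
        support = origs[o],
        dir = stats::setNames(dirs[o], origs[o]),
        flux = netFlux(split, stats::setNames(as.list(v), paste0("v.", rxns))),
        is_em = TRUE)
      emIdx[[length(emIdx) + 1L]] <- combo
    }
  }
  ems[order(vapply(ems, function(e) length(e$support), integer(1)),
            vapply(ems, function(e) paste(e$support, collapse = "\r"),
                   character(1)))]
}

#' Minimal Boolean activation routes to a target
#'
#' The elementary-mode analogue on a Boolean network: all support-minimal
#' node sets T containing the target such that the state "nodes in T on,
#' every other node off" is a fixed point of the network (input nodes
#' outside T held at 0).  Minimality is strict-subset minimality, so the
#' returned family is an antichain.
#'
#' @param net a [BooleanNetwork-class] with at most 20 nodes.
#' @param target target node name.
#' @param maxSize largest route size to return (default: no limit).
#' @return list of character vectors (routes), sorted by (size,
#'   lexicographic).
#' @export
booleanActivationRoutes <- function(net, target, maxSize = NULL) {
  nodes <- net@nodes
  n <- length(nodes)
  if (!target %in% nodes) stop("target not in network", call. = FALSE)
  if (n > 20L)
    stop("route enumeration is limited to 20 nodes (got ", n, ")",
         call. = FALSE)
  others <- setdiff(nodes, target)
  k <- length(others)
  ## all states with target = 1, vectorised over 2^k rows
  M <- matrix(0L, nrow = 2^k, ncol = n, dimnames = list(NULL, nodes))
  M[, target] <- 1L
  if (k) {
    bits <- as.matrix(expand.grid(rep(list(0:1), k)))
    M[, others] <- bits
  }
  ok <- rep(TRUE, nrow(M))
  for (nm in names(net@rules)) {
    f <- evalCircuit(net@rules[[nm]], function(r) M[, r])
    ok <- ok & (f == M[, nm])
  }
  states <- M[ok, , drop = FALSE]
  routes <- apply(states, 1L, function(s) sort(nodes[s == 1L]),
                  simplify = FALSE)
  sizes <- lengths(routes)
  o <- order(sizes, vapply(routes, paste, character(1), collapse = "\r"))
  routes <- routes[o]
  keep <- logical(length(routes))
  minimal <- list()
  for (i in seq_along(routes)) {
    if (!any(vapply(minimal, function(m) all(m %in% routes[[i]]),
                    logical(1)))) {
      minimal[[length(minimal) + 1L]] <- routes[[i]]
      keep[i] <- TRUE
    }
  }
  out <- routes[keep]
  if (!is.null(maxSize)) out <- out[lengths(out) <= maxSize]
  out
}

#' Elementary-mode selectivity check
#'
#' A support passes when it is one of the network-A routes (set equality)
#' and none of the network-B routes: the intervention then corresponds to
#' a minimal steady-state pathway present only in network A.
#'
#' @param S character vector (candidate support).
#' @param routesA,routesB route lists computed for the same target, as
#'   returned by [booleanActivationRoutes()] or EM supports.
#' @return logical(1).
#' @export
emSelectivityCheck <- function(S, routesA, routesB) {
  inA <- any(vapply(routesA, function(r) setequal(r, S), logical(1)))
  if (!inA || !length(S)) return(FALSE)
  !any(vapply(routesB, function(r) setequal(r, S), logical(1)))
}
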