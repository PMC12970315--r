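#' @include AllClasses.R boolnet-io.R stoich.R
NULL

## Run a generator with a fixed RNG seed without disturbing the caller's
## RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' The MKMN two-network case study
#'
#' Loads the bundled reconstruction of the MKMN network pair: two
#' 13-node circuits sharing every node name, where the pathological
#' network A differs from the healthy network B by the additional
#' r3 -> C2 linkage (and the consequent C2 -> C4 dependency).  Network B
#' decomposes into three minimal activation routes to the target C9;
#' network A into one.  The rule files live under
#' \code{system.file("extdata", package = "BoolIntervene")} and are plain
#' data — users can substitute the published topology without code
#' changes.
#'
#' @return a [NetworkPair-class] (A pathological, B healthy).
#' @examples
#' pair <- makeMKMNPair()
#' length(sharedNodes(netA(pair), netB(pair)))
#' @export
makeMKMNPair <- function() {
  dir <- system.file("extdata", package = "BoolIntervene")
  NetworkPair(readRules(file.path(dir, "mkmn_A.bnet")),
              readRules(file.path(dir, "mkmn_B.bnet")))
}

#' Toy stoichiometric models with known elementary-mode sets
#'
#' Small fixtures for the steady-state machinery:
#' \describe{
#'   \item{chain}{A -> B -> C with A and C boundary: exactly 1 EM.}
#'   \item{parallel}{two disjoint routes A -> C (via B1 and via B2), A and
#'     C boundary: exactly 2 EMs.}
#'   \item{cycle}{an entry exchange -> A, the 3-cycle A -> B -> C -> A,
#'     and an exit exchange C ->: 2 EMs (the internal cycle, and the
#'     through-route entry-A-B-C-exit).}
#' }
#'
#' @param kind \code{"chain"}, \code{"parallel"} or \code{"cycle"}.
#' @return a [StoichiometricModel-class].
#' @export
makeToyStoich <- function(kind = c("chain", "parallel", "cycle")) {
  kind <- match.arg(kind)
  switch(kind,
    chain = {
      N <- matrix(c(-1, 1, 0,
                    0, -1, 1), nrow = 3,
                  dimnames = list(c("A", "B", "C"), c("r1", "r2")))
      StoichiometricModel(N, boundary = c("A", "C"))
    },
    parallel = {
      N <- matrix(0, 4, 4,
                  dimnames = list(c("A", "B1", "B2", "C"),
                                  c("r1", "r2", "r3", "r4")))
      N["A", "r1"] <- -1; N["B1", "r1"] <- 1
      N["B1", "r2"] <- -1; N["C", "r2"] <- 1
      N["A", "r3"] <- -1; N["B2", "r3"] <- 1
      N["B2", "r4"] <- -1; N["C", "r4"] <- 1
      StoichiometricModel(N, boundary = c("A", "C"))
    },
    cycle = {
      N <- matrix(0, 3, 5,
                  dimnames = list(c("A", "B", "C"),
                                  c("e_in", "r1", "r2", "r3", "e_out")))
      N["A", "e_in"] <- 1
      N["A", "r1"] <- -1; N["B", "r1"] <- 1
      N["B", "r2"] <- -1; N["C", "r2"] <- 1
      N["C", "r3"] <- -1; N["A", "r3"] <- 1
      N["C", "e_out"] <- -1
      StoichiometricModel(N)
    })
}

#' Configuration for the random network-pair generator
#'
#' @param nNodes total node count.
#' @param nInputs number of input (source) nodes.
#' @param edgeDensity probability that each eligible earlier node regulates
#'   a given node.
#' @param nEdgeDiffs number of regulator edges differing between the two
#'   generated networks (0 gives an identical pair).
#' @param seed integer RNG seed; the generated pair is byte-identical
#'   across runs for a fixed configuration.
#' @return a validated configuration list of class \code{PairGenConfig}.
#' @export
pairGenConfig <- function(nNodes, nInputs, edgeDensity = 0.3,
                          nEdgeDiffs = 1L, seed = 0L) {
  stopifnot(nNodes >= 2, nInputs >= 1, nInputs < nNodes,
            edgeDensity > 0, edgeDensity <= 1, nEdgeDiffs >= 0)
  structure(list(nNodes = as.integer(nNodes), nInputs = as.integer(nInputs),
                 edgeDensity = edgeDensity, nEdgeDiffs = as.integer(nEdgeDiffs),
                 seed = as.integer(seed)),
            class = "PairGenConfig")
}

ruleTextFromSpec <- function(nodes, inputs, spec) {
  lines <- sprintf("input %s = 1", inputs)
  for (nm in names(spec)) {
    s <- spec[[nm]]
    lits <- ifelse(s$neg, paste0("!", nodes[s$parents]), nodes[s$parents])
    op <- if (s$kind == "AND") " & " else " | "
    lines <- c(lines, sprintf("%s = %s", nm, paste(lits, collapse = op)))
  }
  lines
}

#' Generate a random structurally similar network pair
#'
#' Builds an acyclic random Boolean network A (each regulated node takes a
#' random AND or OR over earlier nodes, individual literals negated with
#' probability 0.25) and derives B by adding or removing exactly
#' \code{nEdgeDiffs} regulator edges at random gates.  Both networks share
#' the full node set and every non-input node has a rule in both, so any
#' regulated node is a candidate target.
#'
#' @param cfg a configuration from [pairGenConfig()].
#' @return a [NetworkPair-class].
#' @export
randomPair <- function(cfg) {
  stopifnot(inherits(cfg, "PairGenConfig"))
  withSeed(cfg$seed, {
    n <- cfg$nNodes
    nodes <- paste0("n", seq_len(n))
    inputs <- nodes[seq_len(cfg$nInputs)]
    specA <- list()
    for (i in seq.int(cfg$nInputs + 1L, n)) {
      elig <- seq_len(i - 1L)
      sel <- elig[stats::runif(length(elig)) < cfg$edgeDensity]
      if (!length(sel)) sel <- elig[sample.int(length(elig), 1L)]
      specA[[nodes[i]]] <- list(
        parents = sel,
        neg = stats::runif(length(sel)) < 0.25,
        kind = if (stats::runif(1) < 0.5) "AND" else "OR")
    }
    ## derive B by modifying one regulator edge at a time; each pick
    ## touches a fresh (node, parent) pair so the symmetric difference of
    ## the edge sets grows by exactly one per step, and a removal never
    ## strips a node's last regulator
    specB <- specA
    touched <- character(0)
    for (step in seq_len(cfg$nEdgeDiffs)) {
      cand <- list()
      for (i in seq.int(cfg$nInputs + 1L, n)) {
        nm <- nodes[i]
        pres <- specB[[nm]]$parents
        for (p in setdiff(seq_len(i - 1L), pres)) {
          key <- paste(nm, p)
          if (!key %in% touched)
            cand[[length(cand) + 1L]] <- list(node = nm, parent = p, op = "add")
        }
        if (length(pres) >= 2L)
          for (p in pres) {
            key <- paste(nm, p)
            if (!key %in% touched)
              cand[[length(cand) + 1L]] <- list(node = nm, parent = p, op = "rem")
          }
      }
      if (!length(cand))
        stop("cannot realise ", cfg$nEdgeDiffs, " edge differences: ",
             "no further candidate modifications exist", call. = FALSE)
      mod <- cand[[sample.int(length(cand), 1L)]]
      touched <- c(touched, paste(mod$node, mod$parent))
      s <- specB[[mod$node]]
      if (mod$op == "add") {
        s$parents <- c(s$parents, mod$parent)
        s$neg <- c(s$neg, stats::runif(1) < 0.25)
      } else {
        keep <- s$parents != mod$parent
        s$parents <- s$parents[keep]
        s$neg <- s$neg[keep]
      }
      specB[[mod$node]] <- s
    }
    NetworkPair(parseRules(ruleTextFromSpec(nodes, inputs, specA)),
                parseRules(ruleTextFromSpec(nodes, inputs, specB)))
  })
}

#' Write the bundled fixtures to a directory
#'
#' Emits the MKMN rule files and the toy stoichiometric reaction tables so
#' they can be inspected or edited outside the package.
#'
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
writeFixtures <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  src <- system.file("extdata", package = "BoolIntervene")
  paths <- character(0)
  for (f in c("mkmn_A.bnet", "mkmn_B.bnet")) {
    p <- file.path(dir, f)
    file.copy(file.path(src, f), p, overwrite = TRUE)
    paths <- c(paths, p)
  }
  for (kind in c("chain", "parallel", "cycle")) {
    p <- file.path(dir, paste0("toy_", kind, ".tsv"))
    writeReactionTable(makeToyStoich(kind), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
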