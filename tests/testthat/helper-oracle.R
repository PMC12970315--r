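# Independent oracles used across the suite.
#
# The rule dialect (`&`, `|`, `!`, NOT > AND > OR) is also valid R syntax
# with the same precedence, so the oracle evaluates serialized rule
# expressions with R's own parser and logical operators -- a path fully
# separate from the package's gate-circuit machinery and from the MILP
# encoding it is used to check.

oracleExprs <- function(net) {
  lines <- serializeRules(net)
  rules <- grep("^input ", lines, invert = TRUE, value = TRUE)
  nm <- sub("\\s*=.*$", "", rules)
  ex <- lapply(sub("^[^=]*=\\s*", "", rules), function(s) parse(text = s)[[1]])
  names(ex) <- nm
  ex
}

# Evaluate one node's rule on a named logical list/data.frame of states.
oracleEval <- function(ex, env) as.integer(eval(ex, env))

# For every one of the 2^n states: its bit encoding and the bitmask of
# "violated" nodes (regulated nodes whose rule output differs from their
# state; input nodes differing from their default).  A state s is a fixed
# point of the network perturbed by clamping support S (to z = s[S]) iff
# violBits(s) is contained in the bitmask of S.
oracleNetTables <- function(net) {
  nodes <- nodeNames(net)
  n <- length(nodes)
  stopifnot(n <= 20)
  S <- as.matrix(expand.grid(rep(list(0:1), n)))
  colnames(S) <- nodes
  env <- as.data.frame(S == 1)
  ex <- oracleExprs(net)
  viol <- matrix(FALSE, nrow(S), n, dimnames = list(NULL, nodes))
  defs <- inputDefaults(net)
  for (nm in nodes) {
    viol[, nm] <- if (nm %in% names(ex)) oracleEval(ex[[nm]], env) != S[, nm]
                  else S[, nm] != defs[[nm]]
  }
  bitw <- 2^(seq_len(n) - 1)
  list(nodes = nodes,
       stateBits = as.integer(S %*% bitw),
       violBits = as.integer(viol %*% bitw))
}

popcount <- function(x)
  vapply(x, function(m) sum(bitwAnd(m, as.integer(2^(0:19))) > 0L),
         numeric(1))

maskToSupport <- function(mask, nodes)
  sort(nodes[bitwAnd(mask, as.integer(2^(seq_along(nodes) - 1))) > 0L])

# Exhaustive-search oracle for single-network modulation: the minimal
# clamping supports that admit a fixed point with the target at d.
# Returns NULL when infeasible, else list(objective, supports).
oracleSingleOptimal <- function(net, target, d) {
  tb <- oracleNetTables(net)
  bit <- as.integer(2^(match(target, tb$nodes) - 1))
  keep <- (bitwAnd(tb$stateBits, bit) > 0L) == (d == 1)
  masks <- unique(tb$violBits[keep])
  if (!length(masks)) return(NULL)
  pc <- popcount(masks)
  best <- sort(unique(masks[pc == min(pc)]))
  list(objective = min(pc),
       supports = lapply(best, maskToSupport, nodes = tb$nodes))
}

# Exhaustive-search oracle for selective modulation with a shared (tied)
# intervention: over all pairs of states (sA with target dA, sB with
# target dB), a support works iff it contains both violation sets and the
# two states agree on it; the minimal supports are the minimal unions.
oracleSelectiveOptimal <- function(pair, target, dA, dB) {
  ta <- oracleNetTables(netA(pair))
  tb <- oracleNetTables(netB(pair))
  stopifnot(identical(ta$nodes, tb$nodes))
  bit <- as.integer(2^(match(target, ta$nodes) - 1))
  kA <- (bitwAnd(ta$stateBits, bit) > 0L) == (dA == 1)
  kB <- (bitwAnd(tb$stateBits, bit) > 0L) == (dB == 1)
  if (!any(kA) || !any(kB)) return(NULL)
  sA <- ta$stateBits[kA]; vA <- ta$violBits[kA]
  sB <- tb$stateBits[kB]; vB <- tb$violBits[kB]
  D <- outer(sA, sB, bitwXor)        # nodes where the two states differ
  W <- outer(vA, vB, bitwOr)         # union of violation sets
  ok <- bitwAnd(D, W) == 0L
  if (!any(ok)) return(NULL)
  masks <- unique(W[ok])
  pc <- popcount(masks)
  best <- sort(unique(masks[pc == min(pc)]))
  list(objective = min(pc),
       supports = lapply(best, maskToSupport, nodes = ta$nodes))
}

supportsOf <- function(solutions) lapply(solutions, function(s) s@support)

expect_same_support_family <- function(got, want) {
  fmt <- function(x)
    sort(vapply(lapply(x, sort), paste, character(1), collapse = ","))
  expect_identical(fmt(got), fmt(want))
}
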