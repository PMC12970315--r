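# Small fixture networks built in code.

chainNet <- function() parseRules("input a = 1\nb = a\nt = b")

# Truth table of a whole network's update over every assignment of all
# nodes, computed through the package's gate circuits.  Nodes are taken
# in sorted order so networks that differ only in declaration order
# produce comparable tables.
stepTable <- function(net) {
  nodes <- sort(nodeNames(net))
  stopifnot(length(nodes) <= 13)
  states <- as.matrix(expand.grid(rep(list(0:1), length(nodes))))
  colnames(states) <- nodes
  t(apply(states, 1L, function(s) synchronousStep(net, s)[nodes]))
}

# Check a list of constraints (as produced by the encode* functions)
# against a named 0/1 assignment.
satisfies <- function(constraints, assign) {
  for (cn in constraints) {
    lhs <- sum(cn$coefs * assign[names(cn$coefs)])
    ok <- switch(cn$sense,
                 "<=" = lhs <= cn$rhs + 1e-9,
                 ">=" = lhs >= cn$rhs - 1e-9,
                 "="  = abs(lhs - cn$rhs) <= 1e-9)
    if (!ok) return(FALSE)
  }
  TRUE
}

# All 0/1 assignments over the given variable names, as a list of named
# vectors.
allAssignments <- function(vars) {
  g <- as.matrix(expand.grid(rep(list(0:1), length(vars))))
  colnames(g) <- vars
  lapply(seq_len(nrow(g)), function(i) g[i, ])
}
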