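test_that("gate encodings have exactly the truth table as feasible set", {
  truth <- list(
    AND = function(a) as.integer(all(a == 1)),
    OR  = function(a) as.integer(any(a == 1)))
  for (kind in c("AND", "OR")) {
    for (k in 1:4) {
      ins <- paste0("a", seq_len(k))
      cons <- encodeGate(kind, "w", ins)
      for (assign in allAssignments(c(ins, "w"))) {
        want <- truth[[kind]](assign[ins]) == assign[["w"]]
        expect_identical(satisfies(cons, assign), want)
      }
    }
  }
  consNot <- encodeGate("NOT", "w", "a")
  for (assign in allAssignments(c("a", "w")))
    expect_identical(satisfies(consNot, assign),
                     assign[["w"]] == 1 - assign[["a"]])
  consLit <- encodeGate("LITERAL", "w", "a")
  for (assign in allAssignments(c("a", "w")))
    expect_identical(satisfies(consLit, assign),
                     assign[["w"]] == assign[["a"]])
  expect_error(encodeGate("NOT", "w", c("a", "b")), "exactly one input")
  expect_error(encodeGate("AND", "w", character(0)), "at least one input")
  expect_error(encodeGate("XOR", "w", "a"), "unknown gate kind")
})

test_that("perturbation linkage forces x = (1-u)*xhat + u*z exactly", {
  cons <- encodePerturbationLinkage("x", "xhat", "u", "z")
  expect_length(cons, 4L)
  for (assign in allAssignments(c("x", "xhat", "u", "z"))) {
    want <- assign[["x"]] ==
      (1 - assign[["u"]]) * assign[["xhat"]] + assign[["u"]] * assign[["z"]]
    expect_identical(satisfies(cons, assign), want)
  }
})

test_that("shared coupling equates final values exactly when unperturbed", {
  cons <- encodeSharedCoupling("xA", "xB", "u")
  expect_length(cons, 2L)
  for (assign in allAssignments(c("xA", "xB", "u"))) {
    want <- assign[["u"]] == 1 || assign[["xA"]] == assign[["xB"]]
    expect_identical(satisfies(cons, assign), want)
  }
})

test_that("single-target examples solve to the known optima", {
  net <- parseRules("input a = 1\nt = a")
  sat <- buildSingleTargetMILP(net, singleProblem("t", 1))
  sols <- enumerateOptimalSupports(sat$lp, sat$index)
  expect_length(sols, 1L)
  expect_identical(sols[[1]]@support, character(0))
  expect_identical(sols[[1]]@objective, 0L)

  unsat <- buildSingleTargetMILP(net, singleProblem("t", 0))
  sols0 <- enumerateOptimalSupports(unsat$lp, unsat$index)
  expect_same_support_family(supportsOf(sols0), list("a", "t"))

  chain <- buildSingleTargetMILP(chainNet(), singleProblem("t", 0))
  solsc <- enumerateOptimalSupports(chain$lp, chain$index)
  expect_same_support_family(supportsOf(solsc), list("a", "b", "t"))

  expect_error(buildSingleTargetMILP(net, singleProblem("zz", 0)),
               "not in network")
})

test_that("selective build couples the intervention and finds the MKMN family", {
  pair <- makeMKMNPair()
  built <- buildSelectiveMILP(pair, selectiveProblem("C9", 0, 1))
  sols <- enumerateOptimalSupports(built$lp, built$index)
  expect_same_support_family(supportsOf(sols), list("C6", "C7", "r3"))
  expect_identical(attr(sols, "optimum"), 1)
  for (s in sols) {
    expect_identical(unname(s@enforced$A[s@support]), 0L)
    expect_identical(unname(s@enforced$B[s@support]), 0L)
  }
})

test_that("identical networks with a tied intervention are infeasible", {
  net <- chainNet()
  pair <- NetworkPair(net, net)
  built <- buildSelectiveMILP(pair, selectiveProblem("t", 0, 1, tieZ = TRUE))
  res <- milpSolve(built$lp)
  expect_identical(res$status, "infeasible")
})

test_that("untied enforced values admit the trivial target clamp", {
  pair <- makeMKMNPair()
  built <- buildSelectiveMILP(pair, selectiveProblem("C9", 0, 1, tieZ = FALSE))
  sols <- enumerateOptimalSupports(built$lp, built$index)
  sups <- supportsOf(sols)
  expect_true(list("C9") %in% sups)
  expect_identical(attr(sols, "optimum"), 1)
})

test_that("state coupling on all shared nodes makes tied selection infeasible", {
  pair <- makeMKMNPair()
  built <- buildSelectiveMILP(pair, selectiveProblem("C9", 0, 1),
                              coupleShared = TRUE)
  expect_identical(milpSolve(built$lp)$status, "infeasible")
  ## dropping the coupling rows can only enlarge the feasible set
  rel <- buildSelectiveMILP(pair, selectiveProblem("C9", 0, 1))
  expect_identical(milpSolve(rel$lp)$status, "optimal")
})

test_that("encoding soundness: feasible x vectors are the perturbed fixed points", {
  ## for random small networks and random clamps (u, z), the assignments
  ## accepted by the constraint system (with x fixed) are exactly the
  ## fixed points of the clamped network that satisfy the target row
  set.seed(4)
  for (rep in 1:12) {
    net <- netA(randomPair(pairGenConfig(nNodes = 5, nInputs = 2,
                                         edgeDensity = 0.5, nEdgeDiffs = 1,
                                         seed = 100 + rep)))
    nodes <- nodeNames(net)
    target <- nodes[length(nodes)]
    d <- rep %% 2L
    built <- buildSingleTargetMILP(net, singleProblem(target, d))
    S <- nodes[stats::runif(length(nodes)) < 0.3]
    z <- stats::setNames(as.integer(stats::runif(length(S)) < 0.5), S)
    lp <- built$lp
    for (nm in nodes) {
      lp <- lpFixVar(lp, built$index$u[[nm]], as.numeric(nm %in% S))
      if (nm %in% S) lp <- lpFixVar(lp, built$index$z$A[[nm]], z[[nm]])
    }
    clamped <- applyIntervention(net, S, z)
    for (assign in allAssignments(nodes)) {
      lpx <- lp
      for (nm in nodes)
        lpx <- lpFixVar(lpx, built$index$x$A[[nm]], assign[[nm]])
      feasible <- milpSolve(lpx)$status == "optimal"
      ## clamped nodes sit at z and unperturbed inputs at their defaults;
      ## free nodes must be step-invariant
      defsOk <- all(vapply(inputNodes(clamped), function(nm)
        assign[[nm]] == inputDefaults(clamped)[[nm]], logical(1)))
      want <- isFixedPoint(clamped, assign) && defsOk &&
        assign[[target]] == d
      expect_identical(feasible, want)
    }
  }
})

test_that("objective of any solution equals its support size", {
  pair <- makeMKMNPair()
  built <- buildSelectiveMILP(pair, selectiveProblem("C9", 0, 1))
  res <- milpSolve(built$lp)
  uVals <- res$values[built$index$u]
  expect_identical(round(res$objective), sum(round(uVals)))
  sols <- enumerateOptimalSupports(built$lp, built$index)
  for (s in sols) expect_identical(s@objective, length(s@support))
})

test_that("variable naming is deterministic and the LP export is stable", {
  net <- parseRules("input a = 1\nt = a")
  b1 <- buildSingleTargetMILP(net, singleProblem("t", 0))
  b2 <- buildSingleTargetMILP(net, singleProblem("t", 0))
  expect_identical(b1$lp@varIds, b2$lp@varIds)
  expect_true(all(c("u.a", "u.t", "A.a.x", "A.t.xhat", "A.t.z") %in%
                  b1$lp@varIds))
  f1 <- tempfile(fileext = ".lp"); f2 <- tempfile(fileext = ".lp")
  writeLP(b1$lp, f1); writeLP(b2$lp, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_match(readLines(f1)[1], "Minimize")
  unlink(c(f1, f2))
})
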