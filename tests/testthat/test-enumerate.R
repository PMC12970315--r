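test_that("optimal-support enumeration finds every alternative optimum", {
  built <- buildSingleTargetMILP(chainNet(), singleProblem("t", 0))
  sols <- enumerateOptimalSupports(built$lp, built$index)
  expect_same_support_family(supportsOf(sols), list("a", "b", "t"))
  expect_false(attr(sols, "truncated"))

  ## unique optimum: singleton list
  net <- parseRules("input a = 1\nt = a")
  b1 <- buildSingleTargetMILP(net, singleProblem("t", 1))
  expect_length(enumerateOptimalSupports(b1$lp, b1$index), 1L)
})

test_that("the MKMN selective pool is exactly {C6},{C7},{r3}", {
  pair <- makeMKMNPair()
  built <- buildSelectiveMILP(pair, selectiveProblem("C9", 0, 1))
  sols <- enumerateOptimalSupports(built$lp, built$index)
  expect_same_support_family(supportsOf(sols), list("C6", "C7", "r3"))
})

test_that("exclusion cuts remove only the incumbent support", {
  built <- buildSingleTargetMILP(chainNet(), singleProblem("t", 0))
  sols <- enumerateOptimalSupports(built$lp, built$index)
  ## every enumerated support remains feasible on the original model
  for (s in sols) {
    lp <- built$lp
    for (nm in names(built$index$u))
      lp <- lpFixVar(lp, built$index$u[[nm]], as.numeric(nm %in% s@support))
    expect_identical(milpSolve(lp)$status, "optimal")
  }
  ## and the cut built from one support excludes exactly that pattern
  cut <- BoolIntervene:::exclusionCut(built$index, "b")
  lp <- lpAddConstraint(built$lp, cut$coefs, cut$sense, cut$rhs)
  again <- enumerateOptimalSupports(lp, built$index)
  expect_same_support_family(supportsOf(again), list("a", "t"))
})

test_that("ranked enumeration is complete up to the objective cap", {
  built <- buildSingleTargetMILP(chainNet(), singleProblem("t", 0))
  ranked <- enumerateRanked(built$lp, built$index, maxObjective = 2)
  objs <- vapply(ranked, function(s) s@objective, integer(1))
  expect_true(all(diff(objs) >= 0))
  ## all supports of sizes 1 and 2 that force t = 0: any nonempty subset
  ## of {a, b, t} works (clamping the earliest clamped node to 0
  ## propagates), so sizes 1 and 2 give 3 + 3 supports
  expect_identical(objs, c(1L, 1L, 1L, 2L, 2L, 2L))
  expect_same_support_family(
    supportsOf(ranked),
    list("a", "b", "t", c("a", "b"), c("a", "t"), c("b", "t")))

  ## cap at the optimum reproduces the optimal enumeration
  atOpt <- enumerateRanked(built$lp, built$index, maxObjective = 1)
  expect_same_support_family(supportsOf(atOpt),
                             supportsOf(enumerateOptimalSupports(
                               built$lp, built$index)))
})

test_that("ranked enumeration verified against the exhaustive oracle", {
  net <- netA(randomPair(pairGenConfig(nNodes = 6, nInputs = 2,
                                       edgeDensity = 0.5, nEdgeDiffs = 1,
                                       seed = 5)))
  target <- rev(nodeNames(net))[1]
  built <- buildSingleTargetMILP(net, singleProblem(target, 0))
  sols <- enumerateOptimalSupports(built$lp, built$index)
  want <- oracleSingleOptimal(net, target, 0)
  expect_same_support_family(supportsOf(sols), want$supports)
})

test_that("subset scan returns the first contained A-solution", {
  mk <- function(support) new("InterventionSolution",
    support = sort(support), enforced = list(A = stats::setNames(
      integer(length(support)), sort(support))),
    objective = length(support), verifiedMinimal = NA,
    emStatus = "unchecked")
  a1 <- mk(c("C6", "C7", "r3", "C9"))
  a2 <- mk("C1")
  b1 <- mk(c("C6", "C7", "r3", "C9", "C10", "r4"))
  hit <- subsetScan(list(a2, a1), list(b1))
  ## a2 comes first but is not contained; a1 is
  expect_identical(hit@support, a1@support)
  expect_identical(attr(hit, "matchedSupportB"), b1@support)

  expect_null(subsetScan(list(mk("x")), list(mk("y"))))
  ## subset includes equality
  eq <- subsetScan(list(a1), list(mk(c("C6", "C7", "r3", "C9"))))
  expect_identical(eq@support, a1@support)
  ## scanning honours objective order
  small <- mk("C6")
  hit2 <- subsetScan(list(a1, small), list(b1))
  expect_identical(hit2@support, small@support)
})

test_that("the enumeration limit flags truncation", {
  built <- buildSingleTargetMILP(chainNet(), singleProblem("t", 0))
  sols <- enumerateOptimalSupports(built$lp, built$index, limit = 2)
  expect_length(sols, 2L)
  expect_true(attr(sols, "truncated"))
})
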