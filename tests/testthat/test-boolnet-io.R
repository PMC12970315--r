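test_that("parser builds the declared nodes, gates and input defaults", {
  net <- parseRules("input a\ninput b\nc = a & b")
  expect_identical(nodeNames(net), c("a", "b", "c"))
  expect_identical(inputNodes(net), c("a", "b"))
  circ <- networkRules(net)$c
  expect_length(circ$gates, 1L)
  expect_identical(circ$gates[[1]]$kind, "AND")

  ## one-node feedback parses (cycles between nodes are allowed)
  loop <- parseRules("x = !x")
  expect_identical(nodeNames(loop), "x")
  expect_identical(synchronousStep(loop, c(x = 0L)), c(x = 1L))

  ## undeclared names become inputs with default 1
  net2 <- parseRules("c = a & b")
  expect_setequal(inputNodes(net2), c("a", "b"))
  expect_identical(unname(inputDefaults(net2)[c("a", "b")]), c(1L, 1L))

  ## explicit defaults are kept
  net3 <- parseRules("input a = 0\nt = a")
  expect_identical(inputDefaults(net3)[["a"]], 0L)
})

test_that("parser reports errors with line numbers", {
  expect_error(parseRules("a = b\na = c"), "line 2.*duplicate rule")
  expect_error(parseRules("input a\na = b"), "line 2.*declared input")
  expect_error(parseRules("a = b &"), "line 1")
  expect_error(parseRules("a = (b"), "line 1.*expected")
  expect_error(parseRules("# nothing\n\n"), "empty rule file")
  expect_error(parseRules("a = b ? c"), "line 1.*unexpected character")
})

test_that("operator precedence is NOT > AND > OR", {
  net <- parseRules("y = !a & b | c")
  ## (!a & b) | c
  expect_identical(synchronousStep(net, c(a = 0L, b = 1L, c = 0L, y = 0L))[["y"]], 1L)
  expect_identical(synchronousStep(net, c(a = 1L, b = 1L, c = 0L, y = 0L))[["y"]], 0L)
  expect_identical(synchronousStep(net, c(a = 1L, b = 0L, c = 1L, y = 0L))[["y"]], 1L)
  withParens <- parseRules("y = !(a & b) | c")
  expect_identical(
    synchronousStep(withParens, c(a = 1L, b = 1L, c = 0L, y = 0L))[["y"]], 0L)
  expect_identical(
    synchronousStep(withParens, c(a = 1L, b = 0L, c = 0L, y = 0L))[["y"]], 1L)
})

test_that("synchronous step matches the gate truth tables", {
  net <- parseRules("input a\ninput b\nc = a & b")
  expect_identical(synchronousStep(net, c(a = 1L, b = 1L, c = 0L)),
                   c(a = 1L, b = 1L, c = 1L))
  expect_identical(synchronousStep(net, c(a = 1L, b = 0L, c = 1L)),
                   c(a = 1L, b = 0L, c = 0L))
})

test_that("fixed points are exactly the step-invariant states", {
  net <- parseRules("input a\ninput b\nc = a & b")
  expect_true(isFixedPoint(net, c(a = 1L, b = 1L, c = 1L)))
  expect_false(isFixedPoint(net, c(a = 1L, b = 1L, c = 0L)))
  loop <- parseRules("x = !x")
  expect_false(isFixedPoint(loop, c(x = 0L)))
  expect_false(isFixedPoint(loop, c(x = 1L)))
})

test_that("the all-route-nodes-on state of MKMN network B is a fixed point", {
  b <- netB(makeMKMNPair())
  route <- c("C6", "C7", "r3", "C9")
  s <- stats::setNames(integer(length(nodeNames(b))), nodeNames(b))
  s[route] <- 1L
  expect_true(isFixedPoint(b, s))
})

test_that("shared nodes are the exact name intersection", {
  net <- parseRules("input a\ninput b\nc = a & b")
  expect_setequal(sharedNodes(net, net), nodeNames(net))
  other <- parseRules("input x\ny = x")
  expect_length(sharedNodes(net, other), 0L)
  pair <- makeMKMNPair()
  expect_length(sharedNodes(netA(pair), netB(pair)), 13L)
})

test_that("serialize/parse round trip preserves every truth table", {
  cases <- list(
    "input a\ninput b\nc = a & b",
    "y = !a & b | c\nz = !(a | b) & !c",
    "x = !x\nw = x | !w",
    serializeRules(netA(makeMKMNPair())))
  for (txt in cases) {
    net <- parseRules(txt)
    back <- parseRules(serializeRules(net))
    expect_setequal(nodeNames(back), nodeNames(net))
    expect_identical(inputDefaults(back)[sort(inputNodes(back))],
                     inputDefaults(net)[sort(inputNodes(net))])
    expect_identical(stepTable(back), stepTable(net))
  }
})

test_that("JSON round trip preserves the network", {
  net <- parseRules("input a = 0\ny = !a & b | c")
  back <- networkFromJSON(networkToJSON(net))
  expect_identical(nodeNames(back), nodeNames(net))
  expect_identical(inputDefaults(back)[sort(inputNodes(back))],
                   inputDefaults(net)[sort(inputNodes(net))])
  expect_identical(stepTable(back), stepTable(net))
})

test_that("gate evaluation agrees with R's own logical operators", {
  ## the dialect is valid R with identical precedence, so R's parser and
  ## logical ops form an independent evaluator
  set.seed(11)
  for (rep in 1:20) {
    pair <- randomPair(pairGenConfig(nNodes = 6, nInputs = 2,
                                     edgeDensity = 0.5, nEdgeDiffs = 1,
                                     seed = rep))
    net <- netA(pair)
    ex <- oracleExprs(net)
    states <- as.matrix(expand.grid(rep(list(0:1), length(nodeNames(net)))))
    colnames(states) <- nodeNames(net)
    env <- as.data.frame(states == 1)
    for (nm in names(ex)) {
      viaCircuit <- apply(states, 1L, function(s)
        synchronousStep(net, s)[[nm]])
      expect_identical(viaCircuit, oracleEval(ex[[nm]], env))
    }
  }
})

test_that("clamping and simulation reach consistent steady states", {
  net <- chainNet()
  clamped <- applyIntervention(net, "a", c(a = 0L))
  fp <- simulateToFixedPoint(clamped)
  expect_identical(unname(fp[c("a", "b", "t")]), c(0L, 0L, 0L))
  expect_true(isFixedPoint(clamped, fp))
  ## an unresolvable oscillation yields NULL
  expect_null(simulateToFixedPoint(parseRules("x = !x")))
})
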