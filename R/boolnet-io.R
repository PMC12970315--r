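#' @include AllClasses.R AllGenerics.R
NULL

## ---- rule-expression tokenizer and recursive-descent parser ------------
##
## Dialect: `name = expression` with operators `&`, `|`, `!`, parentheses
## and ASCII names [A-Za-z0-9_]+; precedence NOT > AND > OR.  Lines
## `input name [= 0|1]` declare source nodes.  `#` starts a comment.  The
## bare tokens `0` and `1` are constants, not node names.

tokenizeExpr <- function(txt, lineNo) {
  pat <- "[A-Za-z0-9_]+|&|\\||!|\\(|\\)"
  m <- gregexpr(pat, txt)[[1]]
  if (m[1] == -1L)
    stop(sprintf("line %d: empty expression", lineNo), call. = FALSE)
  toks <- regmatches(txt, gregexpr(pat, txt))[[1]]
  consumed <- sum(attr(m, "match.length"))
  leftover <- gsub("\\s", "", txt)
  if (nchar(leftover) != sum(nchar(toks)))
    stop(sprintf("line %d: unexpected character in expression '%s'",
                 lineNo, trimws(txt)), call. = FALSE)
  toks
}

## Grammar: expr := term ('|' term)* ; term := factor ('&' factor)* ;
## factor := '!' factor | '(' expr ')' | name | 0 | 1
parseExpr <- function(toks, lineNo) {
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- peek(); pos <<- pos + 1L; t }
  expect <- function(t) {
    got <- take()
    if (is.na(got) || got != t)
      stop(sprintf("line %d: expected '%s', got '%s'", lineNo, t,
                   ifelse(is.na(got), "end of line", got)), call. = FALSE)
  }
  pFactor <- function() {
    t <- peek()
    if (is.na(t))
      stop(sprintf("line %d: unexpected end of expression", lineNo),
           call. = FALSE)
    if (t == "!") { take(); return(list(type = "not", arg = pFactor())) }
    if (t == "(") {
      take(); e <- pExpr(); expect(")"); return(e)
    }
    if (t %in% c("&", "|", ")"))
      stop(sprintf("line %d: unexpected '%s'", lineNo, t), call. = FALSE)
    take()
    if (t %in% c("0", "1"))
      return(list(type = "const", value = as.integer(t)))
    list(type = "name", name = t)
  }
  pTerm <- function() {
    args <- list(pFactor())
    while (!is.na(peek()) && peek() == "&") { take(); args <- c(args, list(pFactor())) }
    if (length(args) == 1L) args[[1]] else list(type = "and", args = args)
  }
  pExpr <- function() {
    args <- list(pTerm())
    while (!is.na(peek()) && peek() == "|") { take(); args <- c(args, list(pTerm())) }
    if (length(args) == 1L) args[[1]] else list(type = "or", args = args)
  }
  out <- pExpr()
  if (!is.na(peek()))
    stop(sprintf("line %d: trailing tokens after expression", lineNo),
         call. = FALSE)
  out
}

## Compile an AST into an ordered gate list.  Chains of the same
## associative operator are flattened into one k-ary gate, matching the
## k-ary AND/OR linearisation used downstream.
compileCircuit <- function(ast) {
  gates <- list()
  counter <- 0L
  newGate <- function(kind, inputs, value = NA_integer_) {
    counter <<- counter + 1L
    id <- paste0("g", counter)
    gates[[length(gates) + 1L]] <<-
      list(id = id, kind = kind, inputs = inputs, value = value)
    id
  }
  emit <- function(node) {
    switch(node$type,
      name  = node$name,
      const = newGate("CONST", character(0), node$value),
      not   = newGate("NOT", emit(node$arg)),
      and   = newGate("AND", vapply(flatten(node, "and"), emit, character(1))),
      or    = newGate("OR",  vapply(flatten(node, "or"), emit, character(1))),
      stop("unknown AST node type"))
  }
  flatten <- function(node, type) {
    out <- list()
    for (a in node$args)
      if (a$type == type) out <- c(out, flatten(a, type)) else out <- c(out, list(a))
    out
  }
  top <- emit(ast)
  ## a bare name/constant at top level still needs a gate carrying the value
  if (!length(gates) || gates[[length(gates)]]$id != top)
    top <- newGate("LITERAL", top)
  list(gates = gates, output = top)
}

astNames <- function(ast) {
  switch(ast$type,
    name  = ast$name,
    const = character(0),
    not   = astNames(ast$arg),
    unique(unlist(lapply(ast$args, astNames))))
}

#' Parse a Boolean network from rule text
#'
#' Reads the plain-text rule dialect: one `node = expression` line per
#' regulated node (operators `&`, `|`, `!`, parentheses, precedence
#' NOT > AND > OR), `input node [= 0|1]` lines declaring source nodes, and
#' `#` comments.  Semicolons may be used in place of newlines.  Node names
#' referenced but never declared become input nodes with default value 1
#' ("present"), the convention under which source compounds of the bundled
#' case studies are available unless perturbed.
#'
#' @param text character: the rule file content (a single string or a
#'   vector of lines).
#' @return a [BooleanNetwork-class].
#' @examples
#' net <- parseRules("input a\ninput b\nc = a & b")
#' nodeNames(net)
#' @export
parseRules <- function(text) {
  raw <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  raw <- sub("#.*$", "", raw)           # comments end at the line, not at `;`
  lineNo <- seq_along(raw)
  ## expand `;` separators, keeping the originating line number
  parts <- strsplit(raw, ";", fixed = TRUE)
  parts[!lengths(parts)] <- list("")
  lines <- unlist(parts)
  lineNo <- rep(lineNo, lengths(parts))
  keep <- nzchar(trimws(lines))
  lines <- trimws(lines[keep]); lineNo <- lineNo[keep]
  if (!length(lines)) stop("empty rule file", call. = FALSE)

  declared <- character(0)        # in order of first appearance
  inputs <- character(0)
  defaults <- integer(0)
  ruleAst <- list()
  note <- function(nms) declared <<- union(declared, nms)

  namePat <- "[A-Za-z0-9_]+"
  for (i in seq_along(lines)) {
    ln <- lines[i]; no <- lineNo[i]
    inputMatch <- regmatches(ln, regexec(
      sprintf("^input\\s+(%s)\\s*(=\\s*([01]))?\\s*$", namePat), ln))[[1]]
    if (length(inputMatch)) {
      nm <- inputMatch[2]
      if (nm %in% inputs || nm %in% names(ruleAst))
        stop(sprintf("line %d: duplicate declaration of '%s'", no, nm),
             call. = FALSE)
      inputs <- c(inputs, nm)
      defaults[nm] <- if (nzchar(inputMatch[4])) as.integer(inputMatch[4]) else 1L
      note(nm)
      next
    }
    ruleMatch <- regmatches(ln, regexec(
      sprintf("^(%s)\\s*=\\s*(.+)$", namePat), ln))[[1]]
    if (!length(ruleMatch))
      stop(sprintf("line %d: cannot parse '%s'", no, ln), call. = FALSE)
    nm <- ruleMatch[2]
    if (nm %in% c("0", "1"))
      stop(sprintf("line %d: '%s' is a constant, not a node name", no, nm),
           call. = FALSE)
    if (nm %in% names(ruleAst))
      stop(sprintf("line %d: duplicate rule for node '%s'", no, nm),
           call. = FALSE)
    if (nm %in% inputs)
      stop(sprintf("line %d: node '%s' declared input but given a rule",
                   no, nm), call. = FALSE)
    ast <- parseExpr(tokenizeExpr(ruleMatch[3], no), no)
    ruleAst[[nm]] <- ast
    note(nm); note(astNames(ast))
  }

  ## auto-declare referenced-but-undefined names as inputs with default 1
  auto <- setdiff(declared, c(inputs, names(ruleAst)))
  inputs <- c(inputs, auto)
  if (length(auto)) defaults[auto] <- 1L

  rules <- lapply(ruleAst, compileCircuit)
  new("BooleanNetwork", nodes = declared, rules = rules, inputs = inputs,
      inputDefaults = defaults[inputs])
}

#' Read a Boolean network from a rule file
#' @param path file path.
#' @return a [BooleanNetwork-class].
#' @export
readRules <- function(path) parseRules(readLines(path, warn = FALSE))

## ---- circuit evaluation ------------------------------------------------

## Evaluate a circuit given `get(name)` returning the (possibly
## vectorised) 0/1 value of a node; returns the output gate's value.
evalCircuit <- function(circ, get) {
  vals <- list()
  ref <- function(r) if (!is.null(vals[[r]])) vals[[r]] else get(r)
  for (g in circ$gates) {
    v <- switch(g$kind,
      CONST   = g$value,
      LITERAL = ref(g$inputs),
      NOT     = 1 - ref(g$inputs),
      AND     = Reduce(function(a, b) a * b, lapply(g$inputs, ref)),
      OR      = {
        s <- Reduce(`+`, lapply(g$inputs, ref))
        (s > 0) + 0
      })
    vals[[g$id]] <- v
  }
  vals[[circ$output]]
}

gateCensus <- function(net) {
  kinds <- unlist(lapply(net@rules, function(circ)
    vapply(circ$gates, `[[`, character(1), "kind")))
  tab <- c(AND = 0L, OR = 0L, NOT = 0L, LITERAL = 0L, CONST = 0L)
  if (length(kinds)) {
    tt <- table(kinds)
    tab[names(tt)] <- as.integer(tt)
  }
  tab
}

#' Synchronous update of a network state
#'
#' Applies every regulated node's Boolean function to the current state;
#' input nodes keep their value.  The state must cover all nodes.
#'
#' @param net a [BooleanNetwork-class].
#' @param state named 0/1 vector over all nodes of \code{net}.
#' @return the successor state (named integer vector in node order).
#' @export
synchronousStep <- function(net, state) {
  stopifnot(all(net@nodes %in% names(state)))
  s <- state[net@nodes]
  out <- s
  for (nm in names(net@rules))
    out[nm] <- evalCircuit(net@rules[[nm]], function(r) s[[r]])
  storage.mode(out) <- "integer"
  out
}

#' Test whether a state is a fixed point
#'
#' A state is a fixed point (steady state) when the synchronous update
#' leaves it unchanged; fixed points are exactly the states preserved under
#' any asynchronous update order as well.
#'
#' @inheritParams synchronousStep
#' @return logical(1).
#' @export
isFixedPoint <- function(net, state) {
  s <- state[net@nodes]
  identical(as.integer(synchronousStep(net, s)), as.integer(s))
}

#' Clamp nodes of a network to fixed values
#'
#' Returns a network in which the supported nodes are turned into input
#' nodes held at the enforced values \code{z} (their rules are dropped).
#' This is the dynamical counterpart of the MILP's perturbation flags.
#'
#' @param net a [BooleanNetwork-class].
#' @param support character vector of nodes to clamp.
#' @param z named 0/1 vector of enforced values over \code{support} (or a
#'   single value recycled).
#' @return a [BooleanNetwork-class].
#' @export
applyIntervention <- function(net, support, z) {
  if (!length(support)) return(net)
  stopifnot(all(support %in% net@nodes))
  if (length(z) == 1L && is.null(names(z)))
    z <- stats::setNames(rep(as.integer(z), length(support)), support)
  stopifnot(all(support %in% names(z)))
  rules <- net@rules[setdiff(names(net@rules), support)]
  inputs <- union(net@inputs, support)
  defaults <- net@inputDefaults
  defaults[support] <- as.integer(z[support])
  inputs <- intersect(net@nodes, inputs)   # keep node order
  new("BooleanNetwork", nodes = net@nodes, rules = rules,
      inputs = inputs, inputDefaults = defaults[inputs])
}

#' Iterate the synchronous update to a fixed point
#'
#' Starts from \code{state} (default: inputs at their defaults, all other
#' nodes 0) and applies [synchronousStep()] until the state repeats or
#' \code{maxIter} is reached.
#'
#' @inheritParams synchronousStep
#' @param state optional starting state; defaults to inputs-at-defaults.
#' @param maxIter iteration cap (default \code{2 * n + 2}).
#' @return the fixed point reached, or NULL if the trajectory did not
#'   converge (e.g. entered a cycle).
#' @export
simulateToFixedPoint <- function(net, state = NULL, maxIter = NULL) {
  n <- length(net@nodes)
  if (is.null(maxIter)) maxIter <- 2L * n + 2L
  if (is.null(state)) {
    state <- stats::setNames(integer(n), net@nodes)
    state[net@inputs] <- net@inputDefaults[net@inputs]
  }
  s <- state[net@nodes]
  for (i in seq_len(maxIter)) {
    nxt <- synchronousStep(net, s)
    if (identical(as.integer(nxt), as.integer(s))) return(s)
    s <- nxt
  }
  NULL
}

#' Shared nodes of two networks
#'
#' The exact, case-sensitive intersection of the two node-name sets;
#' cross-network identity is by name only.
#'
#' @param a,b [BooleanNetwork-class] objects.
#' @return character vector.
#' @export
sharedNodes <- function(a, b) intersect(a@nodes, b@nodes)

#' Construct a network pair
#'
#' @param a,b [BooleanNetwork-class] objects (A: pathological, B: healthy).
#' @return a [NetworkPair-class]; the shared node set is computed, never
#'   user-asserted.
#' @export
NetworkPair <- function(a, b)
  new("NetworkPair", netA = a, netB = b, shared = sharedNodes(a, b))

## ---- serialization -----------------------------------------------------

## Render a circuit back into the rule dialect, parenthesising by
## precedence (NOT > AND > OR).
circuitToExpression <- function(circ) {
  txt <- list(); prec <- list()
  ref <- function(r, need) {
    if (is.null(txt[[r]])) return(r)            # node name: atomic
    s <- txt[[r]]
    if (prec[[r]] < need) paste0("(", s, ")") else s
  }
  for (g in circ$gates) {
    out <- switch(g$kind,
      CONST   = list(as.character(g$value), 3L),
      LITERAL = list(ref(g$inputs, 0L),
                     if (is.null(prec[[g$inputs]])) 3L else prec[[g$inputs]]),
      NOT     = list(paste0("!", ref(g$inputs, 3L)), 3L),
      AND     = list(paste(vapply(g$inputs, ref, character(1), need = 2L),
                           collapse = " & "), 2L),
      OR      = list(paste(vapply(g$inputs, ref, character(1), need = 1L),
                           collapse = " | "), 1L))
    txt[[g$id]] <- out[[1]]; prec[[g$id]] <- out[[2]]
  }
  txt[[circ$output]]
}

#' Serialize a network to rule text
#'
#' Writes the network in the same dialect [parseRules()] reads; parsing the
#' result yields a network with identical truth tables for every node.
#'
#' @param net a [BooleanNetwork-class].
#' @return character vector of lines.
#' @export
serializeRules <- function(net) {
  c(sprintf("input %s = %d", net@inputs, net@inputDefaults[net@inputs]),
    vapply(names(net@rules), function(nm)
      sprintf("%s = %s", nm, circuitToExpression(net@rules[[nm]])),
      character(1)))
}

#' Write a network to a rule file
#' @param net a [BooleanNetwork-class].
#' @param path file path.
#' @return invisibly, \code{path}.
#' @export
writeRules <- function(net, path) {
  writeLines(serializeRules(net), path)
  invisible(path)
}

#' JSON serialization of a Boolean network
#'
#' A programmatic exchange format: node list, input defaults, and rules as
#' expression strings in the rule dialect.
#'
#' @param net a [BooleanNetwork-class].
#' @return a JSON string.
#' @export
networkToJSON <- function(net) {
  rules <- vapply(names(net@rules), function(nm)
    circuitToExpression(net@rules[[nm]]), character(1))
  jsonlite::toJSON(list(
    nodes = net@nodes,
    inputs = net@inputs,
    input_defaults = as.list(stats::setNames(as.integer(net@inputDefaults),
                                             names(net@inputDefaults))),
    rules = as.list(rules)), auto_unbox = TRUE, pretty = TRUE)
}

#' @rdname networkToJSON
#' @param json JSON string produced by [networkToJSON()].
#' @export
networkFromJSON <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  txt <- c(sprintf("input %s = %d", obj$inputs,
                   as.integer(unlist(obj$input_defaults)[obj$inputs])),
           sprintf("%s = %s", names(obj$rules), unlist(obj$rules)))
  net <- parseRules(txt)
  ## restore original node order
  stopifnot(setequal(net@nodes, obj$nodes))
  net@nodes <- as.character(obj$nodes)
  validObject(net)
  net
}

## Truth table of one node's rule over all assignments of its regulators;
## used by round-trip tests and kept internal.
ruleRegulators <- function(net, node) {
  circ <- net@rules[[node]]
  refs <- unlist(lapply(circ$gates, `[[`, "inputs"))
  gateIds <- vapply(circ$gates, `[[`, character(1), "id")
  unique(setdiff(refs, gateIds))
}
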