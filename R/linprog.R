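#' @include AllClasses.R
NULL

## ---- incremental builder ----------------------------------------------
##
## Constructing a LinearProgram slot-by-slot is O(n^2) in R; encoders use
## this environment-based builder and freeze to the S4 class at the end.

lpBuilder <- function() {
  b <- new.env(parent = emptyenv())
  b$ids <- character(0); b$lb <- numeric(0); b$ub <- numeric(0)
  b$int <- logical(0)
  b$coefs <- list(); b$sense <- character(0); b$rhs <- numeric(0)
  b$obj <- numeric(0); b$dir <- "min"
  b
}

lpAddVar <- function(b, id, lb = 0, ub = 1, integer = TRUE) {
  b$ids <- c(b$ids, id)
  b$lb <- c(b$lb, lb); b$ub <- c(b$ub, ub); b$int <- c(b$int, integer)
  id
}

lpAddConstr <- function(b, coefs, sense, rhs) {
  n <- length(b$coefs)
  b$coefs[[n + 1L]] <- coefs
  b$sense <- c(b$sense, sense)
  b$rhs <- c(b$rhs, rhs)
  invisible(b)
}

lpSetObjective <- function(b, coefs, direction = "min") {
  b$obj <- coefs; b$dir <- direction
  invisible(b)
}

lpBuild <- function(b) {
  new("LinearProgram", varIds = b$ids, lb = b$lb, ub = b$ub, isInt = b$int,
      constrMat = b$coefs, sense = b$sense, rhs = b$rhs,
      objective = b$obj, direction = b$dir)
}

#' Construct a linear program directly
#'
#' @param varIds character vector of variable ids.
#' @param lb,ub numeric bounds (recycled).
#' @param isInt logical, integer (binary) flags (recycled).
#' @param constraints list of \code{list(coefs, sense, rhs)} where
#'   \code{coefs} is a named numeric vector.
#' @param objective named numeric vector.
#' @param direction \code{"min"} or \code{"max"}.
#' @return a [LinearProgram-class].
#' @export
LinearProgram <- function(varIds, lb = 0, ub = 1, isInt = TRUE,
                          constraints = list(), objective = numeric(0),
                          direction = "min") {
  n <- length(varIds)
  new("LinearProgram", varIds = varIds,
      lb = rep_len(lb, n), ub = rep_len(ub, n), isInt = rep_len(isInt, n),
      constrMat = lapply(constraints, `[[`, "coefs"),
      sense = vapply(constraints, `[[`, character(1), "sense"),
      rhs = vapply(constraints, `[[`, numeric(1), "rhs"),
      objective = objective, direction = direction)
}

#' Append a constraint to a linear program
#'
#' Used by the enumeration machinery to add no-good (exclusion) cuts.
#'
#' @param lp a [LinearProgram-class].
#' @param coefs named numeric vector of coefficients.
#' @param sense \code{"<="}, \code{"="} or \code{">="}.
#' @param rhs numeric(1).
#' @return the extended [LinearProgram-class].
#' @export
lpAddConstraint <- function(lp, coefs, sense, rhs) {
  lp@constrMat <- c(lp@constrMat, list(coefs))
  lp@sense <- c(lp@sense, sense)
  lp@rhs <- c(lp@rhs, rhs)
  lp
}

#' Fix a variable to a value (or tighten its bounds)
#'
#' @param lp a [LinearProgram-class].
#' @param id variable id.
#' @param value numeric(1); both bounds are set to it.
#' @return the modified [LinearProgram-class].
#' @export
lpFixVar <- function(lp, id, value) {
  i <- match(id, lp@varIds)
  if (is.na(i)) stop("unknown variable id: ", id, call. = FALSE)
  lp@lb[i] <- value; lp@ub[i] <- value
  lp
}

#' Export a program in the LP file format
#'
#' Writes the model in the standard CPLEX-style LP text format with the
#' package's deterministic variable names, so it can be inspected or solved
#' with any external solver.
#'
#' @param lp a [LinearProgram-class].
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeLP <- function(lp, path) {
  term <- function(coefs) {
    if (!length(coefs)) return("0 dummy")
    paste(sprintf("%+g %s", unname(coefs), names(coefs)), collapse = " ")
  }
  con <- file(path, "w"); on.exit(close(con))
  writeLines(ifelse(lp@direction == "min", "Minimize", "Maximize"), con)
  writeLines(paste(" obj:", term(lp@objective)), con)
  writeLines("Subject To", con)
  senseTxt <- c("<=" = "<=", "=" = "=", ">=" = ">=")
  for (i in seq_along(lp@constrMat))
    writeLines(sprintf(" c%d: %s %s %g", i, term(lp@constrMat[[i]]),
                       senseTxt[[lp@sense[i]]], lp@rhs[i]), con)
  writeLines("Bounds", con)
  for (i in seq_along(lp@varIds))
    writeLines(sprintf(" %g <= %s <= %g", lp@lb[i], lp@varIds[i], lp@ub[i]),
               con)
  if (any(lp@isInt)) {
    writeLines("Binaries", con)
    writeLines(paste("", paste(lp@varIds[lp@isInt], collapse = " ")), con)
  }
  writeLines("End", con)
  invisible(path)
}
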