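#' @include AllClasses.R
NULL

#' Construct a stoichiometric model
#'
#' @param N numeric matrix (species x reactions); dimnames, if present,
#'   supply default species/reaction names.
#' @param species,reactions optional name vectors overriding the dimnames.
#' @param irreversible logical per reaction (default all TRUE).
#' @param boundary character vector of species exempt from balancing.
#' @return a [StoichiometricModel-class].
#' @export
StoichiometricModel <- function(N, species = rownames(N),
                                reactions = colnames(N),
                                irreversible = TRUE,
                                boundary = character(0)) {
  N <- as.matrix(N)
  if (is.null(species))
    species <- sprintf("M%d", seq_len(nrow(N)))
  if (is.null(reactions))
    reactions <- sprintf("R%d", seq_len(ncol(N)))
  dimnames(N) <- list(if (length(species)) species,
                      if (length(reactions)) reactions)
  new("StoichiometricModel", species = species, reactions = reactions,
      N = N, irreversible = rep_len(irreversible, ncol(N)),
      boundary = boundary)
}

#' Reaction names of a model
#' @param x a [StoichiometricModel-class].
#' @return character vector.
#' @export
setGeneric("reactionNames", function(x) standardGeneric("reactionNames"))

#' @rdname reactionNames
#' @export
setMethod("reactionNames", "StoichiometricModel", function(x) x@reactions)

#' Stoichiometric matrix of a model
#' @param x a [StoichiometricModel-class].
#' @return numeric matrix (species x reactions).
#' @export
setGeneric("stoichMatrix", function(x) standardGeneric("stoichMatrix"))

#' @rdname stoichMatrix
#' @export
setMethod("stoichMatrix", "StoichiometricModel", function(x) x@N)

## Split reversible reactions into irreversible forward/backward pairs.
## Returns list(model, map) where map has columns split, orig, dir and the
## split model is entirely irreversible.
splitReversible <- function(model) {
  rev <- which(!model@irreversible)
  if (!length(rev)) {
    map <- data.frame(split = model@reactions, orig = model@reactions,
                      dir = rep("+", length(model@reactions)),
                      stringsAsFactors = FALSE)
    return(list(model = model, map = map))
  }
  Nf <- model@N
  Nb <- -model@N[, rev, drop = FALSE]
  fNames <- model@reactions
  fNames[rev] <- paste0(model@reactions[rev], "_f")
  bNames <- paste0(model@reactions[rev], "_b")
  N2 <- cbind(Nf, Nb)
  colnames(N2) <- c(fNames, bNames)
  map <- data.frame(
    split = c(fNames, bNames),
    orig = c(model@reactions, model@reactions[rev]),
    dir = c(ifelse(seq_along(model@reactions) %in% rev, "+", "+"),
            rep("-", length(rev))),
    stringsAsFactors = FALSE)
  list(model = StoichiometricModel(N2, species = model@species,
                                   irreversible = TRUE,
                                   boundary = model@boundary),
       map = map)
}

## ---- text formats ------------------------------------------------------

parseEquation <- function(eq, lineNo = NA) {
  pos <- regexpr("->", eq, fixed = TRUE)
  if (pos == -1L)
    stop("cannot parse reaction equation '", eq, "'", call. = FALSE)
  sides <- c(substr(eq, 1L, pos - 1L), substring(eq, pos + 2L))
  parseSide <- function(s, sign) {
    s <- trimws(s)
    if (!nzchar(s)) return(stats::setNames(numeric(0), character(0)))
    terms <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
    out <- numeric(0)
    for (t in terms) {
      m <- regmatches(t, regexec("^([0-9.]+\\s+)?([A-Za-z0-9_.-]+)$", t))[[1]]
      if (!length(m))
        stop("cannot parse reaction term '", t, "'", call. = FALSE)
      coef <- if (nzchar(trimws(m[2]))) as.numeric(trimws(m[2])) else 1
      sp <- m[3]
      out[sp] <- (if (is.na(out[sp])) 0 else out[sp]) + sign * coef
    }
    out
  }
  lhs <- parseSide(sides[1], -1)
  rhs <- parseSide(sides[2], +1)
  both <- union(names(lhs), names(rhs))
  stats::setNames(
    vapply(both, function(sp) {
      v <- 0
      if (sp %in% names(lhs)) v <- v + lhs[[sp]]
      if (sp %in% names(rhs)) v <- v + rhs[[sp]]
      v
    }, numeric(1)), both)
}

#' Read a stoichiometric model from a reaction table
#'
#' Tab-separated file with header columns \code{reaction}, \code{equation}
#' and \code{irreversible}; equations are written \code{"A + 2 B -> C"}
#' (an empty side denotes an exchange reaction).  A comment line
#' \code{# boundary: A C} marks boundary species.
#'
#' @param path file path.
#' @return a [StoichiometricModel-class].
#' @export
readReactionTable <- function(path) {
  lines <- readLines(path, warn = FALSE)
  boundary <- character(0)
  bl <- grep("^#\\s*boundary:", lines, value = TRUE)
  if (length(bl))
    boundary <- strsplit(trimws(sub("^#\\s*boundary:", "", bl[1])),
                         "\\s+")[[1]]
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  tab <- utils::read.delim(text = paste(lines, collapse = "\n"),
                           stringsAsFactors = FALSE)
  need <- c("reaction", "equation", "irreversible")
  if (!all(need %in% names(tab)))
    stop("reaction table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  coefs <- lapply(tab$equation, parseEquation)
  species <- unique(unlist(lapply(coefs, names)))
  N <- matrix(0, length(species), nrow(tab),
              dimnames = list(species, tab$reaction))
  for (j in seq_along(coefs)) N[names(coefs[[j]]), j] <- coefs[[j]]
  StoichiometricModel(N, irreversible = as.logical(tab$irreversible),
                      boundary = intersect(boundary, species))
}

#' Write a stoichiometric model as a reaction table
#' @param model a [StoichiometricModel-class].
#' @param path file path.
#' @return invisibly, \code{path}.
#' @export
writeReactionTable <- function(model, path) {
  eqn <- vapply(seq_along(model@reactions), function(j) {
    col <- model@N[, j]
    side <- function(sel, sgn) {
      nm <- names(col)[sel]
      cf <- abs(col[sel])
      paste(ifelse(cf == 1, nm, paste(cf, nm)), collapse = " + ")
    }
    paste(side(col < 0), "->", side(col > 0))
  }, character(1))
  lines <- c(
    if (length(model@boundary))
      paste("# boundary:", paste(model@boundary, collapse = " ")),
    "reaction\tequation\tirreversible",
    sprintf("%s\t%s\t%s", model@reactions, trimws(eqn),
            model@irreversible))
  writeLines(lines, path)
  invisible(path)
}

#' Read a stoichiometric model from a dense matrix file
#'
#' Tab-separated numeric matrix with reaction names in the header and
#' species names in the first column; an optional leading comment line
#' \code{# boundary: ...} marks boundary species, and an optional
#' \code{# reversible: ...} line lists reversible reactions.
#'
#' @param path file path.
#' @return a [StoichiometricModel-class].
#' @export
readStoichMatrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  boundary <- character(0); reversible <- character(0)
  bl <- grep("^#\\s*boundary:", lines, value = TRUE)
  if (length(bl))
    boundary <- strsplit(trimws(sub("^#\\s*boundary:", "", bl[1])), "\\s+")[[1]]
  rl <- grep("^#\\s*reversible:", lines, value = TRUE)
  if (length(rl))
    reversible <- strsplit(trimws(sub("^#\\s*reversible:", "", rl[1])), "\\s+")[[1]]
  lines <- lines[!grepl("^\\s*#", lines)]
  tab <- utils::read.delim(text = paste(lines, collapse = "\n"),
                           row.names = 1, check.names = FALSE)
  N <- as.matrix(tab)
  StoichiometricModel(N, irreversible = !(colnames(N) %in% reversible),
                      boundary = intersect(boundary, rownames(N)))
}
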