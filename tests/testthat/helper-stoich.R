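# Random small stoichiometric models (all irreversible): a mix of
# exchange and internal conversion reactions over a handful of species.
randomStoichModel <- function(seed, nSpecies = 4, nReactions = 8) {
  set.seed(seed)
  sp <- paste0("S", seq_len(nSpecies))
  N <- matrix(0, nSpecies, nReactions,
              dimnames = list(sp, paste0("r", seq_len(nReactions))))
  for (j in seq_len(nReactions)) {
    u <- stats::runif(1)
    if (u < 0.2) {
      N[sample.int(nSpecies, 1), j] <- 1          # exchange in
    } else if (u < 0.4) {
      N[sample.int(nSpecies, 1), j] <- -1         # exchange out
    } else {
      ij <- sample.int(nSpecies, 2)
      N[ij[1], j] <- -1; N[ij[2], j] <- 1         # conversion
    }
  }
  StoichiometricModel(N)
}

emSupports <- function(ems) lapply(ems, `[[`, "support")

# Check the dual route: the support-minimality MILP must classify every
# feasible support exactly as the brute-force EM enumeration does
# (feasible supports are the supersets of EM supports; the minimal ones
# are the EMs themselves).
checkMinimalityAgreement <- function(model, bigM = 1000, epsTot = 1e-3) {
  rxns <- reactionNames(model)
  ems <- emSupports(enumerateEMsBruteForce(model, bigM = bigM,
                                           epsTot = epsTot))
  nOK <- 0L
  for (mask in seq_len(2^length(rxns)) - 1L) {
    S <- rxns[bitwAnd(mask, as.integer(2^(seq_along(rxns) - 1))) > 0L]
    if (!length(S)) next
    containsEM <- any(vapply(ems, function(e) all(e %in% S), logical(1)))
    if (!containsEM) next
    isEM <- any(vapply(ems, function(e) setequal(e, S), logical(1)))
    got <- supportMinimalityMILP(model, S, bigM = bigM, epsTot = epsTot)
    if (!identical(got, isEM))
      stop(sprintf("disagreement on {%s}: milp=%s em=%s",
                   paste(S, collapse = ","), got, isEM))
    nOK <- nOK + 1L
  }
  nOK
}
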