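## Dense two-phase primal simplex with Bland's anti-cycling rule.
##
## Solves   min c'x   s.t.  A x {<=,=,>=} b,  0 <= x <= ub
## for the small continuous subproblems of the flux-validation programs and
## for the LP relaxations inside the branch-and-bound solver.  Problem
## sizes here are tens of rows/columns, so a dense tableau is appropriate.
## Finite upper bounds are converted to explicit rows.

simplexSolve <- function(A, sense, b, cObj, ub = NULL, tol = 1e-9,
                         maxIter = 20000L) {
  A <- as.matrix(A)
  n <- ncol(A)
  if (n == 0L) {
    ok <- all((sense == "<=" & b >= -tol) | (sense == ">=" & b <= tol) |
              (sense == "=" & abs(b) <= tol))
    return(list(status = if (ok) "optimal" else "infeasible",
                x = numeric(0), obj = 0))
  }
  if (!is.null(ub)) {
    fin <- which(is.finite(ub))
    if (length(fin)) {
      rows <- matrix(0, length(fin), n)
      rows[cbind(seq_along(fin), fin)] <- 1
      A <- rbind(A, rows)
      sense <- c(sense, rep("<=", length(fin)))
      b <- c(b, ub[fin])
    }
  }
  m <- nrow(A)
  ## normalise rhs >= 0
  neg <- which(b < 0)
  if (length(neg)) {
    A[neg, ] <- -A[neg, , drop = FALSE]
    b[neg] <- -b[neg]
    sense[neg] <- c("<=" = ">=", ">=" = "<=", "=" = "=")[sense[neg]]
  }
  ## slack / surplus / artificial columns
  nSlack <- sum(sense == "<=")
  nSurp <- sum(sense == ">=")
  nArt <- sum(sense != "<=")
  Tm <- cbind(A, matrix(0, m, nSlack + nSurp + nArt))
  basis <- integer(m)
  sI <- n; pI <- n + nSlack; aI <- n + nSlack + nSurp
  for (i in seq_len(m)) {
    if (sense[i] == "<=") {
      sI <- sI + 1L; Tm[i, sI] <- 1; basis[i] <- sI
    } else if (sense[i] == ">=") {
      pI <- pI + 1L; Tm[i, pI] <- -1
      aI <- aI + 1L; Tm[i, aI] <- 1; basis[i] <- aI
    } else {
      aI <- aI + 1L; Tm[i, aI] <- 1; basis[i] <- aI
    }
  }
  nTot <- ncol(Tm)
  artCols <- seq.int(n + nSlack + nSurp + 1L, length.out = nArt)
  rhs <- b

  pivot <- function(r, j) {
    piv <- Tm[r, j]
    Tm[r, ] <<- Tm[r, ] / piv
    rhs[r] <<- rhs[r] / piv
    for (i in seq_len(m)) {
      if (i == r) next
      f <- Tm[i, j]
      if (abs(f) > 0) {
        Tm[i, ] <<- Tm[i, ] - f * Tm[r, ]
        rhs[i] <<- rhs[i] - f * rhs[r]
      }
    }
    basis[r] <<- j
  }

  runPhase <- function(cc, allowed) {
    iter <- 0L
    repeat {
      iter <- iter + 1L
      if (iter > maxIter) return("iteration-limit")
      cB <- cc[basis]
      red <- cc - as.vector(crossprod(Tm, cB))   # reduced costs
      red[!allowed] <- Inf
      ent <- which(red < -tol)
      if (!length(ent)) return("optimal")
      j <- ent[1L]                               # Bland: smallest index
      pos <- which(Tm[, j] > tol)
      if (!length(pos)) return("unbounded")
      ratio <- rhs[pos] / Tm[pos, j]
      best <- pos[ratio <= min(ratio) + tol]
      r <- best[which.min(basis[best])]          # Bland tie-break
      pivot(r, j)
    }
  }

  ## Phase 1: drive artificials to zero
  if (nArt) {
    c1 <- numeric(nTot); c1[artCols] <- 1
    st <- runPhase(c1, allowed = rep(TRUE, nTot))
    if (st != "optimal") return(list(status = "infeasible", x = NULL, obj = NA))
    if (sum(c1[basis] * rhs) > 1e-7)
      return(list(status = "infeasible", x = NULL, obj = NA))
    ## pivot any degenerate artificial out of the basis
    for (i in seq_len(m)) {
      if (basis[i] %in% artCols) {
        cand <- setdiff(which(abs(Tm[i, ]) > tol), artCols)
        if (length(cand)) pivot(i, cand[1L])
      }
    }
  }
  allowed <- rep(TRUE, nTot); allowed[artCols] <- FALSE
  c2 <- numeric(nTot); c2[seq_len(n)] <- cObj
  st <- runPhase(c2, allowed)
  if (st == "unbounded") return(list(status = "unbounded", x = NULL, obj = NA))
  if (st != "optimal") return(list(status = "infeasible", x = NULL, obj = NA))
  x <- numeric(nTot)
  x[basis] <- rhs
  xs <- x[seq_len(n)]
  list(status = "optimal", x = xs, obj = sum(cObj * xs))
}
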