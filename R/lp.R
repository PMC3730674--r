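## Linear programming layer.
##
## All optimizations in the package go through .solveLP(), which solves
##
##   max/min  c' x   s.t.  Aeq x = beq,  Aineq x <= bineq,  lb <= x <= ub
##
## The primary backend is a package-authored bounded-variable primal
## simplex (two-phase, dense) using Bland's anti-cycling rule, which makes
## termination certain and handles the heavily degenerate all-zero-RHS
## programs (steady-state constraints, goal programs) that this package
## produces. Small dilution coefficients can occasionally upset a pivot
## path, so on failure the same program is re-solved with an alternate LP
## method (pracma::linprog's Big-M simplex) before reporting failure.
## A solve counter supports auditing how many LPs an algorithm consumed.

.lpState <- new.env(parent = emptyenv())
.lpState$count <- 0L

#' Number of LP solves performed so far
#'
#' Diagnostic counter of LP-layer invocations (fallback retries within one
#' invocation are not counted separately). Useful to verify single-LP
#' guarantees, e.g. that [findUnblocked()] performs exactly one solve.
#'
#' @param reset reset the counter to zero.
#' @return integer count (before any reset).
#' @export
lpSolveCount <- function(reset = FALSE) {
  n <- .lpState$count
  if (reset) .lpState$count <- 0L
  n
}

## Bounded-variable primal simplex: max c'x s.t. Ax = b, lb <= x <= ub.
## The basic values are recomputed from the basis every iteration with one
## step of iterative refinement (never maintained incrementally), so the
## working point always is the true basic solution even when degenerate
## pivots leave the basis moderately ill-conditioned. Entering follows
## Bland's smallest-index rule (rotated under prolonged degenerate
## stalling); leaving pivots on the largest tied |element|, and an entering
## variable whose tied rows offer no pivot above tolPiv is rejected rather
## than allowed to make the basis numerically singular. Returns
## list(status = "optimal" | "infeasible" | "unbounded" | "maxit", x).
.simplexBounded <- function(cc, A, b, lb, ub, tol = 1e-9,
                            tolPiv = 1e-7, tolBound = 5e-9,
                            rule = c("bland", "dantzig"),
                            maxit = NULL) {
  rule <- match.arg(rule)
  m <- nrow(A); n <- ncol(A)
  if (is.null(maxit)) maxit <- 200L * (n + m) + 5000L

  ## artificials carry the same tight gate: any slack in them is equality
  ## violation of the original rows, the main leak channel
  tolBoundF <- rep_len(tolBound, n + m)
  ## phase-1 artificials: one per row, signed so the start is feasible
  x0 <- ifelse(is.finite(lb), lb, 0)
  r0 <- as.numeric(b - A %*% x0)
  sgn <- ifelse(r0 >= 0, 1, -1)
  Afull <- cbind(A, diag(sgn, nrow = m))
  lbF <- c(lb, rep(0, m))
  ubF <- c(ub, rep(Inf, m))
  basis <- n + seq_len(m)
  atUpper <- rep(FALSE, n + m)     # state of nonbasic variables

  ## solve with iterative refinement to convergence: refinement gains
  ## accuracy at rate cond(M)*eps per step, so even strongly
  ## ill-conditioned bases yield rounding-accurate solutions after a few
  ## iterations; NULL when the factorization fails outright
  refineSolve <- function(M, v) {
    z <- tryCatch(solve(M, v), error = function(e) NULL)
    if (is.null(z)) return(NULL)
    for (k in 1:5) {
      d <- tryCatch(solve(M, v - M %*% z), error = function(e) NULL)
      if (is.null(d)) break
      z <- z + d
      if (max(abs(d)) <= 1e-12 * (1 + max(abs(z)))) break
    }
    z
  }

  runPhase <- function(cvec, basis, atUpper, itBudget) {
    N <- length(cvec)
    it <- 0L
    stall <- 0L
    lastObj <- -Inf
    repeat {
      it <- it + 1L
      if (it > itBudget) return(list(status = "maxit"))
      B <- Afull[, basis, drop = FALSE]
      nonbasic <- setdiff(seq_len(N), basis)
      ## current vertex: nonbasic at their bounds, basic solved exactly
      xF <- numeric(N)
      xF[nonbasic] <- ifelse(atUpper[nonbasic], ubF[nonbasic],
                             lbF[nonbasic])
      rhs <- b - Afull[, nonbasic, drop = FALSE] %*% xF[nonbasic]
      xB <- refineSolve(B, rhs)
      if (is.null(xB)) return(list(status = "singular"))
      xF[basis] <- as.numeric(xB)

      y <- refineSolve(t(B), cvec[basis])
      if (is.null(y)) return(list(status = "singular"))
      dvec <- cvec[nonbasic] - as.numeric(crossprod(Afull[, nonbasic,
                                                          drop = FALSE], y))
      up <- atUpper[nonbasic]
      ## the entering threshold equals the pivot tolerance: reduced costs
      ## below it are epsilon-matrix arithmetic noise and admitting them
      ## causes degenerate two-cycles
      elig <- (!up & dvec > tolPiv) | (up & dvec < -tolPiv)
      ## skip fixed variables (lb == ub): they can never improve
      elig <- elig & (ubF[nonbasic] - lbF[nonbasic] > tol)
      if (!any(elig))
        return(list(status = "optimal", certified = TRUE, x = xF,
                    basis = basis, atUpper = atUpper))

      objNow <- sum(cvec * xF)
      if (objNow > lastObj + tol) { lastObj <- objNow; stall <- 0L }
      else stall <- stall + 1L
      sel <- sort(nonbasic[elig])
      ## entering order: Bland's smallest index, or Dantzig's steepest
      ## reduced cost (an independent pivot path used to escape stalls);
      ## under prolonged degenerate stalling, rotate to break cycles
      if (rule == "dantzig")
        sel <- sel[order(-abs(dvec[match(sel, nonbasic)]))]
      if (stall > N && length(sel) > 1) {
        k <- 1 + it %% length(sel)
        sel <- c(sel[k:length(sel)], sel[seq_len(k - 1)])
      }
      pivoted <- FALSE
      for (e in sel) {
        sigma <- if (atUpper[e]) -1 else 1
        dir <- refineSolve(B, Afull[, e])
        if (is.null(dir)) return(list(status = "singular"))
        ## basic variable i changes by -sigma * dir_i per unit step
        chg <- -sigma * as.numeric(dir)
        lim <- rep(Inf, m)
        dec <- chg < -tol
        inc <- chg > tol
        lim[dec] <- (xF[basis[dec]] - lbF[basis[dec]]) / (-chg[dec])
        lim[inc] <- (ubF[basis[inc]] - xF[basis[inc]]) / chg[inc]
        ## a basic value marginally outside its bounds limits at zero (a
        ## degenerate pivot pulls it back), never at a negative step
        lim <- pmax(lim, 0)
        flipLim <- ubF[e] - lbF[e]
        theta <- min(lim, flipLim)
        if (!is.finite(theta)) return(list(status = "unbounded"))
        if (theta >= flipLim - tol && flipLim <= min(lim)) {
          atUpper[e] <- !atUpper[e]       # bound flip, basis unchanged
          pivoted <- TRUE
          break
        }
        ## leaving variable: among rows tied at the minimal ratio, pivot
        ## on the largest |element| for numerical stability; reject the
        ## entering variable when no tied row offers a pivot >= tolPiv
        cand <- which(lim <= theta + tol * (1 + abs(theta)))
        solid <- cand[abs(chg[cand]) >= tolPiv]
        if (length(solid) == 0) next
        ord <- if (stall > N) solid[order(basis[solid])]
               else solid[order(-abs(chg[solid]))]
        for (l in ord) {
          ## tentative pivot, verified: a noise-scale pivot element can
          ## leave a basis whose exact solution violates the bounds -- in
          ## that case undo and try the next candidate
          leavingVar <- basis[l]
          basis2 <- basis; basis2[l] <- e
          atUpper2 <- atUpper
          atUpper2[leavingVar] <- chg[l] > 0
          B2 <- Afull[, basis2, drop = FALSE]
          nb2 <- setdiff(seq_len(N), basis2)
          x2 <- numeric(N)
          x2[nb2] <- ifelse(atUpper2[nb2], ubF[nb2], lbF[nb2])
          rhs2 <- b - Afull[, nb2, drop = FALSE] %*% x2[nb2]
          ## solve with iterative refinement and require the refinement to
          ## have converged: an ill-conditioned basis is acceptable exactly
          ## when its solution is still computable to rounding accuracy
          ## (the forward error a residual check cannot see)
          xB2 <- tryCatch(solve(B2, rhs2), error = function(err) NULL)
          if (is.null(xB2)) next
          converged <- FALSE
          for (k in 1:6) {
            d <- tryCatch(solve(B2, rhs2 - B2 %*% xB2),
                          error = function(err) NULL)
            if (is.null(d)) break
            xB2 <- xB2 + d
            if (max(abs(d)) <= 1e-11) { converged <- TRUE; break }
          }
          if (!converged) next
          x2[basis2] <- as.numeric(xB2)
          ## the tolerance here is rounding-scale, deliberately: with
          ## dilution coefficients of order 1e-5 against bounds of order
          ## 1e3, even 1e-8 of bound violation can flip the optimum; it is
          ## per-variable so that callers can keep it meaningful in the
          ## original (pre-equilibration) units
          tolB <- tolBoundF * (1 + max(abs(xB2)))
          if (any(x2 - lbF < -tolB) ||
              any(x2 - pmin(ubF, .Machine$double.xmax) > tolB)) next
          basis <- basis2
          atUpper <- atUpper2
          pivoted <- TRUE
          break
        }
        if (pivoted) break
      }
      if (!pivoted)
        ## improving directions remain but every pivot was numerically
        ## unacceptable: the vertex is feasible yet possibly suboptimal,
        ## so flag it for cross-checking against the alternate backend
        return(list(status = "optimal", certified = FALSE, x = xF,
                    basis = basis, atUpper = atUpper))
    }
  }

  ## phase 1: drive artificial infeasibility to zero
  c1 <- c(rep(0, n), rep(-1, m))
  p1 <- runPhase(c1, basis, atUpper, maxit)
  if (!identical(p1$status, "optimal")) return(list(status = p1$status))
  if (sum(abs(p1$x[n + seq_len(m)])) > 1e-7)
    return(list(status = if (isTRUE(p1$certified)) "infeasible" else
      "stuck"))
  ## freeze artificials at zero for phase 2
  ubF[n + seq_len(m)] <- 0
  p2 <- runPhase(c(cc, rep(0, m)), p1$basis, p1$atUpper, maxit)
  if (!identical(p2$status, "optimal")) return(list(status = p2$status))
  list(status = "optimal", certified = isTRUE(p2$certified),
       x = p2$x[seq_len(n)])
}

.lpFeasible <- function(x, Aeq, beq, Aineq, bineq, lb, ub, tol = 1e-6) {
  if (is.null(x) || any(is.na(x))) return(FALSE)
  if (!is.null(Aeq) && nrow(Aeq) > 0 &&
      max(abs(Aeq %*% x - beq)) > tol * max(1, max(abs(beq)))) return(FALSE)
  if (!is.null(Aineq) && nrow(Aineq) > 0 &&
      max(Aineq %*% x - bineq) > tol) return(FALSE)
  if (min(x - lb) < -tol || max(x - ub) > tol) return(FALSE)
  TRUE
}

## Returns list(status = "optimal" | "infeasible" | "error",
##              objective, x). Infeasible -> objective NA.
.solveLP <- function(obj, Aeq = NULL, beq = NULL, Aineq = NULL,
                     bineq = NULL, lb = NULL, ub, maximize = TRUE) {
  .lpState$count <- .lpState$count + 1L
  n <- length(obj)
  if (is.null(lb)) lb <- rep(0, n)
  if (!is.null(Aeq)) { Aeq <- as.matrix(Aeq); storage.mode(Aeq) <- "double" }
  if (!is.null(Aineq)) { Aineq <- as.matrix(Aineq); storage.mode(Aineq) <- "double" }
  nIneq <- if (is.null(Aineq)) 0L else nrow(Aineq)

  ## standard form: slack per inequality row
  A <- rbind(
    if (nIneq > 0) cbind(Aineq, diag(nIneq)) else NULL,
    if (!is.null(Aeq)) cbind(Aeq, matrix(0, nrow(Aeq), nIneq)) else NULL)
  b <- c(bineq, beq)
  cc <- c(if (maximize) obj else -obj, rep(0, nIneq))
  ## equilibrate before solving: scale each variable by its finite upper
  ## bound and each row to unit maximum magnitude. The raw systems mix
  ## dilution coefficients (~1e-5) with flux caps (~1e3); without scaling,
  ## their bases are so ill-conditioned that rounding-level infeasibility
  ## can flip an optimum
  lbAll <- c(lb, rep(0, nIneq))
  ubAll <- c(ub, rep(Inf, nIneq))
  colS <- ifelse(is.finite(ubAll) & ubAll > 0, ubAll, 1)
  As <- sweep(A, 2, colS, `*`)
  rowS <- rep(1, nrow(As))
  ## Ruiz iterations: alternately pull every row and column maximum toward
  ## one; a single pass leaves the delta-coupling rows at ~1e-6
  for (pass in 1:4) {
    r <- sqrt(apply(abs(As), 1, max)); r[r == 0] <- 1
    As <- sweep(As, 1, r, `/`); rowS <- rowS * r
    cs <- sqrt(apply(abs(As), 2, max)); cs[cs == 0] <- 1
    As <- sweep(As, 2, cs, `/`); colS <- colS / cs
  }
  ## bound-violation gate in scaled units: refined solves are accurate to
  ## ~1e-13 there, and 1e-12 scaled stays below the ~1e-8 flux-unit level
  ## at which leakage through near-infeasibility can flip an optimum
  res <- .simplexBounded(cc * colS, As, b / rowS,
                         lb = lbAll / colS, ub = ubAll / colS,
                         tolBound = 5e-12)
  if (!is.null(res$x)) res$x <- res$x * colS
  own <- NULL
  if (identical(res$status, "optimal")) {
    x <- res$x[seq_len(n)]
    if (.lpFeasible(x, Aeq, beq, Aineq, bineq, lb, ub)) {
      own <- list(status = "optimal", objective = sum(obj * x), x = x)
      if (isTRUE(res$certified)) return(own)
      ## uncertified vertex (termination by pivot rejection): feasible but
      ## possibly suboptimal. Retry along independent pivot paths -- the
      ## Dantzig rule, and a deterministic sub-tolerance jitter of the
      ## finite upper bounds that separates degenerate vertices -- and
      ## keep the best feasible answer.
      jit <- 3e-8 * (1 + (seq_along(ubAll) * 7L) %% 13L)
      ubJ <- ifelse(is.finite(ubAll), (ubAll + jit) / colS, Inf)
      trials <- list(
        list(ub = ubAll / colS, rule = "dantzig"),
        list(ub = ubJ, rule = "bland"),
        list(ub = ubJ, rule = "dantzig"))
      for (tr in trials) {
        resT <- .simplexBounded(cc * colS, As, b / rowS,
                                lb = lbAll / colS, ub = tr$ub,
                                rule = tr$rule, tolBound = 5e-12)
        if (!identical(resT$status, "optimal")) next
        xT <- (resT$x * colS)[seq_len(n)]
        if (!.lpFeasible(xT, Aeq, beq, Aineq, bineq, lb, ub)) next
        oT <- sum(obj * xT)
        if (if (maximize) oT > own$objective else oT < own$objective)
          own <- list(status = "optimal", objective = oT, x = xT)
        if (isTRUE(resT$certified)) return(own)
      }
      ## fall through and compare against the alternate backend as well
    }
  }
  if (identical(res$status, "infeasible"))
    return(list(status = "infeasible", objective = NA_real_, x = NULL))

  ## alternate LP method: pracma's Big-M simplex (different pivot path).
  ## pracma's .lp.create indexes into which(lb > 0) without guarding the
  ## empty case, so an all-zero lb must be passed as NULL.
  m <- nIneq + (if (is.null(Aeq)) 0 else nrow(Aeq))
  iter <- max(5000L, 100L * (n + m))
  alt <- tryCatch(
    pracma::linprog(cc = obj, A = Aineq, b = bineq, Aeq = Aeq, beq = beq,
                    lb = if (any(lb > 0)) lb else NULL, ub = ub,
                    maxiter = iter, bigM = 1e6, maximize = maximize),
    error = function(e) list(errno = -99L, x = NA_real_))
  if (alt$errno == 1 && .lpFeasible(alt$x, Aeq, beq, Aineq, bineq, lb, ub)) {
    altRes <- list(status = "optimal", objective = sum(obj * alt$x),
                   x = alt$x)
    if (is.null(own)) return(altRes)
    better <- if (maximize) altRes$objective > own$objective else
      altRes$objective < own$objective
    return(if (better) altRes else own)
  }
  if (!is.null(own)) return(own)
  if (alt$errno %in% c(-2L, -4L))
    return(list(status = "infeasible", objective = NA_real_, x = NULL))
  list(status = "error", objective = NA_real_, x = NULL)
}
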