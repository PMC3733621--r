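#' Solve the steady state of a kinetic model
#'
#' Finds positive normalized concentrations c with \eqn{S r(c) = 0} over
#' the internal metabolites. The root search runs in log-concentration
#' coordinates (positivity is automatic) with a damped Newton iteration
#' started from c = 1 (conditions are perturbations of the reference
#' state, whose steady state is exactly c = 1). If the Newton iteration
#' stalls, the solver falls back to dynamic relaxation
#' (\code{\link{relaxToSteadyState}}) and then re-polishes the relaxed
#' state.
#'
#' @param model a \code{KineticModel}.
#' @param start optional named numeric of starting concentrations
#'   (default all 1).
#' @param boundary optional named numeric of boundary-species normalized
#'   concentrations (default 1), e.g. extracellular glucose.
#' @param tol residual tolerance relative to \code{max(1, max|v|)}
#'   (default 1e-9).
#' @param maxIter maximum Newton iterations (default 100).
#' @param fallback use dynamic relaxation if the root search stalls?
#' @param errorOnFail raise an error on nonconvergence (default) or return
#'   the best iterate with \code{converged = FALSE}?
#' @return a list of class \code{"steadyStateSolution"}: \code{c} (named
#'   concentrations), \code{r} (named rates), \code{residual_norm} (max
#'   absolute balance), \code{converged}, \code{iterations}.
#' @export
solveSteadyState <- function(model, start = NULL, boundary = NULL,
                             tol = 1e-9, maxIter = 100L, fallback = TRUE,
                             errorOnFail = TRUE) {
  cp <- model@compiled
  n <- length(cp$intIdx)
  bFull <- boundaryTemplate(model, boundary)
  vScale <- max(1, max(abs(cp$v)))
  atol <- tol * vScale

  x <- rep(0, n)
  if (!is.null(start)) {
    idx <- match(cp$intIds, names(start))
    x[!is.na(idx)] <- log(start[idx[!is.na(idx)]])
  }

  res <- newtonLog(model, x, bFull, atol, maxIter)
  if (!res$converged && fallback) {
    rel <- tryCatch(
      relaxCore(model, exp(res$x), bFull, horizon = 1e5,
                dcTol = atol * 1e-2),
      error = function(e) NULL)
    if (!is.null(rel)) {
      res2 <- newtonLog(model, log(rel$cInt), bFull, atol, maxIter)
      if (res2$fnorm < res$fnorm) res <- res2
    }
  }
  if (!res$converged && errorOnFail) {
    cond <- structure(
      class = c("gmakin_nonconvergence", "error", "condition"),
      list(message = sprintf(
        "steady-state solver did not converge (residual %.3e > %.3e)",
        res$fnorm, atol),
        call = sys.call(-1),
        best = stats::setNames(exp(res$x), cp$intIds),
        residual_norm = res$fnorm))
    stop(cond)
  }
  makeSolution(model, exp(res$x), bFull, res$iter, res$fnorm, atol)
}

makeSolution <- function(model, cInt, bFull, iter, fnorm, atol) {
  cp <- model@compiled
  cFull <- bFull
  cFull[cp$intIdx] <- cInt
  r <- stats::setNames(rateKernel(model, cFull),
                       model@network@reactions$id)
  structure(list(
    c = stats::setNames(cInt, cp$intIds),
    r = r,
    residual_norm = fnorm,
    converged = fnorm <= atol,
    iterations = iter), class = "steadyStateSolution")
}

#' @export
print.steadyStateSolution <- function(x, ...) {
  cat("steadyStateSolution:", length(x$c), "metabolites;",
      if (x$converged) "converged" else "NOT converged",
      "in", x$iterations, "iterations; residual",
      format(x$residual_norm, digits = 3), "\n")
  invisible(x)
}

## damped Newton on F(x) = S r(exp(x)) in log space, finite-difference
## Jacobian, Levenberg regularization when near-singular, step cap 2 in
## log units per iteration
newtonLog <- function(model, x, bFull, atol, maxIter) {
  n <- length(x)
  F <- balanceKernel(model, exp(x), bFull)
  fnorm <- max(abs(F))
  best <- list(x = x, fnorm = fnorm, iter = 0L,
               converged = fnorm <= atol)
  if (best$converged) return(best)
  h <- 1e-7
  for (it in seq_len(maxIter)) {
    J <- matrix(0, n, n)
    for (j in seq_len(n)) {
      xj <- x; xj[j] <- xj[j] + h
      J[, j] <- (balanceKernel(model, exp(xj), bFull) - F) / h
    }
    p <- tryCatch(-solve(J, F), error = function(e) NULL)
    if (is.null(p) || anyNA(p)) {
      mu <- 1e-8 * max(abs(J))
      p <- tryCatch(-solve(J + diag(mu, n), F), error = function(e) NULL)
      if (is.null(p) || anyNA(p)) break
    }
    pmax_ <- max(abs(p))
    if (pmax_ > 2) p <- p * (2 / pmax_)
    t <- 1; ok <- FALSE
    for (ls in 1:30) {
      xn <- x + t * p
      Fn <- tryCatch(balanceKernel(model, exp(xn), bFull),
                     error = function(e) NULL)
      if (!is.null(Fn) && all(is.finite(Fn)) &&
          max(abs(Fn)) < fnorm * (1 - 1e-4 * t)) { ok <- TRUE; break }
      t <- t / 2
    }
    if (!ok) break
    x <- xn; F <- Fn; fnorm <- max(abs(F))
    if (fnorm < best$fnorm)
      best <- list(x = x, fnorm = fnorm, iter = it,
                   converged = fnorm <= atol)
    if (fnorm <= atol) break
  }
  best$iter <- max(best$iter, 1L)
  best
}

#' Relax a kinetic model to steady state by ODE integration
#'
#' Integrates \eqn{C \dot c = S r(c)} (in log-concentration coordinates,
#' which keeps concentrations positive) with a stiff integrator until the
#' concentration time-derivative falls below threshold or the horizon is
#' reached. Steady states do not depend on the normalization
#' concentrations C, which only set the relaxation time scales; C defaults
#' to 1. This is the package's independent cross-check for the Newton
#' root solver (and its fallback).
#'
#' @param model a \code{KineticModel}.
#' @param c0 named numeric starting concentrations (default all 1).
#' @param C optional named numeric of absolute normalization
#'   concentrations (default 1, or the network's \code{ref_conc} values
#'   where set if \code{C = "ref"}).
#' @param horizon integration horizon in model time units (default 1e5).
#' @param dcTol convergence threshold on \eqn{\max |\dot c|}
#'   (default 1e-11 scaled by \code{max(1, max|v|)}).
#' @param boundary optional boundary-species concentrations.
#' @return a \code{"steadyStateSolution"} (converged reflects the
#'   threshold).
#' @export
relaxToSteadyState <- function(model, c0 = NULL, C = NULL, horizon = 1e5,
                               dcTol = NULL, boundary = NULL) {
  cp <- model@compiled
  bFull <- boundaryTemplate(model, boundary)
  vScale <- max(1, max(abs(cp$v)))
  if (is.null(dcTol)) dcTol <- 1e-11 * vScale
  cInt <- rep(1, length(cp$intIdx))
  if (!is.null(c0)) {
    idx <- match(cp$intIds, names(c0))
    cInt[!is.na(idx)] <- c0[idx[!is.na(idx)]]
  }
  rel <- relaxCore(model, cInt, bFull, horizon, dcTol, C)
  atol <- 1e-9 * vScale
  makeSolution(model, rel$cInt, bFull, rel$steps, rel$fnorm, atol)
}

relaxCore <- function(model, cInt, bFull, horizon, dcTol, C = NULL) {
  cp <- model@compiled
  n <- length(cp$intIdx)
  Cvec <- rep(1, n)
  if (identical(C, "ref")) {
    rc <- model@network@metabolites$ref_conc[cp$intIdx]
    Cvec[!is.na(rc)] <- rc[!is.na(rc)]
  } else if (!is.null(C) && !identical(C, "ref")) {
    idx <- match(cp$intIds, names(C))
    Cvec[!is.na(idx)] <- C[idx[!is.na(idx)]]
  }
  deriv <- function(t, y, parms) {
    cc <- exp(y)
    f <- balanceKernel(model, cc, bFull)
    list(f / (Cvec * cc))
  }
  y <- log(cInt)
  tEnd <- 1; tTot <- 0; steps <- 0L
  repeat {
    out <- suppressWarnings(
      deSolve::lsoda(y, c(0, tEnd), deriv, parms = NULL,
                     rtol = 1e-10, atol = 1e-12, maxsteps = 20000))
    y <- as.numeric(out[nrow(out), -1])
    if (any(!is.finite(y)) || any(abs(y) > 50))
      stop("dynamic relaxation diverged (concentration out of bounds)")
    tTot <- tTot + tEnd
    steps <- steps + 1L
    cc <- exp(y)
    f <- balanceKernel(model, cc, bFull)
    dc <- max(abs(f / (Cvec * cc)))
    if (dc <= dcTol || tTot >= horizon) {
      return(list(cInt = cc, fnorm = max(abs(f)), steps = steps,
                  dc = dc))
    }
    tEnd <- min(tEnd * 10, horizon - tTot)
  }
}
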