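#' Chemostat setup
#'
#' Describes the continuous-culture context: imposed dilution rate D (at
#' steady state the growth rate must equal D or the culture washes out),
#' the feed glucose concentration (normalized; calibrated by
#' \code{\link{calibrateChemostat}} so that the reference condition gives
#' biomass X = 1 and extracellular glucose s = 1), the glucose uptake
#' reaction and the extracellular glucose species it consumes, and the
#' biomass floor below which the culture is declared washed out.
#'
#' @param dilutionRate imposed dilution rate D (> 0), per hour.
#' @param glucoseUptakeReaction reaction id of the glucose uptake step.
#' @param glucoseMet metabolite id of the extracellular glucose species
#'   (a boundary metabolite consumed by the uptake reaction).
#' @param feedGlucose normalized feed concentration (NA until calibrated).
#' @param biomassFloor fraction of the reference biomass below which the
#'   culture counts as washed out (default 1e-3).
#' @return a list of class \code{"chemostatSetup"}.
#' @export
chemostatSetup <- function(dilutionRate, glucoseUptakeReaction, glucoseMet,
                           feedGlucose = NA_real_, biomassFloor = 1e-3) {
  stopifnot(dilutionRate > 0, biomassFloor > 0, biomassFloor < 1)
  structure(list(dilutionRate = dilutionRate,
                 glucoseUptakeReaction = glucoseUptakeReaction,
                 glucoseMet = glucoseMet,
                 feedGlucose = feedGlucose,
                 biomassFloor = biomassFloor),
            class = "chemostatSetup")
}

#' Calibrate a model and chemostat setup to the reference condition
#'
#' Sets the growth correction factor lambda so that the reference growth
#' rate equals the dilution rate, and the feed glucose concentration so
#' that the reference culture sits at biomass X = 1 and extracellular
#' glucose s = 1: \code{lambda = D / mu_raw(reference)} and
#' \code{feed = 1 + q_glc,ref / D}. After calibration,
#' \code{\link{simulateChemostat}} on the unstressed model returns X = 1,
#' s = 1. Calibration is idempotent.
#'
#' @param model a \code{KineticModel} with a phi table (biomass drains).
#' @param setup a \code{\link{chemostatSetup}}.
#' @return list with elements \code{model} (lambda set), \code{setup}
#'   (feed set), \code{lambda}, \code{feedGlucose}.
#' @export
calibrateChemostat <- function(model, setup) {
  stopifnot(inherits(setup, "chemostatSetup"))
  k <- match(setup$glucoseUptakeReaction, model@network@reactions$id)
  if (is.na(k)) stop("unknown glucose uptake reaction: ",
                     setup$glucoseUptakeReaction)
  if (!(setup$glucoseMet %in% model@network@metabolites$id))
    stop("unknown extracellular glucose species: ", setup$glucoseMet)
  sol <- solveSteadyState(model)
  muRawUnit <- modelGrowthRate(model, sol$r) / model@params@lambda
  if (muRawUnit <= 0) stop("zero reference growth rate; cannot calibrate")
  lambda <- setup$dilutionRate / muRawUnit
  qRef <- abs(sol$r[setup$glucoseUptakeReaction])
  if (qRef <= 0) stop("zero reference glucose uptake; cannot calibrate")
  setup$feedGlucose <- 1 + qRef / setup$dilutionRate
  model@params@lambda <- lambda
  list(model = model, setup = setup, lambda = unname(lambda),
       feedGlucose = unname(setup$feedGlucose))
}

#' Simulate a chemostat culture at steady state
#'
#' Solves jointly for intracellular concentrations c, extracellular
#' glucose s and biomass X: the intracellular balances are zero given s,
#' the growth rate matches the dilution rate, \eqn{\mu(c(s)) = D}, and the
#' extracellular glucose balance closes,
#' \eqn{D (feed - s) = q_{glc}(s, c) X}. Only extracellular glucose is
#' environment-coupled; other exchange products are free sinks. If no
#' solution with biomass above the floor exists the culture is washed out
#' (X = 0).
#'
#' @param model a calibrated \code{KineticModel} (see
#'   \code{\link{calibrateChemostat}}).
#' @param setup a calibrated \code{\link{chemostatSetup}} (feed set).
#' @param sTol relative tolerance of the root search on s (default 1e-8).
#' @return a list of class \code{"chemostatSolution"}: \code{solution}
#'   (inner steady state), \code{biomass}, \code{extracellularGlucose},
#'   \code{growthRate}, \code{washedOut}.
#' @export
simulateChemostat <- function(model, setup, sTol = 1e-8) {
  stopifnot(inherits(setup, "chemostatSetup"))
  if (is.na(setup$feedGlucose))
    stop("chemostat setup is not calibrated (feedGlucose is NA); ",
         "run calibrateChemostat first")
  D <- setup$dilutionRate
  feed <- setup$feedGlucose
  glcMet <- setup$glucoseMet
  qRxn <- setup$glucoseUptakeReaction

  lastSol <- NULL
  innerSolve <- function(s) {
    b <- stats::setNames(s, glcMet)
    start <- if (is.null(lastSol)) NULL else lastSol$c
    ## a quick Newton failure is the washout signal here; skip the slow
    ## relaxation fallback
    sol <- solveSteadyState(model, start = start, boundary = b,
                            fallback = FALSE, errorOnFail = FALSE)
    if (sol$converged) lastSol <<- sol
    sol
  }
  ## growth excess over the dilution rate; a state where the inner solve
  ## fails counts as unable to sustain growth
  h <- function(s) {
    sol <- innerSolve(s)
    if (!sol$converged) return(-D)
    modelGrowthRate(model, sol$r) - D
  }

  washed <- function() {
    structure(list(solution = NULL, biomass = 0,
                   extracellularGlucose = feed, growthRate = NA_real_,
                   washedOut = TRUE), class = "chemostatSolution")
  }

  ## track the solution branch outward from the reference point s = 1
  ## (warm-started along the way), rather than jumping to extreme glucose
  ## concentrations where the inner solve is ill-conditioned
  sMin <- 1e-8 * feed
  s1 <- min(1, feed)
  h1 <- h(s1)
  if (abs(h1) <= 1e-7 * max(1, D)) {
    sStar <- s1            # calibrated reference point
  } else if (h1 > 0) {
    ## root below s = 1: shrink geometrically until growth falls short
    hi <- s1; hHi <- h1
    lo <- hi; hLo <- hHi
    repeat {
      lo <- lo / 1.4
      hLo <- h(lo)
      if (hLo < 0) break
      hi <- lo; hHi <- hLo
      if (lo <= sMin) break
    }
    sStar <- if (hLo >= 0) lo    # grows even at trace glucose
      else stats::uniroot(h, lower = lo, upper = hi, f.lower = hLo,
                          f.upper = hHi, tol = sTol * feed)$root
  } else {
    ## root above s = 1: expand geometrically toward the feed
    lo <- s1; hLo <- h1; hi <- lo
    repeat {
      if (hi >= feed) return(washed())
      hi <- min(hi * 1.4, feed)
      hHi <- h(hi)
      if (hHi >= 0) break
      lo <- hi; hLo <- hHi
    }
    sStar <- stats::uniroot(h, lower = lo, upper = hi, f.lower = hLo,
                            f.upper = hHi, tol = sTol * feed)$root
  }
  sol <- innerSolve(sStar)
  if (!sol$converged) return(washed())
  q <- abs(sol$r[qRxn])
  X <- if (q > 0) D * (feed - sStar) / q else 0
  if (!is.finite(X) || X < setup$biomassFloor) return(washed())
  structure(list(solution = sol, biomass = unname(X),
                 extracellularGlucose = unname(sStar),
                 growthRate = unname(modelGrowthRate(model, sol$r)),
                 washedOut = FALSE),
            class = "chemostatSolution")
}

#' @export
print.chemostatSolution <- function(x, ...) {
  if (x$washedOut) cat("chemostatSolution: washed out (X = 0)\n")
  else cat("chemostatSolution: X =", format(x$biomass, digits = 4),
           " s =", format(x$extracellularGlucose, digits = 4),
           " mu =", format(x$growthRate, digits = 4), "\n")
  invisible(x)
}
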