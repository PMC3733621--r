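#' Sum of squared errors of log concentration changes
#'
#' \eqn{\sum (\log c^{pred} - \log c^{obs})^2} over the metabolites shared
#' by both vectors. The inputs are normalized concentrations (ratios to
#' the reference condition), so the metric compares log fold-changes.
#'
#' @param predicted named positive numeric (predicted normalized
#'   concentrations).
#' @param observed named positive numeric (observed concentration ratios).
#' @return scalar SSE.
#' @export
sseLogConcentrations <- function(predicted, observed) {
  shared <- intersect(names(predicted), names(observed))
  if (!length(shared))
    stop("no shared metabolite ids between predicted and observed")
  if (any(predicted[shared] <= 0) || any(observed[shared] <= 0))
    stop("concentrations must be positive")
  sum((log(predicted[shared]) - log(observed[shared]))^2)
}

#' Normalized SSE of exchange fluxes
#'
#' Sum of squared errors between predicted and treated experimental
#' fluxes, normalized by the SSE between the reference and treated
#' experimental values over the same ids. A prediction that simply
#' reproduces the reference condition scores exactly 1.0; lower is closer
#' to the treated culture.
#'
#' @param predicted named numeric of predicted exchange fluxes (may
#'   include a biomass yield entry).
#' @param treated named numeric of experimental values for the treated
#'   culture.
#' @param reference named numeric of experimental values for the
#'   reference culture.
#' @return scalar normalized SSE.
#' @export
normalizedSSEFluxes <- function(predicted, treated, reference) {
  shared <- Reduce(intersect, list(names(predicted), names(treated),
                                   names(reference)))
  if (!length(shared)) stop("no shared flux ids")
  den <- sum((reference[shared] - treated[shared])^2)
  if (den == 0)
    stop("reference and treated experimental values coincide ",
         "(zero denominator)")
  sum((predicted[shared] - treated[shared])^2) / den
}

#' Pearson correlation between paired values
#'
#' @param x,y paired numeric vectors (matched by names when both are
#'   named, otherwise by position).
#' @param logScale compute the correlation of the logarithms (both
#'   vectors must then be positive)?
#' @return correlation coefficient.
#' @export
pearsonCorrelation <- function(x, y, logScale = FALSE) {
  if (!is.null(names(x)) && !is.null(names(y))) {
    shared <- intersect(names(x), names(y))
    x <- x[shared]; y <- y[shared]
  }
  if (length(x) < 3) stop("need at least 3 pairs")
  if (logScale) {
    if (any(x <= 0) || any(y <= 0))
      stop("log-scale correlation needs positive values")
    x <- log(x); y <- log(y)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in one of the inputs")
  stats::cor(x, y)
}

## golden-section minimization on [lo, hi]; returns list(x, f)
goldenSection <- function(f, lo, hi, tol = 1e-3) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
  f1 <- f(c1); f2 <- f(c2)
  while (b - a > tol) {
    if (f1 <= f2) { b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - gr * (b - a); f1 <- f(c1)
    } else { a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + gr * (b - a); f2 <- f(c2) }
  }
  if (f1 <= f2) list(x = c1, f = f1) else list(x = c2, f = f2)
}

#' Rank reactions by their ability to explain observed concentration
#' changes (mechanism-of-action analysis)
#'
#' Simulates the perturbation of each intracellular reaction, one at a
#' time (forward and backward rates of reversible reactions
#' individually), multiplying its rate by a constant within
#' \code{kBounds} chosen to minimize the SSE of the predicted vs observed
#' log concentration changes, and ranks the reactions by the minimized
#' SSE normalized by the unperturbed SSE. Perturbations that markedly
#' reduce the inconsistency between model and data point to modeling
#' omissions - candidate mechanisms of action of the applied stress.
#'
#' @param model baseline condition-specific \code{KineticModel}.
#' @param observed named positive numeric of observed concentration
#'   ratios.
#' @param kBounds factor interval searched (default \code{c(0.1, 10)});
#'   the search runs on the log scale (golden section, tolerance 1e-3 in
#'   log units) with factor 1 always admissible.
#' @param scope reaction ids to perturb; defaults to intracellular
#'   reactions (those not touching a boundary-role metabolite).
#' @return data.frame sorted by ascending \code{normalized_sse} (ties
#'   broken by reaction id, then direction): columns \code{reaction},
#'   \code{direction} (whole/forward/backward), \code{optimal_factor},
#'   \code{sse}, \code{normalized_sse}, \code{converged}. Perturbations
#'   whose re-solve failed are flagged and ranked last.
#' @export
rankTargets <- function(model, observed, kBounds = c(0.1, 10),
                        scope = NULL) {
  base <- solveSteadyState(model)
  if (!base$converged) stop("baseline model does not converge")
  baseSse <- sseLogConcentrations(base$c, observed)

  if (is.null(scope)) {
    met <- model@network@metabolites
    S <- model@network@stoich
    bnd <- met$role == "boundary"
    touches <- Matrix::colSums(abs(S[bnd, , drop = FALSE])) > 0
    scope <- model@network@reactions$id[!touches]
  }
  rxn <- model@network@reactions
  rows <- list()
  for (id in scope) {
    k <- match(id, rxn$id)
    if (is.na(k)) stop("scope names unknown reaction: ", id)
    dirs <- if (rxn$reversible[k]) c("forward", "backward") else "whole"
    for (dir in dirs) {
      obj <- function(t) {
        m <- perturbModel(model, id, dir, exp(t))
        sol <- solveSteadyState(m, start = base$c, errorOnFail = FALSE)
        if (!sol$converged) return(Inf)
        sseLogConcentrations(sol$c, observed)
      }
      opt <- goldenSection(obj, log(kBounds[1]), log(kBounds[2]),
                           tol = 1e-3)
      ## factor 1 (no perturbation) is always admissible; prefer it on ties
      if (baseSse <= opt$f + 1e-12) {
        kOpt <- 1; sse <- baseSse
      } else { kOpt <- exp(opt$x); sse <- opt$f }
      conv <- is.finite(sse)
      rows[[length(rows) + 1L]] <- data.frame(
        reaction = id, direction = dir,
        optimal_factor = if (conv) kOpt else NA_real_,
        sse = if (conv) sse else NA_real_,
        normalized_sse = if (!conv) NA_real_
          else if (baseSse == 0) 1 else sse / baseSse,
        converged = conv, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  ord <- order(!out$converged, out$normalized_sse, out$reaction,
               out$direction)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Coupled inhibition schedule for the histidine-starvation analysis
#'
#' The serine-to-glycine inhibition factor is varied linearly with the
#' histidine-synthesis inhibition factor, through the calibration points
#' (k_his = 1, k_ser_gly = 1) and (k_his = 0.487, k_ser_gly = 0.0227),
#' clipped below at a small positive floor.
#'
#' @param kHis histidine-synthesis inhibition factor in (0, 1].
#' @param floor lower clip (default 1e-6).
#' @return the coupled serine-to-glycine factor.
#' @export
inhibitionSchedule <- function(kHis, floor = 1e-6) {
  slope <- (1 - 0.0227) / (1 - 0.487)
  pmax(1 + slope * (kHis - 1), floor)
}

#' Maximum tolerated inhibition depth in a chemostat
#'
#' Bisects the inhibition factor k in [0, 1] applied by the model builder
#' for the washout boundary of the chemostat culture, and returns the
#' tolerated inhibition depth 1 - k* (0 = washes out at any inhibition,
#' 1 = survives complete inhibition).
#'
#' @param buildModel function(k) returning a calibrated
#'   \code{KineticModel} with inhibition level k applied (k = 1 no
#'   inhibition, 0 complete).
#' @param setup a calibrated \code{\link{chemostatSetup}}.
#' @param width bisection width on k (default 1e-3).
#' @return tolerated depth 1 - k* in [0, 1].
#' @export
toleranceInhibition <- function(buildModel, setup, width = 1e-3) {
  survives <- function(k)
    !simulateChemostat(buildModel(k), setup)$washedOut
  if (!survives(1)) {
    warning("culture washes out already without inhibition; tolerance 0",
            call. = FALSE)
    return(0)
  }
  if (survives(0)) return(1)
  lo <- 0; hi <- 1        # washout at lo, survival at hi
  while (hi - lo > width) {
    mid <- (lo + hi) / 2
    if (survives(mid)) hi <- mid else lo <- mid
  }
  1 - (lo + hi) / 2
}

#' Maximum tolerated WOA uptake rate in a chemostat
#'
#' Bisects the weak-organic-acid uptake rate for the point where the
#' steady-state biomass falls to \code{biomassFraction} of the reference
#' value (default 5 percent), the tolerance measure of the WOA analyses.
#'
#' @param buildModel function(w) returning a calibrated
#'   \code{KineticModel} with WOA uptake rate w.
#' @param setup a calibrated \code{\link{chemostatSetup}}.
#' @param biomassFraction biomass threshold as a fraction of reference
#'   (default 0.05).
#' @param width relative bisection width (default 1e-3).
#' @param wMax upper search bound for the uptake rate (bracket doubling
#'   starts at 1 and stops here; default 1e6).
#' @return tolerated uptake rate (0 when biomass is already below the
#'   threshold without stress).
#' @export
toleranceWOA <- function(buildModel, setup, biomassFraction = 0.05,
                         width = 1e-3, wMax = 1e6) {
  stopifnot(biomassFraction > 0, biomassFraction <= 1)
  X <- function(w) {
    cs <- simulateChemostat(buildModel(w), setup)
    if (cs$washedOut) 0 else cs$biomass
  }
  target <- biomassFraction
  x0 <- X(0)
  if (x0 <= target + 1e-12) {
    if (x0 < target - 1e-9)
      warning("biomass below threshold already without stress; ",
              "tolerance 0", call. = FALSE)
    return(0)
  }
  hi <- 1
  while (X(hi) > target && hi < wMax) hi <- hi * 2
  if (hi >= wMax)
    stop("no washout below uptake rate ", wMax)
  lo <- hi / 2
  if (X(lo) <= target) lo <- 0
  while ((hi - lo) > width * max(hi, 1)) {
    mid <- (lo + hi) / 2
    if (X(mid) > target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

## shared add-one-in / leave-one-out contribution algebra for NTC and NUC
normalizedContribution <- function(measure, g, subset) {
  gFull <- g
  gNone <- stats::setNames(rep(1, length(g)), names(g))
  gPlus <- gNone; gPlus[subset] <- gFull[subset]
  gMinus <- gFull; gMinus[subset] <- 1
  cache <- new.env(parent = emptyenv())
  m <- function(gs) {
    key <- paste(format(gs, digits = 17), collapse = ",")
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- measure(gs)
    cache[[key]] <- val
    val
  }
  tolGED <- m(gFull); tolNo <- m(gNone)
  delta <- tolGED - tolNo
  if (delta == 0)
    stop("expression changes do not alter the tolerance ",
         "(delta = 0); contribution metric undefined")
  plus <- m(gPlus) - tolNo
  minus <- tolGED - m(gMinus)
  0.5 * (plus + minus) / delta
}

#' Normalized tolerance change (NTC) of a reaction subset
#'
#' Quantifies the contribution of the expression changes of a subset of
#' reactions to the inhibition tolerance of the culture: the average of
#' the add-one-in change (tolerance with only the subset's expression
#' changes minus tolerance with none) and the leave-one-out change
#' (tolerance with all changes minus tolerance with all but the
#' subset's), normalized by the total expression-driven tolerance change.
#' Reactions with no expression change score exactly 0; the subset of all
#' changed reactions scores 1 by construction.
#'
#' @param buildModel function(g, k) returning a calibrated
#'   \code{KineticModel} with expression vector g and inhibition level k.
#' @param g named expression vector of the condition (GED scenario).
#' @param subset reaction ids whose contribution is scored (size 1 for
#'   per-reaction NTC; pairs/triplets probe coordinated regulation).
#' @param setup calibrated \code{\link{chemostatSetup}}.
#' @param width bisection width passed to
#'   \code{\link{toleranceInhibition}}.
#' @return scalar NTC.
#' @export
ntc <- function(buildModel, g, subset, setup, width = 1e-3) {
  stopifnot(all(subset %in% names(g)))
  normalizedContribution(
    function(gs) toleranceInhibition(function(k) buildModel(gs, k),
                                     setup, width = width),
    g, subset)
}

#' Normalized uptake change (NUC) of a reaction subset
#'
#' Same contribution algebra as \code{\link{ntc}}, with the tolerated
#' WOA uptake rate (\code{\link{toleranceWOA}}) as the underlying
#' tolerance measure.
#'
#' @param buildModel function(g, w) returning a calibrated
#'   \code{KineticModel} with expression vector g and WOA uptake rate w.
#' @param g named expression vector of the condition.
#' @param subset reaction ids to score.
#' @param setup calibrated \code{\link{chemostatSetup}}.
#' @param biomassFraction threshold for \code{\link{toleranceWOA}}.
#' @param width relative bisection width.
#' @return scalar NUC.
#' @export
nuc <- function(buildModel, g, subset, setup, biomassFraction = 0.05,
                width = 1e-3) {
  stopifnot(all(subset %in% names(g)))
  normalizedContribution(
    function(gs) toleranceWOA(function(w) buildModel(gs, w), setup,
                              biomassFraction = biomassFraction,
                              width = width),
    g, subset)
}

#' Biomass dose-response to WOA uptake
#'
#' Predicts the steady-state chemostat biomass over a grid of WOA uptake
#' rates for several expression scenarios: the measured expression
#' changes (GED), no expression changes (No GED), and log-scale
#' extrapolated expression changes (ratios raised to the given power).
#' Washout is encoded as biomass 0.
#'
#' @param buildModel function(g, w) returning a calibrated
#'   \code{KineticModel}.
#' @param g named expression vector of the condition.
#' @param uptakeGrid increasing grid of (normalized) WOA uptake rates.
#' @param setup calibrated \code{\link{chemostatSetup}}.
#' @param extrapolation log-scale extrapolation factor for the third
#'   scenario (default 2; NA skips it).
#' @return data.frame with columns \code{scenario}, \code{uptake},
#'   \code{biomass}.
#' @export
doseResponse <- function(buildModel, g, uptakeGrid, setup,
                         extrapolation = 2) {
  stopifnot(!is.unsorted(uptakeGrid))
  scen <- list(GED = g,
               NoGED = stats::setNames(rep(1, length(g)), names(g)))
  if (!is.na(extrapolation))
    scen[[paste0("extrapolated", extrapolation)]] <-
      extrapolateExpression(g, extrapolation)
  rows <- lapply(names(scen), function(nm) {
    gs <- scen[[nm]]
    X <- vapply(uptakeGrid, function(w) {
      cs <- simulateChemostat(buildModel(gs, w), setup)
      if (cs$washedOut) 0 else cs$biomass
    }, numeric(1))
    data.frame(scenario = nm, uptake = uptakeGrid, biomass = X,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Sweep model parameters and evaluate a prediction metric
#'
#' Rebuilds and evaluates the model over a finite parameter grid,
#' recording the metric value per grid point and flagging points of
#' nonconvergence with NA.
#'
#' @param buildModel function(row) taking one grid row (as a list) and
#'   returning a \code{KineticModel}.
#' @param grid data.frame, one column per swept parameter.
#' @param metric function(solution, model) returning a scalar, where
#'   \code{solution} is the steady-state solution of the built model.
#' @return \code{grid} with added columns \code{metric} and
#'   \code{converged}.
#' @export
sensitivitySweep <- function(buildModel, grid, metric) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1)
  vals <- numeric(nrow(grid)); conv <- logical(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    model <- buildModel(as.list(grid[i, , drop = FALSE]))
    sol <- solveSteadyState(model, errorOnFail = FALSE)
    conv[i] <- sol$converged
    vals[i] <- if (sol$converged) metric(sol, model) else NA_real_
  }
  grid$metric <- vals
  grid$converged <- conv
  grid
}
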