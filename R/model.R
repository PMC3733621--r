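#' Assemble a condition-specific kinetic model
#'
#' Translates a metabolic network plus reference flux distribution,
#' reaction-level expression ratios and rate parameters into a kinetic
#' model whose mass balances are \eqn{f(c) = S r(c)} over the internal
#' metabolites. By construction, with all normalized concentrations at 1,
#' g = 1, no inhibition and no WOA stress, \eqn{r(c) = v} exactly, so
#' c = 1 is the reference steady state whenever \eqn{S v = 0}.
#'
#' Inhibition factors multiply the entire rate of the named reaction
#' (factor 1 = no inhibition, 0 = complete). A positive WOA uptake adds a
#' fixed ATP consumption \code{atpPerWoa * woaUptake} to the ATP balance,
#' modeling the ATP-dependent export of protons and anions.
#'
#' @param network a \code{MetabolicNetwork}.
#' @param ref a \code{ReferenceState} covering every reaction (forward/
#'   backward splits are computed here from the betas in \code{params} if
#'   not already present).
#' @param g named numeric of reaction-level expression ratios; reactions
#'   not named default to 1. An \code{ExpressionVector} from
#'   \code{\link{aggregateExpression}} works directly.
#' @param params a \code{RateParameters}.
#' @return a \code{\linkS4class{KineticModel}}.
#' @export
assembleModel <- function(network, ref, g = numeric(0),
                          params = rateParameters()) {
  stopifnot(is(network, "MetabolicNetwork"), is(ref, "ReferenceState"),
            is(params, "RateParameters"))
  validObject(params)
  rxn <- network@reactions
  met <- network@metabolites
  nr <- nrow(rxn)

  miss <- setdiff(rxn$id, names(ref@v))
  if (length(miss))
    stop("reference state missing flux for reaction(s): ",
         paste(miss, collapse = ", "))
  v <- ref@v[rxn$id]

  gg <- stats::setNames(rep(1, nr), rxn$id)
  if (length(g)) {
    unknown <- setdiff(names(g), rxn$id)
    if (length(unknown))
      stop("expression ratio for unknown reaction(s): ",
           paste(unknown, collapse = ", "))
    if (any(g <= 0)) stop("expression ratios must be strictly positive")
    gg[names(g)] <- g
  }

  kInh <- stats::setNames(rep(1, nr), rxn$id)
  if (length(params@inhibition)) {
    unknown <- setdiff(names(params@inhibition), rxn$id)
    if (length(unknown))
      stop("inhibition factor for unknown reaction(s): ",
           paste(unknown, collapse = ", "))
    kInh[names(params@inhibition)] <- params@inhibition
  }
  if (length(params@betaOverrides)) {
    unknown <- setdiff(names(params@betaOverrides), rxn$id)
    if (length(unknown))
      stop("beta override for unknown reaction(s): ",
           paste(unknown, collapse = ", "))
  }

  irrev <- !rxn$reversible &
    rxn$class %in% c("mass_action_irreversible", "amino_acid_drain",
                     "generic_drain")
  if (any(v[irrev] < -1e-12 * max(1, max(abs(v)))))
    stop("negative reference flux on irreversible reaction(s): ",
         paste(rxn$id[irrev & v < 0], collapse = ", "))

  ## forward/backward split for reversible reactions
  betas <- stats::setNames(rep(params@beta, nr), rxn$id)
  betas[names(params@betaOverrides)] <- params@betaOverrides
  revSel <- rxn$class == "mass_action_reversible"
  vf <- numeric(nr); vb <- numeric(nr)
  if (any(revSel)) {
    sp <- splitReversible(v[revSel], betas[revSel])
    vf[revSel] <- sp$vf; vb[revSel] <- sp$vb
  }
  refSplit <- new("ReferenceState", v = v,
                  vf = stats::setNames(vf[revSel], rxn$id[revSel]),
                  vb = stats::setNames(vb[revSel], rxn$id[revSel]))

  ## exponent matrices (reactions x all metabolites): substrate and
  ## product kinetic orders, class-specific
  nm <- nrow(met)
  S <- network@stoich
  triS <- Matrix::summary(as(S, "TsparseMatrix"))
  subI <- integer(0); subJ <- integer(0); subX <- numeric(0)
  prdI <- integer(0); prdJ <- integer(0); prdX <- numeric(0)
  for (k in seq_len(nr)) {
    rows <- triS$i[triS$j == k]
    coefs <- triS$x[triS$j == k]
    if (!length(rows)) next
    st <- stats::setNames(coefs, met$id[rows])
    m <- kineticOrdersFor(network, k, st)
    cls <- rxn$class[k]
    isSub <- coefs < 0
    if (cls %in% c("amino_acid_drain", "generic_drain")) {
      subI <- c(subI, rep.int(k, sum(isSub)))
      subJ <- c(subJ, rows[isSub])
      subX <- c(subX, rep.int(params@alpha, sum(isSub)))
    } else if (cls != "fixed_exchange") {
      subI <- c(subI, rep.int(k, sum(isSub)))
      subJ <- c(subJ, rows[isSub])
      subX <- c(subX, unname(m[met$id[rows[isSub]]]))
      prdI <- c(prdI, rep.int(k, sum(!isSub)))
      prdJ <- c(prdJ, rows[!isSub])
      prdX <- c(prdX, unname(m[met$id[rows[!isSub]]]))
    }
  }
  Msub <- Matrix::sparseMatrix(i = subI, j = subJ, x = subX,
                               dims = c(nr, nm))
  Mprod <- Matrix::sparseMatrix(i = prdI, j = prdJ, x = prdX,
                                dims = c(nr, nm))

  intSel <- met$role == "internal"
  woaVec <- numeric(sum(intSel))
  names(woaVec) <- met$id[intSel]
  if (params@woaUptake > 0) {
    if (!(params@atpMet %in% met$id[intSel]))
      stop("WOA stress needs internal ATP species '", params@atpMet, "'")
    woaVec[params@atpMet] <- -params@atpPerWoa * params@woaUptake
  }

  if (any(rxn$class == "amino_acid_drain")) {
    if (!any(met$amino_acid))
      stop("amino_acid_drain reactions but no amino_acid-flagged metabolites")
    dr <- which(rxn$class %in% c("amino_acid_drain", "generic_drain"))
    missPhi <- setdiff(rxn$id[dr], names(params@phi))
    if (length(missPhi) && length(params@phi))
      warning("phi missing for drain(s): ",
              paste(missPhi, collapse = ", "), call. = FALSE)
  }

  compiled <- list(
    nr = nr, nm = nm,
    classes = rxn$class,
    gamma = as.numeric(rxn$gamma),
    v = unname(v), vfFull = vf, vbFull = vb,
    gVec = unname(gg), kI = unname(kInh),
    Msub = Msub, Mprod = Mprod,
    intIdx = which(intSel),
    intIds = met$id[intSel],
    metIds = met$id,
    aaIdx = which(met$amino_acid),
    alpha = params@alpha,
    Sint = S[intSel, , drop = FALSE],
    woaVec = woaVec,
    scale = rep(1, nr), scaleF = rep(1, nr), scaleB = rep(1, nr),
    isIrr = rxn$class == "mass_action_irreversible",
    isRev = revSel,
    isAAD = rxn$class == "amino_acid_drain",
    isGD  = rxn$class == "generic_drain",
    isFix = rxn$class == "fixed_exchange"
  )
  new("KineticModel", network = network, ref = refSplit, g = gg,
      params = params, compiled = compiled)
}

#' Evaluate the reaction rates of a kinetic model
#'
#' @param model a \code{KineticModel}.
#' @param conc named numeric of internal-metabolite normalized
#'   concentrations (default all 1).
#' @param boundary optional named numeric overriding boundary-species
#'   normalized concentrations (default 1), e.g. extracellular glucose in
#'   chemostat simulations.
#' @return named numeric vector of reaction rates.
#' @export
modelRates <- function(model, conc = NULL, boundary = NULL) {
  cp <- model@compiled
  cFull <- rep(1, cp$nm)
  if (!is.null(conc)) {
    idx <- match(names(conc), cp$metIds)
    if (anyNA(idx)) stop("unknown metabolite(s) in conc")
    cFull[idx] <- conc
  }
  if (!is.null(boundary)) {
    idx <- match(names(boundary), cp$metIds)
    if (anyNA(idx)) stop("unknown metabolite(s) in boundary")
    cFull[idx] <- boundary
  }
  if (any(cFull <= 0)) stop("nonpositive concentration")
  stats::setNames(rateKernel(model, cFull), model@network@reactions$id)
}

## fast path: cFull is the full concentration vector in metabolite order
rateKernel <- function(model, cFull) {
  cp <- model@compiled
  x <- log(cFull)
  la <- as.numeric(cp$Msub %*% x)
  lb <- as.numeric(cp$Mprod %*% x)
  base <- cp$kI * cp$gVec * cp$scale
  r <- numeric(cp$nr)
  if (any(cp$isIrr)) {
    s <- cp$isIrr
    r[s] <- base[s] * cp$v[s] * exp((la[s] - lb[s]) / cp$gamma[s])
  }
  if (any(cp$isRev)) {
    s <- cp$isRev
    r[s] <- base[s] * (cp$scaleF[s] * cp$vfFull[s] * exp(la[s]) -
                       cp$scaleB[s] * cp$vbFull[s] * exp(lb[s]))
  }
  if (any(cp$isAAD)) {
    s <- cp$isAAD
    if (!length(cp$aaIdx)) stop("amino_acid_drain without amino-acid set")
    mn <- min(cFull[cp$aaIdx])
    r[s] <- base[s] * cp$v[s] * exp(la[s]) * mn^cp$alpha
  }
  if (any(cp$isGD)) {
    s <- cp$isGD
    r[s] <- base[s] * cp$v[s] * exp(la[s])
  }
  if (any(cp$isFix)) {
    s <- cp$isFix
    r[s] <- base[s] * cp$v[s]
  }
  r
}

#' Evaluate the mass-balance residual of a kinetic model
#'
#' \eqn{f(c) = S r(c)} restricted to internal metabolites, plus the fixed
#' WOA ATP burden when active. Zero at a steady state.
#'
#' @inheritParams modelRates
#' @return named numeric vector over internal metabolites.
#' @export
modelBalance <- function(model, conc = NULL, boundary = NULL) {
  cp <- model@compiled
  cFull <- rep(1, cp$nm)
  if (!is.null(conc)) {
    idx <- match(names(conc), cp$metIds)
    if (anyNA(idx)) stop("unknown metabolite(s) in conc")
    cFull[idx] <- conc
  }
  if (!is.null(boundary)) {
    idx <- match(names(boundary), cp$metIds)
    if (anyNA(idx)) stop("unknown metabolite(s) in boundary")
    cFull[idx] <- boundary
  }
  r <- rateKernel(model, cFull)
  stats::setNames(as.numeric(cp$Sint %*% r) + unname(cp$woaVec), cp$intIds)
}

## internal fast balance over internal-concentration vector (ordered)
balanceKernel <- function(model, cInt, boundaryFull) {
  cp <- model@compiled
  cFull <- boundaryFull
  cFull[cp$intIdx] <- cInt
  as.numeric(cp$Sint %*% rateKernel(model, cFull)) + unname(cp$woaVec)
}

## full concentration template with boundary overrides applied
boundaryTemplate <- function(model, boundary = NULL) {
  cp <- model@compiled
  cFull <- rep(1, cp$nm)
  if (!is.null(boundary)) {
    idx <- match(names(boundary), cp$metIds)
    if (anyNA(idx)) stop("unknown metabolite(s) in boundary")
    cFull[idx] <- boundary
  }
  cFull
}

#' Growth rate of a model at given reaction rates
#'
#' Applies \code{\link{growthRate}} to the drain-flux entries (those with
#' a phi coefficient) of a rate vector.
#'
#' @param model a \code{KineticModel}.
#' @param rates named rate vector from \code{\link{modelRates}} (or a
#'   steady-state solution's rates).
#' @return scalar growth rate.
#' @export
modelGrowthRate <- function(model, rates) {
  phi <- model@params@phi
  if (!length(phi)) stop("model has no phi table (no biomass drains)")
  growthRate(rates[names(phi)], model@params)
}

## scale a reaction's rate: direction "whole" multiplies the full rate,
## "forward"/"backward" scale vf/vb individually (reversible only)
perturbModel <- function(model, reaction, direction = "whole", factor = 1) {
  k <- match(reaction, model@network@reactions$id)
  if (is.na(k)) stop("unknown reaction id: ", reaction)
  cp <- model@compiled
  if (direction == "whole") cp$scale[k] <- cp$scale[k] * factor
  else if (direction == "forward") cp$scaleF[k] <- cp$scaleF[k] * factor
  else if (direction == "backward") cp$scaleB[k] <- cp$scaleB[k] * factor
  else stop("direction must be whole/forward/backward")
  model@compiled <- cp
  model
}

#' @rdname referenceFluxes
#' @export
setMethod("referenceFluxes", "KineticModel", function(x) x@ref@v)

#' @rdname referenceFluxes
#' @export
setMethod("referenceFluxes", "ReferenceState", function(x) x@v)

#' Reference fluxes and expression ratios of a model
#'
#' @param x a \code{KineticModel} or \code{ReferenceState}.
#' @name referenceFluxes
NULL

#' @rdname expressionRatios
#' @export
setMethod("expressionRatios", "KineticModel", function(x) x@g)

#' Expression ratios of a model
#' @param x a \code{KineticModel}.
#' @name expressionRatios
NULL

#' @rdname rateParameters
#' @export
setMethod("rateParams", "KineticModel", function(x) x@params)

setMethod("show", "KineticModel", function(object) {
  cat("KineticModel:", object@compiled$nr, "reactions,",
      length(object@compiled$intIds), "internal metabolites\n")
  cat("  alpha =", object@params@alpha, " beta =", object@params@beta,
      " lambda =", object@params@lambda, "\n")
  ng <- sum(object@g != 1)
  cat("  expression ratios != 1:", ng,
      " inhibited reactions:", length(object@params@inhibition),
      " WOA uptake:", object@params@woaUptake, "\n")
})

#' Construct a ReferenceState
#'
#' @param v named numeric, reaction id -> reference flux.
#' @return a \code{ReferenceState} (splits filled at model assembly).
#' @export
referenceState <- function(v) {
  if (is.data.frame(v))
    v <- stats::setNames(as.numeric(v[[2]]), as.character(v[[1]]))
  new("ReferenceState", v = v)
}
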