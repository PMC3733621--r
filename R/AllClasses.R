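#' @import methods
#' @importFrom Matrix Matrix sparseMatrix t colSums rowSums drop0
NULL

KINETIC_CLASSES <- c("mass_action_irreversible", "mass_action_reversible",
                     "amino_acid_drain", "generic_drain", "fixed_exchange")

METABOLITE_ROLES <- c("internal", "boundary", "biomass-sink")

#' MetabolicNetwork: a metabolic network reconstruction
#'
#' Holds the metabolite table, the reaction table (reversibility, lumping
#' step count gamma, gene-protein-reaction rule, kinetic class), the full
#' stoichiometric matrix (metabolites x reactions, negative = consumed),
#' and optional per-reaction kinetic-order overrides. The stoichiometric
#' matrix used for mass balances is the restriction to metabolites of role
#' \code{"internal"}; boundary and biomass-sink species are open pools that
#' are excluded from steady-state balances.
#'
#' @slot metabolites data.frame with columns \code{id}, \code{name},
#'   \code{role} (one of internal/boundary/biomass-sink),
#'   \code{ref_conc} (absolute reference concentration, may be NA; only the
#'   dynamic-relaxation oracle uses it), \code{amino_acid} (logical flag
#'   marking the amino-acid pool used by the drain-rate coupling term).
#' @slot reactions data.frame with columns \code{id}, \code{reversible},
#'   \code{gamma} (number of irreversible steps lumped into the reaction;
#'   1 for individual reactions), \code{lumped}, \code{class} (kinetic
#'   class), \code{gpr} (gene association string, "" if none).
#' @slot stoich sparse Matrix, metabolites x reactions, signed coefficients.
#' @slot kineticOrders named list (by reaction id) of named numeric vectors
#'   (by metabolite id) overriding the default kinetic orders.
#'
#' @export
setClass("MetabolicNetwork",
  slots = c(
    metabolites  = "data.frame",
    reactions    = "data.frame",
    stoich       = "Matrix",
    kineticOrders = "list"
  )
)

setValidity("MetabolicNetwork", function(object) {
  rep <- validateNetworkCore(object)
  if (length(rep) == 0L) TRUE else paste(rep, collapse = "; ")
})

#' ReferenceState: reference flux distribution with forward/backward split
#'
#' The reference flux vector v over all reactions, plus (once a beta split
#' has been applied) the nonnegative forward and backward parts vf, vb of
#' each reversible reaction, satisfying vf - vb = v exactly.
#'
#' @slot v named numeric, reaction id -> reference flux.
#' @slot vf,vb named numeric over reversible reactions (may be empty before
#'   the split is applied).
#' @export
setClass("ReferenceState",
  slots = c(v = "numeric", vf = "numeric", vb = "numeric"),
  prototype = prototype(vf = numeric(0), vb = numeric(0))
)

setValidity("ReferenceState", function(object) {
  msgs <- character(0)
  if (is.null(names(object@v)) || anyDuplicated(names(object@v)))
    msgs <- c(msgs, "v must be named with unique reaction ids")
  if (length(object@vf) != length(object@vb))
    msgs <- c(msgs, "vf and vb must have equal length")
  if (length(object@vf)) {
    if (any(object@vf < 0) || any(object@vb < 0))
      msgs <- c(msgs, "vf and vb must be nonnegative")
    net <- object@v[names(object@vf)]
    if (any(abs(object@vf - object@vb - net) >
            1e-9 * pmax(1, abs(net))))
      msgs <- c(msgs, "vf - vb must equal v for every split reaction")
  }
  if (length(msgs) == 0L) TRUE else paste(msgs, collapse = "; ")
})

#' RateParameters: condition-specific model parameters
#'
#' The small set of fitting parameters of the kinetic rate laws.
#'
#' @slot alpha kinetic order of the biomass drain fluxes (default 0.1).
#' @slot beta global forward/backward split for reversible reactions
#'   (default 30; beta = 1 degenerates to an irreversible law).
#' @slot betaOverrides named numeric, reaction id -> beta, for reactions in
#'   reversible parallel routes whose betas must satisfy cycle-consistency.
#' @slot lambda growth-rate correction factor (default 1).
#' @slot xMW biomass molecular weight in normalized units (default 1).
#' @slot phi named numeric, drain reaction id -> moles carbon per mole of
#'   precursor, used by the growth rate.
#' @slot inhibition named numeric, reaction id -> multiplicative inhibition
#'   factor in (0, 1]; 1 = no inhibition, 0 = complete.
#' @slot woaUptake nonnegative weak-organic-acid uptake rate (imposes an
#'   ATP-consumption burden on the energy balance).
#' @slot atpPerWoa ATP consumed per unit WOA taken up (default 2: one ATP
#'   for proton export, one for anion export).
#' @slot atpMet metabolite id of the pooled ATP species (default "ATP").
#' @export
setClass("RateParameters",
  slots = c(
    alpha = "numeric", beta = "numeric", betaOverrides = "numeric",
    lambda = "numeric", xMW = "numeric", phi = "numeric",
    inhibition = "numeric", woaUptake = "numeric", atpPerWoa = "numeric",
    atpMet = "character"
  ),
  prototype = prototype(
    alpha = 0.1, beta = 30, betaOverrides = numeric(0), lambda = 1,
    xMW = 1, phi = numeric(0), inhibition = numeric(0), woaUptake = 0,
    atpPerWoa = 2, atpMet = "ATP"
  )
)

setValidity("RateParameters", function(object) {
  msgs <- character(0)
  if (object@alpha <= 0) msgs <- c(msgs, "alpha must be > 0")
  if (object@beta < 1) msgs <- c(msgs, "beta must be >= 1")
  if (length(object@betaOverrides) && any(object@betaOverrides < 1))
    msgs <- c(msgs, "beta overrides must be >= 1")
  if (object@lambda <= 0) msgs <- c(msgs, "lambda must be > 0")
  if (length(object@inhibition) &&
      (any(object@inhibition <= 0) || any(object@inhibition > 1)))
    msgs <- c(msgs, "inhibition factors must lie in (0, 1]")
  if (object@woaUptake < 0) msgs <- c(msgs, "woaUptake must be >= 0")
  if (object@atpPerWoa < 0) msgs <- c(msgs, "atpPerWoa must be >= 0")
  if (length(msgs) == 0L) TRUE else paste(msgs, collapse = "; ")
})

#' KineticModel: assembled condition-specific kinetic model
#'
#' The product of \code{\link{assembleModel}}: a network plus reference
#' state, reaction-level expression vector g, and rate parameters, compiled
#' into fast rate and balance evaluators. With all normalized concentrations
#' at 1, g = 1 and no stress, the rates reproduce the reference fluxes
#' exactly, so c = 1 is a steady state of the reference condition.
#'
#' @slot network a \code{MetabolicNetwork}.
#' @slot ref a \code{ReferenceState} (with forward/backward splits filled).
#' @slot g named numeric, reaction id -> overall expression ratio.
#' @slot params a \code{RateParameters}.
#' @slot compiled internal list of precomputed index structures.
#' @export
setClass("KineticModel",
  slots = c(
    network = "MetabolicNetwork",
    ref = "ReferenceState",
    g = "numeric",
    params = "RateParameters",
    compiled = "list"
  )
)
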