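#' Elementary kinetic rate laws
#'
#' The reduced generalized-mass-action rate expressions of the framework.
#' All concentrations are normalized to the reference condition, so the
#' laws are built to satisfy the reference identity: at c = 1 with g = 1
#' the rate equals the reference flux v exactly. Because enzyme abundance
#' multiplies every law, each rate is exactly linear in the overall
#' expression ratio g.
#'
#' \describe{
#' \item{irreversibleRate}{\eqn{r = v g (\prod_i [A_i]^{m_i} / \prod_j
#'   [B_j]^{m_j})^{1/\gamma}}. Products inhibit the rate so that reactions
#'   downstream of an irreversible step can still influence the pathway
#'   flux; the 1/gamma exponent (gamma = number of irreversible steps
#'   lumped into the reaction) damps the concentration sensitivity of
#'   lumped reactions, with the gamma -> Inf limit r -> v g.}
#' \item{reversibleRate}{\eqn{r = g (v^f \prod_i [A_i]^{m_i} - v^b \prod_j
#'   [B_j]^{m_j})} with the forward/backward parts from
#'   \code{\link{splitReversible}}.}
#' \item{aminoAcidDrainRate}{\eqn{r = v g \prod_i [A_i]^\alpha \,
#'   (\min_j [A_j])^\alpha} where i runs over the metabolites consumed by
#'   the drain (one amino acid and ATP) and j over \emph{all} amino acids:
#'   a low level of any amino acid slows protein synthesis and thereby
#'   every amino-acid drain.}
#' \item{genericDrainRate}{\eqn{r = v g \prod_i [A_i]^\alpha} over the
#'   consumed metabolites (lipid, carbohydrate, RNA and one-carbon
#'   drains).}
#' }
#'
#' @param reaction a reaction list as returned by \code{\link{getReaction}}
#'   (fields stoich, orders, gamma, class).
#' @param v nonnegative reference flux of the reaction.
#' @param g overall expression ratio (positive).
#' @param conc named numeric vector of normalized concentrations covering
#'   the reaction's metabolites (values must be positive).
#' @param vf,vb nonnegative forward and backward reference rates.
#' @param alpha drain kinetic order (small, default 0.1: drains have low
#'   sensitivity to precursor concentrations).
#' @param aminoAcids character vector of all amino-acid metabolite ids
#'   (for the min-coupling term); their concentrations must be present in
#'   \code{conc}.
#' @return the reaction rate (scalar).
#' @name rate-laws
NULL

checkConc <- function(conc, ids) {
  miss <- setdiff(ids, names(conc))
  if (length(miss))
    stop("missing concentration(s): ", paste(miss, collapse = ", "))
  if (any(conc[ids] <= 0))
    stop("nonpositive concentration(s): ",
         paste(ids[conc[ids] <= 0], collapse = ", "))
}

#' @rdname rate-laws
#' @export
irreversibleRate <- function(reaction, v, g, conc) {
  stopifnot(v >= 0, g > 0, reaction$gamma >= 1)
  st <- reaction$stoich
  m <- reaction$orders
  ids <- names(st)
  checkConc(conc, ids)
  sub <- ids[st < 0]
  prodm <- ids[st > 0]
  ratio <- prod(conc[sub]^m[sub]) / prod(conc[prodm]^m[prodm])
  v * g * ratio^(1 / reaction$gamma)
}

#' @rdname rate-laws
#' @export
splitReversible <- function(v, beta) {
  if (any(beta < 1)) stop("beta must be >= 1")
  ## v > 0: vf = beta v, vb = (beta-1) v. For v < 0 the printed assignment
  ## is applied to |v| (larger part backward) so that vf - vb = v and both
  ## parts stay nonnegative, preserving the reference identity r = v.
  av <- abs(v)
  vf <- ifelse(v >= 0, beta * av, (beta - 1) * av)
  vb <- vf - v
  list(vf = vf, vb = vb)
}

#' @rdname rate-laws
#' @export
reversibleRate <- function(reaction, vf, vb, g, conc) {
  stopifnot(vf >= 0, vb >= 0, g > 0)
  st <- reaction$stoich
  m <- reaction$orders
  ids <- names(st)
  checkConc(conc, ids)
  sub <- ids[st < 0]
  prodm <- ids[st > 0]
  g * (vf * prod(conc[sub]^m[sub]) - vb * prod(conc[prodm]^m[prodm]))
}

#' @rdname rate-laws
#' @export
aminoAcidDrainRate <- function(reaction, v, g, alpha, conc, aminoAcids) {
  stopifnot(v >= 0, g > 0, alpha > 0)
  if (length(aminoAcids) == 0)
    stop("amino_acid_drain rate requires a nonempty amino-acid set")
  st <- reaction$stoich
  consumed <- names(st)[st < 0]
  checkConc(conc, union(consumed, aminoAcids))
  v * g * prod(conc[consumed]^alpha) * min(conc[aminoAcids])^alpha
}

#' @rdname rate-laws
#' @export
genericDrainRate <- function(reaction, v, g, alpha, conc) {
  stopifnot(v >= 0, g > 0, alpha > 0)
  st <- reaction$stoich
  consumed <- names(st)[st < 0]
  checkConc(conc, consumed)
  v * g * prod(conc[consumed]^alpha)
}

#' Biomass growth rate from precursor drain rates
#'
#' \eqn{\mu = (\lambda / X_{MW}) \sum_i \phi_i r_i} over the biomass drain
#' fluxes only, where phi_i is the moles of carbon per mole of precursor
#' and lambda a correction factor (calibrated so the reference growth rate
#' matches the chemostat dilution rate; see
#' \code{\link{calibrateChemostat}}). Growth can stay positive even when
#' individual drains are zero.
#'
#' @param drainRates named numeric vector of drain-reaction rates.
#' @param params a \code{RateParameters} (slots lambda, xMW, phi).
#' @return growth rate (scalar, nonnegative at nonnegative drain rates).
#' @export
growthRate <- function(drainRates, params) {
  ids <- names(drainRates)
  miss <- setdiff(ids, names(params@phi))
  if (length(miss))
    stop("phi (carbon per precursor) missing for drain(s): ",
         paste(miss, collapse = ", "))
  (params@lambda / params@xMW) * sum(params@phi[ids] * drainRates)
}

#' Construct RateParameters
#'
#' @param alpha drain kinetic order (default 0.1).
#' @param beta global forward/backward split (default 30).
#' @param betaOverrides named numeric per-reaction beta overrides.
#' @param lambda growth correction factor (default 1).
#' @param xMW biomass molecular weight in normalized units (default 1).
#' @param phi named numeric, drain reaction id -> mol carbon per mol
#'   precursor.
#' @param inhibition named numeric inhibition factors in (0, 1].
#' @param woaUptake weak-organic-acid uptake rate (default 0).
#' @param atpPerWoa ATP cost per WOA taken up (default 2).
#' @param atpMet id of the pooled ATP species (default "ATP").
#' @return a validated \code{RateParameters}.
#' @export
rateParameters <- function(alpha = 0.1, beta = 30,
                           betaOverrides = numeric(0), lambda = 1, xMW = 1,
                           phi = numeric(0), inhibition = numeric(0),
                           woaUptake = 0, atpPerWoa = 2, atpMet = "ATP") {
  new("RateParameters", alpha = alpha, beta = beta,
      betaOverrides = betaOverrides, lambda = lambda, xMW = xMW, phi = phi,
      inhibition = inhibition, woaUptake = woaUptake,
      atpPerWoa = atpPerWoa, atpMet = atpMet)
}
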