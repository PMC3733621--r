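## Two-step product-inhibited chain E_ext -> A -> P_ext with unit orders;
## closed-form steady state: [A] = sqrt(g1/g2), flux = v * sqrt(g1 g2)
twoStepChain <- function(v = 3) {
  net <- MetabolicNetwork(
    metabolites = data.frame(id = c("E_ext", "A", "P_ext"),
                             role = c("boundary", "internal", "boundary")),
    reactions = data.frame(id = c("r1", "r2")),
    stoich = list(c(E_ext = -1, A = 1), c(A = -1, P_ext = 1)))
  list(network = net, ref = referenceState(c(r1 = v, r2 = v)), v = v)
}

## three-metabolite toy (A -> B, B -> C) used by the parser examples
threeMetToyTSV <- function(path) {
  writeLines(c("id\tequation\tgamma\tgpr\tclass",
               "r1\tA -> B\t1\t\tmass_action_irreversible",
               "r2\tB -> C_ext\t1\t\tmass_action_irreversible"),
             path)
  path
}

## reaction list for direct rate-law evaluation
plainReaction <- function(stoich, gamma = 1,
                          class = "mass_action_irreversible",
                          orders = NULL) {
  m <- ifelse(abs(stoich) == 2, 2, 1)
  names(m) <- names(stoich)
  if (!is.null(orders)) m[names(orders)] <- orders
  list(id = "rx", stoich = stoich, reversible = FALSE, gamma = gamma,
       class = class, orders = m)
}

## calibrated chemostat context on a toy fixture with drains
toyChemostat <- function(seed = 1, nDrains = 2, n = 6, D = 0.1) {
  fx <- makeToyNetwork("branched", n = n, nBranches = 1,
                       fractionReversible = 0, nDrains = nDrains,
                       seed = seed)
  params <- rateParameters(phi = fx$phi)
  m <- assembleModel(fx$network, fx$ref, params = params)
  setup <- chemostatSetup(dilutionRate = D,
                          glucoseUptakeReaction = "upt",
                          glucoseMet = "S_ext")
  cal <- calibrateChemostat(m, setup)
  c(fx, list(setup = cal$setup, lambda = cal$lambda, params = params))
}

## model builder over (expression vector, inhibition factor on reaction)
toyInhibitionFamily <- function(ctx, target) {
  function(g, k) {
    p <- ctx$params
    p@lambda <- ctx$lambda
    p@inhibition <- stats::setNames(max(k, 1e-9), target)
    assembleModel(ctx$network, ctx$ref, g, p)
  }
}

## model builder over (expression vector, WOA uptake rate)
toyWoaFamily <- function(ctx) {
  function(g, w) {
    p <- ctx$params
    p@lambda <- ctx$lambda
    p@woaUptake <- w
    assembleModel(ctx$network, ctx$ref, g, p)
  }
}

unitExpression <- function(network) {
  stats::setNames(rep(1, nrow(reactions(network))), reactionIds(network))
}
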