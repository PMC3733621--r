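test_that("log-concentration SSE matches hand arithmetic", {
  expect_equal(sseLogConcentrations(c(a = 1, b = 2), c(a = 1, b = 2)), 0)
  expect_equal(sseLogConcentrations(c(a = 2), c(a = 1)), log(2)^2)
  expect_error(sseLogConcentrations(c(a = 1), c(b = 1)), "shared")
})

test_that("normalized flux SSE is anchored at the reference prediction", {
  trt <- c(glc = 12, eth = 21, co2 = 22)
  ref <- c(glc = 6, eth = 10, co2 = 10)
  expect_equal(normalizedSSEFluxes(trt, trt, ref), 0)
  expect_equal(normalizedSSEFluxes(ref, trt, ref), 1)
  mid <- (trt + ref) / 2
  expect_equal(normalizedSSEFluxes(mid, trt, ref), 0.25)
  expect_error(normalizedSSEFluxes(trt, trt, trt), "denominator")
})

test_that("pearson correlation handles sign, log scale and degeneracy", {
  x <- c(1, 2, 3)
  expect_equal(pearsonCorrelation(x, 2 * x), 1)
  expect_equal(pearsonCorrelation(x, -x), -1)
  expect_equal(pearsonCorrelation(c(1, 2, 3), c(1, 2, 4)), 0.981,
               tolerance = 1e-3)
  expect_equal(pearsonCorrelation(c(1, 4, 9), c(1, 8, 27), logScale = TRUE),
               1)
  expect_error(pearsonCorrelation(c(1, 2), c(1, 2)), "3 pairs")
  expect_error(pearsonCorrelation(x, c(1, 1, 1)), "variance")
})

test_that("the coupled inhibition schedule interpolates its anchors", {
  expect_equal(inhibitionSchedule(1), 1)
  expect_equal(inhibitionSchedule(0.487), 0.0227, tolerance = 1e-12)
  expect_equal(inhibitionSchedule(0.7435), 0.51135, tolerance = 1e-12)
  expect_gte(inhibitionSchedule(0.1), 1e-6)   # clipped at the floor
})

test_that("ranking recovers a planted perturbation with its factor", {
  fx <- makeToyNetwork("branched", n = 6, nBranches = 2, seed = 21)
  cond <- makeCondition(fx$network, fx$ref, c(stp3 = 0.3), noiseCv = 0)
  m0 <- assembleModel(fx$network, fx$ref)
  rk <- rankTargets(m0, cond$observed$c)
  expect_equal(rk$reaction[1], "stp3")
  expect_equal(rk$optimal_factor[1], 0.3, tolerance = 5e-3)
  expect_lt(rk$normalized_sse[1], 0.05)
  expect_true(all(diff(rk$normalized_sse) >= -1e-12))
})

test_that("observations equal to baseline leave every factor at 1", {
  fx <- makeToyNetwork("branched", n = 5, seed = 22)
  m0 <- assembleModel(fx$network, fx$ref)
  base <- solveSteadyState(m0)
  rk <- rankTargets(m0, base$c)
  expect_true(all(rk$optimal_factor == 1))
  expect_true(all(rk$normalized_sse == 1))
})

test_that("reversible reactions are perturbed directionally", {
  fx <- makeToyNetwork("branched", n = 6, fractionReversible = 0.5,
                       seed = 23)
  cond <- makeCondition(fx$network, fx$ref, c(stp2 = 2), noiseCv = 0)
  m0 <- assembleModel(fx$network, fx$ref)
  rk <- rankTargets(m0, cond$observed$c)
  revIds <- reactions(fx$network)$id[reactions(fx$network)$reversible]
  revRows <- rk[rk$reaction %in% revIds, ]
  if (nrow(revRows))
    expect_setequal(unique(revRows$direction), c("forward", "backward"))
  irrRows <- rk[!rk$reaction %in% revIds, ]
  expect_true(all(irrRows$direction == "whole"))
})

test_that("inhibition tolerance is 1 when the target carries no flux", {
  ctx <- toyChemostat(seed = 5)
  ## a reaction with zero reference flux cannot couple to growth
  net <- ctx$network
  met <- metabolites(net)
  met <- rbind(met, data.frame(id = "Z_ext", name = "Z_ext",
                               role = "boundary", ref_conc = NA,
                               amino_acid = FALSE))
  rxn <- rbind(reactions(net),
               data.frame(id = "dead", reversible = FALSE, gamma = 1L,
                          lumped = FALSE,
                          class = "mass_action_irreversible", gpr = ""))
  sto <- c(lapply(reactionIds(net), function(id)
    getReaction(net, id)$stoich), list(c(M1 = -1, Z_ext = 1)))
  net2 <- MetabolicNetwork(met, rxn, sto)
  ref2 <- referenceState(c(ctx$ref@v, dead = 0))
  p <- rateParameters(phi = ctx$phi)
  m <- assembleModel(net2, ref2, params = p)
  setup <- chemostatSetup(0.1, "upt", "S_ext")
  cal <- calibrateChemostat(m, setup)
  build <- function(k) {
    pp <- p; pp@lambda <- cal$lambda
    pp@inhibition <- c(dead = max(k, 1e-9))
    assembleModel(net2, ref2, params = pp)
  }
  expect_equal(toleranceInhibition(build, cal$setup), 1)
})

test_that("inhibition tolerance grows with a compensating upregulation", {
  ctx <- toyChemostat(seed = 6)
  ## inhibit a biomass drain: its rate enters the growth sum directly,
  ## so the washout boundary responds strongly to k and to g
  target <- "drn1"
  family <- toyInhibitionFamily(ctx, target)
  gNone <- unitExpression(ctx$network)
  gComp <- gNone; gComp[target] <- 2   # upregulation of the target itself
  tolNone <- toleranceInhibition(function(k) family(gNone, k), ctx$setup)
  tolComp <- toleranceInhibition(function(k) family(gComp, k), ctx$setup)
  expect_gt(tolComp, tolNone + 1e-3)
  ## repeat run is identical to bisection width
  tolAgain <- toleranceInhibition(function(k) family(gNone, k), ctx$setup)
  expect_identical(tolNone, tolAgain)
})

test_that("NTC scores the null at 0 and the full subset at 1", {
  ctx <- toyChemostat(seed = 6)
  target <- "drn1"
  family <- toyInhibitionFamily(ctx, target)
  g <- unitExpression(ctx$network)
  g[target] <- 2
  g["stp1"] <- 1.3
  ## unchanged reaction scores exactly 0
  expect_identical(ntc(family, g, "stp4", ctx$setup), 0)
  ## full changed set scores exactly 1
  expect_identical(ntc(family, g, c(target, "stp1"), ctx$setup), 1)
  ## a reaction carrying the whole effect scores ~1 alone
  g2 <- unitExpression(ctx$network)
  g2[target] <- 2
  expect_equal(ntc(family, g2, target, ctx$setup), 1, tolerance = 1e-9)
})

test_that("WOA tolerance boundary scales inversely with the ATP cost", {
  ctx <- toyChemostat(seed = 7)
  makeBuild <- function(atpCost) {
    function(w) {
      p <- ctx$params; p@lambda <- ctx$lambda
      p@woaUptake <- w; p@atpPerWoa <- atpCost
      assembleModel(ctx$network, ctx$ref, params = p)
    }
  }
  t2 <- toleranceWOA(makeBuild(2), ctx$setup)
  t4 <- toleranceWOA(makeBuild(4), ctx$setup)
  expect_gt(t2, 0)
  expect_equal(t4 / t2, 0.5, tolerance = 5e-3)
  ## threshold at the reference biomass itself gives zero tolerance
  expect_equal(toleranceWOA(makeBuild(2), ctx$setup, biomassFraction = 1),
               0)
})

test_that("NUC nulls and dominant contributions mirror the NTC algebra", {
  ctx <- toyChemostat(seed = 8)
  family <- toyWoaFamily(ctx)
  gAtp <- unitExpression(ctx$network)
  gAtp["stp1"] <- 1.6              # boosts the ATP-producing step
  expect_identical(nuc(family, gAtp, "stp4", ctx$setup), 0)
  expect_equal(nuc(family, gAtp, "stp1", ctx$setup), 1, tolerance = 1e-9)
  ## upregulated uptake increases the tolerated WOA burden
  gUp <- unitExpression(ctx$network)
  gUp["upt"] <- 1.5
  wNone <- toleranceWOA(function(w) family(unitExpression(ctx$network), w),
                        ctx$setup)
  wUp <- toleranceWOA(function(w) family(gUp, w), ctx$setup)
  expect_gt(wUp, wNone)
})

test_that("dose-response curves fall with uptake and reward adaptation", {
  ctx <- toyChemostat(seed = 9)
  family <- toyWoaFamily(ctx)
  g <- unitExpression(ctx$network)
  g["stp1"] <- 1.5                 # relieves the ATP bottleneck
  grid <- c(0, 0.2, 0.4, 0.8, 1.6)
  dr <- doseResponse(family, g, grid, ctx$setup, extrapolation = 2)
  expect_setequal(unique(dr$scenario), c("GED", "NoGED", "extrapolated2"))
  for (sc in unique(dr$scenario)) {
    X <- dr$biomass[dr$scenario == sc]
    pk <- which.max(X)
    expect_true(all(diff(X[pk:length(X)]) <= 1e-8))
  }
  ## stronger (extrapolated) adaptation tolerates at least as much uptake
  lastAlive <- function(sc) {
    X <- dr$biomass[dr$scenario == sc]
    max(c(0, grid[X > 0.05]))
  }
  expect_gte(lastAlive("extrapolated2"), lastAlive("GED"))
  expect_gte(lastAlive("GED"), lastAlive("NoGED"))
})

test_that("sensitivity sweeps are deterministic and flag the beta axis", {
  fx <- makeToyNetwork("branched", n = 6, fractionReversible = 0.3,
                       seed = 24)
  cond <- makeCondition(fx$network, fx$ref, c(stp2 = 1.5), noiseCv = 0)
  grid <- data.frame(beta = c(2, 10, 30, 100, 30))
  build <- function(row)
    assembleModel(fx$network, fx$ref, cond$g,
                  params = rateParameters(beta = row$beta))
  sw <- sensitivitySweep(build, grid,
                         function(sol, model)
                           sseLogConcentrations(sol$c, cond$truth$c))
  expect_true(all(sw$converged))
  ## duplicate grid points give identical rows
  expect_identical(sw$metric[3], sw$metric[5])
  ## flux predictions are robust to beta on a cycle-free network
  expect_lt(max(sw$metric) - min(sw$metric), 0.05)
})
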