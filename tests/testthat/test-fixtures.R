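test_that("toy generation is pure and mass-consistent", {
  a <- makeToyNetwork("chain", n = 3, seed = 7)
  b <- makeToyNetwork("chain", n = 3, seed = 7)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  d <- makeToyNetwork("chain", n = 3, seed = 8)
  expect_false(identical(a$ref@v, d$ref@v))
  for (fx in list(a,
                  makeToyNetwork("diamond", seed = 1),
                  makeToyNetwork("branched", n = 7, nBranches = 2,
                                 nDrains = 3, fractionReversible = 0.3,
                                 seed = 5))) {
    expect_length(validateNetwork(fx$network), 0L)
    S <- as.matrix(stoichMatrix(fx$network))
    expect_lt(max(abs(S %*% fx$ref@v)), 1e-12)
    irr <- !reactions(fx$network)$reversible
    expect_true(all(fx$ref@v[irr] >= -1e-12))
  }
  expect_error(makeToyNetwork("diamond", n = 3), "n >= 4")
})

test_that("diamond topology exposes parallel routes to the beta logic", {
  fx <- makeToyNetwork("diamond", seed = 2)
  net <- fx$network
  net@reactions$reversible[2:5] <- TRUE
  net@reactions$class[2:5] <- "mass_action_reversible"
  ## both branches flow forward: the cycle ratio product is already 1,
  ## so detection leaves the global beta untouched without warnings
  expect_silent(ov <- assignBetas(net, fx$ref, 30))
  expect_length(ov, 0L)
  ## a branch running backward makes the product of ratios irreducible
  ## to 1 with beta >= 1: the cycle is detected and reported by name
  u <- unname(fx$ref@v["upt"])
  refBad <- referenceState(c(upt = u, br1a = u + 1, br2a = -1,
                             br1b = u + 1, br2b = -1, exp = u))
  expect_warning(ov2 <- assignBetas(net, refBad, 30), "br2")
  expect_length(ov2, 0L)
})

test_that("yeast-like fixture matches the published scale", {
  fx <- makeYeastLikeFixture()
  net <- fx$network
  expect_identical(length(internalMetabolites(net)), 75L)
  expect_identical(nrow(reactions(net)), 125L)
  gprs <- reactions(net)$gpr
  genes <- unique(unlist(lapply(gprs[nzchar(gprs)],
                                function(g) gprGenes(parseGPR(g)))))
  expect_identical(length(genes), 309L)
  expect_identical(sum(nzchar(gprs)), 96L)
  expect_equal(unname(fx$ref@v["GLCupt"]), 6.09, tolerance = 1e-9)
  expect_length(validateNetwork(net), 0L)
  ## structural features: lumped reactions, both drain classes
  expect_true(any(reactions(net)$gamma > 1))
  expect_true(any(reactions(net)$class == "amino_acid_drain"))
  expect_true(any(reactions(net)$class == "generic_drain"))
  ## the assembled model sits at the reference steady state
  m <- assembleModel(net, fx$ref, params = rateParameters(phi = fx$phi))
  sol <- solveSteadyState(m)
  expect_true(sol$converged)
  expect_equal(unname(sol$c), rep(1, 75))
})

test_that("lognormal noise has the requested log-scale spread", {
  vals <- rep(2, 1e4)
  noisy <- addNoise(vals, 0.1, seed = 3)
  expect_equal(stats::sd(log(noisy)), 0.1, tolerance = 0.02 * 0.1 + 3e-3)
  expect_identical(addNoise(vals, 0, seed = 3), vals)
  expect_identical(addNoise(vals, 0.1, seed = 3),
                   addNoise(vals, 0.1, seed = 3))
  ## additive flux noise keeps signs of magnitude and seeds determinism
  fl <- c(-2, 0.5, 4)
  n1 <- addNoise(fl, 0.05, seed = 4, type = "additive")
  expect_identical(n1, addNoise(fl, 0.05, seed = 4, type = "additive"))
  expect_false(identical(n1, fl))
})

test_that("condition generation returns exact truth and seeded noise", {
  fx <- makeToyNetwork("branched", n = 6, seed = 9)
  c0 <- makeCondition(fx$network, fx$ref, c(stp2 = 2), noiseCv = 0)
  expect_identical(c0$observed$c, c0$truth$c)
  m <- assembleModel(fx$network, fx$ref, c0$g)
  sol <- solveSteadyState(m)
  expect_equal(c0$truth$c, sol$c)
  c1 <- makeCondition(fx$network, fx$ref, c(stp2 = 2), seed = 5,
                      noiseCv = 0.1)
  c2 <- makeCondition(fx$network, fx$ref, c(stp2 = 2), seed = 5,
                      noiseCv = 0.1)
  expect_identical(c1$observed, c2$observed)
  expect_false(identical(c1$observed$c, c1$truth$c))
  ## empirical CV over replicates approaches the requested CV
  reps <- vapply(1:400, function(s)
    makeCondition(fx$network, fx$ref, c(stp2 = 2), seed = s,
                  noiseCv = 0.1)$observed$c[["M2"]], numeric(1))
  expect_lt(abs(stats::sd(log(reps)) - 0.1), 0.01)
})
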