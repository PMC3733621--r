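test_that("irreversible rate law matches hand evaluations", {
  rx <- plainReaction(c(A = -1, B = 1))
  conc <- c(A = 1, B = 1)
  expect_equal(irreversibleRate(rx, v = 2, g = 1, conc), 2)
  expect_equal(irreversibleRate(rx, v = 2, g = 1.5, conc), 3)
  rx2 <- plainReaction(c(A = -1, B = 1), gamma = 2)
  expect_equal(irreversibleRate(rx2, v = 2, g = 1, c(A = 4, B = 1)),
               2 * sqrt(4))
  ## monotone in substrate, antitone in product
  expect_gt(irreversibleRate(rx, 2, 1, c(A = 2, B = 1)),
            irreversibleRate(rx, 2, 1, c(A = 1, B = 1)))
  expect_lt(irreversibleRate(rx, 2, 1, c(A = 1, B = 2)),
            irreversibleRate(rx, 2, 1, c(A = 1, B = 1)))
  expect_error(irreversibleRate(rx, 2, 1, c(A = -1, B = 1)),
               "nonpositive")
})

test_that("the lumping exponent damps concentration sensitivity", {
  conc <- c(A = 3, B = 0.5)
  prev <- Inf
  for (gm in c(1, 2, 4, 8, 32, 128)) {
    rx <- plainReaction(c(A = -1, B = 1), gamma = gm)
    dev <- abs(irreversibleRate(rx, 2, 1.3, conc) - 2 * 1.3)
    expect_lte(dev, prev + 1e-12)
    prev <- dev
  }
  expect_lt(prev, 0.05)   # gamma -> Inf limit is v * g
})

test_that("reversible split conserves the net flux for any beta", {
  expect_equal(splitReversible(2, 30), list(vf = 60, vb = 58))
  expect_equal(splitReversible(0, 30), list(vf = 0, vb = 0))
  expect_equal(splitReversible(-2, 30), list(vf = 58, vb = 60))
  expect_error(splitReversible(2, 0.5), "beta")
  for (beta in c(1, 1.5, 30, 1e4)) {
    for (v in c(-7.3, -1, 0, 0.02, 5)) {
      sp <- splitReversible(v, beta)
      expect_lte(abs(sp$vf - sp$vb - v),
                 4e-16 * max(1, sp$vf, sp$vb))
      expect_gte(sp$vf, 0)
      expect_gte(sp$vb, 0)
    }
  }
})

test_that("reversible rate law reproduces the reference and can reverse", {
  rx <- plainReaction(c(A = -1, B = 1), class = "mass_action_reversible")
  sp <- splitReversible(2, 30)
  expect_equal(reversibleRate(rx, sp$vf, sp$vb, 1, c(A = 1, B = 1)), 2)
  expect_equal(reversibleRate(rx, sp$vf, sp$vb, 2, c(A = 1, B = 1)), 4)
  ## near-equilibrium reactions reverse easily at large beta
  expect_equal(reversibleRate(rx, sp$vf, sp$vb, 1, c(A = 1, B = 2)),
               60 - 58 * 2)
})

test_that("amino-acid drain couples to the scarcest amino acid", {
  rx <- plainReaction(c(AA1 = -1, ATP = -1, X_bio = 1),
                      class = "amino_acid_drain")
  aas <- c("AA1", "AA2")
  conc <- c(AA1 = 1, AA2 = 1, ATP = 1)
  expect_equal(aminoAcidDrainRate(rx, 4, 1.5, 0.1, conc, aas), 6)
  conc2 <- c(AA1 = 0.5, AA2 = 1, ATP = 1)
  expect_equal(aminoAcidDrainRate(rx, 1, 1, 0.1, conc2, aas), 0.5^0.2)
  ## another amino acid low while the consumed one is at reference
  conc3 <- c(AA1 = 1, AA2 = 0.2, ATP = 1)
  expect_equal(aminoAcidDrainRate(rx, 1, 1, 0.1, conc3, aas), 0.2^0.1)
  expect_error(aminoAcidDrainRate(rx, 1, 1, 0.1, conc, character(0)),
               "amino-acid set")
})

test_that("generic drain follows the low-sensitivity power law", {
  rx <- plainReaction(c(P = -1, Y_bio = 1), class = "generic_drain")
  expect_equal(genericDrainRate(rx, 3, 2, 0.1, c(P = 1)), 6)
  expect_equal(genericDrainRate(rx, 1, 1, 0.1, c(P = 1024)), 2)
  expect_equal(genericDrainRate(rx, 5, 1, 1e-9, c(P = 37)), 5,
               tolerance = 1e-6)
})

test_that("growth rate is the phi-weighted drain sum with correction", {
  p <- rateParameters(lambda = 1, xMW = 1, phi = c(d1 = 2, d2 = 2))
  expect_equal(growthRate(c(d1 = 3, d2 = 1), p), 8)
  p2 <- rateParameters(lambda = 0.98, xMW = 1, phi = c(d1 = 2, d2 = 2))
  expect_equal(growthRate(c(d1 = 3, d2 = 1), p2), 0.98 * 8)
  ## one drain halved with equal phi over two equal drains
  expect_equal(growthRate(c(d1 = 1, d2 = 2), p) /
                 growthRate(c(d1 = 2, d2 = 2), p), 0.75)
  ## positive even with a zero drain
  expect_gt(growthRate(c(d1 = 0, d2 = 2), p), 0)
  expect_error(growthRate(c(d3 = 1), p), "phi")
})

test_that("every rate law is exactly linear in the expression ratio", {
  fx <- makeToyNetwork("branched", n = 6, nDrains = 2,
                       fractionReversible = 0.4, seed = 5)
  ids <- reactionIds(fx$network)
  conc <- stats::setNames(
    exp(seq(-0.4, 0.4, length.out = length(internalMetabolites(fx$network)))),
    internalMetabolites(fx$network))
  for (scale in c(0.25, 3)) {
    g1 <- unitExpression(fx$network)
    g2 <- g1 * scale
    m1 <- assembleModel(fx$network, fx$ref, g1)
    m2 <- assembleModel(fx$network, fx$ref, g2)
    expect_equal(modelRates(m2, conc), scale * modelRates(m1, conc),
                 tolerance = 1e-13)
  }
})

test_that("assembled models satisfy the reference identity", {
  fixtures <- list(
    makeToyNetwork("chain", n = 4, seed = 2),
    makeToyNetwork("diamond", n = 4, seed = 3),
    makeToyNetwork("branched", n = 7, nDrains = 3,
                   fractionReversible = 0.5, seed = 4),
    makeYeastLikeFixture())
  for (fx in fixtures) {
    phi <- if (length(fx$phi)) fx$phi else numeric(0)
    m <- assembleModel(fx$network, fx$ref,
                       params = rateParameters(phi = phi))
    r <- modelRates(m)
    vmax <- max(1, max(abs(fx$ref@v)))
    expect_lt(max(abs(r - fx$ref@v[names(r)])), 1e-12 * vmax)
    expect_lt(max(abs(modelBalance(m))), 1e-12 * vmax)
  }
})

test_that("a perturbed expression ratio unbalances only its neighborhood", {
  fx <- makeToyNetwork("chain", n = 5, seed = 8)
  m <- assembleModel(fx$network, fx$ref, c(stp2 = 2))
  f <- modelBalance(m)
  expect_true(all(abs(f[c("M2", "M3")]) > 1e-6))
  expect_true(all(abs(f[c("M1", "M4", "M5")]) < 1e-12))
})

test_that("WOA stress shifts the ATP balance by the fixed export cost", {
  fx <- makeToyNetwork("branched", n = 6, nDrains = 2, seed = 6)
  p0 <- rateParameters(phi = fx$phi)
  p1 <- rateParameters(phi = fx$phi, woaUptake = 30, atpPerWoa = 2)
  f0 <- modelBalance(assembleModel(fx$network, fx$ref, params = p0))
  f1 <- modelBalance(assembleModel(fx$network, fx$ref, params = p1))
  expect_equal(f1["ATP"] - f0["ATP"], c(ATP = -60))
  other <- setdiff(names(f0), "ATP")
  expect_equal(f1[other], f0[other])
})

test_that("inhibition factors multiply the whole reaction rate", {
  fx <- makeToyNetwork("chain", n = 4, seed = 9)
  p <- rateParameters(inhibition = c(stp2 = 0.25))
  m <- assembleModel(fx$network, fx$ref, params = p)
  r <- modelRates(m)
  expect_equal(unname(r["stp2"]), unname(0.25 * fx$ref@v["stp2"]))
  expect_equal(r[c("upt", "stp1")], fx$ref@v[c("upt", "stp1")])
})
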