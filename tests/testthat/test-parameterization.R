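test_that("microarray preprocessing scales, medians and smooths", {
  genes <- sprintf("g%02d", 1:40)
  set.seed(42)
  base <- exp(stats::rnorm(40, 5, 1))
  raw <- do.call(rbind, lapply(1:3, function(rep) {
    rbind(data.frame(gene_id = genes, condition = "trt", replicate = rep,
                     intensity = base * 0.5),
          data.frame(gene_id = genes, condition = "ref", replicate = rep,
                     intensity = base * 2))
  }))
  ## arrays differ by a global factor of 4; after per-array scaling to
  ## mean 150 and smoothing, all ratios are exactly 1
  out <- preprocessMicroarray(raw, "trt", "ref")
  expect_equal(out$ratio, rep(1, 40), tolerance = 1e-12)

  ## per-array scaling to mean 150: reference levels come back rescaled
  refVals <- c(10, 20, 30, 40, 50, 60, 70, 80, 90, 100)
  one <- data.frame(gene_id = sprintf("h%02d", 1:10), condition = "x",
                    replicate = 1, intensity = refVals * 3)
  two <- data.frame(gene_id = sprintf("h%02d", 1:10), condition = "y",
                    replicate = 1, intensity = refVals)
  res <- preprocessMicroarray(rbind(one, two), "x", "y")
  expect_equal(sort(res$reference_intensity),
               sort(refVals * 150 / mean(refVals)))
  expect_equal(res$ratio, rep(1, 10), tolerance = 1e-10)

  expect_error(preprocessMicroarray(
    data.frame(gene_id = "g", condition = "t", replicate = 1,
               intensity = -1), "t", "t"), "intensity")
})

test_that("expression aggregation follows the GPR rules", {
  net <- MetabolicNetwork(
    data.frame(id = c("A", "B")),
    data.frame(id = c("r1", "r2", "r3", "r4", "r5"),
               gpr = c("gA", "g1 and g2", "g1 or g2", "",
                       "gA ; g1 and g2")),
    list(c(A = -1, B = 1), c(A = -1, B = 1), c(A = -1, B = 1),
         c(A = -1, B = 1), c(A = -1, B = 1)))
  ratios <- c(gA = 1.8, g1 = 1.2, g2 = 0.8)
  g <- aggregateExpression(net, ratios)
  expect_equal(unname(g["r1"]), 1.8)                   # single gene
  expect_equal(unname(g["r2"]), 0.8)                   # AND = min
  expect_equal(unname(g["r3"]), 1.0)                   # OR unweighted mean
  expect_equal(unname(g["r4"]), 1.0)                   # no GPR
  expect_equal(unname(g["r5"]), sqrt(1.8 * 0.8))       # lumped steps: geomean

  ## OR weighted by reference intensities: (2*100 + 1*300)/(100+300)
  gw <- aggregateExpression(net, c(gA = 1, g1 = 2, g2 = 1),
                            referenceIntensities = c(g1 = 100, g2 = 300))
  expect_equal(unname(gw["r3"]), (200 + 300) / 400)

  ## missing genes default to 1 with a warning
  expect_warning(g2 <- aggregateExpression(net, c(g1 = 1.2, g2 = 0.8)),
                 "gA")
  expect_equal(unname(g2["r1"]), 1)
  ## identity properties
  ones <- c(gA = 1, g1 = 1, g2 = 1)
  expect_true(all(aggregateExpression(net, ones) == 1))
})

test_that("reference flux estimation solves the minimum-norm problem", {
  ## unique flux on a linear chain
  fx <- makeToyNetwork("chain", n = 3, seed = 2)
  est <- estimateReferenceFluxes(fx$network, c(upt = 5))
  expect_equal(unname(est@v), rep(5, 4), tolerance = 1e-9)
  S <- as.matrix(stoichMatrix(fx$network))
  expect_lt(max(abs(S %*% est@v)), 1e-9)

  ## minimum norm splits a diamond symmetrically
  dm <- makeToyNetwork("diamond", seed = 3)
  est2 <- estimateReferenceFluxes(dm$network, c(upt = 4))
  expect_equal(unname(est2@v[c("br1a", "br2a")]), c(2, 2),
               tolerance = 1e-8)

  ## inconsistent measurements are rejected with residuals
  expect_error(estimateReferenceFluxes(fx$network, c(upt = 5, exp = 7)),
               "infeasible")

  ## irreversibility is enforced
  est3 <- estimateReferenceFluxes(dm$network, c(upt = 4, br1a = 3.5))
  expect_true(all(est3@v[!reactions(dm$network)$reversible] > -1e-10))
  expect_equal(unname(est3@v["br2a"]), 0.5, tolerance = 1e-8)
})

test_that("reference flux estimates recover toy ground truth exactly", {
  for (seed in c(4, 9)) {
    fx <- makeToyNetwork("chain", n = 4, seed = seed)
    est <- estimateReferenceFluxes(fx$network,
                                   fx$ref@v[c("upt")])
    expect_equal(est@v, fx$ref@v, tolerance = 1e-9)
  }
})

test_that("beta assignment is empty without reversible cycles", {
  fx <- makeToyNetwork("chain", n = 5, fractionReversible = 0.5,
                       seed = 6)
  ov <- assignBetas(fx$network, fx$ref, 30)
  expect_length(ov, 0L)
})

test_that("beta assignment balances a two-route reversible loop", {
  net <- MetabolicNetwork(
    data.frame(id = c("S_ext", "A", "B", "P_ext"),
               role = c("boundary", "internal", "internal", "boundary")),
    data.frame(id = c("upt", "ra", "rb", "exp"),
               reversible = c(FALSE, TRUE, TRUE, FALSE),
               class = c("mass_action_irreversible",
                         "mass_action_reversible",
                         "mass_action_reversible",
                         "mass_action_irreversible")),
    list(c(S_ext = -1, A = 1), c(A = -1, B = 1), c(A = -1, B = 1),
         c(B = -1, P_ext = 1)))
  ref <- referenceState(c(upt = 4, ra = 2, rb = 2, exp = 4))
  ov <- assignBetas(net, ref, 30)
  ## equal fluxes in the same direction are already cycle-consistent
  full <- stats::setNames(rep(30, 2), c("ra", "rb"))
  full[names(ov)] <- ov
  rho <- full / (full - 1)
  expect_equal(rho[["ra"]] / rho[["rb"]], 1, tolerance = 1e-10)
  expect_equal(unname(full), c(30, 30))
})

test_that("beta assignment matches a brute-force cycle-consistency search", {
  ## reversible triangle A->B->C plus direct A->C, fluxes (2, 1, 1)
  net <- MetabolicNetwork(
    data.frame(id = c("S_ext", "A", "B", "C", "P_ext"),
               role = c("boundary", rep("internal", 3), "boundary")),
    data.frame(id = c("upt", "rab", "rbc", "rac", "exp"),
               reversible = c(FALSE, TRUE, TRUE, TRUE, FALSE),
               class = c("mass_action_irreversible",
                         rep("mass_action_reversible", 3),
                         "mass_action_irreversible")),
    list(c(S_ext = -1, A = 1), c(A = -1, B = 1), c(B = -1, C = 1),
         c(A = -1, C = 1), c(C = -1, P_ext = 1)))
  ref <- referenceState(c(upt = 3, rab = 2, rbc = 2, rac = 1, exp = 3))
  ov <- assignBetas(net, ref, 30)
  expect_true(length(ov) >= 1)
  betas <- stats::setNames(rep(30, 3), c("rab", "rbc", "rac"))
  betas[names(ov)] <- ov
  expect_true(all(betas >= 1))
  ## cycle product of (vf/vb) ratios equals 1 at the reference
  rho <- betas / (betas - 1)       # all fluxes positive here
  cycleProd <- rho[["rab"]] * rho[["rbc"]] / rho[["rac"]]
  expect_equal(cycleProd, 1, tolerance = 1e-9)

  ## brute-force oracle: grid search over log-ratio perturbations
  x0 <- log(30 / 29)
  grid <- seq(0.2, 2, by = 0.005) * x0
  best <- NULL; bestDev <- Inf
  for (x1 in grid) for (x2 in grid) {
    x3 <- x1 + x2                 # cycle constraint x1 + x2 - x3 = 0
    dev <- (x1 - x0)^2 + (x2 - x0)^2 + (x3 - x0)^2
    if (dev < bestDev - 1e-15) { bestDev <- dev; best <- c(x1, x2, x3) }
  }
  xPkg <- log(betas / (betas - 1))
  devPkg <- sum((xPkg - x0)^2)
  expect_lte(devPkg, bestDev + 1e-6)
})

test_that("split conservation holds under beta overrides", {
  net <- MetabolicNetwork(
    data.frame(id = c("S_ext", "A", "B", "P_ext"),
               role = c("boundary", "internal", "internal", "boundary")),
    data.frame(id = c("upt", "ra", "rb", "exp"),
               reversible = c(FALSE, TRUE, TRUE, FALSE)),
    list(c(S_ext = -1, A = 1), c(A = -1, B = 1), c(A = -1, B = 1),
         c(B = -1, P_ext = 1)))
  ref <- referenceState(c(upt = 4, ra = 3, rb = 1, exp = 4))
  m <- assembleModel(net, ref,
                     params = rateParameters(
                       betaOverrides = c(ra = 12.5, rb = 4)))
  expect_equal(m@ref@vf - m@ref@vb, ref@v[c("ra", "rb")])
})

test_that("log-scale extrapolation obeys identity and composition laws", {
  expect_equal(extrapolateExpression(4, 2), 16)
  expect_equal(extrapolateExpression(1, 7.3), 1)
  expect_equal(extrapolateExpression(0.5, 2), 0.25)
  g <- c(a = 0.2, b = 1, c = 3.7)
  expect_equal(extrapolateExpression(g, 0), c(a = 1, b = 1, c = 1))
  expect_equal(extrapolateExpression(g, 1), g)
  expect_equal(extrapolateExpression(extrapolateExpression(g, 1.7), 2.2),
               extrapolateExpression(g, 1.7 * 2.2), tolerance = 1e-12)
})

test_that("expression shuffling is a seeded permutation", {
  g <- stats::setNames(c(10, 1, 1, 1, 1, 1), paste0("r", 1:6))
  s1 <- shuffleExpression(g, 7)
  s2 <- shuffleExpression(g, 7)
  expect_identical(s1, s2)
  expect_setequal(unname(s1), unname(g))
  expect_identical(names(s1), names(g))
  ## the outlier lands uniformly across positions
  hits <- integer(6)
  for (seed in 1:600) {
    s <- shuffleExpression(g, seed)
    hits[which(s == 10)] <- hits[which(s == 10)] + 1L
  }
  p <- 1 / 6
  se <- sqrt(600 * p * (1 - p))
  expect_true(all(abs(hits - 100) <= 4 * se))
  ## global RNG state untouched
  set.seed(123); before <- .Random.seed
  invisible(shuffleExpression(g, 99))
  expect_identical(.Random.seed, before)
})
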