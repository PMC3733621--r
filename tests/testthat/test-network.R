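test_that("TSV reader transcribes a toy network and its stoichiometry", {
  path <- withr::local_tempfile(fileext = ".tsv")
  threeMetToyTSV(path)
  net <- readNetwork(path)
  expect_equal(nrow(reactions(net)), 2L)
  expect_setequal(internalMetabolites(net), c("A", "B"))
  S <- as.matrix(stoichMatrix(net))
  expect_equal(S[c("A", "B"), c("r1", "r2")],
               matrix(c(-1, 1, 0, -1), 2, 2,
                      dimnames = list(c("A", "B"), c("r1", "r2"))))
})

test_that("tabular and JSON round trips are the identity", {
  fx <- makeToyNetwork("branched", n = 5, nDrains = 2, seed = 11,
                       fractionReversible = 0.3)
  for (dialect in c("tsv", "json")) {
    p1 <- withr::local_tempfile(fileext = paste0(".", dialect))
    mp <- if (dialect == "tsv")
      withr::local_tempfile(fileext = ".tsv") else NULL
    writeNetwork(fx$network, p1, dialect = dialect, metabolitesPath = mp)
    net2 <- if (dialect == "tsv") readNetwork(p1, metabolitesPath = mp)
            else readNetwork(p1)
    expect_equal(reactions(net2), reactions(fx$network))
    expect_equal(as.matrix(stoichMatrix(net2, internal = FALSE))[
                   metaboliteIds(fx$network), ],
                 as.matrix(stoichMatrix(fx$network, internal = FALSE)))
    ## second write is byte-identical (canonical ordering)
    p2 <- withr::local_tempfile(fileext = paste0(".", dialect))
    writeNetwork(net2, p2, dialect = dialect)
    if (dialect == "json") {
      writeNetwork(fx$network, p1, dialect = "json")
      expect_identical(readLines(p2), readLines(p1))
    }
  }
})

test_that("malformed network files raise parse errors naming the record", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tequation", "r1\tA + -> B"), path)
  expect_error(readNetwork(path), "r1")
  writeLines(c("id\tequation", "r1\tA -> B", "r1\tB -> C"), path)
  expect_error(readNetwork(path), "duplicate")
  writeLines(c("id\tequation\tnonsense", "r1\tA -> B\t7"), path)
  expect_warning(readNetwork(path), "nonsense")
})

test_that("validateNetwork reports structural violations", {
  fx <- makeToyNetwork("chain", n = 3, seed = 1)
  expect_length(validateNetwork(fx$network), 0L)

  net <- fx$network
  net@reactions$gamma[2] <- 2L   # gamma > 1 without the lumped flag
  expect_match(validateNetworkCore(net), "lumped", all = FALSE)

  net2 <- fx$network
  net2@reactions$gamma[2] <- 2L
  net2@reactions$lumped[2] <- TRUE
  net2@reactions$reversible[2] <- TRUE
  expect_match(validateNetworkCore(net2), "irreversible", all = FALSE)

  expect_error(
    MetabolicNetwork(data.frame(id = "A"), data.frame(id = "r1"),
                     list(c(A = -1, Zz = 1))),
    "Zz")
})

test_that("GPR parser handles grammar, precedence and malformed input", {
  expect_equal(parseGPR("G1"), list(op = "leaf", gene = "G1"))
  tree <- parseGPR("(G1 or G2) and G3")
  expect_equal(tree$op, "and")
  expect_equal(tree$children[[1]]$op, "or")
  expect_setequal(gprGenes(tree), c("G1", "G2", "G3"))
  ## "and" binds tighter than "or"
  tree2 <- parseGPR("G1 or G2 and G3")
  expect_equal(tree2$op, "or")
  expect_null(parseGPR(""))
  expect_null(parseGPR("   "))
  expect_error(parseGPR("G1 or (G2 and"), "parse error")
  expect_error(parseGPR("G1 and or G2"), "parse error")
  expect_error(parseGPR("(G1 or G2"), "parenthes")
})

test_that("SBML round trip preserves stoichiometry, flags and annotations", {
  fx <- makeToyNetwork("branched", n = 5, nDrains = 2,
                       fractionReversible = 0.4, seed = 3)
  net <- fx$network
  net@reactions$gamma[2] <- 3L
  net@reactions$lumped[2] <- TRUE
  net@reactions$reversible[2] <- FALSE
  net@reactions$class[2] <- "mass_action_irreversible"
  path <- withr::local_tempfile(fileext = ".xml")
  writeSBML(net, path, ref = fx$ref)
  back <- readSBML(path)
  expect_equal(reactions(back$network)$gamma,
               reactions(net)$gamma)
  expect_equal(reactions(back$network)$reversible,
               reactions(net)$reversible)
  expect_equal(reactions(back$network)$class, reactions(net)$class)
  expect_equal(as.matrix(stoichMatrix(back$network, internal = FALSE))[
                 metaboliteIds(net), reactionIds(net)],
               as.matrix(stoichMatrix(net, internal = FALSE)))
  expect_equal(back$ref@v[reactionIds(net)], fx$ref@v[reactionIds(net)],
               tolerance = 1e-12)
  ## empty network refuses to export
  empty <- MetabolicNetwork(data.frame(id = "A", role = "boundary"),
                            data.frame(id = character(0)),
                            list())
  expect_error(writeSBML(empty, path), "no reactions")
})

test_that("stoichiometric matrix columns reproduce reaction stoichiometry", {
  for (seed in 1:3) {
    fx <- makeToyNetwork("branched", n = 5, nDrains = 1, seed = seed)
    S <- stoichMatrix(fx$network, internal = FALSE)
    for (id in reactionIds(fx$network)) {
      rx <- getReaction(fx$network, id)
      col <- S[, id]
      expect_equal(col[names(rx$stoich)], rx$stoich,
                   ignore_attr = TRUE)
      expect_true(all(col[setdiff(rownames(S), names(rx$stoich))] == 0))
    }
  }
})
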