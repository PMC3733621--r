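#' Generate a toy metabolic network with a consistent reference state
#'
#' Builds small networks with known topology and a reference flux
#' distribution constructed by routing a seeded uptake flux through the
#' network (branch splits drawn from the seeded RNG), then polished onto
#' the null space of S so that \eqn{\|S v\|_\infty} is at machine
#' precision. With \code{nDrains > 0} the network gains a pooled ATP
#' species (produced by the first pathway step, with the coefficient that
#' balances total drain consumption) and biomass drain reactions, at
#' least one of class \code{amino_acid_drain} (its precursor flagged as an
#' amino acid) and the rest generic, plus a phi (carbon content) table.
#'
#' @param topology \code{"chain"} (linear pathway of \code{n} internal
#'   metabolites), \code{"diamond"} (two parallel routes joining the same
#'   metabolite pair; requires \code{n >= 4}), or \code{"branched"}
#'   (backbone of \code{n} with \code{nBranches} side branches to
#'   exports).
#' @param n number of backbone internal metabolites.
#' @param nBranches branch count (branched topology).
#' @param fractionReversible fraction of interior conversion steps marked
#'   reversible.
#' @param nDrains number of biomass drain fluxes to attach.
#' @param seed integer seed; generation is pure (identical arguments and
#'   seed give identical output).
#' @return list with elements \code{network} (a
#'   \code{MetabolicNetwork}), \code{ref} (a \code{ReferenceState}) and
#'   \code{phi} (named numeric, possibly empty).
#' @export
makeToyNetwork <- function(topology = c("chain", "diamond", "branched"),
                           n = 5, nBranches = 2, fractionReversible = 0,
                           nDrains = 0, seed = 1) {
  topology <- match.arg(topology)
  if (topology == "diamond" && n < 4)
    stop("diamond topology needs n >= 4")
  if (topology == "chain" && n < 2) stop("chain needs n >= 2")
  if (topology == "branched" && n < 3) stop("branched needs n >= 3")
  withSeed(seed, {
    mets <- character(0); rid <- character(0)
    st <- list(); flux <- numeric(0)

    addRxn <- function(id, stoich, v) {
      rid <<- c(rid, id); st[[length(st) + 1L]] <<- stoich
      flux <<- c(flux, v)
    }
    u <- stats::runif(1, 2, 8)

    if (topology == "chain") {
      mets <- paste0("M", seq_len(n))
      addRxn("upt", c(S_ext = -1, M1 = 1), u)
      for (i in seq_len(n - 1))
        addRxn(paste0("stp", i),
               stats::setNames(c(-1, 1), mets[i + 0:1]), u)
      addRxn("exp", stats::setNames(c(-1, 1), c(mets[n], "P_ext")), u)
      interior <- paste0("stp", seq_len(n - 1))
      backbone <- mets
    } else if (topology == "diamond") {
      mets <- c("A", "B1", "B2", "C")
      w <- stats::runif(1, 0.3, 0.7)
      addRxn("upt", c(S_ext = -1, A = 1), u)
      addRxn("br1a", c(A = -1, B1 = 1), u * w)
      addRxn("br2a", c(A = -1, B2 = 1), u * (1 - w))
      addRxn("br1b", c(B1 = -1, C = 1), u * w)
      addRxn("br2b", c(B2 = -1, C = 1), u * (1 - w))
      addRxn("exp", c(C = -1, P_ext = 1), u)
      interior <- c("br1a", "br2a", "br1b", "br2b")
      backbone <- c("A", "C")
    } else {
      mets <- paste0("M", seq_len(n))
      pos <- unique(round(seq(2, n - 1, length.out = nBranches)))
      bmets <- paste0("B", seq_along(pos))
      mets <- c(mets, bmets)
      addRxn("upt", c(S_ext = -1, M1 = 1), u)
      fin <- u
      for (i in seq_len(n - 1)) {
        bk <- which(pos == i)
        if (length(bk)) {
          w <- stats::runif(1, 0.15, 0.4)
          bf <- fin * w
          addRxn(paste0("brn", bk), stats::setNames(c(-1, 1),
                 c(paste0("M", i), bmets[bk])), bf)
          addRxn(paste0("bex", bk), stats::setNames(c(-1, 1),
                 c(bmets[bk], paste0("B", bk, "_ext"))), bf)
          fin <- fin - bf
        }
        addRxn(paste0("stp", i),
               stats::setNames(c(-1, 1), paste0("M", i + 0:1)), fin)
      }
      addRxn("exp", stats::setNames(c(-1, 1), c(paste0("M", n), "P_ext")),
             fin)
      interior <- grep("^(stp|brn)", rid, value = TRUE)
      backbone <- paste0("M", seq_len(n))
    }

    aaMets <- character(0)
    phi <- numeric(0)
    if (nDrains > 0) {
      mets <- c(mets, "ATP")
      cand <- rev(backbone)[seq_len(min(nDrains, length(backbone) - 1))]
      if (length(cand) < nDrains)
        stop("not enough backbone metabolites for ", nDrains, " drains")
      drainFlux <- numeric(0)
      for (d in seq_len(nDrains)) {
        src <- cand[d]
        ## divert a seeded share of the flux through src into the drain
        through <- sum(vapply(seq_along(st), function(k)
          if (!is.na(st[[k]][src]) && st[[k]][src] > 0) flux[k] else 0,
          numeric(1)))
        w <- stats::runif(1, 0.1, 0.25)
        df <- through * w
        cls <- if (d <= ceiling(nDrains / 2)) "amino_acid_drain"
               else "generic_drain"
        if (cls == "amino_acid_drain") aaMets <- c(aaMets, src)
        addRxn(paste0("drn", d),
               stats::setNames(c(-1, -1, 1),
                               c(src, "ATP", paste0("D", d, "_bio"))), df)
        drainFlux <- c(drainFlux, df)
        ## downstream steps consuming src lose the diverted flux
        for (k in seq_along(st))
          if (!is.na(st[[k]][src]) && st[[k]][src] < 0 &&
              !grepl("^drn", rid[k]))
            flux[k] <- flux[k] - df
        ## propagate reduction down the backbone past src
        idx <- match(src, backbone)
        if (!is.na(idx) && idx < length(backbone)) {
          down <- backbone[(idx + 1):length(backbone)]
          for (k in seq_along(st)) {
            sk <- st[[k]]
            if (grepl("^(stp|exp)", rid[k]) &&
                any(names(sk)[sk < 0] %in% down))
              flux[k] <- flux[k] - df
          }
        }
      }
      ## ATP produced by the first interior step, coefficient balancing
      ## total drain consumption
      k1 <- match(interior[1], rid)
      coefATP <- sum(drainFlux) / flux[k1]
      st[[k1]] <- c(st[[k1]], ATP = coefATP)
      phi <- stats::setNames(stats::runif(nDrains, 1, 4),
                             paste0("drn", seq_len(nDrains)))
    }

    metIds <- unique(c(mets, unlist(lapply(st, names))))
    metDf <- data.frame(
      id = metIds,
      role = ifelse(grepl("_ext$", metIds), "boundary",
             ifelse(grepl("_bio$", metIds), "biomass-sink", "internal")),
      amino_acid = metIds %in% aaMets,
      stringsAsFactors = FALSE)

    revFlag <- rep(FALSE, length(rid))
    names(revFlag) <- rid
    if (fractionReversible > 0 && length(interior)) {
      nRev <- round(fractionReversible * length(interior))
      if (nRev > 0)
        revFlag[sample(interior, nRev)] <- TRUE
    }
    cls <- ifelse(grepl("^drn", rid),
                  vapply(seq_along(rid), function(k) {
                    if (!grepl("^drn", rid[k])) return("x")
                    sk <- st[[k]]
                    src <- names(sk)[sk < 0 & names(sk) != "ATP"]
                    if (src %in% aaMets) "amino_acid_drain"
                    else "generic_drain"
                  }, character(1)),
                  ifelse(revFlag, "mass_action_reversible",
                         "mass_action_irreversible"))
    rxnDf <- data.frame(id = rid, reversible = unname(revFlag), gamma = 1L,
                        lumped = FALSE, class = cls, gpr = "",
                        stringsAsFactors = FALSE)
    net <- MetabolicNetwork(metDf, rxnDf, st)

    v <- stats::setNames(flux, rid)
    Sint <- as.matrix(stoichMatrix(net, internal = TRUE))
    pol <- pinvSolve(Sint, as.numeric(Sint %*% v))
    v <- v - stats::setNames(pol$x, rid)
    list(network = net, ref = referenceState(v), phi = phi)
  })
}

#' Additive or multiplicative noise on a table of values
#'
#' Log-normal multiplicative noise (mean-preserving on the log scale; the
#' sd of the log values equals \code{cv}) for positive quantities such as
#' concentrations and ratios, or additive Gaussian noise with
#' sd = cv * |value| for signed quantities such as fluxes.
#'
#' @param values numeric vector (positive for lognormal).
#' @param cv coefficient of variation (0 = identity).
#' @param seed integer seed.
#' @param type \code{"lognormal"} or \code{"additive"}.
#' @return perturbed vector, names preserved.
#' @export
addNoise <- function(values, cv, seed, type = c("lognormal", "additive")) {
  type <- match.arg(type)
  stopifnot(cv >= 0)
  if (cv == 0) return(values)
  withSeed(seed, {
    if (type == "lognormal") {
      if (any(values <= 0)) stop("lognormal noise needs positive values")
      values * exp(stats::rnorm(length(values), 0, cv))
    } else {
      values + stats::rnorm(length(values), 0, cv * abs(values))
    }
  })
}

#' Generate a condition with known ground truth
#'
#' Builds an expression vector from a mapping of perturbed reactions (1
#' elsewhere), solves the resulting condition-specific model, and emits
#' observed concentration ratios and fluxes with multiplicative
#' (concentrations) / additive (fluxes) noise of the given coefficient of
#' variation, alongside the noise-free truth. This is the ground-truth
#' generator behind the recovery tests of the mechanism-of-action
#' ranking.
#'
#' @param network a \code{MetabolicNetwork}.
#' @param ref a \code{ReferenceState}.
#' @param perturbed named numeric, reaction id -> true expression ratio.
#' @param seed integer seed for the noise draws.
#' @param noiseCv coefficient of variation (0 = exact observations).
#' @param params optional \code{RateParameters} (phi etc.).
#' @return list with \code{g}, \code{model}, \code{truth} (list c, fluxes)
#'   and \code{observed} (list c, fluxes).
#' @export
makeCondition <- function(network, ref, perturbed, seed = 1, noiseCv = 0,
                          params = rateParameters()) {
  unknown <- setdiff(names(perturbed), network@reactions$id)
  if (length(unknown))
    stop("perturbed unknown reaction(s): ", paste(unknown, collapse = ", "))
  g <- stats::setNames(rep(1, nrow(network@reactions)),
                       network@reactions$id)
  g[names(perturbed)] <- perturbed
  model <- assembleModel(network, ref, g, params)
  sol <- solveSteadyState(model)
  if (!sol$converged)
    stop("condition generation failed: perturbed model did not converge")
  obsC <- addNoise(sol$c, noiseCv, seed, "lognormal")
  obsV <- addNoise(sol$r, noiseCv, seed + 1L, "additive")
  list(g = g, model = model,
       truth = list(c = sol$c, fluxes = sol$r),
       observed = list(c = obsC, fluxes = obsV))
}
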