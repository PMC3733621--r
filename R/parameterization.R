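#' Preprocess raw microarray intensities into expression ratios
#'
#' Replicated raw intensities for a treatment and a reference condition
#' are turned into per-gene expression ratios: each array is scaled so its
#' average intensity is 150.0; the per-gene expression level of each
#' condition is the median across replicates; the treatment/reference
#' log-ratios are Lowess-smoothed against the mean log-intensity (MA
#' coordinates) and the fitted intensity-dependent trend is subtracted;
#' ratios are computed from the smoothed values.
#'
#' @param raw data.frame in long format with columns \code{gene_id},
#'   \code{condition}, \code{replicate}, \code{intensity} (all intensities
#'   must be positive).
#' @param treatment condition label of the treatment arrays.
#' @param reference condition label of the reference arrays.
#' @param lowessSpan Lowess smoother span on (mean log-intensity,
#'   log-ratio) coordinates (default 0.3).
#' @return data.frame with columns \code{gene_id}, \code{ratio}
#'   (treatment / reference after smoothing) and \code{reference_intensity}
#'   (scaled reference level, usable as OR-branch weights in
#'   \code{\link{aggregateExpression}}).
#' @export
preprocessMicroarray <- function(raw, treatment, reference,
                                 lowessSpan = 0.3) {
  need <- c("gene_id", "condition", "replicate", "intensity")
  stopifnot(all(need %in% names(raw)))
  if (any(raw$intensity <= 0))
    stop("nonpositive intensity value(s) in raw data")
  if (!all(c(treatment, reference) %in% raw$condition))
    stop("treatment/reference condition not present in raw data")
  raw <- raw[raw$condition %in% c(treatment, reference), ]

  ## scale each array (condition x replicate) to mean intensity 150.0
  key <- interaction(raw$condition, raw$replicate, drop = TRUE)
  means <- tapply(raw$intensity, key, mean)
  raw$intensity <- raw$intensity * (150 / as.numeric(means[key]))

  med <- function(cond) {
    sub <- raw[raw$condition == cond, ]
    out <- tapply(sub$intensity, sub$gene_id, stats::median)
    stats::setNames(as.numeric(out), names(out))
  }
  trt <- med(treatment)
  ref <- med(reference)
  genes <- intersect(names(trt), names(ref))
  trt <- trt[genes]; ref <- ref[genes]

  M <- log2(trt) - log2(ref)
  A <- (log2(trt) + log2(ref)) / 2
  fit <- stats::lowess(A, M, f = lowessSpan)
  trend <- stats::approx(fit$x, fit$y, xout = A, rule = 2, ties = mean)$y
  ratio <- 2^(M - trend)
  data.frame(gene_id = genes, ratio = unname(ratio),
             reference_intensity = unname(ref),
             stringsAsFactors = FALSE)
}

## minimum-norm least-squares solve via SVD (handles redundant rows);
## returns list(x, residual)
pinvSolve <- function(A, b, rtol = 1e-12) {
  sv <- svd(A)
  keep <- sv$d > rtol * max(sv$d, 1e-300)
  x <- sv$v[, keep, drop = FALSE] %*%
    ((crossprod(sv$u[, keep, drop = FALSE], b)) / sv$d[keep])
  list(x = as.numeric(x), residual = as.numeric(A %*% x - b))
}

#' Estimate a reference flux distribution from exchange measurements
#'
#' When a full flux distribution (e.g. from 13C-labeling) is not
#' available, a reasonable reference estimate is the minimum-norm flux
#' vector consistent with the measured exchange rates: minimize
#' \eqn{\sum_j v_j^2} subject to \eqn{S v = 0} over internal metabolites,
#' the measured exchange fluxes fixed (hard constraints, absolute
#' tolerance \code{exchangeTol}), and nonnegativity of irreversible
#' reactions (enforced by an active-set iteration). The result is polished
#' onto the null space of S so the conservation residual is at machine
#' precision.
#'
#' @param network a \code{MetabolicNetwork}.
#' @param measured named numeric (reaction id -> measured rate) or a
#'   2-column data.frame.
#' @param exchangeTol absolute feasibility tolerance on the measured
#'   constraints (default 1e-6).
#' @return a \code{ReferenceState}.
#' @export
estimateReferenceFluxes <- function(network, measured, exchangeTol = 1e-6) {
  if (is.data.frame(measured))
    measured <- stats::setNames(as.numeric(measured[[2]]),
                                as.character(measured[[1]]))
  rids <- network@reactions$id
  unknown <- setdiff(names(measured), rids)
  if (length(unknown))
    stop("measured rate for unknown reaction(s): ",
         paste(unknown, collapse = ", "))
  Sint <- as.matrix(stoichMatrix(network, internal = TRUE))
  nr <- length(rids)
  mIdx <- match(names(measured), rids)
  Emeas <- matrix(0, length(mIdx), nr)
  Emeas[cbind(seq_along(mIdx), mIdx)] <- 1
  A0 <- rbind(Sint, Emeas)
  b0 <- c(rep(0, nrow(Sint)), unname(measured))
  irrevIdx <- which(!network@reactions$reversible)

  active <- integer(0)
  for (pass in seq_len(length(irrevIdx) + 1L)) {
    A <- A0; b <- b0
    if (length(active)) {
      Eact <- matrix(0, length(active), nr)
      Eact[cbind(seq_along(active), active)] <- 1
      A <- rbind(A, Eact); b <- c(b, rep(0, length(active)))
    }
    sol <- pinvSolve(A, b)
    resMeas <- sol$residual[nrow(Sint) + seq_along(mIdx)]
    if (max(abs(sol$residual[seq_len(nrow(Sint))])) > exchangeTol ||
        max(abs(resMeas)) > exchangeTol) {
      det <- paste(sprintf("%s: residual %.3e", names(measured),
                           resMeas), collapse = "; ")
      stop("exchange measurements are inconsistent with mass ",
           "conservation (infeasible constraint set): ", det)
    }
    v <- sol$x
    viol <- irrevIdx[v[irrevIdx] < -1e-10]
    viol <- setdiff(viol, active)
    if (!length(viol)) break
    active <- c(active, viol[which.min(v[viol])])
  }
  small <- v[irrevIdx] < 0 & v[irrevIdx] > -1e-10
  v[irrevIdx][small] <- 0

  ## null-space polish: remove the (tiny) component of v outside ker(Sint)
  pol <- pinvSolve(Sint, as.numeric(Sint %*% v))
  v <- v - pol$x
  referenceState(stats::setNames(v, rids))
}

#' Assign beta splits consistent on reversible parallel routes
#'
#' All reversible reactions get the global beta, except members of
#' reversible parallel routes (two disjoint reversible paths joining the
#' same metabolite pair, detected as cycles of the undirected reaction
#' graph built from the reversible reactions). Within each such cycle, the
#' member betas are rescaled so that the product of forward/backward rate
#' ratios (vf/vb) around the cycle, evaluated at the reference fluxes,
#' equals 1 (Wegscheider-style thermodynamic consistency); the rescaling
#' is the minimal log-scale adjustment. The splits still satisfy
#' vf - vb = v. A cycle whose reference fluxes make consistency impossible
#' with beta >= 1 (or that contains a zero reference flux) falls back to
#' the global beta with a warning naming the cycle.
#'
#' @param network a \code{MetabolicNetwork}.
#' @param ref a \code{ReferenceState} (reference fluxes orient the cycle
#'   ratios).
#' @param betaGlobal global beta (default 30; must be > 1 for the ratio
#'   rescaling to be defined).
#' @return named numeric of per-reaction beta overrides (empty when the
#'   network has no reversible cycles).
#' @export
assignBetas <- function(network, ref, betaGlobal = 30) {
  if (betaGlobal < 1) stop("betaGlobal must be >= 1")
  rxn <- network@reactions
  revIdx <- which(rxn$reversible & rxn$class == "mass_action_reversible")
  if (length(revIdx) < 2 || betaGlobal == 1)
    return(stats::setNames(numeric(0), character(0)))
  S <- network@stoich
  met <- network@metabolites$id

  ## one undirected edge per reversible reaction: first substrate ->
  ## first product (reaction ids label the edges)
  ed <- do.call(rbind, lapply(revIdx, function(k) {
    col <- S[, k]
    sub <- met[which(col < 0)]
    prd <- met[which(col > 0)]
    if (!length(sub) || !length(prd)) return(NULL)
    data.frame(from = sub[1], to = prd[1], rxn = rxn$id[k],
               stringsAsFactors = FALSE)
  }))
  if (is.null(ed) || nrow(ed) < 2)
    return(stats::setNames(numeric(0), character(0)))
  g <- igraph::graph_from_data_frame(ed, directed = FALSE)

  ## fundamental cycles from a spanning forest: each non-tree edge closes
  ## exactly one cycle through the tree path between its endpoints
  tree <- igraph::mst(g)
  treePairs <- igraph::as_edgelist(tree)
  allPairs <- igraph::as_edgelist(g)
  edgeKey <- function(m) paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
  inTree <- logical(nrow(allPairs))
  tk <- edgeKey(treePairs)
  used <- rep(FALSE, length(tk))
  ak <- edgeKey(allPairs)
  for (i in seq_along(ak)) {
    j <- which(!used & tk == ak[i])
    if (length(j)) { inTree[i] <- TRUE; used[j[1]] <- TRUE }
  }

  v <- ref@v
  x0 <- log(betaGlobal / (betaGlobal - 1))
  x <- stats::setNames(rep(x0, nrow(ed)), ed$rxn)

  for (i in which(!inTree)) {
    ends <- allPairs[i, ]
    path <- igraph::shortest_paths(tree, from = ends[1], to = ends[2],
                                   output = "epath")$epath[[1]]
    if (length(path) == 0) next
    pathPairs <- igraph::as_edgelist(tree)[as.integer(path), , drop = FALSE]
    ## reconstruct reaction sequence and traversal orientation
    cyc <- character(0); sigma <- numeric(0)
    at <- ends[1]
    for (pe in seq_len(nrow(pathPairs))) {
      pp <- pathPairs[pe, ]
      nxt <- if (pp[1] == at) pp[2] else pp[1]
      ## find the ed row for this tree edge
      row <- which((ed$from == pp[1] & ed$to == pp[2]) |
                   (ed$from == pp[2] & ed$to == pp[1]))[1]
      cyc <- c(cyc, ed$rxn[row])
      sigma <- c(sigma, if (ed$from[row] == at) 1 else -1)
      at <- nxt
    }
    ## closing (non-tree) edge from ends[2] back to ends[1]
    cyc <- c(cyc, ed$rxn[i])
    sigma <- c(sigma, if (ed$from[i] == ends[2]) 1 else -1)

    vi <- v[cyc]
    if (any(vi == 0)) {
      warning("reversible cycle [", paste(cyc, collapse = ", "),
              "] has a zero reference flux; keeping global beta",
              call. = FALSE)
      next
    }
    tau <- sigma * sign(vi)
    if (sum(tau^2) == 0 || sum(tau) == 0) next  # already consistent
    xc <- x[cyc]
    proj <- xc - tau * sum(tau * xc) / sum(tau^2)
    if (any(proj <= 0)) {
      warning("reversible cycle [", paste(cyc, collapse = ", "),
              "] cannot satisfy consistency with beta >= 1; ",
              "keeping global beta", call. = FALSE)
      next
    }
    x[cyc] <- proj
  }
  changed <- abs(x - x0) > 1e-12
  rho <- exp(x[changed])
  stats::setNames(rho / (rho - 1), names(x)[changed])
}

#' Extrapolate an expression vector on the log scale
#'
#' Multiplies expression ratios by \code{factor} on the logarithmic scale,
#' i.e. maps g to g^factor: factor 1 is the identity, factor 0 maps every
#' ratio to 1 (no change), factor 2 doubles every log-ratio. Used to probe
#' graded transcriptional responses at higher stress levels.
#'
#' @param g named numeric expression vector (positive) or 2-column
#'   data.frame.
#' @param factor real extrapolation factor.
#' @return same shape as \code{g}.
#' @export
extrapolateExpression <- function(g, factor) {
  if (is.data.frame(g)) {
    g[[2]] <- g[[2]]^factor
    return(g)
  }
  g^factor
}

#' Shuffle expression values (null-model permutation)
#'
#' Permutes the values of an expression vector or profile uniformly at
#' random under the given seed, preserving the multiset of values. Used
#' for the shuffled-expression null that checks results are not artifacts
#' of arbitrary data. The caller's RNG state is left untouched.
#'
#' @param g named numeric vector or data.frame whose second column holds
#'   the values.
#' @param seed integer seed.
#' @return same type as \code{g}, values permuted.
#' @export
shuffleExpression <- function(g, seed) {
  perm <- withSeed(seed, {
    n <- if (is.data.frame(g)) nrow(g) else length(g)
    sample.int(n)
  })
  if (is.data.frame(g)) {
    g[[2]] <- g[[2]][perm]
    g
  } else stats::setNames(g[perm], names(g))
}

## evaluate expr under a temporary RNG seed, restoring global state
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
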