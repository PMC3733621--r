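#' Construct a MetabolicNetwork
#'
#' Assembles and validates a network from a metabolite table, a reaction
#' table and a stoichiometry specification.
#'
#' @param metabolites data.frame with at least an \code{id} column; optional
#'   \code{name}, \code{role} (default "internal"), \code{ref_conc},
#'   \code{amino_acid}.
#' @param reactions data.frame with at least an \code{id} column; optional
#'   \code{reversible} (default FALSE), \code{gamma} (default 1),
#'   \code{lumped} (default \code{gamma > 1}), \code{class} (defaulted from
#'   reversibility), \code{gpr} (default "").
#' @param stoich either a matrix/Matrix (metabolites x reactions) or a list
#'   (one entry per reaction) of named numeric vectors mapping metabolite id
#'   to signed coefficient (negative = consumed).
#' @param kineticOrders optional named list (by reaction id) of named numeric
#'   kinetic-order overrides.
#'
#' @return a validated \code{\linkS4class{MetabolicNetwork}}.
#' @export
MetabolicNetwork <- function(metabolites, reactions, stoich,
                             kineticOrders = list()) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  stopifnot("id" %in% names(metabolites), "id" %in% names(reactions))
  metabolites$id <- as.character(metabolites$id)
  reactions$id <- as.character(reactions$id)
  nm <- nrow(metabolites); nr <- nrow(reactions)
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  if (is.null(metabolites$role))
    metabolites$role <- rep("internal", nm)
  if (is.null(metabolites$ref_conc))
    metabolites$ref_conc <- rep(NA_real_, nm)
  if (is.null(metabolites$amino_acid))
    metabolites$amino_acid <- rep(FALSE, nm)
  if (is.null(reactions$reversible))
    reactions$reversible <- rep(FALSE, nr)
  if (is.null(reactions$gamma)) reactions$gamma <- rep(1L, nr)
  reactions$gamma <- as.integer(reactions$gamma)
  if (is.null(reactions$lumped)) reactions$lumped <- reactions$gamma > 1L
  if (is.null(reactions$class))
    reactions$class <- ifelse(reactions$reversible,
                              "mass_action_reversible",
                              "mass_action_irreversible")
  if (is.null(reactions$gpr)) reactions$gpr <- rep("", nr)
  reactions$gpr[is.na(reactions$gpr)] <- ""
  ## canonical column order (round-trip stability)
  metabolites <- metabolites[, c("id", "name", "role", "ref_conc",
                                 "amino_acid")]
  reactions <- reactions[, c("id", "reversible", "gamma", "lumped",
                             "class", "gpr")]

  if (is.list(stoich) && !is.matrix(stoich) && !inherits(stoich, "Matrix")) {
    if (length(stoich) != nrow(reactions))
      stop("stoich list must have one entry per reaction")
    i <- integer(0); j <- integer(0); x <- numeric(0)
    for (k in seq_along(stoich)) {
      sk <- stoich[[k]]
      if (length(sk) == 0) next
      mi <- match(names(sk), metabolites$id)
      if (anyNA(mi))
        stop("reaction '", reactions$id[k], "' references undeclared ",
             "metabolite(s): ",
             paste(names(sk)[is.na(mi)], collapse = ", "))
      i <- c(i, mi); j <- c(j, rep.int(k, length(sk))); x <- c(x, sk)
    }
    S <- Matrix::sparseMatrix(i = i, j = j, x = x,
                              dims = c(nrow(metabolites), nrow(reactions)),
                              dimnames = list(metabolites$id, reactions$id))
  } else {
    S <- Matrix::Matrix(stoich, sparse = TRUE)
    dimnames(S) <- list(metabolites$id, reactions$id)
  }
  rownames(metabolites) <- NULL
  rownames(reactions) <- NULL
  new("MetabolicNetwork", metabolites = metabolites, reactions = reactions,
      stoich = S, kineticOrders = kineticOrders)
}

## Core invariant checks shared by validity and validateNetwork().
validateNetworkCore <- function(object) {
  msgs <- character(0)
  met <- object@metabolites
  rxn <- object@reactions
  S <- object@stoich
  if (anyDuplicated(met$id))
    msgs <- c(msgs, paste0("duplicate metabolite id(s): ",
      paste(unique(met$id[duplicated(met$id)]), collapse = ", ")))
  if (anyDuplicated(rxn$id))
    msgs <- c(msgs, paste0("duplicate reaction id(s): ",
      paste(unique(rxn$id[duplicated(rxn$id)]), collapse = ", ")))
  if (!all(met$role %in% METABOLITE_ROLES))
    msgs <- c(msgs, "metabolite role must be internal/boundary/biomass-sink")
  if (!all(rxn$class %in% KINETIC_CLASSES))
    msgs <- c(msgs, paste0("unknown kinetic class: ",
      paste(setdiff(rxn$class, KINETIC_CLASSES), collapse = ", ")))
  if (nrow(S) != nrow(met) || ncol(S) != nrow(rxn))
    msgs <- c(msgs, "stoich dimensions do not match tables")
  if (any(rxn$gamma < 1L))
    msgs <- c(msgs, paste0("gamma must be >= 1 (reaction ",
      paste(rxn$id[rxn$gamma < 1L], collapse = ", "), ")"))
  bad <- rxn$gamma > 1L & !rxn$lumped
  if (any(bad))
    msgs <- c(msgs, paste0("gamma > 1 requires the lumped flag (reaction ",
      paste(rxn$id[bad], collapse = ", "), ")"))
  ## gamma counts irreversible steps, so a lumped reaction containing any
  ## (gamma > 1 implies at least one) must itself be irreversible
  bad <- rxn$reversible & rxn$gamma > 1L
  if (any(bad))
    msgs <- c(msgs, paste0("reversible reaction with irreversible lumped ",
      "steps (gamma > 1) must be irreversible: ",
      paste(rxn$id[bad], collapse = ", ")))
  intIds <- met$id[met$role == "internal"]
  if (length(intIds)) {
    used <- Matrix::rowSums(abs(S[match(intIds, met$id), , drop = FALSE])) > 0
    if (nrow(rxn) > 0 && any(!used))
      msgs <- c(msgs, paste0("internal metabolite(s) in no reaction: ",
        paste(intIds[!used], collapse = ", ")))
  }
  drains <- rxn$class == "amino_acid_drain"
  if (any(drains) && !any(met$amino_acid))
    msgs <- c(msgs, "amino_acid_drain reactions require amino_acid-flagged metabolites")
  msgs
}

#' Validate a network against its structural invariants
#'
#' Always returns a (possibly empty) character vector of violations rather
#' than raising; an empty report means the network is valid.
#'
#' @param network a \code{MetabolicNetwork}.
#' @return character vector of violation messages; empty iff valid.
#' @export
validateNetwork <- function(network) {
  stopifnot(is(network, "MetabolicNetwork"))
  validateNetworkCore(network)
}

#' Accessors for MetabolicNetwork
#'
#' @param x a \code{MetabolicNetwork} (or \code{KineticModel} where noted).
#' @param internal logical; restrict the stoichiometric matrix to internal
#'   metabolites (the rows entering steady-state balances)?
#' @name MetabolicNetwork-accessors
NULL

#' @rdname MetabolicNetwork-accessors
#' @export
setMethod("metabolites", "MetabolicNetwork", function(x) x@metabolites)

#' @rdname MetabolicNetwork-accessors
#' @export
setMethod("reactions", "MetabolicNetwork", function(x) x@reactions)

#' @rdname MetabolicNetwork-accessors
#' @export
setMethod("metaboliteIds", "MetabolicNetwork", function(x) x@metabolites$id)

#' @rdname MetabolicNetwork-accessors
#' @export
setMethod("reactionIds", "MetabolicNetwork", function(x) x@reactions$id)

#' @rdname MetabolicNetwork-accessors
#' @export
setMethod("internalMetabolites", "MetabolicNetwork",
  function(x) x@metabolites$id[x@metabolites$role == "internal"])

#' @rdname MetabolicNetwork-accessors
#' @export
setMethod("stoichMatrix", "MetabolicNetwork", function(x, internal = TRUE) {
  if (internal) {
    keep <- x@metabolites$role == "internal"
    x@stoich[keep, , drop = FALSE]
  } else x@stoich
})

setMethod("show", "MetabolicNetwork", function(object) {
  met <- object@metabolites
  cat("MetabolicNetwork with", nrow(met), "metabolites (",
      sum(met$role == "internal"), "internal ) and",
      nrow(object@reactions), "reactions\n")
  cat("  reversible:", sum(object@reactions$reversible),
      " lumped:", sum(object@reactions$lumped),
      " with GPR:", sum(nzchar(object@reactions$gpr)), "\n")
})

#' Extract one reaction as a self-contained list
#'
#' Returns the reaction's stoichiometry (named signed coefficients),
#' kinetic orders (defaults applied: order 2 where the absolute coefficient
#' is exactly 2, otherwise 1, unless overridden), reversibility, gamma and
#' kinetic class. This is the argument form the elementary rate-law
#' functions take.
#'
#' @param network a \code{MetabolicNetwork}.
#' @param id reaction id.
#' @return list with elements id, stoich, reversible, gamma, class, orders.
#' @export
getReaction <- function(network, id) {
  k <- match(id, network@reactions$id)
  if (is.na(k)) stop("unknown reaction id: ", id)
  col <- network@stoich[, k]
  nz <- which(col != 0)
  st <- stats::setNames(as.numeric(col[nz]), network@metabolites$id[nz])
  list(id = id,
       stoich = st,
       reversible = network@reactions$reversible[k],
       gamma = network@reactions$gamma[k],
       class = network@reactions$class[k],
       orders = kineticOrdersFor(network, k, st))
}

## Default kinetic orders for reaction column k with stoich st:
## |coefficient| == 2 -> 2, else 1; overridden per reaction id.
kineticOrdersFor <- function(network, k, st) {
  m <- ifelse(abs(st) == 2, 2, 1)
  names(m) <- names(st)
  ov <- network@kineticOrders[[network@reactions$id[k]]]
  if (!is.null(ov)) m[names(ov)] <- ov
  m
}
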