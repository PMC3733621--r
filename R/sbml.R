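SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
MATHML_NS <- "http://www.w3.org/1998/Math/MathML"

## tiny MathML builders (strings; wrapped in <math> at the call site)
mmlCi <- function(x) paste0("<ci> ", x, " </ci>")
mmlCn <- function(x) paste0("<cn> ", format(x, digits = 15), " </cn>")
mmlApply <- function(op, ...) {
  paste0("<apply><", op, "/>", paste0(..., collapse = ""), "</apply>")
}
mmlProdPow <- function(ids, orders) {
  if (!length(ids)) return(mmlCn(1))
  terms <- mapply(function(id, m) {
    if (m == 1) mmlCi(id) else mmlApply("power", mmlCi(id), mmlCn(m))
  }, ids, orders)
  if (length(terms) == 1) terms[[1]]
  else mmlApply("times", paste0(terms, collapse = ""))
}

## rate law of one reaction as a MathML string (parameters referenced by
## id: v_<rxn>, g_<rxn>, vf_<rxn>, vb_<rxn>, alpha)
rateMathML <- function(rx) {
  st <- rx$stoich; m <- rx$orders
  sub <- names(st)[st < 0]; prd <- names(st)[st > 0]
  vg <- c(mmlCi(paste0("v_", rx$id)), mmlCi(paste0("g_", rx$id)))
  body <- if (rx$class == "mass_action_irreversible") {
    ratio <- mmlApply("divide", mmlProdPow(sub, m[sub]),
                      mmlProdPow(prd, m[prd]))
    core <- if (rx$gamma > 1)
      mmlApply("power", ratio,
               mmlApply("divide", mmlCn(1), mmlCn(rx$gamma)))
    else ratio
    mmlApply("times", vg[1], vg[2], core)
  } else if (rx$class == "mass_action_reversible") {
    mmlApply("times", mmlCi(paste0("g_", rx$id)),
      mmlApply("minus",
        mmlApply("times", mmlCi(paste0("vf_", rx$id)),
                 mmlProdPow(sub, m[sub])),
        mmlApply("times", mmlCi(paste0("vb_", rx$id)),
                 mmlProdPow(prd, m[prd]))))
  } else if (rx$class %in% c("amino_acid_drain", "generic_drain")) {
    mmlApply("times", vg[1], vg[2],
      if (length(sub))
        mmlApply("power", mmlProdPow(sub, rep(1, length(sub))),
                 mmlCi("alpha"))
      else mmlCn(1))
  } else {
    mmlApply("times", vg[1], vg[2])
  }
  paste0('<math xmlns="', MATHML_NS, '">', body, "</math>")
}

#' Export a network (and reference fluxes) to SBML Level 3 Version 1
#'
#' Writes species (with boundary flags), reactions (stoichiometry,
#' reversibility), generalized-mass-action kinetic laws as MathML, and a
#' package annotation per reaction carrying the lumping step count gamma,
#' the kinetic class, the GPR string and the reference flux, so that
#' re-import reproduces the network exactly.
#'
#' @param network a \code{MetabolicNetwork} (must contain reactions).
#' @param path output file path.
#' @param ref optional \code{ReferenceState}; fluxes stored per reaction.
#' @return the path, invisibly.
#' @export
writeSBML <- function(network, path, ref = NULL) {
  if (nrow(network@reactions) == 0)
    stop("cannot export SBML: no reactions")
  doc <- xml2::xml_new_root("sbml", xmlns = SBML_NS, level = "3",
                            version = "1")
  mdl <- xml2::xml_add_child(doc, "model", id = "gmakin_model")
  cmp <- xml2::xml_add_child(mdl, "listOfCompartments")
  xml2::xml_add_child(cmp, "compartment", id = "cell", constant = "true")

  los <- xml2::xml_add_child(mdl, "listOfSpecies")
  met <- network@metabolites
  for (i in seq_len(nrow(met))) {
    sp <- xml2::xml_add_child(los, "species",
      id = met$id[i], name = met$name[i], compartment = "cell",
      hasOnlySubstanceUnits = "false",
      boundaryCondition = if (met$role[i] == "internal") "false" else "true",
      constant = "false")
    ann <- xml2::xml_add_child(sp, "annotation")
    xml2::xml_add_child(ann, "speciesInfo",
      role = met$role[i],
      aminoAcid = tolower(as.character(met$amino_acid[i])),
      refConc = as.character(met$ref_conc[i]))
  }

  lor <- xml2::xml_add_child(mdl, "listOfReactions")
  rxn <- network@reactions
  for (i in seq_len(nrow(rxn))) {
    rx <- getReaction(network, rxn$id[i])
    re <- xml2::xml_add_child(lor, "reaction", id = rxn$id[i],
      reversible = tolower(as.character(rxn$reversible[i])),
      fast = "false")
    ann <- xml2::xml_add_child(re, "annotation")
    xml2::xml_add_child(ann, "reactionInfo",
      gamma = as.character(rxn$gamma[i]),
      lumped = tolower(as.character(rxn$lumped[i])),
      kineticClass = rxn$class[i],
      gpr = rxn$gpr[i],
      refFlux = if (is.null(ref)) "" else
        as.character(ref@v[rxn$id[i]]))
    st <- rx$stoich
    if (any(st < 0)) {
      lre <- xml2::xml_add_child(re, "listOfReactants")
      for (id in names(st)[st < 0])
        xml2::xml_add_child(lre, "speciesReference", species = id,
          stoichiometry = as.character(abs(st[id])), constant = "true")
    }
    if (any(st > 0)) {
      lpr <- xml2::xml_add_child(re, "listOfProducts")
      for (id in names(st)[st > 0])
        xml2::xml_add_child(lpr, "speciesReference", species = id,
          stoichiometry = as.character(st[id]), constant = "true")
    }
    kl <- xml2::xml_add_child(re, "kineticLaw")
    mathNode <- xml2::read_xml(rateMathML(rx))
    xml2::xml_add_child(kl, mathNode)
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Import a network from SBML
#'
#' Reads SBML written by \code{\link{writeSBML}} (and plain SBML L3 core:
#' species, reactions, stoichiometry, reversibility; the package
#' annotations for gamma/class/GPR/reference flux are used when present).
#'
#' @param path SBML file path.
#' @return list with \code{network} (a \code{MetabolicNetwork}) and
#'   \code{ref} (a \code{ReferenceState}, or NULL when the file carries
#'   no flux annotations).
#' @export
readSBML <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  spNodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  if (!length(spNodes)) stop("SBML file has no species: ", path)
  att <- function(nodes, a, default = NA_character_) {
    v <- xml2::xml_attr(nodes, a)
    ifelse(is.na(v), default, v)
  }
  info <- lapply(spNodes, function(n)
    xml2::xml_find_first(n, "./annotation/speciesInfo"))
  role <- vapply(seq_along(spNodes), function(i) {
    r <- if (!inherits(info[[i]], "xml_missing"))
      xml2::xml_attr(info[[i]], "role") else NA_character_
    if (!is.na(r)) r
    else if (identical(xml2::xml_attr(spNodes[[i]], "boundaryCondition"),
                       "true")) "boundary" else "internal"
  }, character(1))
  aa <- vapply(seq_along(spNodes), function(i) {
    if (inherits(info[[i]], "xml_missing")) return(FALSE)
    identical(xml2::xml_attr(info[[i]], "aminoAcid"), "true")
  }, logical(1))
  rc <- vapply(seq_along(spNodes), function(i) {
    if (inherits(info[[i]], "xml_missing")) return(NA_real_)
    suppressWarnings(as.numeric(xml2::xml_attr(info[[i]], "refConc")))
  }, numeric(1))
  met <- data.frame(id = att(spNodes, "id"),
                    name = att(spNodes, "name", ""),
                    role = role, ref_conc = rc, amino_acid = aa,
                    stringsAsFactors = FALSE)
  met$name[!nzchar(met$name)] <- met$id[!nzchar(met$name)]

  rxNodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  if (!length(rxNodes)) stop("SBML file has no reactions: ", path)
  ids <- att(rxNodes, "id")
  stoichs <- list(); gammas <- integer(0); classes <- character(0)
  gprs <- character(0); lumps <- logical(0); vref <- numeric(0)
  haveV <- FALSE
  for (i in seq_along(rxNodes)) {
    n <- rxNodes[[i]]
    s <- numeric(0)
    for (side in c("listOfReactants", "listOfProducts")) {
      refs <- xml2::xml_find_all(n, paste0("./", side, "/speciesReference"))
      for (r in refs) {
        sp <- xml2::xml_attr(r, "species")
        coef <- as.numeric(xml2::xml_attr(r, "stoichiometry"))
        if (is.na(coef)) coef <- 1
        if (side == "listOfReactants") coef <- -coef
        s[sp] <- (if (sp %in% names(s)) s[sp] else 0) + coef
      }
    }
    stoichs[[i]] <- s
    ri <- xml2::xml_find_first(n, "./annotation/reactionInfo")
    if (!inherits(ri, "xml_missing")) {
      gammas[i] <- as.integer(xml2::xml_attr(ri, "gamma"))
      lumps[i] <- identical(xml2::xml_attr(ri, "lumped"), "true")
      classes[i] <- xml2::xml_attr(ri, "kineticClass")
      gprs[i] <- xml2::xml_attr(ri, "gpr")
      fv <- suppressWarnings(as.numeric(xml2::xml_attr(ri, "refFlux")))
      vref[i] <- fv
      if (!is.na(fv)) haveV <- TRUE
    } else {
      gammas[i] <- 1L; lumps[i] <- FALSE; classes[i] <- NA_character_
      gprs[i] <- ""; vref[i] <- NA_real_
    }
  }
  gprs[is.na(gprs)] <- ""
  rxn <- data.frame(id = ids,
                    reversible = att(rxNodes, "reversible",
                                     "false") == "true",
                    gamma = gammas, lumped = lumps,
                    gpr = gprs, stringsAsFactors = FALSE)
  if (!all(is.na(classes))) rxn$class <- classes
  net <- MetabolicNetwork(met, rxn, stoichs)
  ref <- if (haveV) referenceState(stats::setNames(vref, ids)) else NULL
  list(network = net, ref = ref)
}
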