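#' Read a metabolic network reconstruction
#'
#' Reads a network in one of three dialects:
#' \describe{
#'   \item{tsv}{a tab-separated reaction table with header columns
#'     \code{id}, \code{equation} (e.g. \code{"A + 2 B -> C"}; \code{"<->"}
#'     marks a reversible reaction), and optional \code{gamma}, \code{gpr},
#'     \code{class}. Unknown columns are ignored with a warning. Metabolite
#'     roles come from a companion metabolite table (argument
#'     \code{metabolitesPath}, columns \code{id}, \code{name}, \code{role},
#'     \code{ref_conc}, \code{amino_acid}); without one, ids suffixed
#'     \code{_ext} are boundary, \code{_bio} biomass sinks, the rest
#'     internal.}
#'   \item{json}{a single JSON object with \code{metabolites},
#'     \code{reactions} and \code{kinetic_orders} fields as written by
#'     \code{\link{writeNetwork}}.}
#'   \item{sbml}{SBML Level 3 Version 1, see \code{\link{readSBML}}.}
#' }
#'
#' @param path file path.
#' @param dialect one of \code{"tsv"}, \code{"json"}, \code{"sbml"};
#'   guessed from the file extension by default.
#' @param metabolitesPath optional companion metabolite TSV (tsv dialect).
#' @return a validated \code{\linkS4class{MetabolicNetwork}}.
#' @export
readNetwork <- function(path, dialect = c("auto", "tsv", "json", "sbml"),
                        metabolitesPath = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(path))
    dialect <- switch(ext, json = "json", xml = "sbml", sbml = "sbml", "tsv")
  }
  if (!file.exists(path)) stop("network file not found: ", path)
  switch(dialect,
         tsv = readNetworkTSV(path, metabolitesPath),
         json = readNetworkJSON(path),
         sbml = readSBML(path)$network)
}

#' Write a metabolic network reconstruction
#'
#' Writes the tabular (TSV) or JSON dialect read back by
#' \code{\link{readNetwork}}; re-reading reproduces the network exactly
#' (canonical ordering preserved). For SBML use \code{\link{writeSBML}}.
#'
#' @param network a \code{MetabolicNetwork}.
#' @param path output file path.
#' @param dialect \code{"tsv"} or \code{"json"}.
#' @param metabolitesPath optional metabolite-table path (tsv dialect);
#'   when given, roles, reference concentrations and amino-acid flags
#'   survive the round trip exactly.
#' @export
writeNetwork <- function(network, path, dialect = c("tsv", "json"),
                         metabolitesPath = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "json") return(writeNetworkJSON(network, path))
  rxn <- network@reactions
  df <- data.frame(id = rxn$id,
                   equation = vapply(rxn$id, function(id)
                     formatEquation(getReaction(network, id)), character(1)),
                   gamma = rxn$gamma,
                   gpr = rxn$gpr,
                   class = rxn$class,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(metabolitesPath)) {
    met <- network@metabolites
    utils::write.table(met[, c("id", "name", "role", "ref_conc",
                               "amino_acid")],
                       metabolitesPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

readNetworkTSV <- function(path, metabolitesPath = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "", check.names = FALSE)
  needed <- c("id", "equation")
  if (!all(needed %in% names(df)))
    stop("network TSV must have header columns 'id' and 'equation': ", path)
  known <- c("id", "equation", "gamma", "gpr", "class")
  extra <- setdiff(names(df), known)
  if (length(extra))
    warning("ignoring unknown column(s) in ", path, ": ",
            paste(extra, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$id))
    stop("duplicate reaction id(s) in ", path, ": ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  parsed <- lapply(seq_len(nrow(df)), function(k) {
    eq <- tryCatch(parseEquation(df$equation[k]),
                   error = function(e)
                     stop("record ", k, " (reaction '", df$id[k], "'): ",
                          conditionMessage(e), call. = FALSE))
    eq
  })
  metIds <- unique(unlist(lapply(parsed, function(p) names(p$stoich))))
  if (!is.null(metabolitesPath)) {
    met <- utils::read.table(metabolitesPath, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE, quote = "")
    unknown <- setdiff(metIds, met$id)
    if (length(unknown))
      stop("equation references metabolite(s) not in ", metabolitesPath,
           ": ", paste(unknown, collapse = ", "))
  } else {
    met <- data.frame(id = metIds,
                      name = metIds,
                      role = ifelse(grepl("_ext$", metIds), "boundary",
                             ifelse(grepl("_bio$", metIds), "biomass-sink",
                                    "internal")),
                      ref_conc = NA_real_,
                      amino_acid = FALSE,
                      stringsAsFactors = FALSE)
  }
  rxn <- data.frame(
    id = df$id,
    reversible = vapply(parsed, `[[`, logical(1), "reversible"),
    gamma = if (is.null(df$gamma)) 1L else as.integer(df$gamma),
    gpr = if (is.null(df$gpr)) "" else ifelse(is.na(df$gpr), "", df$gpr),
    class = if (is.null(df$class)) NA_character_ else df$class,
    stringsAsFactors = FALSE)
  if (all(is.na(rxn$class))) rxn$class <- NULL
  MetabolicNetwork(met, rxn, lapply(parsed, `[[`, "stoich"))
}

writeNetworkJSON <- function(network, path) {
  obj <- list(
    metabolites = network@metabolites,
    reactions = cbind(network@reactions,
                      equation = vapply(network@reactions$id, function(id)
                        formatEquation(getReaction(network, id)),
                        character(1))),
    kinetic_orders = network@kineticOrders)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

readNetworkJSON <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rxn <- as.data.frame(obj$reactions, stringsAsFactors = FALSE)
  parsed <- lapply(rxn$equation, parseEquation)
  rxn$equation <- NULL
  ko <- lapply(obj$kinetic_orders, unlist)
  MetabolicNetwork(as.data.frame(obj$metabolites, stringsAsFactors = FALSE),
                   rxn, lapply(parsed, `[[`, "stoich"),
                   kineticOrders = ko)
}

## "A + 2 B -> C" / "A <-> B". Coefficients are plain numbers preceding a
## metabolite token; terms separated by '+'.
parseEquation <- function(text) {
  rev <- grepl("<->", text, fixed = TRUE)
  arrow <- if (rev) "<->" else "->"
  sides <- strsplit(text, arrow, fixed = TRUE)[[1]]
  if (length(sides) != 2)
    stop("malformed equation (need one '", arrow, "'): '", text, "'")
  parseSide <- function(side, sign) {
    side <- trimws(side)
    if (!nzchar(side)) return(numeric(0))
    if (grepl("^\\+|\\+\\s*\\+|\\+$", side))
      stop("malformed stoichiometry (dangling '+') in '", text, "'")
    terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1]])
    out <- numeric(0)
    for (tm in terms) {
      if (!nzchar(tm)) stop("malformed stoichiometry term in '", text, "'")
      bits <- strsplit(tm, "[[:space:]]+")[[1]]
      if (length(bits) == 1) { coef <- 1; id <- bits }
      else if (length(bits) == 2) {
        coef <- suppressWarnings(as.numeric(bits[1]))
        if (is.na(coef))
          stop("malformed coefficient '", bits[1], "' in '", text, "'")
        id <- bits[2]
      } else stop("malformed stoichiometry term '", tm, "' in '", text, "'")
      out[id] <- (if (is.na(out[id])) 0 else out[id]) + sign * coef
    }
    out
  }
  lhs <- parseSide(sides[1], -1)
  rhs <- parseSide(sides[2], +1)
  st <- lhs
  for (id in names(rhs)) st[id] <- (if (id %in% names(st)) st[id] else 0) + rhs[id]
  st <- st[st != 0]
  if (length(st) == 0) stop("empty stoichiometry in '", text, "'")
  list(stoich = st, reversible = rev)
}

formatEquation <- function(rx) {
  st <- rx$stoich
  fmt <- function(ids, coefs) {
    if (!length(ids)) return("")
    paste(mapply(function(id, cf) {
      if (cf == 1) id
      else paste(format(cf, digits = 17, trim = TRUE,
                        scientific = FALSE), id)
    }, ids, abs(coefs)), collapse = " + ")
  }
  lhs <- st[st < 0]; rhs <- st[st > 0]
  arrow <- if (rx$reversible) "<->" else "->"
  paste(fmt(names(lhs), lhs), arrow, fmt(names(rhs), rhs))
}
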