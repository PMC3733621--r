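#' Parse a gene-protein-reaction (GPR) rule
#'
#' Parses boolean gene-association strings such as
#' \code{"(G1 or G2) and G3"} into an expression tree. Connectives
#' \code{and}/\code{or} are case-insensitive; parentheses group. Lumped
#' reactions may carry one rule per step, separated by \code{";"}; each
#' step is parsed separately and the result is a \code{steps} node (the
#' expression aggregator combines steps by geometric mean).
#'
#' @param text GPR string; empty (or whitespace) yields an empty
#'   association.
#' @return a list tree with nodes \code{list(op = "leaf", gene = id)},
#'   \code{list(op = "and"/"or", children = list(...))},
#'   \code{list(op = "steps", children = list(...))}, or \code{NULL} for an
#'   empty association.
#' @examples
#' parseGPR("(G1 or G2) and G3")
#' @export
parseGPR <- function(text) {
  if (is.null(text) || is.na(text) || !nzchar(trimws(text))) return(NULL)
  parts <- strsplit(text, ";", fixed = TRUE)[[1]]
  parts <- parts[nzchar(trimws(parts))]
  trees <- lapply(parts, parseGPRExpr)
  if (length(trees) == 1L) trees[[1]] else list(op = "steps", children = trees)
}

parseGPRExpr <- function(text) {
  toks <- gprTokens(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks; st$pos <- 1L
  tree <- gprParseOr(st)
  if (st$pos <= length(st$toks))
    stop("GPR parse error in '", text, "': unexpected token '",
         st$toks[st$pos], "'")
  tree
}

gprTokens <- function(text) {
  text <- gsub("([()])", " \\1 ", text)
  toks <- strsplit(trimws(text), "[[:space:]]+")[[1]]
  toks[nzchar(toks)]
}

gprPeek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA
gprNext <- function(st) { t <- gprPeek(st); st$pos <- st$pos + 1L; t }

gprParseOr <- function(st) {
  left <- gprParseAnd(st)
  kids <- list(left)
  while (!is.na(gprPeek(st)) && tolower(gprPeek(st)) == "or") {
    gprNext(st)
    kids <- c(kids, list(gprParseAnd(st)))
  }
  if (length(kids) == 1L) left else list(op = "or", children = kids)
}

gprParseAnd <- function(st) {
  left <- gprParseAtom(st)
  kids <- list(left)
  while (!is.na(gprPeek(st)) && tolower(gprPeek(st)) == "and") {
    gprNext(st)
    kids <- c(kids, list(gprParseAtom(st)))
  }
  if (length(kids) == 1L) left else list(op = "and", children = kids)
}

gprParseAtom <- function(st) {
  t <- gprNext(st)
  if (is.na(t)) stop("GPR parse error: dangling connective")
  if (t == "(") {
    inner <- gprParseOr(st)
    cl <- gprNext(st)
    if (is.na(cl) || cl != ")")
      stop("GPR parse error: unbalanced parentheses")
    return(inner)
  }
  if (t == ")" || tolower(t) %in% c("and", "or"))
    stop("GPR parse error: unexpected token '", t, "'")
  list(op = "leaf", gene = t)
}

#' Genes referenced by a GPR tree
#' @param tree a tree from \code{\link{parseGPR}} (or \code{NULL}).
#' @return character vector of gene ids.
#' @export
gprGenes <- function(tree) {
  if (is.null(tree)) return(character(0))
  if (tree$op == "leaf") return(tree$gene)
  unique(unlist(lapply(tree$children, gprGenes)))
}

## Evaluate one GPR tree given per-gene ratios and optional reference
## intensities. AND = min (complex limited by its scarcest subunit);
## OR = reference-intensity-weighted mean of child ratios (capacity of
## isoenzymes adds); steps (lumped sequential reactions) = geometric mean.
evalGPR <- function(tree, ratios, refInt = NULL, warnMissing = TRUE) {
  if (is.null(tree)) return(1)
  switch(tree$op,
    leaf = {
      r <- ratios[tree$gene]
      if (is.na(r)) {
        if (warnMissing)
          warning("gene '", tree$gene,
                  "' missing from expression data; ratio defaulted to 1",
                  call. = FALSE)
        r <- 1
      }
      unname(r)
    },
    and = min(vapply(tree$children, evalGPR, numeric(1),
                     ratios = ratios, refInt = refInt,
                     warnMissing = warnMissing)),
    or = {
      vals <- vapply(tree$children, evalGPR, numeric(1),
                     ratios = ratios, refInt = refInt,
                     warnMissing = warnMissing)
      w <- rep(1, length(vals))
      if (!is.null(refInt)) {
        ## weight each branch by its reference intensity where available;
        ## branch intensity = sum over its genes
        w <- vapply(tree$children, function(ch) {
          gi <- refInt[gprGenes(ch)]
          if (all(is.na(gi))) 1 else sum(gi, na.rm = TRUE)
        }, numeric(1))
      }
      sum(w * vals) / sum(w)
    },
    steps = {
      vals <- vapply(tree$children, evalGPR, numeric(1),
                     ratios = ratios, refInt = refInt,
                     warnMissing = warnMissing)
      exp(mean(log(vals)))
    },
    stop("malformed GPR tree node: ", tree$op)
  )
}

#' Aggregate per-gene expression ratios to reaction level
#'
#' Computes the overall expression ratio g of every reaction from per-gene
#' ratios via its GPR rule: reactions without a rule get g = 1; AND nodes
#' take the minimum of their children (a complex is limited by its scarcest
#' subunit); OR nodes take the mean of their children weighted by reference
#' intensities when provided (isoenzyme capacities add); the per-step rules
#' of lumped reactions (";"-separated) combine by geometric mean, matching
#' the multiplicative role of g in a lumped flux. Genes absent from
#' \code{ratios} default to 1 with a warning.
#'
#' @param network a \code{MetabolicNetwork}.
#' @param ratios named numeric vector (or 2-column data.frame gene_id,
#'   ratio) of per-gene expression ratios (condition / reference).
#' @param referenceIntensities optional named numeric vector of per-gene
#'   reference-condition intensities used to weight OR branches.
#' @return named numeric vector g over all reactions (an
#'   \code{ExpressionVector} in the model's sense: strictly positive,
#'   1 where no gene association).
#' @export
aggregateExpression <- function(network, ratios,
                                referenceIntensities = NULL) {
  if (is.data.frame(ratios)) {
    stopifnot(ncol(ratios) >= 2)
    ratios <- stats::setNames(as.numeric(ratios[[2]]),
                              as.character(ratios[[1]]))
  }
  if (any(ratios <= 0)) stop("expression ratios must be strictly positive")
  rxn <- network@reactions
  g <- stats::setNames(rep(1, nrow(rxn)), rxn$id)
  missing <- character(0)
  for (k in seq_len(nrow(rxn))) {
    if (!nzchar(rxn$gpr[k])) next
    tree <- parseGPR(rxn$gpr[k])
    miss <- setdiff(gprGenes(tree), names(ratios))
    missing <- c(missing, miss)
    g[k] <- evalGPR(tree, ratios, refInt = referenceIntensities,
                    warnMissing = FALSE)
  }
  if (length(missing))
    warning("gene(s) missing from expression data, ratio defaulted to 1: ",
            paste(unique(missing), collapse = ", "), call. = FALSE)
  g
}
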