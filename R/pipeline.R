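CONFIG_KEYS <- list(
  paths = c("network", "metabolites", "fluxes", "exchanges", "expression",
            "observed", "output_dir"),
  parameters = c("alpha", "beta", "lambda", "x_mw", "inhibition",
                 "woa_uptake", "atp_per_woa", "atp_met", "phi"),
  solver = c("tol_residual", "max_iter"),
  chemostat = c("dilution_rate", "glucose_uptake_reaction", "glucose_met",
                "biomass_floor", "feed_glucose"),
  analysis = c("k_bounds", "biomass_fraction", "lowess_span",
               "uptake_grid", "extrapolation", "inhibit_reactions",
               "subset", "sweep"),
  seed = character(0))

#' Load and validate a pipeline run configuration
#'
#' Reads the YAML configuration driving \code{\link{runPipeline}}. The
#' schema is strict: unknown keys are rejected, and all referenced input
#' files must exist at load time.
#'
#' @param path YAML file path.
#' @return validated config list (class \code{"runConfig"}).
#' @export
loadRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), names(CONFIG_KEYS))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (blk in intersect(names(cfg), names(CONFIG_KEYS))) {
    if (blk == "seed") next
    bad <- setdiff(names(cfg[[blk]]), CONFIG_KEYS[[blk]])
    if (length(bad))
      stop("unknown key(s) in '", blk, "': ", paste(bad, collapse = ", "))
  }
  for (p in setdiff(names(cfg$paths), "output_dir")) {
    if (!file.exists(cfg$paths[[p]]))
      stop("input file for paths$", p, " not found: ", cfg$paths[[p]])
  }
  cfg$config_path <- path
  class(cfg) <- "runConfig"
  cfg
}

cfgParams <- function(cfg, phiDefault = numeric(0)) {
  p <- cfg$parameters
  rateParameters(
    alpha = p$alpha %||% 0.1,
    beta = p$beta %||% 30,
    lambda = p$lambda %||% 1,
    xMW = p$x_mw %||% 1,
    phi = if (!is.null(p$phi)) unlist(p$phi) else phiDefault,
    inhibition = if (!is.null(p$inhibition)) unlist(p$inhibition)
                 else numeric(0),
    woaUptake = p$woa_uptake %||% 0,
    atpPerWoa = p$atp_per_woa %||% 2,
    atpMet = p$atp_met %||% "ATP")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

cfgModel <- function(cfg) {
  net <- readNetwork(cfg$paths$network,
                     metabolitesPath = cfg$paths$metabolites)
  if (!is.null(cfg$paths$fluxes)) {
    fl <- utils::read.table(cfg$paths$fluxes, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    ref <- referenceState(fl)
  } else if (!is.null(cfg$paths$exchanges)) {
    ex <- utils::read.table(cfg$paths$exchanges, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    ref <- estimateReferenceFluxes(net, ex)
  } else stop("config needs paths$fluxes or paths$exchanges")
  g <- numeric(0)
  if (!is.null(cfg$paths$expression)) {
    expr <- utils::read.table(cfg$paths$expression, sep = "\t",
                              header = TRUE, stringsAsFactors = FALSE)
    g <- aggregateExpression(net, expr)
  }
  params <- cfgParams(cfg)
  list(network = net, ref = ref, g = g, params = params,
       model = assembleModel(net, ref, g, params))
}

writeTSV <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

runMetadata <- function(cfg, outDir, extra = list()) {
  meta <- c(list(
    seed = cfg$seed %||% NA,
    config_md5 = if (!is.null(cfg$config_path))
      unname(tools::md5sum(cfg$config_path)) else NA,
    package_version = as.character(utils::packageVersion("gmakin")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")), extra)
  jsonlite::write_json(meta, file.path(outDir, "run-metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the model-construction and analysis pipeline
#'
#' Single entry point wiring configuration, model construction,
#' steady-state solving and the model-based analyses; the thin command
#' line wrapper in \code{inst/scripts/gmakin.R} exposes it as a shell
#' tool. Outputs are TSV tables plus a JSON run-metadata sidecar in the
#' configured output directory.
#'
#' @param config a config list from \code{\link{loadRunConfig}} (or a
#'   path to a YAML file).
#' @param subcommand one of \code{build}, \code{solve}, \code{chemostat},
#'   \code{rank-targets}, \code{dose-response}, \code{make-fixtures}.
#' @param outDir output directory (defaults to
#'   \code{config$paths$output_dir}).
#' @return invisibly, a list of the files written (and the main result
#'   object).
#' @export
runPipeline <- function(config,
                        subcommand = c("build", "solve", "chemostat",
                                       "rank-targets", "dose-response",
                                       "make-fixtures"),
                        outDir = NULL) {
  subcommand <- match.arg(subcommand)
  if (is.character(config)) config <- loadRunConfig(config)
  outDir <- outDir %||% config$paths$output_dir %||% "."
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  result <- NULL

  if (subcommand == "make-fixtures") {
    fx <- makeYeastLikeFixture()
    files <- c(
      writeNetwork(fx$network, file.path(outDir, "yeast_like.tsv"),
                   metabolitesPath = file.path(outDir,
                                               "yeast_like_metabolites.tsv")),
      writeTSV(data.frame(reaction_id = names(fx$ref@v),
                          flux = unname(fx$ref@v)),
               file.path(outDir, "yeast_like_fluxes.tsv")),
      writeTSV(data.frame(drain_id = names(fx$phi),
                          phi = unname(fx$phi)),
               file.path(outDir, "yeast_like_phi.tsv")))
    toy <- makeToyNetwork("branched", n = 6, seed = config$seed %||% 1)
    files <- c(files,
      writeNetwork(toy$network, file.path(outDir, "toy_branched.tsv")),
      writeTSV(data.frame(reaction_id = names(toy$ref@v),
                          flux = unname(toy$ref@v)),
               file.path(outDir, "toy_branched_fluxes.tsv")))
    result <- fx
  } else if (subcommand == "build") {
    ctx <- cfgModel(config)
    files <- c(
      writeNetwork(ctx$network, file.path(outDir, "network.tsv"),
                   metabolitesPath = file.path(outDir, "metabolites.tsv")),
      writeSBML(ctx$network, file.path(outDir, "model.sbml"),
                ref = ctx$ref),
      writeTSV(data.frame(reaction_id = names(ctx$ref@v),
                          flux = unname(ctx$ref@v)),
               file.path(outDir, "reference_fluxes.tsv")))
    result <- ctx$model
  } else if (subcommand == "solve") {
    ctx <- cfgModel(config)
    tol <- config$solver$tol_residual %||% 1e-9
    sol <- solveSteadyState(ctx$model, tol = tol,
                            maxIter = config$solver$max_iter %||% 100L)
    files <- c(
      writeTSV(data.frame(metabolite = names(sol$c),
                          concentration = unname(sol$c)),
               file.path(outDir, "concentrations.tsv")),
      writeTSV(data.frame(reaction = names(sol$r),
                          rate = unname(sol$r)),
               file.path(outDir, "rates.tsv")))
    jsonlite::write_json(
      list(converged = sol$converged, residual_norm = sol$residual_norm,
           iterations = sol$iterations),
      file.path(outDir, "diagnostics.json"), auto_unbox = TRUE,
      digits = NA)
    files <- c(files, file.path(outDir, "diagnostics.json"))
    result <- sol
  } else if (subcommand == "chemostat") {
    ctx <- cfgModel(config)
    ch <- config$chemostat
    if (is.null(ch$dilution_rate))
      stop("chemostat subcommand needs chemostat$dilution_rate")
    setup <- chemostatSetup(ch$dilution_rate,
                            ch$glucose_uptake_reaction, ch$glucose_met,
                            feedGlucose = ch$feed_glucose %||% NA_real_,
                            biomassFloor = ch$biomass_floor %||% 1e-3)
    refModel <- assembleModel(ctx$network, ctx$ref,
                              params = ctx$params)
    cal <- calibrateChemostat(refModel, setup)
    condModel <- assembleModel(ctx$network, ctx$ref, ctx$g,
      params = {p <- ctx$params; p@lambda <- cal$lambda; p})
    cs <- simulateChemostat(condModel, cal$setup)
    out <- list(biomass = cs$biomass,
                extracellular_glucose = cs$extracellularGlucose,
                growth_rate = cs$growthRate, washed_out = cs$washedOut,
                lambda = cal$lambda, feed_glucose = cal$feedGlucose)
    jsonlite::write_json(out, file.path(outDir, "chemostat.json"),
                         auto_unbox = TRUE, digits = NA)
    files <- file.path(outDir, "chemostat.json")
    result <- cs
  } else if (subcommand == "rank-targets") {
    if (is.null(config$paths$observed))
      stop("rank-targets needs paths$observed ",
           "(TSV of metabolite concentration ratios)")
    ctx <- cfgModel(config)
    obs <- utils::read.table(config$paths$observed, sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE)
    obsV <- stats::setNames(as.numeric(obs[[2]]), as.character(obs[[1]]))
    kb <- config$analysis$k_bounds %||% c(0.1, 10)
    rk <- rankTargets(ctx$model, obsV, kBounds = as.numeric(kb))
    files <- writeTSV(rk, file.path(outDir, "ranked_targets.tsv"))
    result <- rk
  } else if (subcommand == "dose-response") {
    ctx <- cfgModel(config)
    ch <- config$chemostat
    if (is.null(ch$dilution_rate))
      stop("dose-response needs the chemostat block")
    setup <- chemostatSetup(ch$dilution_rate,
                            ch$glucose_uptake_reaction, ch$glucose_met,
                            biomassFloor = ch$biomass_floor %||% 1e-3)
    refModel <- assembleModel(ctx$network, ctx$ref, params = ctx$params)
    cal <- calibrateChemostat(refModel, setup)
    grid <- as.numeric(config$analysis$uptake_grid %||%
                         seq(0, 10, by = 1))
    gFull <- if (length(ctx$g)) ctx$g else
      stats::setNames(rep(1, nrow(reactions(ctx$network))),
                      reactionIds(ctx$network))
    build <- function(g, w) {
      p <- ctx$params; p@lambda <- cal$lambda; p@woaUptake <- w
      assembleModel(ctx$network, ctx$ref, g, p)
    }
    dr <- doseResponse(build, gFull, grid, cal$setup,
                       extrapolation = config$analysis$extrapolation
                       %||% 2)
    files <- writeTSV(dr, file.path(outDir, "dose_response.tsv"))
    result <- dr
  }
  runMetadata(config, outDir, list(subcommand = subcommand,
                                   files = basename(files)))
  invisible(list(files = files, result = result))
}
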