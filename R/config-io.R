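#' Read and write full simulation configurations as JSON
#'
#' The JSON file has three blocks: `locus` (see [readLocusConfig()]),
#' `dfe` and `simulation`. `writeSimulationConfig()` emits a complete echo
#' of a configuration (including the applied rescaling factor and the
#' package version) so that runs are reproducible from their metadata.
#'
#' @param path JSON file path.
#' @return `readSimulationConfig()` returns a list with elements `config`
#'   ([SimulationConfig-class]), `template` ([LocusTemplate-class]) and
#'   `dfe` ([DFEConfig-class]).
#' @export
readSimulationConfig <- function(path) {
  js <- jsonlite::fromJSON(path)
  template <- readLocusConfig(path)
  d <- js$dfe %||% list()
  dfe <- dfeConfig(
    pNeutralExon = d$p_neutral_exon %||% 0.25,
    gammaMeanS = d$gamma_mean_s %||% -0.000154,
    gammaShape = d$gamma_shape %||% 0.245,
    hDel = d$h_del %||% 0.5,
    tsrSBefore = d$tsr_s_before %||% 0)
  s <- js$simulation %||% list()
  config <- simulationConfig(
    N = s$N %||% 42000L,
    muSite = s$mu_site %||% 3.0e-8,
    recSite = s$rec_site %||% 7.4e-9,
    burninMultiplier = s$burnin_multiplier %||% 10,
    selGenerations = s$sel_generations %||% 30L,
    survivalRatio = s$survival_ratio %||% 20,
    herbicideOn = s$herbicide_on %||% TRUE,
    seed = s$seed %||% NA_integer_,
    engine = s$engine %||% "linked",
    pruneEvery = s$prune_every %||% 150L)
  if (!is.null(s$rescale_lambda) && s$rescale_lambda > 1) {
    config@rescaleLambda <- as.numeric(s$rescale_lambda)
    validObject(config)
  }
  list(config = config, template = template, dfe = dfe)
}

#' @rdname readSimulationConfig
#' @param config a [SimulationConfig-class].
#' @param template a [LocusTemplate-class].
#' @param dfe a [DFEConfig-class].
#' @export
writeSimulationConfig <- function(config, template, dfe, path) {
  ex <- exonIntervals(template)
  js <- list(
    locus = list(length_bp = template@lengthBp,
                 exon_intervals = lapply(seq_len(nrow(ex)), function(i)
                   c(ex[i, 1L], ex[i, 2L])),
                 tsr_sites = template@tsrSites,
                 name = template@name),
    dfe = list(p_neutral_exon = dfe@pNeutralExon,
               gamma_mean_s = dfe@gammaMeanS,
               gamma_shape = dfe@gammaShape,
               h_del = dfe@hDel,
               tsr_s_before = dfe@tsrSBefore),
    simulation = list(N = config@N, mu_site = config@muSite,
                      rec_site = config@recSite,
                      burnin_multiplier = config@burninMultiplier,
                      sel_generations = config@selGenerations,
                      survival_ratio = config@survivalRatio,
                      herbicide_on = config@herbicideOn,
                      rescale_lambda = config@rescaleLambda,
                      seed = config@seed,
                      engine = config@engine,
                      prune_every = config@pruneEvery),
    software = list(package = "herbisweep",
                    version = as.character(
                      utils::packageVersion("herbisweep"))))
  jsonlite::write_json(js, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
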