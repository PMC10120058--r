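#' Classify a replicate by the origin of its surviving TSR alleles
#'
#' Among TSR origins present at the final recorded generation with
#' frequency at or above `threshold` (default one copy, `1/(2N)`): if at
#' least one originated during the burn-in the replicate is classified
#' `"sgv"` (runs mixing standing and de novo origins count as standing
#' variation); if all surviving origins arose during the selection phase it
#' is `"de_novo_only"`; with no surviving origin it is `"none"`.
#'
#' @param trajectory a TSR trajectory data.frame from
#'   [runSelectionPhase()] (columns generation, origin_id, frequency,
#'   origin_gen, origin_phase).
#' @param N diploid population size (for the default threshold).
#' @param threshold presence threshold on final frequency; default
#'   `1/(2N)`, i.e. at least one copy.
#' @param finalGeneration generation at which presence is assessed
#'   (default: the last generation in the table).
#' @return one-row data.frame: `classification`, `n_origins_final`,
#'   `n_origins_ever`, `aggregate_tsr_freq_final` (sum of surviving
#'   origin frequencies, capped at 1).
#' @export
classifyReplicate <- function(trajectory, N, threshold = NULL,
                              finalGeneration = NULL) {
  needed <- c("generation", "origin_id", "frequency", "origin_phase")
  if (!all(needed %in% names(trajectory)))
    stop("malformed trajectory: need columns ",
         paste(needed, collapse = ", "))
  if (is.null(threshold)) threshold <- 1 / (2 * N)
  if (is.null(finalGeneration))
    finalGeneration <- if (nrow(trajectory)) max(trajectory$generation)
                       else 0L
  fin <- trajectory[trajectory$generation == finalGeneration &
                    trajectory$frequency >= threshold, , drop = FALSE]
  cls <- if (nrow(fin) == 0L) "none"
         else if (any(fin$origin_phase == "burnin")) "sgv"
         else "de_novo_only"
  data.frame(
    classification = cls,
    n_origins_final = length(unique(fin$origin_id)),
    n_origins_ever = length(unique(trajectory$origin_id)),
    aggregate_tsr_freq_final = min(1, sum(fin$frequency)))
}

#' Aggregate replicate summaries
#'
#' @param summaries data.frame of per-replicate rows from
#'   [runReplicates()] / [classifyReplicate()].
#' @param trajectories optional list of per-replicate trajectory tables;
#'   when given, per-class mean aggregate-TSR-frequency trajectories are
#'   included.
#' @return list with `n_reps`, `proportion_sgv`, `proportion_de_novo_only`,
#'   `proportion_none` (summing to 1), `origin_histogram` (table of
#'   `n_origins_final`), `prop_multi_origin` (fraction of replicates with
#'   two or more surviving origins) and optionally `mean_trajectories`.
#' @export
aggregateReplicates <- function(summaries, trajectories = NULL) {
  if (nrow(summaries) == 0L) stop("no summaries to aggregate")
  if ("config_hash" %in% names(summaries) &&
      length(unique(summaries$config_hash)) > 1L)
    stop("summaries come from different configurations")
  n <- nrow(summaries)
  cls <- summaries$classification
  out <- list(
    n_reps = n,
    proportion_sgv = mean(cls == "sgv"),
    proportion_de_novo_only = mean(cls == "de_novo_only"),
    proportion_none = mean(cls == "none"),
    origin_histogram = table(factor(summaries$n_origins_final,
                                    levels = 0:max(summaries$n_origins_final))),
    prop_multi_origin = mean(summaries$n_origins_final >= 2L))
  if (!is.null(trajectories)) {
    byClass <- split(seq_len(n), cls)
    out$mean_trajectories <- lapply(byClass, function(idx) {
      agg <- lapply(trajectories[idx], function(tr) {
        if (!nrow(tr)) return(NULL)
        stats::aggregate(frequency ~ generation, tr, sum)
      })
      agg <- do.call(rbind, agg)
      if (is.null(agg) || !nrow(agg))
        return(data.frame(generation = integer(), mean_freq = numeric()))
      res <- stats::aggregate(frequency ~ generation, agg, mean)
      names(res) <- c("generation", "mean_freq")
      res
    })
  }
  out
}

#' Census of standing TSR alleles under neutrality
#'
#' Runs `nReps` independent burn-ins with herbicide selection off,
#' recording every `sampleEvery` generations how many distinct TSR origins
#' segregate simultaneously. Emulates the neutral drift census of TSR
#' alleles in field populations before the start of herbicide selection.
#'
#' @param config a [SimulationConfig-class] with `herbicideOn = FALSE`.
#' @param template a [LocusTemplate-class].
#' @param dfe a [DFEConfig-class].
#' @param nReps number of replicate burn-ins.
#' @param sampleEvery sampling interval in generations.
#' @param baseSeed integer base seed (replicate i uses `baseSeed + i`).
#' @return list with `census` (list of per-replicate data.frames),
#'   `max_per_replicate` (integer vector) and `max_overall`.
#' @export
neutralCensus <- function(config, template, dfe, nReps = 100L,
                          sampleEvery = 100L, baseSeed = 1L) {
  if (config@herbicideOn)
    stop("neutralCensus requires a configuration with herbicideOn = FALSE")
  nReps <- .assertCount(nReps, "nReps", 1L)
  sampleEvery <- .assertCount(sampleEvery, "sampleEvery", 1L)
  census <- vector("list", nReps)
  for (i in seq_len(nReps)) {
    set.seed(baseSeed + i)
    cfg <- config
    cfg@seed <- NA_integer_
    st <- runBurnin(cfg, template, dfe, censusEvery = sampleEvery)
    census[[i]] <- attr(st, "census")
  }
  mx <- vapply(census, function(cs)
    if (nrow(cs)) max(cs$n_tsr_origins) else 0L, integer(1))
  list(census = census, max_per_replicate = mx, max_overall = max(mx))
}
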